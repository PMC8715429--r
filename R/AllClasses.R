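#' @import methods
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' GenomeRecord: an annotated assembly with rRNA features and lineage
#'
#' Container for one bacterial genome assembly: its contig sequences, the 16S
#' rRNA gene features retained from the annotation, and the taxonomic lineage
#' joined from a lineage table.
#'
#' @slot assemblyId single assembly identifier.
#' @slot contigs a \linkS4class{DNAStringSet} of contig sequences.
#' @slot features a \linkS4class{GRanges} of 16S rRNA gene features
#'   (metadata column \code{product}).
#' @slot lineage named character with elements \code{genus}, \code{species},
#'   \code{strain} (may be \code{NA} before taxonomy filtering).
#'
#' @exportClass GenomeRecord
setClass("GenomeRecord",
  representation(assemblyId = "character",
                 contigs = "DNAStringSet",
                 features = "GRanges",
                 lineage = "character"))

setValidity("GenomeRecord", function(object) {
  msgs <- character()
  if (length(object@assemblyId) != 1L)
    msgs <- c(msgs, "assemblyId must be length 1")
  feats <- object@features
  if (length(feats)) {
    sn <- as.character(GenomicRanges::seqnames(feats))
    if (!all(sn %in% names(object@contigs))) {
      msgs <- c(msgs, "feature seqnames not all found among contig names")
    } else {
      w <- Biostrings::width(object@contigs)[match(sn, names(object@contigs))]
      if (any(GenomicRanges::start(feats) < 1L) ||
          any(GenomicRanges::end(feats) > w))
        msgs <- c(msgs, "feature coordinates outside contig bounds")
    }
    if (!all(as.character(GenomicRanges::strand(feats)) %in% c("+", "-")))
      msgs <- c(msgs, "feature strand must be '+' or '-'")
  }
  need <- c("genus", "species", "strain")
  if (!all(need %in% names(object@lineage)))
    msgs <- c(msgs, "lineage must carry genus, species and strain")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn GenomeRecord show method
#' @param object a GenomeRecord
#' @export
setMethod("show", "GenomeRecord", function(object) {
  cat("GenomeRecord", object@assemblyId, "\n",
      " ", length(object@contigs), "contig(s),",
      length(object@features), "16S rRNA feature(s)\n",
      "  lineage:", paste(object@lineage[c("genus", "species", "strain")],
                          collapse = " / "), "\n")
})

#' LinkedLocusSet: 16S gene copies joined to their upstream regions
#'
#' A set of "linked loci": one 16S rRNA gene copy each, oriented 5'->3',
#' together with up to \code{upstreamLen} bases immediately 5' of the gene
#' start (in gene orientation). Minus-strand genes and their upstream windows
#' are reverse-complemented at extraction time so that
#' \code{upstreamSeq + geneSeq} reads contiguously along the chromosome.
#'
#' @slot locusId unique locus identifiers.
#' @slot assemblyId assembly of origin, one per locus.
#' @slot geneSeq \linkS4class{DNAStringSet} of gene sequences.
#' @slot upstreamSeq \linkS4class{DNAStringSet} of upstream sequences.
#' @slot upstreamTruncated logical; TRUE when the contig edge yielded fewer
#'   than the requested number of upstream bases.
#' @slot lineage DataFrame with columns genus, species, strain (one row per
#'   locus).
#' @slot metadata list of extraction bookkeeping (discard counters etc.).
#'
#' @exportClass LinkedLocusSet
setClass("LinkedLocusSet",
  representation(locusId = "character",
                 assemblyId = "character",
                 geneSeq = "DNAStringSet",
                 upstreamSeq = "DNAStringSet",
                 upstreamTruncated = "logical",
                 lineage = "DataFrame",
                 metadata = "list"))

setValidity("LinkedLocusSet", function(object) {
  n <- length(object@locusId)
  lens <- c(length(object@assemblyId), length(object@geneSeq),
            length(object@upstreamSeq), length(object@upstreamTruncated),
            nrow(object@lineage))
  if (!all(lens == n)) return("slot lengths differ")
  if (anyDuplicated(object@locusId)) return("locusId values must be unique")
  TRUE
})

#' @describeIn LinkedLocusSet number of loci
#' @param x a LinkedLocusSet
#' @export
setMethod("length", "LinkedLocusSet", function(x) length(x@locusId))

#' @describeIn LinkedLocusSet subset loci
#' @param i index
#' @param j,drop,... ignored
#' @export
setMethod("[", "LinkedLocusSet", function(x, i, j, ..., drop = TRUE) {
  new("LinkedLocusSet",
      locusId = x@locusId[i], assemblyId = x@assemblyId[i],
      geneSeq = x@geneSeq[i], upstreamSeq = x@upstreamSeq[i],
      upstreamTruncated = x@upstreamTruncated[i],
      lineage = x@lineage[i, , drop = FALSE], metadata = x@metadata)
})

#' @describeIn LinkedLocusSet show method
#' @param object a LinkedLocusSet
#' @export
setMethod("show", "LinkedLocusSet", function(object) {
  cat("LinkedLocusSet with", length(object), "loci from",
      length(unique(object@assemblyId)), "assemblies\n")
  if (length(object)) {
    cat("  gene lengths:",
        paste(range(Biostrings::width(object@geneSeq)), collapse = "-"),
        "bp; upstream lengths:",
        paste(range(Biostrings::width(object@upstreamSeq)), collapse = "-"),
        "bp\n")
  }
})

#' ClusterLinkage: nested read clusterings supporting the a_f abundance
#'
#' Links the deduplicated merged-read clusters (b-clusters) with the
#' forward-prefix clusters (a-clusters) of the same read universe. The per-OTU
#' abundance a_f averages, over the j b-clusters, the fraction of each
#' b-cluster's reads falling inside the a-cluster.
#'
#' @slot bClusters list of character vectors of read names.
#' @slot aClusters named list of character vectors of read names.
#' @slot totalPairs number of filtered read pairs (abundance-flag universe).
#' @slot minClusterFrac a-clusters holding fewer than this fraction of
#'   \code{totalPairs} are flagged not-for-assembly.
#'
#' @exportClass ClusterLinkage
setClass("ClusterLinkage",
  representation(bClusters = "list",
                 aClusters = "list",
                 totalPairs = "integer",
                 minClusterFrac = "numeric"))

setValidity("ClusterLinkage", function(object) {
  if (length(object@bClusters) < 1L) return("need at least one b-cluster")
  if (any(lengths(object@bClusters) == 0L)) return("empty b-cluster")
  TRUE
})

#' @describeIn ClusterLinkage number of b-clusters (j)
#' @param x a ClusterLinkage
#' @export
setMethod("length", "ClusterLinkage", function(x) length(x@bClusters))

#' @describeIn ClusterLinkage show method
#' @param object a ClusterLinkage
#' @export
setMethod("show", "ClusterLinkage", function(object) {
  cat("ClusterLinkage:", length(object@bClusters), "b-cluster(s),",
      length(object@aClusters), "a-cluster(s),",
      object@totalPairs, "read pairs\n")
})

#' SimCommunity: a synthetic community with ground truth
#'
#' The output of \code{\link{generateCommunity}}: simulated annotated genomes
#' plus the truth tables that downstream recovery tests compare against.
#'
#' @slot genomes list of \linkS4class{GenomeRecord}.
#' @slot operons DataFrame with one row per rRNA operon copy: assembly_id,
#'   locus_id, copy index, gene and upstream sequence (gene orientation).
#' @slot abundance named numeric, true relative genome abundances (sums to 1).
#' @slot spec the \code{\link{communitySpec}} list used for generation.
#'
#' @exportClass SimCommunity
setClass("SimCommunity",
  representation(genomes = "list",
                 operons = "DataFrame",
                 abundance = "numeric",
                 spec = "list"))

#' @describeIn SimCommunity show method
#' @param object a SimCommunity
#' @export
setMethod("show", "SimCommunity", function(object) {
  cat("SimCommunity:", length(object@genomes), "genome(s),",
      nrow(object@operons), "rRNA operon(s)\n")
})

#' Accessors for the core classes
#'
#' @param x object
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneSeq", function(x) standardGeneric("geneSeq"))
#' @rdname accessors
#' @export
setMethod("geneSeq", "LinkedLocusSet", function(x) x@geneSeq)

#' @rdname accessors
#' @export
setGeneric("upstreamSeq", function(x) standardGeneric("upstreamSeq"))
#' @rdname accessors
#' @export
setMethod("upstreamSeq", "LinkedLocusSet", function(x) x@upstreamSeq)

#' @rdname accessors
#' @export
setGeneric("locusId", function(x) standardGeneric("locusId"))
#' @rdname accessors
#' @export
setMethod("locusId", "LinkedLocusSet", function(x) x@locusId)

#' @rdname accessors
#' @export
setGeneric("assemblyId", function(x) standardGeneric("assemblyId"))
#' @rdname accessors
#' @export
setMethod("assemblyId", "LinkedLocusSet", function(x) x@assemblyId)
#' @rdname accessors
#' @export
setMethod("assemblyId", "GenomeRecord", function(x) x@assemblyId)

#' @rdname accessors
#' @export
setGeneric("lineage", function(x) standardGeneric("lineage"))
#' @rdname accessors
#' @export
setMethod("lineage", "LinkedLocusSet", function(x) x@lineage)
#' @rdname accessors
#' @export
setMethod("lineage", "GenomeRecord", function(x) x@lineage)

#' @rdname accessors
#' @export
setGeneric("truthOperons", function(x) standardGeneric("truthOperons"))
#' @rdname accessors
#' @export
setMethod("truthOperons", "SimCommunity", function(x) x@operons)

#' @rdname accessors
#' @export
setGeneric("trueAbundance", function(x) standardGeneric("trueAbundance"))
#' @rdname accessors
#' @export
setMethod("trueAbundance", "SimCommunity", function(x) x@abundance)

#' @rdname accessors
#' @export
setGeneric("communityGenomes", function(x) standardGeneric("communityGenomes"))
#' @rdname accessors
#' @export
setMethod("communityGenomes", "SimCommunity", function(x) x@genomes)

#' @rdname accessors
#' @export
setGeneric("bClusters", function(x) standardGeneric("bClusters"))
#' @rdname accessors
#' @export
setMethod("bClusters", "ClusterLinkage", function(x) x@bClusters)

#' @rdname accessors
#' @export
setGeneric("aClusters", function(x) standardGeneric("aClusters"))
#' @rdname accessors
#' @export
setMethod("aClusters", "ClusterLinkage", function(x) x@aClusters)
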