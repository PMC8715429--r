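# Synthetic annotated communities with multi-copy rRNA operons and the
# semi-targeted read simulator with chain-termination fragment lengths.
#
# Distinct operon copies sit at distinct chromosomal locations, so each copy
# slot carries its own ancestral upstream sequence (shared down the lineage,
# mutated at the per-rank upstream rates); the gene body descends from a
# single ancestral template whose inter-primer sites stay conserved so that
# primer matching finds every primer exactly.

.GENE_LAYOUT <- list(varLens = c(100L, 200L, rep(130L, 7L)),
                     primerLen = 20L, tailLen = 30L)

#' Specification of a synthetic community
#'
#' @param nGenera,speciesPerGenus,strainsPerSpecies community shape
#'   (defaults 4, 2, 2).
#' @param copiesPerGenome integer, or one integer per genome (default 4).
#' @param geneRates named per-rank substitution rates (per variable-window
#'   site) applied along genus -> species -> strain;
#'   default c(genus = 0.04, species = 0.01, strain = 0.003).
#' @param upstreamRates per-rank rates for the upstream locus; default 5x the
#'   gene rates, mirroring the lower conservation of near-16S sequence.
#' @param intragenomicSnpRate per-site, per-copy substitution rate (default
#'   0.002).
#' @param upstreamLen upstream locus length (default 1000).
#' @param sharedUpstream all copy slots share one ancestral upstream locus
#'   (default FALSE: one independent locus per copy slot).
#' @param abundance optional relative genome abundances (must sum to 1;
#'   default uniform).
#' @param seed RNG seed.
#' @return a validated spec list for \code{\link{generateCommunity}}.
#' @export
communitySpec <- function(nGenera = 4L, speciesPerGenus = 2L,
                          strainsPerSpecies = 2L, copiesPerGenome = 4L,
                          geneRates = c(genus = 0.04, species = 0.01,
                                        strain = 0.003),
                          upstreamRates = 5 * geneRates,
                          intragenomicSnpRate = 0.002,
                          upstreamLen = 1000L, sharedUpstream = FALSE,
                          abundance = NULL, seed = 1L) {
  nGenomes <- nGenera * speciesPerGenus * strainsPerSpecies
  copies <- rep_len(as.integer(copiesPerGenome), nGenomes)
  rates <- c(geneRates, upstreamRates, intragenomicSnpRate)
  if (any(rates < 0) || any(rates > 0.3))
    .stopf("substitution rates must lie in [0, 0.3]")
  if (is.null(abundance)) abundance <- rep(1 / nGenomes, nGenomes)
  if (abs(sum(abundance) - 1) > 1e-8)
    .stopf("abundances must sum to 1")
  list(nGenera = nGenera, speciesPerGenus = speciesPerGenus,
       strainsPerSpecies = strainsPerSpecies, copiesPerGenome = copies,
       geneRates = geneRates, upstreamRates = upstreamRates,
       intragenomicSnpRate = intragenomicSnpRate,
       upstreamLen = as.integer(upstreamLen),
       sharedUpstream = isTRUE(sharedUpstream),
       abundance = abundance, seed = as.integer(seed))
}

# positions of variable windows and of each primer site on the template gene
.geneLayout <- function(primerSet) {
  vl <- .GENE_LAYOUT$varLens
  pl <- .GENE_LAYOUT$primerLen
  stopifnot(nrow(primerSet) == length(vl),
            all(nchar(primerSet$sequence) == pl))
  pos <- 0L
  varSites <- integer(0)
  primerStart <- integer(length(vl))
  for (k in seq_along(vl)) {
    varSites <- c(varSites, (pos + 1L):(pos + vl[k]))
    pos <- pos + vl[k]
    primerStart[k] <- pos + 1L
    pos <- pos + pl
  }
  list(varSites = varSites, primerStart = primerStart,
       geneLen = pos + .GENE_LAYOUT$tailLen)
}

#' Generate a synthetic annotated community
#'
#' Builds an ancestral 16S template with nine variable windows separated by
#' the conserved primer sites of \code{primerSet}, mutates it down the
#' genus -> species -> strain hierarchy at the spec's per-rank rates
#' (upstream loci at their own rates), adds per-copy intragenomic SNPs,
#' and places the operon copies on random strands at non-overlapping
#' positions with 2 kb flanks on a single contig per genome.
#'
#' @param spec a \code{\link{communitySpec}}.
#' @param primerSet primer table (default \code{\link{defaultPrimerSet}}).
#' @return a \linkS4class{SimCommunity}.
#' @export
generateCommunity <- function(spec, primerSet = defaultPrimerSet()) {
  set.seed(spec$seed)
  lay <- .geneLayout(primerSet)
  U <- spec$upstreamLen
  # ancestral template: random variable windows, fixed primer sites
  gene <- character(lay$geneLen)
  gene[lay$varSites] <- sample(c("A", "C", "G", "T"),
                               length(lay$varSites), replace = TRUE)
  for (k in seq_len(nrow(primerSet))) {
    idx <- lay$primerStart[k]:(lay$primerStart[k] + .GENE_LAYOUT$primerLen - 1L)
    gene[idx] <- strsplit(primerSet$sequence[k], "")[[1L]]
  }
  tailIdx <- (lay$geneLen - .GENE_LAYOUT$tailLen + 1L):lay$geneLen
  gene[tailIdx] <- sample(c("A", "C", "G", "T"), .GENE_LAYOUT$tailLen,
                          replace = TRUE)
  ancGene <- paste(gene, collapse = "")
  maxCopies <- max(spec$copiesPerGenome)
  ancUp <- if (spec$sharedUpstream)
    rep(list(.randSeq(U)), maxCopies)
  else replicate(maxCopies, .randSeq(U), simplify = FALSE)

  genomes <- list()
  opRows <- list()
  gIdx <- 0L
  for (gi in seq_len(spec$nGenera)) {
    genusGene <- .mutateSeq(ancGene, spec$geneRates["genus"], lay$varSites)
    genusUp <- lapply(ancUp, .mutateSeq, rate = spec$upstreamRates["genus"])
    for (si in seq_len(spec$speciesPerGenus)) {
      spGene <- .mutateSeq(genusGene, spec$geneRates["species"], lay$varSites)
      spUp <- lapply(genusUp, .mutateSeq, rate = spec$upstreamRates["species"])
      for (ti in seq_len(spec$strainsPerSpecies)) {
        gIdx <- gIdx + 1L
        stGene <- .mutateSeq(spGene, spec$geneRates["strain"], lay$varSites)
        stUp <- lapply(spUp, .mutateSeq, rate = spec$upstreamRates["strain"])
        nCopies <- spec$copiesPerGenome[gIdx]
        genus <- sprintf("G%02d", gi)
        species <- sprintf("G%02d_S%d", gi, si)
        strain <- sprintf("G%02d_S%d_T%d", gi, si, ti)
        asm <- strain
        # per-copy sequences
        copyGene <- character(nCopies); copyUp <- character(nCopies)
        for (cc in seq_len(nCopies)) {
          copyGene[cc] <- .mutateSeq(stGene, spec$intragenomicSnpRate,
                                     lay$varSites)
          copyUp[cc] <- .mutateSeq(stUp[[cc]], spec$intragenomicSnpRate)
        }
        # assemble the contig: 2 kb flanks between operons, random strands
        pieces <- character(0)
        starts <- integer(nCopies); ends <- integer(nCopies)
        strands <- character(nCopies)
        pos <- 0L
        for (cc in seq_len(nCopies)) {
          flank <- .randSeq(2000L)
          pieces <- c(pieces, flank)
          pos <- pos + 2000L
          strand <- sample(c("+", "-"), 1L)
          seg <- paste0(copyUp[cc], copyGene[cc])
          if (strand == "+") {
            starts[cc] <- pos + U + 1L
            ends[cc] <- pos + U + nchar(copyGene[cc])
            pieces <- c(pieces, seg)
          } else {
            starts[cc] <- pos + 1L
            ends[cc] <- pos + nchar(copyGene[cc])
            pieces <- c(pieces, .revcomp(seg))
          }
          strands[cc] <- strand
          pos <- pos + nchar(seg)
        }
        pieces <- c(pieces, .randSeq(2000L))
        contig <- paste(pieces, collapse = "")
        feats <- GenomicRanges::GRanges(
          seqnames = "chr1",
          ranges = IRanges::IRanges(starts, ends),
          strand = strands,
          type = "rRNA", product = "16S ribosomal RNA")
        genomes[[asm]] <- new(
          "GenomeRecord", assemblyId = asm,
          contigs = Biostrings::DNAStringSet(c(chr1 = contig)),
          features = feats,
          lineage = c(genus = genus, species = species, strain = strain))
        opRows[[asm]] <- S4Vectors::DataFrame(
          assembly_id = asm,
          locus_id = sprintf("%s|chr1:%d-%d(%s)", asm, starts, ends, strands),
          copy = seq_len(nCopies),
          gene_seq = copyGene, upstream_seq = copyUp,
          genus = genus, species = species, strain = strain)
      }
    }
  }
  new("SimCommunity", genomes = genomes,
      operons = do.call(rbind, unname(opRows)),
      abundance = stats::setNames(spec$abundance, names(genomes)),
      spec = spec)
}

#' Write a community as FASTA + GFF3 + lineage TSV
#'
#' @param sim a \linkS4class{SimCommunity}.
#' @param dir output directory (created if missing).
#' @return invisibly, a data.frame with the per-genome file paths.
#' @export
writeCommunity <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(sim@genomes, function(g) {
    fa <- file.path(dir, paste0(g@assemblyId, ".fasta"))
    gff <- file.path(dir, paste0(g@assemblyId, ".gff3"))
    Biostrings::writeXStringSet(g@contigs, fa)
    rtracklayer::export(g@features, gff, format = "gff3")
    data.frame(assembly_id = g@assemblyId, fasta = fa, gff = gff,
               genus = g@lineage[["genus"]],
               species = g@lineage[["species"]],
               strain = g@lineage[["strain"]], stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, unname(rows))
  utils::write.table(
    manifest[c("assembly_id", "genus", "species", "strain")],
    file.path(dir, "lineage.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(manifest)
}

# position of the extension-priming site (start of the V2-terminating primer)
.primingSite <- function(primerSet) {
  .geneLayout(primerSet)$primerStart[2L]
}

#' The semi-targeted extension primer implied by a primer set
#'
#' The extension primer anneals at the conserved site between the V2 and V3
#' regions, oriented toward the upstream sequence: it is the reverse
#' complement of the V2-terminating primer site.
#'
#' @param primerSet primer table (default \code{\link{defaultPrimerSet}}).
#' @return primer sequence as it appears at the start of R1.
#' @export
extensionPrimer <- function(primerSet = defaultPrimerSet()) {
  .revcomp(primerSet$sequence[primerSet$name == "V2"])
}

#' Simulate semi-targeted paired-end reads
#'
#' Per sampled operon (probability proportional to genome abundance, each
#' copy weighted equally, so a genome's read share is proportional to
#' abundance x copy number), a single primer extends from the conserved
#' priming site toward the upstream locus, terminating after each
#' incorporated base with probability \code{terminationProb} (extension
#' length is geometric with mean about 1/p, truncated at the template end).
#' R1 reads the nascent strand from the primer (through V2 and V1 into the
#' upstream locus); R2 reads back from the termination point. Fragments
#' shorter than the read length yield correspondingly shorter reads
#' (adapter read-through trimmed). Substitution errors are uniform at
#' \code{errorRate}; qualities are constant Q30.
#'
#' @param sim a \linkS4class{SimCommunity}.
#' @param nPairs number of read pairs.
#' @param terminationProb per-base chain-termination probability p.
#' @param readLen read length (default 300).
#' @param errorRate per-base substitution error rate (default 0.001).
#' @param seed RNG seed.
#' @param primerSet primer table (default \code{\link{defaultPrimerSet}}).
#' @return list with \code{pairs} (id, r1, r2, q1, q2) and
#'   \code{provenance} (id, assembly_id, locus_id, fragmentLen).
#' @export
simulateSt16sReads <- function(sim, nPairs, terminationProb = 1/350,
                               readLen = 300L, errorRate = 0.001,
                               seed = 1L, primerSet = defaultPrimerSet()) {
  stopifnot(terminationProb > 0, terminationProb < 1)
  set.seed(seed)
  ops <- sim@operons
  p2s <- .primingSite(primerSet)
  pl <- .GENE_LAYOUT$primerLen
  primerRead <- extensionPrimer(primerSet)
  full <- paste0(ops$upstream_seq, ops$gene_seq)
  Fu <- nchar(ops$upstream_seq) + p2s - 1L
  w <- sim@abundance[ops$assembly_id]
  opIdx <- sample.int(nrow(ops), nPairs, replace = TRUE, prob = w)
  N <- pmin(stats::rgeom(nPairs, terminationProb) + 1L, Fu[opIdx])
  addErr <- function(s) {
    if (errorRate <= 0) return(s)
    vapply(s, function(x) .mutateSeq(x, errorRate), "", USE.NAMES = FALSE)
  }
  r1 <- character(nPairs); r2 <- character(nPairs)
  for (i in seq_len(nPairs)) {
    o <- opIdx[i]
    ext <- .revcomp(substr(full[o], Fu[o] - N[i] + 1L, Fu[o]))
    r1[i] <- substr(paste0(primerRead, ext), 1L, readLen)
    r2len <- min(readLen, N[i] + pl)
    fstart <- Fu[o] - N[i] + 1L
    r2[i] <- substr(full[o], fstart, fstart + r2len - 1L)
  }
  r1 <- addErr(r1); r2 <- addErr(r2)
  ids <- sprintf("read%06d", seq_len(nPairs))
  q <- function(s) strrep("?", nchar(s))  # constant Q30
  list(pairs = data.frame(id = ids, r1 = r1, r2 = r2,
                          q1 = q(r1), q2 = q(r2), stringsAsFactors = FALSE),
       provenance = data.frame(id = ids,
                               assembly_id = ops$assembly_id[opIdx],
                               locus_id = ops$locus_id[opIdx],
                               fragmentLen = N + pl,
                               stringsAsFactors = FALSE))
}

#' Truth-derived near-16S contigs
#'
#' One contig per operon in read (extension) orientation: the V1-V2 portion
#' of the gene followed by an upstream stretch whose extent varies by copy
#' index, emulating the variable assembly reach of real genome-linked
#' contigs.
#'
#' @param sim a \linkS4class{SimCommunity}.
#' @param upstreamExtentBase,upstreamExtentStep upstream reach of copy c is
#'   base + step * c, capped at the upstream locus length (defaults 450 and
#'   50).
#' @param primerSet primer table (default \code{\link{defaultPrimerSet}}).
#' @return data.frame with columns id, seq, abundance, assembly_id, copy.
#' @export
truthContigs <- function(sim, upstreamExtentBase = 450L,
                         upstreamExtentStep = 50L,
                         primerSet = defaultPrimerSet()) {
  ops <- sim@operons
  p2s <- .primingSite(primerSet)
  full <- paste0(ops$upstream_seq, ops$gene_seq)
  Fu <- nchar(ops$upstream_seq) + p2s - 1L
  extent <- pmin(upstreamExtentBase + upstreamExtentStep * ops$copy,
                 nchar(ops$upstream_seq))
  from <- Fu - (p2s - 1L) - extent + 1L
  seqs <- vapply(seq_len(nrow(ops)), function(i)
    .revcomp(substr(full[i], from[i], Fu[i])), "")
  data.frame(id = ops$locus_id, seq = seqs, abundance = 1,
             assembly_id = ops$assembly_id, copy = ops$copy,
             stringsAsFactors = FALSE)
}

#' Reference catalog in contig orientation
#'
#' One labelled reference per operon, covering the extension-reachable
#' near-16S region (priming site through the full upstream locus, reverse
#' complemented into contig orientation). Stands in for a general sequence
#' database during global contig cleanup.
#'
#' @param sim a \linkS4class{SimCommunity}.
#' @param groupBy lineage rank used as the catalog label (default
#'   \code{"genus"}).
#' @param primerSet primer table (default \code{\link{defaultPrimerSet}}).
#' @return data.frame with columns name, genus, seq.
#' @export
referenceCatalog <- function(sim, groupBy = c("genus", "species",
                                              "assembly_id"),
                             primerSet = defaultPrimerSet()) {
  groupBy <- match.arg(groupBy)
  ops <- sim@operons
  p2s <- .primingSite(primerSet)
  pl <- .GENE_LAYOUT$primerLen
  full <- paste0(ops$upstream_seq, ops$gene_seq)
  hi <- nchar(ops$upstream_seq) + p2s - 1L + pl
  data.frame(name = ops$locus_id,
             genus = as.character(ops[[groupBy]]),
             seq = .revcomp(substr(full, 1L, hi)),
             stringsAsFactors = FALSE)
}

#' Simulate a mock community DNA standard
#'
#' An even 8- or 20-member community: one genus, species and strain per
#' genome, even abundances, per-genome 16S copy numbers drawn uniformly from
#' \code{copiesRange}. Optionally the first genome's copy number is fixed
#' (e.g. 6, the classic six-operon Listeria-like layout) for copy-number
#' recovery tests.
#'
#' @param preset \code{"even8"} or \code{"even20"}.
#' @param seed RNG seed.
#' @param copiesRange candidate copy numbers (default 1:10).
#' @param firstGenomeCopies fixed copy number for genome 1 (default NULL).
#' @param ... further arguments to \code{\link{communitySpec}} overriding
#'   the defaults.
#' @return a \linkS4class{SimCommunity}.
#' @export
simulateMockStandard <- function(preset = c("even8", "even20"), seed = 1L,
                                 copiesRange = 1:10,
                                 firstGenomeCopies = NULL, ...) {
  preset <- match.arg(preset)
  n <- if (preset == "even8") 8L else 20L
  set.seed(seed)
  copies <- sample(copiesRange, n, replace = TRUE)
  if (!is.null(firstGenomeCopies)) copies[1L] <- as.integer(firstGenomeCopies)
  spec <- communitySpec(nGenera = n, speciesPerGenus = 1L,
                        strainsPerSpecies = 1L, copiesPerGenome = copies,
                        seed = seed, ...)
  generateCommunity(spec)
}
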