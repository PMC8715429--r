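# Reading annotated genomes, extracting 16S genes with upstream regions, and
# the dataset-construction filters.

.PRODUCT_PATTERN <- "^16S ribosomal RNA"

#' Read a lineage table
#'
#' @param path TSV with header \code{assembly_id, genus, species, strain}.
#' @return data.frame with those columns; empty strings become \code{NA}.
#' @export
readLineageTable <- function(path) {
  if (!file.exists(path)) .stopf("lineage table not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("assembly_id", "genus", "species", "strain")
  if (!all(need %in% names(df)))
    .stopf("lineage table must have columns %s", paste(need, collapse = ", "))
  for (col in need) df[[col]][!nzchar(df[[col]])] <- NA_character_
  df[need]
}

.readFeatureTable <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 5L)
  if (length(bad))
    .stopf("malformed feature table line %d in %s", bad[1L], path,
           class = "near16S_parse_error")
  df <- data.frame(
    contig = vapply(parts, `[[`, "", 1L),
    start = suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L))),
    end = suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L))),
    strand = vapply(parts, `[[`, "", 4L),
    product = vapply(parts, `[[`, "", 5L),
    stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end) | df$start > df$end)
  if (length(bad))
    .stopf("malformed coordinates on line %d of %s", bad[1L], path,
           class = "near16S_parse_error")
  df
}

#' Parse an annotated genome and retain its 16S rRNA features
#'
#' Reads a (multi-)FASTA assembly and its annotation (GFF3, or a tab-separated
#' GenBank-derived feature table with columns contig, start, end, strand,
#' product; 1-based closed coordinates) and keeps every feature whose product
#' string matches the prefix pattern \code{"16S ribosomal RNA.*"}.
#'
#' @param fastaPath path to the assembly FASTA.
#' @param annotationPath path to the annotation (\code{.gff}/\code{.gff3} for
#'   GFF3, anything else is read as a feature table).
#' @param lineageRow one row of a lineage table (list or single-row
#'   data.frame with genus, species, strain), or \code{NULL}.
#' @return a \linkS4class{GenomeRecord}.
#' @export
parseGenome <- function(fastaPath, annotationPath, lineageRow = NULL) {
  for (p in c(fastaPath, annotationPath)) {
    if (!file.exists(p) || file.size(p) == 0L)
      .stopf("missing or empty assembly file: %s", p,
             class = "near16S_missing_assembly")
  }
  contigs <- Biostrings::readDNAStringSet(fastaPath)
  names(contigs) <- sub("\\s.*$", "", names(contigs))

  if (grepl("\\.gff3?$", annotationPath, ignore.case = TRUE)) {
    gr <- tryCatch(rtracklayer::import(annotationPath, format = "gff3"),
                   error = function(e)
                     .stopf("GFF3 parse error in %s: %s", annotationPath,
                            conditionMessage(e), class = "near16S_parse_error"))
    prod <- as.character(gr$product)
    if (all(is.na(prod)) && !is.null(gr$Name)) prod <- as.character(gr$Name)
    prod[is.na(prod)] <- ""
    keep <- grepl(.PRODUCT_PATTERN, prod)
    feats <- GenomicRanges::GRanges(
      seqnames = as.character(GenomicRanges::seqnames(gr))[keep],
      ranges = IRanges::IRanges(GenomicRanges::start(gr)[keep],
                                GenomicRanges::end(gr)[keep]),
      strand = as.character(GenomicRanges::strand(gr))[keep],
      product = prod[keep])
  } else {
    tab <- .readFeatureTable(annotationPath)
    keep <- grepl(.PRODUCT_PATTERN, tab$product)
    tab <- tab[keep, , drop = FALSE]
    feats <- GenomicRanges::GRanges(
      seqnames = tab$contig,
      ranges = IRanges::IRanges(tab$start, tab$end),
      strand = tab$strand, product = tab$product)
  }
  lin <- c(genus = NA_character_, species = NA_character_,
           strain = NA_character_)
  if (!is.null(lineageRow)) {
    lineageRow <- as.list(lineageRow)
    for (k in names(lin)) if (!is.null(lineageRow[[k]]))
      lin[k] <- as.character(lineageRow[[k]])
  }
  aid <- if (!is.null(lineageRow) && !is.null(lineageRow$assembly_id))
    as.character(lineageRow$assembly_id)
  else sub("\\.[^.]*$", "", basename(fastaPath))
  new("GenomeRecord", assemblyId = aid, contigs = contigs,
      features = feats, lineage = lin)
}

#' Extract 16S gene copies linked to their upstream regions
#'
#' Each retained 16S feature yields the gene sequence in 5'->3' orientation
#' plus up to \code{upstreamLen} bases immediately 5' of the gene start in
#' gene orientation: for minus-strand genes both windows are taken from the
#' genomically 3' side and reverse-complemented. Genes with length outside
#' \code{[minGeneLen, maxGeneLen]} are dropped and counted; upstream windows
#' cut short by a contig edge are retained but flagged truncated.
#'
#' @param genome a \linkS4class{GenomeRecord}.
#' @param upstreamLen upstream window size in bases (default 1000).
#' @param minGeneLen,maxGeneLen retained gene length bounds (default
#'   1000 and 2000).
#' @return a \linkS4class{LinkedLocusSet}; discard counts are in its
#'   \code{metadata}.
#' @export
extractLinkedLoci <- function(genome, upstreamLen = 1000L,
                              minGeneLen = 1000L, maxGeneLen = 2000L) {
  stopifnot(upstreamLen > 0L)
  feats <- genome@features
  ids <- character(0); genes <- character(0); ups <- character(0)
  trunc <- logical(0)
  nLenDiscard <- 0L
  if (length(feats)) {
    sn <- as.character(GenomicRanges::seqnames(feats))
    st <- GenomicRanges::start(feats)
    en <- GenomicRanges::end(feats)
    strd <- as.character(GenomicRanges::strand(feats))
    for (i in seq_along(feats)) {
      glen <- en[i] - st[i] + 1L
      if (glen < minGeneLen || glen > maxGeneLen) {
        nLenDiscard <- nLenDiscard + 1L
        next
      }
      contig <- as.character(genome@contigs[[sn[i]]])
      clen <- nchar(contig)
      gene <- substr(contig, st[i], en[i])
      if (strd[i] == "+") {
        from <- max(1L, st[i] - upstreamLen)
        up <- if (st[i] > 1L) substr(contig, from, st[i] - 1L) else ""
        isTrunc <- (st[i] - upstreamLen) < 1L
      } else {
        gene <- .revcomp(gene)
        to <- min(clen, en[i] + upstreamLen)
        up <- if (en[i] < clen) .revcomp(substr(contig, en[i] + 1L, to)) else ""
        isTrunc <- (en[i] + upstreamLen) > clen
      }
      ids <- c(ids, sprintf("%s|%s:%d-%d(%s)", genome@assemblyId, sn[i],
                            st[i], en[i], strd[i]))
      genes <- c(genes, gene)
      ups <- c(ups, up)
      trunc <- c(trunc, isTrunc)
    }
  }
  n <- length(ids)
  lin <- S4Vectors::DataFrame(
    genus = rep(genome@lineage[["genus"]], n),
    species = rep(genome@lineage[["species"]], n),
    strain = rep(genome@lineage[["strain"]], n))
  new("LinkedLocusSet",
      locusId = ids, assemblyId = rep(genome@assemblyId, n),
      geneSeq = Biostrings::DNAStringSet(
        if (n) genes else character(0)),
      upstreamSeq = Biostrings::DNAStringSet(
        if (n) ups else character(0)),
      upstreamTruncated = trunc, lineage = lin,
      metadata = list(nDiscardedLength = nLenDiscard,
                      nFeatures = length(feats)))
}

#' Combine LinkedLocusSet objects
#'
#' @param ... LinkedLocusSet objects.
#' @return one LinkedLocusSet; metadata discard counters are summed.
#' @export
combineLoci <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) &&
      !is(sets[[1L]], "LinkedLocusSet")) sets <- sets[[1L]]
  new("LinkedLocusSet",
      locusId = unlist(lapply(sets, function(s) s@locusId)),
      assemblyId = unlist(lapply(sets, function(s) s@assemblyId)),
      geneSeq = do.call(c, lapply(sets, function(s) s@geneSeq)),
      upstreamSeq = do.call(c, lapply(sets, function(s) s@upstreamSeq)),
      upstreamTruncated = unlist(lapply(sets, function(s) s@upstreamTruncated)),
      lineage = do.call(rbind, lapply(sets, function(s) s@lineage)),
      metadata = list(nDiscardedLength = sum(vapply(
        sets, function(s) s@metadata$nDiscardedLength %||% 0L, numeric(1)))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply the dataset-construction filters
#'
#' Applies, in order: (1) whole-genome removal when a genome's lineage lacks
#' genus or species; (2) whole-genome removal when at least one locus of the
#' genome failed primer QC (the \code{regionQcFail} flags); (3) per-locus
#' removal of sequences whose gene or upstream window contains any non-ACGT
#' (wildcard) letter. An audit log records per-step counts.
#'
#' @param loci a \linkS4class{LinkedLocusSet}.
#' @param regionQcFail optional logical vector (one per locus): TRUE when the
#'   locus was rejected by \code{\link{qcAndSplit}}.
#' @param dropTruncated also drop loci with truncated upstream windows
#'   (default FALSE; truncation is flagged, not fatal).
#' @return list with \code{loci} (retained \linkS4class{LinkedLocusSet}) and
#'   \code{audit} (data.frame of per-step counts).
#' @export
filterDataset <- function(loci, regionQcFail = NULL, dropTruncated = FALSE) {
  audit <- data.frame(step = character(0), lociRemoved = integer(0),
                      genomesRemoved = integer(0), lociRemaining = integer(0),
                      stringsAsFactors = FALSE)
  note <- function(step, removedLoci, removedGenomes, remaining) {
    rbind(audit, data.frame(step = step, lociRemoved = removedLoci,
                            genomesRemoved = removedGenomes,
                            lociRemaining = remaining,
                            stringsAsFactors = FALSE))
  }
  if (length(loci) == 0L) {
    audit <- note("input", 0L, 0L, 0L)
    return(list(loci = loci, audit = audit))
  }
  keep <- rep(TRUE, length(loci))

  # (1) taxonomy: genomes without genus or species
  lin <- loci@lineage
  badGenome <- is.na(lin$genus) | is.na(lin$species) |
    !nzchar(as.character(lin$genus)) | !nzchar(as.character(lin$species))
  badAsm <- unique(loci@assemblyId[badGenome])
  drop1 <- loci@assemblyId %in% badAsm
  keep <- keep & !drop1
  audit <- note("taxonomy", sum(drop1), length(badAsm), sum(keep))

  # (2) primer QC: whole genome removed if any of its loci failed
  if (!is.null(regionQcFail)) {
    stopifnot(length(regionQcFail) == length(loci))
    badAsm2 <- unique(loci@assemblyId[regionQcFail & keep])
    drop2 <- keep & loci@assemblyId %in% badAsm2
    keep <- keep & !drop2
    audit <- note("primer_qc", sum(drop2), length(badAsm2), sum(keep))
  }

  # (3) wildcard letters in gene or upstream
  wild <- grepl("[^ACGT]", as.character(loci@geneSeq)) |
    grepl("[^ACGT]", as.character(loci@upstreamSeq))
  drop3 <- keep & wild
  keep <- keep & !drop3
  audit <- note("wildcards", sum(drop3), 0L, sum(keep))

  if (dropTruncated) {
    drop4 <- keep & loci@upstreamTruncated
    keep <- keep & !drop4
    audit <- note("truncated_upstream", sum(drop4), 0L, sum(keep))
  }
  list(loci = loci[keep], audit = audit)
}

#' Write an audit log as JSON lines
#'
#' @param audit data.frame from \code{\link{filterDataset}}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeAuditLog <- function(audit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(audit))) {
    writeLines(jsonlite::toJSON(as.list(audit[i, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}
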