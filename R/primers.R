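# Locating inter-region primers on 16S genes, QC of their order, and
# splitting genes into hypervariable sub-regions V1-V9.

#' Read a primer set
#'
#' @param path TSV with header \code{name, sequence} (5'->3', IUPAC codes
#'   allowed), ordered to match the expected 5'->3' layout on the gene.
#' @return data.frame with columns name and sequence.
#' @export
readPrimerSet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("name", "sequence") %in% names(df)))
    .stopf("primer TSV must have columns name, sequence")
  if (anyDuplicated(df$name)) .stopf("primer names must be unique")
  df$sequence <- toupper(df$sequence)
  df[c("name", "sequence")]
}

#' Bundled synthetic V1-V9 primer set
#'
#' The fixed primer set used by the synthetic community generator: nine
#' 20-mers, each named after the hypervariable region located upstream of its
#' hybridization site.
#'
#' @return data.frame with columns name and sequence.
#' @export
defaultPrimerSet <- function() {
  readPrimerSet(system.file("extdata", "primers_v1_v9.tsv",
                            package = "near16S"))
}

# Score one gapped/ungapped placement of primer vs a gene substring by global
# alignment: IUPAC-compatible match +1, mismatch -2, gap -2 per column.
# Returns list(score, mismatches) where mismatches counts substitutions plus
# indel columns.
.scorePlacement <- function(primer, sub) {
  if (is.null(.near16S_env$iupacMat)) {
    .near16S_env$iupacMat <- .iupacScoreMatrix(1, -2)
  }
  m <- .near16S_env$iupacMat
  pa <- Biostrings::pairwiseAlignment(
    pattern = primer, subject = sub, type = "global",
    substitutionMatrix = {
      # square matrix over full IUPAC alphabet for pairwiseAlignment
      alph <- rownames(m)
      sq <- matrix(-2, length(alph), length(alph),
                   dimnames = list(alph, alph))
      sq[, c("A", "C", "G", "T")] <- m
      sq
    },
    gapOpening = 0, gapExtension = 2)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  indel <- ap == "-" | as_ == "-"
  compat <- !indel & .iupacCompatible(ap, as_)
  list(score = sum(compat) * 1 + sum(!compat & !indel) * -2 +
         sum(indel) * -2,
       mismatches = sum(!compat & !indel) + sum(indel))
}

.near16S_env <- new.env(parent = emptyenv())

#' Find the best placement of each primer on a 16S gene
#'
#' Per primer, every local placement within \code{maxMismatches} edits is
#' scored (IUPAC-compatible match +1, mismatch -2, gap -2); the best-scoring
#' placement is kept, ties broken by leftmost start. Placements whose
#' substitution + indel count exceeds \code{maxMismatches} are reported
#' absent. IUPAC degeneracies in the primer match any compatible base without
#' penalty.
#'
#' @param geneSeq one gene sequence (character or DNAString).
#' @param primerSet data.frame from \code{\link{readPrimerSet}}.
#' @param maxMismatches mismatch + indel budget (default 2).
#' @return data.frame with one row per primer: name, found, start, end,
#'   mismatches, score (1-based closed coordinates on the gene).
#' @export
findPrimerHits <- function(geneSeq, primerSet, maxMismatches = 2L) {
  geneSeq <- toupper(as.character(geneSeq))
  stopifnot(nchar(geneSeq) > 0L, maxMismatches >= 0L)
  subj <- Biostrings::DNAString(geneSeq)
  out <- lapply(seq_len(nrow(primerSet)), function(i) {
    primer <- primerSet$sequence[i]
    hits <- Biostrings::matchPattern(
      primer, subj, max.mismatch = maxMismatches, with.indels = TRUE,
      fixed = c(pattern = FALSE, subject = TRUE))
    if (length(hits) == 0L)
      return(data.frame(name = primerSet$name[i], found = FALSE,
                        start = NA_integer_, end = NA_integer_,
                        mismatches = NA_integer_, score = NA_real_))
    best <- NULL
    for (h in seq_along(hits)) {
      sub <- as.character(hits[[h]])
      sc <- .scorePlacement(primer, sub)
      if (sc$mismatches > maxMismatches) next
      cand <- list(start = Biostrings::start(hits)[h],
                   end = Biostrings::end(hits)[h],
                   mismatches = sc$mismatches, score = sc$score)
      if (is.null(best) || cand$score > best$score ||
          (cand$score == best$score && cand$start < best$start)) best <- cand
    }
    if (is.null(best))
      return(data.frame(name = primerSet$name[i], found = FALSE,
                        start = NA_integer_, end = NA_integer_,
                        mismatches = NA_integer_, score = NA_real_))
    data.frame(name = primerSet$name[i], found = TRUE,
               start = best$start, end = best$end,
               mismatches = best$mismatches, score = best$score)
  })
  do.call(rbind, out)
}

#' QC primer order and split a gene into hypervariable regions
#'
#' Rejects the locus when any expected primer is absent or when the hit order
#' is non-sequential (each primer must start after the previous primer's end).
#' Otherwise region V_k spans from the end of primer k-1's hit (gene start for
#' V1) to the base before primer k's hit start.
#'
#' @param geneSeq the gene sequence (for bounds checking).
#' @param hits data.frame from \code{\link{findPrimerHits}}.
#' @return list with \code{rejected} (logical); on rejection a \code{reason}
#'   code (\code{"missing-primer:<name>"} or
#'   \code{"non-sequential:<name1>/<name2>"}); otherwise \code{regions}, a
#'   data.frame (region, start, end; 1-based closed on the gene).
#' @export
qcAndSplit <- function(geneSeq, hits) {
  missing_ <- hits$name[!hits$found]
  if (length(missing_))
    return(list(rejected = TRUE,
                reason = paste0("missing-primer:", missing_[1L])))
  n <- nrow(hits)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      if (hits$start[i + 1L] <= hits$end[i])
        return(list(rejected = TRUE,
                    reason = sprintf("non-sequential:%s/%s",
                                     hits$name[i], hits$name[i + 1L])))
    }
  }
  starts <- c(1L, hits$end[-n] + 1L)
  ends <- hits$start - 1L
  if (any(ends < starts))
    return(list(rejected = TRUE,
                reason = sprintf("non-sequential:%s/%s",
                                 hits$name[max(1L, which(ends < starts)[1L] - 1L)],
                                 hits$name[which(ends < starts)[1L]])))
  list(rejected = FALSE,
       hits = hits,
       regions = data.frame(region = hits$name, start = starts, end = ends,
                            stringsAsFactors = FALSE))
}

#' Map all loci of a set against a primer set
#'
#' Convenience wrapper running \code{\link{findPrimerHits}} and
#' \code{\link{qcAndSplit}} over a \linkS4class{LinkedLocusSet}.
#'
#' @param loci a \linkS4class{LinkedLocusSet}.
#' @param primerSet data.frame from \code{\link{readPrimerSet}}.
#' @param maxMismatches mismatch budget per primer (default 2).
#' @return named list (by locusId) of \code{\link{qcAndSplit}} results.
#' @export
mapRegions <- function(loci, primerSet, maxMismatches = 2L) {
  genes <- as.character(loci@geneSeq)
  res <- lapply(genes, function(g) {
    qcAndSplit(g, findPrimerHits(g, primerSet, maxMismatches))
  })
  names(res) <- loci@locusId
  res
}

#' Build composite sequences for a region specification
#'
#' The composite is \code{upstream_prefix(L) + region}, where the upstream
#' prefix is the L bases immediately 5' of the gene start and the region is
#' one of: \code{"gene"} (full gene), \code{"V1V2"} (gene start through the
#' start of the V2-terminating primer), or a single region name from the
#' region map (e.g. \code{"V4"}).
#'
#' @param loci a \linkS4class{LinkedLocusSet}.
#' @param regionMaps output of \code{\link{mapRegions}} (required unless
#'   \code{region = "gene"} with \code{upstreamLen = 0}).
#' @param region \code{"gene"}, \code{"V1V2"} or a region name.
#' @param upstreamLen upstream prefix length L (default 0).
#' @return named character vector of composites (NA for loci rejected by QC or
#'   with insufficient upstream sequence).
#' @export
regionComposite <- function(loci, regionMaps = NULL, region = "V1V2",
                            upstreamLen = 0L) {
  genes <- as.character(loci@geneSeq)
  ups <- as.character(loci@upstreamSeq)
  n <- length(loci)
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    part <- NA_character_
    if (region == "gene") {
      part <- genes[i]
    } else {
      rm_ <- regionMaps[[loci@locusId[i]]]
      if (is.null(rm_) || isTRUE(rm_$rejected)) next
      if (region == "V1V2") {
        v2 <- rm_$hits[rm_$hits$name == "V2", , drop = FALSE]
        if (nrow(v2) != 1L) next
        part <- substr(genes[i], 1L, v2$start - 1L)
      } else {
        rg <- rm_$regions[rm_$regions$region == region, , drop = FALSE]
        if (nrow(rg) != 1L) next
        part <- substr(genes[i], rg$start, rg$end)
      }
    }
    if (upstreamLen > 0L) {
      nu <- nchar(ups[i])
      if (nu < upstreamLen) next  # insufficient upstream: excluded
      part <- paste0(substr(ups[i], nu - upstreamLen + 1L, nu), part)
    }
    out[i] <- part
  }
  names(out) <- loci@locusId
  out
}

#' Write per-locus region intervals as a BED-like TSV
#'
#' Output coordinates are 0-based half-open.
#'
#' @param regionMaps output of \code{\link{mapRegions}}.
#' @param path output TSV.
#' @return invisibly, the path.
#' @export
writeRegionTable <- function(regionMaps, path) {
  rows <- list()
  for (id in names(regionMaps)) {
    rm_ <- regionMaps[[id]]
    if (isTRUE(rm_$rejected)) next
    rg <- rm_$regions
    rows[[id]] <- data.frame(locus_id = id, region = rg$region,
                             start = rg$start - 1L, end = rg$end,
                             stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_id = character(0), region = character(0),
               start = integer(0), end = integer(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
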