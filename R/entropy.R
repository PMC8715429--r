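# Per-column Shannon entropy conservation profiles over MSAs.

#' Per-column Shannon entropy of a multiple sequence alignment
#'
#' Columns in which the reference sequence holds a gap are removed. For each
#' retained column the base fractions P_i are computed over non-gap residues
#' (gaps are excluded from the denominator) and
#' \deqn{S = -\sum_i P_i \log_4 P_i} with \eqn{0 \log 0 := 0}. The log base 4
#' normalizes S to [0, 1]: S = 1 when A, C, G and T each occupy a quarter of
#' the column, S = 0 when a single base occupies it entirely. A column whose
#' non-reference rows are all gaps is emitted as \code{NA}.
#'
#' @param msa character vector of equal-length gapped sequences (or a
#'   DNAStringSet / path accepted by \code{\link{readMSA}}).
#' @param referenceIndex row used for column retention (default 1).
#' @param regionLabel optional label stored on the result (e.g. "upstream",
#'   "gene").
#' @return data.frame with columns position (reference coordinate), S, and
#'   A, C, G, T counts; attribute \code{regionLabel}.
#' @export
columnEntropy <- function(msa, referenceIndex = 1L, regionLabel = NULL) {
  msa <- readMSA(msa)
  n <- length(msa)
  stopifnot(referenceIndex >= 1L, referenceIndex <= n)
  mat <- .charMatrix(msa)
  refGap <- mat[referenceIndex, ] == "-"
  mat <- mat[, !refGap, drop = FALSE]
  L <- ncol(mat)
  counts <- matrix(0L, L, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (b in colnames(counts)) counts[, b] <- colSums(mat == b)
  denom <- rowSums(counts)
  P <- counts / ifelse(denom == 0, 1, denom)
  plogp <- P * log(P, base = 4)
  plogp[P == 0] <- 0
  S <- -rowSums(plogp)
  # all non-reference rows gaps -> undefined
  if (n > 1L) {
    others <- mat[-referenceIndex, , drop = FALSE]
    allGap <- colSums(others != "-") == 0L
    S[allGap] <- NA_real_
  }
  out <- data.frame(position = seq_len(L), S = S,
                    A = counts[, "A"], C = counts[, "C"],
                    G = counts[, "G"], T = counts[, "T"])
  attr(out, "regionLabel") <- regionLabel
  out
}

#' Mean column entropy per member of a taxonomic rank
#'
#' For each member of a rank (e.g. each genus), samples its loci under the
#' caps, aligns the chosen region sequences and returns the mean column
#' entropy. Sampling is uniform under the given seed with at most
#' \code{maxMembers} members per rank, \code{maxSub} sub-members (next-rank
#' groups) per member, and \code{maxStrainsPerSpecies} strains per species.
#'
#' @param loci data.frame with columns genus, species, strain and seq (the
#'   region sequence already composited per locus).
#' @param rank \code{"genus"} or \code{"species"}: the rank whose members are
#'   profiled.
#' @param maxMembers,maxSub,maxStrainsPerSpecies sampling caps (defaults 20,
#'   5, 2).
#' @param seed RNG seed for the sampling.
#' @param aligned set TRUE when \code{loci$seq} is already gapped/aligned.
#' @return data.frame with columns member, meanS and n (sequences used);
#'   members with fewer than 2 sequences are skipped (attribute
#'   \code{skipped}).
#' @export
rankEntropyDistribution <- function(loci, rank = c("genus", "species"),
                                    maxMembers = 20L, maxSub = 5L,
                                    maxStrainsPerSpecies = 2L,
                                    seed = 1L, aligned = FALSE) {
  rank <- match.arg(rank)
  set.seed(seed)
  sub <- if (rank == "genus") "species" else "strain"
  capSample <- function(x, k) if (length(x) <= k) x else sample(x, k)

  members <- unique(loci[[rank]])
  members <- capSample(members, maxMembers)
  rows <- list(); skipped <- character(0)
  for (m in members) {
    sel <- loci[loci[[rank]] == m, , drop = FALSE]
    keepSub <- capSample(unique(sel[[sub]]), maxSub)
    sel <- sel[sel[[sub]] %in% keepSub, , drop = FALSE]
    # cap strains per species
    keep <- logical(nrow(sel))
    for (sp in unique(sel$species)) {
      idx <- which(sel$species == sp)
      strains <- capSample(unique(sel$strain[idx]), maxStrainsPerSpecies)
      keep[idx[sel$strain[idx] %in% strains]] <- TRUE
    }
    sel <- sel[keep, , drop = FALSE]
    if (nrow(sel) < 2L) {
      skipped <- c(skipped, m)
      next
    }
    msa <- if (aligned) sel$seq else alignSeqs(sel$seq)
    ent <- columnEntropy(msa, referenceIndex = 1L)
    rows[[m]] <- data.frame(member = m, meanS = mean(ent$S, na.rm = TRUE),
                            n = nrow(sel), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(member = character(0), meanS = numeric(0), n = integer(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
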