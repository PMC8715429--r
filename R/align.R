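# Multiple sequence alignment: progressive profile-profile Needleman-Wunsch
# over a 6-mer UPGMA guide tree. A pre-aligned input path (readMSA) keeps
# parity with externally produced alignments.

.charMatrix <- function(seqs) {
  do.call(rbind, strsplit(seqs, "", fixed = TRUE))
}

.profileCounts <- function(mat) {
  # 4 x L counts of A,C,G,T per column (gaps contribute nothing)
  L <- ncol(mat)
  out <- matrix(0, 4L, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (b in rownames(out)) out[b, ] <- colSums(mat == b)
  out
}

.applyOps <- function(mat, ops, code) {
  # expand alignment matrix with gap columns where ops == other profile only
  L <- sum(ops == 1L | ops == code)
  out <- matrix("-", nrow(mat), length(ops))
  out[, ops == 1L | ops == code] <- mat
  out
}

#' Progressive multiple sequence alignment
#'
#' Builds a UPGMA guide tree from Euclidean distances between 6-mer frequency
#' profiles, then merges alignments by profile-profile global alignment with
#' affine gaps (open 10, extend 1; column score averages pairwise match +2 /
#' mismatch -1). Intended for the moderate-size alignments used by the
#' conservation and OTU analyses; accepts 2 or more sequences.
#'
#' @param seqs character vector or DNAStringSet of unaligned sequences.
#' @param gapOpen,gapExt affine gap penalties (positive; defaults 10 and 1).
#' @param match,mismatch substitution scores (defaults +2 and -1).
#' @return character vector of equal-length gapped sequences, in input order.
#' @export
alignSeqs <- function(seqs, gapOpen = 10, gapExt = 1, match = 2,
                      mismatch = -1) {
  seqs <- toupper(as.character(seqs))
  n <- length(seqs)
  if (n == 0L) .stopf("no sequences to align")
  if (n == 1L) {
    warning("single sequence: returned unaligned")
    return(seqs)
  }
  # guide tree from 6-mer profiles
  kw <- max(1L, min(6L, min(nchar(seqs))))
  km <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = kw, as.prob = TRUE)
  d <- stats::dist(km)
  if (all(d == 0)) d[] <- d + seq_along(d) * 1e-9  # stable tie order
  tree <- stats::hclust(d, method = "average")

  alignments <- lapply(seqs, function(s) {
    m <- matrix(strsplit(s, "", fixed = TRUE)[[1L]], nrow = 1L)
    m
  })
  rowIds <- as.list(seq_len(n))
  merged <- vector("list", n - 1L)
  mergedIds <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    pick <- function(idx) {
      if (idx < 0) list(a = alignments[[-idx]], id = rowIds[[-idx]])
      else list(a = merged[[idx]], id = mergedIds[[idx]])
    }
    A <- pick(tree$merge[step, 1L])
    B <- pick(tree$merge[step, 2L])
    ops <- .profileAlignCpp(.profileCounts(A$a), .profileCounts(B$a),
                            nrow(A$a), nrow(B$a),
                            gapOpen, gapExt, match, mismatch)
    newA <- .applyOps(A$a, ops, 2L)
    newB <- .applyOps(B$a, ops, 3L)
    merged[[step]] <- rbind(newA, newB)
    mergedIds[[step]] <- c(A$id, B$id)
  }
  final <- merged[[n - 1L]]
  ord <- order(mergedIds[[n - 1L]])
  out <- apply(final[ord, , drop = FALSE], 1L, paste, collapse = "")
  names(out) <- names(seqs)
  out
}

#' Read (or validate) a pre-aligned FASTA
#'
#' @param x path to an aligned FASTA, or a character vector of gapped
#'   sequences.
#' @return character vector of equal-length aligned sequences.
#' @export
readMSA <- function(x) {
  seqs <- if (length(x) == 1L && file.exists(x)) {
    s <- Biostrings::readBStringSet(x)
    stats::setNames(toupper(as.character(s)), names(s))
  } else toupper(as.character(x))
  if (length(unique(nchar(seqs))) > 1L)
    .stopf("pre-aligned sequences must have equal lengths")
  seqs
}
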