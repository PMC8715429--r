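# RDP-style bootstrap naive-Bayes taxonomic classifier and leave-clade-out
# cross-validated accuracy.

#' Train an RDP-style word-presence naive-Bayes model
#'
#' Each training sequence contributes its set of distinct k-mers (words).
#' The corpus-wide word prior is \eqn{P_w = (n_w + 0.5) / (N + 1)} over the N
#' training sequences; the taxon-conditional probability is
#' \eqn{P(w | t) = (m_w + P_w) / (M_t + 1)} where \eqn{m_w} counts the
#' taxon's sequences containing w.
#'
#' @param seqs character vector of training sequences.
#' @param taxa taxon label per sequence (>= 2 distinct labels).
#' @param k word size (default 8).
#' @return an object of class \code{RdpModel}: list with \code{k},
#'   \code{taxa} and the per-taxon log-probability matrix.
#' @export
trainRdp <- function(seqs, taxa, k = 8L) {
  stopifnot(length(seqs) == length(taxa))
  ok <- !is.na(seqs) & nchar(seqs) >= k
  if (!all(ok)) {
    warning(sum(!ok), " sequence(s) shorter than k excluded from training")
    seqs <- seqs[ok]; taxa <- taxa[ok]
  }
  taxa <- as.character(taxa)
  if (length(unique(taxa)) < 2L) .stopf("need at least 2 taxa to train")
  pres <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = k) > 0L
  N <- nrow(pres)
  prior <- (colSums(pres) + 0.5) / (N + 1)
  labs <- sort(unique(taxa))
  logp <- matrix(0, length(labs), ncol(pres),
                 dimnames = list(labs, NULL))
  for (t in labs) {
    idx <- which(taxa == t)
    m <- colSums(pres[idx, , drop = FALSE])
    logp[t, ] <- log((m + prior) / (length(idx) + 1))
  }
  structure(list(k = as.integer(k), taxa = labs, logProb = logp),
            class = "RdpModel")
}

#' @export
print.RdpModel <- function(x, ...) {
  cat("RdpModel: k =", x$k, ",", length(x$taxa), "taxa\n")
  invisible(x)
}

.queryWords <- function(seq, k) {
  which(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(seq), width = k) > 0L)
}

#' Classify a sequence with bootstrap support
#'
#' Each of \code{nBootstrap} replicates draws \code{floor(W/8)} of the
#' query's W distinct words with replacement, scores the joint log-probability
#' per taxon, and votes for the argmax; the reported support is the vote
#' fraction of the winning taxon.
#'
#' @param seq query sequence (must be at least k bases long).
#' @param model an \code{RdpModel}.
#' @param nBootstrap bootstrap replicates (default 100).
#' @param seed RNG seed.
#' @return list with \code{taxon} and \code{support} in [0, 1].
#' @export
classifyRdp <- function(seq, model, nBootstrap = 100L, seed = 1L) {
  if (nchar(seq) < model$k) .stopf("sequence shorter than k = %d", model$k)
  set.seed(seed)
  words <- .queryWords(seq, model$k)
  W <- length(words)
  m <- max(1L, W %/% 8L)
  lp <- model$logProb[, words, drop = FALSE]
  votes <- integer(length(model$taxa))
  for (b in seq_len(nBootstrap)) {
    draw <- sample.int(W, m, replace = TRUE)
    sc <- rowSums(lp[, draw, drop = FALSE])
    votes[which.max(sc)] <- votes[which.max(sc)] + 1L
  }
  win <- which.max(votes)
  list(taxon = model$taxa[win], support = votes[win] / nBootstrap)
}

#' Leave-clade-out cross-validated classification accuracy
#'
#' Clades (by default strains) are partitioned into folds so that all
#' sequences of a held-out clade appear only in validation; per fold the
#' model is retrained and every validation sequence is classified at the
#' label rank (by default species). Accuracy is the ratio of accurate
#' predictions (correct label AND bootstrap support strictly above the
#' cutoff) to all predictions.
#'
#' @param loci data.frame with columns seq, plus the label and clade columns.
#' @param labelCol column holding the rank being predicted (default
#'   "species").
#' @param cladeCol column holding the held-out clade (default "strain").
#' @param k word size (default 8).
#' @param nFolds folds (default 5; clade count must be >= nFolds).
#' @param nBootstrap bootstrap replicates per classification (default 100).
#' @param cutoff bootstrap support cutoff (default 0.80, strict).
#' @param seed RNG seed for fold assignment and bootstrap.
#' @return list with \code{folds} (per-fold accuracies),
#'   \code{meanAccuracy} and \code{cutoff}.
#' @export
leaveCladeOutCV <- function(loci, labelCol = "species", cladeCol = "strain",
                            k = 8L, nFolds = 5L, nBootstrap = 100L,
                            cutoff = 0.80, seed = 1L) {
  set.seed(seed)
  loci <- loci[!is.na(loci$seq), , drop = FALSE]
  clades <- unique(loci[[cladeCol]])
  if (length(clades) < nFolds)
    .stopf("%d clades < %d folds", length(clades), nFolds)
  foldOf <- stats::setNames(
    rep_len(seq_len(nFolds), length(clades))[sample.int(length(clades))],
    clades)
  acc <- numeric(nFolds)
  for (f in seq_len(nFolds)) {
    heldClades <- names(foldOf)[foldOf == f]
    val <- loci[loci[[cladeCol]] %in% heldClades, , drop = FALSE]
    trn <- loci[!(loci[[cladeCol]] %in% heldClades), , drop = FALSE]
    stopifnot(!any(trn[[cladeCol]] %in% heldClades))
    if (nrow(val) == 0L) { acc[f] <- NA_real_; next }
    model <- trainRdp(trn$seq, trn[[labelCol]], k = k)
    good <- 0L
    for (i in seq_len(nrow(val))) {
      cl <- classifyRdp(val$seq[i], model, nBootstrap = nBootstrap,
                        seed = seed + i)
      if (cl$taxon == val[[labelCol]][i] && cl$support > cutoff)
        good <- good + 1L
    }
    acc[f] <- good / nrow(val)
  }
  list(folds = acc, meanAccuracy = mean(acc, na.rm = TRUE), cutoff = cutoff)
}
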