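# OTU clustering across identity thresholds and the four clustering-quality
# metrics scored against species labels.

#' Pairwise distances from an MSA
#'
#' Distance between two aligned sequences is the mismatch fraction over the
#' compared columns: internal gaps count as differences, end-gaps (columns
#' outside either sequence's first/last non-gap position) are ignored, and
#' shared gap columns are not differences.
#'
#' @param msa character vector of equal-length aligned sequences.
#' @return a symmetric numeric distance matrix.
#' @export
msaDistance <- function(msa) {
  msa <- readMSA(msa)
  mat <- .charMatrix(msa)
  n <- nrow(mat)
  nonGap <- mat != "-"
  firsts <- apply(nonGap, 1L, function(x) which(x)[1L])
  lasts <- apply(nonGap, 1L, function(x) utils::tail(which(x), 1L))
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      lo <- max(firsts[i], firsts[j])
      hi <- min(lasts[i], lasts[j])
      if (hi < lo) { d[i, j] <- d[j, i] <- 1; next }
      a <- mat[i, lo:hi]; b <- mat[j, lo:hi]
      use <- !(a == "-" & b == "-")
      d[i, j] <- d[j, i] <- if (any(use)) mean(a[use] != b[use]) else 0
    }
  }
  d
}

#' Cluster sequences into OTUs at an identity threshold
#'
#' Average-neighbour (UPGMA) hierarchical clustering of MSA mismatch
#' distances, cut at distance 1 - threshold.
#'
#' @param x character vector of sequences, or a precomputed distance matrix
#'   (when \code{distances = TRUE}).
#' @param threshold identity threshold in (0, 1), e.g. 0.97.
#' @param aligned TRUE when \code{x} is already aligned.
#' @param distances TRUE when \code{x} is a distance matrix.
#' @return list with \code{assignments} (named integer cluster ids) and
#'   \code{threshold}.
#' @export
clusterOTUs <- function(x, threshold, aligned = FALSE, distances = FALSE) {
  if (distances) {
    d <- x
  } else {
    msa <- if (aligned) readMSA(x) else alignSeqs(x)
    d <- msaDistance(msa)
  }
  if (length(d) == 0L || nrow(d) == 0L)
    return(list(assignments = integer(0), threshold = threshold))
  if (nrow(d) == 1L)
    return(list(assignments = stats::setNames(1L, rownames(d)),
                threshold = threshold))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(hc, h = 1 - threshold)
  list(assignments = cl, threshold = threshold)
}

#' Richness ratio between species count and OTU count
#'
#' @param S number of distinct species.
#' @param O number of OTUs.
#' @return min(S, O) / max(S, O).
#' @export
richnessRatio <- function(S, O) {
  stopifnot(S >= 1L, O >= 1L)
  min(S, O) / max(S, O)
}

#' Pair-level MCC, NMI and bijection of a clustering against species labels
#'
#' MCC is computed over the pair-level confusion (TP: pairs of sequences in
#' the same species and same cluster; FP: same cluster, different species;
#' FN: same species, different cluster; TN: the rest). NMI is mutual
#' information normalized by the arithmetic mean of the two partition
#' entropies (natural logs). Bijection is the fraction of species whose
#' sequences occupy exactly one cluster containing nothing else.
#'
#' @param assignments cluster ids, one per sequence.
#' @param labels species labels, one per sequence.
#' @return list with \code{mcc}, \code{nmi}, \code{bijection} (NA when a
#'   denominator degenerates, e.g. a single cluster and a single species).
#' @export
pairConfusionMetrics <- function(assignments, labels) {
  stopifnot(length(assignments) == length(labels))
  n <- length(labels)
  tab <- table(labels, assignments)
  choose2 <- function(x) x * (x - 1) / 2
  TP <- sum(choose2(tab))
  sameCluster <- sum(choose2(colSums(tab)))
  sameSpecies <- sum(choose2(rowSums(tab)))
  total <- choose2(n)
  FP <- sameCluster - TP
  FN <- sameSpecies - TP
  TN <- total - TP - FP - FN
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (den == 0) NA_real_ else (TP * TN - FP * FN) / den

  p <- tab / n
  pr <- rowSums(p); pc <- colSums(p)
  H <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  Hu <- H(pr); Hv <- H(pc)
  pi_ <- p[p > 0]
  outer_ <- outer(pr, pc)[p > 0]
  I <- sum(pi_ * log(pi_ / outer_))
  nmi <- if ((Hu + Hv) == 0) NA_real_ else I / mean(c(Hu, Hv))

  pureSpecies <- vapply(rownames(tab), function(sp) {
    cls <- which(tab[sp, ] > 0)
    length(cls) == 1L && sum(tab[, cls]) == tab[sp, cls]
  }, logical(1L))
  bijection <- mean(pureSpecies)

  list(mcc = mcc, nmi = nmi, bijection = bijection)
}

#' Sweep clustering thresholds and find the per-metric optimum
#'
#' Aligns the sequences once, clusters at every threshold, scores the four
#' metrics, and reports each metric's argmax threshold (ties resolved toward
#' the lowest threshold). In representative mode, each species is represented
#' by a single randomly selected strain.
#'
#' @param loci data.frame with columns species, strain and seq.
#' @param thresholds identity thresholds to sweep (default 0.90 to 0.995 by
#'   0.005).
#' @param representative sample one strain per species first (default FALSE).
#' @param seed RNG seed for representative sampling.
#' @return list with \code{table} (one row per threshold: threshold, S, O,
#'   richness, mcc, nmi, bijection) and \code{optimal} (named numeric of
#'   argmax thresholds).
#' @export
optimalThresholdSweep <- function(loci, thresholds = seq(0.90, 0.995, 0.005),
                                  representative = FALSE, seed = 1L) {
  set.seed(seed)
  if (representative) {
    keep <- logical(nrow(loci))
    for (sp in unique(loci$species)) {
      idx <- which(loci$species == sp)
      st <- sample(unique(loci$strain[idx]), 1L)
      keep[idx[loci$strain[idx] == st]] <- TRUE
    }
    loci <- loci[keep, , drop = FALSE]
  }
  msa <- alignSeqs(loci$seq)
  d <- msaDistance(msa)
  S <- length(unique(loci$species))
  rows <- lapply(thresholds, function(th) {
    cl <- clusterOTUs(d, th, distances = TRUE)$assignments
    O <- length(unique(cl))
    m <- pairConfusionMetrics(cl, loci$species)
    data.frame(threshold = th, S = S, O = O,
               richness = richnessRatio(S, O),
               mcc = m$mcc, nmi = m$nmi, bijection = m$bijection)
  })
  tab <- do.call(rbind, rows)
  argmax <- function(v) {
    if (all(is.na(v))) return(NA_real_)
    tab$threshold[which(v == max(v, na.rm = TRUE))[1L]]
  }
  list(table = tab,
       optimal = c(richness = argmax(tab$richness), mcc = argmax(tab$mcc),
                   nmi = argmax(tab$nmi), bijection = argmax(tab$bijection)))
}
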