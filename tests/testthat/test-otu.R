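test_that("clusterOTUs merges below and splits above the distance cut", {
  set.seed(40)
  s <- randSeqChr(100)
  mut <- function(x, k) {
    pos <- sample(nchar(x), k)
    ch <- strsplit(x, "")[[1]]
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  far <- mut(s, 10)   # 10% distance
  near <- mut(s, 2)   # 2% distance
  cl1 <- clusterOTUs(c(s, far), threshold = 0.97, aligned = TRUE)
  expect_equal(length(unique(cl1$assignments)), 2L)
  cl2 <- clusterOTUs(c(s, near), threshold = 0.97, aligned = TRUE)
  expect_equal(length(unique(cl2$assignments)), 1L)
  # identical sequences at any threshold -> one cluster
  cl3 <- clusterOTUs(c(s, s, s), threshold = 0.999, aligned = TRUE)
  expect_equal(length(unique(cl3$assignments)), 1L)
})

test_that("richness ratio follows min/max and is symmetric", {
  expect_equal(richnessRatio(8, 8), 1.0)
  expect_equal(richnessRatio(10, 5), 0.5)
  expect_equal(richnessRatio(5, 10), 0.5)
})

test_that("a perfect clustering scores 1 on all three pair metrics", {
  labels <- rep(c("s1", "s2", "s3"), each = 4)
  m <- pairConfusionMetrics(labels, labels)
  expect_equal(m$mcc, 1.0)
  expect_equal(m$nmi, 1.0)
  expect_equal(m$bijection, 1.0)
})

test_that("crossed clusters yield bijection 0; a pure split gives 2/3", {
  labels <- c("s1", "s1", "s2", "s2")
  crossed <- c(1, 2, 1, 2)
  expect_equal(pairConfusionMetrics(crossed, labels)$bijection, 0)
  labels3 <- rep(c("s1", "s2", "s3"), each = 2)
  split1 <- c(1, 4, 2, 2, 3, 3)  # s1 split into two pure clusters
  expect_equal(pairConfusionMetrics(split1, labels3)$bijection, 2 / 3)
})

test_that("single cluster and single species degenerate to NA", {
  m <- pairConfusionMetrics(rep(1, 5), rep("s", 5))
  expect_true(is.na(m$mcc))
  expect_true(is.na(m$nmi))
})

test_that("pair metrics agree with exhaustive pair enumeration", {
  set.seed(41)
  for (rep_ in 1:15) {
    n <- sample(10:30, 1)
    labels <- sample(paste0("s", 1:4), n, replace = TRUE)
    cl <- sample(1:5, n, replace = TRUE)
    m <- pairConfusionMetrics(cl, labels)
    # oracle: enumerate all pairs
    TP <- FP <- FN <- TN <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ss <- labels[i] == labels[j]
      sc <- cl[i] == cl[j]
      if (ss && sc) TP <- TP + 1
      else if (!ss && sc) FP <- FP + 1
      else if (ss && !sc) FN <- FN + 1
      else TN <- TN + 1
    }
    den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
    mccO <- if (den == 0) NA_real_ else (TP * TN - FP * FN) / den
    expect_equal(m$mcc, mccO, tolerance = 1e-12)
  }
})

test_that("NMI and MCC are invariant under cluster-label permutation", {
  set.seed(42)
  labels <- sample(paste0("s", 1:3), 20, replace = TRUE)
  cl <- sample(1:4, 20, replace = TRUE)
  m1 <- pairConfusionMetrics(cl, labels)
  perm <- sample(4)
  m2 <- pairConfusionMetrics(perm[cl], labels)
  expect_equal(m1$mcc, m2$mcc)
  expect_equal(m1$nmi, m2$nmi)
})

test_that("raising the threshold never decreases the cluster count", {
  set.seed(43)
  seqs <- replicate(12, randSeqChr(80))
  msa <- alignSeqs(seqs)
  d <- msaDistance(msa)
  Os <- vapply(c(0.80, 0.90, 0.95, 0.99), function(th)
    length(unique(clusterOTUs(d, th, distances = TRUE)$assignments)),
    numeric(1))
  expect_true(!is.unsorted(Os))
})

test_that("msaDistance counts gaps as differences but ignores end-gaps", {
  msa <- c("ACGTACGT", "ACG-ACGT", "--GTACGT")
  d <- msaDistance(msa)
  expect_equal(d[1, 2], 1 / 8)  # internal gap counts
  expect_equal(d[1, 3], 0)      # leading end-gap ignored
})

test_that("threshold sweep finds the species boundary on clean divergence", {
  set.seed(44)
  base <- randSeqChr(300)
  mut <- function(x, k) {
    ch <- strsplit(x, "")[[1]]
    pos <- sample(length(ch), k)
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  # 3 species at ~6% mutual divergence, strains at ~0.7%
  loci <- do.call(rbind, lapply(1:3, function(sp) {
    anc <- mut(base, 18)
    do.call(rbind, lapply(1:3, function(st)
      data.frame(species = paste0("S", sp), strain = paste0("S", sp, "T", st),
                 seq = mut(anc, 2), stringsAsFactors = FALSE)))
  }))
  sw <- optimalThresholdSweep(loci, thresholds = seq(0.90, 0.99, 0.01))
  best <- sw$table[sw$table$threshold == sw$optimal["mcc"], ]
  expect_equal(best$O, 3L)
  expect_equal(best$mcc, 1.0)
  expect_true(all(sw$optimal >= 0.90 & sw$optimal <= 0.99))
})

test_that("representative mode is reproducible under a fixed seed", {
  set.seed(45)
  loci <- data.frame(species = rep(c("S1", "S2"), each = 4),
                     strain = rep(paste0("T", 1:4), 2),
                     seq = replicate(8, randSeqChr(60)))
  s1 <- optimalThresholdSweep(loci, thresholds = 0.95,
                              representative = TRUE, seed = 7)
  s2 <- optimalThresholdSweep(loci, thresholds = 0.95,
                              representative = TRUE, seed = 7)
  expect_identical(s1$table, s2$table)
})
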