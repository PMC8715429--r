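test_that("identical sequences align gap-free", {
  set.seed(20)
  s <- randSeqChr(200)
  msa <- alignSeqs(c(s, s))
  expect_equal(msa, c(s, s))
})

test_that("ACGT vs ACT aligns with one gap and three match columns", {
  msa <- alignSeqs(c("ACGT", "ACT"))
  expect_equal(nchar(msa[1]), 4L)
  m1 <- strsplit(msa[1], "")[[1]]
  m2 <- strsplit(msa[2], "")[[1]]
  expect_equal(sum(m2 == "-"), 1L)
  expect_equal(sum(m1 == m2 & m1 != "-"), 3L)
})

test_that("pre-aligned input with unequal lengths errors", {
  expect_error(readMSA(c("AC-GT", "ACGT")), "equal length")
})

test_that("single sequence is returned unchanged with a warning", {
  expect_warning(out <- alignSeqs("ACGTACGTA"), "single")
  expect_equal(unname(out), "ACGTACGTA")
})

test_that("aligner recovers a shared indel structure among mutated copies", {
  set.seed(21)
  base <- randSeqChr(300)
  del <- paste0(substr(base, 1, 100), substr(base, 131, 300))
  msa <- alignSeqs(c(base, del, base))
  expect_equal(length(unique(nchar(msa))), 1L)
  expect_equal(gsub("-", "", msa[2]), del)
  expect_equal(gsub("-", "", msa[1]), base)
})

test_that("entropy anchors: uniform column is 1, single-base column is 0", {
  msa <- c("AA", "CA", "GA", "TA")
  ent <- columnEntropy(msa)
  expect_equal(ent$S, c(1, 0))
})

test_that("a half-and-half column has entropy 0.5", {
  ent <- columnEntropy(c("A", "A", "C", "C"))
  expect_equal(ent$S, 0.5)
})

test_that("reference-gap columns are removed, reference coordinates kept", {
  msa <- c("A-CG", "AACG", "AACG")
  ent <- columnEntropy(msa, referenceIndex = 1)
  expect_equal(nrow(ent), 3L)  # column 2 dropped (reference gap)
  expect_equal(ent$S, rep(0, 3))
})

test_that("column with only gaps among non-reference rows is NA", {
  msa <- c("ACG", "A-G", "A-G")
  ent <- columnEntropy(msa)
  expect_true(is.na(ent$S[2]))
})

test_that("entropy is invariant to row permutation", {
  set.seed(22)
  msa <- replicate(6, randSeqChr(50))
  msa <- alignSeqs(msa)
  e1 <- columnEntropy(msa, referenceIndex = 1)
  perm <- c(1, sample(2:6))
  e2 <- columnEntropy(msa[perm], referenceIndex = 1)
  expect_equal(e1$S, e2$S)
})

test_that("duplicating a sequence matches recomputation from counts", {
  set.seed(23)
  msa <- alignSeqs(replicate(4, randSeqChr(60)))
  dup <- c(msa, msa[2])
  e <- columnEntropy(dup, referenceIndex = 1)
  counts <- as.matrix(e[c("A", "C", "G", "T")])
  P <- counts / rowSums(counts)
  expS <- -rowSums(ifelse(P > 0, P * log(P, 4), 0))
  expect_equal(e$S, expS)
})

test_that("two-symbol column entropy is maximal at p = 0.5", {
  S2 <- function(k, n) {
    p <- k / n
    q <- 1 - p
    -sum(c(p, q)[c(p, q) > 0] * log(c(p, q)[c(p, q) > 0], 4))
  }
  n <- 20
  vals <- vapply(0:n, S2, numeric(1), n = n)
  expect_equal(which.max(vals), n / 2 + 1)
})

test_that("rank entropy separates fast upstream from slow gene divergence", {
  spec <- communitySpec(nGenera = 3L, speciesPerGenus = 2L,
                        strainsPerSpecies = 2L, copiesPerGenome = 2L,
                        geneRates = c(genus = 0.02, species = 0.008,
                                      strain = 0.002),
                        upstreamRates = c(genus = 0.2, species = 0.08,
                                          strain = 0.02),
                        sharedUpstream = TRUE, seed = 99L)
  sim <- generateCommunity(spec)
  tab <- truthLocusTable(sim)
  entGene <- rankEntropyDistribution(transform(tab, seq = gene),
                                     rank = "genus", seed = 5)
  entUp <- rankEntropyDistribution(transform(tab, seq = upstream),
                                   rank = "genus", seed = 5)
  expect_gt(mean(entUp$meanS), mean(entGene$meanS))

  # genus-level members are more diverse than species-level members
  entSp <- rankEntropyDistribution(transform(tab, seq = upstream),
                                   rank = "species", seed = 5)
  expect_gt(mean(entUp$meanS), mean(entSp$meanS))
})

test_that("members with identical sequences give mean entropy 0 and
           tiny members are skipped", {
  tab <- data.frame(genus = c("G1", "G1", "G1", "G2"),
                    species = c("S1", "S1", "S2", "S3"),
                    strain = paste0("T", 1:4),
                    seq = c("ACGTACGTAA", "ACGTACGTAA", "ACGTACGTAA",
                            "ACGTACGTAA"))
  res <- rankEntropyDistribution(tab, rank = "genus", seed = 1)
  expect_equal(res$meanS[res$member == "G1"], 0)
  expect_true("G2" %in% attr(res, "skipped"))
})
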