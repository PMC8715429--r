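mkLoci <- function(strainCopies, speciesOf = NULL, genusOf = NULL) {
  # strainCopies: named list strain -> character vector of composites
  rows <- lapply(names(strainCopies), function(st) {
    data.frame(genus = if (is.null(genusOf)) "G" else genusOf[[st]],
               species = if (is.null(speciesOf)) "S" else speciesOf[[st]],
               strain = st, seq = strainCopies[[st]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("the worked two-strain example gives 100%, 50% and mean 75%", {
  loci <- mkLoci(list(X = "AAAA", Y = c("CCCC", "CCCC")))
  r <- copyIdentifiability(loci, level = "intra_strain")
  expect_equal(r$perMember[["X"]], 1.0)
  expect_equal(r$perMember[["Y"]], 0.5)
  expect_equal(r$meanFraction, 0.75)
})

test_that("all-unique copies give mean 1; four identical copies give 1/4", {
  lociU <- mkLoci(list(A = c("AA", "AC"), B = c("GG", "GT")))
  expect_equal(copyIdentifiability(lociU, "intra_strain")$meanFraction, 1)
  loci4 <- mkLoci(list(A = rep("ACGT", 4)))
  expect_equal(unname(copyIdentifiability(loci4, "intra_strain")$perMember),
               0.25)
})

test_that("mean is 1 iff every member's copies are pairwise distinct", {
  set.seed(30)
  for (rep_ in 1:20) {
    nStr <- sample(2:5, 1)
    copies <- lapply(seq_len(nStr), function(i)
      replicate(sample(1:4, 1),
                paste(sample(c("A", "C"), 6, TRUE), collapse = "")))
    names(copies) <- paste0("T", seq_len(nStr))
    r <- copyIdentifiability(mkLoci(copies), "intra_strain")
    allDistinct <- all(vapply(copies, function(x)
      !anyDuplicated(x), logical(1)))
    expect_equal(r$meanFraction == 1, allDistinct)
  }
})

test_that("adding a duplicate copy never increases any member's fraction", {
  set.seed(31)
  copies <- list(A = c("AAAA", "AACA", "GGGG"), B = c("TTTT", "TTGT"))
  base <- copyIdentifiability(mkLoci(copies), "intra_strain")$perMember
  copies$A <- c(copies$A, copies$A[1])
  more <- copyIdentifiability(mkLoci(copies), "intra_strain")$perMember
  expect_true(all(more[names(base)] <= base))
})

test_that("extending the composite never decreases identifiability", {
  set.seed(32)
  for (rep_ in 1:10) {
    short <- replicate(8, paste(sample(c("A", "G"), 4, TRUE), collapse = ""))
    ext <- paste0(short, replicate(8, paste(
      sample(c("A", "C", "G", "T"), 4, TRUE), collapse = "")))
    lociS <- mkLoci(list(A = short[1:4], B = short[5:8]))
    lociE <- mkLoci(list(A = ext[1:4], B = ext[5:8]))
    fS <- copyIdentifiability(lociS, "intra_strain")$meanFraction
    fE <- copyIdentifiability(lociE, "intra_strain")$meanFraction
    expect_gte(fE, fS)
  }
})

test_that("inter-strain pools copies within species with >= 2 strains", {
  loci <- mkLoci(list(T1 = c("AAAA", "CCCC"), T2 = "AAAA", T3 = "GGGG"),
                 speciesOf = list(T1 = "S1", T2 = "S1", T3 = "S2"))
  r <- copyIdentifiability(loci, level = "inter_strain")
  # S2 has one strain -> excluded; S1 pools {AAAA, CCCC, AAAA} -> 2/3
  expect_equal(names(r$perMember), "S1")
  expect_equal(unname(r$perMember), 2 / 3)
})

test_that("strain identifiability matches the definition on small cases", {
  # disjoint variant sets -> 1.0
  l1 <- mkLoci(list(A = c("AA", "AC"), B = c("GG")))
  expect_equal(unname(strainIdentifiability(l1)), 1.0)
  # identical variant sets -> 0.0
  l2 <- mkLoci(list(A = "AA", B = "AA"))
  expect_equal(unname(strainIdentifiability(l2)), 0.0)
  # {A, B identical to A, C unique} -> 1/3
  l3 <- mkLoci(list(A = "AA", B = "AA", C = "CC"))
  expect_equal(unname(strainIdentifiability(l3)), 1 / 3)
})

test_that("strain identifiability agrees with a brute-force oracle", {
  set.seed(33)
  for (rep_ in 1:10) {
    nStr <- sample(3:8, 1)
    copies <- lapply(seq_len(nStr), function(i)
      replicate(sample(1:3, 1),
                paste(sample(c("A", "C"), 3, TRUE), collapse = "")))
    names(copies) <- paste0("T", seq_len(nStr))
    loci <- mkLoci(copies)
    got <- unname(strainIdentifiability(loci))
    # oracle: exhaustive pairwise comparison of copy sets
    ident <- vapply(names(copies), function(st) {
      others <- unlist(copies[setdiff(names(copies), st)])
      any(vapply(copies[[st]], function(s) !(s %in% others), logical(1)))
    }, logical(1))
    expect_equal(got, mean(ident))
  }
})

test_that("upstream length sweep is monotone and anchored at L = 0", {
  set.seed(34)
  # operons differ only at upstream position -300
  up <- replicate(3, randSeqChr(1000))
  base <- randSeqChr(1000)
  up <- vapply(1:3, function(i) {
    x <- base
    substr(x, 701, 701) <- c("A", "C", "G")[i]
    x
  }, "")
  v1v2 <- randSeqChr(320)
  loci <- data.frame(genus = "G", species = "S", strain = "T",
                     upstream = up, v1v2 = v1v2)
  sw <- upstreamLengthSweep(loci, lengths = c(0, 200, 400, 600),
                            level = "intra_strain")
  # L = 0 reduces to V1V2-only identifiability (all identical -> 1/3)
  expect_equal(unname(sw["0"]), 1 / 3)
  expect_equal(unname(sw["200"]), 1 / 3)   # SNP at -300 not yet covered
  expect_equal(unname(sw["400"]), 1)       # covered from L = 400
  expect_true(!is.unsorted(sw))
  # identical operons at all L -> constant curve
  lociSame <- data.frame(genus = "G", species = "S", strain = "T",
                         upstream = rep(base, 3), v1v2 = v1v2)
  swSame <- upstreamLengthSweep(lociSame, lengths = c(0, 500, 1000),
                                level = "intra_strain")
  expect_equal(unname(swSame), rep(1 / 3, 3))
})

test_that("nearest non-identical distances match exhaustive edit distance", {
  res <- nearestNonidenticalDistances(c("ACGT", "ACGA", "AGGA"),
                                      nQueries = 3, k = 5, seed = 1)
  i <- which(res$queries == 1)
  expect_equal(res$distances[[i]], c(1, 2))
  expect_true(all(res$short))
  # all identical -> empty lists, flagged
  resId <- nearestNonidenticalDistances(rep("AAAA", 4), nQueries = 2)
  expect_true(all(lengths(resId$distances) == 0))
  expect_true(all(resId$short))
})

test_that("higher upstream divergence widens near-16S neighbour distances", {
  sim <- smallCommunity()  # upstream rates 5x gene rates
  tab <- truthLocusTable(sim)
  near <- paste0(substr(tab$upstream, 601, 1000), tab$v1v2)
  dNear <- unlist(nearestNonidenticalDistances(near, k = 3,
                                               seed = 2)$distances)
  dGene <- unlist(nearestNonidenticalDistances(tab$v1v2, k = 3,
                                               seed = 2)$distances)
  expect_gt(median(dNear), median(dGene))
})
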