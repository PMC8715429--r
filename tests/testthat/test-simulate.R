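test_that("zero rates yield identical operons across the community", {
  spec <- communitySpec(nGenera = 2L, speciesPerGenus = 1L,
                        strainsPerSpecies = 2L, copiesPerGenome = 2L,
                        geneRates = c(genus = 0, species = 0, strain = 0),
                        upstreamRates = c(genus = 0, species = 0,
                                          strain = 0),
                        intragenomicSnpRate = 0, sharedUpstream = TRUE,
                        seed = 70L)
  sim <- generateCommunity(spec)
  ops <- truthOperons(sim)
  expect_equal(length(unique(paste0(ops$upstream_seq, ops$gene_seq))), 1L)
})

test_that("per-copy upstream loci are independent, shared down the lineage", {
  sim <- smallCommunity()
  ops <- truthOperons(sim)
  one <- ops[ops$assembly_id == ops$assembly_id[1], ]
  # copies within a genome: unrelated upstream loci
  d <- utils::adist(one$upstream_seq)
  expect_gt(min(d[upper.tri(d)]), 200)
  # the same copy slot across two strains of one species: closely related
  sameSp <- ops[ops$species == ops$species[1] & ops$copy == 1L, ]
  expect_lt(utils::adist(sameSp$upstream_seq[1], sameSp$upstream_seq[2]),
            100)
})

test_that("intragenomic SNP counts follow the binomial expectation", {
  rate <- 0.01
  spec <- communitySpec(nGenera = 1L, speciesPerGenus = 1L,
                        strainsPerSpecies = 1L, copiesPerGenome = 30L,
                        geneRates = c(genus = 0, species = 0, strain = 0),
                        upstreamRates = c(genus = 0, species = 0,
                                          strain = 0),
                        intragenomicSnpRate = rate, sharedUpstream = TRUE,
                        upstreamLen = 1000L, seed = 71L)
  sim <- generateCommunity(spec)
  ops <- truthOperons(sim)
  # substitutions per upstream vs the shared ancestor (recovered as the
  # per-site majority consensus over 30 copies): Binomial(1000, rate)
  mat <- do.call(rbind, strsplit(ops$upstream_seq, ""))
  anc <- apply(mat, 2, function(col) names(which.max(table(col))))
  nDiff <- rowSums(sweep(mat, 2, anc, `!=`))
  m <- mean(nDiff)
  exp_ <- 1000 * rate
  sd_ <- sqrt(1000 * rate * (1 - rate) / nrow(ops))
  expect_lt(abs(m - exp_), 3 * sd_ + 1e-9)
})

test_that("generation and read simulation are seed-deterministic", {
  spec <- communitySpec(nGenera = 1L, speciesPerGenus = 1L,
                        strainsPerSpecies = 2L, copiesPerGenome = 2L,
                        seed = 72L)
  s1 <- generateCommunity(spec)
  s2 <- generateCommunity(spec)
  expect_identical(as.character(s1@genomes[[1]]@contigs),
                   as.character(s2@genomes[[1]]@contigs))
  r1 <- simulateSt16sReads(s1, nPairs = 50, seed = 5)
  r2 <- simulateSt16sReads(s2, nPairs = 50, seed = 5)
  expect_identical(r1$pairs, r2$pairs)
  expect_identical(r1$provenance, r2$provenance)
  # byte-identical files
  d1 <- tempfile(); d2 <- tempfile()
  writeCommunity(s1, d1); writeCommunity(s2, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("error-free reads map back to their source operon", {
  sim <- smallCommunity()
  rd <- simulateSt16sReads(sim, nPairs = 30, errorRate = 0,
                           terminationProb = 1 / 300, seed = 6)
  ops <- truthOperons(sim)
  full <- paste0(ops$upstream_seq, ops$gene_seq)
  for (i in seq_len(10)) {
    src <- match(rd$provenance$locus_id[i], ops$locus_id)
    # R2 is a plus-strand (gene orientation) window of its source operon
    expect_true(grepl(rd$pairs$r2[i], full[src], fixed = TRUE))
  }
})

test_that("a private upstream SNP appears only in reads of its operon", {
  spec <- communitySpec(nGenera = 1L, speciesPerGenus = 1L,
                        strainsPerSpecies = 1L, copiesPerGenome = 2L,
                        geneRates = c(genus = 0, species = 0, strain = 0),
                        upstreamRates = c(genus = 0, species = 0,
                                          strain = 0),
                        intragenomicSnpRate = 0, sharedUpstream = TRUE,
                        seed = 73L)
  sim <- generateCommunity(spec)
  # plant a private SNP at upstream position -300 of copy 2
  ops <- sim@operons
  u <- ops$upstream_seq[2]
  old <- substr(u, 701, 701)
  substr(u, 701, 701) <- setdiff(c("A", "C", "G", "T"), old)[1]
  sim@operons$upstream_seq[2] <- u
  rd <- simulateSt16sReads(sim, nPairs = 400, errorRate = 0,
                           terminationProb = 1 / 500, seed = 7)
  snpWindow <- substr(u, 691, 711)
  carries <- grepl(snpWindow, rd$pairs$r2, fixed = TRUE)
  from2 <- rd$provenance$locus_id == ops$locus_id[2]
  expect_true(any(carries))
  expect_true(all(from2[carries]))
})

test_that("fragment lengths are geometric with mean 1/p", {
  sim <- smallCommunity()
  p <- 0.01
  rd <- simulateSt16sReads(sim, nPairs = 10000, terminationProb = p,
                           readLen = 100, errorRate = 0, seed = 8)
  ext <- rd$provenance$fragmentLen - nchar(extensionPrimer())
  m <- mean(ext)
  expect_lt(abs(m - 1 / p) / (1 / p), 0.05)
  # chi-square goodness of fit against geometric(p), pooled tail
  br <- c(seq(0, 400, 50), Inf)
  obs <- table(cut(ext, br))
  pr <- diff(pgeom(br, p))
  ok <- pr > 0
  chi <- suppressWarnings(chisq.test(as.numeric(obs)[ok], p = pr[ok],
                                     rescale.p = TRUE))
  expect_gt(chi$p.value, 0.01)
})

test_that("p -> 0 drives every fragment to the template end", {
  sim <- smallCommunity()
  rd <- simulateSt16sReads(sim, nPairs = 40, terminationProb = 1e-9,
                           errorRate = 0, seed = 9)
  maxExt <- 1000 + 320  # upstream + gene bases 5' of the priming site
  expect_true(all(rd$provenance$fragmentLen ==
                    maxExt + nchar(extensionPrimer())))
})

test_that("mock standards have even abundances and drawn copy numbers", {
  sim <- simulateMockStandard("even8", seed = 74, firstGenomeCopies = 6)
  expect_length(trueAbundance(sim), 8L)
  expect_true(all(abs(trueAbundance(sim) - 1 / 8) < 1e-12))
  ops <- truthOperons(sim)
  copies <- table(ops$assembly_id)
  expect_equal(unname(copies[names(trueAbundance(sim))[1]]), 6L)
  expect_true(all(copies >= 1 & copies <= 10))
  # determinism of the truth table
  sim2 <- simulateMockStandard("even8", seed = 74, firstGenomeCopies = 6)
  expect_identical(as.data.frame(truthOperons(sim2)),
                   as.data.frame(ops))
})

test_that("raising upstream divergence widens near-16S neighbour gaps", {
  meds <- vapply(c(0.02, 0.08, 0.2), function(r) {
    spec <- communitySpec(nGenera = 2L, speciesPerGenus = 2L,
                          strainsPerSpecies = 2L, copiesPerGenome = 2L,
                          geneRates = c(genus = 0.01, species = 0.005,
                                        strain = 0.002),
                          upstreamRates = c(genus = r, species = r / 2,
                                            strain = r / 5),
                          sharedUpstream = TRUE, seed = 75L)
    sim <- generateCommunity(spec)
    ops <- truthOperons(sim)
    near <- paste0(substr(ops$upstream_seq, 601, 1000),
                   substr(ops$gene_seq, 1, 320))
    stats::median(unlist(nearestNonidenticalDistances(near, k = 3,
                                                      seed = 3)$distances))
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})
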