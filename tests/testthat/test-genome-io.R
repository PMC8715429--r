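test_that("parseGenome retains features by product pattern", {
  set.seed(1)
  contig <- randSeqChr(5000)
  toy <- writeToyGenome(contig, list(
    list(start = 1000, end = 2500, strand = "+",
         product = "16S ribosomal RNA"),
    list(start = 3000, end = 4200, strand = "+",
         product = "23S ribosomal RNA"),
    list(start = 300, end = 400, strand = "-",
         product = "16S ribosomal RNA (partial)")))
  g <- parseGenome(toy$fasta, toy$annotation,
                   list(assembly_id = "toy", genus = "G", species = "S",
                        strain = "T"))
  expect_s4_class(g, "GenomeRecord")
  expect_equal(length(g@features), 2L)  # 23S excluded, "(partial)" kept
  expect_setequal(g@features$product,
                  c("16S ribosomal RNA", "16S ribosomal RNA (partial)"))
})

test_that("missing or empty assembly files raise a distinct error", {
  expect_error(parseGenome(tempfile(), tempfile()),
               class = "near16S_missing_assembly")
  empty <- tempfile(); file.create(empty)
  expect_error(parseGenome(empty, empty),
               class = "near16S_missing_assembly")
})

test_that("malformed coordinates raise a parse error naming the line", {
  set.seed(2)
  toy <- writeToyGenome(randSeqChr(100), list(
    list(start = "50", end = "x", strand = "+",
         product = "16S ribosomal RNA")))
  expect_error(parseGenome(toy$fasta, toy$annotation),
               class = "near16S_parse_error")
})

test_that("extraction is strand-aware and length-filtered", {
  set.seed(3)
  contig <- randSeqChr(9000)
  toy <- writeToyGenome(contig, list(
    list(start = 5001, end = 6500, strand = "+",
         product = "16S ribosomal RNA"),          # plus strand, 1500 bp
    list(start = 7001, end = 7900, strand = "+",
         product = "16S ribosomal RNA")))          # 900 bp -> dropped
  g <- parseGenome(toy$fasta, toy$annotation,
                   list(assembly_id = "toy", genus = "G", species = "S",
                        strain = "T"))
  loci <- extractLinkedLoci(g, upstreamLen = 1000)
  expect_equal(length(loci), 1L)
  expect_equal(loci@metadata$nDiscardedLength, 1L)
  expect_equal(as.character(geneSeq(loci))[[1L]], substr(contig, 5001, 6500))
  expect_equal(as.character(upstreamSeq(loci))[[1L]],
               substr(contig, 4001, 5000))
  expect_false(loci@upstreamTruncated[1L])
})

test_that("minus-strand extraction is the reverse complement round trip", {
  set.seed(4)
  contig <- randSeqChr(8000)
  toyF <- writeToyGenome(contig, list(
    list(start = 2001, end = 3400, strand = "+",
         product = "16S ribosomal RNA")))
  toyR <- writeToyGenome(revcompChr(contig), list(
    list(start = 8000 - 3400 + 1, end = 8000 - 2001 + 1, strand = "-",
         product = "16S ribosomal RNA")))
  lin <- list(assembly_id = "toy", genus = "G", species = "S", strain = "T")
  lf <- extractLinkedLoci(parseGenome(toyF$fasta, toyF$annotation, lin), 800)
  lr <- extractLinkedLoci(parseGenome(toyR$fasta, toyR$annotation, lin), 800)
  expect_equal(as.character(geneSeq(lf)), as.character(geneSeq(lr)),
               ignore_attr = TRUE)
  expect_equal(as.character(upstreamSeq(lf)), as.character(upstreamSeq(lr)),
               ignore_attr = TRUE)
})

test_that("upstream truncation at the contig edge is flagged, not fatal", {
  set.seed(5)
  contig <- randSeqChr(2000)
  toy <- writeToyGenome(contig, list(
    list(start = 501, end = 1800, strand = "+",
         product = "16S ribosomal RNA")))
  loci <- extractLinkedLoci(parseGenome(toy$fasta, toy$annotation, NULL),
                            upstreamLen = 1000)
  expect_true(loci@upstreamTruncated[1L])
  expect_equal(nchar(as.character(upstreamSeq(loci))[[1L]]), 500L)
})

test_that("filterDataset applies wildcard, taxonomy and whole-genome rules", {
  tab <- smallLocusTable()
  loci <- tab$locusSet
  n <- length(loci)

  # wildcard: inject an N into one upstream
  l2 <- loci
  up <- as.character(l2@upstreamSeq)
  up[1] <- sub("^.", "N", up[1])
  l2@upstreamSeq <- Biostrings::DNAStringSet(up)
  f <- filterDataset(l2)
  expect_equal(length(f$loci), n - 1L)
  expect_equal(f$audit$lociRemoved[f$audit$step == "wildcards"], 1L)

  # taxonomy: blank one genome's species drops all its loci
  l3 <- loci
  asm1 <- l3@assemblyId[1]
  l3@lineage$species[l3@assemblyId == asm1] <- NA_character_
  f3 <- filterDataset(l3)
  expect_equal(length(f3$loci), n - sum(loci@assemblyId == asm1))

  # primer QC: one failing locus removes its whole genome
  fail <- rep(FALSE, n)
  fail[which(loci@assemblyId == asm1)[1]] <- TRUE
  f4 <- filterDataset(loci, regionQcFail = fail)
  expect_equal(length(f4$loci), n - sum(loci@assemblyId == asm1))

  # audit conservation: removed + remaining == input
  expect_equal(sum(f4$audit$lociRemoved) + length(f4$loci), n)
})

test_that("retained gene lengths always lie in 1000-2000", {
  tab <- smallLocusTable()
  w <- nchar(tab$loci$gene)
  expect_true(all(w >= 1000 & w <= 2000))
})
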