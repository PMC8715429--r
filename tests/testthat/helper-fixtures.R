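# Fixtures built in code: a toy genome writer and a small cached community.

# Write a single-contig genome FASTA + feature-table annotation and return
# the two paths.
writeToyGenome <- function(contig, features, dir = tempfile("toy")) {
  dir.create(dir, showWarnings = FALSE)
  fa <- file.path(dir, "toy.fasta")
  writeLines(c(">chr1", contig), fa)
  ann <- file.path(dir, "toy.tsv")
  writeLines(
    vapply(features, function(f)
      paste(f$contig %||% "chr1", f$start, f$end, f$strand, f$product,
            sep = "\t"), ""),
    ann)
  list(fasta = fa, annotation = ann, dir = dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

randSeqChr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcompChr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# a small community reused by several files (built once per test run)
smallCommunity <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- communitySpec(nGenera = 2L, speciesPerGenus = 2L,
                            strainsPerSpecies = 2L, copiesPerGenome = 3L,
                            seed = 42L)
      cache <<- generateCommunity(spec)
    }
    cache
  }
})

# cached extraction of smallCommunity() through the file-IO path
smallLocusTable <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- tempfile("comm")
      writeCommunity(smallCommunity(), d)
      cache <<- buildLocusTable(d)
    }
    cache
  }
})

# truth-side locus table (bypasses file IO) for analysis-module tests
truthLocusTable <- function(sim, v1v2Len = 320L) {
  ops <- truthOperons(sim)
  data.frame(locus_id = ops$locus_id, assembly_id = ops$assembly_id,
             genus = as.character(ops$genus),
             species = as.character(ops$species),
             strain = as.character(ops$strain),
             gene = ops$gene_seq, upstream = ops$upstream_seq,
             v1v2 = substr(ops$gene_seq, 1L, v1v2Len),
             stringsAsFactors = FALSE)
}

# brute-force oracle: connected components by repeated sweeps over the
# full boolean adjacency matrix
bruteComponents <- function(adj) {
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        m <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}
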