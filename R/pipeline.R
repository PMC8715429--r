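# Bespoke computational stages of st16S-seq read processing: preprocessing,
# overlap merging, dereplication, swarm-style d-clustering, cluster linkage,
# contig cleanup, per-OTU abundance and copy-number calling.

#' Read paired FASTQ files into a pair table
#'
#' @param r1Path,r2Path paths to the R1 and R2 FASTQ files (gzip accepted).
#' @return data.frame with columns id, r1, r2, q1, q2.
#' @export
readPairedFastq <- function(r1Path, r2Path) {
  f1 <- Biostrings::readDNAStringSet(r1Path, format = "fastq",
                                     with.qualities = TRUE)
  f2 <- Biostrings::readDNAStringSet(r2Path, format = "fastq",
                                     with.qualities = TRUE)
  id1 <- sub("\\s.*$", "", names(f1))
  id2 <- sub("\\s.*$", "", names(f2))
  common <- intersect(id1, id2)
  m1 <- match(common, id1); m2 <- match(common, id2)
  data.frame(id = common,
             r1 = as.character(f1)[m1], r2 = as.character(f2)[m2],
             q1 = as.character(S4Vectors::mcols(f1)$qualities)[m1],
             q2 = as.character(S4Vectors::mcols(f2)$qualities)[m2],
             stringsAsFactors = FALSE)
}

#' Write a pair table as paired FASTQ
#'
#' @param pairs data.frame with columns id, r1, r2, q1, q2.
#' @param r1Path,r2Path output paths (".gz" suffix enables compression).
#' @return invisibly, the two paths.
#' @export
writePairedFastq <- function(pairs, r1Path, r2Path) {
  wr <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(quals),
      compress = grepl("\\.gz$", path))
  }
  wr(pairs$r1, pairs$q1, pairs$id, r1Path)
  wr(pairs$r2, pairs$q2, pairs$id, r2Path)
  invisible(c(r1Path, r2Path))
}

# Hamming-with-offset scan: does `primer` occur within the first `restrict`
# start positions of `seq` with at most `maxMismatch` substitutions?
.primerAtStart <- function(seqs, primer, restrict, maxMismatch) {
  pl <- nchar(primer)
  pat <- Biostrings::DNAString(primer)
  vapply(seqs, function(s) {
    lim <- min(restrict, nchar(s) - pl + 1L)
    if (lim < 1L) return(FALSE)
    hits <- Biostrings::matchPattern(
      pat, Biostrings::DNAString(substr(s, 1L, lim + pl - 1L)),
      max.mismatch = maxMismatch, with.indels = FALSE,
      fixed = c(pattern = FALSE, subject = TRUE))
    length(hits) > 0L
  }, logical(1L), USE.NAMES = FALSE)
}

#' Filter and primer-trim read pairs
#'
#' Drops pairs in which either read is shorter than \code{minLen} or contains
#' an N; drops pairs whose R2 begins with the 16S targeting primer (Hamming
#' distance <= 1 anywhere within the first 40 bases); trims the primer from
#' R1 (edit distance <= 2, search restricted to the first 50 bases),
#' removing everything through the primer end.
#'
#' @param pairs data.frame with columns id, r1, r2, q1, q2.
#' @param primer the 16S targeting primer as it appears at the R1 start.
#' @param minLen minimum read length (default 250).
#' @param r2Restrict,r2MaxMismatch R2 primer-screen window and Hamming budget
#'   (defaults 40 and 1).
#' @param r1Restrict,r1MaxEdit R1 primer-trim search window and edit budget
#'   (defaults 50 and 2).
#' @return list with \code{pairs} (filtered, R1 trimmed) and \code{counts}
#'   (per-rule drop counts).
#' @export
preprocessReads <- function(pairs, primer, minLen = 250L,
                            r2Restrict = 40L, r2MaxMismatch = 1L,
                            r1Restrict = 50L, r1MaxEdit = 2L) {
  counts <- c(input = nrow(pairs), short = 0L, withN = 0L,
              r2Primer = 0L, output = 0L)
  if (nrow(pairs) == 0L)
    return(list(pairs = pairs, counts = counts))
  short <- nchar(pairs$r1) < minLen | nchar(pairs$r2) < minLen
  counts["short"] <- sum(short)
  pairs <- pairs[!short, , drop = FALSE]
  hasN <- grepl("N", pairs$r1, fixed = TRUE) |
    grepl("N", pairs$r2, fixed = TRUE)
  counts["withN"] <- sum(hasN)
  pairs <- pairs[!hasN, , drop = FALSE]
  if (nrow(pairs)) {
    r2hit <- .primerAtStart(pairs$r2, primer, r2Restrict, r2MaxMismatch)
    counts["r2Primer"] <- sum(r2hit)
    pairs <- pairs[!r2hit, , drop = FALSE]
  }
  # trim primer from R1 start
  if (nrow(pairs)) {
    pl <- nchar(primer)
    pat <- Biostrings::DNAString(primer)
    for (i in seq_len(nrow(pairs))) {
      window <- substr(pairs$r1[i], 1L, r1Restrict + pl + r1MaxEdit)
      hits <- Biostrings::matchPattern(
        pat, Biostrings::DNAString(window), max.mismatch = r1MaxEdit,
        with.indels = TRUE, fixed = c(pattern = FALSE, subject = TRUE))
      if (length(hits) && Biostrings::start(hits)[1L] <= r1Restrict) {
        cut <- Biostrings::end(hits)[1L]
        pairs$r1[i] <- substr(pairs$r1[i], cut + 1L, nchar(pairs$r1[i]))
        pairs$q1[i] <- substr(pairs$q1[i], cut + 1L, nchar(pairs$q1[i]))
      }
    }
  }
  counts["output"] <- nrow(pairs)
  list(pairs = pairs, counts = counts)
}

#' Merge overlapping read pairs
#'
#' Finds the best gapless 3' overlap between R1 and the reverse complement of
#' R2 (seeded by the R2 prefix, scored as matches minus twice the
#' mismatches); pairs whose best overlap is at least \code{minOverlap} long
#' with at most \code{maxMismatchFrac} mismatches gain a \code{merged}
#' sequence equal to R1 plus the non-overlapping tail of the
#' reverse-complemented R2. Disagreements inside the overlap are resolved
#' toward the higher-quality base.
#'
#' @param pairs data.frame with columns id, r1, r2, q1, q2.
#' @param minOverlap minimum overlap length (default 20).
#' @param maxMismatchFrac maximum mismatch fraction in the overlap (default
#'   0.1).
#' @return the input with an added \code{merged} column (NA when unmerged).
#' @export
mergeOverlaps <- function(pairs, minOverlap = 20L, maxMismatchFrac = 0.1) {
  pairs$merged <- NA_character_
  if (nrow(pairs) == 0L) return(pairs)
  rc2 <- .revcomp(pairs$r2)
  qc2 <- vapply(pairs$q2, function(q)
    paste(rev(strsplit(q, "")[[1L]]), collapse = ""), "",
    USE.NAMES = FALSE)
  for (i in seq_len(nrow(pairs))) {
    r1 <- pairs$r1[i]; r2 <- rc2[i]
    n1 <- nchar(r1); n2 <- nchar(r2)
    if (n1 < minOverlap || n2 < minOverlap) next
    seed <- substr(r2, 1L, minOverlap)
    hits <- Biostrings::matchPattern(
      seed, Biostrings::DNAString(r1), max.mismatch = 2L,
      with.indels = FALSE)
    if (length(hits) == 0L) next
    a1 <- strsplit(r1, "")[[1L]]
    a2 <- strsplit(r2, "")[[1L]]
    best <- NULL
    for (s in Biostrings::start(hits)) {
      if (s < 1L || s > n1) next  # edge hits padded by mismatches
      ov <- min(n1 - s + 1L, n2)
      if (ov < minOverlap) next
      mm <- sum(a1[s:(s + ov - 1L)] != a2[1:ov])
      if (mm / ov > maxMismatchFrac) next
      sc <- ov - 2 * mm
      if (is.null(best) || sc > best$sc) best <- list(s = s, ov = ov, mm = mm,
                                                      sc = sc)
    }
    if (is.null(best)) next
    s <- best$s; ov <- best$ov
    # resolve overlap disagreements toward the higher-quality base
    ovIdx <- which(a1[s:(s + ov - 1L)] != a2[1:ov])
    if (length(ovIdx)) {
      q1c <- strsplit(pairs$q1[i], "")[[1L]]
      q2c <- strsplit(qc2[i], "")[[1L]]
      for (o in ovIdx) {
        if (utf8ToInt(q2c[o]) > utf8ToInt(q1c[s + o - 1L]))
          a1[s + o - 1L] <- a2[o]
      }
    }
    tail_ <- if (ov < n2) substr(r2, ov + 1L, n2) else ""
    pairs$merged[i] <- paste0(paste(a1[1:(s + ov - 1L)], collapse = ""),
                              tail_)
  }
  pairs
}

#' Exact dereplication
#'
#' Collapses identical sequences (after uppercasing), preserving total count,
#' ordered by decreasing size with lexicographic tie-break.
#'
#' @param seqs character vector.
#' @param names_ optional read names (default seq_along).
#' @return data.frame with columns seq and size; attribute \code{members} is
#'   the list of read names per unique sequence.
#' @export
dereplicate <- function(seqs, names_ = NULL) {
  if (is.null(names_)) names_ <- as.character(seq_along(seqs))
  seqs <- toupper(seqs)
  groups <- split(names_, seqs)
  sizes <- lengths(groups)
  ord <- order(-sizes, names(groups))
  out <- data.frame(seq = names(groups)[ord],
                    size = as.integer(sizes[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "members") <- unname(groups[ord])
  out
}

#' Swarm-style d-clustering of dereplicated sequences
#'
#' Iterative single-linkage agglomeration: the highest-abundance unassigned
#' unique sequence seeds a cluster, any unique sequence within edit distance
#' d of any cluster member is attached, and attachment repeats to closure.
#' d = 0 reproduces the dereplication classes.
#'
#' @param uniques data.frame from \code{\link{dereplicate}} (columns seq,
#'   size).
#' @param d maximum edit distance for attachment (typically 1 or 2).
#' @return integer vector of cluster ids (1 = first-seeded), one per unique
#'   sequence.
#' @export
swarmCluster <- function(uniques, d) {
  n <- nrow(uniques)
  if (n == 0L) return(integer(0))
  assigned <- rep(NA_integer_, n)
  cl <- 0L
  nb <- if (d > 0L && n > 1L) .editNeighbors(uniques$seq, d) else
    rep(list(integer(0)), n)
  for (i in seq_len(n)) {
    if (!is.na(assigned[i])) next
    cl <- cl + 1L
    assigned[i] <- cl
    frontier <- i
    while (length(frontier)) {
      hit <- setdiff(unique(unlist(nb[frontier])), which(!is.na(assigned)))
      assigned[hit] <- cl
      frontier <- hit
    }
  }
  assigned
}

# neighbour lists under edit distance <= d, pruned by sequence length
# (|len_i - len_j| > d already implies distance > d)
.editNeighbors <- function(seqs, d) {
  n <- length(seqs)
  lens <- nchar(seqs)
  nb <- vector("list", n)
  ord <- order(lens)
  for (oi in seq_len(n)) {
    i <- ord[oi]
    cand <- ord[seq_len(n) > oi]
    cand <- cand[lens[cand] - lens[i] <= d]
    if (!length(cand)) next
    dd <- as.integer(utils::adist(seqs[i], seqs[cand]))
    hit <- cand[dd <= d]
    if (length(hit)) {
      nb[[i]] <- c(nb[[i]], hit)
      for (h in hit) nb[[h]] <- c(nb[[h]], i)
    }
  }
  nb
}

#' Link two read clusterings
#'
#' Builds the \linkS4class{ClusterLinkage} between deduplicated merged-read
#' clusters (b-clusters) and forward-prefix clusters (a-clusters); a-clusters
#' holding fewer than \code{minClusterFrac} of the filtered read pairs are
#' flagged not-for-assembly.
#'
#' @param bClusters list of character vectors of read names.
#' @param aClusters named list of character vectors of read names.
#' @param totalPairs filtered read-pair count (defaults to the a-cluster
#'   universe size).
#' @param minClusterFrac flag threshold (default 0.001).
#' @return a \linkS4class{ClusterLinkage}.
#' @export
linkClusterings <- function(bClusters, aClusters, totalPairs = NULL,
                            minClusterFrac = 0.001) {
  if (is.null(totalPairs)) totalPairs <- length(unique(unlist(aClusters)))
  if (is.null(names(aClusters)) && length(aClusters))
    names(aClusters) <- paste0("a", seq_along(aClusters))
  new("ClusterLinkage", bClusters = bClusters, aClusters = aClusters,
      totalPairs = as.integer(totalPairs),
      minClusterFrac = minClusterFrac)
}

#' a-clusters flagged for assembly
#'
#' @param linkage a \linkS4class{ClusterLinkage}.
#' @return named logical: TRUE when the a-cluster holds at least
#'   \code{minClusterFrac} of the filtered read pairs.
#' @export
forAssembly <- function(linkage) {
  lengths(linkage@aClusters) >= linkage@minClusterFrac * linkage@totalPairs
}

#' Per-OTU relative abundance a_f
#'
#' For an a-cluster a, \deqn{a_f = \frac{1}{j} \sum_{b}
#' \frac{n(b \cap a)}{n(b)}} summing over the j b-clusters. When the
#' a-clusters partition the union of the b-clusters, the a_f values sum to 1.
#'
#' @param linkage a \linkS4class{ClusterLinkage}.
#' @return named numeric of a_f values, one per a-cluster.
#' @export
abundanceAf <- function(linkage) {
  j <- length(linkage@bClusters)
  if (j < 1L) .stopf("need at least one b-cluster")
  if (any(lengths(linkage@bClusters) == 0L)) .stopf("empty b-cluster")
  vapply(linkage@aClusters, function(a) {
    sum(vapply(linkage@bClusters, function(b) {
      length(intersect(b, a)) / length(b)
    }, numeric(1L))) / j
  }, numeric(1L))
}

#' Within-cluster contig cleanup
#'
#' Applies, in order: (i) clustering of the contigs' first 230 bp
#' (single-linkage at edit distance 2, then 96 % identity), keeping only the
#' dominant cluster; (ii) removal of contigs shorter than 52 % of the
#' maximum contig length; (iii) removal of contigs contained within a longer
#' contig, i.e. whose fragment excluding the last 20 bp aligns at more than
#' 98 % identity with an aligned fraction of at least 0.9 of the whole
#' contig's length.
#'
#' @param contigs data.frame with columns id, seq and (optionally) abundance.
#' @param prefixLen 5'-prefix length for step (i) (default 230).
#' @param prefixD edit-distance linkage for step (i) (default 2).
#' @param prefixIdentity identity linkage for step (i) (default 0.96).
#' @param minLenFrac step (ii) length fraction (default 0.52).
#' @param containIdentity,containFraction,excl3p step (iii) thresholds
#'   (defaults 0.98, 0.9 and 20).
#' @return list with \code{contigs} (retained rows) and \code{log}
#'   (data.frame of per-rule discards).
#' @export
cleanupWithinCluster <- function(contigs, prefixLen = 230L, prefixD = 2L,
                                 prefixIdentity = 0.96, minLenFrac = 0.52,
                                 containIdentity = 0.98,
                                 containFraction = 0.9, excl3p = 20L) {
  if (is.null(contigs$abundance)) contigs$abundance <- 1
  log_ <- data.frame(id = character(0), rule = character(0),
                     stringsAsFactors = FALSE)
  note <- function(ids, rule) {
    if (length(ids))
      log_ <<- rbind(log_, data.frame(id = ids, rule = rule,
                                      stringsAsFactors = FALSE))
  }
  if (nrow(contigs) == 0L) return(list(contigs = contigs, log = log_))

  # (i) 5'-prefix clustering; keep dominant cluster
  pref <- substr(contigs$seq, 1L, prefixLen)
  n <- nrow(contigs)
  if (n > 1L) {
    dm <- .editDist(pref)
    lens <- outer(nchar(pref), nchar(pref), pmax)
    link <- dm <= prefixD | (1 - dm / lens) >= prefixIdentity
    comp <- .components(link)
    sizes <- tapply(contigs$abundance, comp, sum)
    dominant <- as.integer(names(sizes)[which.max(sizes)])
    note(contigs$id[comp != dominant], "atypical-5prime")
    contigs <- contigs[comp == dominant, , drop = FALSE]
  }

  # (ii) short contigs
  maxLen <- max(nchar(contigs$seq))
  short <- nchar(contigs$seq) < minLenFrac * maxLen
  note(contigs$id[short], "short")
  contigs <- contigs[!short, , drop = FALSE]

  # (iii) containment
  if (nrow(contigs) > 1L) {
    ord <- order(-nchar(contigs$seq))
    contigs <- contigs[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(contigs))
    for (i in 2:nrow(contigs)) {
      n_i <- nchar(contigs$seq[i])
      for (j in seq_len(i - 1L)) {
        if (!keep[j] || nchar(contigs$seq[j]) <= n_i) next
        aln <- .overlapAlign(contigs$seq[i], contigs$seq[j])
        if (aln$alignedFraction >= containFraction &&
            .headIdentity(aln, excl3p, n_i) > containIdentity) {
          keep[i] <- FALSE
          note(contigs$id[i], "contained")
          break
        }
      }
    }
    contigs <- contigs[keep, , drop = FALSE]
  }
  list(contigs = contigs, log = log_)
}

# connected components of a logical adjacency matrix (single linkage)
.components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cl <- cl + 1L
    frontier <- i
    comp[i] <- cl
    while (length(frontier)) {
      cand <- which(is.na(comp))
      if (!length(cand)) break
      hit <- cand[colSums(adj[frontier, cand, drop = FALSE]) > 0L]
      comp[hit] <- cl
      frontier <- hit
    }
  }
  comp
}

#' Global contig cleanup against a reference catalog
#'
#' Contigs from all source clusters are aligned against a labelled reference
#' catalog. A contig is kept when its best reference alignment covers at
#' least 90 % of the contig's length, starts by the fifth base from the
#' contig's 5' terminus, and the matched reference region contains fewer
#' than 5 Ns. Each contig is assigned the genus of its best match; within
#' each source cluster only contigs of the genus with the largest median
#' contig length survive, and contig 3' ends extending beyond the matched
#' region are trimmed. A final containment pass discards a contig contained
#' in a longer one at >= 96 % identity across 99 % of its length, unless the
#' 3'-terminal 15 bp or 50 bp window identity falls below 80 % (the
#' diverging-copy rescue); equal-length contigs meeting the containment
#' criteria are resolved toward the higher abundance.
#'
#' @param contigSets named list (by source cluster) of data.frames with
#'   columns id, seq, abundance.
#' @param catalog data.frame with columns name, genus and seq (reference
#'   sequences in contig orientation).
#' @param minAlignedFrac,maxStartOffset,maxRefN reference-match thresholds
#'   (defaults 0.9, 5, 5).
#' @param containIdentity,containCoverage containment thresholds (defaults
#'   0.96, 0.99).
#' @param rescueWindows,rescueIdentity 3'-rescue windows and threshold
#'   (defaults c(15, 50) and 0.80).
#' @return list with \code{contigs} (data.frame id, seq, abundance, genus,
#'   sourceCluster) and \code{log}.
#' @export
cleanupGlobal <- function(contigSets, catalog, minAlignedFrac = 0.9,
                          maxStartOffset = 5L, maxRefN = 5L,
                          containIdentity = 0.96, containCoverage = 0.99,
                          rescueWindows = c(15L, 50L),
                          rescueIdentity = 0.80) {
  if (nrow(catalog) == 0L) .stopf("empty reference catalog")
  log_ <- data.frame(id = character(0), rule = character(0),
                     stringsAsFactors = FALSE)
  note <- function(ids, rule) {
    if (length(ids))
      log_ <<- rbind(log_, data.frame(id = ids, rule = rule,
                                      stringsAsFactors = FALSE))
  }
  rows <- list()
  for (srcName in names(contigSets)) {
    cs <- contigSets[[srcName]]
    if (is.null(cs) || nrow(cs) == 0L) next
    if (is.null(cs$abundance)) cs$abundance <- 1
    for (i in seq_len(nrow(cs))) {
      best <- NULL
      for (r in seq_len(nrow(catalog))) {
        aln <- .overlapAlign(cs$seq[i], catalog$seq[r])
        if (is.null(best) || aln$score > best$aln$score)
          best <- list(aln = aln, ref = r)
      }
      aln <- best$aln
      refSeq <- catalog$seq[best$ref]
      refRegion <- substr(refSeq, aln$subjectStart, aln$subjectEnd)
      nN <- lengths(regmatches(refRegion, gregexpr("N", refRegion)))
      ok <- aln$alignedFraction >= minAlignedFrac &&
        aln$patternStart <= maxStartOffset && nN < maxRefN
      if (!ok) {
        note(cs$id[i], "no-reference-match")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        id = cs$id[i],
        seq = substr(cs$seq[i], 1L, aln$patternEnd),  # trim 3' overhang
        abundance = cs$abundance[i],
        genus = catalog$genus[best$ref],
        sourceCluster = srcName, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(list(contigs = data.frame(id = character(0), seq = character(0),
                                     abundance = numeric(0),
                                     genus = character(0),
                                     sourceCluster = character(0)),
                log = log_))
  contigs <- do.call(rbind, rows)

  # typical genus per source cluster: largest median contig length
  keep <- rep(TRUE, nrow(contigs))
  for (srcName in unique(contigs$sourceCluster)) {
    idx <- which(contigs$sourceCluster == srcName)
    med <- tapply(nchar(contigs$seq[idx]), contigs$genus[idx], stats::median)
    typical <- names(med)[which.max(med)]
    bad <- idx[contigs$genus[idx] != typical]
    note(contigs$id[bad], "atypical-genus")
    keep[bad] <- FALSE
  }
  contigs <- contigs[keep, , drop = FALSE]

  # global containment with 3'-divergence rescue
  if (nrow(contigs) > 1L) {
    ord <- order(-nchar(contigs$seq), -contigs$abundance)
    contigs <- contigs[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(contigs))
    for (i in 2:nrow(contigs)) {
      n_i <- nchar(contigs$seq[i])
      for (j in seq_len(i - 1L)) {
        if (!keep[j]) next
        n_j <- nchar(contigs$seq[j])
        if (n_j < n_i) next
        aln <- .overlapAlign(contigs$seq[i], contigs$seq[j])
        contained <- aln$identity >= containIdentity &&
          aln$alignedFraction >= containCoverage
        if (!contained) next
        rescued <- any(vapply(rescueWindows, function(w)
          .tailIdentity(aln, w, n_i) < rescueIdentity, logical(1L)))
        if (rescued) next
        if (n_j == n_i) {
          # same length: keep the higher abundance (j is >= by ordering)
          keep[i] <- FALSE
          note(contigs$id[i], "duplicate-lower-abundance")
        } else {
          keep[i] <- FALSE
          note(contigs$id[i], "contained")
        }
        break
      }
    }
    contigs <- contigs[keep, , drop = FALSE]
  }
  rownames(contigs) <- NULL
  list(contigs = contigs, log = log_)
}

#' Call 16S copy numbers from cleaned contigs
#'
#' The detected copy number of a group equals the number of retained contigs
#' assigned to it.
#'
#' @param cleaned result of \code{\link{cleanupGlobal}} (or a data.frame with
#'   a grouping column).
#' @param groupBy grouping column (default \code{"genus"}).
#' @return named integer of contig counts per group (0-row input yields an
#'   empty vector).
#' @export
callCopyNumber <- function(cleaned, groupBy = "genus") {
  contigs <- if (is.data.frame(cleaned)) cleaned else cleaned$contigs
  if (nrow(contigs) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(contigs[[groupBy]])
  stats::setNames(as.integer(tab), names(tab))
}
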