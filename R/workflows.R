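# Orchestration of the two workflows: the in-silico analysis of genomes and
# the semi-targeted read pipeline.

#' Build the per-locus analysis table from files on disk
#'
#' Runs extraction, primer mapping and dataset filtering over a directory of
#' assemblies, producing the table consumed by the conservation,
#' identifiability, OTU and classification analyses.
#'
#' @param manifest data.frame with columns assembly_id, fasta, gff (as
#'   written by \code{\link{writeCommunity}}), or a directory containing
#'   \code{<assembly>.fasta} / \code{<assembly>.gff3} and
#'   \code{lineage.tsv}.
#' @param lineage lineage table (data.frame); read from the directory when
#'   \code{manifest} is a path.
#' @param primerSet primer table (default \code{\link{defaultPrimerSet}}).
#' @param upstreamLen upstream window (default 1000).
#' @return list with \code{loci} (data.frame: locus_id, assembly_id, genus,
#'   species, strain, gene, upstream, v1v2), \code{audit} and
#'   \code{regionMaps}.
#' @export
buildLocusTable <- function(manifest, lineage = NULL,
                            primerSet = defaultPrimerSet(),
                            upstreamLen = 1000L) {
  if (is.character(manifest) && length(manifest) == 1L) {
    dir <- manifest
    lineage <- readLineageTable(file.path(dir, "lineage.tsv"))
    manifest <- data.frame(
      assembly_id = lineage$assembly_id,
      fasta = file.path(dir, paste0(lineage$assembly_id, ".fasta")),
      gff = file.path(dir, paste0(lineage$assembly_id, ".gff3")),
      stringsAsFactors = FALSE)
  }
  stopifnot(!is.null(lineage))
  sets <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- lineage[lineage$assembly_id == manifest$assembly_id[i], ,
                   drop = FALSE]
    g <- parseGenome(manifest$fasta[i], manifest$gff[i],
                     if (nrow(row)) row[1L, ] else NULL)
    extractLinkedLoci(g, upstreamLen = upstreamLen)
  })
  loci <- combineLoci(sets)
  maps <- mapRegions(loci, primerSet)
  qcFail <- vapply(maps[loci@locusId], function(m) isTRUE(m$rejected),
                   logical(1L))
  filt <- filterDataset(loci, regionQcFail = qcFail)
  loci <- filt$loci
  v1v2 <- regionComposite(loci, maps, region = "V1V2")
  df <- data.frame(locus_id = loci@locusId,
                   assembly_id = loci@assemblyId,
                   genus = as.character(loci@lineage$genus),
                   species = as.character(loci@lineage$species),
                   strain = as.character(loci@lineage$strain),
                   gene = as.character(geneSeq(loci)),
                   upstream = as.character(upstreamSeq(loci)),
                   v1v2 = unname(v1v2[loci@locusId]),
                   stringsAsFactors = FALSE)
  list(loci = df, audit = filt$audit, regionMaps = maps, locusSet = loci)
}

#' Run the in-silico analysis workflow
#'
#' extract -> regions -> entropy -> identifiability -> OTU metrics ->
#' leave-clade-out classification, writing JSON/TSV reports plus a manifest
#' of input file hashes.
#'
#' @param genomeDir directory with assemblies, GFF3s and lineage.tsv.
#' @param outDir report directory (created).
#' @param seed seed forwarded to every random operation.
#' @param upstreamPrefix upstream prefix length for the near-16S composite
#'   (default 400).
#' @param thresholds OTU thresholds (default 0.90 to 0.99 by 0.01).
#' @param primerSet primer table.
#' @return invisibly, the report list.
#' @export
runInsilico <- function(genomeDir, outDir, seed = 1L, upstreamPrefix = 400L,
                        thresholds = seq(0.90, 0.99, 0.01),
                        primerSet = defaultPrimerSet()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- "extract"
  res <- tryCatch({
    tab <- buildLocusTable(genomeDir, primerSet = primerSet)
    loci <- tab$loci
    writeAuditLog(tab$audit, file.path(outDir, "audit.jsonl"))
    stage <- "regions"
    writeRegionTable(tab$regionMaps, file.path(outDir, "regions.tsv"))

    stage <- "entropy"
    nearSpec <- function(df) {
      L <- upstreamPrefix
      ok <- nchar(df$upstream) >= L & !is.na(df$v1v2)
      df <- df[ok, , drop = FALSE]
      df$seq <- paste0(substr(df$upstream, nchar(df$upstream) - L + 1L,
                              nchar(df$upstream)), df$v1v2)
      df
    }
    entGene <- rankEntropyDistribution(
      transform(loci, seq = gene), rank = "genus", seed = seed)
    entUp <- rankEntropyDistribution(
      transform(loci, seq = upstream), rank = "genus", seed = seed)
    utils::write.table(
      rbind(cbind(region = "gene", entGene),
            cbind(region = "upstream", entUp)),
      file.path(outDir, "entropy.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)

    stage <- "identifiability"
    near <- nearSpec(loci)
    ident <- lapply(c("intra_strain", "inter_strain", "inter_species"),
                    function(lv) {
      r <- copyIdentifiability(near, level = lv, seed = seed)
      list(level = lv, meanFraction = r$meanFraction,
           perMember = as.list(r$perMember))
    })
    jsonlite::write_json(ident, file.path(outDir, "identifiability.json"),
                         auto_unbox = TRUE, digits = NA)

    stage <- "otus"
    sweep <- optimalThresholdSweep(transform(near, seq = seq),
                                   thresholds = thresholds, seed = seed)
    utils::write.table(sweep$table, file.path(outDir, "otus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "classify-cv"
    cv <- leaveCladeOutCV(near, seed = seed)
    jsonlite::write_json(cv, file.path(outDir, "classification.json"),
                         auto_unbox = TRUE, digits = NA)

    stage <- "manifest"
    files <- list.files(genomeDir, full.names = TRUE)
    manifest <- data.frame(file = basename(files),
                           md5 = tools::md5sum(files),
                           stringsAsFactors = FALSE)
    utils::write.table(manifest, file.path(outDir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(loci = loci, identifiability = ident, otus = sweep,
         classification = cv)
  }, error = function(e) {
    .stopf("in-silico workflow failed at stage '%s': %s", stage,
           conditionMessage(e), class = "near16S_stage_error")
  })
  invisible(res)
}

# most abundant unique 5'-prefix per a-cluster, used to anchor contigs
.clusterRepresentatives <- function(aAssign, aUniques) {
  vapply(seq_len(max(aAssign)), function(cl) {
    aUniques$seq[which(aAssign == cl)[1L]]  # uniques are size-desc ordered
  }, "")
}

#' Run the semi-targeted read pipeline
#'
#' preprocess -> merge -> dereplicate -> swarm -> link -> cleanup ->
#' abundance -> copy numbers. Contigs are supplied externally (from any
#' assembler, or the simulator's truth-derived fragments); the pipeline
#' assigns them to forward-prefix clusters, cleans them within and across
#' clusters against the reference catalog, and reports per-genus a_f
#' abundances, detected copy numbers and copy-number-corrected abundances.
#'
#' @param pairs read-pair table (id, r1, r2, q1, q2).
#' @param contigs data.frame with columns id, seq (and optional abundance).
#' @param catalog reference catalog (name, genus, seq).
#' @param primer extension primer as at the R1 start (default
#'   \code{\link{extensionPrimer}}).
#' @param d1 swarm d for merged-read (b) clustering (default 1).
#' @param d2 swarm d for forward-prefix (a) clustering (default 2).
#' @param prefixA forward-prefix length for a-clustering (default 240).
#' @param minClusterFrac minimum a-cluster read fraction for assembly
#'   (default 0.001).
#' @param minLen preprocessing length cutoff (default 250).
#' @return list with \code{counts}, \code{linkage}, \code{af} (per
#'   a-cluster), \code{cleaned}, \code{copyNumber} (per genus),
#'   \code{abundance} (per-genus table: af, copyNumber, corrected).
#' @export
runPipeline <- function(pairs, contigs, catalog,
                        primer = extensionPrimer(), d1 = 1L, d2 = 2L,
                        prefixA = 240L, minClusterFrac = 0.001,
                        minLen = 250L) {
  pre <- preprocessReads(pairs, primer, minLen = minLen)
  pp <- pre$pairs
  if (nrow(pp) == 0L)
    return(list(counts = pre$counts, linkage = NULL,
                af = numeric(0), cleaned = NULL,
                copyNumber = integer(0),
                abundance = data.frame(genus = character(0), af = numeric(0),
                                       copyNumber = integer(0),
                                       corrected = numeric(0))))
  pp <- mergeOverlaps(pp)

  # quantification route: merged reads -> derep -> swarm d1 -> b-clusters
  merged <- pp[!is.na(pp$merged), , drop = FALSE]
  bU <- dereplicate(merged$merged, merged$id)
  bAssign <- swarmCluster(bU, d1)
  bMembers <- attr(bU, "members")
  bClusters <- lapply(split(seq_len(nrow(bU)), bAssign),
                      function(ix) unlist(bMembers[ix], use.names = FALSE))

  # assembly route: forward 5'-prefixes -> derep -> swarm d2 -> a-clusters
  pref <- substr(pp$r1, 1L, prefixA)
  aU <- dereplicate(pref, pp$id)
  aAssign <- swarmCluster(aU, d2)
  aMembers <- attr(aU, "members")
  aClusters <- lapply(split(seq_len(nrow(aU)), aAssign),
                      function(ix) unlist(aMembers[ix], use.names = FALSE))
  names(aClusters) <- paste0("a", seq_along(aClusters))

  linkage <- linkClusterings(bClusters, aClusters, totalPairs = nrow(pp),
                             minClusterFrac = minClusterFrac)
  af <- if (length(bClusters)) abundanceAf(linkage) else numeric(0)

  # assign external contigs to for-assembly a-clusters via their 5' prefixes
  useA <- which(forAssembly(linkage))
  reps <- .clusterRepresentatives(aAssign, aU)
  contigSets <- stats::setNames(
    rep(list(NULL), length(useA)), names(aClusters)[useA])
  if (length(useA) && nrow(contigs)) {
    cpref <- substr(contigs$seq, 1L, prefixA)
    dm <- .editDist(cpref, reps[useA])
    best <- apply(dm, 1L, which.min)
    for (i in seq_len(nrow(contigs))) {
      cl <- names(aClusters)[useA[best[i]]]
      contigSets[[cl]] <- rbind(contigSets[[cl]], contigs[i, , drop = FALSE])
    }
  }
  cleanedSets <- lapply(contigSets, function(cs) {
    if (is.null(cs)) NULL else cleanupWithinCluster(cs)$contigs
  })
  cleaned <- cleanupGlobal(cleanedSets[!vapply(cleanedSets, is.null,
                                               logical(1L))], catalog)
  copyNumber <- callCopyNumber(cleaned)

  # per-genus abundance: sum a_f over clusters assigned to the genus
  clusterGenus <- unique(cleaned$contigs[c("sourceCluster", "genus")])
  afGenus <- stats::setNames(numeric(0), character(0))
  for (g in unique(clusterGenus$genus)) {
    cls <- clusterGenus$sourceCluster[clusterGenus$genus == g]
    afGenus[g] <- sum(af[cls])
  }
  corrected <- afGenus / copyNumber[names(afGenus)]
  corrected <- corrected / sum(corrected)
  abundance <- data.frame(genus = names(afGenus),
                          af = unname(afGenus),
                          copyNumber = unname(copyNumber[names(afGenus)]),
                          corrected = unname(corrected),
                          stringsAsFactors = FALSE)
  list(counts = pre$counts, linkage = linkage, af = af, cleaned = cleaned,
       copyNumber = copyNumber, abundance = abundance)
}
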