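# Identifiable 16S gene copies, identifiable strains, and
# nearest-non-identical-sequence distances.

.capSample <- function(x, k) if (length(x) <= k) x else sample(x, k)

.applyIdentifiabilityCaps <- function(loci, level, maxStrainsPerSpecies,
                                      maxSpeciesPerGenus) {
  # strains limited per species at every level
  keep <- logical(nrow(loci))
  for (sp in unique(loci$species)) {
    idx <- which(loci$species == sp)
    strains <- .capSample(unique(loci$strain[idx]), maxStrainsPerSpecies)
    keep[idx[loci$strain[idx] %in% strains]] <- TRUE
  }
  loci <- loci[keep, , drop = FALSE]
  if (level %in% c("inter_strain", "inter_species")) {
    # only species with at least two strains
    nStrains <- tapply(loci$strain, loci$species,
                       function(s) length(unique(s)))
    loci <- loci[loci$species %in% names(nStrains)[nStrains >= 2L], ,
                 drop = FALSE]
  }
  if (level == "inter_species") {
    keep <- logical(nrow(loci))
    for (g in unique(loci$genus)) {
      idx <- which(loci$genus == g)
      spp <- .capSample(unique(loci$species[idx]), maxSpeciesPerGenus)
      keep[idx[loci$species[idx] %in% spp]] <- TRUE
    }
    loci <- loci[keep, , drop = FALSE]
  }
  loci
}

#' Fraction of identifiable 16S gene copies
#'
#' Per member of the comparison level, the fraction of identifiable copies is
#' the number of unique composite sequence variants divided by the total
#' number of copies; the statistic is the mean over members. Members are
#' strains (intra-strain), species pooling their strains' copies
#' (inter-strain; only species with at least two strains), or genera pooling
#' their species (inter-species). Caps: at most
#' \code{maxStrainsPerSpecies} strains per species at every level, and at
#' most \code{maxSpeciesPerGenus} species per genus at the inter-species
#' level; sampling under the caps is uniform at the given seed.
#'
#' @param loci data.frame with columns genus, species, strain and seq (the
#'   composite sequence of each gene copy).
#' @param level \code{"intra_strain"}, \code{"inter_strain"} or
#'   \code{"inter_species"}.
#' @param maxStrainsPerSpecies,maxSpeciesPerGenus caps (default 10 each).
#' @param seed RNG seed for cap sampling.
#' @return list with \code{level}, \code{perMember} (named fractions) and
#'   \code{meanFraction}; members without sequences are excluded.
#' @export
copyIdentifiability <- function(loci,
                                level = c("intra_strain", "inter_strain",
                                          "inter_species"),
                                maxStrainsPerSpecies = 10L,
                                maxSpeciesPerGenus = 10L, seed = 1L) {
  level <- match.arg(level)
  set.seed(seed)
  loci <- loci[!is.na(loci$seq), , drop = FALSE]
  loci <- .applyIdentifiabilityCaps(loci, level, maxStrainsPerSpecies,
                                    maxSpeciesPerGenus)
  memberCol <- switch(level, intra_strain = "strain",
                      inter_strain = "species", inter_species = "genus")
  if (nrow(loci) == 0L)
    return(list(level = level, perMember = numeric(0),
                meanFraction = NA_real_))
  frac <- tapply(loci$seq, loci[[memberCol]],
                 function(s) length(unique(s)) / length(s))
  frac <- stats::setNames(as.numeric(frac), names(frac))
  list(level = level, perMember = frac, meanFraction = mean(frac))
}

#' Fraction of identifiable strains per species
#'
#' A strain is identifiable when at least one of its copies carries a
#' composite sequence that appears in no other strain of the same species.
#'
#' @param loci data.frame with columns species, strain and seq.
#' @return named numeric: per species (with >= 2 strains), the fraction of
#'   identifiable strains.
#' @export
strainIdentifiability <- function(loci) {
  loci <- loci[!is.na(loci$seq), , drop = FALSE]
  out <- c()
  for (sp in unique(loci$species)) {
    sel <- loci[loci$species == sp, , drop = FALSE]
    strains <- unique(sel$strain)
    if (length(strains) < 2L) next
    ident <- vapply(strains, function(st) {
      own <- unique(sel$seq[sel$strain == st])
      others <- sel$seq[sel$strain != st]
      any(!(own %in% others))
    }, logical(1L))
    out[sp] <- mean(ident)
  }
  out
}

#' Identifiability as a function of upstream fragment length
#'
#' Composites are \code{upstream_prefix(L) + V1V2}; loci whose upstream
#' window is shorter than L are excluded (default) or kept with the full
#' available prefix when \code{truncatedAction = "flag"}.
#'
#' @param loci data.frame with columns genus, species, strain, upstream and
#'   v1v2 (plain sequences).
#' @param lengths upstream prefix lengths, ascending (bases).
#' @param level comparison level, see \code{\link{copyIdentifiability}}.
#' @param truncatedAction \code{"exclude"} or \code{"flag"}.
#' @param seed RNG seed passed through to the cap sampling.
#' @return named numeric: mean identifiable fraction per length.
#' @export
upstreamLengthSweep <- function(loci, lengths = c(0L, 200L, 400L, 600L,
                                                  800L, 1000L),
                                level = "intra_strain",
                                truncatedAction = c("exclude", "flag"),
                                seed = 1L) {
  truncatedAction <- match.arg(truncatedAction)
  stopifnot(!is.unsorted(lengths))
  out <- stats::setNames(numeric(length(lengths)), as.character(lengths))
  for (i in seq_along(lengths)) {
    L <- lengths[i]
    nu <- nchar(loci$upstream)
    if (truncatedAction == "exclude") {
      sel <- loci[nu >= L, , drop = FALSE]
      pre <- substr(sel$upstream, nchar(sel$upstream) - L + 1L,
                    nchar(sel$upstream))
    } else {
      sel <- loci
      pre <- substr(sel$upstream, pmax(1L, nu - L + 1L), nu)
    }
    sel$seq <- paste0(pre, sel$v1v2)
    out[i] <- copyIdentifiability(sel, level = level,
                                  seed = seed)$meanFraction
  }
  out
}

#' Distances to the closest non-identical sequences
#'
#' For sampled query sequences, computes edit distances (substitutions +
#' indels) to every distinct sequence in the set, skips identical sequences
#' (distance 0), and reports the k smallest distances per query.
#'
#' @param seqs character vector of sequences.
#' @param nQueries number of uniformly sampled queries (default
#'   \code{min(1000, length(seqs))}).
#' @param k neighbours per query (default 5).
#' @param seed RNG seed for query sampling.
#' @return list with \code{queries} (indices), \code{distances} (list of up
#'   to k sorted distances per query) and \code{short} (logical flag when
#'   fewer than k non-identical neighbours exist).
#' @export
nearestNonidenticalDistances <- function(seqs, nQueries = NULL, k = 5L,
                                         seed = 1L) {
  set.seed(seed)
  n <- length(seqs)
  if (is.null(nQueries)) nQueries <- min(1000L, n)
  stopifnot(nQueries <= n)
  qi <- sort(.capSample(seq_len(n), nQueries))
  uni <- unique(seqs)
  d <- .editDist(seqs[qi], uni)
  dists <- vector("list", length(qi))
  short <- logical(length(qi))
  for (i in seq_along(qi)) {
    di <- sort(d[i, d[i, ] > 0])
    if (length(di) < k) short[i] <- TRUE
    dists[[i]] <- utils::head(di, k)
  }
  list(queries = qi, distances = dists, short = short)
}
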