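# Internal sequence helpers shared across modules.

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.randSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitution mutagenesis at a fixed per-site rate; positions restricted to
# `sites` when given (1-based). Returns the mutated string.
.mutateSeq <- function(seq, rate, sites = NULL) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (is.null(sites)) sites <- seq_along(chars)
  hit <- sites[stats::runif(length(sites)) < rate]
  if (length(hit)) {
    for (i in hit) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    }
  }
  paste(chars, collapse = "")
}

# IUPAC-aware base compatibility matrix: +1 when the primer letter's expansion
# contains the subject base, -2 otherwise (blastn-short-like scoring).
.iupacScoreMatrix <- function(match = 1, mismatch = -2) {
  codes <- Biostrings::IUPAC_CODE_MAP
  letters_ <- names(codes)
  m <- matrix(mismatch, length(letters_), 4,
              dimnames = list(letters_, c("A", "C", "G", "T")))
  for (p in letters_) {
    exp <- strsplit(codes[[p]], "", fixed = TRUE)[[1L]]
    m[p, intersect(exp, colnames(m))] <- match
  }
  m
}

.iupacCompatible <- function(primerChar, baseChar) {
  exp <- Biostrings::IUPAC_CODE_MAP[primerChar]
  !is.na(exp) & vapply(seq_along(primerChar), function(i) {
    grepl(baseChar[i], exp[i], fixed = TRUE)
  }, logical(1L))
}

# Levenshtein distance matrix (substitutions + indels), via C adist.
.editDist <- function(a, b = a) {
  utils::adist(a, b)
}

# Overlap (ends-free) alignment of a shorter sequence against a longer one.
# Returns per-column detail needed by the contig cleanup rules: aligned
# fraction of the pattern, identity over all aligned columns, identity
# excluding the last `excl3p` pattern positions, identity over the 3'-terminal
# windows of the pattern, and the matched pattern/subject spans.
.overlapAlign <- function(pattern, subject) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = pattern, subject = subject, type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE),
    gapOpening = 4, gapExtension = 2)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  inP <- ap != "-"
  matchCol <- ap == as_ & inP & as_ != "-"
  patPos <- cumsum(inP)            # pattern coordinate at each column
  pstart <- Biostrings::start(Biostrings::pattern(pa))
  pend <- Biostrings::end(Biostrings::pattern(pa))
  sstart <- Biostrings::start(Biostrings::subject(pa))
  send <- Biostrings::end(Biostrings::subject(pa))
  list(
    patternStart = pstart, patternEnd = pend,
    subjectStart = sstart, subjectEnd = send,
    alignedFraction = (pend - pstart + 1L) / nchar(pattern),
    nColumns = length(ap),
    identity = mean(matchCol),
    score = Biostrings::score(pa),
    columns = data.frame(patternPos = patPos + pstart - 1L,
                         match = matchCol, patternGap = !inP,
                         stringsAsFactors = FALSE)
  )
}

# Identity over the last `w` aligned pattern positions of an .overlapAlign fit.
.tailIdentity <- function(aln, w, patternLen) {
  cols <- aln$columns
  keep <- !cols$patternGap & cols$patternPos > patternLen - w
  if (!any(keep)) return(0)
  mean(cols$match[keep])
}

# Identity excluding the last `excl` pattern positions.
.headIdentity <- function(aln, excl, patternLen) {
  cols <- aln$columns
  keep <- cols$patternPos <= patternLen - excl
  if (!any(keep)) return(1)
  mean(cols$match[keep])
}

.stopf <- function(fmt, ..., class = "near16S_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
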