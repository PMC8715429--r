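---
title: "Methods: genome-linked 16S analysis and semi-targeted read processing"
author: "near16S"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-linked 16S analysis and semi-targeted read processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The 16S rRNA gene is the standard phylogenetic marker for bacterial community
profiling, but it is highly conserved: distinct species — and, even more so,
distinct strains and distinct gene copies within one genome — often carry
identical hypervariable-region sequences. Copy-number variation (typically
1–15 operons per genome) further distorts read-count-based abundance
estimates. The genomic sequence immediately upstream (5′, in gene
orientation) of each 16S copy is not under the same selective constraint:
distinct operon copies sit at entirely different chromosomal locations, so
their upstream contexts are essentially unrelated sequences, and even between
close strains the upstream locus diverges faster than the gene. Linking each
16S copy to its upstream context ("near-16S" region) therefore makes copies,
strains and species separable where the gene alone is not.

Semi-targeted 16S sequencing (st16S-seq) captures exactly this linkage with a
single primer: extension starts at a conserved site between the V2 and V3
regions, oriented toward the gene start, and is terminated stochastically by
oligonucleotide-tethered dideoxynucleotides (OTDDNs), which double as adapter
carriers. The forward read (R1) then always starts at the priming site and
reads V2, V1 and onward into the upstream locus; the reverse read (R2) starts
at the (random) termination point and reads back. The OTDDN:dNTP molar ratio
sets the per-base termination probability and hence the fragment-length
distribution.

This package implements, in R, (i) the in-silico framework quantifying the
discriminatory power of near-16S regions on annotated genomes, (ii) the
bespoke computational stages of st16S-seq read analysis, and (iii) a
synthetic-community generator plus read simulator that together form a
self-contained, download-free test bed.

## Dataset construction

`parseGenome()` retains annotation features whose product string matches the
prefix pattern `"16S ribosomal RNA.*"` (case-sensitive; a missing or empty
assembly file raises a distinct `missing-assembly` error).
`extractLinkedLoci()` orients every gene 5′→3′, keeps genes of 1000–2000 bp,
and links each to up to 1000 bp of upstream sequence; for minus-strand genes
the upstream window is the genomically 3′ flank, reverse-complemented.
Windows cut short by a contig edge are flagged, not dropped — analyses that
need a full prefix exclude them explicitly. `filterDataset()` applies, in
order: whole-genome removal when genus or species is missing; whole-genome
removal when any locus of the genome failed primer QC; per-locus removal of
sequences containing non-ACGT letters. The audit log records per-step counts
so that retained = input − Σ removed always holds.

Coordinates are 1-based closed internally — the native convention of the
GRanges/IRanges stack this package is built on — and 0-based half-open in the
exported BED-like region tables.

## Hypervariable regions

`findPrimerHits()` scores every placement of each inter-region primer within
the edit budget (default 2, substitutions plus indel columns) using a
blastn-short-like scheme: IUPAC-compatible match +1, mismatch −2, gap −2.
The best-scoring placement wins, ties resolved to the leftmost start —
BLAST-style bitscores depend on unstated program parameters, so determinism
was preferred over irreproducible tie behaviour.
`qcAndSplit()` rejects a locus when a primer is absent or hits are
non-sequential; region V\_k spans from the end of primer k−1's hit (gene
start for V1) to the start of primer k's hit, so each primer is named after
the region upstream of its hybridization site. The default composite for
downstream analyses is V1–V2: gene start through the start of the
V2-terminating primer (320 bp with the bundled synthetic primer set; the
real-gene scale is ~341 bp).

## Conservation profile

Column-wise Shannon entropy over a multiple sequence alignment,

$$S = -\sum_i P_i \log_4 P_i,$$

with \(P_i\) the fraction of base \(i\) in the column; the log base 4
normalizes to \([0,1]\) (uniform column → 1, single base → 0). Columns where
the designated reference row (default the first sequence) holds a gap are
removed; gaps are excluded from the \(P_i\) denominator so that the four-base
log base stays meaningful, and a column whose non-reference rows are all gaps
is reported as missing rather than 0. Treating gaps as a fifth symbol is a
defensible alternative; the choice here is explicit and localized in
`columnEntropy()`.

Alignments come from a progressive aligner (UPGMA guide tree on 6-mer
frequency profiles; profile–profile Needleman–Wunsch in C++ with match +2,
mismatch −1, affine gaps opening −10 and extending −1), or from any
pre-aligned FASTA via `readMSA()` — keeping parity with externally produced
alignments without adding a dependency. `rankEntropyDistribution()` samples
at most 20 members per rank, 5 sub-members per member and 2 strains per
species (uniformly, under the caller's seed) before aligning and averaging.

## Identifiability statistics

A gene copy is *identifiable* within a comparison group when its composite
sequence (V1–V2, full gene, or upstream-prefix(L)+V1–V2) is an exact-string
unique variant; no similarity threshold is involved. Per member the fraction
is unique variants / total copies, and the statistic is the mean over
members. Grouping units: strains (intra-strain), species pooling their
strains' copies (inter-strain, species with ≥ 2 strains only), genera
pooling their species (inter-species). Caps of 10 strains/species (all
levels) and 10 species/genus (inter-species) are applied by uniform sampling
under a recorded seed. Pooling does not deduplicate within-strain copies
first (a pooled multiset), which is the stricter reading.

A *strain* is identifiable when at least one of its copies occurs in no
other strain of the same species (`strainIdentifiability()`).
`upstreamLengthSweep()` grows the upstream prefix, excluding (by default)
loci whose upstream window is shorter than the requested prefix.
`nearestNonidenticalDistances()` reports edit distances (substitutions +
indels) from sampled queries to their k closest non-identical neighbours —
the diagnostic separating genuine sequence variants from PCR/sequencing
artifacts, which sit 1–3 edits away.

## OTU clustering metrics

Distances are MSA mismatch fractions (internal gaps count as differences,
end-gaps are ignored, shared gaps are not differences); clustering is
average-neighbour hierarchical, cut at 1 − threshold — the classic Mothur
default, chosen because it is deterministic and oracle-checkable.
Four quality metrics against species labels: richness ratio min(S,O)/max(S,O);
pair-level Matthews correlation (TP = same-species-same-cluster pairs, and
so on — the contingency construction is stated because citation alone does
not fix it); normalized mutual information with natural logs, normalized by
the arithmetic mean of the two partition entropies; and bijection, the
fraction of species whose sequences occupy exactly one cluster containing
nothing else. Degenerate denominators (single cluster and single species)
yield missing values rather than 0.

## Taxonomic classification

An RDP-style word-presence naive-Bayes classifier (`trainRdp()`), word size
8, corpus prior \((n_w + 0.5)/(N+1)\), taxon-conditional
\((m_w + P_w)/(M+1)\). Each of 100 bootstrap replicates draws ⌊W/8⌋ of the
query's W distinct words with replacement; support is the vote fraction of
the winning taxon. Accuracy under `leaveCladeOutCV()` holds out whole clades
(strains by default) across 5 folds, retrains per fold and region, and
counts a prediction accurate only when the label is correct **and** support
strictly exceeds 0.80. The denominator is all validation sequences,
including those left below the support cutoff — the stricter of the two
readings of "all predictions".

## Read-pipeline core

* `preprocessReads()`: drops pairs with a read < 250 nt or containing N;
  drops pairs whose R2 begins with the targeting primer (Hamming ≤ 1 within
  the first 40 bases — a read-through signature); trims the primer off R1
  (edit ≤ 2, first 50 bases).
* `mergeOverlaps()`: best gapless 3′ overlap (≥ 20 nt, ≤ 10 % mismatches)
  between R1 and the reverse-complemented R2, seeded by an exact-ish prefix
  match; disagreements resolve toward the higher-quality base.
* `dereplicate()` + `swarmCluster(d)`: exact collapse, then iterative
  single-linkage agglomeration attaching any unique sequence within edit
  distance d of any cluster member (d = 1 for merged-read "b-clusters",
  d = 2 for 240 bp forward-prefix "a-clusters"). The implementation seeds by
  abundance and expands to closure; a brute-force connected-components oracle
  checks equivalence in the tests. Candidate neighbours are pruned by length
  difference (|Δlen| > d implies edit distance > d).
* `linkClusterings()` + `abundanceAf()`: with j b-clusters,
  \(a_f = \frac1j \sum_b n(b \cap a)/n(b)\); a-clusters holding < 0.001 of
  the filtered pairs (read as filtered on-target pairs) are excluded from
  assembly. The summation runs over all j b-clusters — the printed index
  admits no other consistent reading.
* `cleanupWithinCluster()`: keep the dominant 230 bp-prefix cluster
  (single-linkage d = 2 or ≥ 96 % identity); drop contigs < 52 % of the
  maximum length; drop contigs contained in a longer one at > 98 % identity
  (excluding the last 20 bp) over ≥ 0.9 of their length.
* `cleanupGlobal()`: contigs must align to a labelled reference catalog over
  ≥ 90 % of their length, starting by base 5, with < 5 Ns in the matched
  reference region; per source cluster only the genus with the largest
  median contig length survives, 3′ overhangs beyond the match are trimmed;
  a final containment pass (≥ 96 % identity over 99 % of length) spares
  contigs whose 3′-terminal 15 bp or 50 bp window identity falls below 80 %
  — the rescue that keeps genuinely distinct 16S copies diverging only near
  the contig end; equal-length duplicates resolve toward higher abundance.
  "Identity" throughout is matches / alignment columns from an ends-free
  overlap alignment of the shorter sequence against the longer — identity
  thresholds alone do not fix a denominator, so this package states one.
  Screening against the whole-nt BLAST database is replaced by a
  user-supplied labelled catalog with identical acceptance thresholds,
  removing a multi-GB database dependency while preserving every stated
  rule; likewise TPM-based abundance is replaced by the read-count a\_f,
  and assembly proper (external assemblers) is out of scope — the cleanup
  accepts contigs from any assembler or from truth-derived simulator
  fragments.
* `callCopyNumber()`: detected copy number = retained contigs per group.

## The simulator and what it does (not) emulate

`generateCommunity()` builds an ancestral 16S template with nine variable
windows separated by the conserved sites of the bundled primer set (so primer
matching is exact on every simulated gene), then mutates it down a
genus → species → strain hierarchy. Upstream loci evolve at independently
configurable (default 5×) rates. Crucially, each operon copy *slot* carries
its own ancestral upstream sequence, shared down the lineage — reflecting
that distinct operons occupy distinct chromosomal loci; `sharedUpstream =
TRUE` gives the degenerate single-locus mode used for rate-calibration
tests. Per-copy intragenomic SNPs, random strands, 2 kb flanks and GFF3
annotations complete the genomes.

`simulateSt16sReads()` draws operons proportional to genome abundance × copy
number, extends from the priming site with per-base termination probability p
(length geometric, mean ≈ 1/p, truncated at the template end — the linear
proxy for the OTDDN:dNTP mole fraction), and emits R1 from the primer and R2
from the termination point, trimming adapter read-through. Errors are
substitution-only at a uniform rate with constant Q30 qualities — enough to
exercise edit-distance clustering; indel errors, quality decay along the
read, PCR chimeras and GC-content structure are deliberately not modelled,
so passing tests say nothing about those failure modes on real data.
`truthContigs()` emulates variable assembly reach by giving copy c an
upstream extent of 450 + 50·c bases.

Default study conditions: even 8- or 20-member mock communities with copy
numbers uniform on 1–10; read length 300; termination probability 1/350
(mean fragment ≈ 370 bp, sitting inside the window where a 2×300 bp pair
both survives the 250 nt length filter and still overlaps for merging);
error rate 0.001. Test problem sizes are a few thousand read pairs and
communities of 8–24 genomes — orders of magnitude below a genome-database
survey (tens of thousands of assemblies, hundreds of thousands of read
pairs per sample), which is why the package reproduces the *statistics and
their orderings* rather than any database-scale percentage.

## Numerical and design choices

* Tie-breaks: primer placements → leftmost; classifier votes → first taxon
  in sorted order; OTU sweep argmax → lowest threshold.
* The upstream window may overlap a neighbouring annotated gene; no masking
  is applied (the defining experiment captures whatever lies upstream).
* Every stochastic routine takes an explicit seed; identical seeds give
  byte-identical outputs (tested).
* The even-mock abundance check correlates observed per-genus a\_f with the
  expected read distribution (abundance × copy number, normalized) — the
  construction used for mock-community validation — because the
  copy-number-corrected truth vector of an even community is constant and a
  correlation against it is undefined; corrected abundances are instead
  required to recover the even profile within a small absolute deviation.

## Limitations

Upstream windows are extracted only relative to annotated gene coordinates —
mis-annotated starts shift the linkage. The progressive aligner is a general
workhorse, not a 16S-aware aligner; for large or distant alignments an
external MSA can be supplied pre-aligned. The pipeline's copy-number call
counts retained contigs, so copies whose near-16S regions are identical over
the contig reach collapse (correctly reported as one) and sparse coverage of
an operon removes its contig entirely. The classifier is genus/species
agnostic about rank semantics: it predicts whatever labels it was trained
on.
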