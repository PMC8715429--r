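# near16S

Genome-linked 16S rRNA analysis and semi-targeted read processing.

## What this is for

16S rRNA amplicon profiling cannot reliably separate close species, strains,
or the several gene copies inside one genome: the gene is too conserved, and
copy-number variation distorts abundance estimates. The genomic region
immediately upstream of each 16S copy (the **near-16S** region) does not
share this constraint — distinct operon copies sit at distinct chromosomal
loci, and even between close strains the upstream locus diverges faster than
the gene. Semi-targeted 16S sequencing (st16S-seq) links each gene copy to
its upstream context with a single primer extension that is terminated
stochastically by oligonucleotide-tethered dideoxynucleotides, so the forward
read always starts inside the gene (V2 → V1 → upstream) while the reverse
read starts at a random upstream position.

`near16S` is for researchers who want to (a) quantify how much taxonomic
resolution upstream regions add on annotated genomes, and (b) run the
computational core of st16S-seq read analysis. It provides:

* **In-silico framework** — extraction of 16S genes with linked upstream
  regions from FASTA + GFF3 (strand-aware, length-filtered, audited);
  primer-based splitting into hypervariable regions V1–V9 with order QC;
  per-column Shannon entropy conservation profiles
  (S = −Σᵢ Pᵢ log₄ Pᵢ ∈ [0, 1]); the **identifiability statistic** (mean
  over group members of unique composite variants / total copies, at
  intra-strain, inter-strain and inter-species levels, with the standard
  sampling caps); identifiable-strain fractions; nearest-non-identical
  distances; OTU clustering scored by richness ratio min(S,O)/max(S,O),
  pair-level MCC, NMI and bijection; an RDP-style bootstrap naive-Bayes
  classifier with leave-clade-out 5-fold cross-validation.
* **Pipeline core** — read preprocessing, overlap merging, exact
  dereplication, swarm-style d-clustering, linkage of the two clusterings,
  per-OTU abundance a_f = (1/j) Σ_b n(b ∩ a)/n(b), the contig cleanup rules
  (dominant 5′-prefix cluster, 52 % length rule, containment with the
  3′-divergence rescue, reference-catalog screening), copy-number calling
  and copy-number-corrected abundances.
* **Simulator** — annotated multi-operon communities with a controlled
  genus → species → strain divergence hierarchy (upstream loci evolving
  faster than the gene, one independent upstream locus per operon copy
  slot), and paired-end st16S-seq reads with geometric fragment lengths
  governed by a per-base chain-termination probability.

## Worked example

How much does the upstream region add? Simulate a 12-strain community
(2 genera × 2 species × 3 strains, 3 operons per genome, upstream divergence
5× the gene's) and compare three composites:

```r
library(near16S)
spec <- communitySpec(nGenera = 2, speciesPerGenus = 2, strainsPerSpecies = 3,
                      copiesPerGenome = 3,
                      geneRates = c(genus = 0.04, species = 0.002, strain = 5e-4),
                      upstreamRates = 5 * c(genus = 0.04, species = 0.002, strain = 5e-4),
                      intragenomicSnpRate = 2e-4, seed = 1)
sim <- generateCommunity(spec)
ops <- as.data.frame(truthOperons(sim))
tab <- data.frame(genus = ops$genus, species = ops$species, strain = ops$strain,
                  upstream = ops$upstream_seq, v1v2 = substr(ops$gene_seq, 1, 320),
                  gene = ops$gene_seq)
near <- transform(tab, seq = paste0(substr(upstream, 601, 1000), v1v2))
v12  <- transform(tab, seq = v1v2)
gene <- transform(tab, seq = gene)
sapply(list(`V1-V2` = v12, `full gene` = gene, `near-16S(400)+V1-V2` = near),
  function(df) c(copy   = copyIdentifiability(df, "intra_strain", seed = 1)$meanFraction,
                 strain = mean(strainIdentifiability(df))))
```

```
       V1-V2 full gene near-16S(400)+V1-V2
copy   0.361     0.611                   1
strain 0.250     0.917                   1
```

Reading: within a genome, V1–V2 distinguishes only 36 % of gene copies and
the full gene 61 %, while 400 bp of upstream sequence linked to V1–V2 makes
every copy unique; likewise every strain becomes identifiable. The worked
textbook case of the statistic — strain X with one copy, strain Y with two
identical copies — gives per-strain fractions 100 % and 50 % and a dataset
mean of 75 %:

```r
copyIdentifiability(data.frame(genus = "G", species = "S",
                               strain = c("X", "Y", "Y"),
                               seq = c("AAAA", "CCCC", "CCCC")),
                    level = "intra_strain")$meanFraction
#> [1] 0.75
```

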