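# oscexcess

Out-of-frame stop codon (OSC) excess analysis for bacterial coding
sequences.

A ribosome that slips into the +1 or +2 reading frame translates nonsense
until it meets a stop codon in its new frame. The *ambush hypothesis*
proposes that coding sequences are selected to hide such off-frame stops as
a fail-safe against accidental frameshifts. Whether real genomes carry an
*excess* of OSCs depends entirely on the null model: this package implements
the scanning and the null-model comparison machinery for anyone who wants to
measure that excess rigorously, and a synthetic-genome generator so that
every stage is testable without downloading a single genome.

For a genome, the density of a codon set *C* in off-frame *f* is

```
D(C, f) = 100 * (number of complete off-frame codons in C, frame f) / (total in-frame codons)
```

and its excess against a null simulator is the standard score

```
Z = (D_real - mean(D_sim)) / sd(D_sim),    p = 2 * pnorm(-|Z|)
```

over 200 replicate simulations per genome, with Benjamini–Hochberg
correction across genomes; a genome "has an excess" when Z > 0 and the
corrected p < 0.05.

**What's included**

* CDS filtering (length, alphabet, internal stops, terminal stop) under
  NCBI translation tables 11 and 4 (table 4 reads TGA as tryptophan);
  FASTA + metadata and GenBank flat-file readers.
* Off-frame scanning and densities per 100 codons for the three stops and
  their same-composition sense controls (TAC, TAT, TGC, TGG, TGT).
* Four null simulators: within-CDS codon shuffle, codon-position-aware
  Markov chains (orders 2 and 5), synonymous-site resampling within coding
  blocks, and synonymous-codon resampling.
* Z / p / BH-FDR excess tables, genome-set summaries, and Spearman
  correlations of excess with GC content.
* The dicodon-context test: A use at site 3 vs site 6 of Ile|Ile (+1 TAA)
  and Val|Val (+1 TAG) repeats followed by a C/T-starting codon, paired
  signed-rank across genomes, with an A/T-ending restriction to control
  GC3.
* Genetic-code comparison: pooled loess of density on GC content, then
  Kruskal–Wallis on residuals between table-11 and table-4 cohorts.
* Codon Adaptation Index with the half-split protocol (CAI from the trimmed
  first half, density from the second half of each CDS).
* A synthetic cohort generator with controllable GC3, codon-usage
  sharpness, table conventions, and injectable OSC or dicodon bias.

## Worked example

```r
library(oscexcess)

# one CDS; the +2 frame reads GGA|TAA|TTA, so the off-frame TAA density is
# 100 * 1/4 codons = 25
g <- genome_record("demo", c(cds1 = "ATGGATAATTAA"))
osc_density(g, "TAA", "+2")
#> [1] 25

# codon-shuffle null for a two-internal-codon CDS: one of the two
# permutations forms a +1 TGA, so the exact null mean is 12.5
e <- run_ensemble(genome_record("x", c(c1 = "ATGAAAGGGTAA")),
                  "shuffle", n_reps = 200, seed = 1)
mean(e$sims[, "TGA", "+1"])
#> [1] 11.625   # Monte-Carlo estimate of the exact 12.5

# a synthetic cohort and the full excess pipeline
coh <- generate_cohort(20, gc3_range = c(0.25, 0.75), seed = 7)
res <- run_excess_pipeline(coh$genomes, models = "shuffle",
                           n_reps = 200, seed = 8)
subset(res$summary, codon_set == "stops" & frame == "+1")
#>     model codon_set frame n_genomes n_excess pct_excess n_negative pct_negative
#> 1 shuffle     stops    +1        20        0          0          0            0
```

The cohort above is generated with internal codons drawn i.i.d., so codon
order is exchangeable and the shuffle null is true by construction: excess
counts stay at the false-positive rate. Injecting enrichment moves them —
`inject_osc_bias(genome, "TAA", "+1", delta)` adopts OSC-forming synonyms
with probability `delta` and the synonymous-site model then recovers
positive Z scores.

## The analysis workflow

The `analysis/` directory holds the end-to-end study as numbered scripts
(run from the repository root, in order; outputs land under `results/`):

| script | what it does |
|---|---|
| `01_synthesize_cohort.R` | builds table-11 and table-4 cohorts, writes FASTA/metadata/truth |
| `02_excess_simulations.R` | shuffle + synonymous-site ensembles, excess tables and GC correlations |
| `03_dicodon_context.R` | dicodon site-usage tests, plus a planted-bias demonstration |
| `04_code_comparison.R` | loess/Kruskal–Wallis comparison of the two genetic codes |
| `05_expression_cai.R` | CAI half-split analysis on one genome |

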