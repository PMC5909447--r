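---
title: "Measuring out-of-frame stop codon excess: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring out-of-frame stop codon excess: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question

A ribosome that slips out of frame translates nonsense until it happens upon
a stop codon in its new reading frame. The ambush hypothesis proposes that
bacterial coding sequences are under selection to carry such out-of-frame
stop codons (OSCs) as a fail-safe: the more off-frame stops a CDS hides, the
sooner an accidentally frameshifted ribosome terminates. Testing this idea
reduces to a deceptively simple comparison — are OSCs more frequent in real
coding sequences than in null sequences with the same coding constraints? —
whose answer depends heavily on how the null is constructed. This package
implements the full comparison machinery: off-frame scanning, four
null-sequence simulators, Z-score excess statistics, a dicodon-context
codon-usage test, a genetic-code comparison at matched GC content, and
expression stratification via the Codon Adaptation Index (CAI), together
with a synthetic-genome generator that makes every stage testable without
any external data.

## Sequence model and filtering

Coding sequences are held as vectors of codon ids. A CDS enters analysis
only if it (1) has a length divisible by three, (2) contains only A, C, G,
T, (3) has no in-frame stop codon before its end, and (4) terminates in a
stop codon of its genome's translation table — TAA/TAG/TGA under NCBI table
11, TAA/TAG under table 4, where TGA encodes tryptophan. Rejections are
values with reason codes, not errors, so attrition is reportable.
Ambiguity codes are not resolved: any non-ACGT character rejects the CDS.

Frames are defined against 1-based nucleotide coordinates: the +1 frame
codon grid starts at position 2, the +2 frame at position 3. Each off-frame
codon therefore spans one adjacent in-frame codon pair, which is what makes
genome-scale scanning cheap: all off-frame counts are functions of pair
counts. A CDS of *n* codons yields exactly *n* − 1 complete codons in each
off-frame. Scanning covers the whole CDS including the start and terminal
stop codon, and the density denominator is the total codon count; because
the same convention is applied to real and simulated sequences, Z scores are
unaffected by this choice. The −1/−2 frames are not scanned; their costs
mirror +2/+1. OSC density is reported per 100 codons:
100 × (off-frame count) / (total codons), summed over CDSs for a genome.

## The four null models

All simulators copy the start codon and the terminal stop verbatim and act
only on internal codons.

**Codon shuffle.** Internal codons are uniformly permuted within each CDS.
This preserves length, GC content, codon and amino-acid multisets exactly;
only codon *order* is randomised, so it asks whether OSC-forming codon
*pairings* exceed chance.

**Codon-position-aware Markov models (orders 2 and 5).** Transition counts
are collected over all internal regions (start/stop discounted), keyed by
the context string *and* the codon position (phase) of the sampled
nucleotide. Simulation keeps the real start codon plus the first 2 or 5
internal nucleotides as seed and samples until the internal length matches,
then appends the real stop. Contexts never observed are handled by backing
off to the next-lower order, ending at the phase-specific mononucleotide
distribution; back-off was chosen over add-one smoothing so that no
unobserved transition is ever invented. The simulated sequence's own phase
(position mod 3) drives the bookkeeping, so context keys stay well defined
for the whole synthesis. Seed nucleotides are copied verbatim every
replicate.

**Synonymous-site model.** Third-position nucleotide frequencies are counted
within each *coding block* — the synonyms of an amino acid sharing their
first two nucleotides, so the 6-fold amino acids (Leu, Ser, Arg) split into
2-fold and 4-fold blocks — and each internal codon is resampled within its
own block. Amino-acid sequence and block membership of every position are
preserved exactly; only the synonymous site is questioned.

**Synonymous-codon model.** As above but pooled across blocks: each codon
is resampled from the full synonym set of its amino acid. Both resamplers
keep the first codon fixed even when it is a non-ATG start, since swapping
a GTG/TTG start for a Val/Leu synonym would break the start convention.

**Ensembles.** Each genome is re-simulated `n_reps = 200` times (every CDS
independently each replicate, no caching), and genome-level densities of
the tracked codon sets — TAA, TAG, TGA, their same-composition sense
controls TAC, TAT, TGC, TGG, TGT, and the pooled stop set — are recorded in
frames +1, +2, and Both. A run is reproducible from a single seed; the RNG
stream is consumed sequentially (one stream per run rather than one split
stream per replicate — the package does not parallelise, so a single
sequential stream gives the same reproducibility guarantee with less
machinery).

## Excess statistics

For each (genome, codon set, frame, model), the excess is the standard
score

> Z = (real density − mean simulated density) / sd(simulated densities)

with the *n* − 1 standard-deviation estimator; a zero-spread ensemble is
flagged undefined rather than assigned ±∞. P values are two-tailed normal
tails, 2Φ(−|Z|): the analyses report both positive and significant
*negative* excesses, which implies a two-sided view, and positive-excess
significance additionally requires Z > 0. Multiple testing is corrected by
Benjamini–Hochberg, with the correction family defined as all genomes
sharing one (model, codon set, frame) triple — one corrected p value per
genome per family. Correlations of excess with genome GC use tie-aware
Spearman ranks with asymptotic two-sided p values.

## The dicodon-context test

In a repeat of two identical amino acids followed by a codon starting with
C or T (class Y), only the *first* codon's synonymous site can complete an
off-frame stop: isoleucine repeats (ATH|ATH|YNN) can encode +1 TAA through
an A at site 3, valine repeats (GTN|GTN|YNN) +1 TAG. Under stop-codon
selection, A use should be higher at site 3 than at site 6; the follower
constraint guarantees the second codon cannot complete a stop, and because
both codons encode the same amino acid the local usage pressures are
matched. Every adjacent pair of a longer repeat is scanned (for isoleucine
the follower of an inner window is itself A-starting, so inner windows
never qualify — the scan is still defined pairwise). The optional
restriction to A/T-ending synonyms controls GC3 within the comparison and
can only shrink the context count. Per genome, contexts are pooled across
CDSs into proportions A3 and A6; genomes with no contexts are excluded
listwise. The cross-genome comparison is a two-sided *paired* Wilcoxon
signed-rank test on A3 − A6 (zero differences dropped, normal
approximation) — the paired-consistent test for per-genome differences —
plus a tie-aware Spearman correlation of log(A3/A6) with GC3. The
generalised configuration exposes the target nucleotide and follower class
as parameters so that T-use variants for +2 targets can be expressed.

## Comparing genetic codes

Genomes in which TGA is read as tryptophan have no TGA stop function, so
off-frame TGA selection should weaken there. Raw density comparisons would
be confounded by GC (table-4 genomes are AT-rich); instead a single loess
regression of density on whole-CDS GC content is fitted over *both* groups
pooled — the fit never sees the labels — and residuals are compared between
groups with a tie-corrected Kruskal–Wallis test (retained even for two
groups), reporting group mean residuals alongside. Loess defaults are span
0.75, local degree 2, tricube weights, no robustness iterations, with exact
("direct") surface evaluation; these are configurable since no single
parameterisation is canonical. An all-tied residual vector returns
statistic 0 and p 1. Densities for both cohorts are computed with an
explicit shared codon set so that the comparison never depends on each
genome's own stop-set definition. Supporting utilities cover genus
deduplication (first genome per genus in input order), a 500 kb
genome-size floor when metadata is present, and Z-rank restriction of a
cohort (e.g. keeping the top genomes of one genus by +1 TGA Z score).

## Expression stratification by CAI

Relative adaptiveness *w* is computed from a highly expressed reference set
— gene names matching the ribosomal-protein ranges rplA–rplF, rplI–rplU and
rpsB–rpsU, case-insensitively, with a warning under 20 matches and an error
at zero — and CAI is the geometric mean of *w* over a codon stretch,
excluding stops and single-synonym amino acids. Zero-count reference codons
are floored at *w* = 0.01 (the convention of classic CAI software); an
amino acid absent from the reference contributes neutrally (*w* = 1).

To keep the expression proxy independent of the density measurement, each
CDS is split: the first 30 nucleotides are discarded (5′ regions are biased
to ease ribosome binding), CAI is measured on the first half of the
remainder rounded down to whole codons, and OSC density on the second half
of the full CDS, codon-aligned. Under this arithmetic the two windows may
share a short central stretch (codons 21–25 of a 40-codon CDS) — the hard
guarantee is that the CAI window never touches the trimmed 5′ region — and
CDSs of 36 nt or less are excluded. Per-genome association of CAI with
second-half density is a tie-aware Spearman correlation, undefined when
either variable is constant.

## The synthetic-genome generator

The generator produces cohorts with exactly the structure the statistics
assume, so calibration and power are checkable by construction:

* **Amino-acid profile.** A fixed average bacterial proteome composition
  (20 constants embedded in the package, overridable) keeps cohorts
  comparable.
* **Codon usage.** Per-amino-acid synonym probabilities are drawn from a
  symmetric Dirichlet (concentration 20 by default: clearly non-uniform
  usage without degenerate extremes) and exponentially tilted toward or
  away from G/C-ending synonyms; the tilt is solved by root finding so the
  expected GC3 of the codon stream matches the target, with clamping and a
  warning outside the achievable range.
* **Genomes.** Each CDS is an ATG start, internal codons drawn i.i.d. from
  the usage table (sense codons only, so in-frame stops cannot arise and
  the filter passes by construction), and a terminal stop drawn uniformly
  from the table's stop set. Default cohorts use 60–100 CDSs of 60–240
  codons per genome: large enough that genome densities are well resolved,
  small enough that hundreds of 200-replicate ensembles run on a laptop.
  Because internal codons are i.i.d., codon order is exchangeable and the
  shuffle null is calibrated *exactly* by construction.
* **OSC enrichment.** `inject_osc_bias()` makes one left-to-right pass; at
  each internal codon whose downstream neighbour would complete the target
  OSC, the OSC-forming synonym is adopted with probability δ (uniformly
  among candidates when the amino acid offers two). The amino-acid sequence
  never changes, δ = 0 is the identity in distribution, δ = 1 saturates
  every eligible site, and expected target density is monotone in δ.
  Eligibility is evaluated against the pre-pass sequence with the
  downstream codon held fixed; interactions with the next site's own
  eligibility are second-order and accepted.
* **Dicodon bias.** `inject_context_bias()` redraws the first codon's
  synonymous site at each qualifying context with the target nucleotide's
  probability raised by an absolute δ over its generative value, so the
  expected A3 − A6 difference equals δ exactly.

What the generator deliberately does *not* emulate: location-specific codon
usage along the CDS, motif or domain structure, context-dependent
mutational biases, operon organisation, programmed frameshift sites, or any
real phylogenetic correlation between genomes. Green tests therefore
certify the *machinery* — scanning, simulators, calibration, and power
against planted signals — not any biological conclusion about real genomes,
where exactly those unmodelled features are the hard part.

## Numerical and scale choices

* Problem sizes in the test suite are chosen for a single CPU: 200-genome
  calibration cohorts at 200 replicates, 50 + 50 enrichment recovery at
  δ = 0.15, 100 null dicodon cohorts of 20 genomes plus 20 planted cohorts
  of 100 genomes, 60 planted and 100 null loess/Kruskal–Wallis cohorts, and
  1,000-CDS conservation sweeps.
* Monte-Carlo comparisons against exact enumeration use a 3-standard-error
  band; calibration checks use the 99% binomial envelope around the nominal
  rate.
* Degenerate inputs resolve explicitly: zero simulation spread, constant
  correlation inputs, and zero-context genomes are flagged undefined (`NA`)
  rather than propagated as infinities; an all-zero paired difference
  vector returns p = 1; empty p-vector input returns empty output.
* Ties are handled by the tie-aware forms throughout (Spearman asymptotic
  p, tie-corrected Kruskal–Wallis, signed-rank with zeros dropped).

## Known limitations

* The synonymous-site and synonymous-codon nulls are *plug-in* nulls: the
  resampling tables are estimated from the same genome they score, which
  couples the real density to the simulated mean and makes the resulting Z
  scores mildly conservative — most visibly for +1-frame pooled stops,
  where the largest share of synonymous sites participates in the scored
  patterns. The shuffle null has no such coupling. The direction is always
  conservative, never anti-conservative.
* Markov back-off at unseen contexts is a documented choice, not a
  canonical one; at order 5 on small genomes many contexts resolve at lower
  orders.
* Empirical-rank p values are out of scope: p is always extrapolated from
  Z through the normal tail, which is only as good as the near-normality of
  the replicate densities (excellent for genome-scale counts, poor for very
  small single CDSs).
* The frameshift cost/probability machinery that would weight OSCs by
  translational context (tRNA repertoires, per-codon slippage
  probabilities) is exposed only as a hook and deliberately not modelled.
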