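Package: oscexcess
Title: Out-of-Frame Stop Codon Excess Analysis for Bacterial Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Scans bacterial coding sequences for codons read in the +1 and +2
    frames and quantifies the excess of out-of-frame stop codons (OSCs) against
    four null-sequence simulators: codon-position-aware Markov chains (orders 2
    and 5), within-CDS codon shuffling, synonymous-site resampling within coding
    blocks, and synonymous-codon resampling. Excess is measured by Z scores over
    replicate simulations with normal-approximation p values and
    Benjamini-Hochberg correction. Additional analyses include the
    dicodon-context codon-usage test on amino-acid repeats, comparison of
    translation-table 11 and table 4 genomes via loess residuals and
    Kruskal-Wallis tests, and Codon Adaptation Index stratification with a
    half-split protocol. A synthetic-genome generator with controllable GC3,
    codon usage, and injectable OSC enrichment makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
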