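# Independent oracles and small fixture builders shared across tests.
# Everything here deliberately avoids the package's pair-lookup code paths:
# off-frame codons are counted by substring extraction, permutations are
# enumerated explicitly, and BH is the literal step-up definition.

# count occurrences of `codon` read in an off-frame of a CDS string
# (+1: start positions 2,5,8,...; +2: positions 3,6,9,...)
count_offframe_substr <- function(seq, codon, frame) {
  offset <- if (frame == "+1") 1L else 2L
  starts <- seq.int(1L + offset, nchar(seq) - 2L, by = 3L)
  sum(substring(seq, starts, starts + 2L) == codon)
}

# density per 100 codons by substring counting
density_substr <- function(seq, codons, frames) {
  n <- nchar(seq) / 3
  cnt <- 0
  for (fr in frames) for (cd in codons)
    cnt <- cnt + count_offframe_substr(seq, cd, fr)
  100 * cnt / n
}

# all permutations of 1..n (n <= 7)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# exact mean off-frame density of `codons` in `frames` over all internal-codon
# permutations of a CDS string
exact_shuffle_mean <- function(seq, codons, frames) {
  n <- nchar(seq) / 3
  cods <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  if (n <= 3) return(density_substr(seq, codons, frames))
  internal <- cods[2:(n - 1)]
  P <- all_perms(length(internal))
  vals <- apply(P, 1, function(p) {
    density_substr(paste(c(cods[1], internal[p], cods[n]), collapse = ""),
                   codons, frames)
  })
  mean(vals)
}

# literal step-up Benjamini-Hochberg
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# random valid CDS string: ATG + k internal sense codons + stop
random_cds <- function(n_internal, table = translation_table(11)) {
  sense <- setdiff(seq_len(64), table$stop_ids)
  ids <- c(codon_id("ATG"), sample(sense, n_internal, replace = TRUE),
           sample(table$stop_ids, 1))
  codons_to_seq(ids)
}

# small synthetic genome for unit tests
tiny_genome <- function(n_cds = 10, gc3 = 0.4, seed = NULL,
                        cds_len_range = c(20, 60), table_id = 11) {
  if (!is.null(seed)) set.seed(seed)
  u <- sample_codon_usage(gc3, table = translation_table(table_id))
  generate_genome("tiny", u, n_cds = n_cds, cds_len_range = cds_len_range)
}

# write a small two-record GenBank flat file and return its path; the CDSs
# are hand-placed so the expected sequences are known exactly
write_genbank_fixture <- function() {
  genome <- paste0("ATGGATAATTAA", "AAA", "TTACCCTTTCAT", "AAA",
                   "ATGCCC", "AAA", "TGGTAA", strrep("A", 15))
  chunks <- substring(genome, seq(1, nchar(genome), 10),
                      pmin(seq(10, nchar(genome) + 9, 10), nchar(genome)))
  path <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       TESTREC1                 60 bp    DNA     linear   BCT",
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     gene            1..12",
    "                     /gene=\"rplA\"",
    "     CDS             1..12",
    "                     /gene=\"rplA\"",
    "                     /product=\"test protein 1\"",
    "     CDS             complement(16..27)",
    "                     /gene=\"rpsB\"",
    "     CDS             join(31..36,40..45)",
    "                     /product=\"unnamed\"",
    "ORIGIN",
    paste("        1", paste(tolower(chunks), collapse = " ")),
    "//"), path)
  path
}
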