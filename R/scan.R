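# Off-frame codon scanning and OSC density.
#
# Frames follow the genome coordinate convention: the +1 frame codon grid
# starts at nucleotide position 2 (1-based), the +2 frame at position 3.
# A CDS of n codons yields exactly n-1 complete codons in each off-frame,
# and each off-frame codon is a function of one adjacent in-frame codon pair.

FRAME_LEVELS <- c("+1", "+2", "Both")

# counts over the 64 codons in each off-frame for a flat genome (or any
# codon vector with pair structure)
pair_frame_counts <- function(cod, pair_left) {
  a <- cod[pair_left]
  b <- cod[pair_left + 1L]
  idx <- a + (b - 1L) * 64L  # column-major [a, b]
  list(plus1 = tabulate(PAIR_PLUS1[idx], nbins = 64L),
       plus2 = tabulate(PAIR_PLUS2[idx], nbins = 64L))
}

#' Scan the off-frame codons of a CDS
#'
#' Counts every complete trinucleotide read in the +1 frame (nucleotide
#' positions 2,5,8,...) and +2 frame (positions 3,6,9,...) across the whole
#' CDS, including the start and terminal stop codons.
#'
#' @param cds a `coding_sequence`, a nucleotide string, or a codon-id vector.
#' @return list with `plus1` and `plus2` (named integer vectors over the 64
#'   codons) and `n_codons`.
#' @examples
#' sc <- scan_offframe_codons("ATGGATAATTAA")
#' sc$plus2[["TAA"]]   # 1
#' @export
scan_offframe_codons <- function(cds) {
  cod <- as_codon_ids(cds)
  n <- length(cod)
  if (n < 2L) stop("CDS must have at least 2 codons to define off-frame codons")
  cnt <- pair_frame_counts(cod, seq_len(n - 1L))
  names(cnt$plus1) <- CODONS
  names(cnt$plus2) <- CODONS
  list(plus1 = cnt$plus1, plus2 = cnt$plus2, n_codons = n)
}

# resolve a codon-set spec ("stops", codon strings, or ids) to codon ids
resolve_codon_set <- function(codon_set, table = NULL) {
  if (is.character(codon_set) && length(codon_set) == 1L &&
      tolower(codon_set) == "stops") {
    if (is.null(table)) stop("codon_set = \"stops\" needs a translation table")
    return(table$stop_ids)
  }
  if (is.character(codon_set)) codon_id(codon_set) else as.integer(codon_set)
}

# density per 100 codons from frame counts
density_from_counts <- function(counts, set_ids, frames, n_codons) {
  num <- 0
  if (any(frames %in% c("+1", "Both"))) num <- num + sum(counts$plus1[set_ids])
  if (any(frames %in% c("+2", "Both"))) num <- num + sum(counts$plus2[set_ids])
  100 * num / n_codons
}

#' Out-of-frame codon density of a genome
#'
#' Density per 100 codons of a codon set in the chosen off-frames, pooled
#' over all CDSs: `100 * sum(counts) / sum(n_codons)`. Frames `c("+1","+2")`
#' (or `"Both"`) sum the two frame numerators over the same denominator.
#'
#' @param genome a `genome_record` (or a single `coding_sequence`).
#' @param codon_set character vector of trinucleotides, codon ids, or the
#'   keyword `"stops"` for the genome table's stop set.
#' @param frames subset of `c("+1","+2")`, or `"Both"`.
#' @return density per 100 codons (numeric scalar).
#' @examples
#' g <- genome_record("g", c(x = "ATGGATAATTAA"))
#' osc_density(g, "TAA", "+2")   # 25
#' @export
osc_density <- function(genome, codon_set = "stops", frames = c("+1", "+2")) {
  stopifnot(length(codon_set) >= 1)
  frames <- match.arg(frames, FRAME_LEVELS, several.ok = TRUE)
  if (inherits(genome, "coding_sequence")) {
    cod <- genome$codons
    flat <- list(cod = cod, pair_left = seq_len(length(cod) - 1L),
                 n_codons = length(cod))
    table <- NULL
  } else {
    if (length(genome$codons) == 0L) stop("genome has no CDSs")
    flat <- genome$flat
    table <- genome$table
  }
  set_ids <- resolve_codon_set(codon_set, table)
  cnt <- pair_frame_counts(flat$cod, flat$pair_left)
  density_from_counts(cnt, set_ids, frames, flat$n_codons)
}

#' Off-frame codon density over a codon range of one CDS
#'
#' Used by the CAI half-split protocol: counts off-frame codons whose pair
#' lies entirely inside `codon_range` and divides by the number of codons in
#' the range.
#'
#' @param cds `coding_sequence` or codon-id vector.
#' @param codon_set codons as in [osc_density()] (no `"stops"` keyword).
#' @param frames subset of `c("+1","+2")` or `"Both"`.
#' @param codon_range integer length-2: first and last codon index (1-based).
#' @return density per 100 codons within the range.
#' @export
osc_density_region <- function(cds, codon_set, frames = "+1",
                               codon_range = NULL) {
  cod <- as_codon_ids(cds)
  frames <- match.arg(frames, FRAME_LEVELS, several.ok = TRUE)
  if (is.null(codon_range)) codon_range <- c(1L, length(cod))
  k1 <- codon_range[1]; k2 <- codon_range[2]
  stopifnot(k1 >= 1, k2 <= length(cod), k2 >= k1)
  sub <- cod[k1:k2]
  if (length(sub) < 2L) return(0)
  cnt <- pair_frame_counts(sub, seq_len(length(sub) - 1L))
  density_from_counts(cnt, resolve_codon_set(codon_set), frames, length(sub))
}

#' Per-genome density table
#'
#' One row per tracked codon and frame, for TSV export.
#'
#' @param genome a `genome_record`.
#' @param codon_sets named list of codon sets; default the eight TAN/TGN
#'   codons analysed throughout plus the pooled stop set.
#' @param frames frames to report.
#' @return data.frame with `genome_id`, `codon`, `frame`, `density`.
#' @export
density_table <- function(genome, codon_sets = tracked_codon_sets(genome$table),
                          frames = FRAME_LEVELS) {
  rows <- expand.grid(codon = names(codon_sets), frame = frames,
                      stringsAsFactors = FALSE)
  rows$genome_id <- genome$genome_id
  rows$density <- mapply(function(cs, fr)
    osc_density(genome, codon_sets[[cs]], fr), rows$codon, rows$frame)
  rows[, c("genome_id", "codon", "frame", "density")]
}

#' Default tracked codon sets
#'
#' The eight TAN/TGN codons compared throughout the analysis (the three stops
#' TAA, TAG, TGA and the same-composition sense codons TAC, TAT, TGC, TGG,
#' TGT) plus the pooled stop set of the supplied table.
#'
#' @param table a `trans_table` (defaults to table 11).
#' @return named list of codon-string vectors.
#' @export
tracked_codon_sets <- function(table = translation_table(11)) {
  singles <- c("TAA", "TAG", "TGA", "TAC", "TAT", "TGC", "TGG", "TGT")
  sets <- as.list(singles)
  names(sets) <- singles
  sets$stops <- table$stop_codons
  sets
}
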