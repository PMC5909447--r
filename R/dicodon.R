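# Dicodon-context codon-usage test: in an amino-acid repeat followed by a
# codon starting with C or T (class Y), only the FIRST codon's synonymous
# site can complete an off-frame stop, so under stop-codon selection the
# target nucleotide should be used more at site 3 than at site 6.
# Isoleucine repeats (ATH|ATH|YNN) probe +1 TAA; valine repeats
# (GTN|GTN|YNN) probe +1 TAG.

#' Configuration for the dicodon-context test
#'
#' @param amino_acid `"Ile"` (probes +1 TAA) or `"Val"` (probes +1 TAG).
#' @param restricted restrict BOTH repeat codons to A/T-ending synonyms
#'   (controls GC3 within the comparison).
#' @param table_id NCBI translation table id used to enumerate synonyms.
#' @param follower_class allowed first nucleotides of the follower codon
#'   (default Y = C/T, which guarantees the second codon cannot complete a
#'   stop).
#' @param nucleotide the synonymous-site nucleotide whose usage is compared
#'   (default `"A"`; the generalised `"T"` variant probes +2 contexts).
#' @return object of class `dicodon_config`.
#' @export
dicodon_config <- function(amino_acid = c("Ile", "Val"), restricted = FALSE,
                           table_id = 11, follower_class = c("C", "T"),
                           nucleotide = "A") {
  amino_acid <- match.arg(amino_acid)
  table <- translation_table(table_id)
  aa1 <- c(Ile = "I", Val = "V")[[amino_acid]]
  ids <- which(table$codon_to_aa == aa1)
  if (restricted) ids <- ids[CODON_NT3[ids] %in% c(1L, 4L)]  # A or T ending
  structure(
    list(amino_acid = amino_acid, restricted = restricted,
         target = if (amino_acid == "Ile") "+1 TAA" else "+1 TAG",
         pair_ids = ids, follower_nt = match(follower_class, NUC),
         nucleotide = nucleotide,
         label = paste0(amino_acid, if (restricted) "_AT" else "_all")),
    class = "dicodon_config")
}

#' Find dicodon contexts in a CDS
#'
#' Scans in-frame codon triples (i, i+1, i+2): a context is emitted when
#' codons i and i+1 both encode the configured amino acid (both restricted to
#' A/T-ending synonyms when the restriction flag is set) and codon i+2 starts
#' with a follower-class nucleotide. Overlapping contexts from longer repeats
#' are all emitted.
#'
#' @param cds `coding_sequence`, nucleotide string, or codon-id vector.
#' @param config a `dicodon_config`.
#' @return data.frame with `site3` and `site6`: the third nucleotides of
#'   codons i and i+1.
#' @export
find_contexts <- function(cds, config) {
  cod <- as_codon_ids(cds)
  n <- length(cod)
  empty <- data.frame(site3 = character(0), site6 = character(0),
                      stringsAsFactors = FALSE)
  if (n < 3L) return(empty)
  i <- seq_len(n - 2L)
  hit <- cod[i] %in% config$pair_ids & cod[i + 1L] %in% config$pair_ids &
    CODON_NT1[cod[i + 2L]] %in% config$follower_nt
  i <- i[hit]
  if (!length(i)) return(empty)
  data.frame(site3 = NUC[CODON_NT3[cod[i]]],
             site6 = NUC[CODON_NT3[cod[i + 1L]]],
             stringsAsFactors = FALSE)
}

#' Genome-level dicodon site usage
#'
#' Pools contexts over all CDSs and reports the proportion of contexts using
#' the configured nucleotide at site 3 and at site 6, the log usage ratio,
#' and the genome's GC3.
#'
#' @param genome a `genome_record`.
#' @param config a `dicodon_config`.
#' @return one-row data.frame: `genome_id`, `config`, `n_contexts`, `a3`,
#'   `a6`, `log_ratio` (`NA` when either proportion is 0), `gc3`. Genomes
#'   with zero contexts have `a3`/`a6` `NA` and are excluded from paired
#'   tests.
#' @export
genome_site_usage <- function(genome, config) {
  ctx <- do.call(rbind, lapply(genome$codons, find_contexts, config = config))
  n <- if (is.null(ctx)) 0L else nrow(ctx)
  if (n == 0L) {
    a3 <- a6 <- lr <- NA_real_
  } else {
    a3 <- mean(ctx$site3 == config$nucleotide)
    a6 <- mean(ctx$site6 == config$nucleotide)
    lr <- if (a3 > 0 && a6 > 0) log(a3 / a6) else NA_real_
  }
  data.frame(genome_id = genome$genome_id, config = config$label,
             n_contexts = n, a3 = a3, a6 = a6, log_ratio = lr,
             gc3 = genome$gc3, stringsAsFactors = FALSE)
}

#' Paired cross-genome test of site-3 versus site-6 usage
#'
#' Two-sided paired Wilcoxon signed-rank test of per-genome (a3 - a6)
#' differences (zero differences dropped, normal approximation), with the
#' cross-genome mean proportions and the count of genomes where a3 > a6.
#'
#' @param cohort data.frame of rows from [genome_site_usage()] (genomes with
#'   zero contexts are excluded listwise).
#' @return list: `statistic`, `p`, `mean_a3`, `mean_a6`, `n_greater`, `n`.
#' @export
paired_context_test <- function(cohort) {
  d <- cohort[!is.na(cohort$a3) & cohort$n_contexts > 0, , drop = FALSE]
  diffs <- d$a3 - d$a6
  if (!length(diffs)) stop("no genomes with qualifying contexts")
  if (all(diffs == 0))
    return(list(statistic = 0, p = 1, mean_a3 = mean(d$a3),
                mean_a6 = mean(d$a6), n_greater = 0L, n = nrow(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(d$a3, d$a6, paired = TRUE, exact = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       mean_a3 = mean(d$a3), mean_a6 = mean(d$a6),
       n_greater = sum(diffs > 0), n = nrow(d))
}

#' Correlation of the site-usage log ratio with GC3
#'
#' Tie-aware Spearman correlation of `log(a3/a6)` with genome GC3; genomes
#' with an undefined log ratio are dropped.
#'
#' @param cohort data.frame of rows from [genome_site_usage()].
#' @return list with `rho`, `p`, `n`.
#' @export
usage_gc3_correlation <- function(cohort) {
  spearman_test(cohort$gc3, cohort$log_ratio)
}
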