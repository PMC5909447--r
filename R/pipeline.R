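# End-to-end pipeline drivers tying the stages together. Each is idempotent
# given (inputs, seed) and optionally writes its result tables as TSV; the
# numbered scripts under analysis/ are thin wrappers around these.

#' Run the excess-simulation pipeline over a genome set
#'
#' For each genome and each requested null model: a replicate-simulation
#' ensemble, the per-(codon set, frame) excess table with Z / p / BH-q, the
#' genome-set excess summary, and Spearman correlations of Z with GC content.
#'
#' @param genomes list of `genome_record`s.
#' @param models subset of `c("shuffle","synsite","syncodon","markov2","markov5")`.
#' @param n_reps replicate simulations per genome (default 200).
#' @param seed integer seed covering the whole run.
#' @param alpha significance level for the excess summary.
#' @param out_dir optional directory for TSV outputs.
#' @return list with `excess` (full table), `summary`, `gc_correlation`.
#' @export
run_excess_pipeline <- function(genomes, models = c("shuffle", "synsite"),
                                n_reps = 200, seed = 1, alpha = 0.05,
                                out_dir = NULL) {
  if (!length(genomes)) stop("empty genome set")
  set.seed(as.integer(seed))
  tables <- list()
  for (model in models) {
    ens <- lapply(genomes, run_ensemble, model_kind = model, n_reps = n_reps)
    tables[[model]] <- excess_table(ens)
  }
  excess <- do.call(rbind, tables)
  rownames(excess) <- NULL
  gc <- stats::setNames(vapply(genomes, function(g) g$gc, numeric(1)),
                        vapply(genomes, function(g) g$genome_id, character(1)))
  summary <- summarize_excess(excess, alpha = alpha)
  gc_cor <- excess_gc_correlation(excess, gc)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_table(excess, file.path(out_dir, "excess.tsv"))
    write_tsv_table(summary, file.path(out_dir, "excess_summary.tsv"))
    write_tsv_table(gc_cor, file.path(out_dir, "excess_gc_correlation.tsv"))
  }
  list(excess = excess, summary = summary, gc_correlation = gc_cor)
}

#' Run the dicodon-context pipeline
#'
#' Per configuration: per-genome site-usage proportions, the paired
#' signed-rank test of site-3 versus site-6 usage, and the Spearman
#' correlation of the usage log ratio with GC3.
#'
#' @param genomes list of `genome_record`s.
#' @param configs list of `dicodon_config`s (default: Ile and Val, each
#'   unrestricted and A/T-restricted).
#' @param out_dir optional directory for TSV outputs.
#' @return list with `usage` (per-genome table) and `tests` (one row per
#'   config: paired-test and correlation results).
#' @export
run_dicodon_pipeline <- function(genomes, configs = default_dicodon_configs(),
                                 out_dir = NULL) {
  usage <- do.call(rbind, lapply(configs, function(cfg)
    do.call(rbind, lapply(genomes, genome_site_usage, config = cfg))))
  rownames(usage) <- NULL
  tests <- do.call(rbind, lapply(configs, function(cfg) {
    u <- usage[usage$config == cfg$label, , drop = FALSE]
    pt <- paired_context_test(u)
    gc <- usage_gc3_correlation(u)
    data.frame(config = cfg$label, target = cfg$target, n = pt$n,
               mean_a3 = pt$mean_a3, mean_a6 = pt$mean_a6,
               n_greater = pt$n_greater, statistic = pt$statistic,
               p = pt$p, rho_gc3 = gc$rho, p_gc3 = gc$p,
               stringsAsFactors = FALSE)
  }))
  rownames(tests) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_table(usage, file.path(out_dir, "dicodon_usage.tsv"))
    write_tsv_table(tests, file.path(out_dir, "dicodon_tests.tsv"))
  }
  list(usage = usage, tests = tests)
}

#' Default dicodon configurations
#'
#' Ile (+1 TAA) and Val (+1 TAG), each with all synonyms and with the
#' A/T-ending (GC3-controlled) restriction.
#'
#' @param table_id NCBI translation table id.
#' @return list of `dicodon_config`s.
#' @export
default_dicodon_configs <- function(table_id = 11) {
  list(dicodon_config("Ile", FALSE, table_id),
       dicodon_config("Ile", TRUE, table_id),
       dicodon_config("Val", FALSE, table_id),
       dicodon_config("Val", TRUE, table_id))
}

#' Run the genetic-code comparison pipeline
#'
#' @param cohort11,cohort4 lists of `genome_record`s using tables 11 and 4.
#' @param codon_sets,frames,span passed to [compare_code_cohorts()].
#' @param out_dir optional directory for TSV outputs.
#' @return list with `comparisons` (list of `residual_comparison`) and
#'   `summary` (one row per codon set and frame).
#' @export
run_code_comparison <- function(cohort11, cohort4,
                                codon_sets = list(stops = c("TAA", "TAG", "TGA"),
                                                  TAA = "TAA", TAG = "TAG",
                                                  TGA = "TGA"),
                                frames = c("Both", "+1", "+2"), span = 0.75,
                                out_dir = NULL) {
  cmp <- compare_code_cohorts(cohort11, cohort4, codon_sets, frames, span)
  summary <- do.call(rbind, lapply(cmp, function(x)
    data.frame(codon_set = x$codon_set, frame = x$frame,
               statistic = x$statistic, p = x$p,
               mr_table11 = unname(x$group_means["table11"]),
               mr_table4 = unname(x$group_means["table4"]),
               stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    detail <- do.call(rbind, lapply(cmp, function(x) {
      d <- x$data; d$codon_set <- x$codon_set; d$frame <- x$frame; d
    }))
    rownames(detail) <- NULL
    write_tsv_table(detail, file.path(out_dir, "code_compare_residuals.tsv"))
    write_tsv_table(summary, file.path(out_dir, "code_compare_summary.tsv"))
  }
  list(comparisons = cmp, summary = summary)
}

#' Run the CAI pipeline over one genome
#'
#' Selects the ribosomal reference set (or uses explicit indices), computes
#' relative adaptiveness from the reference CAI halves, and the per-CDS
#' CAI-versus-second-half-density association.
#'
#' @param genome a `genome_record`.
#' @param reference optional integer indices of reference CDSs (default:
#'   ribosomal-protein gene-name selection).
#' @param codon_set,frames density target (defaults: genome stop set, +1).
#' @param out_dir optional directory for TSV output.
#' @return list with `w`, `association` (rho, p, n), and `per_cds`.
#' @export
run_cai_pipeline <- function(genome, reference = NULL, codon_set = "stops",
                             frames = "+1", out_dir = NULL) {
  if (is.null(reference)) reference <- select_reference_set(genome)
  w <- compute_w(genome$codons[reference], genome$table)
  assoc <- cai_density_association(genome, w, codon_set, frames)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tab <- assoc$per_cds
    tab$genome_id <- genome$genome_id
    write_tsv_table(tab, file.path(out_dir,
                                   paste0("cai_", genome$genome_id, ".tsv")))
  }
  list(w = w, association = assoc[c("rho", "p", "n")],
       per_cds = assoc$per_cds)
}
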