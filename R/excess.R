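# Excess statistics: Z scores against simulation ensembles, two-tailed
# normal-approximation p values, BH-FDR across genomes, genome-set summaries,
# and Spearman correlations of excess with GC content.

#' Z score of a real density against simulated densities
#'
#' `z = (real - mean(sims)) / sd(sims)` with the n-1 standard-deviation
#' estimator. A zero-spread ensemble is flagged undefined (`NA`) rather than
#' assigned an infinite score.
#'
#' @param real observed density.
#' @param sims numeric vector of at least two simulated densities.
#' @return numeric Z, or `NA` when `sd(sims) == 0`.
#' @export
z_score <- function(real, sims) {
  if (length(sims) < 2L) stop("need at least 2 simulated values")
  s <- stats::sd(sims)
  if (s == 0) return(NA_real_)
  (real - mean(sims)) / s
}

#' Two-tailed normal p value from a Z score
#'
#' @param z numeric Z score(s).
#' @return `2 * pnorm(-|z|)`.
#' @export
p_from_z <- function(z) {
  2 * stats::pnorm(-abs(z))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up BH with monotonicity enforcement, stable under input order.
#'
#' @param pvals numeric vector of p values in `[0, 1]`.
#' @return vector of q values in input order (empty input gives empty output).
#' @export
bh_fdr <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' Excess table from simulation ensembles
#'
#' Combines ensembles (typically one per genome for a shared model) into the
#' per-(genome, codon set, frame) excess table with Z, p, and BH q values.
#' The correction family is all genomes sharing one (model, codon set, frame)
#' triple, so one corrected p value is reported per genome per family.
#'
#' @param ensembles list of `simulation_ensemble` objects.
#' @return data.frame with columns `genome_id`, `model`, `codon_set`,
#'   `frame`, `real_density`, `sim_mean`, `sim_sd`, `z`, `p`, `q`.
#' @export
excess_table <- function(ensembles) {
  if (inherits(ensembles, "simulation_ensemble")) ensembles <- list(ensembles)
  rows <- do.call(rbind, lapply(ensembles, function(e) {
    s <- ensemble_summary(e)
    s$z <- mapply(function(cs, fr) z_score(e$real[cs, fr], e$sims[, cs, fr]),
                  s$codon_set, s$frame)
    s
  }))
  rows$p <- p_from_z(rows$z)
  rows$q <- NA_real_
  fam <- interaction(rows$model, rows$codon_set, rows$frame, drop = TRUE)
  for (f in levels(fam)) {
    i <- which(fam == f & !is.na(rows$p))
    rows$q[i] <- bh_fdr(rows$p[i])
  }
  rownames(rows) <- NULL
  rows
}

#' Summarise significant excesses across a genome set
#'
#' A genome has a significant positive excess when `z > 0` and its
#' BH-corrected p value is below `alpha`; significant negative excesses
#' (`z < 0`) are counted alongside.
#'
#' @param results an excess table from [excess_table()] (must contain `z` and
#'   `q`; `q` is recomputed per family when absent).
#' @param alpha significance level (default 0.05).
#' @return data.frame per (model, codon_set, frame): `n_genomes`,
#'   `n_excess`, `pct_excess`, `n_negative`, `pct_negative`.
#' @export
summarize_excess <- function(results, alpha = 0.05) {
  if (is.null(results$q)) {
    results$q <- NA_real_
    fam <- interaction(results$model, results$codon_set, results$frame, drop = TRUE)
    for (f in levels(fam)) {
      i <- which(fam == f & !is.na(results$p))
      results$q[i] <- bh_fdr(results$p[i])
    }
  }
  agg <- function(d) {
    data.frame(model = d$model[1], codon_set = d$codon_set[1],
               frame = d$frame[1], n_genomes = nrow(d),
               n_excess = sum(d$z > 0 & d$q < alpha, na.rm = TRUE),
               pct_excess = 100 * sum(d$z > 0 & d$q < alpha, na.rm = TRUE) / nrow(d),
               n_negative = sum(d$z < 0 & d$q < alpha, na.rm = TRUE),
               pct_negative = 100 * sum(d$z < 0 & d$q < alpha, na.rm = TRUE) / nrow(d),
               stringsAsFactors = FALSE)
  }
  parts <- split(results,
                 interaction(results$model, results$codon_set, results$frame,
                             drop = TRUE))
  out <- do.call(rbind, lapply(parts, agg))
  rownames(out) <- NULL
  out
}

# tie-aware Spearman correlation with asymptotic two-sided p; NA on
# degenerate input
spearman_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlation of OSC excess with genome GC content
#'
#' Spearman rank correlation (tie-aware, two-sided asymptotic p) of genome Z
#' scores against genome GC content, per (model, codon set, frame) family.
#'
#' @param results an excess table from [excess_table()].
#' @param gc_by_genome named numeric vector of GC fractions indexed by
#'   `genome_id`.
#' @return data.frame per family with `rho`, `p`, `n`.
#' @export
excess_gc_correlation <- function(results, gc_by_genome) {
  results$gc <- unname(gc_by_genome[results$genome_id])
  parts <- split(results,
                 interaction(results$model, results$codon_set, results$frame,
                             drop = TRUE))
  out <- do.call(rbind, lapply(parts, function(d) {
    st <- spearman_test(d$gc, d$z)
    data.frame(model = d$model[1], codon_set = d$codon_set[1],
               frame = d$frame[1], rho = st$rho, p = st$p, n = st$n,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Restrict to the top genomes of one excess family by Z score
#'
#' @param results excess table rows sharing one (model, codon_set, frame) key.
#' @param top_n number of genomes to keep (descending Z, ties broken by
#'   `genome_id`).
#' @return the selected rows.
#' @export
rank_restrict <- function(results, top_n) {
  key <- unique(results[, c("model", "codon_set", "frame")])
  if (nrow(key) != 1L)
    stop("rank_restrict expects rows from a single (model, codon_set, frame) family")
  if (top_n > nrow(results)) {
    warning("top_n exceeds the number of genomes; returning all")
    top_n <- nrow(results)
  }
  ord <- order(-results$z, results$genome_id)
  out <- results[ord[seq_len(top_n)], , drop = FALSE]
  rownames(out) <- NULL
  out
}
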