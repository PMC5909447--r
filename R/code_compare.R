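# Translation-table 11 versus table 4 comparison: a pooled loess regression
# of OSC density on GC content removes the compositional trend; residuals
# are then compared between code groups with Kruskal-Wallis tests.

#' Loess fit of density on GC content
#'
#' Locally weighted polynomial regression (tricube weights, local degree 2 by
#' default, no robustness iterations) evaluated at each genome's GC.
#'
#' @param x GC fractions.
#' @param y densities per 100 codons.
#' @param span loess span (default 0.75).
#' @param degree local polynomial degree (default 2).
#' @return list with `fitted`, `residuals` (`y - fitted`), `span`, `model`.
#' @export
fit_loess <- function(x, y, span = 0.75, degree = 2) {
  stopifnot(length(x) == length(y))
  if (length(x) < 10L)
    stop("loess fit needs at least 10 genomes pooled across both groups")
  fit <- tryCatch(
    stats::loess(y ~ x, span = span, degree = degree, family = "gaussian",
                 control = stats::loess.control(surface = "direct")),
    error = function(e)
      stop("loess fit failed (span = ", span,
           " may be too small for local neighbourhoods): ",
           conditionMessage(e)))
  fitted <- stats::predict(fit, newdata = data.frame(x = x))
  list(fitted = fitted, residuals = y - fitted, span = span, model = fit)
}

#' Kruskal-Wallis test of residuals between groups
#'
#' Tie-corrected Kruskal-Wallis on residual ranks, with group mean residuals.
#'
#' @param residuals numeric residual vector.
#' @param labels group labels (same length).
#' @return list: `statistic`, `p`, `group_means` (named), `n_per_group`.
#' @export
residual_group_test <- function(residuals, labels) {
  labels <- as.character(labels)
  stopifnot(length(residuals) == length(labels))
  tab <- table(labels)
  if (length(tab) < 2L || any(tab == 0))
    stop("need at least two non-empty groups")
  if (length(unique(residuals)) == 1L)  # all tied: no rank information
    return(list(statistic = 0, p = 1,
                group_means = tapply(residuals, labels, mean),
                n_per_group = as.vector(tab)))
  kw <- stats::kruskal.test(residuals, factor(labels))
  list(statistic = unname(kw$statistic), p = kw$p.value,
       group_means = tapply(residuals, labels, mean),
       n_per_group = as.vector(tab))
}

#' Compare genetic-code groups at matched GC content
#'
#' Fits one pooled loess of density on GC over BOTH groups (the fit is blind
#' to group labels), extracts residuals, and compares residual distributions
#' between groups with a Kruskal-Wallis test.
#'
#' @param data data.frame with columns `genome_id`, `group`, `gc`, `density`
#'   (one row per genome, one codon set and frame at a time).
#' @param codon_set label for the codon set (metadata only).
#' @param frame label for the frame (metadata only).
#' @param span loess span (default 0.75).
#' @return object of class `residual_comparison`: the input table augmented
#'   with `fitted` and `residual`, plus `statistic`, `p`, `group_means`.
#' @export
compare_codes <- function(data, codon_set = "stops", frame = "Both",
                          span = 0.75) {
  stopifnot(all(c("genome_id", "group", "gc", "density") %in% names(data)))
  fit <- fit_loess(data$gc, data$density, span = span)
  data$fitted <- fit$fitted
  data$residual <- fit$residuals
  test <- residual_group_test(data$residual, data$group)
  structure(
    list(codon_set = codon_set, frame = frame, span = span, data = data,
         statistic = test$statistic, p = test$p,
         group_means = test$group_means),
    class = "residual_comparison")
}

#' @export
print.residual_comparison <- function(x, ...) {
  cat(sprintf("<residual_comparison> %s %s | KW = %.3f, p = %.3g\n",
              x$codon_set, x$frame, x$statistic, x$p))
  gm <- x$group_means
  for (g in names(gm)) cat(sprintf("  mean residual [%s] = %.4f\n", g, gm[[g]]))
  invisible(x)
}

#' Compare table-11 and table-4 genome cohorts
#'
#' Computes OSC densities identically for both cohorts (explicit codon set,
#' so the comparison does not depend on each genome's own stop set) and runs
#' [compare_codes()] for every requested codon set and frame.
#'
#' @param cohort11,cohort4 lists of `genome_record`s.
#' @param codon_sets named list of codon sets (default: pooled stops
#'   TAA/TAG/TGA and each stop singly).
#' @param frames frames to test (default `c("Both", "+1", "+2")`).
#' @param span loess span.
#' @return named list of `residual_comparison` objects (`<set>|<frame>`).
#' @export
compare_code_cohorts <- function(cohort11, cohort4,
                                 codon_sets = list(stops = c("TAA", "TAG", "TGA"),
                                                   TAA = "TAA", TAG = "TAG",
                                                   TGA = "TGA"),
                                 frames = c("Both", "+1", "+2"),
                                 span = 0.75) {
  genomes <- c(cohort11, cohort4)
  group <- c(rep("table11", length(cohort11)), rep("table4", length(cohort4)))
  gc <- vapply(genomes, function(g) g$gc, numeric(1))
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  out <- list()
  for (cs in names(codon_sets)) for (fr in frames) {
    dens <- vapply(genomes, osc_density, numeric(1),
                   codon_set = codon_sets[[cs]], frames = fr)
    d <- data.frame(genome_id = ids, group = group, gc = gc, density = dens,
                    stringsAsFactors = FALSE)
    out[[paste(cs, fr, sep = "|")]] <- compare_codes(d, cs, fr, span = span)
  }
  out
}
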