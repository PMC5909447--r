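# Codon-position-aware Markov sequence models (orders 2 and 5).
#
# Training discounts the start and terminal stop codon of every CDS; windows
# slide one nucleotide at a time over the internal region, and transition
# probabilities are keyed by the context string AND the codon position
# (phase) of the nucleotide being sampled.  Lower-order distributions down to
# the phase-specific mononucleotide distribution are trained alongside for
# back-off at contexts never observed.

internal_nt_chars <- function(cod) {
  # internal codons -> interleaved nucleotide characters
  n <- length(cod)
  if (n <= 2L) return(character(0))
  ci <- cod[2:(n - 1L)]
  NUC[as.vector(rbind(CODON_NT1[ci], CODON_NT2[ci], CODON_NT3[ci]))]
}

#' Build a codon-position-aware Markov model from a genome
#'
#' @param genome a `genome_record` (CDSs already filtered).
#' @param order Markov order, 2 or 5.
#' @return object of class `markov_model` with per-order transition
#'   environments (orders `order` down to 0, each keyed by
#'   `"<context>:<phase>"`).
#' @export
build_markov_model <- function(genome, order = 2) {
  stopifnot(order %in% c(2L, 5L) || (order >= 1 && order == round(order)))
  order <- as.integer(order)
  cds_nt <- lapply(genome$codons, internal_nt_chars)
  cds_nt <- cds_nt[lengths(cds_nt) > 0L]
  if (!length(cds_nt) || max(lengths(cds_nt)) <= order)
    stop("genome has no internal sequence longer than the model order (",
         order, ")")
  envs <- vector("list", order + 1L)
  for (k in 0:order) {
    keys <- character(0); succ <- character(0)
    for (v in cds_nt) {
      L <- length(v)
      if (L < k + 1L) next
      i <- seq_len(L - k)          # context start positions
      t <- i + k                   # target positions
      ctx <- if (k == 0L) "" else
        vapply(i, function(ii) paste(v[ii:(ii + k - 1L)], collapse = ""), "")
      keys <- c(keys, paste0(ctx, ":", (t - 1L) %% 3L + 1L))
      succ <- c(succ, v[t])
    }
    cnt <- table(keys, factor(succ, levels = NUC))
    e <- new.env(parent = emptyenv(), size = nrow(cnt))
    p <- cnt / rowSums(cnt)
    for (r in seq_len(nrow(cnt)))
      assign(rownames(cnt)[r], as.numeric(p[r, ]), envir = e)
    envs[[k + 1L]] <- e
  }
  structure(list(order = order, envs = envs,
                 table_id = genome$table$table_id),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat("<markov_model> order", x$order, "with",
      length(ls(x$envs[[x$order + 1L]])), "contexts\n")
  invisible(x)
}

# transition distribution with recursive back-off to lower orders
markov_lookup <- function(model, out, pos, phase) {
  for (k in seq.int(min(model$order, pos - 1L), 0L)) {
    ctx <- if (k == 0L) "" else paste(out[(pos - k):(pos - 1L)], collapse = "")
    p <- model$envs[[k + 1L]][[paste0(ctx, ":", phase)]]
    if (!is.null(p)) return(p)
  }
  rep.int(0.25, 4)  # unreachable when the order-0 phase was trained
}

#' Simulate a CDS under a Markov model
#'
#' The output keeps the real start codon and the first `order` internal
#' nucleotides as seed, then samples nucleotide by nucleotide (conditioning
#' on the trailing `order` nucleotides and the simulated sequence's own codon
#' phase) until the internal length matches, and appends the real stop codon.
#'
#' @param cds `coding_sequence`, nucleotide string, or codon-id vector.
#' @param model a `markov_model` trained on the same genome.
#' @return simulated nucleotide string; same length, start, and stop as the
#'   input.
#' @export
simulate_cds_markov <- function(cds, model) {
  cod <- as_codon_ids(cds)
  n <- length(cod)
  if (n <= 2L) return(codons_to_seq(cod))
  real_internal <- internal_nt_chars(cod)
  Li <- length(real_internal)
  seed_len <- min(model$order, Li)
  out <- character(Li)
  out[seq_len(seed_len)] <- real_internal[seq_len(seed_len)]
  if (Li > seed_len) {
    for (pos in (seed_len + 1L):Li) {
      phase <- (pos - 1L) %% 3L + 1L
      p <- markov_lookup(model, out, pos, phase)
      out[pos] <- NUC[sample.int(4L, 1L, prob = p)]
    }
  }
  paste0(CODONS[cod[1L]], paste(out, collapse = ""), CODONS[cod[n]])
}
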