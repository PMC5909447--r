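# Null-sequence simulators that operate on internal codons only (the start
# codon and terminal stop are always copied verbatim): within-CDS codon
# shuffling, synonymous-site resampling within coding blocks, and
# synonymous-codon resampling pooled across blocks.
#
# All three have a vectorised "flat" engine used by the ensemble driver and a
# per-CDS public wrapper; the wrappers call the same engine on a one-CDS flat
# layout so there is a single code path.

# ---- codon shuffle ---------------------------------------------------------

# uniform within-CDS permutation of internal codons (order() on a random key
# within each CDS group is a uniform permutation)
sim_shuffle_flat <- function(flat) {
  cod <- flat$cod
  idx <- which(flat$internal)
  if (length(idx) > 1L) {
    ord <- order(flat$cds_i[idx], stats::runif(length(idx)))
    cod[idx] <- cod[idx][ord]
  }
  cod
}

#' Shuffle the internal codons of a CDS
#'
#' Removes the start and terminal stop codon, uniformly permutes the internal
#' codons, and re-attaches start and stop. Uses the current RNG stream.
#'
#' @param cds `coding_sequence`, nucleotide string, or codon-id vector.
#' @return simulated nucleotide string of the same length.
#' @export
shuffle_codons <- function(cds) {
  cod <- as_codon_ids(cds)
  n <- length(cod)
  if (n <= 3L) return(codons_to_seq(cod))  # no or one internal codon
  flat <- list(cod = cod, cds_i = rep.int(1L, n),
               internal = c(FALSE, rep.int(TRUE, n - 2L), FALSE))
  codons_to_seq(sim_shuffle_flat(flat))
}

# ---- shared categorical-resampling machinery -------------------------------

# Build per-codon replacement tables: for each codon id, the candidate
# replacement ids and their cumulative probabilities (count-normalised from
# the genome).  `groups` is a list mapping codon id -> candidate ids.
build_repl_tables <- function(counts, groups, max_k) {
  repl_id <- matrix(0L, 64, max_k)
  repl_cum <- matrix(1, 64, max_k)
  available <- rep.int(FALSE, 64)
  probs <- vector("list", 64)
  for (c_id in seq_len(64)) {
    cand <- groups[[c_id]]
    if (is.null(cand)) next
    cnt <- counts[cand]
    tot <- sum(cnt)
    if (tot == 0) next
    available[c_id] <- TRUE
    p <- cnt / tot
    k <- length(cand)
    repl_id[c_id, seq_len(k)] <- cand
    repl_cum[c_id, seq_len(k)] <- cumsum(p)
    repl_cum[c_id, ] <- pmin(repl_cum[c_id, ], 1)
    if (k < max_k) repl_cum[c_id, (k + 1):max_k] <- 1
    probs[[c_id]] <- data.frame(codon = CODONS[c_id], replacement = CODONS[cand],
                                prob = as.numeric(p), stringsAsFactors = FALSE)
  }
  list(repl_id = repl_id, repl_cum = repl_cum, available = available,
       probs = do.call(rbind, probs[available]))
}

# resample internal codons from a replacement-table object
sim_resample_flat <- function(flat, tab) {
  cod <- flat$cod
  idx <- which(flat$internal)
  if (length(idx) == 0L) return(cod)
  cvec <- cod[idx]
  u <- stats::runif(length(idx))
  j <- rep.int(1L, length(idx))
  for (k in seq_len(ncol(tab$repl_cum) - 1L))
    j <- j + (u > tab$repl_cum[cbind(cvec, k)])
  cod[idx] <- tab$repl_id[cbind(cvec, j)]
  cod
}

check_available <- function(tab, cvec, what) {
  bad <- unique(cvec[!tab$available[cvec]])
  if (length(bad))
    stop("codon(s) ", paste(CODONS[bad], collapse = ","),
         " absent from the genome-trained ", what)
}

internal_codon_counts <- function(genome) {
  tabulate(genome$flat$cod[genome$flat$internal], nbins = 64L)
}

# ---- synonymous-site model -------------------------------------------------

#' Build a synonymous-site table from a genome
#'
#' Nucleotide frequencies at synonymous (third) sites are counted over the
#' genome's internal codons and normalised within each coding block: the set
#' of an amino acid's synonyms sharing their first two nucleotides. The
#' 6-fold amino acids (Leu, Ser, Arg) therefore split into their 2-fold and
#' 4-fold blocks; 1-fold amino acids have a single deterministic entry.
#'
#' @param genome a `genome_record`.
#' @return object of class `synsite_table`; `$probs` tabulates the
#'   within-block replacement probabilities.
#' @export
build_synsite_table <- function(genome) {
  aa <- genome$table$codon_to_aa
  groups <- lapply(seq_len(64), function(c_id) {
    if (aa[c_id] == "*") return(NULL)
    which(CODON_NT1 == CODON_NT1[c_id] & CODON_NT2 == CODON_NT2[c_id] &
            aa == aa[c_id])
  })
  tab <- build_repl_tables(internal_codon_counts(genome), groups, max_k = 4L)
  tab$table_id <- genome$table$table_id
  class(tab) <- "synsite_table"
  tab
}

#' Simulate a CDS under the synonymous-site model
#'
#' Each internal codon is replaced by a codon of the same amino acid and the
#' same coding block, with its synonymous site drawn from the block's
#' genome-wide frequencies. The amino-acid sequence and block membership of
#' every position are preserved exactly; start and stop are copied unchanged.
#'
#' @param cds `coding_sequence`, nucleotide string, or codon-id vector.
#' @param table a `synsite_table` built from the same genome.
#' @return simulated nucleotide string.
#' @export
simulate_cds_synsite <- function(cds, table) {
  cod <- as_codon_ids(cds)
  n <- length(cod)
  if (n <= 2L) return(codons_to_seq(cod))
  internal <- c(FALSE, rep.int(TRUE, n - 2L), FALSE)
  check_available(table, cod[internal], "synonymous-site table")
  flat <- list(cod = cod, internal = internal)
  codons_to_seq(sim_resample_flat(flat, table))
}

# ---- synonymous-codon model ------------------------------------------------

#' Build a codon-usage table from a genome
#'
#' Codon frequencies over the genome's internal codons, normalised per amino
#' acid with all coding blocks of 6-fold amino acids pooled.
#'
#' @param genome a `genome_record`.
#' @return object of class `codon_usage_table`; `$probs` tabulates per-amino-
#'   acid codon probabilities.
#' @export
build_codon_usage <- function(genome) {
  aa <- genome$table$codon_to_aa
  groups <- lapply(seq_len(64), function(c_id) {
    if (aa[c_id] == "*") return(NULL)
    which(aa == aa[c_id])
  })
  tab <- build_repl_tables(internal_codon_counts(genome), groups, max_k = 6L)
  tab$table_id <- genome$table$table_id
  class(tab) <- "codon_usage_table"
  tab
}

#' Simulate a CDS under the synonymous-codon model
#'
#' Each internal codon is resampled from the full synonym set of its amino
#' acid (blocks pooled); start and stop are copied unchanged.
#'
#' @inheritParams simulate_cds_synsite
#' @param usage a `codon_usage_table` built from the same genome.
#' @return simulated nucleotide string.
#' @export
simulate_cds_syncodon <- function(cds, usage) {
  cod <- as_codon_ids(cds)
  n <- length(cod)
  if (n <= 2L) return(codons_to_seq(cod))
  internal <- c(FALSE, rep.int(TRUE, n - 2L), FALSE)
  check_available(usage, cod[internal], "codon-usage table")
  flat <- list(cod = cod, internal = internal)
  codons_to_seq(sim_resample_flat(flat, usage))
}
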