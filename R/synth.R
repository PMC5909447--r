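# Synthetic bacterial genome cohorts with the statistical structure the
# analyses assume: controllable GC3 via tilted within-amino-acid codon usage,
# a fixed bacterial-like amino-acid profile, table 11/4 start/stop
# conventions, and injectable enrichment of OSC-forming synonymous choices.
# Internal codons are drawn i.i.d., so codon order is exchangeable and the
# shuffle null is calibrated by construction.

# average bacterial proteome amino-acid composition (fractions sum to 1)
BACTERIAL_AA_FREQ <- c(
  A = 0.095, R = 0.055, N = 0.040, D = 0.054, C = 0.012, E = 0.058,
  Q = 0.044, G = 0.074, H = 0.022, I = 0.060, L = 0.105, K = 0.044,
  M = 0.028, F = 0.039, P = 0.044, S = 0.058, T = 0.054, W = 0.014,
  Y = 0.029, V = 0.071)

#' Sample a codon-usage table targeting a GC3 value
#'
#' Per-amino-acid synonym probabilities are drawn from a symmetric Dirichlet
#' (the `concentration` parameter sets how far usage may deviate from
#' uniform) and then exponentially tilted toward or away from G/C-ending
#' codons so that the expected third-site G+C fraction of a random codon
#' stream matches `gc3_target`. Amino-acid frequencies follow a fixed
#' bacterial-like profile.
#'
#' @param gc3_target target GC3 in (0, 1).
#' @param concentration Dirichlet concentration (larger = closer to uniform
#'   within each amino acid; default 20).
#' @param table a `trans_table` (default table 11).
#' @param aa_freq amino-acid frequency profile (default the built-in
#'   bacterial average, renormalised over the table's amino acids).
#' @return object of class `synth_usage`: `codon_probs` (length 64, i.i.d.
#'   sense-codon distribution), `aa_probs` (per-amino-acid synonym
#'   probabilities), `gc3_target`, `gc3_expected`.
#' @export
sample_codon_usage <- function(gc3_target, concentration = 20,
                               table = translation_table(11),
                               aa_freq = BACTERIAL_AA_FREQ) {
  stopifnot(gc3_target > 0, gc3_target < 1)
  aa <- table$codon_to_aa
  aas <- setdiff(sort(unique(aa)), "*")
  f <- aa_freq[aas]
  if (anyNA(f)) stop("aa_freq lacks entries for: ",
                     paste(aas[is.na(f)], collapse = ","))
  f <- f / sum(f)
  ids <- lapply(aas, function(a) which(aa == a))
  base <- lapply(ids, function(v) {
    d <- stats::rgamma(length(v), shape = concentration)
    d / sum(d)
  })
  g3 <- lapply(ids, function(v) CODON_GC3[v])
  expected_gc3 <- function(s) {
    e <- vapply(seq_along(aas), function(i) {
      w <- base[[i]] * exp(s * g3[[i]])
      sum(w * g3[[i]]) / sum(w)
    }, numeric(1))
    sum(f * e)
  }
  lo <- -30; hi <- 30
  if (expected_gc3(lo) > gc3_target) {
    warning("gc3_target below the achievable minimum; clamping")
    s <- lo
  } else if (expected_gc3(hi) < gc3_target) {
    warning("gc3_target above the achievable maximum; clamping")
    s <- hi
  } else {
    s <- stats::uniroot(function(x) expected_gc3(x) - gc3_target,
                        c(lo, hi), tol = 1e-9)$root
  }
  codon_probs <- numeric(64)
  aa_probs <- vector("list", length(aas))
  names(aa_probs) <- aas
  for (i in seq_along(aas)) {
    w <- base[[i]] * exp(s * g3[[i]])
    w <- w / sum(w)
    aa_probs[[i]] <- stats::setNames(w, CODONS[ids[[i]]])
    codon_probs[ids[[i]]] <- f[[i]] * w
  }
  structure(list(codon_probs = codon_probs, aa_probs = aa_probs,
                 table_id = table$table_id, gc3_target = gc3_target,
                 gc3_expected = expected_gc3(s), tilt = s),
            class = "synth_usage")
}

#' Generate one synthetic genome
#'
#' Each CDS is an ATG start codon, internal codons drawn i.i.d. from the
#' usage table (sense codons only, so in-frame stops cannot occur under the
#' genome's table), and a terminal stop drawn uniformly from the table's stop
#' set. Every generated CDS passes the four CDS filter rules by construction.
#'
#' @param genome_id identifier string.
#' @param usage a `synth_usage` from [sample_codon_usage()].
#' @param n_cds number of CDSs.
#' @param cds_len_range codon-count range per CDS, start and stop included
#'   (default 60-240).
#' @param genus optional genus label.
#' @return a `genome_record`.
#' @export
generate_genome <- function(genome_id, usage, n_cds = 80,
                            cds_len_range = c(60, 240),
                            genus = NA_character_) {
  table <- translation_table(usage$table_id)
  lens <- sample.int(cds_len_range[2] - cds_len_range[1] + 1L, n_cds,
                     replace = TRUE) + cds_len_range[1] - 1L
  n_int <- lens - 2L
  internals <- sample.int(64L, sum(n_int), replace = TRUE,
                          prob = usage$codon_probs)
  stops <- table$stop_ids[sample.int(length(table$stop_ids), n_cds,
                                     replace = TRUE)]
  start <- codon_id("ATG")
  grp <- rep.int(seq_len(n_cds), n_int)
  parts <- split(internals, grp)
  codon_list <- lapply(seq_len(n_cds), function(i)
    c(start, parts[[i]], stops[i]))
  names(codon_list) <- sprintf("%s_cds%04d", genome_id, seq_len(n_cds))
  genome_record(genome_id, codon_list, table_id = usage$table_id,
                genus = genus, genome_size_bp = 3L * sum(lens))
}

# candidate OSC-forming synonyms of each codon for a (target, frame) pair:
# synonyms whose in-pair nucleotides spell the target given a conducive
# downstream codon
osc_synonym_candidates <- function(table, target, frame) {
  t_nt <- nt_indices(target)
  aa <- table$codon_to_aa
  lapply(seq_len(64), function(c_id) {
    if (aa[c_id] == "*") return(integer(0))
    syn <- which(aa == aa[c_id])
    if (frame == "+1")
      syn[CODON_NT2[syn] == t_nt[1] & CODON_NT3[syn] == t_nt[2]]
    else
      syn[CODON_NT3[syn] == t_nt[1]]
  })
}

#' Inject out-of-frame stop enrichment into a genome
#'
#' One left-to-right pass over internal codons with the downstream codon
#' fixed: wherever a synonymous swap of the current codon would create (or
#' the current codon already creates) the target OSC with its downstream
#' neighbour, the OSC-forming synonym is adopted with probability `delta`
#' (chosen uniformly when the amino acid offers more than one). The
#' amino-acid sequence is unchanged and `delta = 0` is the identity in
#' distribution.
#'
#' @param genome a `genome_record`.
#' @param target target stop trinucleotide (default `"TAA"`).
#' @param frame `"+1"` or `"+2"`.
#' @param delta adoption probability in `[0, 1]`.
#' @return a new `genome_record` with the same CDS structure.
#' @export
inject_osc_bias <- function(genome, target = "TAA", frame = "+1", delta) {
  stopifnot(delta >= 0, delta <= 1, frame %in% c("+1", "+2"))
  t_nt <- nt_indices(toupper(target))
  cand <- osc_synonym_candidates(genome$table, toupper(target), frame)
  n_cand <- lengths(cand)
  cand_mat <- matrix(0L, 64, max(n_cand, 1L))
  for (c_id in which(n_cand > 0)) cand_mat[c_id, seq_len(n_cand[c_id])] <- cand[[c_id]]
  flat <- genome$flat
  cod <- flat$cod
  li <- flat$pair_left[flat$internal[flat$pair_left]]
  nxt <- cod[li + 1L]
  cond <- if (frame == "+1") CODON_NT1[nxt] == t_nt[3]
          else CODON_NT1[nxt] == t_nt[2] & CODON_NT2[nxt] == t_nt[3]
  sel <- li[cond & n_cand[cod[li]] > 0L]
  sel <- sel[stats::runif(length(sel)) < delta]
  if (length(sel)) {
    k <- n_cand[cod[sel]]
    pick <- 1L + as.integer(stats::runif(length(sel)) * k) %% k
    cod[sel] <- cand_mat[cbind(cod[sel], pick)]
  }
  rebuild_genome(genome, cod)
}

# rebuild a genome_record from a modified flat codon vector (same layout)
rebuild_genome <- function(genome, cod) {
  codon_list <- split(cod, genome$flat$cds_i)
  names(codon_list) <- names(genome$codons)
  genome_record(genome$genome_id, codon_list,
                table_id = genome$table$table_id, genus = genome$genus,
                genome_size_bp = genome$genome_size_bp,
                gene_names = genome$gene_names)
}

#' Inject a site-3 usage bias into dicodon contexts
#'
#' At every qualifying dicodon context the FIRST codon's synonymous site is
#' redrawn with the configured nucleotide's probability raised by `delta`
#' (absolute, clamped at 1) over its value under `usage`; the other synonyms
#' keep their relative proportions. Site 6 is untouched, so the expected
#' site-3 minus site-6 usage difference equals `delta`.
#'
#' @param genome a `genome_record` generated from `usage`.
#' @param usage the `synth_usage` the genome was generated from.
#' @param config a `dicodon_config`.
#' @param delta absolute increase of the target-nucleotide probability.
#' @return a new `genome_record`.
#' @export
inject_context_bias <- function(genome, usage, config, delta) {
  stopifnot(delta >= 0, delta <= 1)
  syn <- config$pair_ids
  p <- usage$codon_probs[syn]
  p <- p / sum(p)
  is_a <- NUC[CODON_NT3[syn]] == config$nucleotide
  if (!any(is_a)) stop("no ", config$nucleotide, "-ending synonym available")
  p_a <- sum(p[is_a])
  p_a_new <- min(p_a + delta, 1)
  # conditional draws within the A-ending and non-A-ending synonym groups
  pa_grp <- p[is_a] / sum(p[is_a])
  pn_grp <- if (all(is_a)) numeric(0) else p[!is_a] / sum(p[!is_a])
  flat <- genome$flat
  cod <- flat$cod
  i <- seq_len(flat$n_codons - 2L)
  same <- flat$cds_i[i] == flat$cds_i[i + 2L]
  hit <- same & cod[i] %in% syn & cod[i + 1L] %in% syn &
    CODON_NT1[cod[i + 2L]] %in% config$follower_nt & flat$internal[i]
  sel <- i[hit]
  if (length(sel)) {
    use_a <- stats::runif(length(sel)) < p_a_new
    new <- integer(length(sel))
    if (any(use_a))
      new[use_a] <- syn[is_a][sample.int(sum(is_a), sum(use_a), replace = TRUE,
                                         prob = pa_grp)]
    if (any(!use_a))
      new[!use_a] <- syn[!is_a][sample.int(sum(!is_a), sum(!use_a),
                                           replace = TRUE, prob = pn_grp)]
    cod[sel] <- new
  }
  rebuild_genome(genome, cod)
}

#' Generate a synthetic genome cohort
#'
#' @param n_genomes number of genomes.
#' @param gc3_range GC3 targets drawn uniformly from this range (ignored when
#'   `gc3_targets` is given).
#' @param gc3_targets optional explicit per-genome GC3 targets (recycled).
#' @param n_cds_range per-genome CDS-count range (default 60-100).
#' @param cds_len_range per-CDS codon-count range (default 60-240).
#' @param table_ids translation table id(s), recycled across genomes.
#' @param concentration Dirichlet concentration for codon usage.
#' @param enrich optional enrichment spec: `list(target =, frame =, delta =)`
#'   with `delta` scalar or per-genome vector.
#' @param seed optional master seed; the cohort is fully reproducible from it.
#' @return list with `genomes` (list of `genome_record`s) and `truth`
#'   (data.frame: `genome_id`, `table_id`, `n_cds`, `gc3_target`,
#'   `gc3_realized`, `gc`, `delta`).
#' @export
generate_cohort <- function(n_genomes, gc3_range = c(0.25, 0.75),
                            gc3_targets = NULL, n_cds_range = c(60, 100),
                            cds_len_range = c(60, 240), table_ids = 11,
                            concentration = 20, enrich = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(gc3_targets))
    gc3_targets <- stats::runif(n_genomes, gc3_range[1], gc3_range[2])
  gc3_targets <- rep_len(gc3_targets, n_genomes)
  table_ids <- rep_len(table_ids, n_genomes)
  deltas <- if (is.null(enrich)) rep(0, n_genomes)
            else rep_len(enrich$delta, n_genomes)
  genomes <- vector("list", n_genomes)
  for (i in seq_len(n_genomes)) {
    usage <- sample_codon_usage(gc3_targets[i], concentration,
                                translation_table(table_ids[i]))
    nc <- sample.int(n_cds_range[2] - n_cds_range[1] + 1L, 1L) +
      n_cds_range[1] - 1L
    g <- generate_genome(sprintf("synth%03d", i), usage, n_cds = nc,
                         cds_len_range = cds_len_range)
    if (deltas[i] > 0)
      g <- inject_osc_bias(g, enrich$target, enrich$frame, deltas[i])
    genomes[[i]] <- g
  }
  truth <- data.frame(
    genome_id = vapply(genomes, function(g) g$genome_id, character(1)),
    table_id = table_ids,
    n_cds = vapply(genomes, n_cds, integer(1)),
    gc3_target = gc3_targets,
    gc3_realized = vapply(genomes, function(g) g$gc3, numeric(1)),
    gc = vapply(genomes, function(g) g$gc, numeric(1)),
    delta = deltas, stringsAsFactors = FALSE)
  list(genomes = genomes, truth = truth)
}
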