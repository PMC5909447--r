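# Codon Adaptation Index as an expression proxy, with the half-split
# protocol separating the sequence used to measure CAI (first half, after a
# 30-nt 5' trim) from the sequence used to measure OSC density (second half
# of the full CDS), so the two measures never share codons.

#' Select the ribosomal-protein reference set
#'
#' Matches gene names against the highly expressed ribosomal-protein ranges
#' rplA-rplF, rplI-rplU, and rpsB-rpsU (case-insensitive).
#'
#' @param genome a `genome_record` carrying `gene_names`, or `NULL` when
#'   `gene_names` is given directly.
#' @param gene_names optional character vector of gene names (defaults to
#'   `genome$gene_names`).
#' @return integer indices of the reference CDSs; warns when fewer than 20
#'   match, errors when none do.
#' @export
select_reference_set <- function(genome = NULL, gene_names = NULL) {
  if (is.null(gene_names)) gene_names <- genome$gene_names
  if (is.null(gene_names))
    stop("no gene names available; supply an explicit reference list")
  hit <- grepl("^(rpl[A-FI-U]|rps[B-U])$", gene_names, ignore.case = TRUE)
  idx <- which(hit)
  if (!length(idx))
    stop("no ribosomal-protein gene names matched; ",
         "supply an explicit reference CDS list")
  if (length(idx) < 20L)
    warning("only ", length(idx), " reference genes found (expected ~20)")
  idx
}

#' Trim and split a CDS for the CAI protocol
#'
#' Removes the first 30 nucleotides (the 5' region is biased to facilitate
#' ribosome binding), takes the first half of the remainder (rounded down to
#' whole codons) as the CAI half, and the second half of the FULL CDS
#' (codon-aligned) as the density half. The CAI half never touches the first
#' 30 nt; under this convention the two halves may share a short central
#' stretch (e.g. codons 21-25 of a 40-codon CDS).
#'
#' @param cds `coding_sequence`, nucleotide string, or codon-id vector.
#' @return list with `cai_codons` (integer codon ids), `cai_range` and
#'   `density_range` (codon index pairs), or `NULL` when the CDS has 36 nt or
#'   fewer (too short to split).
#' @examples
#' sp <- trim_and_split(strrep("ATGAAA", 20))   # 120 nt
#' sp$cai_range       # codons 11..25
#' sp$density_range   # codons 21..40
#' @export
trim_and_split <- function(cds) {
  cod <- as_codon_ids(cds)
  n <- length(cod)
  if (3L * n <= 36L) return(NULL)
  m <- n - 10L                       # codons after the 30-nt trim
  cai_end <- 10L + m %/% 2L
  dens_start <- n %/% 2L + 1L
  list(cai_codons = cod[11:cai_end],
       cai_range = c(11L, cai_end),
       density_range = c(dens_start, n))
}

#' Relative adaptiveness from a reference gene set
#'
#' Counts codon usage over the CAI halves of the reference CDSs and sets
#' `w(codon) = freq / max synonymous freq` within each amino acid. Codons
#' unobserved in the reference are floored at `w = 0.01`; an amino acid
#' entirely unobserved gets `w = 1` for all its synonyms (uninformative).
#'
#' @param reference_cds list of CDSs (each a `coding_sequence`, string, or
#'   codon-id vector) forming the reference set.
#' @param table a `trans_table` (default table 11).
#' @param w_floor floor for zero-count reference codons (default 0.01).
#' @return object of class `relative_adaptiveness`: numeric `w` of length 64
#'   (NA for stops) plus bookkeeping.
#' @export
compute_w <- function(reference_cds, table = translation_table(11),
                      w_floor = 0.01) {
  counts <- rep.int(0L, 64)
  for (cds in reference_cds) {
    sp <- trim_and_split(cds)
    if (is.null(sp)) next
    counts <- counts + tabulate(sp$cai_codons, nbins = 64L)
  }
  if (sum(counts) == 0L) stop("reference set contributes no usable codons")
  aa <- table$codon_to_aa
  w <- rep(NA_real_, 64)
  for (a in setdiff(unique(aa), "*")) {
    ids <- which(aa == a)
    mx <- max(counts[ids])
    w[ids] <- if (mx == 0L) 1 else pmax(counts[ids] / mx, w_floor)
  }
  structure(list(w = w, counts = counts, table_id = table$table_id,
                 w_floor = w_floor),
            class = "relative_adaptiveness")
}

#' Codon Adaptation Index of a codon stretch
#'
#' Geometric mean of per-codon relative adaptiveness, excluding stop codons
#' and amino acids with a single synonym under the table (Met and Trp for
#' table 11), following the standard CAI definition.
#'
#' @param cds codons of the CAI half (`coding_sequence`, string, or codon-id
#'   vector).
#' @param w a `relative_adaptiveness` object.
#' @param table a `trans_table` matching `w` (default from `w$table_id`).
#' @return CAI value in `(0, 1]`.
#' @export
cai <- function(cds, w, table = translation_table(w$table_id)) {
  cod <- as_codon_ids(cds)
  aa <- table$codon_to_aa
  syn_count <- table(aa[aa != "*"])
  multi <- names(syn_count)[syn_count > 1L]
  keep <- aa[cod] %in% multi
  cod <- cod[keep]
  if (!length(cod)) stop("no multi-synonym codons in the CAI half")
  exp(mean(log(w$w[cod])))
}

#' Association of per-CDS CAI with second-half OSC density
#'
#' For every sufficiently long CDS, CAI is measured on the trimmed first
#' half and OSC density of `codon_set` in `frames` on the second half; the
#' association across the genome's CDSs is a tie-aware Spearman correlation.
#'
#' @param genome a `genome_record`.
#' @param w a `relative_adaptiveness` object (e.g. from the genome's
#'   ribosomal reference set).
#' @param codon_set codon set for the density half (default the genome's
#'   stop set).
#' @param frames frames for the density (default `"+1"`).
#' @return list with `rho`, `p`, `n`, and the per-CDS table (`cds_id`,
#'   `cai`, `density`).
#' @export
cai_density_association <- function(genome, w, codon_set = "stops",
                                    frames = "+1") {
  set_ids <- resolve_codon_set(codon_set, genome$table)
  rows <- lapply(seq_along(genome$codons), function(i) {
    sp <- trim_and_split(genome$codons[[i]])
    if (is.null(sp)) return(NULL)
    data.frame(cds_id = genome$cds_ids[i],
               cai = cai(sp$cai_codons, w, genome$table),
               density = osc_density_region(genome$codons[[i]], set_ids,
                                            frames, sp$density_range),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 10L)
    stop("need at least 10 CDSs with both CAI and density values")
  st <- spearman_test(tab$cai, tab$density)
  list(rho = st$rho, p = st$p, n = st$n, per_cds = tab)
}
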