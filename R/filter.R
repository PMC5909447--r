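# CDS filtering and the genome container.

#' Filter a single coding sequence
#'
#' Applies the four integrity rules in order: (1) length is a multiple of
#' three, (2) alphabet is exactly A/C/G/T, (3) no internal (in-frame) stop
#' codon under the genome's translation table, (4) the terminal codon is in
#' the table's stop set. Rejection is a value, not an error; the reason code
#' names the first failed rule.
#'
#' @param raw_sequence nucleotide string.
#' @param table a `trans_table` (see [translation_table()]).
#' @return list with `accept` (logical) and `reason` (one of `"length"`,
#'   `"alphabet"`, `"internal_stop"`, `"invalid_stop"`, or `NA` on accept).
#' @examples
#' t11 <- translation_table(11)
#' filter_cds("ATGAAATAA", t11)$accept          # TRUE
#' filter_cds("ATGTGATAA", t11)$reason          # "internal_stop"
#' @export
filter_cds <- function(raw_sequence, table) {
  stopifnot(nzchar(raw_sequence))
  s <- toupper(raw_sequence)
  if (nchar(s) %% 3L != 0L)
    return(list(accept = FALSE, reason = "length"))
  v <- nt_indices(s)
  if (anyNA(v))
    return(list(accept = FALSE, reason = "alphabet"))
  n <- length(v) %/% 3L
  i <- seq.int(1L, by = 3L, length.out = n)
  cod <- 16L * (v[i] - 1L) + 4L * (v[i + 1L] - 1L) + v[i + 2L]
  if (n > 1L && any(cod[-n] %in% table$stop_ids))
    return(list(accept = FALSE, reason = "internal_stop"))
  if (!cod[n] %in% table$stop_ids)
    return(list(accept = FALSE, reason = "invalid_stop"))
  list(accept = TRUE, reason = NA_character_)
}

#' Filter a set of coding sequences
#'
#' @param sequences named character vector of nucleotide strings.
#' @param table a `trans_table`.
#' @return data.frame with columns `cds_id`, `accept`, `reason`.
#' @export
filter_cds_set <- function(sequences, table) {
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("cds_", seq_along(sequences))
  res <- lapply(sequences, filter_cds, table = table)
  data.frame(cds_id = ids,
             accept = vapply(res, `[[`, logical(1), "accept"),
             reason = vapply(res, `[[`, character(1), "reason"),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Flat genome layout used by scans and simulators: all codons of all CDSs in
# one integer vector, with CDS membership, an internal-codon mask (neither
# start nor terminal stop), and the left indices of within-CDS adjacent pairs.
build_flat <- function(codon_list) {
  n_per <- lengths(codon_list)
  cod <- unlist(codon_list, use.names = FALSE)
  cds_i <- rep.int(seq_along(codon_list), n_per)
  last <- cumsum(n_per)
  first <- last - n_per + 1L
  internal <- rep.int(TRUE, length(cod))
  internal[first] <- FALSE
  internal[last] <- FALSE
  pair_left <- seq_len(length(cod) - 1L)
  pair_left <- pair_left[cds_i[pair_left] == cds_i[pair_left + 1L]]
  list(cod = cod, cds_i = cds_i, internal = internal,
       pair_left = pair_left, first = first, last = last,
       n_codons = length(cod))
}

#' Build a genome record from coding sequences
#'
#' Filters the supplied CDSs under the genome's translation table (unless
#' `filter = FALSE`, for pre-validated input) and computes GC and GC3 over
#' the retained sequences.
#'
#' @param genome_id identifier string.
#' @param sequences named character vector of CDS nucleotide strings, or a
#'   list of integer codon-id vectors.
#' @param table_id NCBI translation table id (11 or 4).
#' @param genus optional genus label.
#' @param genome_size_bp optional genome size in base pairs (metadata).
#' @param gene_names optional character vector of gene names parallel to
#'   `sequences` (used by the CAI reference-set selector).
#' @param filter apply [filter_cds()] to each sequence (default `TRUE`).
#' @return object of class `genome_record` with elements `genome_id`, `table`,
#'   `cds_ids`, `codons` (list of codon-id vectors), `flat`, `gc`, `gc3`,
#'   `genus`, `genome_size_bp`, `gene_names`, and `rejected` (filter report
#'   for dropped CDSs).
#' @export
genome_record <- function(genome_id, sequences, table_id = 11, genus = NA_character_,
                          genome_size_bp = NA_integer_, gene_names = NULL,
                          filter = TRUE) {
  table <- translation_table(table_id)
  if (is.list(sequences) && !is.character(sequences[[1]])) {
    codon_list <- lapply(sequences, as.integer)
    ids <- names(sequences)
    if (is.null(ids)) ids <- paste0("cds_", seq_along(codon_list))
    rejected <- NULL
  } else {
    sequences <- vapply(sequences, toupper, character(1))
    ids <- names(sequences)
    if (is.null(ids)) ids <- paste0("cds_", seq_along(sequences))
    names(sequences) <- ids
    if (filter) {
      rep <- filter_cds_set(sequences, table)
      rejected <- rep[!rep$accept, , drop = FALSE]
      keep <- rep$accept
    } else {
      rejected <- NULL
      keep <- rep.int(TRUE, length(sequences))
    }
    if (!any(keep)) stop("no CDS passed filtering for genome ", genome_id)
    sequences <- sequences[keep]
    ids <- ids[keep]
    if (!is.null(gene_names)) gene_names <- gene_names[keep]
    codon_list <- lapply(sequences, seq_to_codons)
  }
  flat <- build_flat(codon_list)
  g <- structure(
    list(genome_id = as.character(genome_id), table = table,
         cds_ids = ids, codons = codon_list, flat = flat,
         gc = sum(CODON_GC[flat$cod]) / (3 * flat$n_codons),
         gc3 = mean(CODON_GC3[flat$cod]),
         genus = genus, genome_size_bp = genome_size_bp,
         gene_names = gene_names, rejected = rejected),
    class = "genome_record")
  g
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d CDSs, %d codons, table %d, GC %.3f, GC3 %.3f\n",
              x$genome_id, length(x$codons), x$flat$n_codons,
              x$table$table_id, x$gc, x$gc3))
  invisible(x)
}

#' Number of CDSs in a genome record
#' @param genome a `genome_record`.
#' @export
n_cds <- function(genome) length(genome$codons)

#' GC and GC3 content of a genome's filtered CDSs
#'
#' `gc` is the G+C fraction over all CDS nucleotides; `gc3` the G+C fraction
#' at codon third positions. Both are computed over filtered CDSs only.
#'
#' @param genome a `genome_record`.
#' @return named numeric vector `c(gc =, gc3 =)`.
#' @export
gc_metrics <- function(genome) {
  c(gc = genome$gc, gc3 = genome$gc3)
}

#' Metadata-driven genome-set filtering
#'
#' Optionally keeps one genome per genus (the first in input order) and drops
#' genomes below a minimum size when `genome_size_bp` metadata is present.
#'
#' @param genomes list of `genome_record`s.
#' @param one_per_genus keep only the first genome of each genus.
#' @param min_size_bp minimum genome size (applied only where metadata known).
#' @return filtered list of `genome_record`s.
#' @export
filter_genomes <- function(genomes, one_per_genus = TRUE, min_size_bp = 500000) {
  keep <- rep.int(TRUE, length(genomes))
  sizes <- vapply(genomes, function(g) as.numeric(g$genome_size_bp %||% NA), numeric(1))
  keep[!is.na(sizes) & sizes < min_size_bp] <- FALSE
  if (one_per_genus) {
    genera <- vapply(genomes, function(g) as.character(g$genus %||% NA), character(1))
    known <- which(keep & !is.na(genera))
    dup <- known[duplicated(genera[known])]
    keep[dup] <- FALSE
  }
  genomes[keep]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
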