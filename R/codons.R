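# Core codon machinery: every sequence is held as a vector of codon ids
# (1..64, ACGT base-4 encoding) so that off-frame scans and simulators reduce
# to integer table lookups.

NUC <- c("A", "C", "G", "T")

# codon id <-> trinucleotide table, built once at install time;
# CODONS[id] inverts id = 16*(n1-1) + 4*(n2-1) + n3
CODONS <- character(64)
for (.n1 in 1:4) for (.n2 in 1:4) for (.n3 in 1:4)
  CODONS[16L * (.n1 - 1L) + 4L * (.n2 - 1L) + .n3] <-
    paste0(NUC[.n1], NUC[.n2], NUC[.n3])
rm(.n1, .n2, .n3)

# per-codon-id nucleotide indices (1..4)
CODON_NT1 <- (seq_len(64) - 1L) %/% 16L + 1L
CODON_NT2 <- ((seq_len(64) - 1L) %/% 4L) %% 4L + 1L
CODON_NT3 <- (seq_len(64) - 1L) %% 4L + 1L

# G/C bookkeeping per codon id (for gc and gc3 metrics)
CODON_GC    <- (CODON_NT1 %in% 2:3) + (CODON_NT2 %in% 2:3) + (CODON_NT3 %in% 2:3)
CODON_GC3   <- as.integer(CODON_NT3 %in% 2:3)

# Off-frame pair lookup: for an adjacent in-frame codon pair (a, b), the +1
# frame codon is (a2, a3, b1) and the +2 frame codon is (a3, b1, b2).  Both
# are functions of the pair alone, so genome-wide off-frame counts are pair
# counts.
PAIR_PLUS1 <- matrix(0L, 64, 64)
PAIR_PLUS2 <- matrix(0L, 64, 64)
for (.a in 1:64) {
  PAIR_PLUS1[.a, ] <- 16L * (CODON_NT2[.a] - 1L) + 4L * (CODON_NT3[.a] - 1L) + CODON_NT1
  PAIR_PLUS2[.a, ] <- 16L * (CODON_NT3[.a] - 1L) + 4L * (CODON_NT1 - 1L) + CODON_NT2
}
rm(.a)

# fast char -> nucleotide index map over raw byte values
NT_BYTE_MAP <- rep(NA_integer_, 256)
NT_BYTE_MAP[utf8ToInt("A")] <- 1L
NT_BYTE_MAP[utf8ToInt("C")] <- 2L
NT_BYTE_MAP[utf8ToInt("G")] <- 3L
NT_BYTE_MAP[utf8ToInt("T")] <- 4L

#' Convert a nucleotide string to nucleotide indices
#'
#' @param sequence a single character string over A/C/G/T.
#' @return integer vector of indices into `c("A","C","G","T")`; characters
#'   outside that alphabet map to `NA`.
#' @keywords internal
nt_indices <- function(sequence) {
  NT_BYTE_MAP[utf8ToInt(sequence)]
}

#' Convert a coding sequence string to codon ids
#'
#' @param sequence nucleotide string whose length is a multiple of 3.
#' @return integer vector of codon ids (1..64).
#' @export
seq_to_codons <- function(sequence) {
  v <- nt_indices(sequence)
  n <- length(v)
  if (n %% 3L != 0L)
    stop("sequence length ", n, " is not a multiple of 3")
  if (anyNA(v))
    stop("sequence contains characters outside {A,C,G,T}")
  i <- seq.int(1L, n, by = 3L)
  16L * (v[i] - 1L) + 4L * (v[i + 1L] - 1L) + v[i + 2L]
}

#' Convert codon ids back to a nucleotide string
#'
#' @param codons integer vector of codon ids (1..64).
#' @return a single nucleotide string.
#' @export
codons_to_seq <- function(codons) {
  paste(CODONS[codons], collapse = "")
}

#' Codon id of a trinucleotide
#'
#' @param codon trinucleotide string(s), e.g. `"TAA"`.
#' @return integer codon id(s) in 1..64.
#' @export
codon_id <- function(codon) {
  id <- match(toupper(codon), CODONS)
  if (anyNA(id)) stop("not a valid codon: ", paste(codon[is.na(id)], collapse = ", "))
  id
}

# cache for translation tables (filled lazily; Biostrings supplies the code)
.tt_cache <- new.env(parent = emptyenv())

#' Genetic-code translation table
#'
#' Returns the codon-to-amino-acid map and stop/start codon sets for an NCBI
#' translation table. Table 11 is the standard bacterial code (stops TAA, TAG,
#' TGA); table 4 reassigns TGA to tryptophan (stops TAA, TAG), as used by
#' *Mycoplasma* and relatives.
#'
#' @param table_id integer NCBI table id; 11 and 4 are supported.
#' @return an object of class `trans_table` with elements `table_id`,
#'   `codon_to_aa` (length-64 character vector indexed by codon id, `"*"` for
#'   stop), `stop_codons`, `stop_ids`, `start_codons`.
#' @export
translation_table <- function(table_id) {
  key <- as.character(table_id)
  if (!key %in% c("4", "11"))
    stop("only NCBI translation tables 11 and 4 are supported")
  if (!is.null(.tt_cache[[key]])) return(.tt_cache[[key]])
  gc <- Biostrings::getGeneticCode(key)
  aa <- character(64)
  aa[codon_id(names(gc))] <- unname(gc)
  stops <- CODONS[aa == "*"]
  starts <- unique(c("ATG", attr(gc, "alt_init_codons")))
  tt <- structure(
    list(table_id = as.integer(table_id),
         codon_to_aa = aa,
         stop_codons = stops,
         stop_ids = codon_id(stops),
         start_codons = starts),
    class = "trans_table")
  .tt_cache[[key]] <- tt
  tt
}

#' @export
print.trans_table <- function(x, ...) {
  cat("NCBI translation table", x$table_id,
      "| stops:", paste(x$stop_codons, collapse = ","), "\n")
  invisible(x)
}

#' Translate codon ids to amino acids
#'
#' @param codons integer codon ids.
#' @param table a `trans_table`.
#' @return character vector of single-letter amino acids (`"*"` for stop).
#' @export
translate_codons <- function(codons, table) {
  table$codon_to_aa[codons]
}

#' Construct a coding-sequence object
#'
#' @param cds_id identifier string.
#' @param sequence nucleotide string (length a multiple of 3, A/C/G/T only).
#' @return object of class `coding_sequence`: `cds_id`, `sequence`, `codons`
#'   (integer codon ids), `n_codons`.
#' @export
coding_sequence <- function(cds_id, sequence) {
  sequence <- toupper(sequence)
  codons <- seq_to_codons(sequence)
  structure(
    list(cds_id = as.character(cds_id), sequence = sequence,
         codons = codons, n_codons = length(codons)),
    class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat("<coding_sequence>", x$cds_id, "-", x$n_codons, "codons\n")
  invisible(x)
}

# coerce a string or coding_sequence to codon ids
as_codon_ids <- function(x) {
  if (inherits(x, "coding_sequence")) x$codons
  else if (is.character(x) && length(x) == 1L) seq_to_codons(toupper(x))
  else if (is.integer(x) || is.numeric(x)) as.integer(x)
  else stop("cannot interpret input as a coding sequence")
}
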