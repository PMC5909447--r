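# Readers and writers: multi-FASTA CDS collections with a tabular metadata
# sidecar, GenBank flat files (CDS feature extraction), and TSV result
# tables.

#' Read CDS sequences from a multi-FASTA file
#'
#' @param path FASTA file (one record per CDS).
#' @return named character vector of uppercase nucleotide strings.
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write CDS sequences to a multi-FASTA file
#'
#' @param sequences named character vector of nucleotide strings.
#' @param path output path.
#' @export
write_cds_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), filepath = path)
  invisible(path)
}

#' Read the genome metadata sidecar
#'
#' Tab-separated with columns `genome_id`, `table_id`, `genus`,
#' `genome_size_bp` (and optionally `file`).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_genome_metadata <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a data.frame as TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- GenBank flat-file CDS extraction --------------------------------------

# parse a location string: simple "a..b", "complement(...)", "join(...)"
# (one nesting level, as found in bacterial CDS features)
parse_gb_location <- function(loc) {
  comp <- FALSE
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    comp <- TRUE
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc))
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",")[[1]]
  m <- regmatches(parts, regexec("^(\\d+)\\.\\.(\\d+)$", trimws(parts)))
  if (any(lengths(m) != 3)) return(NULL)   # unsupported location form
  starts <- as.integer(vapply(m, `[`, "", 2))
  ends <- as.integer(vapply(m, `[`, "", 3))
  list(starts = starts, ends = ends, complement = comp)
}

revcomp_chars <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

#' Extract CDS features from a GenBank flat file
#'
#' Parses LOCUS records, pulls every CDS feature (simple, `complement`, and
#' single-level `join` locations), and returns the coding-orientation
#' nucleotide sequence together with the `/gene` qualifier when present.
#'
#' @param path GenBank flat file (possibly multi-record).
#' @return data.frame with `record`, `cds_id`, `gene`, `sequence`.
#' @export
read_genbank_cds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec_start <- grep("^LOCUS", lines)
  rec_end <- grep("^//", lines)
  if (!length(rec_start)) stop("no LOCUS record found in ", path)
  out <- list()
  for (r in seq_along(rec_start)) {
    block <- lines[rec_start[r]:rec_end[r]]
    locus <- strsplit(trimws(block[1]), "\\s+")[[1]][2]
    ori <- grep("^ORIGIN", block)
    seq_lines <- block[(ori + 1):(length(block) - 1)]
    genome_seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    feat <- grep("^     \\S", block)
    cds_rows <- feat[grepl("^     CDS\\s", block[feat])]
    for (k in seq_along(cds_rows)) {
      i <- cds_rows[k]
      # location may continue over lines that are not qualifiers
      loc <- sub("^     CDS\\s+", "", block[i])
      j <- i + 1L
      while (j <= length(block) && grepl("^\\s{10,}", block[j]) &&
             !grepl("^\\s+/", block[j]) && !j %in% feat) {
        loc <- paste0(loc, trimws(block[j]))
        j <- j + 1L
      }
      # qualifiers until the next feature key of any kind
      nxt <- feat[feat > i]
      qual_end <- if (length(nxt)) nxt[1] - 1L else ori - 1L
      quals <- if (j > qual_end) character(0) else block[j:qual_end]
      gene <- NA_character_
      gm <- regmatches(quals, regexec("/gene=\"([^\"]+)\"", quals))
      gm <- gm[lengths(gm) == 2]
      if (length(gm)) gene <- gm[[1]][2]
      pl <- parse_gb_location(loc)
      if (is.null(pl)) next
      seg <- paste(substring(genome_seq, pl$starts, pl$ends), collapse = "")
      if (pl$complement) seg <- revcomp_chars(seg)
      out[[length(out) + 1L]] <- data.frame(
        record = locus,
        cds_id = if (!is.na(gene)) gene else sprintf("%s_cds%d", locus, k),
        gene = gene, sequence = seg, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(record = character(0), cds_id = character(0),
                      gene = character(0), sequence = character(0)))
  do.call(rbind, out)
}

#' Build a genome record from a GenBank flat file
#'
#' @param path GenBank file (one genome; multiple records are pooled).
#' @param table_id NCBI translation table id.
#' @param genome_id identifier (defaults to the first LOCUS name).
#' @inheritParams genome_record
#' @return a `genome_record` (CDSs filtered; gene names retained).
#' @export
read_genbank_genome <- function(path, table_id = 11, genome_id = NULL,
                                genus = NA_character_,
                                genome_size_bp = NA_integer_) {
  cds <- read_genbank_cds(path)
  if (!nrow(cds)) stop("no CDS features found in ", path)
  seqs <- stats::setNames(cds$sequence, make.unique(cds$cds_id))
  genome_record(genome_id %||% cds$record[1], seqs, table_id = table_id,
                genus = genus, genome_size_bp = genome_size_bp,
                gene_names = cds$gene)
}

# ---- cohort round trip -----------------------------------------------------

#' Write a synthetic cohort to disk
#'
#' One multi-FASTA per genome plus `metadata.tsv` (genome_id, table_id,
#' genus, genome_size_bp, file) and `truth.tsv`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(cohort$genomes))
  for (i in seq_along(cohort$genomes)) {
    g <- cohort$genomes[[i]]
    seqs <- vapply(g$codons, codons_to_seq, character(1))
    files[i] <- paste0(g$genome_id, ".fasta")
    write_cds_fasta(seqs, file.path(dir, files[i]))
  }
  meta <- data.frame(
    genome_id = vapply(cohort$genomes, function(g) g$genome_id, character(1)),
    table_id = vapply(cohort$genomes, function(g) g$table$table_id, integer(1)),
    genus = vapply(cohort$genomes, function(g) as.character(g$genus %||% NA),
                   character(1)),
    genome_size_bp = vapply(cohort$genomes,
                            function(g) as.integer(g$genome_size_bp %||% NA),
                            integer(1)),
    file = files, stringsAsFactors = FALSE)
  write_tsv_table(meta, file.path(dir, "metadata.tsv"))
  write_tsv_table(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return list with `genomes` and `metadata` (plus `truth` when present).
#' @export
read_cohort <- function(dir) {
  meta <- read_genome_metadata(file.path(dir, "metadata.tsv"))
  genomes <- lapply(seq_len(nrow(meta)), function(i) {
    seqs <- read_cds_fasta(file.path(dir, meta$file[i]))
    genome_record(meta$genome_id[i], seqs, table_id = meta$table_id[i],
                  genus = meta$genus[i],
                  genome_size_bp = meta$genome_size_bp[i])
  })
  truth_path <- file.path(dir, "truth.tsv")
  list(genomes = genomes, metadata = meta,
       truth = if (file.exists(truth_path)) read_genome_metadata(truth_path))
}
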