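t11 <- translation_table(11)
t4 <- translation_table(4)

test_that("translation tables carry the correct stop sets and full codon maps", {
  expect_setequal(t11$stop_codons, c("TAA", "TAG", "TGA"))
  expect_setequal(t4$stop_codons, c("TAA", "TAG"))
  expect_equal(t4$codon_to_aa[codon_id("TGA")], "W")
  expect_true(all(nchar(t11$codon_to_aa) == 1))
  expect_true(all(nchar(t4$codon_to_aa) == 1))
  expect_true("ATG" %in% t11$start_codons)
})

test_that("filter_cds applies the four rules in order with reason codes", {
  expect_true(filter_cds("ATGAAATAA", t11)$accept)
  r <- filter_cds("ATGAAATGA", t4)
  expect_false(r$accept); expect_equal(r$reason, "invalid_stop")
  expect_equal(filter_cds("ATGTGATAA", t11)$reason, "internal_stop")
  expect_equal(filter_cds("ATGAANTAA", t11)$reason, "alphabet")
  expect_equal(filter_cds("ATGAAATAAC", t11)$reason, "length")
  # TGA is Trp under table 4, so an internal TGA passes there but not in 11
  expect_true(filter_cds("ATGTGATAA", t4)$accept)
})

test_that("filtering is idempotent and the codon round trip is exact", {
  set.seed(31)
  for (i in 1:20) {
    s <- random_cds(sample(1:30, 1))
    expect_true(filter_cds(s, t11)$accept)
    cds <- coding_sequence("x", s)
    expect_identical(codons_to_seq(cds$codons), s)
    expect_equal(cds$n_codons, nchar(s) / 3)
  }
})

test_that("off-frame scan matches hand enumeration and substring counting", {
  sc <- scan_offframe_codons("ATGGATAATTAA")
  expect_equal(unname(sc$plus1[c("TGG", "ATA", "ATT")]), c(1L, 1L, 1L))
  expect_equal(sum(sc$plus1), 3L)
  expect_equal(unname(sc$plus2[c("GGA", "TAA", "TTA")]), c(1L, 1L, 1L))
  expect_equal(sc$plus1[["TAA"]], 0L)
  expect_equal(scan_offframe_codons("ATGAAAGGGTAA")$plus1[["TGA"]], 1L)
  expect_error(scan_offframe_codons("ATG"), "at least 2 codons")

  set.seed(32)
  for (i in 1:15) {
    s <- random_cds(sample(1:25, 1))
    sc <- scan_offframe_codons(s)
    n <- nchar(s) / 3
    # frame-count conservation: each frame yields exactly n-1 codons
    expect_equal(sum(sc$plus1), n - 1)
    expect_equal(sum(sc$plus2), n - 1)
    for (cd in c("TAA", "TAG", "TGA", "TGC")) {
      expect_equal(sc$plus1[[cd]], count_offframe_substr(s, cd, "+1"))
      expect_equal(sc$plus2[[cd]], count_offframe_substr(s, cd, "+2"))
    }
  }
})

test_that("osc_density pools counts per 100 codons and is additive in frames", {
  g <- genome_record("g", c(x = "ATGGATAATTAA"))
  expect_equal(osc_density(g, "TAA", "+2"), 25)
  expect_equal(osc_density(g, "TAA", "+1"), 0)
  expect_equal(osc_density(g, "TAA", c("+1", "+2")),
               osc_density(g, "TAA", "+1") + osc_density(g, "TAA", "+2"))
  expect_equal(osc_density(g, "TAA", "Both"), osc_density(g, "TAA", c("+1", "+2")))
  # genome with no off-frame stops at all
  g0 <- genome_record("g0", c(x = "ATGCCGCCGTAA"))
  expect_equal(osc_density(g0, c("TAG", "TGA"), c("+1", "+2")), 0)

  set.seed(33)
  g2 <- tiny_genome(n_cds = 5, seed = 33)
  seqs <- vapply(g2$codons, codons_to_seq, character(1))
  n_tot <- sum(nchar(seqs)) / 3
  for (fr in c("+1", "+2")) {
    expected <- 100 * sum(vapply(seqs, function(s)
      sum(vapply(c("TAA", "TAG", "TGA"), count_offframe_substr,
                 numeric(1), seq = s, frame = fr)), numeric(1))) / n_tot
    expect_equal(osc_density(g2, "stops", fr), expected)
  }
  # density bounds
  d <- osc_density(g2, "stops", c("+1", "+2"))
  expect_gte(d, 0)
  expect_lt(d, 200)
})

test_that("gc metrics are computed over filtered CDS nucleotides", {
  g <- genome_record("h", c(x = "ATGAAATAA"))
  expect_equal(unname(gc_metrics(g)), c(1 / 9, 1 / 3))
  g_gc <- genome_record("s", c(x = "ATGCCGGCGTAG"))  # third sites G,G,G,G
  expect_equal(unname(gc_metrics(g_gc)["gc3"]), 1)
  expect_equal(unname(gc_metrics(g_gc)["gc"]), 8 / 12)
  g_at <- genome_record("a", c(x = "ATGAATATATAA"))
  expect_equal(unname(gc_metrics(g_at)["gc"]), 1 / 12)
})

test_that("genome_record filters rejected CDSs and reports reasons", {
  seqs <- c(ok = "ATGAAATAA", bad_len = "ATGAAATA", bad_stop = "ATGAAAAAA")
  g <- genome_record("mix", seqs)
  expect_equal(length(g$codons), 1L)
  expect_setequal(g$rejected$reason, c("length", "invalid_stop"))
  expect_error(genome_record("none", c(x = "ATGAAAA")), "no CDS passed")
})

test_that("metadata-driven genome-set filtering applies genus and size rules", {
  gs <- list(
    genome_record("a1", c(x = "ATGAAATAA"), genus = "Alpha", genome_size_bp = 6e5),
    genome_record("a2", c(x = "ATGAAATAA"), genus = "Alpha", genome_size_bp = 7e5),
    genome_record("b1", c(x = "ATGAAATAA"), genus = "Beta", genome_size_bp = 4e5),
    genome_record("c1", c(x = "ATGAAATAA"), genus = "Gamma"))
  out <- filter_genomes(gs)
  expect_setequal(vapply(out, function(g) g$genome_id, character(1)),
                  c("a1", "c1"))
})

test_that("FASTA and cohort round trips preserve sequences exactly", {
  dir <- tempfile(); dir.create(dir)
  seqs <- c(a = "ATGAAATAA", b = "ATGGATAATTAA")
  fa <- file.path(dir, "x.fasta")
  write_cds_fasta(seqs, fa)
  expect_identical(read_cds_fasta(fa), seqs)

  coh <- generate_cohort(3, n_cds_range = c(5, 8), cds_len_range = c(10, 30),
                         seed = 35)
  write_cohort(coh, file.path(dir, "coh"))
  back <- read_cohort(file.path(dir, "coh"))
  expect_equal(length(back$genomes), 3L)
  for (i in 1:3)
    expect_identical(back$genomes[[i]]$flat$cod, coh$genomes[[i]]$flat$cod)
  expect_equal(back$truth$genome_id, coh$truth$genome_id)
  unlink(dir, recursive = TRUE)
})

test_that("GenBank CDS extraction handles plain, complement, and join locations", {
  path <- write_genbank_fixture()
  cds <- read_genbank_cds(path)
  expect_equal(nrow(cds), 3L)
  expect_equal(cds$sequence,
               c("ATGGATAATTAA", "ATGAAAGGGTAA", "ATGCCCTGGTAA"))
  expect_equal(cds$gene, c("rplA", "rpsB", NA))
  g <- read_genbank_genome(path)
  expect_equal(length(g$codons), 3L)
  expect_equal(g$gene_names, c("rplA", "rpsB", NA))
  unlink(path)
})
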