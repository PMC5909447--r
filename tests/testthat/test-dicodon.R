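cfg_ile <- dicodon_config("Ile")
cfg_ile_at <- dicodon_config("Ile", restricted = TRUE)
cfg_val <- dicodon_config("Val")

# assemble a CDS string from codon triplets
cds_from <- function(...) paste0("ATG", paste0(c(...), collapse = ""), "TAA")
# trinucleotides of a config's synonym set
codons_of <- function(cfg) vapply(cfg$pair_ids, codons_to_seq, character(1))

test_that("dicodon configs enumerate the correct synonym sets", {
  expect_setequal(codons_of(cfg_ile), c("ATA", "ATC", "ATT"))
  expect_setequal(codons_of(cfg_ile_at), c("ATA", "ATT"))
  expect_setequal(codons_of(cfg_val), c("GTA", "GTC", "GTG", "GTT"))
  expect_equal(cfg_ile$target, "+1 TAA")
  expect_equal(cfg_val$target, "+1 TAG")
})

test_that("find_contexts emits qualifying repeats with follower class Y", {
  # ATA|ATT|TAT: both Ile, follower starts T -> one context (A, T)
  ctx <- find_contexts(cds_from("ATA", "ATT", "TAT"), cfg_ile)
  expect_equal(nrow(ctx), 1)
  expect_equal(ctx$site3, "A"); expect_equal(ctx$site6, "T")
  # follower starting G disqualifies
  expect_equal(nrow(find_contexts(cds_from("ATA", "ATT", "GGG"), cfg_ile)), 0)
  # restricted flag: ATC (C-ending) excluded
  expect_equal(nrow(find_contexts(cds_from("ATC", "ATA", "TTT"), cfg_ile_at)), 0)
  expect_equal(nrow(find_contexts(cds_from("ATC", "ATA", "TTT"), cfg_ile)), 1)
  # a triple repeat scans every adjacent pair, but the first window's
  # follower is itself an Ile codon (A-starting), so only the final window
  # qualifies
  ctx3 <- find_contexts(cds_from("ATA", "ATT", "ATC", "TAT"), cfg_ile)
  expect_equal(nrow(ctx3), 1)
  expect_equal(ctx3$site3, "T")
  expect_equal(ctx3$site6, "C")
  # two independent pairs in one CDS are both emitted
  ctx2 <- find_contexts(cds_from("ATA", "ATT", "TAT", "ATT", "ATA", "CAT"),
                        cfg_ile)
  expect_equal(nrow(ctx2), 2)
  # re-scan stability
  s <- cds_from("ATA", "ATT", "TAT")
  expect_identical(find_contexts(s, cfg_ile), find_contexts(s, cfg_ile))
})

test_that("restriction never increases the context count", {
  set.seed(71)
  for (i in 1:10) {
    g <- tiny_genome(n_cds = 5, seed = 700 + i)
    n_all <- genome_site_usage(g, cfg_ile)$n_contexts
    n_at <- genome_site_usage(g, cfg_ile_at)$n_contexts
    expect_lte(n_at, n_all)
  }
})

test_that("genome_site_usage pools contexts and flags empty genomes", {
  # four CDSs contributing contexts (A,T), (A,A), (C,T), (T,A)
  g <- genome_record("d", c(
    a = cds_from("ATA", "ATT", "TAT"),
    b = cds_from("ATA", "ATA", "CAT"),
    c = cds_from("ATC", "ATT", "TGG"),
    d = cds_from("ATT", "ATA", "CCC")))
  u <- genome_site_usage(g, cfg_ile)
  expect_equal(u$n_contexts, 4)
  expect_equal(u$a3, 0.5)
  expect_equal(u$a6, 0.5)
  expect_equal(u$log_ratio, 0)
  # zero contexts: flagged NA
  g0 <- genome_record("e", c(x = "ATGGGGTAA"))
  u0 <- genome_site_usage(g0, cfg_ile)
  expect_equal(u0$n_contexts, 0)
  expect_true(is.na(u0$a3))
})

test_that("paired context test handles signal, null, and degenerate cohorts", {
  mk <- function(a3, a6) data.frame(
    genome_id = paste0("g", seq_along(a3)), config = "Ile_all",
    n_contexts = 50, a3 = a3, a6 = a6, log_ratio = log(a3 / a6),
    gc3 = runif(length(a3)), stringsAsFactors = FALSE)
  set.seed(72)
  # all differences zero
  r0 <- paired_context_test(mk(rep(0.3, 10), rep(0.3, 10)))
  expect_equal(r0$p, 1); expect_equal(r0$statistic, 0)
  # strong planted signal
  a6 <- runif(30, 0.2, 0.4)
  r1 <- paired_context_test(mk(a6 + 0.15, a6))
  expect_lt(r1$p, 1e-4)
  expect_equal(r1$n_greater, 30)
  # two-sided symmetry under sign flip
  a3 <- runif(20, 0.2, 0.5); b6 <- a3 + rnorm(20, 0, 0.05)
  p_fwd <- paired_context_test(mk(a3, b6))$p
  p_rev <- paired_context_test(mk(b6, a3))$p
  expect_equal(p_fwd, p_rev)
  # zero-context genomes excluded listwise
  d <- mk(a6 + 0.15, a6)
  d$n_contexts[1] <- 0
  expect_equal(paired_context_test(d)$n, 29)
})

test_that("log-ratio/GC3 correlation is tie-aware Spearman with NA dropping", {
  d <- data.frame(genome_id = paste0("g", 1:10), config = "Ile_all",
                  n_contexts = 10, a3 = seq(0.2, 0.65, 0.05), a6 = 0.3,
                  gc3 = seq(0.2, 0.65, 0.05), stringsAsFactors = FALSE)
  d$log_ratio <- log(d$a3 / d$a6)
  expect_equal(usage_gc3_correlation(d)$rho, 1)
  d$log_ratio[1] <- NA
  expect_equal(usage_gc3_correlation(d)$n, 9)
})

test_that("exchangeable third sites give matched site-3 and site-6 usage", {
  # i.i.d. internal codons: site 3 and site 6 draws are exchangeable, so the
  # paired test sees no signal and cross-genome means agree
  set.seed(73)
  rows <- do.call(rbind, lapply(1:25, function(i) {
    g <- tiny_genome(n_cds = 40, gc3 = 0.35, cds_len_range = c(60, 240))
    g$genome_id <- paste0("g", i)
    genome_site_usage(g, cfg_ile)
  }))
  pt <- paired_context_test(rows)
  expect_gt(pt$p, 0.01)
  expect_lt(abs(pt$mean_a3 - pt$mean_a6), 0.05)
})
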