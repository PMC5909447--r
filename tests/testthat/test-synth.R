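t11 <- translation_table(11)

test_that("sampled codon usage hits the GC3 target and is seed-deterministic", {
  set.seed(101)
  for (target in c(0.15, 0.35, 0.5, 0.75, 0.9)) {
    u <- sample_codon_usage(target)
    expect_lt(abs(u$gc3_expected - target), 0.021)
    # realized GC3 of a large i.i.d. codon stream
    ids <- sample(64, 1e5, replace = TRUE, prob = u$codon_probs)
    thirds <- (ids - 1L) %% 4L + 1L   # 2,3 = C,G
    expect_lt(abs(mean(thirds %in% 2:3) - target), 0.021)
  }
  set.seed(5); u1 <- sample_codon_usage(0.4)
  set.seed(5); u2 <- sample_codon_usage(0.4)
  expect_identical(u1$codon_probs, u2$codon_probs)
  # symmetric tilt at 0.5: NNY blocks near-even only in expectation; check
  # the tilt parameter is small when usage is near-uniform
  set.seed(6)
  u_mid <- sample_codon_usage(0.5, concentration = 1e6)
  expect_lt(abs(u_mid$tilt), 0.3)
  expect_warning(sample_codon_usage(0.001), "clamping")
})

test_that("generated genomes pass all four filter rules by construction", {
  set.seed(102)
  for (tid in c(11, 4)) {
    u <- sample_codon_usage(0.3, table = translation_table(tid))
    g <- generate_genome("gen", u, n_cds = 15, cds_len_range = c(10, 60))
    tt <- translation_table(tid)
    for (cod in g$codons) {
      expect_true(filter_cds(codons_to_seq(cod), tt)$accept)
      expect_equal(codons_to_seq(cod[1]), "ATG")
    }
    stops <- vapply(g$codons, function(v) codons_to_seq(v[length(v)]), "")
    expect_true(all(stops %in% tt$stop_codons))
  }
  # table 4 genomes may carry internal TGA (tryptophan)
  set.seed(103)
  u4 <- sample_codon_usage(0.25, table = translation_table(4))
  g4 <- generate_genome("t4", u4, n_cds = 40, cds_len_range = c(60, 240))
  internal <- g4$flat$cod[g4$flat$internal]
  expect_gt(sum(internal == codon_id("TGA")), 0)
  expect_true(all(vapply(g4$codons, function(v)
    codons_to_seq(v[length(v)]), "") %in% c("TAA", "TAG")))
})

test_that("cohorts are reproducible and honour requested structure", {
  c1 <- generate_cohort(4, n_cds_range = c(5, 10), cds_len_range = c(10, 40),
                        seed = 104)
  c2 <- generate_cohort(4, n_cds_range = c(5, 10), cds_len_range = c(10, 40),
                        seed = 104)
  for (i in 1:4)
    expect_identical(c1$genomes[[i]]$flat$cod, c2$genomes[[i]]$flat$cod)
  expect_equal(nrow(c1$truth), 4)
  # GC3 gradient: realized GC3 monotone in the request
  grad <- generate_cohort(5, gc3_targets = c(0.2, 0.35, 0.5, 0.65, 0.8),
                          seed = 105)
  expect_true(all(diff(grad$truth$gc3_realized) > 0))
  # mixed tables: group sizes match the request
  mixed <- generate_cohort(6, table_ids = c(11, 4), n_cds_range = c(5, 8),
                           cds_len_range = c(10, 30), seed = 106)
  expect_equal(mixed$truth$table_id, rep(c(11, 4), 3))
})

test_that("OSC enrichment is monotone in delta and saturates at delta = 1", {
  set.seed(107)
  u <- sample_codon_usage(0.3)
  base <- generate_genome("b", u, n_cds = 60, cds_len_range = c(60, 240))
  dens <- vapply(c(0, 0.3, 1), function(d) {
    set.seed(42)
    osc_density(inject_osc_bias(base, "TAA", "+1", d), "TAA", "+1")
  }, numeric(1))
  expect_true(all(diff(dens) > 0))
  # delta = 0 is the identity here (no eligible site ever switches)
  set.seed(43)
  g0 <- inject_osc_bias(base, "TAA", "+1", 0)
  expect_identical(g0$flat$cod, base$flat$cod)
  # delta = 1: every eligible internal site carries the OSC-forming synonym
  set.seed(44)
  g1 <- inject_osc_bias(base, "TAA", "+1", 1)
  flat <- g1$flat
  li <- flat$pair_left[flat$internal[flat$pair_left]]
  cand <- oscexcess:::osc_synonym_candidates(t11, "TAA", "+1")
  c_id <- flat$cod[li]
  next_starts_A <- vapply(flat$cod[li + 1L],
                          function(x) substr(codons_to_seq(x), 1, 1), "") == "A"
  eligible <- next_starts_A & lengths(cand)[c_id] > 0
  carries_osc <- mapply(function(id) id %in% cand[[id]], c_id)
  expect_true(all(carries_osc[eligible]))
  # amino-acid sequence unchanged by injection
  expect_identical(translate_codons(g1$flat$cod, t11),
                   translate_codons(base$flat$cod, t11))
})

test_that("context-bias injection raises site-3 usage by delta", {
  set.seed(108)
  u <- sample_codon_usage(0.4)
  cfg <- dicodon_config("Ile")
  # large genome so the realized shift is well resolved
  g <- generate_genome("big", u, n_cds = 600, cds_len_range = c(60, 240))
  u0 <- genome_site_usage(g, cfg)
  gb <- inject_context_bias(g, u, cfg, 0.2)
  u1 <- genome_site_usage(gb, cfg)
  expect_equal(u1$n_contexts, u0$n_contexts)  # qualification preserved
  shift <- u1$a3 - u1$a6
  expect_gt(shift, 0.2 - 0.1)
  expect_lt(shift, 0.2 + 0.1)
  # protein unchanged
  expect_identical(translate_codons(gb$flat$cod, t11),
                   translate_codons(g$flat$cod, t11))
})
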