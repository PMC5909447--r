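t11 <- translation_table(11)

test_that("codon shuffle permutes internal codons uniformly and exactly", {
  # one internal codon: the only permutation is the identity
  expect_identical(shuffle_codons("ATGAAATAA"), "ATGAAATAA")
  # two internal codons: both orders, each ~50%
  set.seed(41)
  draws <- replicate(400, shuffle_codons("ATGAAAGGGTAA"))
  expect_setequal(unique(draws), c("ATGAAAGGGTAA", "ATGGGGAAATAA"))
  expect_gt(mean(draws == "ATGAAAGGGTAA"), 0.4)
  expect_lt(mean(draws == "ATGAAAGGGTAA"), 0.6)
  # invariants: codon multiset, length, GC, start/stop all preserved
  set.seed(42)
  for (i in 1:20) {
    s <- random_cds(sample(2:30, 1))
    out <- shuffle_codons(s)
    expect_equal(nchar(out), nchar(s))
    expect_identical(sort(seq_to_codons(out)), sort(seq_to_codons(s)))
    expect_identical(substr(out, 1, 3), substr(s, 1, 3))
    expect_identical(substring(out, nchar(s) - 2), substring(s, nchar(s) - 2))
  }
})

test_that("synonymous-site tables normalise within coding blocks", {
  # genome with Lys codons AAA x3, AAG x1 in internal positions
  g <- genome_record("k", c(a = "ATGAAAAAAAAATAA", b = "ATGAAGTAA"))
  tab <- build_synsite_table(g)
  lys <- tab$probs[tab$probs$codon == "AAA", ]
  expect_equal(lys$prob[lys$replacement == "AAA"], 0.75)
  expect_equal(lys$prob[lys$replacement == "AAG"], 0.25)
  # 6-fold Leu: TT block and CT block tabulated separately
  g6 <- genome_record("l", c(a = "ATGTTATTGCTGCTGTAA"))
  t6 <- build_synsite_table(g6)
  tta <- t6$probs[t6$probs$codon == "TTA", ]
  expect_setequal(tta$replacement, c("TTA", "TTG"))   # never the CT block
  ctg <- t6$probs[t6$probs$codon == "CTG", ]
  expect_true(all(substr(ctg$replacement, 1, 2) == "CT"))
})

test_that("synonymous-site simulation preserves protein, blocks, and ends", {
  set.seed(43)
  g <- tiny_genome(n_cds = 8, seed = 43)
  tab <- build_synsite_table(g)
  for (i in seq_along(g$codons)) {
    real <- g$codons[[i]]
    sim <- seq_to_codons(simulate_cds_synsite(real, tab))
    expect_equal(length(sim), length(real))
    expect_identical(translate_codons(sim, t11), translate_codons(real, t11))
    # block membership: first two nucleotides of every codon unchanged
    expect_identical((sim - 1L) %/% 4L, (real - 1L) %/% 4L)
    expect_identical(sim[1], real[1])
    expect_identical(sim[length(sim)], real[length(real)])
  }
  # Met has no synonyms: always ATG
  expect_identical(simulate_cds_synsite("ATGATGATGTAA", tab), "ATGATGATGTAA")
})

test_that("synonymous-codon model pools blocks and preserves the protein", {
  # Leu usage CTG x2, TTA x2 pooled: resampling can cross blocks
  g <- genome_record("l", c(a = "ATGCTGCTGTTATTATAA"))
  usage <- build_codon_usage(g)
  leu <- usage$probs[usage$probs$codon == "TTA", ]
  expect_equal(leu$prob[leu$replacement == "CTG"], 0.5)
  expect_equal(leu$prob[leu$replacement == "TTA"], 0.5)
  set.seed(44)
  sims <- replicate(200, simulate_cds_syncodon("ATGTTATAA", usage))
  expect_setequal(unique(sims), c("ATGTTATAA", "ATGCTGTAA"))
  # amino-acid sequence always preserved
  g2 <- tiny_genome(n_cds = 6, seed = 45)
  u2 <- build_codon_usage(g2)
  for (i in seq_along(g2$codons)) {
    real <- g2$codons[[i]]
    sim <- seq_to_codons(simulate_cds_syncodon(real, u2))
    expect_identical(translate_codons(sim, t11), translate_codons(real, t11))
  }
})

test_that("syncodon resampling converges to the training usage", {
  set.seed(46)
  g <- tiny_genome(n_cds = 40, seed = 46)
  usage <- build_codon_usage(g)
  sim_counts <- integer(64)
  for (r in 1:30) for (cod in g$codons) {
    s <- seq_to_codons(simulate_cds_syncodon(cod, usage))
    sim_counts <- sim_counts + tabulate(s[2:(length(s) - 1)], 64)
  }
  # total-variation distance between simulated pool and training usage, per aa
  train <- tabulate(g$flat$cod[g$flat$internal], 64)
  for (a in c("L", "K", "G", "A")) {
    ids <- which(t11$codon_to_aa == a)
    p_train <- train[ids] / sum(train[ids])
    p_sim <- sim_counts[ids] / sum(sim_counts[ids])
    expect_lt(sum(abs(p_train - p_sim)) / 2, 0.04)
  }
})

test_that("Markov training is deterministic and keyed by codon position", {
  g <- genome_record("m", c(x = "ATGAAAAAATAA"))
  m <- build_markov_model(g, 2)
  # internal region is AAAAAA: every context (AA, any phase) -> A w.p. 1
  for (phase in 1:3) {
    p <- m$envs[[3]][[paste0("AA:", phase)]]
    if (!is.null(p)) expect_equal(p, c(1, 0, 0, 0))
  }
  m2 <- build_markov_model(g, 2)
  expect_identical(ls(m$envs[[3]]), ls(m2$envs[[3]]))
  set.seed(47)
  expect_identical(simulate_cds_markov("ATGAAAAAATAA", m), "ATGAAAAAATAA")
  expect_error(build_markov_model(genome_record("s", c(x = "ATGTAA")), 2),
               "no internal sequence")
})

test_that("Markov simulation preserves length, start, stop, and recovers
           trained phase-specific composition", {
  set.seed(48)
  g <- tiny_genome(n_cds = 20, seed = 48)
  for (order in c(2L, 5L)) {
    m <- build_markov_model(g, order)
    for (i in sample(seq_along(g$codons), 5)) {
      s <- codons_to_seq(g$codons[[i]])
      out <- simulate_cds_markov(s, m)
      expect_equal(nchar(out), nchar(s))
      expect_identical(substr(out, 1, 3), substr(s, 1, 3))
      expect_identical(substring(out, nchar(s) - 2), substring(s, nchar(s) - 2))
    }
  }
  # composition recovery: phase-3 (synonymous site) mononucleotide
  # distribution of a simulated corpus approaches the trained order-0 table
  m2 <- build_markov_model(g, 2)
  trained <- m2$envs[[1]][[":3"]]
  sim_nt <- integer(4)
  for (cod in g$codons) {
    s <- seq_to_codons(simulate_cds_markov(cod, m2))
    sim_nt <- sim_nt + tabulate((s[2:(length(s) - 1)] - 1L) %% 4L + 1L, 4)
  }
  expect_lt(sum(abs(sim_nt / sum(sim_nt) - trained)) / 2, 0.05)
})

test_that("ensembles are seed-reproducible and reject degenerate inputs", {
  g <- tiny_genome(n_cds = 6, seed = 49)
  e1 <- run_ensemble(g, "shuffle", n_reps = 20, seed = 7)
  e2 <- run_ensemble(g, "shuffle", n_reps = 20, seed = 7)
  expect_identical(e1$sims, e2$sims)
  e3 <- run_ensemble(g, "shuffle", n_reps = 20, seed = 8)
  expect_false(identical(e1$sims, e3$sims))
  expect_error(run_ensemble(g, "shuffle", n_reps = 0), "n_reps")
  expect_error(run_ensemble(g, "frobnicate"), "arg")
})

test_that("shuffle-ensemble means match exact permutation enumeration", {
  # fixed case: 2 internal codons; one order yields +1 TGA, exact mean 12.5
  g <- genome_record("s", c(x = "ATGAAAGGGTAA"))
  expect_equal(exact_shuffle_mean("ATGAAAGGGTAA", "TGA", "+1"), 12.5)
  e <- run_ensemble(g, "shuffle", n_reps = 200, seed = 9)
  mc <- e$sims[, "TGA", "+1"]
  se <- sd(mc) / sqrt(length(mc))
  expect_lt(abs(mean(mc) - 12.5), 3 * se + 1e-9)
  # a handful of random small CDSs, all tracked codons, both frames
  set.seed(50)
  for (i in 1:4) {
    s <- random_cds(sample(2:5, 1))
    gs <- genome_record("r", c(x = s))
    e <- run_ensemble(gs, "shuffle", n_reps = 200)
    for (cd in c("TAA", "TGA", "TGC")) for (fr in c("+1", "+2")) {
      exact <- exact_shuffle_mean(s, cd, fr)
      mc <- e$sims[, cd, fr]
      tol <- 3 * sd(mc) / sqrt(length(mc)) + 1e-9
      expect_lt(abs(mean(mc) - exact), tol + 1e-9)
    }
  }
})
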