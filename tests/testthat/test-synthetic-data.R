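test_that("zero-noise template rows are exactly proportional to the profile", {
  cfg <- synth_expression_config(
    n_genes = 30, noise_cv = 0, low_abundance_fraction = 0,
    templates = list(list(profile = c(2, 1, 4, 6, 3), n = 10L, label = "c6")),
    abundance_scale = 50, seed = 3)
  out <- generate_expression_matrix(cfg)
  planted <- unclass(out$matrix)[out$truth$label == "c6", ]
  for (i in seq_len(nrow(planted))) {
    expect_equal(unname(planted[i, ]), c(2, 1, 4, 6, 3) * 50)
  }
})

test_that("the low-abundance fraction is forced below the filter exactly", {
  cfg <- synth_expression_config(n_genes = 100, low_abundance_fraction = 0.5,
                                 templates = list(), noise_cv = 0.2, seed = 5)
  out <- generate_expression_matrix(cfg)
  below <- apply(out$matrix, 1, max) < 30
  expect_equal(sum(below), 50)
  expect_setequal(out$truth$gene_id[out$truth$label == "low_abundance"],
                  rownames(out$matrix)[below])
})

small_templates <- list(
  list(profile = c(2, 1, 4, 6, 3), n = 20L, label = "cluster6_like"),
  list(profile = c(8, 2, 2, 2, 2), n = 15L, label = "cluster3_like"))

test_that("the generator is deterministic in its seed", {
  cfg <- synth_expression_config(n_genes = 200, templates = small_templates,
                                 seed = 11)
  a <- generate_expression_matrix(cfg)
  b <- generate_expression_matrix(cfg)
  expect_identical(unclass(a$matrix), unclass(b$matrix))
  cfg2 <- synth_expression_config(n_genes = 200, templates = small_templates,
                                  seed = 12)
  expect_false(identical(unclass(a$matrix),
                         unclass(generate_expression_matrix(cfg2)$matrix)))
})

test_that("overfull template sets are a configuration error", {
  expect_error(
    synth_expression_config(
      n_genes = 50,
      templates = list(list(profile = rep(1, 5), n = 60L, label = "big"))),
    "exceed")
  expect_error(synth_expression_config(n_genes = 100, noise_cv = -0.1),
               "non-negative")
})

test_that("candidate sequences hit the requested identity; decoys match length", {
  seqs <- generate_sequences(n_decoys = 10, n_candidates = 2,
                             identity_to_seed = 0.9, seed = 2)
  expect_length(seqs, 12)
  expect_equal(attr(seqs, "labels"),
               rep(c("candidate", "decoy"), c(2, 10)))
  seed <- as.character(adh_seed_sequence())[[1]]
  for (i in 1:2) {
    obs <- sequence_identity(as.character(seqs[[i]]), seed)
    expect_equal(obs, 0.9, tolerance = 0.03)
  }
  expect_true(all(nchar(as.character(seqs)) == nchar(seed)))
})

test_that("identity 1 returns the seed itself; invalid identity errors", {
  seqs <- generate_sequences(0, 1, identity_to_seed = 1, seed = 1)
  expect_identical(as.character(seqs[[1]]), as.character(adh_seed_sequence())[[1]])
  expect_error(generate_sequences(1, 1, identity_to_seed = 0), "identity")
})

test_that("sequence generation is reproducible for a fixed seed", {
  a <- generate_sequences(5, 3, 0.8, seed = 7)
  b <- generate_sequences(5, 3, 0.8, seed = 7)
  expect_identical(as.character(a), as.character(b))
})

test_that("noisy initial rates sit on the rate law in expectation and exactly at cv 0", {
  d0 <- generate_initial_rates(list(Km = 10, Vmax = 40), c(10), 0, seed = 1)
  expect_equal(d0$rate, 20) # S = Km: half saturation
  dKi <- generate_initial_rates(list(Km = 10, Vmax = 40, Ki = 1000),
                                c(100), 0, seed = 1)
  expect_equal(dKi$rate, si_rate(100, 10, 40, 1000)) # curve maximum
  d1 <- generate_initial_rates(list(Km = 10, Vmax = 40), c(1, 10, 100), 0.2,
                               seed = 3, replicates = 2)
  expect_identical(d1, generate_initial_rates(list(Km = 10, Vmax = 40),
                                              c(1, 10, 100), 0.2, seed = 3,
                                              replicates = 2))
  expect_true(all(d1$rate >= 0))
})
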