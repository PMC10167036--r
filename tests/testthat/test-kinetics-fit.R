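paper_design <- c(3, 5, 10, 25, 50, 100, 200)

test_that("zero-noise Michaelis-Menten data are recovered to 1e-6 relative", {
  for (p in list(c(Km = 24.68, Vmax = 63.47), c(Km = 9.96, Vmax = 69.79))) {
    d <- generate_initial_rates(as.list(p), paper_design, noise_cv = 0, seed = 1)
    fit <- fit_michaelis_menten(d)
    expect_true(fit$converged)
    expect_equal(coef(fit)[["Km"]], p[["Km"]], tolerance = 1e-6)
    expect_equal(coef(fit)[["Vmax"]], p[["Vmax"]], tolerance = 1e-6)
  }
})

test_that("zero-noise recovery holds across random parameters and designs", {
  set.seed(42)
  for (i in 1:100) {
    Km <- 10^runif(1, -0.5, 2.5)
    Vmax <- 10^runif(1, 0, 2)
    S <- 10^seq(log10(Km / 8), log10(Km * 8), length.out = 7)
    d <- data.frame(concentration_uM = S, rate = mm_rate(S, Km, Vmax))
    fit <- fit_michaelis_menten(d)
    expect_equal(coef(fit)[["Km"]], Km, tolerance = 1e-6)
    expect_equal(coef(fit)[["Vmax"]], Vmax, tolerance = 1e-6)
  }
})

test_that("Km estimator is usable at realistic assay noise", {
  # median relative Km error over 200 noisy simulations stays under 15%
  errs <- vapply(1:200, function(s) {
    d <- generate_initial_rates(list(Km = 24.68, Vmax = 63.47), paper_design,
                                noise_cv = 0.1, seed = s, replicates = 3)
    abs(coef(fit_michaelis_menten(d))[["Km"]] - 24.68) / 24.68
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})

test_that("saturated (flat) rate data drive Km to its boundary and get flagged", {
  d <- data.frame(concentration_uM = paper_design,
                  rate = rep(50, length(paper_design)))
  fit <- fit_michaelis_menten(d)
  expect_lt(coef(fit)[["Km"]], 1e-5)
  expect_true("Km at boundary" %in% fit$flags)
})

test_that("substrate-inhibition fit recovers a well-bracketed Ki unflagged", {
  Km <- 9.96; Ki <- 500
  Smax <- 50 * sqrt(Km * Ki)
  S <- 10^seq(log10(3), log10(Smax), length.out = 12)
  d <- data.frame(concentration_uM = S, rate = si_rate(S, Km, 69.79, Ki))
  fit <- fit_substrate_inhibition(d)
  expect_equal(coef(fit)[["Ki"]], Ki, tolerance = 0.01)
  expect_false("Ki unidentifiable" %in% fit$flags)
})

test_that("the Ki flag tracks whether the rate optimum is inside the design", {
  # optimum sqrt(Km*Ki) = 70 uM, inside 3-200: Ki is identifiable and the
  # flag stays mostly silent; optimum 223 uM, outside: the flag fires.
  n_flag <- function(Ki, seeds) {
    sum(vapply(seeds, function(s) {
      d <- generate_initial_rates(list(Km = 9.96, Vmax = 69.79, Ki = Ki),
                                  paper_design, noise_cv = 0.05, seed = s,
                                  replicates = 3)
      fit <- fit_substrate_inhibition(d)
      !fit$converged || "Ki unidentifiable" %in% fit$flags
    }, logical(1)))
  }
  expect_lte(n_flag(500, 1:8), 2)
  expect_gte(n_flag(5000, 1:8), 6)
})

test_that("substrate-inhibition model nests Michaelis-Menten on MM data", {
  d <- generate_initial_rates(list(Km = 24.68, Vmax = 63.47), paper_design,
                              noise_cv = 0, seed = 1)
  mm <- fit_michaelis_menten(d)
  si <- fit_substrate_inhibition(d)
  # Ki runs to its upper bound and the SI fit matches the MM fit
  expect_lt(si$rss, 1e-3)
  expect_equal(coef(si)[["Km"]], coef(mm)[["Km"]], tolerance = 1e-2)
})

test_that("fit object methods are coherent", {
  d <- generate_initial_rates(list(Km = 24.68, Vmax = 63.47), paper_design,
                              noise_cv = 0.05, seed = 2)
  fit <- fit_michaelis_menten(d, molar_mass = 40680)
  expect_equal(predict(fit) + residuals(fit), d$rate)
  expect_equal(coef(fit)[["kcat"]],
               coef(fit)[["Vmax"]] * 40680 * 1e-6)
  expect_output(print(fit), "Michaelis-Menten")
  expect_lt(sum(residuals(fit)^2) - fit$rss, 1e-12)
})
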