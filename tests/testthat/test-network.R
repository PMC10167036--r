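test_that("Haldane closure: symmetric case, equilibrium zero flux, irreversible limit", {
  expect_equal(haldane_reverse_params(2.5, 10, 10, 10, 10, Keq = 1), 2.5)
  expect_equal(haldane_reverse_params(2.5, 10, 10, 10, 10, Keq = 1e12),
               2.5e-12)
  # plug the returned reverse turnover into the rate law at the mass-action
  # ratio: net flux vanishes to machine precision
  p <- network_params()
  for (r in c("r1", "r2")) {
    Keq <- p$reactions[[r]]$Keq
    S <- 80; Cox <- 300; P <- 40
    Cred <- Keq * S * Cox / P
    st <- c(ZOH = S, EOH = S, OXO = P, NADPp = Cox, NADPH = Cred, BNADPH = 0)
    expect_lt(abs(reversible_rate(st, p, r)), 1e-12)
  }
})

test_that("net flux: irreversible start, detailed-balance zero, enzyme linearity", {
  p <- network_params()
  st0 <- c(ZOH = 100, EOH = 0, OXO = 0, NADPp = 400, NADPH = 0, BNADPH = 0)
  v <- reversible_rate(st0, p, "r1")
  r <- p$reactions$r1
  irr <- p$enzyme_uM * 60 * r$kcat_f * (100 / r$Km_S) * (400 / r$Km_Cox) /
    ((1 + 100 / r$Km_S) * (1 + 400 / r$Km_Cox))
  expect_gt(v, 0)
  expect_equal(v, irr, tolerance = 1e-12)
  p2 <- network_params(enzyme_uM = 2 * p$enzyme_uM)
  expect_equal(reversible_rate(st0, p2, "r1"), 2 * v, tolerance = 1e-12)
})

test_that("a zero-enzyme system stays frozen", {
  p <- network_params(enzyme_uM = 0)
  sim <- simulate_network(p, network_scenario("fig4E", duration_min = 5))
  tr <- sim$trajectory
  expect_true(all(tr$ZOH == 200))
  expect_true(all(tr$NADPp == 500))
})

test_that("closed runs conserve quinone and cofactor totals to 1e-9 relative", {
  for (preset in c("fig4D", "fig4E")) {
    sim <- simulate_network(network_params(), network_scenario(preset))
    expect_lt(sim$diagnostics$quinone_drift, 1e-9)
    expect_lt(sim$diagnostics$cofactor_drift, 1e-9)
  }
})

test_that("long closed runs converge to the configured equilibrium constants", {
  p <- network_params()
  sim <- simulate_network(p, network_scenario("fig4E", duration_min = 5000,
                                              dt_min = 50))
  fin <- tail(sim$trajectory, 1)
  G1 <- fin$OXO * fin$NADPH / (fin$ZOH * fin$NADPp)
  G2 <- fin$OXO * fin$NADPH / (fin$EOH * fin$NADPp)
  expect_equal(G1, p$reactions$r1$Keq, tolerance = 1e-3)
  expect_equal(G2, p$reactions$r2$Keq, tolerance = 1e-3)
})

test_that("endpoint composition sums to one and orders as reported", {
  sim <- simulate_network(network_params(), network_scenario("fig4E"))
  comp <- endpoint_composition(sim)
  expect_equal(sum(comp), 1, tolerance = 1e-12)
  expect_true(comp[["EOH"]] > comp[["ZOH"]])
  expect_true(comp[["ZOH"]] > comp[["OXO"]])
})

test_that("reduction scenario: substrate consumed fast, strongly E-selective", {
  sim <- simulate_network(network_params(), network_scenario("fig4D"))
  tr <- sim$trajectory
  oxo10 <- tr$OXO[tr$time == 10]
  expect_lt(oxo10 / 200, 0.05)
  comp <- endpoint_composition(sim)
  expect_gt(comp[["EOH"]] / comp[["ZOH"]], 3)
})

test_that("substrate turnover happens on the reported timescale", {
  # half-life of the starting substrate between 1 and 25 minutes
  for (preset in c("fig4D", "fig4E")) {
    sim <- simulate_network(network_params(), network_scenario(preset))
    tr <- sim$trajectory
    sp <- if (preset == "fig4D") "OXO" else "ZOH"
    t_half <- tr$time[which(tr[[sp]] <= 100)[1]]
    expect_gt(t_half, 1 / 60)
    expect_lt(t_half, 25)
  }
})

test_that("near-irreversible parameters drive the Z-alcohol to exhaustion", {
  rx <- default_network_reactions()
  rx$r1$Keq <- 1e9
  rx$r2$Keq <- 1e9
  p <- network_params(reactions = rx)
  # NADPH product inhibition makes the tail slow; integrate long enough
  sim <- simulate_network(p, network_scenario("fig4E", duration_min = 4000,
                                              dt_min = 50))
  comp <- endpoint_composition(sim)
  expect_gt(comp[["EOH"]] + comp[["OXO"]], 0.999)
})

test_that("a sink shifts the free-pool endpoint but not the channeled one", {
  exp_res <- run_sink_experiment()
  expect_lt(exp_res$shift_points[["channeled"]], 1)
  # the sink drains NADPH and pulls the mixture toward the aldehyde
  oxo_shift <- 100 * (exp_res$endpoints$free_pool_sink[["OXO"]] -
                        exp_res$endpoints$free_pool_nosink[["OXO"]])
  expect_gt(oxo_shift, 10)
})

test_that("a zero-strength sink changes nothing in either mode", {
  sc <- network_scenario("fig4E", duration_min = 10)
  base <- simulate_network(network_params(), sc)$trajectory
  for (mode in c("free_pool", "channeled")) {
    p <- network_params(cofactor_mode = mode, sink = list(Vmax = 0, Km = 20))
    tr <- simulate_network(p, sc)$trajectory
    expect_equal(tr$ZOH, base$ZOH, tolerance = 1e-8)
    expect_equal(tr$OXO, base$OXO, tolerance = 1e-8)
  }
})

test_that("channeled closed runs keep the free pool empty yet reach the same endpoint", {
  sc <- network_scenario("fig4E")
  free <- endpoint_composition(simulate_network(network_params(), sc))
  p <- network_params(cofactor_mode = "channeled")
  sim <- simulate_network(p, sc)
  expect_lt(max(sim$trajectory$NADPH), 1e-6)
  expect_equal(endpoint_composition(sim), free, tolerance = 1e-6)
})
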