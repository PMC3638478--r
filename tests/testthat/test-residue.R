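# Analytical residue functions, arrival spectra and transit-time
# distributions, cross-checked against path enumeration and Monte Carlo.

test_that("a single vessel gives the unit rectangle and a one-atom h(t)", {
  R <- single_vessel_residue(2)
  expect_equal(R$breakpoints, c(0, 2))
  expect_equal(R$values, c(1, 0))
  expect_equal(residue_eval(R, c(0, 1.999, 2, 5)), c(1, 1, 0, 0))
  ttd <- transit_time_distribution(R)
  expect_equal(ttd$times, 2)
  expect_equal(ttd$masses, 1)
  expect_equal(ttd$MTT, 2)
  expect_equal(ttd$CTTH, 0)
  expect_capres_error(single_vessel_residue(0), "capres_validation_error")
})

test_that("two vessels in series give one rectangle of the total time", {
  sol <- fx_sol_series(T1 = 1, T2 = 2)
  R <- network_residue(sol)
  expect_equal(residue_eval(R, c(0, 0.5, 1.5, 2.9)), rep(1, 4))
  expect_equal(residue_eval(R, c(3, 10)), c(0, 0))
  expect_equal(residue_integral(R), 3, tolerance = 1e-12)
  # spectrum at the mid node is the single delayed atom
  sp <- arrival_spectra(sol)
  expect_equal(sp$spectra[["1"]]$weights, 1)
  expect_equal(sp$spectra[["1"]]$delays, 1)
})

test_that("a 2:1 parallel pair reproduces the hand-derived staircase", {
  sol <- fx_sol_parallel(q1 = 2, q2 = 1, T1 = 1, T2 = 2)
  R <- network_residue(sol)
  expect_equal(residue_eval(R, c(0, 0.99)), c(1, 1))
  expect_equal(residue_eval(R, c(1, 1.99)), c(1 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(residue_eval(R, 2), 0)
  expect_equal(residue_integral(R), 4 / 3, tolerance = 1e-12)
  ttd <- transit_time_distribution(R)
  expect_equal(ttd$times, c(1, 2))
  expect_equal(ttd$masses, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(ttd$CTTH, sqrt(2 - (4 / 3)^2), tolerance = 1e-12)
})

test_that("diamond arrival spectrum matches explicit path enumeration", {
  sol <- fx_sol_diamond()
  sp <- arrival_spectra(sol)
  outlet <- sp$spectra[["3"]]
  o <- order(outlet$delays)
  expect_equal(outlet$delays[o], c(1, 2), tolerance = 1e-12)
  expect_equal(outlet$weights[o], c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(sum(outlet$weights), 1, tolerance = 1e-9)
})

test_that("network residue equals brute-force path enumeration exactly", {
  fixtures <- list(fx_sol_series(), fx_sol_parallel(), fx_sol_diamond())
  for (sol in fixtures) {
    expect_lt(residue_sup_gap(network_residue(sol),
                              enumerate_paths_residue(sol)), 1e-12)
  }
  # and on a real solved Poiseuille network (12 vessels)
  sol <- solve_flow(fx_small_network())
  expect_lt(residue_sup_gap(network_residue(sol),
                            enumerate_paths_residue(sol)), 1e-12)
})

test_that("residue invariants hold on generated networks", {
  for (seed in c(1, 12)) {
    sol <- solve_flow(generate_network(seed = seed))
    R <- network_residue(sol)
    expect_equal(R$values[1], 1, tolerance = 1e-9)
    expect_true(all(diff(R$values) <= 1e-12))
    expect_equal(R$values[length(R$values)], 0)
    expect_true(all(R$values >= 0 & R$values <= 1 + 1e-9))
    expect_true(is.finite(max(R$breakpoints)))
    # conservation: integral of R = sum(live V) / Q_in = MTT
    mtt <- sum(sol$edges$V[sol$edges$live]) / sol$Q_in
    expect_equal(residue_integral(R), mtt, tolerance = 1e-9)
    # h has unit mass
    ttd <- transit_time_distribution(R)
    expect_equal(sum(ttd$masses), 1, tolerance = 1e-9)
    expect_equal(ttd$MTT, mtt, tolerance = 1e-9)
  }
})

test_that("Monte-Carlo particle tracking agrees with the analytical R", {
  # deterministic path: identical to the rectangle for any n
  schain <- solve_flow(fx_single_vessel())
  expect_lt(residue_sup_gap(network_residue(schain),
                            monte_carlo_residue(schain, 500, seed = 1)), 1e-12)
  # parallel pair: binomial error bound at n = 1e5
  sol <- fx_sol_parallel()
  n <- 1e5
  gap <- residue_sup_gap(network_residue(sol),
                         monte_carlo_residue(sol, n, seed = 42))
  expect_lt(gap, 3 * sqrt(0.25 / n))
  # generated network at n = 1e5
  solg <- solve_flow(generate_network(seed = 8))
  gapg <- residue_sup_gap(network_residue(solg),
                          monte_carlo_residue(solg, 1e5, seed = 8))
  expect_lt(gapg, 0.02)
})

test_that("rescaling pressure rescales the residue time axis exactly", {
  sol <- solve_flow(generate_network(fx_small_config(), seed = 5))
  R1 <- network_residue(sol)
  R2 <- network_residue(rescale_pressure(sol, 2))
  expect_equal(R2$breakpoints, R1$breakpoints / 2, tolerance = 1e-12)
  expect_equal(R2$values, R1$values, tolerance = 1e-12)
})

test_that("occlusion slows the decay of the residue function", {
  # paired across a small ensemble: mean time to R <= 0.01 increases
  seeds <- 1:5
  t_norm <- t_occ <- numeric(0)
  for (s in seeds) {
    net <- generate_network(seed = s)
    occ <- tryCatch(occlude(net, 0.2, seed = s),
                    capres_error = function(e) NULL)
    if (is.null(occ)) next
    t_norm <- c(t_norm, residue_time_below(network_residue(solve_flow(net)), 0.01))
    t_occ <- c(t_occ, residue_time_below(network_residue(solve_flow(occ)), 0.01))
  }
  expect_gt(mean(t_occ), mean(t_norm))
})

test_that("inlet atoms carry flow shares and spectra conserve mass", {
  sol <- solve_flow(generate_network(fx_small_config(), seed = 3))
  sp <- arrival_spectra(sol)
  nodes <- sol$net$nodes
  inlets <- as.character(nodes$id[nodes$role == "arteriole_inlet"])
  shares <- vapply(inlets, function(id) sum(sp$spectra[[id]]$weights),
                   numeric(1))
  expect_equal(sum(shares), 1, tolerance = 1e-9)
  for (id in inlets) expect_equal(sp$spectra[[id]]$delays, 0)
  # all atom weights positive; outlet mass balances the input
  outlets <- as.character(nodes$id[nodes$role == "venule_outlet"])
  out_mass <- sum(vapply(outlets, function(id) {
    s <- sp$spectra[[id]]
    if (is.null(s)) 0 else sum(s$weights)
  }, numeric(1)))
  expect_equal(out_mass, 1, tolerance = 1e-9)
  expect_lt(sp$dropped_mass, 1e-9)
})
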