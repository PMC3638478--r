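# Poiseuille flow solver and apparent-viscosity law.

test_that("apparent viscosity reduces to plasma at zero haematocrit", {
  for (d in c(3, 6, 10, 40))
    expect_equal(apparent_viscosity(d, haematocrit = 0, plasma_viscosity = 1.2),
                 1.2, tolerance = 1e-12)
})

test_that("Pries law variants give their published capillary values", {
  # in-vivo fit at 6 um: 6 e^-0.51 + 3.2 - 2.44 e^(-0.06 * 6^0.645)
  expect_equal(pries_relative_viscosity(6, 0.45, "in_vivo"), 4.79,
               tolerance = 0.01)
  # in-vitro value at 6 um sits near the Fahraeus-Lindqvist minimum
  expect_equal(pries_relative_viscosity(6, 0.45, "in_vitro"),
               220 * exp(-7.8) + 3.2 - 2.44 * exp(-0.06 * 6^0.645),
               tolerance = 1e-12)
  # glass-tube viscosity grows from the capillary minimum toward larger tubes
  expect_lt(pries_relative_viscosity(6, 0.45, "in_vitro"),
            pries_relative_viscosity(50, 0.45, "in_vitro"))
  expect_capres_error(pries_relative_viscosity(-1, 0.45),
                      "capres_validation_error")
})

test_that("single vessel reproduces the closed-form Poiseuille solution", {
  net <- fx_single_vessel(L = 60, d = 6)
  sol <- solve_flow(net, delta_p = 1000, plasma_viscosity = 1.2,
                    haematocrit = 0.45, viscosity_law = "in_vivo")
  mu <- 1.2e-3 * pries_relative_viscosity(6, 0.45, "in_vivo")  # Pa s
  g <- pi * 6^4 / (128 * mu * 60)                              # um^3/(s Pa)
  Q_expected <- g * 1000
  expect_equal(sol$Q_in, Q_expected, tolerance = 1e-12)
  # ~9.2e-14 m^3/s and ~0.018 s at these parameters
  expect_equal(Q_expected * 1e-18, 9.2e-14, tolerance = 0.01)
  e <- sol$edges
  expect_equal(e$T, e$V / e$Q, tolerance = 1e-12)
  expect_equal(e$T, 0.018, tolerance = 0.03)
  h <- haemodynamics(sol)
  expect_equal(h$MTT, e$T)                 # single compartment
})

test_that("symmetric junction splits flow evenly and series halves pressure", {
  soly <- solve_flow(fx_symmetric_y())
  branches <- soly$edges[soly$edges$from == 1, ]
  expect_equal(branches$Q[1], branches$Q[2], tolerance = 1e-12)
  expect_equal(sum(branches$Q), soly$Q_in, tolerance = 1e-12)

  sols <- solve_flow(fx_chain_network(lengths = c(50, 50),
                                      diameters = c(6, 6)),
                     delta_p = 800)
  expect_equal(unname(sols$pressures["1"]), 400, tolerance = 1e-9)
})

test_that("mass is conserved at every interior node", {
  for (seed in c(1, 7)) {
    sol <- solve_flow(generate_network(seed = seed))
    e <- sol$edges[sol$edges$live, ]
    interior <- sol$net$nodes$id[sol$net$nodes$role == "interior"]
    for (v in interior) {
      inflow <- sum(e$Q[e$to == v])
      outflow <- sum(e$Q[e$from == v])
      expect_lt(abs(inflow - outflow), 1e-10 * max(inflow, 1e-30))
    }
    # global conservation: outlet inflow equals Q_in
    outlets <- sol$net$nodes$id[sol$net$nodes$role == "venule_outlet"]
    expect_equal(sum(e$Q[e$to %in% outlets]) - sum(e$Q[e$from %in% outlets]),
                 sol$Q_in, tolerance = 1e-10)
    expect_true(all(e$T > 0 & is.finite(e$T)))
  }
})

test_that("sparse solver matches a dense direct solve on a small graph", {
  net <- fx_small_network()
  sol <- solve_flow(net, delta_p = 1000)
  # independent dense solve of the same Laplacian system in base R
  n <- nrow(net$nodes)
  mu <- apparent_viscosity(net$edges$diameter)
  g <- pi * net$edges$diameter^4 / (128 * (mu * 1e-3) * net$edges$length)
  L <- matrix(0, n, n)
  for (k in seq_len(nrow(net$edges))) {
    i <- net$edges$node_i[k] + 1; j <- net$edges$node_j[k] + 1
    L[i, j] <- L[i, j] - g[k]; L[j, i] <- L[j, i] - g[k]
    L[i, i] <- L[i, i] + g[k]; L[j, j] <- L[j, j] + g[k]
  }
  p <- numeric(n)
  fixed <- net$nodes$role != "interior"
  p[net$nodes$role == "arteriole_inlet"] <- 1000
  free <- which(!fixed)
  p[free] <- solve(L[free, free], -L[free, fixed, drop = FALSE] %*% p[fixed])
  expect_equal(unname(sol$pressures[as.character(net$nodes$id)]),
               p, tolerance = 1e-12)
})

test_that("flow is linear in the driving pressure", {
  net <- generate_network(fx_small_config(), seed = 4)
  sol1 <- solve_flow(net, delta_p = 1000)
  sol2 <- solve_flow(net, delta_p = 2000)
  scaled <- rescale_pressure(sol1, 2)
  expect_equal(scaled$edges$Q, sol2$edges$Q, tolerance = 1e-12)
  expect_equal(scaled$edges$T, sol2$edges$T, tolerance = 1e-12)
  expect_equal(scaled$pressures, sol2$pressures, tolerance = 1e-12)
  expect_equal(scaled$Q_in, sol2$Q_in, tolerance = 1e-12)
  # identity rescale and halved transit times
  expect_equal(rescale_pressure(sol1, 1), sol1)
  expect_equal(rescale_pressure(sol1, 2)$edges$T, sol1$edges$T / 2,
               tolerance = 1e-15)
  expect_capres_error(rescale_pressure(sol1, 0), "capres_validation_error")
})

test_that("haemodynamic quantities satisfy their defining identities", {
  # Q_in equal to 1% of cube volume per minute -> CBF = 1 ml/100ml/min
  net <- fx_single_vessel(L = 60, d = 6, cube_edge = 250)
  sol <- solve_flow(net)
  sol$Q_in <- 0.01 * 250^3 / 60
  h <- haemodynamics(sol)
  expect_equal(h$CBF, 1, tolerance = 1e-12)

  sol2 <- solve_flow(generate_network(seed = 2))
  h2 <- haemodynamics(sol2)
  expect_equal(h2$MTT * h2$CBF, 60 * h2$CBV, tolerance = 1e-9)
  expect_true(all(unlist(h2) >= 0))
})

test_that("disconnected inlet/outlet configurations raise solver errors", {
  nodes <- data.frame(id = 0:3, x = c(0, 100, 200, 300), y = 50, z = 50,
                      role = c("arteriole_inlet", "interior", "interior",
                               "venule_outlet"))
  edges <- data.frame(node_i = c(0L, 2L), node_j = c(1L, 3L),
                      length = c(50, 50), diameter = c(6, 6))
  net <- new_vessel_network_for_tests(nodes, edges, 300)
  expect_capres_error(solve_flow(net), "capres_solver_error")
})
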