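test_that("closed diffusion conserves mass for arbitrary profiles", {
  set.seed(4)
  net <- reaction_network(toy_species()[1:2], list())
  grid <- lake_grid(n_cells = 10)
  init <- model_state(grid, net, list(A = runif(10, 0, 50), B = runif(10, 0, 5)))
  res <- integrate_lake(grid, net, init, t_end = 50, save_every = 10)
  tot <- apply(res$conc, c(1, 3), sum)
  for (s in c("A", "B")) {
    expect_lt(max(abs(tot[s, ] - tot[s, 1])) / tot[s, 1], 10 * res$tolerance)
  }
})

test_that("first-order decay matches the analytic exponential", {
  net <- decay_network(k = 1)  # 1/year
  grid <- still_grid()
  init <- model_state(grid, net, list(A = 8))
  t_half <- log(2) * 365
  res <- integrate_lake(grid, net, init, t_end = t_half, save_every = t_half,
                        tolerance = 1e-10)
  final <- res$conc["A", , dim(res$conc)[3]]
  expect_true(all(abs(final - 4) < 1e-6))
  # B picks up exactly what A loses
  expect_true(all(abs(res$conc["B", , dim(res$conc)[3]] - 4) < 1e-6))
})

test_that("pure diffusion of a pulse matches the dense matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  n <- 23
  net <- reaction_network(toy_species()[1], list())
  grid <- lake_grid(n_cells = n)          # two-layer D(z), zero-flux ends
  pulse <- rep(0, n); pulse[7] <- 100
  init <- model_state(grid, net, list(A = pulse))
  res <- integrate_lake(grid, net, init, t_end = 40, save_every = 5,
                        tolerance = 1e-12)

  # independent discrete heat-equation oracle: explicit tridiagonal
  # Laplacian, dense matrix exponential
  D <- grid$diffusivity
  L <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    d <- D[i + 1]                          # interface between cells i, i+1
    L[i, i] <- L[i, i] - d
    L[i, i + 1] <- L[i, i + 1] + d
    L[i + 1, i + 1] <- L[i + 1, i + 1] - d
    L[i + 1, i] <- L[i + 1, i] + d
  }
  for (ti in seq_along(res$times)) {
    expected <- as.vector(Matrix::expm(L * (res$times[ti] - res$times[1])) %*% pulse)
    expect_lt(max(abs(res$conc["A", , ti] - expected)), 1e-8)
  }

  # qualitative pulse spreading: maximum decays, variance grows
  mx <- apply(res$conc["A", , ], 2, max)
  expect_true(all(diff(mx) < 0))
  depth_var <- apply(res$conc["A", , ], 2, function(p) {
    p <- p / sum(p); sum(p * grid$depths^2) - sum(p * grid$depths)^2
  })
  expect_true(all(diff(depth_var) > 0))
})

test_that("Dirichlet surface and influx bottom boundaries behave as specified", {
  net <- reaction_network(toy_species()[1:2], list())
  grid <- lake_grid(
    n_cells = 6, diffusivity = rep(1, 7),
    surface_bc = list(A = list(type = "dirichlet", value = 10)),
    bottom_bc = list(B = list(type = "influx", value = 2))
  )
  init <- model_state(grid, net, list())
  res <- integrate_lake(grid, net, init, t_end = 2000, save_every = 2000)
  last <- dim(res$conc)[3]
  # A relaxes to the fixed surface value everywhere
  expect_equal(unname(res$conc["A", , last]), rep(10, 6), tolerance = 1e-3)
  # B accumulates at influx rate x time / depth (uniform at long times)
  expect_equal(mean(res$conc["B", , last]), 2 * 2000 / 6, tolerance = 1e-2)
})

test_that("process_rate_profile sums fields additively", {
  syn <- make_scenario(seed = 3, n_free_params = 0, free_processes = character(0))
  res <- syn$result
  f1 <- process_rate_profile(res, "sulfate_reduction")
  f2 <- process_rate_profile(res, "methanogenesis")
  expect_equal(process_rate_profile(res, c("sulfate_reduction", "methanogenesis")),
               f1 + f2)
  expect_error(process_rate_profile(res, "no_such_process"), "unknown process")
})

test_that("column_total sums depth x time with dz weighting and is linear", {
  net <- reaction_network(toy_species()[1], list())
  grid <- lake_grid(n_cells = 23, diffusivity = rep(0, 24))
  init <- model_state(grid, net, list(A = 1))
  res <- integrate_lake(grid, net, init, t_end = 28, save_every = 7)
  expect_equal(column_total(res, "A"), 23 * 5, tolerance = 1e-8)
  res2 <- res
  res2$conc <- res$conc * 2
  expect_equal(column_total(res2, "A"), 2 * column_total(res, "A"))
  res3 <- res
  res3$conc[] <- 0
  expect_identical(column_total(res3, "A"), 0)
  expect_error(column_total(res, "Z"), "unknown species")
})

test_that("element conservation holds across random reaction networks", {
  # closed column (zero-flux boundaries), precipitation possibly active but
  # the precipitate is tracked, so S/N/Fe/C totals must all be conserved
  # (the acceptance suite runs the full 50-network version)
  for (seed in 1:15) {
    net <- random_subnetwork(seed)
    grid <- lake_grid(n_cells = 8)
    init <- model_state(grid, net, random_profiles(seed + 1000, grid))
    res <- integrate_lake(grid, net, init, t_end = 20, save_every = 10,
                          tolerance = 1e-8)
    led <- res$ledger
    for (e in c("S", "N", "Fe", "C")) {
      drift <- max(abs(led[[e]] - led[[e]][1])) / max(led[[e]][1], 1)
      expect_lt(drift, 10 * res$tolerance)
    }
  }
})

test_that("self-convergence: refining dz and tolerance changes totals < 1%", {
  syn_settings <- default_scenario_settings()
  net <- default_network()
  run <- function(n_cells, tol) {
    g0 <- syn_settings$grid
    grid <- lake_grid(n_cells = n_cells, dz = 23 / n_cells,
                      surface_bc = g0$surface_bc, bottom_bc = g0$bottom_bc)
    init <- model_state(grid, net, syn_settings$initial_profiles)
    res <- integrate_lake(grid, net, init, t_end = 56, save_every = 28,
                          tolerance = tol)
    column_total(res, "SO4") / n_cells   # per-cell average scale
  }
  coarse <- run(23, 1e-6)
  fine <- run(46, 1e-8)
  expect_lt(abs(fine * 2 - coarse) / coarse, 0.01)
})

test_that("saved concentrations are nonnegative after clipping and negativity is bounded", {
  syn <- make_scenario(seed = 5, n_free_params = 0, free_processes = character(0))
  # balance-only bookkeeping species (H+, H2O) are exempt from clipping
  tracked <- setdiff(dimnames(syn$result$conc)[[1]], c("H", "H2O"))
  expect_true(all(syn$result$conc[tracked, , ] >= 0))
  expect_lt(max(syn$result$ledger$clipped_mass), 1e-3)
})
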