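test_that("sample_parameters respects bounds, fixing, and truncated-normal moments", {
  specs <- list(parameter_spec("a", 0, 10, center = 5, sigma = 0.5),
                parameter_spec("b", -1, 1))
  m <- sample_parameters(specs, 100, seed = 3)
  expect_identical(dim(m), c(100L, 2L))
  expect_true(all(m[, "a"] >= 0 & m[, "a"] <= 10))
  expect_true(all(m[, "b"] >= -1 & m[, "b"] <= 1))
  # deterministic given seed
  expect_identical(sample_parameters(specs, 100, seed = 3), m)

  # all fixed: identical rows
  fx <- lapply(specs, function(s) { s$fixed <- TRUE; s$fixed_value <- 0.25; s })
  mf <- sample_parameters(fx, 5, seed = 1)
  expect_true(all(mf == 0.25))

  # center mid-bounds, small sigma: empirical mean within 3 s.e. of center
  sp <- list(parameter_spec("x", 0, 10, center = 5, sigma = 0.5))
  big <- sample_parameters(sp, 10000, seed = 7)
  se <- 0.5 / sqrt(10000)
  expect_lt(abs(mean(big) - 5), 3 * se)
})

test_that("f_test agrees with a least-squares oracle and handles edge cases", {
  # brute-force regression oracle via lm()
  v <- c(0, 1, 2, 3); o <- c(0, 1, 2, 4)
  ft <- f_test(v, o)
  lm_fit <- summary(lm(o ~ v))
  expect_equal(ft$F, unname(lm_fit$fstatistic["value"]))
  expect_equal(ft$p, unname(stats::pf(lm_fit$fstatistic[1], 1, 2,
                                      lower.tail = FALSE)))
  expect_equal(ft$slope, unname(coef(lm(o ~ v))[2]))

  # perfect linear fit: essentially zero p
  pf5 <- f_test(1:5, 2 * (1:5) + 1)
  expect_lt(pf5$p, 1e-10)

  # flat response
  flat <- f_test(1:6, rep(3, 6))
  expect_identical(flat$F, 0)
  expect_identical(flat$p, 1)
  expect_error(f_test(rep(2, 5), 1:5), "zero variance")
})

test_that("run_iteration fixes the most sensitive parameter at the best sample", {
  specs <- list(parameter_spec("a", -5, 5), parameter_spec("b", -5, 5),
                parameter_spec("c", -5, 5))
  obj <- function(p) (p[["a"]] - 1)^2 + 0.001 * p[["b"]] + 0.001 * p[["c"]]
  hits <- vapply(1:50, function(s) {
    run_iteration(specs, obj, 200, seed = s)$record$fixed_parameter
  }, character(1))
  expect_gte(mean(hits == "a"), 0.9)

  # the fixed value is the value in the lowest-objective sample
  r <- run_iteration(specs, obj, 200, seed = 4)
  rec <- r$record
  best <- which.min(rec$objectives)
  expect_identical(rec$fixed_value, rec$samples[best, rec$fixed_parameter])

  # burn-in: nothing fixed, centers move
  b <- run_iteration(specs, obj, 200, seed = 4, burn_in = TRUE)
  expect_identical(b$record$fixed_parameter, NA_character_)
  expect_false(any(vapply(b$specs, function(s) s$fixed, logical(1))))
  expect_false(identical(b$record$new_centers,
                         c(a = 0, b = 0, c = 0)))
})

test_that("exact p-value ties are broken by spec order", {
  # objective depends identically on a and b by construction: evaluate on
  # samples where both columns are forced equal via a symmetric objective
  specs <- list(parameter_spec("a", -1, 1), parameter_spec("b", -1, 1))
  ft_a <- f_test(c(1, 2, 3, 4), c(2, 4, 6, 8))
  ft_b <- f_test(c(4, 3, 2, 1), c(8, 6, 4, 2))
  expect_identical(ft_a$p, ft_b$p)
  # a flat objective ties every parameter at p = 1 exactly; the earlier
  # spec entry must win
  r <- run_iteration(specs, function(p) 1, 50, seed = 1)
  expect_identical(r$record$fixed_parameter, "a")
  expect_identical(r$record$stats$p, c(1, 1))
})

test_that("calibrate recovers a separable convex quadratic within 1%", {
  truth <- c(a = 2, b = -1, c = 0.5)
  obj <- function(p) {
    (p[["a"]] - 2)^2 + 2 * (p[["b"]] + 1)^2 + 0.5 * (p[["c"]] - 0.5)^2
  }
  specs <- list(parameter_spec("a", -5, 5), parameter_spec("b", -5, 5),
                parameter_spec("c", -5, 5))
  ok <- 0L
  for (s in 1:20) {
    cr <- calibrate(obj, specs, m = 200, seed = s)
    if (all(abs(cr$polished_point - truth) <= 0.01 * abs(truth))) ok <- ok + 1L
    expect_length(cr$fixing_order, 3)
    expect_setequal(cr$fixing_order, c("a", "b", "c"))
    expect_true(all(cr$polished_point >= -5 & cr$polished_point <= 5))
    expect_lte(cr$final_objective,
               min(vapply(cr$iterations, function(r) r$best_objective,
                          numeric(1))) + 1e-12)
  }
  expect_gte(ok, 19L)
})

test_that("single-parameter calibration degenerates to burn-in + one fix + polish", {
  obj <- function(p) (p[["x"]] - 0.3)^2
  cr <- calibrate(obj, list(parameter_spec("x", 0, 1)), m = 50, seed = 2)
  expect_length(cr$iterations, 2)    # burn-in + 1
  expect_identical(cr$fixing_order, "x")
  expect_equal(unname(cr$polished_point), 0.3, tolerance = 1e-3)
})

test_that("polish respects bounds and never worsens the objective", {
  # stationary start: stays put
  q <- function(p) sum((p - c(x = 1, y = 2))^2)
  at_min <- polish(q, c(x = 1, y = 2), c(0, 0), c(5, 5))
  expect_equal(unname(at_min$par), c(1, 2), tolerance = 1e-4)

  # minimum outside bounds: projection onto the active constraint
  q2 <- function(p) (p[["x"]] - 10)^2 + (p[["y"]] + 3)^2
  kkt <- polish(q2, c(x = 2, y = 2), c(0, 0), c(5, 5))
  expect_equal(unname(kkt$par), c(5, 0), tolerance = 1e-5)

  # monotone decreasing objective on [0, 1]: boundary optimum
  mono <- polish(function(p) 1 - p[["x"]], c(x = 0.4), 0, 1)
  expect_equal(unname(mono$par), 1, tolerance = 1e-6)

  expect_error(polish(function(p) NaN, c(x = 0.5), 0, 1), "not finite")
})

test_that("calibration is bitwise reproducible for identical seeds", {
  obj <- function(p) (p[["a"]] - 2)^2 + (p[["b"]] + 1)^2
  specs <- list(parameter_spec("a", -5, 5), parameter_spec("b", -5, 5))
  c1 <- calibrate(obj, specs, m = 60, seed = 42)
  c2 <- calibrate(obj, specs, m = 60, seed = 42)
  expect_identical(c1, c2)
  c3 <- calibrate(obj, specs, m = 60, seed = 43)
  expect_false(identical(c1$iterations$burn_in$samples,
                         c3$iterations$burn_in$samples))
})

test_that("best objective is nonincreasing across iterations on smooth objectives", {
  obj <- function(p) (p[["a"]] - 1)^2 + (p[["b"]] - 2)^2 + (p[["c"]] + 3)^2
  specs <- list(parameter_spec("a", -5, 5), parameter_spec("b", -5, 5),
                parameter_spec("c", -5, 5))
  n_monotone <- 0L
  for (s in 1:20) {
    cr <- calibrate(obj, specs, m = 100, seed = s)
    bests <- vapply(cr$iterations, function(r) r$best_objective, numeric(1))
    if (all(diff(bests) <= 1e-12)) n_monotone <- n_monotone + 1L
  }
  expect_gte(n_monotone / 20, 0.95)
})

test_that("objective failures discard samples and too many failures error", {
  specs <- list(parameter_spec("a", 0, 1))
  flaky <- function(p) if (p[["a"]] > 0.5) stop("boom") else p[["a"]]^2
  r <- run_iteration(specs, flaky, 50, seed = 8)
  expect_gt(r$record$n_failed, 0)
  expect_lt(nrow(r$record$samples), 50)
  always_bad <- function(p) stop("no")
  expect_error(run_iteration(specs, always_bad, 10, seed = 1), "fewer than 3")
})
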