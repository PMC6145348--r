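#' Parameter specification for the stochastic search
#'
#' @param name Parameter name.
#' @param lower,upper Literature-derived bounds (lower < upper).
#' @param center Initial Gaussian mean; defaults to the bound midpoint.
#' @param sigma Initial Gaussian s.d.; defaults to a quarter of the width.
#' @param sigma_floor_frac Minimum sigma as a fraction of the bound width
#'   (default 0.02), preventing degenerate sampling when centers stall.
#' @return An object of class `parameter_spec`.
#' @export
parameter_spec <- function(name, lower, upper, center = NULL, sigma = NULL,
                           sigma_floor_frac = 0.02) {
  stopifnot(is.character(name), length(name) == 1L, lower < upper)
  width <- upper - lower
  center <- center %||% (lower + width / 2)
  sigma <- sigma %||% (width / 4)
  stopifnot(center >= lower, center <= upper, sigma > 0)
  structure(
    list(name = name, lower = lower, upper = upper, center = center,
         sigma = max(sigma, sigma_floor_frac * width),
         sigma_floor = sigma_floor_frac * width,
         fixed = FALSE, fixed_value = NA_real_),
    class = "parameter_spec"
  )
}

.spec_names <- function(specs) vapply(specs, function(s) s$name, character(1))

#' Read parameter specs from a TSV file
#'
#' Columns: `name`, `lower`, `upper`, optional `center`, `sigma`.
#'
#' @param path TSV file.
#' @return List of [parameter_spec()].
#' @export
read_parameter_specs <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    parameter_spec(df$name[i], df$lower[i], df$upper[i],
                   center = if ("center" %in% names(df)) df$center[i] else NULL,
                   sigma = if ("sigma" %in% names(df)) df$sigma[i] else NULL)
  })
}

# One truncated-normal draw vector by rejection resampling (no atoms at the
# bounds, unlike clipping).
.rtruncnorm <- function(m, center, sigma, lower, upper) {
  out <- numeric(m)
  todo <- seq_len(m)
  while (length(todo)) {
    cand <- stats::rnorm(length(todo), center, sigma)
    ok <- cand >= lower & cand <= upper
    out[todo[ok]] <- cand[ok]
    todo <- todo[!ok]
  }
  out
}

#' Sample a parameter matrix
#'
#' Unfixed parameters are drawn from truncated Gaussians (rejection
#' resampling inside the bounds); fixed parameters are replicated at their
#' fixed value. Deterministic given the seed.
#'
#' @param specs List of [parameter_spec()].
#' @param m Number of samples (>= 3).
#' @param seed Integer RNG seed.
#' @return m x p numeric matrix with parameter names as columns.
#' @export
sample_parameters <- function(specs, m, seed) {
  stopifnot(m >= 3)
  set.seed(seed)
  cols <- lapply(specs, function(s) {
    if (s$fixed) rep(s$fixed_value, m)
    else .rtruncnorm(m, s$center, s$sigma, s$lower, s$upper)
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- .spec_names(specs)
  mat
}

#' Univariate F test of objective sensitivity
#'
#' Regresses the fit metric on one parameter's sampled values and returns
#' the regression F statistic, F = (m - 2) R^2 / (1 - R^2) on (1, m - 2)
#' degrees of freedom, with its p value. A flat response gives F = 0, p = 1.
#'
#' @param values Sampled parameter values (length m >= 3, not all equal).
#' @param objectives Corresponding fit-metric values.
#' @return List with `F`, `p`, `slope`, `r_squared`.
#' @export
f_test <- function(values, objectives) {
  m <- length(values)
  stopifnot(m >= 3, length(objectives) == m)
  if (stats::var(values) == 0) stop("parameter values have zero variance")
  if (stats::var(objectives) == 0) {
    return(list(F = 0, p = 1, slope = 0, r_squared = 0))
  }
  slope <- stats::cov(values, objectives) / stats::var(values)
  r2 <- stats::cor(values, objectives)^2
  Fst <- if (r2 >= 1) Inf else (m - 2) * r2 / (1 - r2)
  p <- stats::pf(Fst, 1, m - 2, lower.tail = FALSE)
  list(F = Fst, p = p, slope = slope, r_squared = r2)
}

#' One iteration of the sequential stochastic search
#'
#' Draws `m` parameter vectors, evaluates the objective for each, and runs
#' the per-parameter F test. Unless this is the burn-in iteration, the
#' parameter with the lowest p value (ties broken by spec order) is fixed at
#' its value in the best (lowest-objective) sample. The Gaussian centers of
#' the remaining parameters are re-set by the regression rule
#' `center' = center - lambda * sigma^2 * slope / sd(objectives)` (clipped to
#' the bounds) and each new sigma is `max(|center' - center|, sigma_floor)`,
#' so the distance moved shapes the next Gaussian.
#'
#' @param specs List of [parameter_spec()]; at least one unfixed.
#' @param objective_fn Function taking a named parameter vector, returning a
#'   finite scalar (failures/NAs discard the sample).
#' @param m Samples per iteration.
#' @param seed Integer seed.
#' @param burn_in If `TRUE`, centers are updated but nothing is fixed.
#' @param lambda Re-centering step scale (default 1).
#' @param incumbent Optional named vector: the best configuration found so
#'   far, re-evaluated as the last of the `m` samples (elitism). With a
#'   deterministic objective this makes the per-iteration best objective
#'   nonincreasing.
#' @return List: updated `specs` plus an `iteration_record`.
#' @export
run_iteration <- function(specs, objective_fn, m, seed, burn_in = FALSE,
                          lambda = 1, incumbent = NULL) {
  nms <- .spec_names(specs)
  unfixed <- which(!vapply(specs, function(s) s$fixed, logical(1)))
  if (!length(unfixed)) stop("all parameters are already fixed")
  samples <- sample_parameters(specs, m, seed)
  if (!is.null(incumbent)) {
    # fixed parameters keep their fixed value even in the incumbent row
    for (j in unfixed) samples[m, j] <- incumbent[[nms[j]]]
  }
  objectives <- vapply(seq_len(m), function(i) {
    v <- tryCatch(objective_fn(samples[i, ]), error = function(e) NA_real_)
    if (!is.finite(v)) NA_real_ else v
  }, numeric(1))
  ok <- !is.na(objectives)
  n_failed <- sum(!ok)
  if (sum(ok) < 3) stop("fewer than 3 valid objective evaluations in iteration")
  samples_ok <- samples[ok, , drop = FALSE]
  obj_ok <- objectives[ok]

  stats_df <- data.frame(name = nms, slope = NA_real_, F = NA_real_,
                         p = NA_real_)
  for (j in unfixed) {
    ft <- f_test(samples_ok[, j], obj_ok)
    stats_df$slope[j] <- ft$slope
    stats_df$F[j] <- ft$F
    stats_df$p[j] <- ft$p
  }

  best <- which.min(obj_ok)
  fixed_parameter <- NA_character_
  fixed_value <- NA_real_
  if (!burn_in) {
    # lowest p, ties broken by spec order (which.min returns the first)
    j_fix <- unfixed[which.min(stats_df$p[unfixed])]
    fixed_parameter <- nms[j_fix]
    fixed_value <- samples_ok[best, j_fix]
    specs[[j_fix]]$fixed <- TRUE
    specs[[j_fix]]$fixed_value <- fixed_value
    specs[[j_fix]]$center <- fixed_value
  }

  sd_obj <- stats::sd(obj_ok)
  for (j in unfixed) {
    if (specs[[j]]$fixed) next
    s <- specs[[j]]
    step <- if (sd_obj > 0) lambda * s$sigma^2 * stats_df$slope[j] / sd_obj else 0
    new_center <- min(max(s$center - step, s$lower), s$upper)
    new_sigma <- max(abs(new_center - s$center), s$sigma_floor)
    specs[[j]]$center <- new_center
    specs[[j]]$sigma <- new_sigma
  }

  record <- structure(
    list(samples = samples_ok, objectives = obj_ok, stats = stats_df,
         fixed_parameter = fixed_parameter, fixed_value = fixed_value,
         best_objective = min(obj_ok), burn_in = burn_in,
         n_failed = n_failed,
         new_centers = stats::setNames(vapply(specs, function(s) s$center, numeric(1)), nms),
         new_sigmas = stats::setNames(vapply(specs, function(s) s$sigma, numeric(1)), nms)),
    class = "iteration_record"
  )
  list(specs = specs, record = record)
}

#' Bounded quasi-Newton polish
#'
#' Local refinement with the limited-memory bounded quasi-Newton method
#' (`stats::optim(method = "L-BFGS-B")`), numerical gradients with step
#' `ndeps_frac` of each bound width. The default step, 1e-3 of the width, is
#' deliberately coarse: the objective is itself computed by an ODE solver,
#' and differences over much smaller steps drown in solver error. Never
#' returns a point worse than the start.
#'
#' @param objective_fn Function of a named parameter vector.
#' @param start Named start vector within bounds.
#' @param lower,upper Bound vectors.
#' @param ndeps_frac Finite-difference step as a fraction of the bound width.
#' @param maxit Iteration cap for the quasi-Newton descent.
#' @param factr Convergence tolerance factor (see [stats::optim()]).
#' @param transform Coordinate parameterization for the descent:
#'   `"identity"` or `"log"`. Rate constants act multiplicatively on the
#'   model, so descending in log coordinates follows their natural geometry;
#'   requires strictly positive bounds.
#' @return List with `par` (named) and `objective`, on the original scale.
#' @export
polish <- function(objective_fn, start, lower, upper, ndeps_frac = 1e-3,
                   maxit = 100, factr = 1e5,
                   transform = c("identity", "log")) {
  transform <- match.arg(transform)
  f0 <- objective_fn(start)
  if (!is.finite(f0)) stop("objective is not finite at the start point")
  nms <- names(start)
  if (transform == "log") {
    stopifnot(all(lower > 0), all(start > 0))
    fwd <- log; bwd <- exp
  } else {
    fwd <- identity; bwd <- identity
  }
  lo <- fwd(lower); up <- fwd(upper)
  wrapped <- function(x) {
    v <- tryCatch(objective_fn(stats::setNames(bwd(x), nms)),
                  error = function(e) Inf)
    if (!is.finite(v)) .Machine$double.xmax else v
  }
  res <- tryCatch(
    stats::optim(par = fwd(start), fn = wrapped, method = "L-BFGS-B",
                 lower = lo, upper = up,
                 control = list(ndeps = pmax(ndeps_frac * (up - lo), 1e-12),
                                factr = factr, maxit = maxit)),
    error = function(e) list(par = fwd(start), value = f0)
  )
  if (res$value <= f0) {
    list(par = stats::setNames(pmin(pmax(bwd(res$par), lower), upper), nms),
         objective = res$value)
  } else {
    list(par = start, objective = f0)
  }
}

#' Full sequential stochastic calibration
#'
#' One burn-in iteration (centers updated, nothing fixed), then one
#' iteration per parameter, each fixing the most sensitive remaining
#' parameter at its best-fitting value, followed by a bounded quasi-Newton
#' polish started at the converged point. Fully reproducible given the seed.
#'
#' @param objective_fn Function of a named parameter vector returning the fit
#'   metric (lower is better).
#' @param specs List of [parameter_spec()].
#' @param m Samples per iteration (default 200; the algorithm is typically
#'   run with 100-1000).
#' @param seed Integer seed; per-iteration seeds are derived from it.
#' @param lambda Re-centering step scale.
#' @param log_file Optional TSV path; one row per iteration is appended.
#' @param polish_control List of overrides for the [polish()] stage
#'   (`ndeps_frac`, `maxit`, `factr`).
#' @return An object of class `calibration_result`: `iterations`,
#'   `fixing_order`, `converged_point`, `polished_point`, `final_objective`,
#'   `burn_in_median`.
#' @export
calibrate <- function(objective_fn, specs, m = 200, seed = 1, lambda = 1,
                      log_file = NULL, polish_control = list()) {
  stopifnot(length(specs) >= 1)
  nms <- .spec_names(specs)
  iterations <- list()
  it_seed <- function(i) (seed * 1000L + i) %% .Machine$integer.max

  res <- run_iteration(specs, objective_fn, m, it_seed(0L), burn_in = TRUE,
                       lambda = lambda)
  specs <- res$specs
  iterations[["burn_in"]] <- res$record
  burn_in_median <- stats::median(res$record$objectives)
  best_row <- which.min(res$record$objectives)
  incumbent <- res$record$samples[best_row, ]

  i <- 1L
  while (any(!vapply(specs, function(s) s$fixed, logical(1)))) {
    res <- run_iteration(specs, objective_fn, m, it_seed(i), burn_in = FALSE,
                         lambda = lambda, incumbent = incumbent)
    specs <- res$specs
    iterations[[sprintf("iter_%02d", i)]] <- res$record
    best_row <- which.min(res$record$objectives)
    incumbent <- res$record$samples[best_row, ]
    i <- i + 1L
  }

  fixing_order <- vapply(iterations[-1L], function(r) r$fixed_parameter, character(1))
  converged <- stats::setNames(
    vapply(specs, function(s) s$fixed_value, numeric(1)), nms)
  lower <- vapply(specs, function(s) s$lower, numeric(1))
  upper <- vapply(specs, function(s) s$upper, numeric(1))
  # two descent passes: restarting L-BFGS-B at its own output recovers
  # progress after line-search stalls on the piecewise-linear MAE surface
  pargs <- utils::modifyList(list(objective_fn = objective_fn,
                                  lower = lower, upper = upper),
                             polish_control)
  pol <- do.call(polish, c(pargs, list(start = converged)))
  pol <- do.call(polish, c(pargs, list(start = pol$par)))

  if (!is.null(log_file)) {
    log_df <- data.frame(
      iteration = names(iterations),
      fixed_parameter = vapply(iterations, function(r)
        ifelse(is.na(r$fixed_parameter), "", r$fixed_parameter), character(1)),
      min_p = vapply(iterations, function(r) min(r$stats$p, na.rm = TRUE), numeric(1)),
      best_objective = vapply(iterations, function(r) r$best_objective, numeric(1))
    )
    utils::write.table(log_df, log_file, sep = "\t", row.names = FALSE, quote = FALSE)
  }

  structure(
    list(iterations = iterations, fixing_order = unname(fixing_order),
         converged_point = converged, polished_point = pol$par,
         final_objective = pol$objective, burn_in_median = burn_in_median),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  cat("  fixing order:", paste(x$fixing_order, collapse = " -> "), "\n")
  cat(sprintf("  final objective: %.6g\n", x$final_objective))
  print(round(x$polished_point, 6))
  invisible(x)
}
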