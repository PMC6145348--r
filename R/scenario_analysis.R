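#' Process-knockout comparison
#'
#' Runs the scenario twice -- with the full network and with the listed
#' processes' rate constants set to zero, all other parameters unchanged --
#' and reports, per species, the concentration summed over all depths and
#' saved times and its percent change relative to the baseline.
#'
#' @param scenario List with elements `grid` ([lake_grid()]), `initial`
#'   ([model_state()] built against `network`), `t_end`, `save_every`,
#'   optional `tolerance`.
#' @param network A [reaction_network()].
#' @param process_labels Processes to knock out (may be empty: identity).
#' @return An object of class `knockout_report`: data frame with `species`,
#'   `total_with`, `total_without`, `percent_change` (NA where the baseline
#'   total is 0), plus both `simulation_result`s.
#' @export
knockout_compare <- function(scenario, network, process_labels) {
  run <- function(net) {
    initial <- scenario$initial
    if (!identical(rownames(initial$conc), names(net$species))) {
      stop("scenario initial state does not match the network")
    }
    integrate_lake(scenario$grid, net, initial, scenario$t_end,
                   save_every = scenario$save_every %||% 7,
                   tolerance = scenario$tolerance %||% 1e-6)
  }
  base <- run(network)
  ko <- run(knockout(network, process_labels))
  spn <- names(network$species)
  tw <- vapply(spn, function(s) column_total(base, s), numeric(1))
  to <- vapply(spn, function(s) column_total(ko, s), numeric(1))
  pc <- ifelse(tw > 0, 100 * (to - tw) / tw, NA_real_)
  structure(
    list(table = data.frame(species = spn, total_with = tw,
                            total_without = to, percent_change = pc,
                            row.names = NULL),
         baseline = base, knocked_out = ko,
         process_labels = process_labels),
    class = "knockout_report"
  )
}

#' @export
print.knockout_report <- function(x, ...) {
  cat("<knockout_report> processes removed:",
      paste(x$process_labels, collapse = ", "), "\n")
  print(transform(x$table, percent_change = round(percent_change, 1)))
  invisible(x)
}

#' Parameter sweep of the knockout impact
#'
#' For each of `n` parameter draws, uniform within the given bounds (or
#' Gaussian around the parameter centers with `sampling = "gaussian"`), runs
#' [knockout_compare()] and aggregates the per-species percent changes.
#' Individual simulation failures are logged and excluded; more than 10%
#' failures is an error. Deterministic given the seed.
#'
#' @param scenario As in [knockout_compare()].
#' @param network Base network; swept parameters are rate constants named by
#'   process label.
#' @param specs List of [parameter_spec()] whose names are process labels.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param process_labels Processes knocked out in every draw.
#' @param sampling `"uniform"` (default) or `"gaussian"`.
#' @return An object of class `sweep_report`: `n_samples`, `seed`, `draws`
#'   (matrix), `percent_change` (species x draw matrix) and `summary`
#'   (per-species mean/min/max).
#' @export
parameter_sweep <- function(scenario, network, specs, n, seed,
                            process_labels, sampling = c("uniform", "gaussian")) {
  sampling <- match.arg(sampling)
  stopifnot(n >= 1)
  set.seed(seed)
  nms <- .spec_names(specs)
  draws <- sapply(specs, function(s) {
    if (sampling == "uniform") stats::runif(n, s$lower, s$upper)
    else .rtruncnorm(n, s$center, s$sigma, s$lower, s$upper)
  })
  draws <- matrix(draws, nrow = n, dimnames = list(NULL, nms))
  spn <- names(network$species)
  pc <- matrix(NA_real_, nrow = length(spn), ncol = n,
               dimnames = list(spn, NULL))
  failed <- logical(n)
  for (i in seq_len(n)) {
    kin <- lapply(seq_along(nms), function(j) list(k = draws[i, j]))
    names(kin) <- nms
    net_i <- default_network_like(network, kin)
    rep_i <- tryCatch(knockout_compare(scenario, net_i, process_labels),
                      error = function(e) NULL)
    if (is.null(rep_i)) {
      failed[i] <- TRUE
    } else {
      pc[, i] <- rep_i$table$percent_change
    }
  }
  if (mean(failed) > 0.10) {
    stop(sprintf("%d/%d sweep simulations failed", sum(failed), n))
  }
  ok <- !failed
  summ <- data.frame(
    species = spn,
    mean = apply(pc[, ok, drop = FALSE], 1, mean, na.rm = TRUE),
    min = apply(pc[, ok, drop = FALSE], 1, function(v) if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)),
    max = apply(pc[, ok, drop = FALSE], 1, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)),
    row.names = NULL
  )
  structure(
    list(n_samples = n, seed = seed, draws = draws, percent_change = pc,
         n_failed = sum(failed), summary = summ,
         process_labels = process_labels),
    class = "sweep_report"
  )
}

# Rebuild a network with rate-constant overrides keyed by process label,
# keeping every other rate-law field and all stoichiometries.
#' Override rate constants of a network
#'
#' @param network A [reaction_network()].
#' @param kinetics Named list: process label -> list of rate-law overrides
#'   (typically `list(k = value)`).
#' @return The modified network.
#' @export
default_network_like <- function(network, kinetics) {
  labels <- process_labels(network)
  for (nm in names(kinetics)) {
    hit <- which(labels == nm)
    if (!length(hit)) stop("unknown process label: ", nm)
    for (i in hit) {
      network$reactions[[i]]$rate_law <-
        do.call(rate_law, utils::modifyList(
          unclass(network$reactions[[i]]$rate_law), kinetics[[nm]]))
    }
  }
  network
}

#' @export
print.sweep_report <- function(x, ...) {
  cat(sprintf("<sweep_report> n = %d (failed %d), seed = %d\n",
              x$n_samples, x$n_failed, x$seed))
  print(transform(x$summary, mean = round(mean, 1), min = round(min, 1),
                  max = round(max, 1)))
  invisible(x)
}
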