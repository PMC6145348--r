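#' Vertical lake grid
#'
#' A uniform 1D finite-volume grid for the water column, depth increasing
#' downward, cell centers at (i - 1/2) dz. Diffusivity is specified at cell
#' interfaces; the default is a two-layer profile (well-mixed epilimnion over
#' a weakly mixed hypolimnion) with a smooth thermocline transition.
#'
#' @param n_cells Number of cells (default 23).
#' @param dz Cell thickness in m (default 1).
#' @param diffusivity Either a numeric vector of length `n_cells + 1` giving
#'   D (m^2/day) at interfaces 0..n_cells (interface 1 is the lake surface),
#'   or `NULL` to build the two-layer default.
#' @param thermocline_depth Depth of the thermocline in m (default 8).
#' @param D_epi,D_hypo Epilimnion / hypolimnion diffusivities (m^2/day).
#' @param surface_bc Named list; each entry either
#'   `list(type = "dirichlet", value = uM)` or `list(type = "zero_flux")`.
#'   Species without an entry default to zero flux.
#' @param bottom_bc Named list; each entry `list(type = "influx", value =
#'   uM m/day)` or `list(type = "zero_flux")`.
#' @return An object of class `lake_grid`.
#' @export
lake_grid <- function(n_cells = 23L, dz = 1, diffusivity = NULL,
                      thermocline_depth = 8, D_epi = 10, D_hypo = 0.02,
                      surface_bc = list(), bottom_bc = list()) {
  stopifnot(n_cells >= 2L, dz > 0)
  depths <- (seq_len(n_cells) - 0.5) * dz
  if (is.null(diffusivity)) {
    iface <- seq(0L, n_cells) * dz
    diffusivity <- D_hypo + (D_epi - D_hypo) / (1 + exp((iface - thermocline_depth) / 0.5))
  }
  stopifnot(length(diffusivity) == n_cells + 1L, all(diffusivity >= 0))
  structure(
    list(n_cells = as.integer(n_cells), dz = dz, depths = depths,
         diffusivity = diffusivity, surface_bc = surface_bc,
         bottom_bc = bottom_bc),
    class = "lake_grid"
  )
}

#' Initial model state
#'
#' @param grid A [lake_grid()].
#' @param network A [reaction_network()].
#' @param profiles Named list: for each species either a single value
#'   (uniform), a vector of length `n_cells`, or a two-column matrix /
#'   data.frame of (depth, value) pairs interpolated linearly to cell
#'   centers (constant extrapolation beyond the given depths). Species not
#'   listed start at 0.
#' @param time Start time in days (default 0).
#' @return An object of class `model_state`: a species x cell matrix plus time.
#' @export
model_state <- function(grid, network, profiles = list(), time = 0) {
  spn <- names(network$species)
  conc <- matrix(0, nrow = length(spn), ncol = grid$n_cells,
                 dimnames = list(spn, NULL))
  for (nm in names(profiles)) {
    if (!nm %in% spn) stop("unknown species in initial profiles: ", nm)
    p <- profiles[[nm]]
    if (is.matrix(p) || is.data.frame(p)) {
      p <- as.matrix(p)
      conc[nm, ] <- stats::approx(p[, 1], p[, 2], xout = grid$depths,
                                  rule = 2)$y
    } else if (length(p) == 1L) {
      conc[nm, ] <- p
    } else if (length(p) == grid$n_cells) {
      conc[nm, ] <- p
    } else {
      stop("initial profile for ", nm, " has wrong length")
    }
  }
  clip_ok <- !vapply(network$species, function(s) s$balance_only, logical(1))
  if (any(conc[clip_ok, ] < 0)) stop("initial concentrations must be nonnegative")
  structure(list(time = time, conc = conc), class = "model_state")
}

# Stage the flattened model tables into the compiled kernel. State vector
# is cell-major (all species of cell 1, then cell 2, ...) so the Jacobian
# is banded with bandwidth n_species.
.stage_model <- function(grid, network) {
  spn <- names(network$species)
  n_sp <- length(spn)
  n <- grid$n_cells
  dz <- grid$dz
  D <- grid$diffusivity
  mobile <- vapply(network$species, function(s) s$mobile, logical(1))

  # per-species boundary tables, resolved once
  bc_code <- function(bc, kind) {
    type <- integer(n_sp); value <- numeric(n_sp)
    for (i in seq_len(n_sp)) {
      b <- bc[[spn[i]]]
      if (!is.null(b) && identical(b$type, kind)) {
        type[i] <- 1L
        value[i] <- b$value
      }
    }
    list(type = type, value = value)
  }
  surf <- bc_code(grid$surface_bc, "dirichlet")
  bott <- bc_code(grid$bottom_bc, "influx")

  Din <- D[2:n]           # interior interfaces between cells i and i+1
  D0 <- D[1L]             # surface

  # flattened reaction tables (0-based indices for the kernel)
  rx <- unname(network$reactions)
  rl <- lapply(rx, `[[`, "rate_law")
  sp0 <- function(nm) if (is.na(nm)) -1L else match(nm, spn) - 1L
  k_vec <- vapply(rl, `[[`, numeric(1), "k")
  fo <- vapply(rl, `[[`, logical(1), "first_order")
  don <- vapply(rl, function(x) sp0(x$donor), integer(1))
  acc <- vapply(rl, function(x) sp0(x$acceptor), integer(1))
  inh <- vapply(rl, function(x) sp0(x$inhibitor), integer(1))
  num_or <- function(x) if (is.na(x)) 0 else as.numeric(x)
  Kd <- vapply(rl, function(x) num_or(x$K_donor), numeric(1))
  Ka <- vapply(rl, function(x) num_or(x$K_acceptor), numeric(1))
  Ki <- vapply(rl, function(x) num_or(x$K_inhibit), numeric(1))
  st_len <- vapply(rx, function(r) length(r$stoich), integer(1))
  st_off <- c(0L, cumsum(st_len))
  st_sp <- unlist(lapply(rx, function(r) match(names(r$stoich), spn) - 1L),
                  use.names = FALSE)
  st_nu <- unlist(lapply(rx, function(r) unname(r$stoich)), use.names = FALSE)
  if (is.null(st_sp)) { st_sp <- integer(0); st_nu <- numeric(0) }

  .lake_set_params(n_sp, n, dz, D0, Din, as.integer(mobile),
                   surf$type, surf$value, bott$type, bott$value,
                   k_vec, as.integer(fo), don, Kd, acc, Ka, inh, Ki,
                   as.integer(st_off), st_sp, st_nu)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Integrate the 1D lake model
#'
#' Method-of-lines solution of
#' \deqn{\partial_t C_s = \partial_z (D(z) \partial_z C_s) + \sum_r \nu_{s,r} R_r(C)}
#' with the grid's boundary conditions, using a stiff ODE integrator
#' (`deSolve::lsoda`, banded Jacobian). Concentrations are clipped at zero
#' in the saved output, with the clipped mass recorded in the conservation
#' ledger; per-process rate fields are evaluated at every saved time.
#'
#' @param grid A [lake_grid()].
#' @param network A [reaction_network()].
#' @param initial A [model_state()].
#' @param t_end End time (days).
#' @param save_every Output interval (days).
#' @param tolerance Relative solver tolerance (default 1e-6); the absolute
#'   tolerance is `tolerance` uM.
#' @return An object of class `simulation_result` with elements `times`
#'   (days), `conc` (species x cell x time array, uM), `rates` (process x
#'   cell x time array, uM/year), `grid`, `network`, and `ledger` (element
#'   totals and clipped mass per saved time).
#' @export
integrate_lake <- function(grid, network, initial, t_end, save_every = 7,
                           tolerance = 1e-6) {
  stopifnot(inherits(grid, "lake_grid"), inherits(network, "reaction_network"),
            inherits(initial, "model_state"), t_end > initial$time)
  spn <- names(network$species)
  if (!identical(rownames(initial$conc), spn)) {
    stop("initial state species do not match the network")
  }
  n_sp <- length(spn)
  times <- seq(initial$time, t_end, by = save_every)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  .stage_model(grid, network)
  out <- deSolve::lsoda(
    y = as.vector(initial$conc), times = times,
    func = "lake_derivs", dllname = "lakeredox", initfunc = NULL,
    parms = NULL, rtol = tolerance, atol = tolerance,
    jactype = "bandint", bandup = n_sp, banddown = n_sp,
    maxsteps = 100000
  )
  if (attr(out, "istate")[1] < 0) {
    stop(sprintf("solver failed to converge; last valid time %.3f days",
                 max(out[, 1], na.rm = TRUE)))
  }
  n_t <- nrow(out)
  conc <- array(t(out[, -1, drop = FALSE]),
                dim = c(n_sp, grid$n_cells, n_t),
                dimnames = list(spn, NULL, NULL))
  # clip transient negative excursions (order solver tolerance) to zero,
  # logging the clipped mass; balance-only species (H+, H2O) are exempt
  clip_ok <- !vapply(network$species, function(s) s$balance_only, logical(1))
  clipped <- apply(conc[clip_ok, , , drop = FALSE], 3,
                   function(m) -sum(m[m < 0]) * grid$dz)
  neg <- conc < 0
  neg[!clip_ok, , ] <- FALSE
  conc[neg] <- 0

  labels <- process_labels(network)
  rates <- array(0, dim = c(length(labels), grid$n_cells, n_t),
                 dimnames = list(labels, NULL, NULL))
  for (ti in seq_len(n_t)) {
    cl <- asplit(matrix(conc[, , ti], nrow = n_sp,
                        dimnames = list(spn, NULL)), 1)
    for (r in network$reactions) {
      rates[r$process_label, , ti] <- reaction_rate(r, cl)
    }
  }

  elems <- .element_universe(network$species)
  comp <- matrix(0, nrow = length(elems), ncol = n_sp,
                 dimnames = list(elems, spn))
  for (s in network$species) {
    for (e in names(s$elements)) comp[e, s$name] <- s$elements[[e]]
  }
  ledger <- data.frame(time = out[, 1])
  for (e in elems) {
    ledger[[e]] <- vapply(seq_len(n_t), function(ti) {
      sum(comp[e, ] * rowSums(conc[, , ti, drop = FALSE])) * grid$dz
    }, numeric(1))
  }
  ledger$clipped_mass <- clipped

  structure(
    list(times = out[, 1], conc = conc, rates = rates,
         grid = grid, network = network, ledger = ledger,
         tolerance = tolerance),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d species x %d cells x %d times (%.0f-%.0f d)\n",
              dim(x$conc)[1], dim(x$conc)[2], dim(x$conc)[3],
              min(x$times), max(x$times)))
  invisible(x)
}

#' Summed rate field over a set of processes
#'
#' @param result A `simulation_result`.
#' @param process_labels Character vector of process labels.
#' @return cell x time matrix of summed rates (uM/year).
#' @export
process_rate_profile <- function(result, process_labels) {
  unknown <- setdiff(process_labels, dimnames(result$rates)[[1]])
  if (length(unknown)) stop("unknown process label(s): ", paste(unknown, collapse = ", "))
  sub <- result$rates[process_labels, , , drop = FALSE]
  apply(sub, c(2, 3), sum)
}

#' Depth-and-time summed concentration
#'
#' Sums a species' concentration over the column (trapezoid in depth, i.e.
#' cell value times dz on the uniform grid) and over all saved times,
#' matching the "summed over all depths and time points" aggregation used by
#' the knockout comparison.
#'
#' @param result A `simulation_result`.
#' @param species Species name.
#' @return Scalar total (uM m, summed over saved times).
#' @export
column_total <- function(result, species) {
  if (!species %in% dimnames(result$conc)[[1]]) {
    stop("unknown species: ", species)
  }
  sum(result$conc[species, , ]) * result$grid$dz
}

#' Write per-species and per-process TSV fields
#'
#' One TSV per species (uM) and per process (uM/year): rows = depths,
#' columns = saved times; plus `run_log.tsv` with the conservation ledger.
#'
#' @param result A `simulation_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_simulation <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  tcols <- sprintf("t%g", result$times)
  for (sp in dimnames(result$conc)[[1]]) {
    df <- data.frame(depth_m = result$grid$depths, result$conc[sp, , ])
    names(df) <- c("depth_m", tcols)
    f <- file.path(dir, sprintf("conc_%s.tsv", sp))
    utils::write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  for (pl in dimnames(result$rates)[[1]]) {
    df <- data.frame(depth_m = result$grid$depths, result$rates[pl, , ])
    names(df) <- c("depth_m", tcols)
    f <- file.path(dir, sprintf("rate_%s.tsv", pl))
    utils::write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, "run_log.tsv")
  utils::write.table(result$ledger, f, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(files, f))
}
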