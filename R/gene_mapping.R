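#' Normalize a functional-gene depth profile
#'
#' Two-step normalization used for shotgun functional-gene abundances:
#' counts are first scaled to copies per million (CPM) within each sample,
#' then the per-gene profile is L1-normalized across samples so it sums to 1.
#' An all-zero gene yields an all-zero profile with a warning.
#'
#' @param counts Numeric vector of per-sample gene counts (>= 0).
#' @param library_sizes Per-sample total reads (> 0), same length.
#' @param gene_set Gene-set name carried in the result.
#' @param sample_depths Optional sampling depths (m) carried in the result.
#' @return An object of class `gene_profile` with fields `gene_set`,
#'   `sample_depths`, `values`, `normalization_state` (`"l1"`), `all_zero`.
#' @export
normalize_gene_profile <- function(counts, library_sizes,
                                   gene_set = "gene", sample_depths = NULL) {
  if (any(counts < 0)) stop("gene counts must be nonnegative")
  stopifnot(length(counts) == length(library_sizes), all(library_sizes > 0))
  cpm <- counts / library_sizes * 1e6
  tot <- sum(cpm)
  all_zero <- tot == 0
  if (all_zero) {
    warning("all-zero gene profile for '", gene_set, "'")
    vals <- cpm
  } else {
    vals <- cpm / tot
  }
  structure(
    list(gene_set = gene_set,
         sample_depths = sample_depths %||% seq_along(counts),
         values = vals, normalization_state = "l1", all_zero = all_zero),
    class = "gene_profile"
  )
}

#' Default gene-set to process map
#'
#' The six mappings between marker gene sets and modeled processes: pmoABC
#' covers ammonia oxidation plus methane oxidation with oxygen and with
#' sulfate (the monooxygenase is promiscuous); dsrAB covers sulfate
#' reduction and sulfide oxidation with every electron acceptor (the
#' reductase is bidirectional); nosDZ covers heterotrophic plus autotrophic
#' denitrification; mxaCGKL covers methane oxidation with oxygen and
#' sulfate; hoa covers nitrification; ironred covers heterotrophic iron
#' reduction.
#'
#' @return Named list mapping gene-set name to character vector of process labels.
#' @export
default_gene_process_map <- function() {
  list(
    pmoABC  = c("nitrification", "methane_ox_o2", "methane_ox_so4"),
    dsrAB   = c("sulfate_reduction", "sulfide_ox_o2", "sulfide_ox_no3"),
    nosDZ   = c("denitrification", "iron_ox_no3", "sulfide_ox_no3"),
    mxaCGKL = c("methane_ox_o2", "methane_ox_so4"),
    hoa     = c("nitrification"),
    ironred = c("iron_reduction")
  )
}

.interp_to_depths <- function(grid, field_col, depths) {
  if (any(depths < 0) || any(depths > grid$n_cells * grid$dz)) {
    stop("sample depth outside the model grid")
  }
  stats::approx(grid$depths, field_col, xout = depths, rule = 2)$y
}

.nearest_time_index <- function(times, t) which.min(abs(times - t))[1L]

#' Modeled proxy for a gene profile
#'
#' Under the proportionality assumption -- gene relative abundance tracks the
#' relative rate of the processes the gene mediates -- the modeled analogue
#' of a gene profile is the sum of the mapped process-rate fields,
#' interpolated to the sampling depths at the nearest saved time and
#' L1-normalized.
#'
#' @param result A `simulation_result`.
#' @param gpm Gene-process map (named list), e.g. [default_gene_process_map()].
#' @param gene_set Gene-set name present in `gpm`.
#' @param sample_depths Depths (m) to interpolate to.
#' @param sample_time Time (days); the nearest saved time is used.
#' @return A `gene_profile` with L1-normalized modeled values.
#' @export
modeled_gene_proxy <- function(result, gpm, gene_set, sample_depths,
                               sample_time) {
  if (!gene_set %in% names(gpm)) stop("gene set '", gene_set, "' not in map")
  fld <- process_rate_profile(result, gpm[[gene_set]])
  ti <- .nearest_time_index(result$times, sample_time)
  v <- .interp_to_depths(result$grid, fld[, ti], sample_depths)
  tot <- sum(v)
  all_zero <- tot == 0
  if (all_zero) {
    warning("all mapped process rates are zero for '", gene_set, "'")
  } else {
    v <- v / tot
  }
  structure(
    list(gene_set = gene_set, sample_depths = sample_depths, values = v,
         normalization_state = "l1", all_zero = all_zero),
    class = "gene_profile"
  )
}

#' Mean absolute error between two profiles
#'
#' @param observed,modeled Equal-length numeric vectors (or `gene_profile`
#'   objects), both L1-normalized.
#' @return Mean of the absolute differences; at most 1 for L1-normalized
#'   nonnegative profiles of length >= 2.
#' @export
mae <- function(observed, modeled) {
  if (inherits(observed, "gene_profile")) observed <- observed$values
  if (inherits(modeled, "gene_profile")) modeled <- modeled$values
  if (length(observed) != length(modeled)) {
    stop("profile length mismatch: ", length(observed), " vs ", length(modeled))
  }
  mean(abs(observed - modeled))
}

.l1 <- function(v) {
  tot <- sum(v)
  if (tot == 0) {
    warning("L1 normalization of an all-zero profile; left as zeros")
    return(v)
  }
  v / tot
}

#' Joint chemistry + gene fit objective
#'
#' Builds the calibration objective: one MAE per chemistry (species, time)
#' profile and one per gene set, averaged. Chemistry observations are
#' L1-normalized per profile before comparison (as are their modeled
#' counterparts) so that chemistry and gene observables share the \[0, 1\]
#' scale of relative profiles.
#'
#' @param result A `simulation_result`.
#' @param chem_obs Data frame with columns `observable` (species name),
#'   `time_day`, `depth_m`, `value` (uM, raw).
#' @param gene_obs List of `gene_profile` objects (L1-normalized), each with
#'   `sample_depths` set; optionally carrying a `sample_time` attribute
#'   (default: last saved time).
#' @param gpm Gene-process map.
#' @param weights Optional named weights per observable id; default equal.
#' @return An object of class `fit_objective` with `observables`
#'   (per-observable data frame incl. MAE) and `average_mae`.
#' @export
build_objective <- function(result, chem_obs, gene_obs, gpm = default_gene_process_map(),
                            weights = NULL) {
  rows <- list()
  if (!is.null(chem_obs) && nrow(chem_obs)) {
    need <- c("observable", "time_day", "depth_m", "value")
    if (!all(need %in% names(chem_obs))) {
      stop("chem_obs must have columns: ", paste(need, collapse = ", "))
    }
    spn <- dimnames(result$conc)[[1]]
    for (key in unique(paste(chem_obs$observable, chem_obs$time_day))) {
      sub <- chem_obs[paste(chem_obs$observable, chem_obs$time_day) == key, ]
      sp <- sub$observable[1L]
      if (!sp %in% spn) stop("missing observable in simulation: ", sp)
      ti <- .nearest_time_index(result$times, sub$time_day[1L])
      mod <- .interp_to_depths(result$grid, result$conc[sp, , ti], sub$depth_m)
      m <- mae(.l1(sub$value), .l1(mod))
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "chemistry", name = sp, time_day = sub$time_day[1L], mae = m)
    }
  }
  for (gp in gene_obs) {
    st <- attr(gp, "sample_time") %||% max(result$times)
    proxy <- modeled_gene_proxy(result, gpm, gp$gene_set, gp$sample_depths, st)
    m <- mae(gp, proxy)
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "gene", name = gp$gene_set, time_day = st, mae = m)
  }
  if (!length(rows)) stop("no observables supplied")
  obs <- do.call(rbind, rows)
  if (is.null(weights)) {
    avg <- mean(obs$mae)
  } else {
    w <- weights[obs$name]
    if (any(is.na(w))) stop("weights missing for: ",
                            paste(obs$name[is.na(w)], collapse = ", "))
    avg <- sum(w * obs$mae) / sum(w)
  }
  structure(list(observables = obs, average_mae = avg), class = "fit_objective")
}

#' @export
print.fit_objective <- function(x, ...) {
  cat(sprintf("<fit_objective> %d observables, average MAE = %.4f\n",
              nrow(x$observables), x$average_mae))
  invisible(x)
}
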