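# Seed-reproducible synthetic data with the statistical structure the
# analysis assumes: a known-truth lake scenario, noisy chemistry and gene
# observations, and community tables with planted OTU<->MAG matches.

#' Default lake scenario settings
#'
#' The stratified-column season emulated by the generators: a 23 m water
#' column at 1 m resolution, oxic surface boundary, sediment sources of
#' reduced species at the bottom, and a 140-day (late March to mid August)
#' simulation saved weekly.
#'
#' @return List with `grid`, `initial_profiles`, `t_end`, `save_every`.
#' @export
default_scenario_settings <- function() {
  grid <- lake_grid(
    surface_bc = list(
      O2 = list(type = "dirichlet", value = 300),
      CH4 = list(type = "dirichlet", value = 0),
      HS = list(type = "dirichlet", value = 0),
      NH4 = list(type = "dirichlet", value = 0)
    ),
    bottom_bc = list(
      CH4 = list(type = "influx", value = 25),
      NH4 = list(type = "influx", value = 8),
      Fe2 = list(type = "influx", value = 8),
      HS = list(type = "influx", value = 4),
      OM = list(type = "influx", value = 15)
    )
  )
  profiles <- list(
    O2 = cbind(c(0, 6, 10, 12, 23), c(300, 280, 30, 0, 0)),
    NO3 = cbind(c(0, 6, 10, 14, 23), c(10, 20, 40, 30, 5)),
    SO4 = 200,
    NH4 = cbind(c(0, 12, 23), c(0, 5, 40)),
    Fe2 = cbind(c(0, 12, 23), c(0, 5, 80)),
    Fe3 = cbind(c(0, 10, 23), c(1, 5, 20)),
    CH4 = cbind(c(0, 12, 23), c(0, 10, 300)),
    HS = cbind(c(0, 14, 23), c(0, 2, 20)),
    OM = cbind(c(0, 23), c(20, 50))
  )
  list(grid = grid, initial_profiles = profiles, t_end = 140, save_every = 7)
}

#' Calibration bounds for the default rate constants
#'
#' Factor-of-three bounds around the default maximum rates, standing in for
#' literature-derived limits.
#'
#' @param process_names Process labels to bound.
#' @return List of [parameter_spec()].
#' @export
default_rate_bounds <- function(process_names) {
  kin <- .default_kinetics()
  unknown <- setdiff(process_names, names(kin))
  if (length(unknown)) stop("unknown process: ", paste(unknown, collapse = ", "))
  lapply(process_names, function(nm) {
    k0 <- kin[[nm]]$k
    parameter_spec(nm, lower = k0 / 3, upper = k0 * 3)
  })
}

#' Generate a known-truth lake scenario
#'
#' Builds the default 23 m scenario with `n_free_params` rate constants
#' drawn log-uniformly inside their calibration bounds (the truth is
#' recorded), and runs the simulation over the season.
#'
#' @param seed Integer seed.
#' @param n_free_params Number of free rate constants (default 4, drawn for
#'   the processes in `free_processes`).
#' @param free_processes Which process rate constants are free. The default
#'   frees the four primary carbon-oxidation pathways, which compete for
#'   organic matter through distinct electron acceptors and marker genes and
#'   therefore stay identifiable across the whole bound range; secondary
#'   oxidation constants drawn near their lower bound contribute too little
#'   to any observable to be recoverable.
#' @param tolerance Solver tolerance passed to [integrate_lake()].
#' @return List: `truth` (named k vector, specs, seed), `scenario` (grid,
#'   initial, t_end, save_every, tolerance), `network` (at truth), `result`
#'   (the `simulation_result` at truth).
#' @export
make_scenario <- function(seed, n_free_params = 4,
                          free_processes = c("sulfate_reduction",
                                             "iron_reduction",
                                             "methanogenesis",
                                             "denitrification"),
                          tolerance = 1e-6) {
  stopifnot(n_free_params <= length(free_processes))
  free_processes <- free_processes[seq_len(n_free_params)]
  set.seed(seed)
  specs <- default_rate_bounds(free_processes)
  k_true <- vapply(specs, function(s) {
    exp(stats::runif(1, log(s$lower), log(s$upper)))
  }, numeric(1))
  names(k_true) <- free_processes
  kin <- lapply(k_true, function(k) list(k = k))
  network <- default_network(kin)
  st <- default_scenario_settings()
  initial <- model_state(st$grid, network, st$initial_profiles)
  scenario <- list(grid = st$grid, initial = initial, t_end = st$t_end,
                   save_every = st$save_every, tolerance = tolerance)
  result <- integrate_lake(st$grid, network, initial, st$t_end,
                           save_every = st$save_every, tolerance = tolerance)
  list(truth = list(k = k_true, specs = specs, seed = seed),
       scenario = scenario, network = network, result = result)
}

#' Noisy chemistry observations from a simulation
#'
#' Interpolates modeled concentrations to the sampling depths/times and
#' applies mean-preserving multiplicative lognormal noise.
#'
#' @param result A `simulation_result`.
#' @param depths Sampling depths (m); default 1 m to 21 m every 2 m.
#' @param times Sampling times (days); nearest saved times are used.
#' @param noise_sd Lognormal sigma (0 = exact model values).
#' @param seed Integer seed.
#' @param observables Species to observe.
#' @return Data frame: `sample_id`, `observable`, `time_day`, `depth_m`, `value`.
#' @export
make_observations <- function(result, depths = seq(1, 21, by = 2),
                              times = c(0, 45, 85, 115, 140),
                              noise_sd = 0.1, seed = 1,
                              observables = c("SO4", "O2", "NO3", "Fe2")) {
  set.seed(seed)
  rows <- list()
  for (sp in observables) {
    for (tt in times) {
      ti <- .nearest_time_index(result$times, tt)
      v <- .interp_to_depths(result$grid, result$conc[sp, , ti], depths)
      if (noise_sd > 0) {
        v <- v * exp(stats::rnorm(length(v), -noise_sd^2 / 2, noise_sd))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_t%g", sp, tt), observable = sp,
        time_day = tt, depth_m = depths, value = v)
    }
  }
  do.call(rbind, rows)
}

#' Noisy functional-gene tables from a simulation
#'
#' For each gene set of the map, the profile is the L1-normalized summed
#' rate of the mapped processes at the sampling depths, perturbed by
#' multiplicative lognormal noise and renormalized.
#'
#' @param result A `simulation_result`.
#' @param gpm Gene-process map (default [default_gene_process_map()]).
#' @param depths Sampling depths (m).
#' @param sample_time Sampling time (days); default the last saved time
#'   (the shotgun libraries come from the late-season sampling).
#' @param noise_sd Lognormal sigma (0 = noise-free proxy).
#' @param seed Integer seed.
#' @return Named list of `gene_profile` objects, each carrying a
#'   `sample_time` attribute.
#' @export
make_gene_tables <- function(result, gpm = default_gene_process_map(),
                             depths = seq(1, 21, by = 2),
                             sample_time = NULL, noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  sample_time <- sample_time %||% max(result$times)
  out <- lapply(names(gpm), function(gs) {
    gp <- modeled_gene_proxy(result, gpm, gs, depths, sample_time)
    if (noise_sd > 0 && !gp$all_zero) {
      v <- gp$values * exp(stats::rnorm(length(gp$values), 0, noise_sd))
      gp$values <- v / sum(v)
    }
    attr(gp, "sample_time") <- sample_time
    gp
  })
  names(out) <- names(gpm)
  out
}

# nested toy taxonomy: rank r name of lineage key is deterministic, so two
# features share a rank name iff they share the lineage down to that rank
.toy_path <- function(lineage) {
  c("Bacteria",
    sprintf("P%d", lineage[1]),
    sprintf("P%d;C%d", lineage[1], lineage[2]),
    sprintf("P%d;C%d;O%d", lineage[1], lineage[2], lineage[3]),
    sprintf("P%d;C%d;O%d;F%d", lineage[1], lineage[2], lineage[3], lineage[4]),
    sprintf("P%d;C%d;O%d;F%d;G%d", lineage[1], lineage[2], lineage[3],
            lineage[4], lineage[5]))
}

.lineage_widths <- c(10L, 6L, 6L, 8L, 10L)

.random_lineage <- function() vapply(.lineage_widths, sample, integer(1), size = 1)

#' Synthetic community with planted OTU-to-MAG matches
#'
#' Latent populations are depth-Gaussian bumps over the shared sample set.
#' Each planted population appears as an OTU row in both the amplicon table
#' (multinomial counts) and the metagenomic table (independent multinomial
#' counts at lower depth), and as a MAG of 3-10 contigs whose coverages
#' reproduce the latent profile under lognormal noise -- two different noise
#' channels mirroring the two library types. Extra OTUs have no MAG partner.
#' Planted OTU taxonomies match the full 6-rank MAG path, or only its first
#' 5 or 4 ranks; the control set contains the worst (4-rank) matches, so a
#' tolerance trained on controls covers all planted pairs.
#'
#' @param seed Integer seed.
#' @param n_populations Planted OTU/MAG pairs (default 12).
#' @param n_extra_otus OTUs without a MAG partner (default 50).
#' @param n_samples Shared samples (default 11).
#' @param noise_sd Lognormal coverage noise sigma (default 0.2).
#' @param n_controls Planted pairs flagged as known-correct controls
#'   (default 8; must be <= `n_populations`).
#' @return List: `amplicon`, `metagenomic` (OTU count matrices),
#'   `amplicon_reads`, `metagenomic_reads`, `contigs` (data frame),
#'   `mag_reads`, `otu_taxonomy`, `mag_taxonomy`, `planted` (data frame with
#'   `otu_id`, `mag_id`, `control`, `match_depth`), `seed`.
#' @export
make_community <- function(seed, n_populations = 12, n_extra_otus = 50,
                           n_samples = 11, noise_sd = 0.2, n_controls = 8) {
  stopifnot(n_controls <= n_populations, n_samples >= 2)
  set.seed(seed)
  depths <- seq(1, 21, length.out = n_samples)
  samples <- sprintf("s%02d", seq_len(n_samples))

  bump <- function(n) {
    ctr <- stats::runif(n, 0, 23)
    wid <- stats::runif(n, 2, 6)
    amp <- exp(stats::rnorm(n, 0, 0.8))
    t(vapply(seq_len(n), function(i) {
      amp[i] * (exp(-(depths - ctr[i])^2 / (2 * wid[i]^2)) + 0.02)
    }, numeric(length(depths))))
  }
  lat_pop <- bump(n_populations)
  lat_extra <- 0.5 * bump(n_extra_otus)

  otu_ids <- c(sprintf("otu_p%02d", seq_len(n_populations)),
               sprintf("otu_x%02d", seq_len(n_extra_otus)))
  mag_ids <- sprintf("bin_%02d", seq_len(n_populations))
  lat_all <- rbind(lat_pop, lat_extra)
  rownames(lat_all) <- otu_ids
  colnames(lat_all) <- samples

  draw_counts <- function(lib_size) {
    m <- sapply(seq_len(n_samples), function(j) {
      stats::rmultinom(1, lib_size, lat_all[, j])
    })
    dimnames(m) <- list(otu_ids, samples)
    m
  }
  amplicon <- draw_counts(50000L)
  metagenomic <- draw_counts(10000L)

  # MAG contigs: coverage tracks the latent profile with lognormal noise
  contigs <- list()
  for (i in seq_len(n_populations)) {
    nc <- sample(3:10, 1)
    len <- round(stats::runif(nc, 1000, 50000))
    cov <- matrix(0, nrow = nc, ncol = n_samples)
    for (j in seq_len(n_samples)) {
      cov[, j] <- 100 * lat_pop[i, j] * exp(stats::rnorm(nc, 0, noise_sd))
    }
    df <- data.frame(contig_id = sprintf("%s_c%02d", mag_ids[i], seq_len(nc)),
                     bin_id = mag_ids[i], length_bp = len)
    colnames(cov) <- samples
    contigs[[i]] <- cbind(df, as.data.frame(cov))
  }
  contigs <- do.call(rbind, contigs)
  mag_reads <- stats::setNames(rep(1e7, n_samples), samples)

  # taxonomy: planted OTUs match the MAG path down to match_depth ranks;
  # the 4-rank (hardest) matches are confined to the control set
  mag_taxonomy <- vector("list", n_populations)
  otu_taxonomy <- vector("list", n_populations + n_extra_otus)
  ctrl_depths <- rep(c(4, 5, 6), length.out = n_controls)
  nonctrl_depths <- rep(c(6, 5), length.out = n_populations - n_controls)
  match_depth <- c(ctrl_depths, nonctrl_depths)
  seen <- character(0)
  for (i in seq_len(n_populations)) {
    # planted populations are taxonomically distinct at the genus level;
    # without this, colliding lineages make truth recovery ill-posed
    repeat {
      lin <- .random_lineage()
      key <- paste(lin, collapse = ".")
      if (!key %in% seen) break
    }
    seen <- c(seen, key)
    magp <- .toy_path(lin)
    d <- match_depth[i]
    lin2 <- lin
    if (d < 6) {
      # diverge below the matched rank (alter the lineage at position d)
      lin2[d] <- (lin2[d] %% .lineage_widths[d]) + 1L
    }
    otup <- c(magp[seq_len(d)], .toy_path(lin2)[-seq_len(d)])
    mag_taxonomy[[i]] <- magp
    otu_taxonomy[[i]] <- otup
  }
  planted_lin <- lapply(seen, function(k) as.integer(strsplit(k, ".", fixed = TRUE)[[1]]))
  prefix_len <- function(a, b) {
    eq <- a == b
    if (!eq[1]) 0L else as.integer(sum(cumprod(eq)))
  }
  for (i in seq_len(n_extra_otus)) {
    # partner-less OTUs may share a planted MAG's lineage down to the class
    # rank at most; deeper taxonomic twins of a binned population would make
    # "no partner" ill-defined
    repeat {
      lin <- .random_lineage()
      if (all(vapply(planted_lin, prefix_len, integer(1), a = lin) <= 2L)) break
    }
    otu_taxonomy[[n_populations + i]] <- .toy_path(lin)
  }
  names(mag_taxonomy) <- mag_ids
  names(otu_taxonomy) <- otu_ids

  planted <- data.frame(
    otu_id = otu_ids[seq_len(n_populations)], mag_id = mag_ids,
    control = seq_len(n_populations) <= n_controls,
    match_depth = match_depth, stringsAsFactors = FALSE)

  list(amplicon = amplicon, metagenomic = metagenomic,
       amplicon_reads = stats::setNames(colSums(amplicon), samples),
       metagenomic_reads = stats::setNames(colSums(metagenomic), samples),
       contigs = contigs, mag_reads = mag_reads,
       otu_taxonomy = otu_taxonomy, mag_taxonomy = mag_taxonomy,
       planted = planted, sample_depths = depths, seed = seed)
}

#' Run the full OTU-to-MAG matching on a community
#'
#' Normalizes the three tables (dual-axis L1 on the shared sample set),
#' computes the combined metric of every control pair in each dataset,
#' trains the per-dataset tolerances, and runs the one-to-one matcher.
#'
#' @param comm A community as returned by [make_community()] (or the same
#'   structure built from real tables).
#' @return List: `matches` (candidate data frame from [match_otus_mags()]),
#'   `tol_amplicon`, `tol_metagenomic`, `recovery` (fraction of planted
#'   pairs accepted), `false_acceptance` (fraction of partner-less OTUs
#'   accepted).
#' @export
run_matching <- function(comm) {
  amp <- dual_l1_normalize(comm$amplicon / rep(comm$amplicon_reads,
                                               each = nrow(comm$amplicon)))
  met <- dual_l1_normalize(comm$metagenomic / rep(comm$metagenomic_reads,
                                                  each = nrow(comm$metagenomic)))
  magraw <- bin_abundance_matrix(comm$contigs, comm$mag_reads)
  mag <- dual_l1_normalize(magraw)

  ctrl <- comm$planted[comm$planted$control, ]
  m_ctrl <- function(otus) {
    vapply(seq_len(nrow(ctrl)), function(i) {
      f <- taxonomy_fraction(comm$otu_taxonomy[[ctrl$otu_id[i]]],
                             comm$mag_taxonomy[[ctrl$mag_id[i]]])
      combined_distance(otus[ctrl$otu_id[i], ], mag[ctrl$mag_id[i], ], f)
    }, numeric(1))
  }
  tol_a <- train_tolerance(m_ctrl(amp))
  tol_m <- train_tolerance(m_ctrl(met))

  matches <- match_otus_mags(amp, met, mag, comm$otu_taxonomy,
                             comm$mag_taxonomy, tol_a, tol_m)
  acc <- matches[matches$accepted, ]
  key <- paste(acc$otu_id, acc$mag_id)
  planted_key <- paste(comm$planted$otu_id, comm$planted$mag_id)
  recovery <- mean(planted_key %in% key)
  extras <- setdiff(rownames(comm$amplicon), comm$planted$otu_id)
  false_acceptance <- mean(extras %in% acc$otu_id)
  list(matches = matches, tol_amplicon = tol_a, tol_metagenomic = tol_m,
       recovery = recovery, false_acceptance = false_acceptance)
}
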