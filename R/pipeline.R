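#' Validate input tables
#'
#' Schema and consistency checks for the TSV inputs consumed by the
#' matching and calibration stages: required columns, nonnegativity, and
#' sample-set consistency across tables. Returns a machine-readable report
#' rather than erroring on violations.
#'
#' @param paths Named list of file paths; recognised names are `otu_table`
#'   (TSV, first column OTU id, remaining columns samples), `contigs`
#'   (contig records), `taxonomy` (RDP fixed-rank dialect), `observations`
#'   (chemistry observations), `gene_profiles`.
#' @return List with `ok` (logical) and `violations` (data frame with
#'   `file`, `check`, `detail`).
#' @export
validate_inputs <- function(paths) {
  viol <- list()
  note <- function(file, check, detail) {
    viol[[length(viol) + 1L]] <<- data.frame(file = file, check = check,
                                             detail = detail)
  }
  tabs <- list()
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!file.exists(p)) {
      note(p, "readable", "file does not exist")
      next
    }
    df <- tryCatch(utils::read.delim(p, sep = "\t", check.names = FALSE),
                   error = function(e) NULL)
    if (is.null(df)) {
      note(p, "readable", "could not be parsed as TSV")
      next
    }
    tabs[[nm]] <- df
    if (nm %in% c("otu_table")) {
      num <- df[, -1, drop = FALSE]
      bad <- which(as.matrix(num) < 0, arr.ind = TRUE)
      if (nrow(bad)) {
        note(p, "nonnegative", sprintf("negative value at row %d, column '%s'",
                                       bad[1, 1], colnames(num)[bad[1, 2]]))
      }
    }
    if (nm == "contigs") {
      need <- c("contig_id", "bin_id", "length_bp")
      miss <- setdiff(need, names(df))
      if (length(miss)) note(p, "schema", paste("missing columns:",
                                                paste(miss, collapse = ", ")))
      else if (any(df$length_bp <= 0)) note(p, "positive_length",
                                            "contig with nonpositive length")
    }
    if (nm == "observations") {
      need <- c("observable", "time_day", "depth_m", "value")
      miss <- setdiff(need, names(df))
      if (length(miss)) note(p, "schema", paste("missing columns:",
                                                paste(miss, collapse = ", ")))
    }
  }
  if (!is.null(tabs$otu_table) && !is.null(tabs$contigs)) {
    otu_samples <- names(tabs$otu_table)[-1]
    contig_samples <- setdiff(names(tabs$contigs),
                              c("contig_id", "bin_id", "length_bp"))
    if (!length(intersect(otu_samples, contig_samples))) {
      note("otu_table/contigs", "shared_samples",
           "OTU table and contig records share no sample columns")
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(file = character(0), check = character(0), detail = character(0))
  list(ok = nrow(violations) == 0L, violations = violations)
}

#' Run a multi-stage pipeline from a configuration
#'
#' Executes the requested stages in order (`synth`, `simulate`,
#' `calibrate`, `knockout`, `sweep`, `match`), writing each stage's tables
#' under `out_dir` plus a run manifest (command, config digest, seed, input
#' digests, package version, timestamps). Inputs are never mutated. Every
#' stochastic stage takes its seed from `config$seed`; there is no
#' wall-clock default.
#'
#' @param config Either a YAML file path or a list. Fields: `seed`
#'   (required), `stages` (character vector), plus optional per-stage
#'   sections (`synth`, `calibrate`, `knockout`, `sweep`) with the arguments
#'   of the corresponding functions.
#' @param out_dir Output directory.
#' @return Invisibly, a list of stage outputs plus the manifest. Raises a
#'   condition of class `lakeredox_config_error` for schema violations and
#'   `lakeredox_stage_error` for stage failures (with the stage name).
#' @export
run_pipeline <- function(config, out_dir) {
  t0 <- Sys.time()
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- yaml::read_yaml(config)
  }
  fail_cfg <- function(msg) {
    stop(structure(class = c("lakeredox_config_error", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  if (is.null(config$seed)) fail_cfg("config field 'seed' is required")
  stages <- config$stages %||% c("synth", "simulate")
  known <- c("synth", "simulate", "calibrate", "knockout", "sweep", "match")
  bad <- setdiff(stages, known)
  if (length(bad)) fail_cfg(paste("unknown stage(s):", paste(bad, collapse = ", ")))
  if ("sweep" %in% stages || "calibrate" %in% stages) {
    procs <- config$sweep$processes %||% config$calibrate$processes %||%
      c("aerobic_heterotrophy", "denitrification", "sulfate_reduction",
        "sulfide_ox_no3")
    kin <- .default_kinetics()
    missing_bounds <- setdiff(procs, names(kin))
    if (length(missing_bounds)) {
      fail_cfg(paste("no bounds available for parameter(s):",
                     paste(missing_bounds, collapse = ", ")))
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  outputs <- list()
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop(structure(class = c("lakeredox_stage_error", "error", "condition"),
                     list(message = sprintf("stage '%s' failed: %s", name,
                                            conditionMessage(e)),
                          call = NULL, stage = name)))
    })
  }

  scen <- NULL
  if (any(c("synth", "simulate", "calibrate", "knockout", "sweep") %in% stages)) {
    scen <- run_stage("synth", function() {
      make_scenario(seed, n_free_params = config$synth$n_free_params %||% 4)
    })
    outputs$synth <- scen$truth
    yaml::write_yaml(list(seed = seed, k_true = as.list(scen$truth$k)),
                     file.path(out_dir, "truth.yaml"))
  }
  if ("simulate" %in% stages) {
    write_simulation(scen$result, file.path(out_dir, "simulation"))
    outputs$simulate <- scen$result
  }
  if ("knockout" %in% stages) {
    kos <- config$knockout$processes %||% c("sulfide_ox_no3", "methane_ox_no3")
    rep <- run_stage("knockout", function()
      knockout_compare(scen$scenario, scen$network, kos))
    utils::write.table(rep$table, file.path(out_dir, "knockout.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    outputs$knockout <- rep
  }
  if ("sweep" %in% stages) {
    procs <- config$sweep$processes %||% c("sulfide_ox_no3", "methane_ox_no3")
    specs <- default_rate_bounds(procs)
    rep <- run_stage("sweep", function()
      parameter_sweep(scen$scenario, scen$network, specs,
                      n = config$sweep$n %||% 5, seed = seed,
                      process_labels = config$sweep$knockout %||%
                        c("sulfide_ox_no3", "methane_ox_no3")))
    utils::write.table(rep$summary, file.path(out_dir, "sweep.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    outputs$sweep <- rep
  }
  if ("match" %in% stages) {
    comm <- make_community(seed)
    res <- run_stage("match", function() run_matching(comm))
    utils::write.table(res$matches, file.path(out_dir, "matches.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    outputs$match <- res
  }

  manifest <- list(
    command = paste("run_pipeline:", paste(stages, collapse = ",")),
    config_digest = if (!is.null(config_path))
      unname(tools::md5sum(config_path)) else NA_character_,
    seed = seed,
    package_version = as.character(utils::packageVersion("lakeredox")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  outputs$manifest <- manifest
  invisible(outputs)
}
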