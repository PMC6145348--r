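#' Build a calibration objective for the lake model
#'
#' Returns a closure mapping a named vector of rate constants (one per free
#' process) to the average MAE of the resulting simulation against the given
#' chemistry and gene observations. This is the objective handed to
#' [calibrate()].
#'
#' @param scenario Scenario list (`grid`, `initial`, `t_end`, `save_every`,
#'   `tolerance`) as produced by [make_scenario()].
#' @param network Base [reaction_network()]; the free processes' `k` values
#'   are overridden per call.
#' @param chem_obs Chemistry observations data frame (see [build_objective()]).
#' @param gene_obs List of `gene_profile` objects.
#' @param gpm Gene-process map.
#' @return Function of a named parameter vector returning the average MAE.
#' @export
make_lake_objective <- function(scenario, network, chem_obs, gene_obs,
                                gpm = default_gene_process_map()) {
  force(scenario); force(network); force(chem_obs); force(gene_obs); force(gpm)
  function(k) {
    kin <- lapply(as.list(k), function(v) list(k = unname(v)))
    net <- default_network_like(network, kin)
    res <- integrate_lake(scenario$grid, net, scenario$initial,
                          scenario$t_end, scenario$save_every,
                          scenario$tolerance %||% 1e-6)
    suppressWarnings(
      build_objective(res, chem_obs, gene_obs, gpm)$average_mae)
  }
}
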