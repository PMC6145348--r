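# Small fixtures shared across test files; everything is built in code.

toy_species <- function() {
  list(
    species("A", 0L, c(X = 1)),
    species("B", 0L, c(X = 1)),
    species("C", 0L, c(X = 2))
  )
}

# single first-order decay network A -> B on an X-conserving pair
decay_network <- function(k = 1) {
  reaction_network(
    toy_species()[1:2],
    list(reaction("dec", "decay", c(A = -1, B = 1),
                  rate_law(k, donor = "A", first_order = TRUE)))
  )
}

# transport-free grid: all diffusivities zero, no boundary exchange
still_grid <- function(n_cells = 5) {
  lake_grid(n_cells = n_cells, diffusivity = rep(0, n_cells + 1))
}

# random balanced sub-networks of the default process set, with random
# positive rate constants; used by conservation property tests
random_subnetwork <- function(seed) {
  set.seed(seed)
  full <- default_network()
  labels <- process_labels(full)
  keep <- sample(labels, sample(3:10, 1))
  kin <- lapply(keep, function(pl) list(k = stats::runif(1, 50, 5000)))
  names(kin) <- keep
  net <- default_network(kin)
  knockout(net, setdiff(labels, keep))
}

random_profiles <- function(seed, grid) {
  set.seed(seed)
  sp <- c("OM", "O2", "NO3", "SO4", "Fe2", "Fe3", "CH4", "HS", "NH4")
  out <- lapply(sp, function(s) stats::runif(grid$n_cells, 0, 100))
  names(out) <- sp
  out
}
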