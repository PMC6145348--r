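#' Chemical species
#'
#' A species is a named chemical entity with an elemental composition and a
#' formal charge. Particulate species (e.g. precipitated reduced sulfur) are
#' flagged immobile and are excluded from vertical transport.
#'
#' @param name Unique species identifier, e.g. `"HS"`, `"NO3"`.
#' @param charge Signed integer formal charge in elementary charge units.
#' @param elements Named integer vector of element counts, e.g. `c(H = 1, S = 1)`.
#' @param mobile Logical; `TRUE` for dissolved (transported) species.
#' @param balance_only Logical; `TRUE` for species (H+, H2O) tracked only to
#'   close element/charge balances -- excluded from kinetics, transport,
#'   clipping and the nonnegativity requirement (pH and the water budget are
#'   not modeled).
#' @return An object of class `species`.
#' @export
species <- function(name, charge = 0L, elements = integer(0), mobile = TRUE,
                    balance_only = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  elements <- unlist(elements)
  if (length(elements)) {
    stopifnot(!is.null(names(elements)), all(nzchar(names(elements))))
    if (any(elements < 0) || any(elements != round(elements))) {
      stop("element counts must be nonnegative integers")
    }
  }
  structure(
    list(name = name, charge = as.integer(charge),
         elements = elements, mobile = isTRUE(mobile),
         balance_only = isTRUE(balance_only)),
    class = "species"
  )
}

#' Kinetic rate law
#'
#' Dual-Monod kinetics with optional inhibition:
#' \deqn{r = k \frac{[donor]}{K_d + [donor]} \frac{[acceptor]}{K_a + [acceptor]}
#'         \frac{K_i}{K_i + [inhibitor]}}
#' Each factor collapses to 1 when its species is `NA`. With
#' `first_order = TRUE` the law is instead \eqn{r = k [donor]} (used for the
#' reduced-sulfur precipitation sink), and `k` is a first-order constant in
#' 1/year rather than a maximum rate in uM/year.
#'
#' @param k Maximum rate (uM/year), or 1/year when `first_order`.
#' @param donor,acceptor,inhibitor Species names or `NA`.
#' @param K_donor,K_acceptor,K_inhibit Half-saturation / inhibition constants (uM).
#' @param first_order Logical; linear-in-donor kinetics.
#' @return An object of class `rate_law`.
#' @export
rate_law <- function(k, donor = NA, K_donor = NA, acceptor = NA,
                     K_acceptor = NA, inhibitor = NA, K_inhibit = NA,
                     first_order = FALSE) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0)
  chk <- function(sp, K, what) {
    if (!is.na(sp) && (is.na(K) || K <= 0)) {
      stop(sprintf("%s constant must be > 0 when a %s species is set", what, what))
    }
  }
  if (!first_order) {
    chk(donor, K_donor, "donor")
    chk(acceptor, K_acceptor, "acceptor")
    chk(inhibitor, K_inhibit, "inhibitor")
  } else if (is.na(donor)) {
    stop("first-order kinetics require a donor species")
  }
  structure(
    list(k = as.numeric(k), donor = donor, K_donor = K_donor,
         acceptor = acceptor, K_acceptor = K_acceptor,
         inhibitor = inhibitor, K_inhibit = K_inhibit,
         first_order = isTRUE(first_order)),
    class = "rate_law"
  )
}

#' Balanced reaction
#'
#' @param id Reaction identifier.
#' @param process_label Modeled process name (used by gene mapping and knockouts).
#' @param stoich Named numeric vector; reactants negative, products positive.
#' @param rate_law A [rate_law()].
#' @return An object of class `reaction`.
#' @export
reaction <- function(id, process_label, stoich, rate_law) {
  stoich <- unlist(stoich)
  stopifnot(is.character(id), length(id) == 1L,
            is.character(process_label), length(process_label) == 1L,
            is.numeric(stoich), !is.null(names(stoich)),
            inherits(rate_law, "rate_law"))
  if (!any(stoich < 0) || !any(stoich > 0)) {
    stop("a reaction needs at least one reactant and one product")
  }
  structure(
    list(id = id, process_label = process_label,
         stoich = stoich, rate_law = rate_law),
    class = "reaction"
  )
}

#' Reaction network
#'
#' Bundles species and reactions; every reaction must reference known species
#' and balance exactly in every element and in charge.
#'
#' @param species List of [species()] objects.
#' @param reactions List of [reaction()] objects.
#' @param check Verify balance on construction (default `TRUE`).
#' @return An object of class `reaction_network`.
#' @export
reaction_network <- function(species, reactions, check = TRUE) {
  nms <- vapply(species, function(s) s$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate species names: ",
                               paste(nms[duplicated(nms)], collapse = ", "))
  names(species) <- nms
  rids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(rids)) stop("duplicate reaction ids")
  names(reactions) <- rids
  net <- structure(list(species = species, reactions = reactions),
                   class = "reaction_network")
  if (check) {
    for (r in reactions) {
      res <- check_balance(r, species)
      if (any(res != 0)) {
        stop(sprintf("reaction '%s' is unbalanced: %s", r$id,
                     paste(names(res)[res != 0], collapse = ", ")))
      }
    }
  }
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species, %d reactions\n",
              length(x$species), length(x$reactions)))
  for (r in x$reactions) {
    cat(sprintf("  %-18s [%s] k = %g\n", r$id, r$process_label, r$rate_law$k))
  }
  invisible(x)
}

.species_names <- function(species_list) {
  vapply(species_list, function(s) s$name, character(1))
}

.element_universe <- function(species_list) {
  sort(unique(unlist(lapply(species_list, function(s) names(s$elements)))))
}

#' Element and charge residuals of a reaction
#'
#' For every element, the residual is the stoichiometry-weighted sum of
#' element counts (reactants counted negatively); the charge residual is
#' analogous. A balanced reaction returns an all-zero vector. Coefficients in
#' shipped networks are integers, so the arithmetic is exact.
#'
#' @param reaction A [reaction()].
#' @param species List of [species()] defining compositions.
#' @return Named numeric vector of residuals, one per element plus `"charge"`.
#' @export
check_balance <- function(reaction, species) {
  nms <- .species_names(species)
  names(species) <- nms
  unknown <- setdiff(names(reaction$stoich), nms)
  if (length(unknown)) {
    stop("unknown species in reaction '", reaction$id, "': ",
         paste(unknown, collapse = ", "))
  }
  elems <- .element_universe(species[names(reaction$stoich)])
  res <- stats::setNames(numeric(length(elems) + 1L), c(elems, "charge"))
  for (sn in names(reaction$stoich)) {
    nu <- reaction$stoich[[sn]]
    sp <- species[[sn]]
    for (e in names(sp$elements)) res[[e]] <- res[[e]] + nu * sp$elements[[e]]
    res[["charge"]] <- res[["charge"]] + nu * sp$charge
  }
  res
}

#' Balance a reaction in smallest positive integers
#'
#' Solves the element/charge conservation system for the given reactant and
#' product sets with exact rational arithmetic and returns the unique (up to
#' scale) strictly positive integer solution with coprime coefficients.
#'
#' @param reactant_names,product_names Character vectors of species names.
#' @param species List of [species()].
#' @return Named numeric vector of positive integer coefficients, reactants
#'   first. `check_balance()` on the corresponding signed stoichiometry is
#'   all-zero by construction.
#' @export
balance_minimal <- function(reactant_names, product_names, species) {
  nms <- .species_names(species)
  names(species) <- nms
  all_names <- c(reactant_names, product_names)
  unknown <- setdiff(all_names, nms)
  if (length(unknown)) stop("unknown species: ", paste(unknown, collapse = ", "))
  if (anyDuplicated(all_names)) {
    # identity "reactions" (A -> A) are allowed; general duplicates are not
    if (!identical(sort(reactant_names), sort(product_names))) {
      stop("species may not appear on both sides")
    }
    return(stats::setNames(rep(1, length(all_names)), all_names))
  }
  sgn <- c(rep(-1, length(reactant_names)), rep(1, length(product_names)))
  elems <- .element_universe(species[all_names])
  A <- matrix(0, nrow = length(elems) + 1L, ncol = length(all_names),
              dimnames = list(c(elems, "charge"), all_names))
  for (j in seq_along(all_names)) {
    sp <- species[[all_names[j]]]
    for (e in names(sp$elements)) A[e, j] <- sgn[j] * sp$elements[[e]]
    A["charge", j] <- sgn[j] * sp$charge
  }
  basis <- .rat_nullspace(A)
  if (length(basis) == 0L) stop("no nontrivial balanced solution exists")
  if (length(basis) > 1L) stop("solution space is multi-dimensional; the reaction is not uniquely determined")
  stats::setNames(.rat_to_min_integers(basis[[1L]]), all_names)
}

#' Evaluate a reaction's kinetic rate
#'
#' Dual-Monod kinetics (or first-order for precipitation) evaluated at the
#' given concentrations. Vectorised over concentration vectors: `conc` may be
#' a named list/vector of scalars or of equal-length numeric vectors (e.g. one
#' value per depth cell).
#'
#' @param reaction A [reaction()].
#' @param conc Named concentrations (uM), scalars or vectors.
#' @return Rate in uM/year, same length as the concentration vectors.
#' @export
reaction_rate <- function(reaction, conc) {
  rl <- reaction$rate_law
  get_c <- function(sp) {
    if (!sp %in% names(conc)) stop("missing concentration for species '", sp, "'")
    v <- conc[[sp]]
    if (any(v < 0)) stop("negative concentration for species '", sp, "'")
    v
  }
  if (rl$first_order) {
    return(rl$k * get_c(rl$donor))
  }
  r <- rl$k
  if (!is.na(rl$donor)) {
    cd <- get_c(rl$donor)
    r <- r * cd / (rl$K_donor + cd)
  }
  if (!is.na(rl$acceptor)) {
    ca <- get_c(rl$acceptor)
    r <- r * ca / (rl$K_acceptor + ca)
  }
  if (!is.na(rl$inhibitor)) {
    ci <- get_c(rl$inhibitor)
    r <- r * rl$K_inhibit / (rl$K_inhibit + ci)
  }
  r
}

#' Set process rate constants to zero
#'
#' In-silico knockout: returns a copy of the network in which every reaction
#' carrying one of the given process labels has its rate constant set to 0;
#' all other parameters are untouched. Idempotent.
#'
#' @param network A [reaction_network()].
#' @param process_labels Character vector of process labels (may be empty).
#' @return The modified network; the input is not changed.
#' @export
knockout <- function(network, process_labels) {
  if (length(process_labels) == 0L) return(network)
  have <- unique(vapply(network$reactions, function(r) r$process_label, character(1)))
  unknown <- setdiff(process_labels, have)
  if (length(unknown)) stop("unknown process label(s): ", paste(unknown, collapse = ", "))
  for (i in seq_along(network$reactions)) {
    if (network$reactions[[i]]$process_label %in% process_labels) {
      network$reactions[[i]]$rate_law$k <- 0
    }
  }
  network
}

#' Default lake species set
#'
#' Dissolved and particulate species of the default water-column network.
#' Organic matter is represented by the CH2O proxy; oxidised iron by Fe3+;
#' precipitated reduced sulfur (`Sppt`) is an immobile bookkeeping species
#' with the composition of HS- so that the precipitation sink balances.
#'
#' @return Named list of [species()].
#' @export
default_species <- function() {
  sp <- list(
    species("OM",   0L, c(C = 1, H = 2, O = 1)),
    species("O2",   0L, c(O = 2)),
    species("CO2",  0L, c(C = 1, O = 2)),
    species("CH4",  0L, c(C = 1, H = 4)),
    species("NO3", -1L, c(N = 1, O = 3)),
    species("NH4",  1L, c(N = 1, H = 4)),
    species("N2",   0L, c(N = 2)),
    species("SO4", -2L, c(S = 1, O = 4)),
    species("HS",  -1L, c(H = 1, S = 1)),
    species("Fe2",  2L, c(Fe = 1)),
    species("Fe3",  3L, c(Fe = 1)),
    species("H",    1L, c(H = 1), balance_only = TRUE),
    species("H2O",  0L, c(H = 2, O = 1), balance_only = TRUE),
    species("Sppt", -1L, c(H = 1, S = 1), mobile = FALSE)
  )
  names(sp) <- .species_names(sp)
  sp
}

# Default maximum rates (uM/year; Sppt precipitation in 1/year) and
# half-saturation constants (uM) for the 14-process network. Values are
# order-of-magnitude choices typical of seasonally anoxic lake models.
.default_kinetics <- function() {
  list(
    aerobic_heterotrophy = list(k = 6000, donor = "OM", K_donor = 50, acceptor = "O2", K_acceptor = 10),
    denitrification      = list(k = 3000, donor = "OM", K_donor = 50, acceptor = "NO3", K_acceptor = 10, inhibitor = "O2", K_inhibit = 5),
    iron_reduction       = list(k = 1500, donor = "OM", K_donor = 50, acceptor = "Fe3", K_acceptor = 30, inhibitor = "O2", K_inhibit = 5),
    sulfate_reduction    = list(k = 1200, donor = "OM", K_donor = 50, acceptor = "SO4", K_acceptor = 100, inhibitor = "O2", K_inhibit = 5),
    methanogenesis       = list(k = 400,  donor = "OM", K_donor = 80, inhibitor = "O2", K_inhibit = 2),
    nitrification        = list(k = 2000, donor = "NH4", K_donor = 10, acceptor = "O2", K_acceptor = 10),
    methane_ox_o2        = list(k = 3000, donor = "CH4", K_donor = 20, acceptor = "O2", K_acceptor = 10),
    methane_ox_so4       = list(k = 150,  donor = "CH4", K_donor = 20, acceptor = "SO4", K_acceptor = 100, inhibitor = "O2", K_inhibit = 2),
    sulfide_ox_o2        = list(k = 4000, donor = "HS", K_donor = 10, acceptor = "O2", K_acceptor = 10),
    iron_ox_o2           = list(k = 5000, donor = "Fe2", K_donor = 20, acceptor = "O2", K_acceptor = 10),
    iron_ox_no3          = list(k = 1500, donor = "Fe2", K_donor = 20, acceptor = "NO3", K_acceptor = 10, inhibitor = "O2", K_inhibit = 5),
    sulfide_ox_no3       = list(k = 2000, donor = "HS", K_donor = 10, acceptor = "NO3", K_acceptor = 10, inhibitor = "O2", K_inhibit = 5),
    methane_ox_no3       = list(k = 800,  donor = "CH4", K_donor = 20, acceptor = "NO3", K_acceptor = 10, inhibitor = "O2", K_inhibit = 5),
    s_precipitation      = list(k = 3, donor = "HS", first_order = TRUE)
  )
}

# Signed stoichiometries of the 14 default processes; all integer and exactly
# balanced in every element and in charge (CH2O organic-matter proxy).
.default_stoich <- function() {
  list(
    aerobic_heterotrophy = c(OM = -1, O2 = -1, CO2 = 1, H2O = 1),
    denitrification      = c(OM = -5, NO3 = -4, H = -4, CO2 = 5, N2 = 2, H2O = 7),
    iron_reduction       = c(OM = -1, Fe3 = -4, H2O = -1, CO2 = 1, Fe2 = 4, H = 4),
    sulfate_reduction    = c(OM = -2, SO4 = -1, H = -1, CO2 = 2, HS = 1, H2O = 2),
    methanogenesis       = c(OM = -2, CH4 = 1, CO2 = 1),
    nitrification        = c(NH4 = -1, O2 = -2, NO3 = 1, H2O = 1, H = 2),
    methane_ox_o2        = c(CH4 = -1, O2 = -2, CO2 = 1, H2O = 2),
    methane_ox_so4       = c(CH4 = -1, SO4 = -1, H = -1, CO2 = 1, HS = 1, H2O = 2),
    sulfide_ox_o2        = c(HS = -1, O2 = -2, SO4 = 1, H = 1),
    iron_ox_o2           = c(Fe2 = -4, O2 = -1, H = -4, Fe3 = 4, H2O = 2),
    iron_ox_no3          = c(Fe2 = -10, NO3 = -2, H = -12, Fe3 = 10, N2 = 1, H2O = 6),
    sulfide_ox_no3       = c(HS = -5, NO3 = -8, H = -3, SO4 = 5, N2 = 4, H2O = 4),
    methane_ox_no3       = c(CH4 = -5, NO3 = -8, H = -8, CO2 = 5, N2 = 4, H2O = 14),
    s_precipitation      = c(HS = -1, Sppt = 1)
  )
}

#' Default 14-process lake reaction network
#'
#' The modeled process set: primary carbon oxidation with the full ladder of
#' electron acceptors (O2, NO3-, Fe(III), SO4^2-, methanogenesis),
#' re-oxidation of the reduced products (NH4+, CH4, HS-, Fe2+) with O2,
#' sulfate-coupled methane oxidation, autotrophic denitrification by iron
#' oxidation, the two nitrate-coupled oxidations of sulfide and methane, and
#' a first-order precipitation sink for reduced sulfur. All reactions balance
#' exactly; anaerobic processes carry O2 inhibition.
#'
#' @param kinetics Optional named list overriding entries of the default
#'   kinetic table (each entry a list of `rate_law()` arguments).
#' @return A [reaction_network()].
#' @export
default_network <- function(kinetics = NULL) {
  kin <- .default_kinetics()
  if (!is.null(kinetics)) {
    for (nm in names(kinetics)) {
      if (!nm %in% names(kin)) stop("unknown process in kinetics override: ", nm)
      kin[[nm]] <- utils::modifyList(kin[[nm]], kinetics[[nm]])
    }
  }
  st <- .default_stoich()
  reactions <- lapply(names(st), function(pl) {
    reaction(id = pl, process_label = pl, stoich = st[[pl]],
             rate_law = do.call(rate_law, kin[[pl]]))
  })
  reaction_network(default_species(), reactions)
}

#' Process labels of a network
#' @param network A [reaction_network()].
#' @return Character vector of process labels in network order.
#' @export
process_labels <- function(network) {
  unname(vapply(network$reactions, function(r) r$process_label, character(1)))
}

#' Write / read a network definition file
#'
#' Round-trip lossless YAML serialisation of species (name, charge, elements,
#' mobility) and reactions (stoichiometry and rate-law fields).
#'
#' @param network A [reaction_network()].
#' @param path File path.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns the reconstructed [reaction_network()].
#' @export
write_network <- function(network, path) {
  doc <- list(
    species = lapply(unname(network$species), function(s) {
      list(name = s$name, charge = s$charge,
           elements = as.list(s$elements), mobile = s$mobile,
           balance_only = s$balance_only)
    }),
    reactions = lapply(unname(network$reactions), function(r) {
      rl <- r$rate_law
      rl_fields <- rl[!vapply(rl, function(x) length(x) == 1L && is.na(x), logical(1))]
      list(id = r$id, process_label = r$process_label,
           stoich = as.list(r$stoich), rate_law = rl_fields)
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  doc <- yaml::read_yaml(path)
  sp <- lapply(doc$species, function(s) {
    species(s$name, s$charge, unlist(s$elements), s$mobile,
            s$balance_only %||% FALSE)
  })
  rx <- lapply(doc$reactions, function(r) {
    reaction(r$id, r$process_label, unlist(r$stoich),
             do.call(rate_law, r$rate_law))
  })
  reaction_network(sp, rx)
}
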