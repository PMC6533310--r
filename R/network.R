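#' Mass-action reaction networks with regulatory multipliers
#'
#' A reaction network is the mechanistic substrate of the whole package:
#' species, mass-action reactions (optionally scaled by a non-competitive
#' regulatory multiplier), and moiety-conservation laws that tie linearly
#' dependent species to total-abundance parameters.
#'
#' @name network
NULL

#' Declare a species
#'
#' @param name species identifier (unique within a network).
#' @param role one of `"free_inactive"`, `"free_active"`, `"complex"`,
#'   `"other"`.  Free active forms and complexes are the observables of a
#'   perturbation experiment.
#' @param of for `role = "complex"`, character vector of the two constituent
#'   species names.
#' @param module optional module hint used when matching conservation laws
#'   and building partitions.
#' @return a `species` object (named list).
#' @export
species <- function(name, role = c("other", "free_inactive", "free_active", "complex"),
                    of = NULL, module = NA_character_) {
  role <- match.arg(role)
  if (role == "complex") {
    if (is.null(of) || length(of) != 2L) {
      stop_definition("complex species '%s' must list exactly two constituents", name)
    }
  } else if (!is.null(of)) {
    stop_definition("only complex species may declare constituents ('%s')", name)
  }
  structure(list(name = name, role = role, of = of, module = module),
            class = "retromra_species")
}

#' Declare a non-competitive regulatory multiplier
#'
#' The rate of the modified reaction is multiplied by
#' `(1 + u * [effector]/k) / (1 + [effector]/k)`.  The multiplier equals 1
#' when `u = 1` or the effector is absent, and lies strictly between 1 and
#' `u` otherwise, so `u > 1` encodes activation and `0 < u < 1` inhibition.
#'
#' @param effector species name whose concentration drives the multiplier.
#' @param u name of the dimensionless gain parameter.
#' @param k name of the concentration-scale parameter.
#' @return a `regulatory_multiplier` object.
#' @export
regulatory_multiplier <- function(effector, u, k) {
  structure(list(effector = effector, u = u, k = k),
            class = "retromra_multiplier")
}

#' Declare a mass-action reaction
#'
#' @param reactants character vector of reactant species names (repeat a name
#'   for stoichiometric multiplicity).
#' @param products character vector of product species names.
#' @param rate name of the rate-constant parameter.
#' @param modifier optional [regulatory_multiplier()].
#' @return a `reaction` object.
#' @export
reaction <- function(reactants, products, rate, modifier = NULL) {
  if (!is.null(modifier) && !inherits(modifier, "retromra_multiplier")) {
    stop_definition("modifier must be a regulatory_multiplier")
  }
  structure(list(reactants = as.character(reactants),
                 products = as.character(products),
                 rate = rate, modifier = modifier),
            class = "retromra_reaction")
}

#' Declare a moiety-conservation law
#'
#' @param coef named vector of non-negative integer coefficients over species.
#' @param total name of the total-abundance parameter the law evaluates to.
#' @return a `conservation_law` object.
#' @export
conservation_law <- function(coef, total) {
  if (!is_named_numeric(coef)) stop_definition("conservation coefficients must be named")
  if (any(coef < 0) || any(coef != round(coef))) {
    stop_definition("conservation coefficients must be non-negative integers")
  }
  structure(list(coef = coef[coef != 0], total = total),
            class = "retromra_conservation_law")
}

#' Assemble a reaction network
#'
#' Validates cross-references, verifies every declared conservation law
#' against the stoichiometric matrix, and fixes the set of independent
#' species: one species per conservation law (preferring free inactive
#' forms that appear in a single law) is eliminated and reconstructed from
#' its total on demand, so the dynamical state holds only linearly
#' independent concentrations.
#'
#' @param species list of [species()] objects.
#' @param reactions list of [reaction()] objects.
#' @param conservation list of [conservation_law()] objects.
#' @param name optional model name.
#' @return an object of class `mra_network`.
#' @export
mra_network <- function(species, reactions, conservation = list(), name = "model") {
  sp_names <- vapply(species, `[[`, "", "name")
  if (anyDuplicated(sp_names)) {
    stop_definition("duplicated species names: %s",
                    paste(unique(sp_names[duplicated(sp_names)]), collapse = ", "))
  }
  for (sp in species) {
    if (!is.null(sp$of) && !all(sp$of %in% sp_names)) {
      stop_definition("complex '%s' references undeclared constituents", sp$name)
    }
  }
  for (rx in reactions) {
    unknown <- setdiff(c(rx$reactants, rx$products), sp_names)
    if (length(unknown)) {
      stop_definition("reaction '%s' references undeclared species: %s",
                      format_reaction(rx), paste(unknown, collapse = ", "))
    }
    if (!is.null(rx$modifier) && !(rx$modifier$effector %in% sp_names)) {
      stop_definition("modifier effector '%s' is not a declared species",
                      rx$modifier$effector)
    }
  }
  net <- structure(list(species = species, reactions = reactions,
                        conservation = conservation, name = name),
                   class = "mra_network")
  S <- stoichiometric_matrix(net)
  for (law in conservation) {
    v <- law_vector(law, sp_names)
    resid <- as.vector(v %*% S)
    if (any(abs(resid) > 1e-9)) {
      stop_definition("declared conservation law for '%s' is not in the left null space",
                      law$total)
    }
  }
  net$independent <- choose_independent(net)
  net$compiled <- compile_network(net, S)
  net
}

# Precomputed index structures for fast rate evaluation inside ODE solvers.
compile_network <- function(net, S) {
  sp <- species_names(net)
  list(
    S = S,
    rate_names = vapply(net$reactions, `[[`, "", "rate"),
    react_idx = lapply(net$reactions, function(rx) match(rx$reactants, sp)),
    modifiers = lapply(net$reactions, function(rx) {
      if (is.null(rx$modifier)) return(NULL)
      list(e = match(rx$modifier$effector, sp), u = rx$modifier$u, k = rx$modifier$k)
    })
  )
}

format_reaction <- function(rx) {
  paste(paste(rx$reactants, collapse = " + "), "->",
        paste(rx$products, collapse = " + "), "@", rx$rate)
}

species_names <- function(network) vapply(network$species, `[[`, "", "name")

species_roles <- function(network) {
  stats::setNames(vapply(network$species, `[[`, "", "role"), species_names(network))
}

#' Observable species of a network
#'
#' Free active forms and complexes: the quantities a perturbation experiment
#' measures (phospho-blots and co-immunoprecipitated complexes).
#'
#' @param network an `mra_network`.
#' @return character vector of species names.
#' @export
observable_species <- function(network) {
  roles <- species_roles(network)
  names(roles)[roles %in% c("free_active", "complex")]
}

law_vector <- function(law, sp_names) {
  v <- stats::setNames(numeric(length(sp_names)), sp_names)
  unknown <- setdiff(names(law$coef), sp_names)
  if (length(unknown)) {
    stop_definition("conservation law '%s' references undeclared species: %s",
                    law$total, paste(unknown, collapse = ", "))
  }
  v[names(law$coef)] <- law$coef
  v
}

#' Stoichiometric matrix
#'
#' @param network an `mra_network`.
#' @return integer matrix, species in rows and reactions in columns; entry
#'   (s, r) is the net production of species s in reaction r.
#' @export
stoichiometric_matrix <- function(network) {
  sp <- species_names(network)
  nr <- length(network$reactions)
  S <- matrix(0L, nrow = length(sp), ncol = nr,
              dimnames = list(sp, vapply(seq_len(nr), function(j) {
                paste0("r", j, "_", network$reactions[[j]]$rate)
              }, "")))
  for (j in seq_len(nr)) {
    rx <- network$reactions[[j]]
    for (s in rx$reactants) S[s, j] <- S[s, j] - 1L
    for (s in rx$products) S[s, j] <- S[s, j] + 1L
  }
  S
}

# Pick one species to eliminate per conservation law.  Preference order:
# appears in this law only and is a free inactive form, then any species
# unique to the law, then any unused species.  The resulting coefficient
# submatrix over eliminated species must be invertible.
choose_independent <- function(network) {
  sp <- species_names(network)
  laws <- network$conservation
  if (!length(laws)) {
    return(list(independent = sp, eliminated = character(),
                A = matrix(0, 0, 0), B = matrix(0, 0, length(sp)),
                totals = character()))
  }
  counts <- table(unlist(lapply(laws, function(l) names(l$coef))))
  roles <- species_roles(network)
  eliminated <- character(length(laws))
  for (i in seq_along(laws)) {
    cand <- names(laws[[i]]$coef)
    cand <- setdiff(cand, eliminated)
    unique_here <- cand[counts[cand] == 1]
    pick <- unique_here[roles[unique_here] == "free_inactive"]
    if (!length(pick)) pick <- unique_here
    if (!length(pick)) pick <- cand
    if (!length(pick)) {
      stop_definition("cannot select an eliminated species for conservation law '%s'",
                      laws[[i]]$total)
    }
    eliminated[i] <- pick[[1]]
  }
  indep <- setdiff(sp, eliminated)
  # A d = total - B z  with d the eliminated and z the independent species
  A <- matrix(0, length(laws), length(laws),
              dimnames = list(NULL, eliminated))
  B <- matrix(0, length(laws), length(indep), dimnames = list(NULL, indep))
  for (i in seq_along(laws)) {
    cf <- laws[[i]]$coef
    for (s in names(cf)) {
      if (s %in% eliminated) A[i, s] <- cf[[s]] else B[i, s] <- cf[[s]]
    }
  }
  if (abs(det(A)) < 1e-12) {
    stop_definition("conservation laws are not linearly independent")
  }
  list(independent = indep, eliminated = eliminated, A = A, B = B,
       Ainv = solve(A), totals = vapply(laws, `[[`, "", "total"))
}

#' Reconstruct the full concentration vector from independent species
#'
#' Dependent species are recovered from the conservation totals.  Small
#' negative values from numerical round-off are clamped at zero; a value
#' below `-1e-9` times its total triggers a warning because it indicates an
#' inconsistent state rather than round-off.
#'
#' @param network an `mra_network`.
#' @param state named vector over the independent species (a full-length
#'   state is returned unchanged).
#' @param params named parameter vector including the totals.
#' @return named concentration vector over all species.
#' @export
reconstruct_state <- function(network, state, params) {
  sp <- species_names(network)
  if (all(sp %in% names(state))) return(state[sp])
  idx <- network$independent
  missing <- setdiff(idx$independent, names(state))
  if (length(missing)) {
    stop_definition("state is missing independent species: %s",
                    paste(missing, collapse = ", "))
  }
  z <- state[idx$independent]
  totals <- unlist(lapply(idx$totals, function(tn) get_param(params, tn)))
  d <- as.vector(idx$Ainv %*% (totals - as.vector(idx$B %*% z)))
  names(d) <- idx$eliminated
  bad <- d < -1e-9 * pmax(totals, 1e-300)
  if (any(bad)) {
    warning(sprintf("reconstructed concentration(s) negative beyond tolerance: %s",
                    paste(idx$eliminated[bad], collapse = ", ")))
  }
  d[d < 0] <- 0
  full <- stats::setNames(numeric(length(sp)), sp)
  full[names(z)] <- z
  full[names(d)] <- d
  full
}

get_param <- function(params, nm) {
  if (!nm %in% names(params)) stop_definition("missing parameter '%s'", nm)
  params[[nm]]
}

#' Value of a regulatory multiplier at a given state
#'
#' @param modifier a [regulatory_multiplier()].
#' @param conc named full concentration vector.
#' @param params named parameter vector.
#' @return scalar multiplier value.
#' @export
multiplier_value <- function(modifier, conc, params) {
  e <- conc[[modifier$effector]]
  u <- get_param(params, modifier$u)
  k <- get_param(params, modifier$k)
  (1 + u * e / k) / (1 + e / k)
}

#' Reaction rates at a full state
#'
#' @param network an `mra_network`.
#' @param conc named concentration vector over all species.
#' @param params named parameter vector.
#' @return numeric vector of mass-action reaction rates.
#' @export
reaction_rates <- function(network, conc, params) {
  cp <- network$compiled
  k <- unlist(lapply(cp$rate_names, function(nm) get_param(params, nm)))
  rates <- numeric(length(k))
  for (j in seq_along(k)) {
    v <- k[[j]]
    for (i in cp$react_idx[[j]]) v <- v * conc[[i]]
    mod <- cp$modifiers[[j]]
    if (!is.null(mod)) {
      e <- conc[[mod$e]]
      kk <- get_param(params, mod$k)
      v <- v * (1 + get_param(params, mod$u) * e / kk) / (1 + e / kk)
    }
    rates[j] <- v
  }
  rates
}

#' Time derivatives of species concentrations
#'
#' Evaluates mass-action kinetics (with regulatory multipliers where
#' declared).  When `state` covers only the independent species, dependent
#' concentrations are first reconstructed from the conservation totals and
#' the derivative is returned for the independent species only; a full
#' state yields derivatives for every species.
#'
#' @param network an `mra_network`.
#' @param state named concentration vector (independent subset or full).
#' @param params named parameter vector.
#' @return named derivative vector matching the interpretation of `state`.
#' @export
network_rhs <- function(network, state, params) {
  if (any(state < 0)) {
    stop_domain("negative concentration in state: %s",
                paste(names(state)[state < 0], collapse = ", "))
  }
  sp <- species_names(network)
  reduced <- !all(sp %in% names(state))
  conc <- reconstruct_state(network, state, params)
  rates <- reaction_rates(network, conc, params)
  dz <- as.vector(network$compiled$S %*% rates)
  names(dz) <- sp
  if (reduced) dz[network$independent$independent] else dz
}

#' @export
print.mra_network <- function(x, ...) {
  cat(sprintf("<mra_network> %s: %d species (%d independent), %d reactions, %d conservation laws\n",
              x$name, length(x$species), length(x$independent$independent),
              length(x$reactions), length(x$conservation)))
  invisible(x)
}
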