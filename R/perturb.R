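#' Perturbation experiments and global response coefficients
#'
#' The perturbation experiment is simulated once at species level and
#' stored in a response table; global response coefficients for any choice
#' of weighted module outputs are then derived from that single table
#' without re-solving any steady state ("measure once, reweigh many
#' times").
#'
#' @name perturbation_response
NULL

#' Declare a parameter perturbation
#'
#' @param parameter parameter name to perturb.
#' @param magnitude relative magnitude (default 0.10, i.e. 10\%); the
#'   perturbed value is `p*(1 + magnitude)` (and `p*(1 - magnitude)` in
#'   central mode).
#' @param mode `"central"` (two-sided, default) or `"one_sided"`.
#' @return a `perturbation_spec`.
#' @export
perturbation_spec <- function(parameter, magnitude = 0.10,
                              mode = c("central", "one_sided")) {
  mode <- match.arg(mode)
  if (!is.finite(magnitude) || abs(magnitude) <= 0 || abs(magnitude) >= 1) {
    stop_config("perturbation magnitude must satisfy 0 < |m| < 1 (got %g)", magnitude)
  }
  structure(list(parameter = parameter, magnitude = magnitude, mode = mode),
            class = "retromra_perturbation")
}

as_spec_list <- function(specs, magnitude = 0.10, mode = "central") {
  if (is.character(specs)) {
    specs <- lapply(specs, perturbation_spec, magnitude = magnitude, mode = mode)
  }
  if (inherits(specs, "retromra_perturbation")) specs <- list(specs)
  for (s in specs) {
    if (!inherits(s, "retromra_perturbation")) {
      stop_config("specs must be perturbation_spec objects or parameter names")
    }
  }
  params <- vapply(specs, `[[`, "", "parameter")
  if (anyDuplicated(params)) stop_config("perturbation specs must name distinct parameters")
  specs
}

#' Simulate steady-state responses to parameter perturbations
#'
#' Solves the reference steady state and one (one-sided) or two (central)
#' perturbed steady states per spec.  Every condition starts from the same
#' resting initial state, so the result is deterministic given the
#' parameters.
#'
#' @param network an `mra_network`.
#' @param params named parameter vector (the reference point).
#' @param specs list of [perturbation_spec()] objects, or a character
#'   vector of parameter names (10\% central perturbations).
#' @param magnitude,mode defaults applied when `specs` is a character vector.
#' @param control solver control passed to [find_steady_state()].
#' @return object of class `mra_response_table`.
#' @export
run_perturbations <- function(network, params, specs, magnitude = 0.10,
                              mode = "central", control = list()) {
  specs <- as_spec_list(specs, magnitude, mode)
  for (s in specs) {
    if (!s$parameter %in% names(params)) {
      stop_config("perturbation parameter '%s' is not in the parameter set", s$parameter)
    }
    if (params[[s$parameter]] * (1 - abs(s$magnitude)) <= 0) {
      stop_config("perturbation of '%s' would make it non-positive", s$parameter)
    }
  }
  solve1 <- function(p, what) {
    tryCatch(find_steady_state(network, p, control = control),
             error = function(e) {
               stop_numerical("steady-state computation failed for condition '%s': %s",
                              what, conditionMessage(e))
             })
  }
  reference <- solve1(params, "reference")
  conditions <- list()
  for (s in specs) {
    sides <- if (s$mode == "central") c(1, -1) else 1
    for (side in sides) {
      p2 <- params
      p2[[s$parameter]] <- params[[s$parameter]] * (1 + side * s$magnitude)
      id <- paste0(s$parameter, if (side > 0) "+" else "-")
      ss <- solve1(p2, id)
      if (!ss$stable) {
        stop_numerical("condition '%s' converged to an unstable state", id)
      }
      conditions[[id]] <- list(parameter = s$parameter, side = side,
                               magnitude = s$magnitude, mode = s$mode,
                               conc = ss$concentrations)
    }
  }
  structure(list(network_name = network$name,
                 species = species_names(network),
                 observables = observable_species(network),
                 params = params, specs = specs,
                 reference = reference$concentrations,
                 conditions = conditions),
            class = "mra_response_table")
}

#' @export
print.mra_response_table <- function(x, ...) {
  cat(sprintf("<mra_response_table> %s: %d species (%d observable), %d perturbations, %d conditions\n",
              x$network_name, length(x$species), length(x$observables),
              length(x$specs), length(x$conditions)))
  invisible(x)
}

spec_parameters <- function(table) vapply(table$specs, `[[`, "", "parameter")

#' Global response matrix for a choice of weighted outputs
#'
#' Computes `R[i, j] = dln x_i / (dp_j / p_j)`: the log-difference of
#' module output `i` between the perturbed conditions of spec `j`, divided
#' by the fractional parameter change (`2m` central, `m` one-sided).  The
#' MRA system is homogeneous per column, so the choice of denominator
#' cannot change inferred connections.  No steady state is re-solved:
#' changing `weights` just reweighs the stored table.
#'
#' @param table an `mra_response_table` (simulated or read from disk).
#' @param partition an `mra_partition` whose output species are observable
#'   in the table.
#' @param weights named weight vector binding the partition's free slots.
#' @return matrix of class `mra_global_responses` (modules x perturbations)
#'   with the weight vector attached as attribute `"weights"`.
#' @export
global_responses <- function(table, partition, weights = NULL) {
  weights <- resolve_weights(partition, weights)
  out_species <- unique(unlist(lapply(partition$modules, function(m) {
    vapply(m$output, `[[`, "", "species")
  })))
  missing <- setdiff(out_species, table$species)
  if (length(missing)) {
    stop_config("partition output species not in table: %s",
                paste(missing, collapse = ", "))
  }
  x_of <- function(conc) {
    x <- module_outputs(partition, conc, weights)
    if (any(x <= 0)) {
      stop_numerical("module output(s) non-positive (log response undefined): %s",
                     paste(names(x)[x <= 0], collapse = ", "))
    }
    x
  }
  x_ref <- x_of(table$reference)
  params <- spec_parameters(table)
  R <- matrix(NA_real_, nrow = n_modules(partition), ncol = length(table$specs),
              dimnames = list(module_names(partition), params))
  for (j in seq_along(table$specs)) {
    s <- table$specs[[j]]
    up <- table$conditions[[paste0(s$parameter, "+")]]
    if (s$mode == "central") {
      dn <- table$conditions[[paste0(s$parameter, "-")]]
      R[, j] <- (log(x_of(up$conc)) - log(x_of(dn$conc))) / (2 * s$magnitude)
    } else {
      R[, j] <- (log(x_of(up$conc)) - log(x_ref)) / s$magnitude
    }
  }
  structure(R, class = c("mra_global_responses", class(R)), weights = weights)
}

#' Inject multiplicative lognormal measurement noise
#'
#' Every observable concentration in every condition (including the
#' reference) is multiplied by an independent lognormal factor with unit
#' mean and the requested coefficient of variation, mimicking proportional
#' measurement error of quantitative blots.
#'
#' @param table an `mra_response_table`.
#' @param cv coefficient of variation of the noise factor (`cv = 0` returns
#'   the table unchanged).
#' @param seed integer seed; the same seed reproduces the same noised table.
#' @return a new `mra_response_table`.
#' @export
add_noise <- function(table, cv, seed) {
  if (cv < 0) stop_config("cv must be non-negative")
  if (cv == 0) return(table)
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- -sdlog^2 / 2 # unit-mean lognormal
  obs <- table$observables
  with_seed(seed, {
    noise1 <- function(conc) {
      conc[obs] <- conc[obs] * stats::rlnorm(length(obs), meanlog, sdlog)
      conc
    }
    table$reference <- noise1(table$reference)
    table$conditions <- lapply(table$conditions, function(cond) {
      cond$conc <- noise1(cond$conc)
      cond
    })
    table
  })
}
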