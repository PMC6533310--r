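#' Modular partitions and weighted communicating species
#'
#' A partition assigns species to modules and defines each module output
#' (communicating species) as a weighted sum of observable concentrations.
#' A weight slot is either a fixed number (e.g. 1 for the free active form)
#' or the name of a free weight bound at evaluation time; scanning those
#' free weights and nullifying sign-changing connection coefficients is how
#' sequestration-induced connections are detected and removed.
#'
#' @name partition
NULL

#' Define a module
#'
#' @param name module name.
#' @param species character vector of member species.
#' @param output list of output terms; each term is `list(species =, weight =)`
#'   where `weight` is a number (fixed) or a character weight name (free).
#' @return a `module` definition.
#' @export
module_def <- function(name, species, output) {
  for (term in output) {
    if (!is.list(term) || is.null(term$species) || is.null(term$weight)) {
      stop_definition("module '%s': each output term needs species and weight", name)
    }
  }
  structure(list(name = name, species = species, output = output),
            class = "retromra_module")
}

#' Assemble a modular partition
#'
#' @param modules list of [module_def()] objects (order fixes module indices).
#' @param network optional `mra_network` used to validate species references.
#' @return object of class `mra_partition`.
#' @export
mra_partition <- function(modules, network = NULL) {
  nms <- vapply(modules, `[[`, "", "name")
  if (anyDuplicated(nms)) stop_definition("duplicated module names")
  if (!is.null(network)) {
    sp <- species_names(network)
    for (m in modules) {
      bad <- setdiff(c(m$species, vapply(m$output, `[[`, "", "species")), sp)
      if (length(bad)) {
        stop_definition("module '%s' references unknown species: %s",
                        m$name, paste(bad, collapse = ", "))
      }
    }
  }
  for (m in modules) {
    if (!length(m$output)) stop_definition("module '%s' has no output species", m$name)
  }
  structure(list(modules = modules), class = "mra_partition")
}

#' Names of the free weight slots of a partition
#'
#' @param partition an `mra_partition`.
#' @return character vector of weight names (possibly empty).
#' @export
weight_names <- function(partition) {
  w <- unlist(lapply(partition$modules, function(m) {
    vapply(m$output, function(term) {
      if (is.character(term$weight)) term$weight else NA_character_
    }, "")
  }))
  unique(w[!is.na(w)])
}

n_modules <- function(partition) length(partition$modules)

module_names <- function(partition) {
  vapply(partition$modules, `[[`, "", "name")
}

resolve_weights <- function(partition, weights) {
  need <- weight_names(partition)
  if (length(need)) {
    if (is.null(weights) || !all(need %in% names(weights))) {
      stop_config("weights required for slot(s): %s",
                  paste(setdiff(need, names(weights)), collapse = ", "))
    }
    if (any(weights[need] < 0)) stop_config("weights must be non-negative")
  }
  weights
}

#' Evaluate module outputs at a concentration vector
#'
#' @param partition an `mra_partition`.
#' @param conc named concentration vector covering the output species.
#' @param weights named numeric vector binding the free weight slots.
#' @return named vector of module outputs.
#' @export
module_outputs <- function(partition, conc, weights = NULL) {
  weights <- resolve_weights(partition, weights)
  out <- vapply(partition$modules, function(m) {
    sum(vapply(m$output, function(term) {
      w <- if (is.character(term$weight)) weights[[term$weight]] else term$weight
      w * conc[[term$species]]
    }, numeric(1)))
  }, numeric(1))
  stats::setNames(out, module_names(partition))
}

#' @export
print.mra_partition <- function(x, ...) {
  cat(sprintf("<mra_partition> %d modules\n", n_modules(x)))
  for (m in x$modules) {
    terms <- vapply(m$output, function(t) {
      w <- t$weight
      if (is.character(w)) paste0(w, "*", t$species)
      else if (w == 1) t$species
      else paste0(format(w), "*", t$species)
    }, "")
    cat(sprintf("  %s: x = %s\n", m$name, paste(terms, collapse = " + ")))
  }
  invisible(x)
}
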