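#' Solving the MRA system for connection coefficients
#'
#' For each module `i` the MRA equations `sum_k r_ik R_kj = 0` with
#' `r_ii = -1` are solved over `N - 1` perturbations `j` that do not
#' directly affect module `i` (the module insulation condition).  Whether a
#' parameter directly affects a module is declared metadata (preset
#' permissible lists or user declaration); [invariance_check()] validates
#' the declaration empirically, since the governing functions exist only
#' implicitly.
#'
#' @name mra_solver
NULL

# Modules directly affected by a parameter: the declared target list when
# available, else the complement of the permissible lists.
affected_modules <- function(parameter, permissible, direct_targets = NULL) {
  if (!is.null(direct_targets) && parameter %in% names(direct_targets)) {
    return(direct_targets[[parameter]])
  }
  names(permissible)[!vapply(permissible, function(ps) parameter %in% ps, TRUE)]
}

# Can the chosen parameters be matched one-to-one onto the modules they
# must directly affect?  (The canonical MRA design: one perturbation per
# non-self module; two perturbations that both primarily drive the same
# module give a quasi-collinear row system.)
perfect_matching <- function(target_sets, modules) {
  if (!length(modules)) return(TRUE)
  for (k in seq_along(target_sets)) {
    if (modules[1] %in% target_sets[[k]] &&
        perfect_matching(target_sets[-k], modules[-1])) {
      return(TRUE)
    }
  }
  FALSE
}

validate_row_choice <- function(params_j, row, mod_names, permissible,
                                direct_targets = NULL) {
  if (!all(params_j %in% permissible[[row]])) return(FALSE)
  sets <- lapply(params_j, affected_modules, permissible = permissible,
                 direct_targets = direct_targets)
  perfect_matching(sets, setdiff(mod_names, row))
}

#' Select per-row perturbation sets
#'
#' For each module `i`, deterministically selects `N - 1` perturbation
#' specs that are permissible for row `i` (declaration order, preferring
#' specs that extend coverage of the other modules) such that together
#' they directly affect all modules other than `i`.
#'
#' @param partition an `mra_partition` (fixes `N` and module names).
#' @param specs perturbation specs (list or character vector of parameters).
#' @param permissible named list, one character vector of permissible
#'   parameter names per module.
#' @param direct_targets optional named list mapping each parameter to the
#'   modules it directly perturbs; defaults to the complement of the
#'   permissible lists.
#' @return object of class `mra_assignment`: named list of parameter-name
#'   vectors, one per module.
#' @export
assign_perturbations <- function(partition, specs, permissible,
                                 direct_targets = NULL) {
  specs <- as_spec_list(specs)
  spec_params <- vapply(specs, `[[`, "", "parameter")
  mod_names <- module_names(partition)
  n <- length(mod_names)
  if (!all(mod_names %in% names(permissible))) {
    stop_config("permissible lists missing for module(s): %s",
                paste(setdiff(mod_names, names(permissible)), collapse = ", "))
  }
  assignment <- stats::setNames(vector("list", n), mod_names)
  for (row in mod_names) {
    if (n == 1) { assignment[[row]] <- character(0); next }
    cand <- spec_params[spec_params %in% permissible[[row]]]
    need <- setdiff(mod_names, row)
    chosen <- character(0)
    covered <- character(0)
    for (p in cand) { # first pass: extend coverage in declaration order
      if (length(chosen) >= n - 1) break
      gain <- setdiff(intersect(affected_modules(p, permissible, direct_targets),
                                need), covered)
      if (length(gain)) {
        chosen <- c(chosen, p)
        covered <- union(covered, gain)
      }
    }
    for (p in setdiff(cand, chosen)) { # fill remaining slots
      if (length(chosen) >= n - 1) break
      chosen <- c(chosen, p)
    }
    if (length(chosen) < n - 1 || !all(need %in% covered)) {
      stop_config(paste0("row '%s': cannot select %d permissible perturbations ",
                         "covering modules {%s}; candidates were {%s}"),
                  row, n - 1, paste(setdiff(need, covered), collapse = ", "),
                  paste(cand, collapse = ", "))
    }
    assignment[[row]] <- chosen
  }
  structure(assignment, class = "mra_assignment")
}

#' Enumerate alternative valid assignments
#'
#' Starting from the deterministic assignment, varies one row at a time
#' through every valid combination of permissible perturbations for that
#' row (up to `max_per_row` per row).  Useful as input to
#' [invariance_check()].
#'
#' @inheritParams assign_perturbations
#' @param max_per_row cap on alternatives kept per row.
#' @return list of `mra_assignment` objects (the baseline first).
#' @export
enumerate_assignments <- function(partition, specs, permissible,
                                  direct_targets = NULL, max_per_row = 20) {
  specs <- as_spec_list(specs)
  base <- assign_perturbations(partition, specs, permissible, direct_targets)
  spec_params <- vapply(specs, `[[`, "", "parameter")
  mod_names <- module_names(partition)
  n <- length(mod_names)
  out <- list(base)
  if (n == 1) return(out)
  for (row in mod_names) {
    cand <- spec_params[spec_params %in% permissible[[row]]]
    if (length(cand) < n - 1) next
    combos <- utils::combn(cand, n - 1, simplify = FALSE)
    kept <- 0L
    for (cmb in combos) {
      if (kept >= max_per_row) break
      if (identical(sort(cmb), sort(base[[row]]))) next
      if (!validate_row_choice(cmb, row, mod_names, permissible, direct_targets)) next
      alt <- base
      alt[[row]] <- cmb
      out <- c(out, list(alt))
      kept <- kept + 1L
    }
  }
  out
}

#' Solve the MRA linear system
#'
#' Each row `i` of the connection matrix solves
#' `sum_k r_ik R_kj = 0` for all perturbations `j` assigned to the row,
#' with the diagonal fixed at `r_ii = -1`.
#'
#' @param R a global response matrix (modules x perturbations) with
#'   perturbation parameters as column names.
#' @param assignment an `mra_assignment` (or named list of parameter
#'   vectors, one per module row of `R`).
#' @param kappa_max condition-number threshold above which a row is
#'   rejected as ill-conditioned.
#' @param allow_ill keep ill-conditioned rows (flagged) instead of erroring.
#' @return object of class `mra_connection_matrix`: the `N x N` matrix `r`
#'   with attributes `assignment`, `residuals` (per row, max absolute
#'   residual of the MRA equations), `kappa` (per row) and `weights`
#'   (copied from `R` when present).
#' @export
solve_connection_matrix <- function(R, assignment, kappa_max = 1e8, allow_ill = FALSE) {
  mods <- rownames(R)
  n <- length(mods)
  r <- matrix(0, n, n, dimnames = list(mods, mods))
  diag(r) <- -1
  residuals <- stats::setNames(numeric(n), mods)
  kap <- stats::setNames(rep(1, n), mods)
  for (i in seq_len(n)) {
    cols_names <- assignment[[mods[i]]]
    if (n == 1 || !length(cols_names)) {
      if (n > 1) stop_config("row '%s' has no assigned perturbations", mods[i])
      next
    }
    if (length(cols_names) != n - 1) {
      stop_config("row '%s' needs exactly %d perturbations, got %d",
                  mods[i], n - 1, length(cols_names))
    }
    cols <- match(cols_names, colnames(R))
    if (anyNA(cols)) {
      stop_config("row '%s': perturbation(s) %s not in response matrix", mods[i],
                  paste(cols_names[is.na(cols)], collapse = ", "))
    }
    A <- t(R[-i, cols, drop = FALSE])   # A[j, k] = R_kj for k != i
    b <- R[i, cols]
    kap[i] <- kappa(A, exact = TRUE)
    if (!is.finite(kap[i]) || kap[i] > kappa_max) {
      msg <- sprintf("row '%s' ill-conditioned (condition number %.3g)", mods[i], kap[i])
      if (!allow_ill) stop_numerical("%s", msg)
      warning(msg)
    }
    sol <- solve(A, b)
    r[i, -i] <- sol
    residuals[i] <- max(abs(A %*% sol - b))
  }
  structure(r, class = c("mra_connection_matrix", class(r)),
            assignment = assignment, residuals = residuals, kappa = kap,
            weights = attr(R, "weights"))
}

#' @export
print.mra_connection_matrix <- function(x, ...) {
  cat("<mra_connection_matrix>\n")
  print(signif(unclass(x)[, , drop = FALSE], 6))
  asg <- attr(x, "assignment")
  if (!is.null(asg)) {
    for (m in names(asg)) {
      cat(sprintf("  row %s: perturbations {%s}, residual %.2e, kappa %.2g\n",
                  m, paste(asg[[m]], collapse = ", "),
                  attr(x, "residuals")[m], attr(x, "kappa")[m]))
    }
  }
  invisible(x)
}

#' Invariance of the connection matrix across perturbation choices
#'
#' Connection coefficients are properties of the steady state, not of the
#' perturbations used to probe it, *provided* the insulation condition
#' holds for every perturbation used.  This diagnostic solves the MRA
#' system for several alternative assignments and reports the spread of
#' each coefficient: rows whose coefficients move more than `tolerance`
#' violate insulation for at least one of the offered choices.
#'
#' @param table an `mra_response_table`.
#' @param partition an `mra_partition`.
#' @param weights weight vector for the partition's free slots.
#' @param assignments list of at least two `mra_assignment` objects.
#' @param tolerance discrepancy below which a row counts as insulated.
#' @return list with `discrepancy` (N x N matrix of max minus min of each
#'   coefficient across assignments), `insulated` (named logical per row),
#'   `r_list` (connection matrices per assignment), `tolerance`.
#' @export
invariance_check <- function(table, partition, weights = NULL, assignments,
                             tolerance = 1e-6) {
  if (n_modules(partition) > 1 && length(assignments) < 2) {
    stop_config("invariance_check needs at least two alternative assignments")
  }
  R <- global_responses(table, partition, weights)
  r_list <- lapply(assignments, function(a) solve_connection_matrix(R, a))
  arr <- simplify2array(lapply(r_list, unclass))
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1)
  disc <- apply(arr, c(1, 2), function(v) max(v) - min(v))
  dimnames(disc) <- dimnames(r_list[[1]])[1:2]
  insulated <- apply(disc, 1, max) < tolerance
  list(discrepancy = disc, insulated = insulated, r_list = r_list,
       tolerance = tolerance)
}
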