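#' Weight scans, nullifying weights and connection classification
#'
#' The free weights multiply inter-modular complex concentrations inside
#' the module outputs.  Scanning them and watching each connection
#' coefficient distinguishes the two kinds of connection: a coefficient
#' that changes sign along the scan is sequestration-induced (retroactive)
#' and is nullified at the optimal weights, while a coefficient that keeps
#' its sign is regulatory.  All of this reuses one response table; no
#' steady state is ever re-solved.
#'
#' @name weight_analysis
NULL

#' Default weight grid
#'
#' 41 log-spaced points over `[1e-3, 1e3]` plus `a = 0`, covering both the
#' free-form limit (`a -> 0`) and the complex-dominated limit (`a -> Inf`).
#'
#' @return sorted numeric vector of length 42.
#' @export
default_weight_grid <- function() {
  c(0, 10^seq(-3, 3, length.out = 41))
}

# Evaluate the connection matrix at one weight vector; NULL when an output
# goes non-positive (flagged and skipped by callers).
connection_at <- function(table, partition, weights, assignment, kappa_max = 1e8) {
  tryCatch(
    solve_connection_matrix(global_responses(table, partition, weights),
                            assignment, kappa_max = kappa_max),
    retromra_numerical_error = function(e) NULL
  )
}

tie_weights <- function(partition, a) {
  stats::setNames(rep(a, length(weight_names(partition))), weight_names(partition))
}

as_weight_matrix <- function(partition, grid) {
  slots <- weight_names(partition)
  if (!length(slots)) stop_config("partition has no free weight slots to scan")
  if (is.null(dim(grid))) {
    W <- matrix(rep(as.numeric(grid), each = length(slots)),
                ncol = length(slots), byrow = TRUE)
    colnames(W) <- slots
  } else {
    W <- as.matrix(grid)
    if (!all(slots %in% colnames(W))) {
      stop_config("grid must have a column per weight slot: %s",
                  paste(slots, collapse = ", "))
    }
    W <- W[, slots, drop = FALSE]
  }
  if (any(W < 0)) stop_config("weights must be non-negative")
  W
}

#' Scan the weight grid
#'
#' Recomputes outputs, global responses and the connection matrix at every
#' grid point from a single response table, and records sign changes of
#' each off-diagonal coefficient between adjacent grid points.  Values
#' inside the zero band (`zero_tol` times the largest absolute coefficient
#' of the scan) carry no sign information.
#'
#' @param table an `mra_response_table`.
#' @param partition an `mra_partition` with free weight slots.
#' @param assignment an `mra_assignment` for [solve_connection_matrix()].
#' @param grid numeric vector (applied to all slots jointly) or a matrix
#'   with one column per slot; default [default_weight_grid()].
#' @param zero_tol relative zero band for sign detection.
#' @return object of class `mra_weight_scan`: `weights` (grid matrix), `r`
#'   (N x N x grid array, `NA` at skipped points), `ok` (logical), and
#'   `sign_changes` (list per off-diagonal entry of bracketing grid rows).
#' @export
scan_weights <- function(table, partition, assignment, grid = default_weight_grid(),
                         zero_tol = 1e-6) {
  W <- as_weight_matrix(partition, grid)
  G <- nrow(W)
  if (!G) stop_config("empty weight grid")
  mods <- module_names(partition)
  n <- length(mods)
  arr <- array(NA_real_, dim = c(n, n, G), dimnames = list(mods, mods, NULL))
  ok <- logical(G)
  for (g in seq_len(G)) {
    w <- W[g, ]
    r <- connection_at(table, partition, w, assignment)
    if (!is.null(r)) {
      arr[, , g] <- unclass(r)
      ok[g] <- TRUE
    }
  }
  if (!any(ok)) stop_numerical("every grid point failed (outputs non-positive?)")
  band <- zero_tol * max(abs(arr), na.rm = TRUE)
  tied <- length(unique(round(W / pmax(W[, 1], .Machine$double.eps), 12))) <= nrow(W)
  sign_changes <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    v <- arr[i, j, ]
    s <- ifelse(!ok | is.na(v), NA, ifelse(abs(v) <= band, 0, sign(v)))
    idx <- which(!is.na(s) & s != 0)
    brackets <- list()
    if (length(idx) >= 2) {
      flips <- which(s[idx[-1]] * s[idx[-length(idx)]] < 0)
      for (f in flips) {
        brackets <- c(brackets, list(c(idx[f], idx[f + 1])))
      }
    }
    sign_changes[[paste(mods[i], mods[j], sep = "->")]] <- brackets
  }
  structure(list(weights = W, r = arr, ok = ok, band = band,
                 sign_changes = sign_changes, partition = partition,
                 assignment = assignment, tied = tied),
            class = "mra_weight_scan")
}

#' @export
print.mra_weight_scan <- function(x, ...) {
  cat(sprintf("<mra_weight_scan> %d grid points (%d valid), zero band %.2e\n",
              nrow(x$weights), sum(x$ok), x$band))
  nsc <- vapply(x$sign_changes, length, 0L)
  if (any(nsc > 0)) {
    cat("  sign changes:", paste(names(nsc)[nsc > 0], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export a weight scan as tidy data
#'
#' @param scan an `mra_weight_scan`.
#' @return data.frame with one row per (grid point, i, j): weight columns,
#'   module names `i` and `j`, and the coefficient `r`.
#' @export
scan_to_data_frame <- function(scan) {
  mods <- dimnames(scan$r)[[1]]
  out <- list()
  for (g in seq_len(nrow(scan$weights))) {
    if (!scan$ok[g]) next
    for (i in seq_along(mods)) for (j in seq_along(mods)) {
      out[[length(out) + 1]] <- data.frame(
        as.list(scan$weights[g, , drop = TRUE]),
        i = mods[i], j = mods[j], r = scan$r[i, j, g],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

normalize_targets <- function(partition, targets) {
  mods <- module_names(partition)
  lapply(targets, function(t) {
    if (is.character(t)) t <- match(t, mods)
    t <- as.integer(t)
    if (length(t) != 2 || anyNA(t) || t[1] == t[2]) {
      stop_config("each target must be an off-diagonal (i, j) pair")
    }
    t
  })
}

#' Find the weights that nullify target connection coefficients
#'
#' Scalar case (one free weight, one target): bracketed root finding on
#' `a -> r_target(a)`.  Vector case: damped Newton iteration with a
#' numerical Jacobian, seeded from a tied-weight grid scan.  If no sign
#' change exists in the bracket, the scalar case returns a "no nullifying
#' weight" result rather than an error.
#'
#' @param table an `mra_response_table`.
#' @param partition an `mra_partition`.
#' @param assignment an `mra_assignment`.
#' @param targets list of off-diagonal entries to nullify, as `c(i, j)`
#'   index pairs or `c("module_i", "module_j")` name pairs; at most one per
#'   free weight.
#' @param bracket scalar case: interval to search (default from a grid
#'   scan's sign-change bracket).
#' @param tol absolute tolerance on the nullified coefficients.
#' @param zero_tol relative tolerance used to report non-target entries
#'   that also vanish at the solution.
#' @return list with `found` (logical), `weights`, `r` (connection matrix
#'   at the solution), `achieved` (max absolute target coefficient) and
#'   `extra_zeros` (non-target off-diagonal entries that are also zero at
#'   the solution, relative to the largest coefficient).
#' @export
find_a_opt <- function(table, partition, assignment, targets,
                       bracket = NULL, tol = 1e-9, zero_tol = 1e-6) {
  slots <- weight_names(partition)
  targets <- normalize_targets(partition, targets)
  if (length(targets) > length(slots)) {
    stop_config("more targets (%d) than free weights (%d)",
                length(targets), length(slots))
  }
  target_vals <- function(r) {
    vapply(targets, function(t) unclass(r)[t[1], t[2]], numeric(1))
  }
  r_at <- function(w) {
    r <- connection_at(table, partition, w, assignment)
    if (is.null(r)) stop_numerical("connection matrix undefined at weights (%s)",
                                   paste(signif(w, 4), collapse = ", "))
    r
  }
  done <- function(w) {
    r <- r_at(w)
    mods <- module_names(partition)
    ok_idx <- vapply(targets, function(t) paste(t, collapse = ","), "")
    extra <- character(0)
    rmax <- max(abs(unclass(r)))
    for (i in seq_along(mods)) for (j in seq_along(mods)) {
      if (i == j || paste(c(i, j), collapse = ",") %in% ok_idx) next
      if (abs(unclass(r)[i, j]) <= zero_tol * rmax) {
        extra <- c(extra, paste(mods[i], mods[j], sep = "->"))
      }
    }
    list(found = TRUE, weights = w, r = r,
         achieved = max(abs(target_vals(r))), extra_zeros = extra)
  }

  if (length(slots) == 1 && length(targets) == 1) {
    f <- function(a) {
      target_vals(r_at(stats::setNames(a, slots)))
    }
    if (is.null(bracket)) {
      grid <- default_weight_grid()
      vals <- vapply(grid, function(a) tryCatch(f(a), error = function(e) NA_real_),
                     numeric(1))
      idx <- which(!is.na(vals))
      flip <- which(vals[idx[-1]] * vals[idx[-length(idx)]] < 0)
      if (!length(flip)) {
        return(list(found = FALSE, weights = NULL, r = NULL, achieved = NA_real_,
                    extra_zeros = character(0),
                    reason = "no sign change over the default grid"))
      }
      bracket <- grid[c(idx[flip[1]], idx[flip[1] + 1])]
    }
    fl <- f(bracket[1]); fu <- f(bracket[2])
    if (is.na(fl) || is.na(fu) || fl * fu > 0) {
      return(list(found = FALSE, weights = NULL, r = NULL, achieved = NA_real_,
                  extra_zeros = character(0),
                  reason = "no sign change inside the bracket"))
    }
    root <- stats::uniroot(f, interval = bracket, tol = .Machine$double.eps^0.9)
    return(done(stats::setNames(root$root, slots)))
  }

  # vector case: seed from a tied scan, then damped Newton
  if (length(targets) < length(slots)) {
    stop_config("vector case requires one target per free weight (%d slots, %d targets)",
                length(slots), length(targets))
  }
  grid <- default_weight_grid()[-1] # strictly positive for tied seeding
  ssq <- vapply(grid, function(a) {
    r <- connection_at(table, partition, tie_weights(partition, a), assignment)
    if (is.null(r)) return(NA_real_)
    sum(target_vals(r)^2)
  }, numeric(1))
  if (all(is.na(ssq))) stop_numerical("tied seeding scan failed at every grid point")
  a0 <- grid[which.min(ssq)]
  w <- tie_weights(partition, a0)
  f_vec <- function(w) target_vals(r_at(w))
  fw <- f_vec(w)
  for (it in 1:60) {
    if (max(abs(fw)) <= tol) break
    J <- matrix(0, length(targets), length(slots))
    for (k in seq_along(slots)) {
      h <- 1e-6 * max(abs(w[k]), 1e-3)
      wp <- w; wp[k] <- w[k] + h
      wm <- w; wm[k] <- max(w[k] - h, 0)
      J[, k] <- (f_vec(wp) - f_vec(wm)) / (wp[k] - wm[k])
    }
    step <- tryCatch(solve(J, -fw), error = function(e) NULL)
    if (is.null(step)) {
      stop_numerical("singular Jacobian in multivariate weight search at (%s)",
                     paste(signif(w, 4), collapse = ", "))
    }
    lam <- 1
    repeat {
      w_try <- pmax(w + lam * step, 0)
      f_try <- tryCatch(f_vec(w_try), error = function(e) NULL)
      if (!is.null(f_try) && max(abs(f_try)) < max(abs(fw))) {
        w <- w_try; fw <- f_try; break
      }
      lam <- lam / 2
      if (lam < 1e-10) {
        stop_numerical("multivariate weight search stalled at (%s), residual %.3e",
                       paste(signif(w, 4), collapse = ", "), max(abs(fw)))
      }
    }
  }
  if (max(abs(fw)) > tol) {
    stop_numerical("multivariate weight search did not converge: residual %.3e", max(abs(fw)))
  }
  done(w)
}

#' Classify connections from a weight scan
#'
#' Sign change across the scanned range implies a sequestration-induced
#' connection; a consistently nonzero single sign implies a regulatory
#' connection; a coefficient inside the zero band everywhere is absent.
#' Entries with multiple sign changes are labelled ambiguous, never forced
#' into a class.
#'
#' @param scan an `mra_weight_scan` covering small and large weights.
#' @param tolerance absolute zero band; defaults to the scan's band.
#' @return object of class `mra_classification`: `labels` (N x N character
#'   matrix, diagonal `NA`) and `evidence` (per-entry list with the number
#'   of sign changes, bracketing weights, and max absolute coefficient).
#' @export
classify_connections <- function(scan, tolerance = NULL) {
  band <- tolerance %||% scan$band
  mods <- dimnames(scan$r)[[1]]
  n <- length(mods)
  labels <- matrix(NA_character_, n, n, dimnames = list(mods, mods))
  evidence <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    v <- scan$r[i, j, scan$ok]
    key <- paste(mods[i], mods[j], sep = "->")
    nflips <- length(scan$sign_changes[[key]])
    maxabs <- max(abs(v))
    labels[i, j] <- if (maxabs <= band) "absent"
      else if (nflips == 0) "regulatory"
      else if (nflips == 1) "sequestration"
      else "ambiguous"
    brack <- lapply(scan$sign_changes[[key]], function(b) scan$weights[b, 1])
    evidence[[key]] <- list(sign_changes = nflips, max_abs = maxabs,
                            brackets = brack)
  }
  structure(list(labels = labels, evidence = evidence, band = band),
            class = "mra_classification")
}

#' @export
print.mra_classification <- function(x, ...) {
  cat("<mra_classification>\n")
  print(x$labels)
  invisible(x)
}

#' Locate the feedback gain separating the two classification regimes
#'
#' For the three-tier cascade with a tier-3-to-tier-2 feedback, the
#' feedback connection `r_23` classifies as regulatory when the gain `u2`
#' exceeds a parameter-dependent threshold and as sequestration-induced
#' below it.  This helper brackets that threshold empirically by bisection
#' in log-gain, holding the cascade kinetics fixed (the preset's frozen
#' defaults) and varying only `u2`.  No claim is made about the
#' threshold's value; it depends on the kinetic regime.
#'
#' @param k_fb feedback concentration scale.
#' @param bracket gains assumed to lie on opposite sides of the threshold.
#' @param rel_tol relative width of the final bracket.
#' @param grid weight grid used for classification (reduced by default).
#' @return list with `u2` (geometric midpoint of the final bracket),
#'   `bracket`, the classifications at the input endpoints, and `n_eval`.
#'   If both endpoints classify alike, `u2` is `NA` and the bracket is
#'   returned unchanged.
#' @export
find_feedback_threshold <- function(k_fb = 1, bracket = c(1.75, 50.5),
                                    rel_tol = 0.1,
                                    grid = c(0, 10^seq(-2, 2, length.out = 11))) {
  preset <- build_cascade3("3to2", u = min(bracket), k_fb = k_fb)
  params <- preset$params
  part <- preset_partition(preset, "asymmetric")
  perm <- preset_permissible(preset, "asymmetric")
  dt <- preset_direct_targets(preset, "asymmetric")
  specs <- c("X1_tot", "X2_tot", "X3_tot")
  asg <- assign_perturbations(part, specs, perm, dt)
  n_eval <- 0L
  class_at <- function(u2) {
    n_eval <<- n_eval + 1L
    params[["u2"]] <- u2
    tab <- run_perturbations(preset$network, params, specs)
    cls <- classify_connections(scan_weights(tab, part, asg, grid = grid))
    cls$labels["X2", "X3"]
  }
  lo <- min(bracket); hi <- max(bracket)
  c_lo <- class_at(lo); c_hi <- class_at(hi)
  if (identical(c_lo, c_hi)) {
    return(list(u2 = NA_real_, bracket = c(lo, hi), lower_class = c_lo,
                upper_class = c_hi, n_eval = n_eval))
  }
  while ((hi - lo) / hi > rel_tol) {
    mid <- sqrt(lo * hi)
    if (identical(class_at(mid), c_hi)) hi <- mid else lo <- mid
  }
  list(u2 = sqrt(lo * hi), bracket = c(lo, hi), lower_class = c_lo,
       upper_class = c_hi, n_eval = n_eval)
}

#' Minimize the sum of squares of sequestration-induced coefficients
#'
#' When no single weight vector nullifies every sequestration-induced
#' connection exactly (hub-like topologies), minimizing their sum of
#' squares over a bounded weight box minimizes the discrepancy between
#' connection matrices inferred from alternative perturbations.
#' Deterministic multi-start L-BFGS-B (box corners, centre, and the best
#' point of a coarse grid).
#'
#' @param table an `mra_response_table`.
#' @param partition an `mra_partition`.
#' @param assignment an `mra_assignment`.
#' @param entries off-diagonal entries classified as sequestration-induced
#'   (same format as `targets` of [find_a_opt()]).
#' @param bounds length-2 numeric, the weight box applied to every slot.
#' @return list with `weights`, `ssq`, `r` (connection matrix at the
#'   minimizer) and `starts` (objective per start, for diagnostics).
#' @export
minimize_sequestration_ssq <- function(table, partition, assignment, entries,
                                       bounds = c(0, 10)) {
  slots <- weight_names(partition)
  targets <- normalize_targets(partition, entries)
  obj <- function(wv) {
    r <- connection_at(table, partition, stats::setNames(wv, slots), assignment)
    if (is.null(r)) return(1e6)
    sum(vapply(targets, function(t) unclass(r)[t[1], t[2]], numeric(1))^2)
  }
  lo <- rep(bounds[1], length(slots)); hi <- rep(bounds[2], length(slots))
  coarse <- seq(bounds[1], bounds[2], length.out = 11)
  grid_best <- coarse[which.min(vapply(coarse, function(a) obj(rep(a, length(slots))),
                                       numeric(1)))]
  starts <- list(rep(mean(bounds), length(slots)),
                 lo + 1e-3 * (hi - lo), hi - 1e-3 * (hi - lo),
                 rep(grid_best, length(slots)))
  best <- NULL
  vals <- numeric(0)
  for (s in starts) {
    fit <- stats::optim(s, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                        control = list(factr = 1e4, maxit = 500))
    vals <- c(vals, fit$value)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop_numerical("ssq minimization failed from every start")
  w <- stats::setNames(best$par, slots)
  list(weights = w, ssq = best$value,
       r = connection_at(table, partition, w, assignment), starts = vals)
}
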