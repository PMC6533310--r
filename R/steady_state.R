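#' Stable steady states of a reaction network
#'
#' Steady states are computed in two phases: stiff ODE integration
#' ([deSolve::lsoda()]) from a physiological resting state (all protein in
#' the free inactive forms, i.e. all independent species at zero) drives the
#' system onto the stable branch, and damped Newton iteration on the reduced
#' (independent-species) system then polishes the root to tight residuals.
#' Tight residuals matter because connection coefficients are ratios of
#' small finite differences of these states.
#'
#' @name steady_state
NULL

default_ss_control <- function() {
  list(rtol = 1e-10, atol = 1e-12,     # integration tolerances
       polish_tol = 1e-11,             # residual target, scaled by state norm
       stab_eps = 1e-9,                # stability margin for Re(eigenvalues)
       t_max = 1e9, t_start = 100)
}

# numeric Jacobian of the reduced rhs by central differences
reduced_jacobian <- function(network, z, params, h_rel = 1e-6) {
  n <- length(z)
  J <- matrix(0, n, n, dimnames = list(names(z), names(z)))
  for (j in seq_len(n)) {
    h <- h_rel * max(abs(z[j]), 1e-6)
    zp <- z; zp[j] <- z[j] + h
    zm <- z; zm[j] <- max(z[j] - h, 0)
    J[, j] <- (network_rhs(network, zp, params) - network_rhs(network, zm, params)) /
      (zp[j] - zm[j])
  }
  J
}

#' Find a stable steady state
#'
#' @param network an `mra_network`.
#' @param params named vector of strictly positive parameters (rate
#'   constants and conserved totals).
#' @param init optional named initial state over the independent species (or
#'   a full state, which is projected).  Default: all protein in free
#'   inactive forms.
#' @param control optional list overriding solver tolerances (`rtol`,
#'   `atol`, `polish_tol`, `stab_eps`, `t_max`).
#' @return object of class `mra_steady_state`: fields `concentrations` (all
#'   species), `state` (independent species), `residual_norm`, `stable`,
#'   `eigenvalues`, `params`.
#' @export
find_steady_state <- function(network, params, init = NULL, control = list()) {
  ctl <- utils::modifyList(default_ss_control(), control)
  if (any(unlist(params) < 0)) {
    stop_domain("parameters must be non-negative")
  }
  for (tn in network$independent$totals) {
    if (get_param(params, tn) <= 0) stop_domain("total '%s' must be strictly positive", tn)
  }
  idx <- network$independent
  z <- stats::setNames(numeric(length(idx$independent)), idx$independent)
  if (!is.null(init)) {
    init <- init[names(init) %in% idx$independent]
    z[names(init)] <- init
  }
  rhs_ode <- function(t, y, parms) {
    names(y) <- idx$independent
    y[y < 0] <- 0
    list(unname(network_rhs(network, y, params)))
  }
  scale_ref <- max(unlist(lapply(idx$totals, get_param, params = params)), 1)
  res_ok <- function(z) {
    r <- network_rhs(network, z, params)
    max(abs(r)) <= ctl$polish_tol * max(1, scale_ref)
  }
  # phase 1: integrate until the flow has decayed
  t_end <- ctl$t_start
  repeat {
    sol <- deSolve::lsoda(y = unname(z), times = c(0, t_end), func = rhs_ode,
                          parms = NULL, rtol = ctl$rtol, atol = ctl$atol)
    if (attr(sol, "istate")[1] < 0) {
      stop_numerical("ODE integration failed before reaching a steady state (t = %g)", t_end)
    }
    z_new <- stats::setNames(pmax(sol[nrow(sol), -1], 0), idx$independent)
    drift <- max(abs(network_rhs(network, z_new, params)))
    z <- z_new
    if (drift <= 1e-6 * max(1, scale_ref) || t_end >= ctl$t_max) break
    t_end <- t_end * 100
  }
  # phase 2: damped Newton polish on the reduced system
  converged <- FALSE
  for (it in 1:50) {
    f <- network_rhs(network, z, params)
    if (max(abs(f)) <= ctl$polish_tol * max(1, scale_ref)) { converged <- TRUE; break }
    J <- reduced_jacobian(network, z, params)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      z_try <- pmax(z + lam * step, 0)
      f_try <- tryCatch(network_rhs(network, z_try, params), error = function(e) NULL)
      if (!is.null(f_try) && max(abs(f_try)) < max(abs(f))) { z <- z_try; break }
      lam <- lam / 2
      if (lam < 1e-8) break
    }
    if (lam < 1e-8) break
  }
  f <- network_rhs(network, z, params)
  resid <- max(abs(f))
  if (!converged && resid > 1e3 * ctl$polish_tol * max(1, scale_ref)) {
    stop_numerical("steady-state solve did not converge (residual %.3e after integration to t = %g)",
                   resid, t_end)
  }
  J <- reduced_jacobian(network, z, params)
  ev <- eigen(J, only.values = TRUE)$values
  stable <- max(Re(ev)) < -ctl$stab_eps
  if (!stable) {
    warning(sprintf("steady state flagged unstable: max Re(eigenvalue) = %.3e", max(Re(ev))))
  }
  conc <- reconstruct_state(network, z, params)
  # conservation check
  for (law in network$conservation) {
    lhs <- sum(law$coef * conc[names(law$coef)])
    tot <- get_param(params, law$total)
    if (abs(lhs - tot) > 1e-8 * max(tot, 1e-12)) {
      stop_numerical("conservation law '%s' violated at steady state (%.3e vs %.3e)",
                     law$total, lhs, tot)
    }
  }
  structure(list(concentrations = conc, state = z, residual_norm = resid,
                 stable = stable, eigenvalues = ev, params = params),
            class = "mra_steady_state")
}

#' @export
print.mra_steady_state <- function(x, ...) {
  cat(sprintf("<mra_steady_state> residual %.2e, %s\n", x$residual_norm,
              if (x$stable) "stable" else "UNSTABLE"))
  print(signif(x$concentrations, 6))
  invisible(x)
}
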