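# Shared fixtures and independent oracles.  Expensive objects (presets,
# response tables) are computed once per test run and memoised here.

fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fixtures[[key]])) fixtures[[key]] <- force(expr)
  fixtures[[key]]
}

mek_preset <- function() memo("mek", build_mek_erk())

# reference response table: 10% central perturbations of the two totals
mek_table <- function() {
  memo("mek_table", {
    p <- mek_preset()
    run_perturbations(p$network, p$params, c("MEK_tot", "ERK_tot"))
  })
}

mek_assignment <- function(template = "asymmetric") {
  p <- mek_preset()
  assign_perturbations(preset_partition(p, template), c("MEK_tot", "ERK_tot"),
                       preset_permissible(p, template),
                       preset_direct_targets(p, template))
}

cascade_case <- function(feedback = "none", u = 2, k_fb = 1,
                         template = "asymmetric") {
  key <- paste("cascade", feedback, u, k_fb, template, sep = "|")
  memo(key, {
    p <- build_cascade3(feedback, u = u, k_fb = k_fb)
    specs <- c("X1_tot", "X2_tot", "X3_tot")
    part <- preset_partition(p, template)
    list(preset = p, partition = part,
         table = run_perturbations(p$network, p$params, specs),
         assignment = assign_perturbations(part, specs,
                                           preset_permissible(p, template),
                                           preset_direct_targets(p, template)))
  })
}

# A + B -> C, no conservation declared
abc_network <- function() {
  mra_network(
    list(species("A"), species("B"), species("C")),
    list(reaction(c("A", "B"), "C", "k")),
    name = "abc")
}

# open system: synthesis and first-order degradation of every species
open_network <- function() {
  mra_network(
    list(species("A"), species("B")),
    list(reaction(character(0), "A", "ks_a"),
         reaction("A", character(0), "kd_a"),
         reaction(c("A"), c("A", "B"), "ks_b"),
         reaction("B", character(0), "kd_b")),
    name = "open")
}

# random small mass-action network (integer stoichiometry, no declared laws)
random_network <- function(n_species = 6, n_reactions = 7) {
  sp_names <- paste0("S", seq_len(n_species))
  rx <- lapply(seq_len(n_reactions), function(i) {
    nr <- sample(1:2, 1); np <- sample(1:2, 1)
    reaction(sample(sp_names, nr), sample(sp_names, np), paste0("k", i))
  })
  mra_network(lapply(sp_names, species), rx, name = "random")
}

# -------------------------------------------------------------- oracles

# SVD-based left null space (independent of the package's exact rational
# elimination): returns basis matrix (rows are vectors) and its dimension.
svd_left_null <- function(S, tol = 1e-10) {
  n <- nrow(S)
  sv <- svd(t(S), nu = 0, nv = n)
  d <- c(sv$d, rep(0, n - length(sv$d)))
  keep <- d < tol * max(d, 1)
  t(sv$v[, keep, drop = FALSE])
}

# Implicit-function-theorem sensitivity oracle: log-responses of module
# outputs to a fractional parameter change, from Jacobians at the reference
# steady state (no perturbed steady states involved).
ift_responses <- function(network, params, parameters, partition, weights) {
  ss <- find_steady_state(network, params)
  z <- ss$state
  indep <- names(z)
  f_red <- function(zv) {
    unname(network_rhs(network, stats::setNames(pmax(zv, 0), indep), params))
  }
  J <- pracma::jacobian(f_red, unname(z))
  full_of <- function(zv, pv) {
    reconstruct_state(network, stats::setNames(zv, indep), pv)
  }
  x_ref <- module_outputs(partition, ss$concentrations, weights)
  out <- matrix(NA_real_, nrow = length(partition$modules),
                ncol = length(parameters),
                dimnames = list(vapply(partition$modules, `[[`, "", "name"),
                                parameters))
  for (pj in parameters) {
    h <- 1e-7 * params[[pj]]
    pp <- params; pp[[pj]] <- params[[pj]] + h
    pm <- params; pm[[pj]] <- params[[pj]] - h
    dfdp <- (unname(network_rhs(network, z, pp)) -
             unname(network_rhs(network, z, pm))) / (2 * h)
    dz <- -solve(J, dfdp)
    dx <- (module_outputs(partition, full_of(unname(z) + h * dz, pp), weights) -
           module_outputs(partition, full_of(unname(z) - h * dz, pm), weights)) / (2 * h)
    out[, pj] <- params[[pj]] * dx / x_ref
  }
  out
}
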