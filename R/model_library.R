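#' Benchmark model presets
#'
#' Ready-built networks with modular partitions, weighted output templates,
#' permissible-perturbation metadata and documented default parameters.
#' Default kinetic parameters are not literature values: they are drawn by
#' [sample_params()] with seed 0 in the strong-sequestration regime and
#' frozen into the preset, because the claims the package tests are
#' parameter-regime properties rather than single-number properties.
#'
#' @name model_library
NULL

.preset_cache <- new.env(parent = emptyenv())

new_preset <- function(name, network, partitions, default_partition,
                       permissible, notes, sampler_ranges,
                       direct_targets = NULL) {
  structure(list(name = name, network = network, partitions = partitions,
                 default_partition = default_partition,
                 permissible = permissible, direct_targets = direct_targets,
                 notes = notes, sampler_ranges = sampler_ranges,
                 params = NULL, seed_used = NA),
            class = "mra_preset")
}

#' @export
print.mra_preset <- function(x, ...) {
  cat(sprintf("<mra_preset> %s\n", x$name))
  print(x$network)
  cat(sprintf("  templates: %s (default %s)\n",
              paste(names(x$partitions), collapse = ", "), x$default_partition))
  cat(sprintf("  %s\n", x$notes))
  invisible(x)
}

#' Get a partition template from a preset
#'
#' @param preset an `mra_preset`.
#' @param template template name (`"asymmetric"`, `"symmetric"`, `"total"`);
#'   default is the preset's default template.
#' @return an `mra_partition`.
#' @export
preset_partition <- function(preset, template = NULL) {
  template <- template %||% preset$default_partition
  if (!template %in% names(preset$partitions)) {
    stop_config("unknown template '%s' (have: %s)", template,
                paste(names(preset$partitions), collapse = ", "))
  }
  preset$partitions[[template]]
}

#' Permissible perturbation parameters of a preset
#'
#' Parameters declared not to directly affect each module's governing
#' function for the given output template (for weighted templates, the
#' declaration holds at the nullifying weights).  This is metadata, not an
#' inference: [invariance_check()] is the empirical validator.
#'
#' @param preset an `mra_preset`.
#' @param template output template name.
#' @return named list, one character vector of parameter names per module.
#' @export
preset_permissible <- function(preset, template = NULL) {
  template <- template %||% preset$default_partition
  perm <- preset$permissible[[template]]
  if (is.null(perm)) stop_config("no permissible-parameter metadata for template '%s'", template)
  perm
}

#' Declared direct targets of each perturbation parameter
#'
#' Which modules each parameter directly perturbs, for the given output
#' template.  Used to keep perturbation assignments in the canonical MRA
#' design (one perturbation primarily driving each non-self module).
#'
#' @inheritParams preset_permissible
#' @return named list, parameter name to character vector of module names.
#' @export
preset_direct_targets <- function(preset, template = NULL) {
  template <- template %||% preset$default_partition
  preset$direct_targets[[template]]
}

## ---------------------------------------------------------------- MEK/ERK

mek_erk_skeleton <- function() {
  C1 <- "ppMEK..ERK"; C2 <- "pERK..PTP"
  sp <- list(
    species("MEK", "free_inactive", module = "MEK"),
    species("ppMEK", "free_active", module = "MEK"),
    species("ERK", "free_inactive", module = "ERK"),
    species("pERK", "free_active", module = "ERK"),
    species("PTP", "free_inactive", module = "ERK"),
    species(C1, "complex", of = c("ppMEK", "ERK"), module = "MEK"),
    species(C2, "complex", of = c("pERK", "PTP"), module = "ERK")
  )
  rx <- list(
    reaction("MEK", "ppMEK", "k1"),
    reaction("ppMEK", "MEK", "k2"),
    reaction(c("ppMEK", "ERK"), C1, "k3_on"),
    reaction(C1, c("ppMEK", "ERK"), "k3_off"),
    reaction(C1, c("ppMEK", "pERK"), "k4"),
    reaction(c("pERK", "PTP"), C2, "k5_on"),
    reaction(C2, c("pERK", "PTP"), "k5_off"),
    reaction(C2, c("ERK", "PTP"), "k6")
  )
  laws <- list(
    conservation_law(c(MEK = 1, ppMEK = 1, "ppMEK..ERK" = 1), "MEK_tot"),
    conservation_law(c(ERK = 1, "ppMEK..ERK" = 1, pERK = 1, "pERK..PTP" = 1), "ERK_tot"),
    conservation_law(c(PTP = 1, "pERK..PTP" = 1), "PTP_tot")
  )
  net <- mra_network(sp, rx, laws, name = "mek_erk")
  mek_members <- c("MEK", "ppMEK", C1)
  erk_members <- c("ERK", "pERK", "PTP", C2)
  term <- function(s, w) list(species = s, weight = w)
  partitions <- list(
    total = mra_partition(list(
      module_def("MEK", mek_members, list(term("ppMEK", 1), term(C1, 1))),
      module_def("ERK", erk_members, list(term("pERK", 1), term(C2, 1)))
    ), net),
    asymmetric = mra_partition(list(
      module_def("MEK", mek_members, list(term("ppMEK", 1), term(C1, "a"))),
      module_def("ERK", erk_members, list(term("pERK", 1), term(C2, 1)))
    ), net),
    symmetric = mra_partition(list(
      module_def("MEK", mek_members, list(term("ppMEK", 1), term(C1, "a"))),
      module_def("ERK", erk_members, list(term("pERK", 1), term(C2, 1), term(C1, "a")))
    ), net)
  )
  weighted_perm <- list(
    MEK = c("ERK_tot", "PTP_tot", "k3_on", "k3_off", "k4", "k5_on", "k5_off", "k6"),
    ERK = c("MEK_tot")
  )
  permissible <- list(
    total = list(MEK = c("PTP_tot", "k5_on", "k5_off", "k6"),
                 ERK = c("MEK_tot", "k1", "k2")),
    asymmetric = weighted_perm,
    symmetric = weighted_perm
  )
  # which modules each parameter directly perturbs, per output choice
  weighted_targets <- c(
    list(MEK_tot = "MEK", k1 = c("MEK", "ERK"), k2 = c("MEK", "ERK")),
    stats::setNames(rep(list("ERK"), 8),
                    c("ERK_tot", "PTP_tot", "k3_on", "k3_off", "k4",
                      "k5_on", "k5_off", "k6")))
  total_targets <- c(
    list(MEK_tot = "MEK", k1 = "MEK", k2 = "MEK"),
    stats::setNames(rep(list(c("MEK", "ERK")), 4),
                    c("ERK_tot", "k3_on", "k3_off", "k4")),
    stats::setNames(rep(list("ERK"), 4),
                    c("PTP_tot", "k5_on", "k5_off", "k6")))
  direct_targets <- list(total = total_targets,
                         asymmetric = weighted_targets,
                         symmetric = weighted_targets)
  ranges <- function(level) {
    on3 <- switch(level, strong = c(5, 50), moderate = c(0.5, 5),
                  negligible = c(0.002, 0.02))
    off3 <- switch(level, strong = c(0.05, 0.5), moderate = c(0.1, 1),
                   negligible = c(0.5, 5))
    list(MEK_tot = c(0.5, 3), ERK_tot = c(0.5, 3), PTP_tot = c(0.5, 3),
         k1 = c(0.2, 2), k2 = c(0.2, 2),
         k3_on = on3, k3_off = off3, k4 = c(0.2, 2),
         k5_on = c(1, 10), k5_off = c(0.1, 1), k6 = c(0.2, 2))
  }
  new_preset(
    name = "mek_erk", network = net, partitions = partitions,
    default_partition = "asymmetric", permissible = permissible,
    notes = paste("Two-module MEK/ERK cascade with explicit ppMEK..ERK and",
                  "pERK..PTP complexes; first-order ppMEK dephosphorylation;",
                  "kinetic defaults are frozen draws, not literature values."),
    sampler_ranges = ranges, direct_targets = direct_targets
  )
}

#' Build the two-module MEK/ERK preset
#'
#' Seven species (four linearly independent), mass-action kinetics, two
#' modules.  The MEK module output is `[ppMEK] + a*[ppMEK..ERK]`; the ERK
#' module output is `[pERK] + [pERK..PTP]` (template `"asymmetric"`), with
#' `a` additionally added to the ERK output in template `"symmetric"` and
#' fixed at 1 in template `"total"`.
#'
#' @return an `mra_preset` with frozen default parameters
#'   (`sample_params(seed = 0, level = "strong")`).
#' @export
build_mek_erk <- function() {
  key <- "mek_erk"
  if (!is.null(.preset_cache[[key]])) return(.preset_cache[[key]])
  preset <- mek_erk_skeleton()
  preset$params <- sample_params(preset, seed = 0, level = "strong")
  preset$seed_used <- 0L
  .preset_cache[[key]] <- preset
  preset
}

## ------------------------------------------------------------- 3-tier cascade

cascade3_skeleton <- function(feedback, u, k_fb) {
  C12 <- "pX1..X2"; C23 <- "pX2..X3"
  sp <- list(
    species("X1", "free_inactive", module = "X1"),
    species("pX1", "free_active", module = "X1"),
    species("X2", "free_inactive", module = "X2"),
    species("pX2", "free_active", module = "X2"),
    species("X3", "free_inactive", module = "X3"),
    species("pX3", "free_active", module = "X3"),
    species(C12, "complex", of = c("pX1", "X2"), module = "X1"),
    species(C23, "complex", of = c("pX2", "X3"), module = "X2")
  )
  mod1 <- if (feedback == "3to1") regulatory_multiplier("pX3", "u1", "k9") else NULL
  mod2 <- if (feedback == "3to2") regulatory_multiplier("pX3", "u2", "k10") else NULL
  rx <- list(
    reaction("X1", "pX1", "k1", modifier = mod1),
    reaction("pX1", "X1", "k2"),
    reaction(c("pX1", "X2"), C12, "k3_on", modifier = mod2),
    reaction(C12, c("pX1", "X2"), "k3_off"),
    reaction(C12, c("pX1", "pX2"), "k4"),
    reaction("pX2", "X2", "k5"),
    reaction(c("pX2", "X3"), C23, "k6_on"),
    reaction(C23, c("pX2", "X3"), "k6_off"),
    reaction(C23, c("pX2", "pX3"), "k7"),
    reaction("pX3", "X3", "k8")
  )
  laws <- list(
    conservation_law(stats::setNames(c(1, 1, 1), c("X1", "pX1", C12)), "X1_tot"),
    conservation_law(stats::setNames(c(1, 1, 1, 1), c("X2", "pX2", C12, C23)), "X2_tot"),
    conservation_law(stats::setNames(c(1, 1, 1), c("X3", "pX3", C23)), "X3_tot")
  )
  net <- mra_network(sp, rx, laws, name = paste0("cascade3_", feedback))
  term <- function(s, w) list(species = s, weight = w)
  m1 <- c("X1", "pX1", C12); m2 <- c("X2", "pX2", C23); m3 <- c("X3", "pX3")
  partitions <- list(
    total = mra_partition(list(
      module_def("X1", m1, list(term("pX1", 1), term(C12, 1))),
      module_def("X2", m2, list(term("pX2", 1), term(C23, 1))),
      module_def("X3", m3, list(term("pX3", 1)))
    ), net),
    asymmetric = mra_partition(list(
      module_def("X1", m1, list(term("pX1", 1), term(C12, "a1"))),
      module_def("X2", m2, list(term("pX2", 1), term(C23, "a2"))),
      module_def("X3", m3, list(term("pX3", 1)))
    ), net),
    symmetric = mra_partition(list(
      module_def("X1", m1, list(term("pX1", 1), term(C12, "a1"))),
      module_def("X2", m2, list(term("pX2", 1), term(C12, "a1"), term(C23, "a2"))),
      module_def("X3", m3, list(term("pX3", 1), term(C23, "a2")))
    ), net)
  )
  totals_perm <- list(X1 = c("X2_tot", "X3_tot"),
                      X2 = c("X1_tot", "X3_tot"),
                      X3 = c("X1_tot", "X2_tot"))
  weighted_perm <- totals_perm
  weighted_perm$X1 <- c(weighted_perm$X1, "k5", "k8")
  permissible <- list(total = totals_perm, asymmetric = weighted_perm,
                      symmetric = weighted_perm)
  weighted_targets <- list(
    X1_tot = "X1", k1 = "X1", k2 = "X1", u1 = "X1", k9 = "X1",
    X2_tot = "X2", k3_on = "X2", k3_off = "X2", k4 = "X2", k5 = "X2",
    u2 = "X2", k10 = "X2",
    X3_tot = "X3", k6_on = c("X2", "X3"), k6_off = c("X2", "X3"),
    k7 = c("X2", "X3"), k8 = "X3")
  total_targets <- weighted_targets
  total_targets[c("k3_on", "k3_off", "k4")] <- list(c("X1", "X2"))
  direct_targets <- list(total = total_targets,
                         asymmetric = weighted_targets,
                         symmetric = weighted_targets)
  # Tier abundances are graded (scarce upstream activator, large substrate
  # pools) so that each kinase is scarcer than its substrate: this yields
  # strong retroactive sequestration of the scarce enzymes while leaving
  # free substrate available, which keeps the non-competitive regulatory
  # multiplier in its responsive (unsaturated) range.
  ranges <- function(level) {
    on12 <- switch(level, strong = c(0.3, 3), moderate = c(0.1, 1),
                   negligible = c(0.002, 0.02))
    on23 <- switch(level, strong = c(0.1, 1), moderate = c(0.05, 0.5),
                   negligible = c(0.002, 0.02))
    off <- switch(level, strong = c(0.05, 0.5), moderate = c(0.1, 1),
                  negligible = c(0.5, 5))
    list(X1_tot = c(0.3, 1), X2_tot = c(3, 6), X3_tot = c(1, 3),
         k1 = c(0.2, 2), k2 = c(0.2, 2),
         k3_on = on12, k3_off = off, k4 = c(0.2, 2), k5 = c(0.2, 2),
         k6_on = on23, k6_off = off, k7 = c(0.2, 2), k8 = c(0.2, 2))
  }
  fb_note <- switch(feedback,
    none = "no regulatory feedback",
    "3to1" = "non-competitive feedback of pX3 on X1 phosphorylation (u1, k9)",
    "3to2" = "non-competitive feedback of pX3 on pX1..X2 complex formation (u2, k10)")
  preset <- new_preset(
    name = net$name, network = net, partitions = partitions,
    default_partition = "asymmetric", permissible = permissible,
    notes = paste0("Three-tier activation cascade, two-step activation ",
                   "(binding then catalysis), first-order deactivation per ",
                   "tier (deactivation mechanism for tiers 2-3 is an assumption); ",
                   fb_note, "."),
    sampler_ranges = ranges, direct_targets = direct_targets
  )
  preset$feedback <- feedback
  preset$feedback_params <- switch(feedback,
    none = stats::setNames(numeric(0), character(0)),
    "3to1" = c(u1 = u, k9 = k_fb),
    "3to2" = c(u2 = u, k10 = k_fb))
  preset
}

#' Build a three-tier kinase cascade preset
#'
#' Tiers X1 -> X2 -> X3 with two-step activation (enzyme-substrate binding
#' followed by catalysis), first-order deactivation per tier and conserved
#' totals.  Optional non-competitive regulatory feedback from the active
#' tier-3 enzyme: `"3to1"` multiplies the X1 phosphorylation rate by
#' `(1 + u*[pX3]/k_fb)/(1 + [pX3]/k_fb)`, `"3to2"` multiplies the
#' productive pX1..X2 complex formation by the same form.  The feedback is
#' positive for `u > 1` and negative for `0 < u < 1`.
#'
#' @param feedback `"none"`, `"3to1"` or `"3to2"`.
#' @param u dimensionless feedback gain (ignored for `"none"`).
#' @param k_fb feedback concentration scale (ignored for `"none"`).
#' @return an `mra_preset` with frozen default parameters
#'   (`sample_params(seed = 0, level = "strong")` plus the feedback gain).
#' @export
build_cascade3 <- function(feedback = c("none", "3to1", "3to2"), u = 2, k_fb = 1) {
  if (!is.character(feedback) || !feedback[1] %in% c("none", "3to1", "3to2")) {
    stop_definition("unknown feedback tag '%s'", as.character(feedback[1]))
  }
  feedback <- feedback[1]
  if (feedback != "none" && u <= 0) stop_definition("feedback gain u must be positive")
  key <- sprintf("cascade3|%s|%.17g|%.17g", feedback,
                 if (feedback == "none") 0 else u,
                 if (feedback == "none") 0 else k_fb)
  if (!is.null(.preset_cache[[key]])) return(.preset_cache[[key]])
  preset <- cascade3_skeleton(feedback, u, k_fb)
  preset$params <- sample_params(preset, seed = 0, level = "strong")
  preset$seed_used <- 0L
  .preset_cache[[key]] <- preset
  preset
}

## ----------------------------------------------------------------- sampler

#' Inter-modular complexes of a partitioned network
#'
#' @param network an `mra_network`.
#' @param partition an `mra_partition`.
#' @return character vector of complex species whose constituents belong to
#'   different modules.
#' @export
intermodular_complexes <- function(network, partition) {
  membership <- list()
  for (m in partition$modules) for (s in m$species) membership[[s]] <- m$name
  out <- character(0)
  for (sp in network$species) {
    if (sp$role != "complex") next
    mods <- unlist(membership[sp$of])
    if (length(unique(mods)) > 1) out <- c(out, sp$name)
  }
  out
}

constituent_total <- function(network, sp_name) {
  for (law in network$conservation) {
    if (sp_name %in% names(law$coef)) return(law$total)
  }
  NA_character_
}

# sequestration score of one complex: largest fraction of any constituent's
# conserved total held in the complex at steady state
sequestration_fraction <- function(network, conc, params, complex_name) {
  sp <- network$species[[match(complex_name, species_names(network))]]
  fr <- vapply(sp$of, function(cs) {
    tot <- constituent_total(network, cs)
    if (is.na(tot)) return(NA_real_)
    conc[[complex_name]] / get_param(params, tot)
  }, numeric(1))
  max(fr, na.rm = TRUE)
}

#' Sample a reproducible parameter set in a sequestration regime
#'
#' Draws rate constants and totals log-uniformly from regime-specific
#' ranges, solves for the steady state, and accepts the draw when every
#' inter-modular complex holds the required share of at least one
#' constituent's total: at least 20\% for `"strong"`, at most 1\% for
#' `"negligible"`, between 3\% and 20\% for `"moderate"`.
#'
#' @param preset an `mra_preset`.
#' @param seed integer seed; the same seed always yields the same set.
#' @param level `"negligible"`, `"moderate"` or `"strong"`.
#' @param max_tries rejection-sampling budget.
#' @return named parameter vector with attributes `"tries"` and `"level"`.
#' @export
sample_params <- function(preset, seed, level = c("strong", "moderate", "negligible"),
                          max_tries = 100) {
  level <- match.arg(level)
  ranges <- preset$sampler_ranges(level)
  imc <- intermodular_complexes(preset$network, preset_partition(preset))
  fixed <- preset$feedback_params %||% stats::setNames(numeric(0), character(0))
  with_seed(seed, {
    last_diag <- "no draws"
    for (try in seq_len(max_tries)) {
      draw <- vapply(ranges, function(r) exp(stats::runif(1, log(r[1]), log(r[2]))),
                     numeric(1))
      params <- c(draw, fixed)
      ss <- tryCatch(suppressWarnings(find_steady_state(preset$network, params)),
                     error = function(e) NULL)
      if (is.null(ss) || !ss$stable) { last_diag <- "steady state failed/unstable"; next }
      fr <- vapply(imc, function(cx) {
        sequestration_fraction(preset$network, ss$concentrations, params, cx)
      }, numeric(1))
      ok <- switch(level,
        strong = all(fr >= 0.2),
        negligible = all(fr <= 0.01),
        moderate = all(fr >= 0.03 & fr <= 0.2))
      if (ok) {
        attr(params, "tries") <- try
        attr(params, "level") <- level
        return(params)
      }
      last_diag <- sprintf("sequestration fractions: %s",
                           paste(signif(fr, 3), collapse = ", "))
    }
    stop_numerical("sample_params: no accepted draw in %d tries (%s, level %s)",
                   max_tries, last_diag, level)
  })
}
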