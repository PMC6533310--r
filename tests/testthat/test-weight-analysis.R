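test_that("the MEK/ERK weight scan reproduces the sign-change narrative", {
  p <- mek_preset()
  part <- preset_partition(p, "asymmetric")
  tab <- mek_table()
  asg <- mek_assignment()
  scan <- scan_weights(tab, part, asg, grid = c(0, 0.05, 0.2, 0.5, 1, 2, 5))
  r_of <- function(a) scan$r[, , which(scan$weights[, 1] == a)]
  expect_lt(r_of(0)["MEK", "ERK"], 0)   # free-form output: sequestration visible
  expect_gt(r_of(1)["MEK", "ERK"], 0)   # total-phosphoform output: flipped
  expect_gt(r_of(5)["MEK", "ERK"], 0)
  expect_true(all(scan$r["ERK", "MEK", scan$ok] > 0)) # activation throughout
  expect_length(scan$sign_changes[["MEK->ERK"]], 1)
  expect_length(scan$sign_changes[["ERK->MEK"]], 0)

  # single-point grid: one matrix, no sign information
  s1 <- scan_weights(tab, part, asg, grid = 1)
  expect_identical(dim(s1$r)[3], 1L)
  expect_true(all(vapply(s1$sign_changes, length, 0L) == 0L))
})

test_that("the nullifying weight matches the rate-constant ratio", {
  p <- mek_preset()
  tab <- mek_table()
  part <- preset_partition(p, "asymmetric")
  opt <- find_a_opt(tab, part, mek_assignment(), targets = list(c(1, 2)))
  expect_true(opt$found)
  a_true <- p$params[["k1"]] / (p$params[["k1"]] + p$params[["k2"]])
  expect_equal(unname(opt$weights[["a"]]), a_true, tolerance = 1e-8)
  expect_lt(opt$achieved, 1e-9)

  # symmetric outputs nullify at the same weight
  part_s <- preset_partition(p, "symmetric")
  opt_s <- find_a_opt(tab, part_s, mek_assignment("symmetric"),
                      targets = list(c(1, 2)))
  expect_equal(unname(opt_s$weights[["a"]]), a_true, tolerance = 1e-6)
})

test_that("equal forward and reverse rates give a weight of one half", {
  p <- mek_preset()
  params <- p$params
  params[["k2"]] <- params[["k1"]]
  tab <- run_perturbations(p$network, params, c("MEK_tot", "ERK_tot"))
  opt <- find_a_opt(tab, preset_partition(p, "asymmetric"), mek_assignment(),
                    targets = list(c(1, 2)))
  expect_equal(unname(opt$weights[["a"]]), 0.5, tolerance = 1e-8)
})

test_that("a coefficient with no sign change reports no nullifying weight", {
  p <- mek_preset()
  tab <- mek_table()
  res <- find_a_opt(tab, preset_partition(p, "asymmetric"), mek_assignment(),
                    targets = list(c(2, 1))) # the regulatory edge
  expect_false(res$found)
  expect_match(res$reason, "no sign change")
})

test_that("joint nullification in the cascade also clears the skip-level entry", {
  cs <- cascade_case("none")
  opt <- find_a_opt(cs$table, cs$partition, cs$assignment,
                    targets = list(c(1, 2), c(2, 3)))
  expect_true(opt$found)
  a1_true <- cs$preset$params[["k1"]] /
    (cs$preset$params[["k1"]] + cs$preset$params[["k2"]])
  expect_equal(unname(opt$weights[["a1"]]), a1_true, tolerance = 1e-6)
  r <- unclass(opt$r)
  expect_lt(abs(r["X1", "X3"]), 1e-6)
  expect_gt(r["X2", "X1"], 0)
  expect_gt(r["X3", "X2"], 0)
  expect_true("X1->X3" %in% opt$extra_zeros)
})

test_that("classification separates regulatory from sequestration edges", {
  p <- mek_preset()
  scan <- scan_weights(mek_table(), preset_partition(p, "asymmetric"),
                       mek_assignment())
  cls <- classify_connections(scan)
  expect_identical(cls$labels["ERK", "MEK"], "regulatory")
  expect_identical(cls$labels["MEK", "ERK"], "sequestration")
  expect_identical(cls$evidence[["MEK->ERK"]]$sign_changes, 1L)
})

test_that("degenerate scans classify as absent or ambiguous, never forced", {
  mods <- c("M1", "M2")
  skeleton <- function(values) {
    arr <- array(0, dim = c(2, 2, length(values)),
                 dimnames = list(mods, mods, NULL))
    arr[1, 2, ] <- values
    arr[2, 1, ] <- 1
    W <- matrix(seq_along(values), ncol = 1, dimnames = list(NULL, "a"))
    sc <- list(weights = W, r = arr, ok = rep(TRUE, length(values)),
               band = 1e-6, partition = NULL, assignment = NULL)
    # reuse the scanner's own sign-change bookkeeping
    s <- ifelse(abs(values) <= 1e-6, 0, sign(values))
    idx <- which(s != 0)
    br <- list()
    if (length(idx) >= 2) {
      flips <- which(s[idx[-1]] * s[idx[-length(idx)]] < 0)
      for (f in flips) br <- c(br, list(c(idx[f], idx[f + 1])))
    }
    sc$sign_changes <- list("M1->M2" = br, "M2->M1" = list())
    class(sc) <- "mra_weight_scan"
    sc
  }
  cls0 <- classify_connections(skeleton(rep(0, 5)))
  expect_identical(cls0$labels["M1", "M2"], "absent")
  cls2 <- classify_connections(skeleton(c(-1, 1, -1, 1)))
  expect_identical(cls2$labels["M1", "M2"], "ambiguous")
})

test_that("ssq minimization agrees with exact nullification when it exists", {
  p <- mek_preset()
  tab <- mek_table()
  part <- preset_partition(p, "asymmetric")
  asg <- mek_assignment()
  opt <- find_a_opt(tab, part, asg, targets = list(c(1, 2)))
  fit <- minimize_sequestration_ssq(tab, part, asg, entries = list(c(1, 2)),
                                    bounds = c(0, 2))
  expect_equal(unname(fit$weights[["a"]]), unname(opt$weights[["a"]]),
               tolerance = 1e-4)
  expect_lt(fit$ssq, 1e-12)
  # optimality against the named points a = 0 and a = 1
  ssq_at <- function(a) {
    r <- solve_connection_matrix(global_responses(tab, part, c(a = a)), asg)
    r["MEK", "ERK"]^2
  }
  expect_lte(fit$ssq, ssq_at(0))
  expect_lte(fit$ssq, ssq_at(1))
})

test_that("regulatory edges keep their sign between a = 0 and the optimum", {
  p <- mek_preset()
  tab <- mek_table()
  part <- preset_partition(p, "asymmetric")
  asg <- mek_assignment()
  opt <- find_a_opt(tab, part, asg, targets = list(c(1, 2)))
  r0 <- solve_connection_matrix(global_responses(tab, part, c(a = 0)), asg)
  expect_gt(r0["ERK", "MEK"] * unclass(opt$r)["ERK", "MEK"], 0)
})

test_that("nullifying weights restore insulation in the feedback-free cascade", {
  p <- build_cascade3("none")
  part <- preset_partition(p, "asymmetric")
  perm <- preset_permissible(p, "asymmetric")
  dt <- preset_direct_targets(p, "asymmetric")
  specs <- c("X1_tot", "X2_tot", "X3_tot", "k5", "k8")
  tab <- run_perturbations(p$network, p$params, specs)
  asg <- assign_perturbations(part, specs, perm, dt)
  opt <- find_a_opt(tab, part, asg, targets = list(c(1, 2), c(2, 3)), tol = 1e-12)
  alts <- enumerate_assignments(part, specs, perm, dt)
  expect_gte(length(alts), 3)
  # every alternative must pair one X2-driving with one X3-driving spec
  for (a in alts) {
    expect_false(setequal(a$X1, c("X2_tot", "k5")))
    expect_false(setequal(a$X1, c("X3_tot", "k8")))
  }
  inv <- invariance_check(tab, part, opt$weights, alts, tolerance = 1e-6)
  expect_lt(max(inv$discrepancy), 1e-6)
  expect_true(all(inv$insulated))
})

test_that("with a regulatory feedback, insulation is restored in the
           small-perturbation limit", {
  # With a tier-3-to-tier-1 feedback the module outputs are entangled
  # through the loop, and the nullifying weights insulate the rows only to
  # first order in the perturbation magnitude: at 10% the coefficient
  # spread across alternative permissible designs is of order 1e-4, and it
  # shrinks quadratically with the magnitude.
  p <- build_cascade3("3to1", u = 3, k_fb = 1)
  part <- preset_partition(p, "asymmetric")
  perm <- preset_permissible(p, "asymmetric")
  dt <- preset_direct_targets(p, "asymmetric")
  specs <- c("X1_tot", "X2_tot", "X3_tot", "k5", "k8")
  spread_at <- function(m) {
    tab <- run_perturbations(p$network, p$params, specs, magnitude = m)
    asg <- assign_perturbations(part, specs, perm, dt)
    opt <- find_a_opt(tab, part, asg, targets = list(c(1, 2), c(2, 3)),
                      tol = 1e-12)
    alts <- enumerate_assignments(part, specs, perm, dt)
    max(invariance_check(tab, part, opt$weights, alts)$discrepancy)
  }
  d_10pc <- spread_at(0.10)
  d_small <- spread_at(0.002)
  expect_lt(d_small, 1e-6)
  expect_lt(d_small, d_10pc / 100) # quadratic shrinkage, not an offset
})

test_that("the feedback-gain threshold lies between the two printed regimes", {
  thr <- find_feedback_threshold(k_fb = 1, bracket = c(1.75, 50.5), rel_tol = 0.3)
  expect_identical(thr$lower_class, "sequestration")
  expect_identical(thr$upper_class, "regulatory")
  expect_gt(thr$u2, 1.75)
  expect_lt(thr$u2, 50.5)
  expect_lt(diff(thr$bracket) / thr$bracket[2], 0.31)
})

test_that("classification of MEK/ERK is stable across strong-regime draws", {
  p <- mek_preset()
  part <- preset_partition(p, "asymmetric")
  asg <- mek_assignment()
  grid <- c(0, 10^seq(-2, 2, length.out = 11))
  for (seed in 1:20) {
    params <- sample_params(p, seed = seed, level = "strong")
    tab <- run_perturbations(p$network, params, c("MEK_tot", "ERK_tot"))
    cls <- classify_connections(scan_weights(tab, part, asg, grid = grid))
    expect_identical(cls$labels["ERK", "MEK"], "regulatory")
    expect_identical(cls$labels["MEK", "ERK"], "sequestration")
  }
})
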