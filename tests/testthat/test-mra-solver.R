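test_that("perturbations are assigned to rows they do not directly affect", {
  p <- mek_preset()
  asg <- assign_perturbations(preset_partition(p, "total"),
                              c("MEK_tot", "PTP_tot"),
                              preset_permissible(p, "total"))
  expect_identical(asg$MEK, "PTP_tot")
  expect_identical(asg$ERK, "MEK_tot")

  # weighted outputs: ERK_tot becomes permissible for the MEK row
  asg2 <- mek_assignment()
  expect_identical(asg2$MEK, "ERK_tot")
  expect_identical(asg2$ERK, "MEK_tot")

  cs <- cascade_case("none")
  expect_setequal(cs$assignment$X1, c("X2_tot", "X3_tot"))
  expect_setequal(cs$assignment$X2, c("X1_tot", "X3_tot"))
  expect_setequal(cs$assignment$X3, c("X1_tot", "X2_tot"))
})

test_that("a single-module network yields the trivial matrix (-1)", {
  net <- mra_network(list(species("A", "free_inactive"), species("pA", "free_active")),
                     list(reaction("A", "pA", "kf"), reaction("pA", "A", "kr")),
                     list(conservation_law(c(A = 1, pA = 1), "A_tot")),
                     name = "one")
  part <- mra_partition(list(module_def("A", c("A", "pA"),
                                        list(list(species = "pA", weight = 1)))), net)
  asg <- assign_perturbations(part, "A_tot", list(A = character(0)))
  tab <- run_perturbations(net, c(kf = 1, kr = 2, A_tot = 1), "A_tot")
  r <- solve_connection_matrix(global_responses(tab, part), asg)
  expect_equal(unclass(r), matrix(-1, 1, 1, dimnames = list("A", "A")),
               ignore_attr = TRUE)
})

test_that("insufficient permissible perturbations is a configuration error", {
  p <- mek_preset()
  expect_error(assign_perturbations(preset_partition(p, "total"),
                                    c("MEK_tot", "ERK_tot"),
                                    preset_permissible(p, "total")),
               class = "retromra_config_error")
})

test_that("diagonal global responses force the negative identity", {
  R <- diag(c(0.4, -0.7, 0.3))
  dimnames(R) <- list(c("M1", "M2", "M3"), c("p1", "p2", "p3"))
  asg <- structure(list(M1 = c("p2", "p3"), M2 = c("p1", "p3"),
                        M3 = c("p1", "p2")), class = "mra_assignment")
  r <- solve_connection_matrix(R, asg)
  expect_equal(unclass(r), -diag(3), ignore_attr = TRUE)
})

test_that("the two-module closed form is reproduced", {
  R <- matrix(c(0.6, 0.1, 0.2, 0.4), 2, 2,
              dimnames = list(c("M1", "M2"), c("p1", "p2")))
  asg <- structure(list(M1 = "p2", M2 = "p1"), class = "mra_assignment")
  r <- solve_connection_matrix(R, asg)
  expect_equal(r["M1", "M2"], 0.2 / 0.4) # r_12 = R_1j / R_2j
  expect_equal(r["M2", "M1"], 0.1 / 0.6)
  expect_equal(diag(unclass(r)), c(M1 = -1, M2 = -1))
})

test_that("solved rows satisfy the MRA equations against a dense oracle", {
  set.seed(31)
  for (rep in 1:10) {
    R <- matrix(rnorm(9, sd = 1), 3, 3,
                dimnames = list(paste0("M", 1:3), paste0("p", 1:3)))
    asg <- structure(list(M1 = c("p2", "p3"), M2 = c("p1", "p3"),
                          M3 = c("p1", "p2")), class = "mra_assignment")
    r <- tryCatch(solve_connection_matrix(R, asg),
                  retromra_numerical_error = function(e) NULL)
    if (is.null(r)) next # ill-conditioned draw, correctly refused
    for (i in 1:3) {
      for (pj in asg[[i]]) {
        expect_lt(abs(sum(unclass(r)[i, ] * R[, pj])), 1e-10)
      }
      # oracle: explicit inverse route
      cols <- match(asg[[i]], colnames(R))
      A <- t(R[-i, cols]); b <- R[i, cols]
      expect_equal(unname(unclass(r)[i, -i]), unname(as.vector(qr.solve(A) %*% b)),
                   tolerance = 1e-9)
    }
    expect_equal(attr(r, "residuals"), c(M1 = 0, M2 = 0, M3 = 0),
                 tolerance = 1e-10)
  }
})

test_that("ill-conditioned rows are flagged or refused", {
  R <- matrix(c(1, 1, 1 + 1e-13, 1 + 1e-13), 2, 2,
              dimnames = list(c("M1", "M2"), c("p1", "p2")))
  asg <- structure(list(M1 = "p2", M2 = "p1"), class = "mra_assignment")
  r <- solve_connection_matrix(R, asg) # 1x1 rows are perfectly conditioned
  expect_equal(unname(r["M1", "M2"]), 1, tolerance = 1e-9)
  # rows M2 and M3 nearly collinear -> row M1's system is ill-conditioned
  R3 <- rbind(M1 = c(0.3, 0.7, 0.2),
              M2 = c(1, 1, 0.5),
              M3 = c(2, 2.0000001, 1))
  colnames(R3) <- paste0("p", 1:3)
  asg3 <- structure(list(M1 = c("p2", "p3"), M2 = c("p1", "p3"),
                         M3 = c("p1", "p2")), class = "mra_assignment")
  expect_error(solve_connection_matrix(R3, asg3, kappa_max = 10),
               class = "retromra_numerical_error")
  w <- capture_warnings(solve_connection_matrix(R3, asg3, kappa_max = 10,
                                                allow_ill = TRUE))
  expect_true(any(grepl("ill-conditioned", w)))
})

test_that("the inferred topology at a = 1 depends on the perturbation choice", {
  # the inconsistent-topology phenomenon: with outputs measuring total
  # phosphoforms, the retroactive coefficient flips sign between ERK_tot-
  # and PTP_tot-based inference
  p <- mek_preset()
  part <- preset_partition(p, "asymmetric")
  tab <- memo("mek_table_3specs", {
    run_perturbations(p$network, p$params, c("MEK_tot", "ERK_tot", "PTP_tot"))
  })
  R <- global_responses(tab, part, c(a = 1))
  asg_erk <- structure(list(MEK = "ERK_tot", ERK = "MEK_tot"),
                       class = "mra_assignment")
  asg_ptp <- structure(list(MEK = "PTP_tot", ERK = "MEK_tot"),
                       class = "mra_assignment")
  r_erk <- solve_connection_matrix(R, asg_erk)
  r_ptp <- solve_connection_matrix(R, asg_ptp)
  expect_gt(r_erk["MEK", "ERK"], 0)  # ERK_tot says: ERK activates MEK
  expect_lt(r_ptp["MEK", "ERK"], 0)  # PTP_tot says: ERK inhibits MEK
  inv <- invariance_check(tab, part, c(a = 1), list(asg_erk, asg_ptp))
  expect_false(inv$insulated[["MEK"]])
  expect_gt(max(inv$discrepancy), 0.1)
})

test_that("sign patterns match the known topology when sequestration is negligible", {
  p <- mek_preset()
  params <- sample_params(p, seed = 17, level = "negligible")
  tab <- run_perturbations(p$network, params, c("MEK_tot", "ERK_tot"))
  part <- preset_partition(p, "asymmetric")
  r <- solve_connection_matrix(global_responses(tab, part, c(a = 0)),
                               mek_assignment())
  expect_gt(r["ERK", "MEK"], 0)        # real activating edge
  expect_lt(abs(r["MEK", "ERK"]), 0.05) # no real edge back
})
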