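test_that("stoichiometric matrix encodes net production per reaction", {
  S <- stoichiometric_matrix(abc_network())
  expect_identical(dim(S), c(3L, 1L))
  expect_equal(unname(S[, 1]), c(-1, -1, 1))

  # MEK/ERK: the ppMEK row reproduces the signs of its rate equation
  net <- mek_preset()$network
  S <- stoichiometric_matrix(net)
  expect_equal(unname(S["ppMEK", ]), c(1, -1, -1, 1, 1, 0, 0, 0))
  expect_equal(unname(S["ppMEK..ERK", ]), c(0, 0, 1, -1, -1, 0, 0, 0))

  # no reactions -> zero-column matrix
  empty <- mra_network(list(species("A")), list(), name = "empty")
  expect_identical(dim(stoichiometric_matrix(empty)), c(1L, 0L))
})

test_that("network validation rejects broken definitions", {
  expect_error(mra_network(list(species("A")),
                           list(reaction("A", "B", "k"))),
               class = "retromra_definition_error")
  expect_error(species("AB", "complex", of = "A"),
               class = "retromra_definition_error")
  # declared law not in the left null space
  expect_error(
    mra_network(list(species("A"), species("B")),
                list(reaction("A", "B", "k"), reaction("B", character(0), "kd")),
                list(conservation_law(c(A = 1, B = 1), "T"))),
    class = "retromra_definition_error")
})

test_that("conserved moieties recover the declared laws of MEK/ERK", {
  laws <- conserved_moieties(mek_preset()$network)
  expect_length(laws, 3)
  expect_length(attr(laws, "undeclared"), 0)
  totals <- vapply(laws, `[[`, "", "total")
  expect_setequal(totals, c("MEK_tot", "ERK_tot", "PTP_tot"))
  erk <- laws[[which(totals == "ERK_tot")]]
  expect_setequal(names(erk$coef), c("ERK", "ppMEK..ERK", "pERK", "pERK..PTP"))
})

test_that("fully open networks have no conserved moieties", {
  expect_length(conserved_moieties(open_network()), 0)
})

test_that("left null basis is exact on random stoichiometries", {
  set.seed(42)
  for (rep in 1:20) {
    net <- random_network(n_species = sample(4:8, 1), n_reactions = sample(3:9, 1))
    S <- stoichiometric_matrix(net)
    laws <- conserved_moieties(net)
    # dimension check against an independent SVD oracle
    expect_length(laws, nrow(S) - qr(S)$rank)
    for (law in laws) {
      v <- stats::setNames(numeric(nrow(S)), rownames(S))
      v[names(law$coef)] <- law$coef
      expect_equal(max(abs(v %*% S)), 0)
      expect_true(all(law$coef == round(law$coef)))
      # vector lies in the span of the SVD null basis
      NB <- svd_left_null(S)
      if (nrow(NB)) {
        proj <- t(NB) %*% (NB %*% v)
        expect_lt(max(abs(proj - v)) / max(abs(v)), 1e-9)
      }
    }
  }
})

test_that("mass-action rates follow the law of mass action", {
  net <- mek_preset()$network
  params <- mek_preset()$params
  conc <- stats::setNames(c(0, 1, 2, 0, 0, 0.5, 0), species_names(net))
  p2 <- params
  p2[c("k3_on", "k3_off", "k4")] <- c(1, 0.1, 0.2)
  d <- network_rhs(net, conc, p2)
  # d[ppMEK..ERK]/dt = k3_on*[ppMEK]*[ERK] - (k3_off + k4)*[ppMEK..ERK]
  expect_equal(unname(d[["ppMEK..ERK"]]), 1 * 1 * 2 - (0.1 + 0.2) * 0.5)
})

test_that("rhs is zero when no reaction can fire", {
  p <- mek_preset()
  params <- p$params
  params[["k1"]] <- 0
  conc <- stats::setNames(numeric(7), species_names(p$network))
  conc[c("MEK", "ERK", "PTP")] <- c(params[["MEK_tot"]], params[["ERK_tot"]],
                                    params[["PTP_tot"]])
  expect_equal(max(abs(network_rhs(p$network, conc, params))), 0)
})

test_that("rhs rejects negative states and missing parameters", {
  net <- mek_preset()$network
  conc <- stats::setNames(rep(0.1, 7), species_names(net))
  bad <- conc; bad[["ppMEK"]] <- -0.1
  expect_error(network_rhs(net, bad, mek_preset()$params),
               class = "retromra_domain_error")
  expect_error(network_rhs(net, conc, c(k1 = 1)),
               class = "retromra_definition_error")
})

test_that("conservation coefficients annihilate the rhs at random states", {
  set.seed(7)
  net <- mek_preset()$network
  params <- mek_preset()$params
  for (rep in 1:10) {
    conc <- stats::setNames(runif(7, 0, 2), species_names(net))
    d <- network_rhs(net, conc, params)
    for (law in net$conservation) {
      expect_equal(sum(law$coef * d[names(law$coef)]), 0, tolerance = 1e-12)
    }
  }
})

test_that("regulatory multiplier is bounded by 1 and u and inert at u = 1", {
  mod <- regulatory_multiplier("E", "u", "k")
  for (u in c(5, 0.2)) {
    for (e in c(0.01, 0.5, 3, 100)) {
      v <- multiplier_value(mod, c(E = e), c(u = u, k = 0.7))
      expect_gt(v, min(1, u))
      expect_lt(v, max(1, u))
    }
  }
  expect_equal(multiplier_value(mod, c(E = 2), c(u = 1, k = 0.7)), 1)
  expect_equal(multiplier_value(mod, c(E = 0), c(u = 9, k = 0.7)), 1)

  # u = 1 leaves the whole network rhs identical to the unmodified one
  set.seed(11)
  net_fb <- build_cascade3("3to2", u = 1, k_fb = 1)$network
  net_plain <- build_cascade3("none")$network
  params <- c(build_cascade3("none")$params, u2 = 1, k10 = 1)
  for (rep in 1:5) {
    conc <- stats::setNames(runif(8, 0, 1.5), species_names(net_plain))
    expect_equal(network_rhs(net_fb, conc, params),
                 network_rhs(net_plain, conc, params))
  }
})

test_that("full-state integration conserves every moiety to 1e-8", {
  p <- mek_preset()
  net <- p$network
  conc0 <- stats::setNames(numeric(7), species_names(net))
  conc0[c("MEK", "ERK", "PTP")] <- c(p$params[["MEK_tot"]], p$params[["ERK_tot"]],
                                     p$params[["PTP_tot"]])
  sol <- deSolve::lsoda(unname(conc0), times = seq(0, 50, by = 10),
                        func = function(t, y, parms) {
                          names(y) <- species_names(net)
                          list(unname(network_rhs(net, pmax(y, 0), p$params)))
                        }, parms = NULL, rtol = 1e-10, atol = 1e-12)
  for (row in seq_len(nrow(sol))) {
    conc <- stats::setNames(sol[row, -1], species_names(net))
    for (law in net$conservation) {
      tot <- p$params[[law$total]]
      expect_lt(abs(sum(law$coef * conc[names(law$coef)]) - tot) / tot, 1e-8)
    }
  }
})

test_that("dependent species reconstruction clamps round-off and flags errors", {
  p <- mek_preset()
  z <- stats::setNames(numeric(4), p$network$independent$independent)
  full <- reconstruct_state(p$network, z, p$params)
  expect_equal(full[["MEK"]], p$params[["MEK_tot"]])
  # independent species exceeding a total -> warning on reconstruction
  z_bad <- z
  z_bad[["ppMEK"]] <- 2 * p$params[["MEK_tot"]]
  expect_warning(reconstruct_state(p$network, z_bad, p$params), "negative")
})
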