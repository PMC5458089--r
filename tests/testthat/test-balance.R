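# Net-conversion solver and yield/productivity arithmetic.

test_that("mevalonate module consumes 3 AcCoA, 2 NADPH, 3 ATP per IPP", {
  nc <- net_conversion(mevalonate_module(default_model()), "AcCoA", "IPP")
  expect_equal(unname(nc$net["AcCoA"]), -3)
  expect_equal(unname(nc$net["NADPH"]), -2)
  expect_equal(unname(nc$net["ATP"]), -3)
  expect_equal(unname(nc$net["IPP"]), 1)
  # CoA is returned, one CO2 released
  expect_equal(unname(nc$net["CoA"]), 3)
  expect_equal(unname(nc$net["CO2"]), 1)
  # unit fluxes through the six-step chain
  expect_equal(unname(nc$flux[c("Hmgs", "Hmgr", "Mvk", "Pmvk", "Mdc")]),
               rep(1, 5))
})

test_that("glycolysis + Pdh from 1.5 glucose yields 3 AcCoA and 6 NADH", {
  nc <- net_conversion(glycolysis_module(default_model(), include_pdh = TRUE),
                       "Glc", "AcCoA", basis = c(Glc = 1.5))
  expect_equal(unname(nc$net["Glc"]), -1.5)
  expect_equal(unname(nc$net["AcCoA"]), 3)
  expect_equal(unname(nc$net["NADH"]), 6)
  expect_equal(unname(nc$net["ATP"]), 3)   # net 2 ATP per glucose
})

test_that("glycolysis to pyruvate nets 2 ATP per glucose", {
  nc <- net_conversion(glycolysis_module(default_model()), "Glc", "Pyr",
                       basis = c(Glc = 1))
  expect_equal(unname(nc$net["Pyr"]), 2)
  expect_equal(unname(nc$net["ATP"]), 2)
  expect_equal(unname(nc$net["NADH"]), 2)
})

test_that("the full system converts 3 glucose per monoterpene with all pools closed", {
  pools <- c("ATP", "ADP", "NAD", "NADH", "NADP", "NADPH", "CoA", "Pi", "PPi")
  nc <- net_conversion(default_model(), "Glc", "Terpene", frozen = pools)
  expect_equal(unname(nc$net["Glc"]), -3)
  expect_equal(unname(nc$net["Terpene"]), 1)
  expect_equal(unname(nc$net["CO2"]), 8)
  for (p in pools) expect_false(p %in% names(nc$net))
  # independent check: the flux vector lies in the right nullspace of the
  # matrix restricted to all internal + pool species
  S <- stoich_matrix(default_model())
  internal <- setdiff(rownames(S)[rowSums(abs(S)) > 0],
                      c("Glc", "Terpene", "CO2", "O2", "H2O"))
  expect_lt(max(abs(S[internal, ] %*% nc$flux)), 1e-9)
  expect_true(all(nc$flux >= 0))
})

test_that("net conversion fails informatively when intermediates cannot cancel", {
  # without the decarboxylase the chain cannot reach IPP
  m <- subset_model(default_model(), c("PhaA", "Hmgs", "Hmgr", "Mvk", "Pmvk"))
  expect_error(net_conversion(m, "AcCoA", "IPP"), "produce|feasible")
  # under-determined without frozen pools
  expect_error(net_conversion(default_model(), "Glc", "Terpene"),
               "under-determined")
})

test_that("percent yield reproduces the batch-report arithmetic", {
  # 8.87 g/l from 200 mM consumed: 65.1 mM product over 66.7 mM theoretical
  expect_equal(percent_yield(8.87, 200), 97.65, tolerance = 1e-3)
  expect_equal(percent_yield(0, 200), 0)
  expect_error(percent_yield(8.87, 0), "undefined yield")
  expect_error(percent_yield(-1, 200), ">= 0")
})

test_that("yield is linear in titre, inverse-linear in glucose, and inverts exactly", {
  set.seed(5)
  for (i in 1:20) {
    titre <- runif(1, 0.5, 20); gluc <- runif(1, 50, 600)
    expect_equal(percent_yield(2 * titre, gluc), 2 * percent_yield(titre, gluc))
    expect_equal(percent_yield(titre, 2 * gluc), percent_yield(titre, gluc) / 2)
    # forward and inverse modes round-trip to machine precision
    y <- percent_yield(titre, gluc)
    expect_equal(glucose_consumed_for_yield(titre, y), gluc)
  }
  # inverse mode on the high-load batch: 12.5 g/l at 88.3% implies ~312 mM
  expect_equal(glucose_consumed_for_yield(12.5, 88.3), 311.71, tolerance = 1e-4)
})

test_that("productivity is the titre slope over time", {
  expect_equal(productivity(c(0, 48), c(0, 4.94))$mean_g_l_h, 0.1029167,
               tolerance = 1e-6)
  expect_equal(productivity(c(0, 10, 20), c(1, 1, 1))$mean_g_l_h, 0)
  s <- 0.37
  t <- 0:10
  expect_equal(productivity(t, s * t)$mean_g_l_h, s)
  expect_equal(productivity(t, s * t, window_h = 3)$max_window_g_l_h, s)
  expect_error(productivity(c(0, 5, 2), c(0, 1, 2)), "increasing")
})

test_that("cofactor turnover matches a trapezoid oracle and flags recycling", {
  tc <- cached("tc_100_completion",
               simulate_timecourse(set_initial(default_model(), "Glc", 100),
                                   t_end = 2e5, n_out = 201))
  expect_equal(classify_outcome(tc)$status, "completed")
  cyc <- cofactor_cycling_summary(tc)
  # the 4 mM adenine pool is recycled, not stoichiometric: for 100 mM glucose
  # at 4 ATP per glucose the pool must turn over >> (6*100/4)/2 = 75 times
  expect_gt(cyc[["ATP"]], 75)
  expect_gt(cyc[["NAD"]], 10)
  # oracle: time-integrated ATP-producing flux, positive part per reaction
  # (a reversible kinase running backward produces nothing), via an explicit
  # loop and trapezoid rule
  S <- stoich_matrix(tc$model)
  rate <- numeric(length(tc$time))
  for (j in seq_len(ncol(S))) {
    contrib <- S["ATP", j] * tc$fluxes[, j]
    rate <- rate + pmax(contrib, 0)
  }
  atp_produced <- sum(diff(tc$time) * (head(rate, -1) + tail(rate, -1)) / 2)
  expect_equal(cyc[["ATP"]], atp_produced / 4, tolerance = 1e-10)
})

test_that("a NoxE-less stalled run turns the nicotinamide pools over about once", {
  tc <- cached("tc_noxe_ko",
               simulate_timecourse(
                 set_vmax(set_initial(default_model(), "Glc", 250), "NoxE", 0),
                 t_end = 57600))
  cyc <- cofactor_cycling_summary(tc)
  # without the oxidase the NADP pool is reduced about once and stays there;
  # the reverse-Gap shuttle grants NAD a few passes but no sustained cycling
  expect_gt(cyc[["NADP"]], 0.5)
  expect_lt(cyc[["NADP"]], 1.5)
  expect_lt(cyc[["NAD"]], 10)
})
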