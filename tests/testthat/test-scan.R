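# Scan engine: shape classification, degenerate scans, knockouts,
# bottleneck titration, kinase rebalancing.

test_that("shape classification handles the canonical patterns", {
  expect_equal(classify_scan_shape(c(1, 2, 3, 4, 5)), "monotone-saturating")
  expect_equal(classify_scan_shape(c(5, 4, 3, 2, 1)), "monotone-decreasing")
  expect_equal(classify_scan_shape(c(1, 3, 5, 3, 1)), "interior-maximum")
  expect_equal(classify_scan_shape(c(1, 1.001, 0.999, 1)), "flat")
  # a few-percent droop after saturation still reads as saturating
  expect_equal(classify_scan_shape(c(1, 4, 5, 4.9, 4.8)), "monotone-saturating")
  expect_equal(classify_scan_shape(numeric(1)), "flat")
})

test_that("a single-step scan equals a plain simulation", {
  m <- default_model(glucose_mM = 50)
  sc <- scan_parameter(m, list(type = "vmax", id = "Hex"), n_steps = 1L,
                       t_end = 5000, n_out = 11)
  tc <- simulate_timecourse(m, t_end = 5000, n_out = 11)
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$value, get_vmax(m, "Hex"))
  expect_equal(sc$terpene_g_l, tc$observables$terpene_g_l[11])
})

test_that("scan validates its arguments", {
  m <- default_model()
  expect_error(scan_parameter(m, list(type = "vmax", id = "NotThere")),
               "unknown catalyst")
  expect_error(scan_parameter(m, list(type = "init", id = "NotThere")),
               "unknown species")
  expect_error(scan_parameter(m, list(id = "Hex")), "target")
  expect_error(scan_parameter(m, list(type = "vmax", id = "Hex"),
                              bounds = c(-1, 1)), "positive")
})

test_that("a scan over a non-limiting enzyme is flat", {
  m <- default_model(glucose_mM = 50)
  sc <- cached("scan_tpi",
               scan_parameter(m, list(type = "vmax", id = "Tpi"), fold = 4,
                              n_steps = 5, t_end = 10000, n_out = 21))
  expect_equal(attr(sc, "shape"), "flat")
})

test_that("knockout of nothing reproduces the full system; sets are order-invariant", {
  m <- default_model()
  ko0 <- knockout(m, character(), glucose_mM = 50, t_end = 10000, n_out = 21)
  tc <- simulate_timecourse(set_initial(m, "Glc", 50), t_end = 10000, n_out = 21)
  expect_equal(ko0$terpene_g_l[ko0$condition == "full"],
               tc$observables$terpene_g_l[21])

  k1 <- knockout(m, c("Gap", "NoxE"), glucose_mM = 50, t_end = 5000, n_out = 11)
  k2 <- knockout(m, c("NoxE", "Gap"), glucose_mM = 50, t_end = 5000, n_out = 11)
  expect_equal(k1, k2)
  expect_error(knockout(m, "NotAnEnzyme"), "unknown component")
})

test_that("purge-valve knockouts cripple production as in the leave-one-out assay", {
  ko <- cached("ko_valve",
               knockout(default_model(), c("NoxE", "mGap", "Gap")))
  full <- ko$terpene_g_l[ko$condition == "full"]
  noxe <- ko$terpene_g_l[ko$condition == "minus_NoxE"]
  mgap <- ko$terpene_g_l[ko$condition == "minus_mGap"]
  gap <- ko$terpene_g_l[ko$condition == "minus_Gap"]
  expect_gt(full, 3)                      # intact system makes g/l amounts
  expect_lt(noxe, 0.02 * full)            # oxidase loss abolishes production
  expect_lt(mgap, 0.02 * full)            # no NADPH source without mGap
  expect_lt(gap, 0.25 * full)             # NAD-Gap loss strongly reduces it
  bound <- no_purge_bounds(set_initial(default_model(), "Glc", 250))
  expect_lt(noxe, bound$terpene_g_l)
})

test_that("bottleneck titration flags Pdh and restores on un-throttling", {
  bn <- cached("bottlenecks", find_bottlenecks(default_model()))
  expect_true("Pdh" %in% attr(bn, "flagged"))
  # ranking: every flagged catalyst precedes every completed one
  expect_true(all(which(!bn$completed) < min(which(bn$completed))))
  # self-consistency: the baseline itself (everything restored) completes,
  # so restoring any flagged catalyst to baseline excess yields completion
  expect_gt(attr(bn, "baseline_titre_g_l"), 1)
  expect_error(find_bottlenecks(default_model(), reduced_fold = 300),
               "reduced_fold")
  expect_error(find_bottlenecks(default_model(), baseline_fold = 0.5), "folds")
})

test_that("an artificially throttled enzyme is detected (construct-and-detect)", {
  m <- set_vmax(default_model(), "Pgk", 0.05)
  bn <- cached("bottlenecks_pgk",
               find_bottlenecks(m, respect_model_loadings = TRUE))
  expect_true("Pgk" %in% attr(bn, "flagged"))
})

test_that("equal reduction and baseline folds flag nothing", {
  bn <- cached("bottlenecks_null",
               find_bottlenecks(default_model(), baseline_fold = 250,
                                reduced_fold = 250))
  expect_length(attr(bn, "flagged"), 0L)
  expect_lt(max(abs(bn$deficit_g_l)), 1e-6)
})

test_that("scaling the kinase block with hexokinase restores the titre", {
  rb <- cached("rebalance",
               rebalance_experiment(default_model(), hex_fold = c(1, 5),
                                    mevk_pfk_fold = c(1, 5)))
  base <- rb$terpene_g_l[rb$hex_fold == 1 & rb$mevk_pfk_fold == 1]
  broken <- rb$terpene_g_l[rb$hex_fold == 5 & rb$mevk_pfk_fold == 1]
  restored <- rb$terpene_g_l[rb$hex_fold == 5 & rb$mevk_pfk_fold == 5]
  expect_lt(broken, 0.25 * base)       # unbalanced Hex wrecks the titre
  expect_gte(restored, 0.9 * base)     # proportional kinases restore it
  expect_error(rebalance_experiment(default_model(), hex_fold = -1), "positive")
})

test_that("over-loading hexokinase sequesters phosphate in hexose phosphates", {
  m_hex <- set_vmax(default_model(), "Hex", 1.0)
  tc_hex <- cached("tc_hex10x",
                   simulate_timecourse(m_hex, t_end = 1e5, n_out = 101))
  n <- length(tc_hex$time)
  hexP <- sum(tc_hex$conc[n, c("G6P", "F6P", "FBP")] * c(1, 1, 2))
  p_total <- sum(tc_hex$conc[n, ] *
                   conserved_moieties(m_hex, check = FALSE)$total_phosphate)
  expect_gt(hexP / p_total, 0.5)
})
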