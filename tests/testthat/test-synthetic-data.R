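# Synthetic triplicate assay data: determinism, noise calibration,
# yield recovery.

zero_cv <- c(terpene_g_l = 0, hexose_mM = 0, atp_uM = 0, pi_mM = 0)

test_that("zero-CV datasets equal the ground truth exactly", {
  truth <- day_scale_truth()
  dat <- generate_assay_data(default_model(), glucose_mM = 200, days = 0:5,
                             cv = zero_cv, seed = 1, truth = truth)
  gt <- attr(dat, "ground_truth")
  for (i in seq_len(nrow(dat)))
    expect_identical(dat$value[i], gt[gt$day == dat$day[i], dat$observable[i]])
})

test_that("identical seeds give identical datasets; different seeds differ", {
  truth <- day_scale_truth()
  d1 <- generate_assay_data(default_model(), days = 0:5, seed = 42, truth = truth)
  d2 <- generate_assay_data(default_model(), days = 0:5, seed = 42, truth = truth)
  d3 <- generate_assay_data(default_model(), days = 0:5, seed = 43, truth = truth)
  expect_identical(d1, d2)
  expect_false(identical(d1$value, d3$value))
})

test_that("the noise model is mean-unbiased and scales with the stated CV", {
  truth <- day_scale_truth()
  # law of large numbers at cv = 0.05: per-time sample mean within 1%
  big <- generate_assay_data(default_model(), days = c(0, 1, 2), seed = 99,
                             n_reps = 1000, truth = truth,
                             cv = c(terpene_g_l = 0.05, hexose_mM = 0.05,
                                    atp_uM = 0.05, pi_mM = 0.05))
  gt <- attr(big, "ground_truth")
  for (d in c(1, 2)) {
    for (obs in c("terpene_g_l", "hexose_mM", "atp_uM")) {
      mu <- gt[gt$day == d, obs]
      if (mu <= 0) next
      mn <- mean(big$value[big$day == d & big$observable == obs])
      expect_lt(abs(mn - mu) / mu, 0.01)
    }
  }
  # replicate s.d. scales proportionally with cv
  sd_at <- function(cv) {
    d <- generate_assay_data(default_model(), days = c(0, 1), seed = 7,
                             n_reps = 500, truth = truth,
                             cv = c(terpene_g_l = cv, hexose_mM = cv,
                                    atp_uM = cv, pi_mM = cv))
    sd(d$value[d$day == 1 & d$observable == "terpene_g_l"])
  }
  ratio <- sd_at(0.08) / sd_at(0.04)
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("dataset layout is tidy, non-negative, with units", {
  dat <- generate_assay_data(default_model(), days = 0:3, seed = 3,
                             truth = day_scale_truth())
  expect_named(dat, c("day", "replicate", "observable", "value", "units"))
  expect_true(all(dat$value >= 0))
  expect_equal(nrow(dat), 4 * 3 * 4)  # days x replicates x observables
  expect_error(generate_assay_data(default_model(), days = numeric(0)),
               "empty day grid")
  expect_error(generate_assay_data(default_model(), days = c(3, 1)), "sorted")
})

test_that("yield recovery matches the noiseless net conversion", {
  truth <- day_scale_truth()
  dat <- generate_assay_data(default_model(), days = 0:5, cv = zero_cv,
                             seed = 1, truth = truth)
  rec <- recover_yield(dat)
  # noiseless, completed run: all consumed hexose ends as terpene up to the
  # small locked-intermediate residue, so recovered yield is within ~1% of
  # the 3-glucose stoichiometric prediction
  expect_equal(unname(rec$percent_yield["mean"]), 100, tolerance = 0.015)
  expect_equal(unname(rec$percent_yield["sd"]), 0)
  expect_equal(rec$n, 3)
})

test_that("recovered yields are unbiased across seeds and covered by replicate spread", {
  truth <- day_scale_truth()
  gt <- attr(generate_assay_data(default_model(), days = 0:5, cv = zero_cv,
                                 seed = 1, truth = truth), "ground_truth")
  true_yield <- percent_yield(gt$terpene_g_l[6],
                              gt$hexose_mM[1] - gt$hexose_mM[6])
  seeds <- 1:20
  recs <- lapply(seeds, function(s)
    recover_yield(generate_assay_data(default_model(), days = 0:5, seed = s,
                                      truth = truth)))
  means <- vapply(recs, function(r) r$percent_yield[["mean"]], 0)
  sds <- vapply(recs, function(r) r$percent_yield[["sd"]], 0)
  # grand mean within 2 pooled standard errors of the ground truth
  pooled_se <- sqrt(mean(sds^2)) / sqrt(3 * length(seeds))
  expect_lt(abs(mean(means) - true_yield), 2 * pooled_se)
  # per-seed 2-sd intervals cover the truth at least 80% of the time
  covered <- abs(means - true_yield) <= 2 * sds / sqrt(3)
  expect_gte(mean(covered), 0.8)
})

test_that("degenerate datasets propagate the undefined-yield error", {
  dat <- generate_assay_data(default_model(), days = 0:5, cv = zero_cv,
                             seed = 1, truth = day_scale_truth())
  # no glucose consumed: copy day-0 hexose onto the final day
  d0 <- dat$value[dat$day == 0 & dat$observable == "hexose_mM"]
  dat$value[dat$day == 5 & dat$observable == "hexose_mM"] <- d0
  expect_error(recover_yield(dat), "undefined yield")
  # day 0 missing entirely
  expect_error(recover_yield(dat[dat$day > 0, ]), "day-0")
})
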