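test_that("the generator is fully deterministic under a seed", {
  p <- profile_younger(n_days = 1, sampling_rate = 5)
  g1 <- generate_recording(p, 99)
  g2 <- generate_recording(p, 99)
  expect_identical(g1$recording$acc, g2$recording$acc)
  expect_identical(g1$recording$temperature, g2$recording$temperature)
  expect_identical(g1$truth$states, g2$truth$states)
  g3 <- generate_recording(p, 100)
  expect_false(identical(g1$recording$acc, g3$recording$acc))
})

test_that("a noiseless single-state day closes the loop exactly", {
  p <- cohort_profile(n_days = 1, sampling_rate = 5, noise_sd = 0,
                      nonwear_prob_day = 0, slpa_dwell_min = 1e7,
                      sed_dwell_min = 1e7)
  g <- generate_recording(p, 3)
  de <- run_day_pipeline(g$recording, g$truth$wear, g$truth$sleep)
  for (x in de) {
    lvl <- if (x$period == "wake") p$levels[["sedentary"]] else 0.005
    expect_equal(max(abs(x$epochs$values - lvl)), 0, tolerance = 1e-12)
  }
})

test_that("state occupancy matches pipeline time-in-level when noise is off", {
  p <- cohort_profile(n_days = 2, sampling_rate = 5, noise_sd = 0,
                      nonwear_prob_day = 0)
  g <- generate_recording(p, 8)
  de <- run_day_pipeline(g$recording, g$truth$wear, g$truth$sleep)
  wake <- Filter(function(x) x$period == "wake", de)
  tl <- Reduce(`+`, lapply(wake, function(x) time_in_levels(x$epochs)))
  st <- g$truth$states
  occ <- function(s) sum((st$stop - st$start)[st$state == s]) / 60
  # epoch boundaries can straddle state switches: allow one epoch per switch
  n_switch <- nrow(st)
  tol_min <- n_switch * 5 / 60
  expect_equal(unname(tl["sedentary"]), occ("sedentary"), tolerance = tol_min)
  expect_equal(unname(tl["light"]), occ("light"), tolerance = tol_min)
  expect_equal(unname(tl["moderate"]), occ("moderate"), tolerance = tol_min)
  expect_equal(unname(tl["vigorous"]), occ("vigorous"), tolerance = tol_min)
})

test_that("planted calibration distortion is inverted by the truth model", {
  p <- profile_younger(n_days = 1, sampling_rate = 5,
                       scale_range = c(0.95, 1.05),
                       offset_range = c(-0.05, 0.05), noise_sd = 0,
                       nonwear_prob_day = 0)
  g <- generate_recording(p, 12)
  rec_true <- apply_calibration(g$recording, g$truth$calibration)
  # during sleep the device reads pure gravity: norm 1 after correction
  sl <- g$truth$sleep
  sel <- in_intervals(rec_true$time, sl)
  norms <- sqrt(rowSums(rec_true$acc[sel, ]^2))
  expect_equal(mean(abs(norms - (1 + 0.005))), 0, tolerance = 1e-6)
})

test_that("cohorts are reproducible with metadata aligned to recordings", {
  co <- make_cohort(profile_younger(n_days = 1, sampling_rate = 5),
                    profile_older(n_days = 1, sampling_rate = 5),
                    n_per_group = 2, seed = 5)
  expect_equal(length(co$subjects), 4)
  expect_equal(nrow(co$meta), 4)
  expect_setequal(names(co$subjects), co$meta$subject)
  expect_true(all(co$meta$age[co$meta$group == "A"] <= 39))
  expect_true(all(co$meta$age[co$meta$group == "B"] >= 65))
  co2 <- make_cohort(profile_younger(n_days = 1, sampling_rate = 5),
                     profile_older(n_days = 1, sampling_rate = 5),
                     n_per_group = 2, seed = 5)
  expect_identical(co$subjects$S01$recording$acc,
                   co2$subjects$S01$recording$acc)
  expect_identical(co$meta, co2$meta)
})

test_that("younger and older presets separate in the planted directions", {
  gy <- generate_recording(profile_younger(n_days = 2, sampling_rate = 5,
                                           nonwear_prob_day = 0), 61)
  go <- generate_recording(profile_older(n_days = 2, sampling_rate = 5,
                                         nonwear_prob_day = 0), 62)
  f <- function(g) {
    de <- run_day_pipeline(g$recording, g$truth$wear, g$truth$sleep)
    wake <- Filter(function(x) x$period == "wake", de)
    rowMeans(vapply(wake, function(x)
      c(mvpa = unname(time_in_levels(x$epochs)["MVPA"]),
        ig = intensity_gradient(x$epochs)$gradient,
        tp = unname(fragmentation_metrics(x$epochs)["slpa_trans_prob"])),
      numeric(3)))
  }
  my <- f(gy); mo <- f(go)
  expect_gt(my["mvpa"], mo["mvpa"])       # more MVPA time when younger
  expect_gt(my["ig"], mo["ig"])           # shallower intensity gradient
  expect_gt(my["tp"], mo["tp"])           # higher SLPA transition probability
})
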