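test_that("time in levels uses half-open brackets and sums correctly", {
  es <- ep5(rep(0.03, 720))            # 60 min of 0.03 g
  tl <- time_in_levels(es)
  expect_equal(unname(tl["sedentary"]), 60)
  expect_equal(unname(tl["light"] + tl["moderate"] + tl["vigorous"]), 0)

  # a value exactly on the sedentary/light boundary counts as light
  tl2 <- time_in_levels(ep5(c(0.050)))
  expect_equal(unname(tl2["light"]), 5 / 60)
  expect_equal(unname(tl2["sedentary"]), 0)
  # and 0.110 g is moderate (hence MVPA), 0.440 g vigorous
  tl3 <- time_in_levels(ep5(c(0.110, 0.440)))
  expect_equal(unname(tl3["moderate"]), 5 / 60)
  expect_equal(unname(tl3["vigorous"]), 5 / 60)
  expect_equal(unname(tl3["MVPA"]), 10 / 60)
})

test_that("level times match a brute-force histogram on random epochs", {
  set.seed(15)
  cuts <- cut_points()
  for (rep in 1:20) {
    v <- runif(sample(50:500, 1), 0, 0.6)
    es <- ep5(v)
    tl <- time_in_levels(es)
    brute <- c(sum(v < 0.05), sum(v >= 0.05 & v < 0.11),
               sum(v >= 0.11 & v < 0.44), sum(v >= 0.44)) * 5 / 60
    expect_equal(unname(tl[c("sedentary", "light", "moderate", "vigorous")]),
                 brute)
    expect_equal(sum(tl[c("sedentary", "light", "moderate", "vigorous")]),
                 length(v) * 5 / 60)
    expect_equal(unname(tl["MVPA"] + tl["SLPA"]), length(v) * 5 / 60)
  }
})

test_that("bouted time handles continuous and tolerant runs", {
  # 15 continuous MVPA minutes with a 10 min bout requirement -> all 15
  es <- ep_minutes(rep(0.2, 15))
  expect_equal(time_in_bouts(es, "MVPA", 10), 15)
  # 9 MVPA + 2 sedentary + 9 MVPA spans one 80%-criterion bout of 20
  es2 <- ep_minutes(c(rep(0.2, 9), rep(0.02, 2), rep(0.2, 9)))
  expect_equal(time_in_bouts(es2, "MVPA", 10, criterion = 0.8), 20)
  # no MVPA at all
  expect_equal(time_in_bouts(ep_minutes(rep(0.02, 30)), "MVPA", 10), 0)
})

test_that("bouted time equals the brute-force window union on random data", {
  set.seed(16)
  for (rep in 1:25) {
    v <- ifelse(runif(sample(30:120, 1)) < 0.5, 0.2, 0.02)
    es <- ep5(v)
    for (crit in c(0.8, 1.0)) {
      got <- time_in_bouts(es, "MVPA", bout_min = 1, criterion = crit)
      want <- brute_bout_minutes(v >= 0.11, 12, crit, 5)
      expect_equal(got, want)
    }
  }
})

test_that("bouted time is monotone non-increasing in bout length", {
  set.seed(17)
  for (rep in 1:10) {
    v <- ifelse(runif(200) < 0.6, 0.3, 0.01)
    es <- ep5(v)
    t1 <- time_in_bouts(es, "MVPA", 1, 1.0)
    t10 <- time_in_bouts(es, "MVPA", 10, 1.0)
    expect_gte(t1, t10)
  }
})

test_that("maximum windowed acceleration matches brute force", {
  expect_equal(max_windowed_acc(ep_minutes(rep(0.2, 30)), 6), 0.2)
  expect_equal(max_windowed_acc(ep_minutes(rep(0.2, 10)), 15), NA_real_)

  # a 6 min burst of 0.5 g inside a sedentary day
  v <- c(rep(0.02, 120), rep(0.5, 72), rep(0.02, 120))
  es <- ep5(v)
  expect_equal(max_windowed_acc(es, 6), 0.5)

  set.seed(18)
  x <- runif(500, 0, 0.4)
  es2 <- ep5(x)
  m <- 72
  brute <- max(vapply(seq_len(length(x) - m + 1), function(i)
    mean(x[i:(i + m - 1)]), numeric(1)))
  expect_equal(max_windowed_acc(es2, 6), brute)
})

test_that("intensity gradient recovers an exactly log-linear histogram", {
  # counts 11025/(2k+1)^2 in bins k = 0,1,2,3 put ln(time) exactly on a
  # line of slope -2: t_k = (11025/12) (m_k / 0.0125)^-2 minutes
  w <- 0.025
  counts <- 11025 / c(1, 9, 25, 49)
  mids <- (2 * (0:3) + 1) * w / 2
  v <- rep(mids, counts)
  ig <- intensity_gradient(ep5(v))
  b_expected <- log(11025 / 12) + 2 * log(w / 2)
  expect_equal(ig$gradient, -2, tolerance = 1e-10)
  expect_equal(ig$intercept, b_expected, tolerance = 1e-10)
  expect_equal(abs(ig$r_value), 1, tolerance = 1e-10)
  expect_equal(ig$bins_used, 4)
})

test_that("intensity gradient is undefined with fewer than two bins", {
  expect_error(intensity_gradient(ep5(rep(0.03, 100))), "fewer than 2")
})

test_that("intensity gradient is invariant to epoch order", {
  set.seed(19)
  v <- runif(400, 0, 0.5)
  ig1 <- intensity_gradient(ep5(v))
  ig2 <- intensity_gradient(ep5(sample(v)))
  expect_equal(ig1$gradient, ig2$gradient)
  expect_equal(ig1$intercept, ig2$intercept)
})

test_that("power-law intensity draws give the analytic gradient slope", {
  # if epoch time density falls as m^a over the binned range, the log-log
  # regression of time on midpoint recovers slope ~ a
  set.seed(20)
  a <- -1.5
  # inverse-CDF sample from density prop to m^a on [0.0125, 0.8]
  u <- runif(200000)
  lo <- 0.0125; hi <- 0.8
  m <- ((hi^(a + 1) - lo^(a + 1)) * u + lo^(a + 1))^(1 / (a + 1))
  ig <- intensity_gradient(ep5(m))
  expect_equal(ig$gradient, a, tolerance = 0.1)
})

test_that("the endpoint battery returns the documented metric set", {
  set.seed(22)
  v <- ifelse(runif(2000) < 0.8, runif(2000, 0, 0.1),
              runif(2000, 0.11, 0.6))
  out <- compute_endpoints(ep5(v))
  expect_true(all(c("sedentary", "light", "moderate", "vigorous", "MVPA",
                    "SLPA", "MVPA_bout_10min", "max_acc_6min",
                    "max_acc_15min", "IG", "IG_intercept", "IG_r",
                    "mean_ENMO") %in% names(out)))
  expect_equal(unname(out["sedentary"] + out["light"] + out["moderate"] +
                        out["vigorous"]), length(v) * 5 / 60)
})
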