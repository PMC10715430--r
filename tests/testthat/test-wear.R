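test_that("warm worn device is a single wear interval", {
  set.seed(5)
  n <- 3 * 3600 * 10
  rec <- raw_recording((seq_len(n) - 1) / 10,
                       matrix(c(0, 0, 1), n, 3, byrow = TRUE) +
                         matrix(rnorm(3 * n, 0, 0.02), n, 3),
                       temperature = rep(34, n) + rnorm(n, 0, 0.02),
                       sampling_rate = 10)
  iv <- detect_wear(rec)
  expect_equal(nrow(interval_filter(iv, "nonwear")), 0)
  expect_equal(nrow(interval_filter(iv, "wear")), 1)
})

test_that("cold still device is non-wear throughout", {
  n <- 2 * 3600 * 10
  rec <- raw_recording((seq_len(n) - 1) / 10,
                       matrix(c(0, 0, 1), n, 3, byrow = TRUE),
                       temperature = rep(22, n), sampling_rate = 10)
  iv <- detect_wear(rec)
  wear_s <- interval_overlap_s(interval_filter(iv, "wear"), 0, n / 10)
  expect_lt(wear_s / (n / 10), 0.01)
})

test_that("temperature channel is required for the temperature method", {
  expect_error(detect_wear(still_rec(100)), "temperature")
})

test_that("planted doffed blocks are recovered within 5 minutes", {
  set.seed(9)
  p <- profile_younger(n_days = 2, sampling_rate = 10, nonwear_prob_day = 1)
  g <- generate_recording(p, 31)
  det <- interval_filter(detect_wear(g$recording), "nonwear")
  tru <- interval_filter(g$truth$wear, "nonwear")
  expect_gt(nrow(tru), 0)
  for (i in seq_len(nrow(tru))) {
    ov <- det[pmin(det$stop, tru$stop[i]) > pmax(det$start, tru$start[i]), ]
    expect_gt(nrow(ov), 0)
    expect_lt(abs(min(ov$start) - tru$start[i]), 300)
    expect_lt(abs(max(ov$stop) - tru$stop[i]), 300)
  }
})

test_that("wear and non-wear intervals exactly partition the recording", {
  set.seed(13)
  p <- profile_younger(n_days = 1, sampling_rate = 10, nonwear_prob_day = 1)
  g <- generate_recording(p, 17)
  iv <- detect_wear(g$recording)
  dur <- sum(iv$stop - iv$start)
  span <- g$recording$time[length(g$recording$time)] -
    g$recording$time[1] + 0.1
  expect_equal(dur, span, tolerance = 1e-9)
  o <- order(iv$start)
  expect_true(all(abs(iv$start[o][-1] - iv$stop[o][-nrow(iv)]) < 1e-9))
})

test_that("accelerometer-only detection flags long still blocks", {
  set.seed(21)
  fs <- 10
  active <- function(mins) matrix(c(0, 0, 1), mins * 60 * fs, 3,
                                  byrow = TRUE) +
    matrix(rnorm(3 * mins * 60 * fs, 0, 0.15), mins * 60 * fs, 3)
  still <- function(mins) matrix(c(0.1, 0.2, 0.97), mins * 60 * fs, 3,
                                 byrow = TRUE)
  acc <- rbind(active(180), still(90), active(180))
  rec <- raw_recording((seq_len(nrow(acc)) - 1) / fs, acc,
                       sampling_rate = fs)
  iv <- detect_wear_acc_only(rec)
  nw <- interval_filter(iv, "nonwear")
  expect_equal(nrow(nw), 1)
  # the planted block is 180-270 min; one 15 min step of slack either side
  expect_lt(abs(nw$start / 60 - 180), 16)
  expect_lt(abs(nw$stop / 60 - 270), 16)

  iv_all_active <- detect_wear_acc_only(
    raw_recording((seq_len(nrow(active(120))) - 1) / fs, active(120),
                  sampling_rate = fs))
  expect_equal(nrow(interval_filter(iv_all_active, "nonwear")), 0)

  iv_all_still <- detect_wear_acc_only(still_rec(120 * 60 * fs, fs))
  expect_equal(nrow(interval_filter(iv_all_still, "wear")), 0)
})

test_that("wear_time agrees with a brute-force per-second count", {
  set.seed(33)
  for (rep in 1:10) {
    k <- sample(1:5, 1)
    starts <- sort(runif(k, 0, 80000))
    stops <- starts + runif(k, 100, 5000)
    stops <- pmin(stops, c(starts[-1], Inf) - 1)
    iv <- interval_set(starts, stops, rep("wear", k))
    d0 <- runif(1, 0, 40000); d1 <- d0 + 86400
    secs <- seq(0.5, 86400, by = 1) + d0 - 0.5
    brute <- sum(in_intervals(secs, iv)) / 3600
    expect_equal(wear_time(iv, d0, d1), brute, tolerance = 1e-3)
  }
})

test_that("the 10 h daily gate drops short-wear days", {
  iv <- interval_set(c(0, 8 * 3600), c(6 * 3600, 11 * 3600),
                     c("wear", "wear"))
  expect_equal(wear_time(iv, 0, 86400), 9)
  expect_lt(wear_time(iv, 0, 86400), 10)
  full <- interval_set(0, 86400, "wear")
  expect_equal(wear_time(full, 0, 86400), 24)
})
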