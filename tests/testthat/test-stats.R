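test_that("ICC distinguishes agreement from correlation", {
  set.seed(30)
  a <- rnorm(20)
  r1 <- icc(a, a)
  expect_equal(r1$icc, 1, tolerance = 1e-9)
  # a large constant offset preserves correlation but destroys agreement
  r2 <- icc(a, a + 5)
  expect_lt(r2$icc, 0.2)
  expect_equal(stats::cor(a, a + 5), 1)
  expect_true(r2$lower <= r2$icc && r2$icc <= r2$upper)
  expect_error(icc(1:3, 1:3), "at least 5")
})

test_that("ICC approaches the population variance ratio in simulation", {
  set.seed(31)
  sigma_s <- 1; sigma_e <- 0.5
  pop_icc <- sigma_s^2 / (sigma_s^2 + sigma_e^2)   # 0.8
  est <- replicate(200, {
    s <- rnorm(60, 0, sigma_s)
    icc(s + rnorm(60, 0, sigma_e), s + rnorm(60, 0, sigma_e))$icc
  })
  expect_equal(mean(est), pop_icc, tolerance = 0.03)
})

test_that("rmcorr is exact for common within-subject lines", {
  subj <- rep(1:5, each = 4)
  x <- rep(1:4, 5)
  y <- x + rep(c(0, 10, 20, 30, 40), each = 4)   # y = x within subject
  r <- rmcorr(subj, x, y)
  expect_equal(r$r, 1, tolerance = 1e-9)
  expect_equal(r$df, 20 - 5 - 1)
})

test_that("rmcorr equals brute-force ANCOVA sums of squares", {
  set.seed(32)
  subj <- rep(1:5, each = 6)
  x <- rnorm(30)
  y <- 0.6 * x + rep(rnorm(5, 0, 2), each = 6) + rnorm(30, 0, 0.8)
  got <- rmcorr(subj, x, y)
  # brute force: demean x and y within subject, correlate residuals
  xd <- x - ave(x, subj); yd <- y - ave(y, subj)
  r_brute <- sum(xd * yd) / sqrt(sum(xd^2) * sum(yd^2))
  expect_equal(got$r, r_brute, tolerance = 1e-9)
  df <- length(x) - 5 - 1
  t_brute <- r_brute * sqrt(df / (1 - r_brute^2))
  expect_equal(got$p, 2 * pt(-abs(t_brute), df), tolerance = 1e-9)
})

test_that("rmcorr is near zero under within-subject independence", {
  set.seed(34)
  rs <- replicate(200, {
    subj <- rep(1:8, each = 5)
    rmcorr(subj, rnorm(40), rnorm(40))$r
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("the mixed-effects mean difference recovers constants and limits", {
  r <- mmrm_mean_difference(rep(1:6, each = 3), rep(2.5, 18))
  expect_equal(r$mean_diff, 2.5, tolerance = 1e-6)

  # one observation per subject degenerates to the one-sample t-test
  set.seed(35)
  d <- rnorm(10, 0.3)
  r1 <- mmrm_mean_difference(1:10, d)
  tt <- t.test(d)
  expect_equal(r1$mean_diff, unname(tt$estimate), tolerance = 1e-6)
  expect_equal(r1$p, tt$p.value, tolerance = 0.1)
})

test_that("Cohen's d matches its analytic value", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(36)
  a <- rnorm(5000, 0, 1); b <- rnorm(5000, 1, 1)
  expect_equal(cohens_d(a, b), 1, tolerance = 0.05)
  # group summaries like the published fragmentation contrast imply d ~ 2
  a2 <- rnorm(2000, 0.04, 0.01); b2 <- rnorm(2000, 0.02, 0.01)
  expect_equal(cohens_d(a2, b2), 2, tolerance = 0.1)
})

test_that("slope comparison matches hand OLS on 4-point groups", {
  age_a <- c(20, 30, 40, 50); val_a <- c(1.0, 1.9, 3.1, 4.0)
  age_b <- c(60, 70, 80, 90); val_b <- c(4.0, 3.0, 2.2, 1.1)
  sl <- slope_difference(age_a, val_a, age_b, val_b)
  hand <- function(x, y) {
    b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    res <- y - mean(y) - b * (x - mean(x))
    se <- sqrt(sum(res^2) / (length(x) - 2) / sum((x - mean(x))^2))
    c(b, se)
  }
  ha <- hand(age_a, val_a); hb <- hand(age_b, val_b)
  expect_equal(sl$slope_a, ha[1], tolerance = 1e-9)
  expect_equal(sl$slope_b, hb[1], tolerance = 1e-9)
  expect_equal(sl$t, (ha[1] - hb[1]) / sqrt(ha[2]^2 + hb[2]^2),
               tolerance = 1e-9)

  same <- slope_difference(age_a, val_a, age_a, val_a)
  expect_equal(same$slope_a, same$slope_b)
  expect_gt(same$p, 0.99)
})

test_that("a planted slope difference is detected", {
  set.seed(37)
  age_a <- runif(30, 23, 39); age_b <- runif(30, 65, 85)
  val_a <- 2 + 0 * age_a + rnorm(30, 0, 0.02)
  val_b <- 2.5 - 0.01 * age_b + rnorm(30, 0, 0.02)
  expect_lt(slope_difference(age_a, val_a, age_b, val_b)$p, 0.01)
})

test_that("BH adjustment matches hand computation and is monotone", {
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(c(1, 1, 1)), c(1, 1, 1))
  set.seed(38)
  p <- runif(20)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  # significance ordering preserved: adjusted values non-decreasing in raw p
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("the comparison table aggregates all statistics per metric", {
  set.seed(39)
  n_sub <- 8; n_day <- 5
  subj <- rep(sprintf("S%02d", 1:n_sub), each = n_day)
  base <- rep(rnorm(n_sub, 100, 15), each = n_day)
  va <- base + rnorm(n_sub * n_day, 0, 5)
  vb <- va + 2 + rnorm(n_sub * n_day, 0, 1)
  dat <- data.frame(subject = subj, day = rep(1:n_day, n_sub),
                    metric = "MVPA", value_a = va, value_b = vb)
  res <- compare_methods(dat)
  expect_equal(nrow(res), 1)
  expect_gt(res$icc, 0.8)
  expect_gt(res$pearson_r, 0.9)
  expect_equal(res$mmrm_mean_diff, -2, tolerance = 1)
})

test_that("the age-effect table flags a planted group difference under FDR", {
  set.seed(42)
  n <- 15
  meta <- data.frame(subject = sprintf("S%02d", 1:(2 * n)),
                     age = c(runif(n, 23, 39), runif(n, 65, 85)),
                     group = rep(c("younger", "older"), each = n))
  eps <- rbind(
    data.frame(subject = meta$subject, metric = "MVPA",
               value = c(rnorm(n, 98, 30), rnorm(n, 58, 30))),
    data.frame(subject = meta$subject, metric = "null_metric",
               value = rnorm(2 * n, 50, 10)))
  res <- age_effects(eps, meta)
  expect_lt(res$p_mean_fdr[res$metric == "MVPA"], 0.05)
  expect_gt(res$p_mean_fdr[res$metric == "null_metric"], 0.05)
  expect_gte(res$cohens_d[res$metric == "MVPA"], 0)
})
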