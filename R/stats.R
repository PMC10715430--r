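#' Intraclass correlation for two-method agreement
#'
#' Two-way random-effects, single-measure, absolute-agreement ICC(2,1) from
#' the subject x rater ANOVA decomposition, with the F-based 95\% confidence
#' interval. The consistency form ICC(3,1) is reported alongside, since
#' method-comparison studies rarely state which variant they used.
#'
#' @param a,b numeric vectors: the two methods' values for the same
#'   subjects, in subject order.
#' @param conf confidence level (default 0.95).
#' @return List with \code{icc} (ICC(2,1)), \code{lower}, \code{upper},
#'   \code{icc3} (ICC(3,1)), and \code{degenerate} (TRUE when between- and
#'   within-subject variance both vanish).
#' @export
icc <- function(a, b, conf = 0.95) {
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 5L) stop("need at least 5 subjects for the ICC", call. = FALSE)
  k <- 2
  x <- cbind(a, b)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SSE <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1); MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR < 1e-12 && MSE < 1e-12)
    return(list(icc = NA_real_, lower = NA_real_, upper = NA_real_,
                icc3 = NA_real_, degenerate = TRUE))
  icc2 <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  icc3 <- (MSR - MSE) / (MSR + (k - 1) * MSE)
  # McGraw & Wong F-based interval for ICC(2,1)
  alpha <- 1 - conf
  Fj <- MSC / MSE
  vn <- (k - 1) * (n - 1) * (k * icc2 * Fj + n * (1 + (k - 1) * icc2) -
                               k * icc2)^2
  vd <- (n - 1) * k^2 * icc2^2 * Fj^2 +
    (n * (1 + (k - 1) * icc2) - k * icc2)^2
  v <- vn / vd
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  list(icc = icc2, lower = lower, upper = upper, icc3 = icc3,
       degenerate = FALSE)
}

#' Repeated-measures correlation
#'
#' The within-subject association between two variables measured on
#' repeated days, estimated by analysis of covariance with subject as a
#' factor: the common within-subject slope's correlation, on
#' \eqn{N_{obs} - N_{subj} - 1} degrees of freedom.
#'
#' @param subject subject identifier vector.
#' @param x,y paired repeated measurements.
#' @return List with \code{r}, \code{df}, \code{p}.
#' @export
rmcorr <- function(subject, x, y) {
  ok <- is.finite(x) & is.finite(y)
  subject <- factor(subject[ok]); x <- x[ok]; y <- y[ok]
  if (nlevels(subject) < 2L || length(x) < nlevels(subject) + 2L)
    stop("need at least 2 subjects with repeated measurements", call. = FALSE)
  fit <- stats::lm(y ~ subject + x)
  # only the sums of squares are used; anova()'s own F-test warnings on
  # degenerate (perfect-fit) inputs are irrelevant here
  an <- suppressWarnings(stats::anova(fit))
  ss_x <- an["x", "Sum Sq"]
  ss_err <- an["Residuals", "Sum Sq"]
  df <- an["Residuals", "Df"]
  r <- sign(stats::coef(fit)[["x"]]) * sqrt(ss_x / (ss_x + ss_err))
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  list(r = unname(r), df = df, p = unname(p))
}

#' Mixed-effects mean difference across repeated days
#'
#' Fits the per-day differences between two methods as a random-intercept
#' model \eqn{d_{ij} = \mu + b_i + \epsilon_{ij}} (subject random effect,
#' REML) and reports the estimated mean difference with its Wald test and
#' confidence interval. Singular fits fall back to a one-sample t-test on
#' subject means, flagged in the result.
#'
#' @param subject subject identifier vector.
#' @param diff per-observation differences (method A minus method B).
#' @param conf confidence level (default 0.95).
#' @return List with \code{mean_diff}, \code{se}, \code{p}, \code{lower},
#'   \code{upper}, \code{fallback}.
#' @export
mmrm_mean_difference <- function(subject, diff, conf = 0.95) {
  subject <- factor(subject)
  if (nlevels(subject) < 2L)
    stop("need at least 2 subjects", call. = FALSE)
  df0 <- data.frame(subject = subject, d = diff)
  fit <- tryCatch(
    nlme::lme(d ~ 1, random = ~ 1 | subject, data = df0, method = "REML"),
    error = function(e) NULL)
  if (!is.null(fit)) {
    tt <- summary(fit)$tTable
    est <- tt[1, "Value"]; se <- tt[1, "Std.Error"]
    # between-subject degrees of freedom: the intercept is estimated from
    # n_subject effective replicates, not n_observations
    dfree <- nlevels(subject) - 1L
    p <- 2 * stats::pt(-abs(est / se), dfree)
    tcrit <- stats::qt(1 - (1 - conf) / 2, dfree)
    return(list(mean_diff = unname(est), se = unname(se), p = unname(p),
                lower = unname(est - tcrit * se),
                upper = unname(est + tcrit * se), fallback = FALSE))
  }
  sm <- tapply(diff, subject, mean)
  tt <- stats::t.test(sm, conf.level = conf)
  list(mean_diff = unname(tt$estimate), se = unname(tt$stderr),
       p = tt$p.value, lower = tt$conf.int[1], upper = tt$conf.int[2],
       fallback = TRUE)
}

#' Cohen's d standardized effect size
#'
#' Absolute standardized mean difference with the pooled (n-1 weighted)
#' standard deviation. Conventionally 0.2 is small, 0.5 medium, 0.8 large.
#'
#' @param group_a,group_b numeric vectors.
#' @return |d| (non-negative scalar).
#' @export
cohens_d <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]; b <- group_b[is.finite(group_b)]
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2L, nb >= 2L)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop("zero pooled variance", call. = FALSE)
  abs(mean(a) - mean(b)) / sqrt(sp2)
}

#' Compare age slopes between two groups
#'
#' Fits a separate ordinary least-squares regression of the metric on age
#' within each group and tests the slope difference with a Welch-style t
#' statistic on the combined slope standard errors.
#'
#' @param age_a,value_a age (years) and metric values for group A.
#' @param age_b,value_b the same for group B.
#' @return List with \code{slope_a}, \code{slope_b}, \code{se_a},
#'   \code{se_b}, \code{t}, \code{df}, \code{p}.
#' @export
slope_difference <- function(age_a, value_a, age_b, value_b) {
  fit1 <- .slope_fit(age_a, value_a)
  fit2 <- .slope_fit(age_b, value_b)
  se2 <- fit1$se^2 + fit2$se^2
  tval <- (fit1$slope - fit2$slope) / sqrt(se2)
  dfree <- se2^2 / (fit1$se^4 / fit1$df + fit2$se^4 / fit2$df)
  p <- 2 * stats::pt(-abs(tval), dfree)
  list(slope_a = fit1$slope, slope_b = fit2$slope,
       se_a = fit1$se, se_b = fit2$se, t = tval, df = dfree, p = p)
}

.slope_fit <- function(age, value) {
  ok <- is.finite(age) & is.finite(value)
  age <- age[ok]; value <- value[ok]
  if (length(age) < 3L || stats::var(age) == 0)
    stop("need at least 3 observations with age variance", call. = FALSE)
  fit <- stats::lm(value ~ age)
  s <- summary(fit)$coefficients
  list(slope = s["age", "Estimate"], se = s["age", "Std. Error"],
       df = fit$df.residual)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR correction; never decreases a p-value and preserves the
#' significance ordering.
#'
#' @param p vector of raw p-values in [0, 1] (NA allowed).
#' @return Adjusted p-values.
#' @export
fdr_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Method-comparison table for a family of metrics
#'
#' Aggregates the comparison layer over a long-format endpoint table:
#' per metric, the across-day subject means feed the paired t-test, ICC and
#' Pearson correlation, while the repeated days feed the repeated-measures
#' correlation and the mixed-effects mean difference.
#'
#' @param data data frame with columns \code{subject}, \code{day},
#'   \code{metric}, \code{value_a}, \code{value_b}.
#' @return Data frame, one row per metric: \code{icc}, \code{icc_lower},
#'   \code{icc_upper}, \code{mean_diff}, \code{p_paired_t},
#'   \code{pearson_r}, \code{p_pearson}, \code{rmcorr_r}, \code{p_rmcorr},
#'   \code{mmrm_mean_diff}, \code{p_mmrm}.
#' @export
compare_methods <- function(data) {
  stopifnot(all(c("subject", "day", "metric", "value_a", "value_b") %in%
                  names(data)))
  out <- lapply(split(data, data$metric), function(d) {
    ma <- tapply(d$value_a, d$subject, mean, na.rm = TRUE)
    mb <- tapply(d$value_b, d$subject, mean, na.rm = TRUE)
    ic <- icc(ma, mb)
    tt <- stats::t.test(ma, mb, paired = TRUE)
    ct <- stats::cor.test(ma, mb)
    rc <- rmcorr(d$subject, d$value_a, d$value_b)
    mm <- mmrm_mean_difference(d$subject, d$value_a - d$value_b)
    data.frame(metric = d$metric[1], icc = ic$icc, icc_lower = ic$lower,
               icc_upper = ic$upper, mean_diff = unname(tt$estimate),
               p_paired_t = tt$p.value, pearson_r = unname(ct$estimate),
               p_pearson = ct$p.value, rmcorr_r = rc$r, p_rmcorr = rc$p,
               mmrm_mean_diff = mm$mean_diff, p_mmrm = mm$p)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-group age-effect analysis over a family of metrics
#'
#' For each metric: the across-day subject means are compared between the
#' two age groups with a Welch t-test and Cohen's d, per-group age slopes
#' are fitted by OLS and their difference tested, and both p-value families
#' are FDR-adjusted across metrics.
#'
#' @param endpoints data frame with columns \code{subject}, \code{metric},
#'   \code{value} (already averaged across days, one row per
#'   subject-metric) or with a \code{day} column to be averaged here.
#' @param meta data frame with columns \code{subject}, \code{age},
#'   \code{group} (two levels).
#' @return Data frame, one row per metric: group means/SDs, \code{cohens_d},
#'   \code{p_mean}, \code{p_mean_fdr}, \code{slope_a}, \code{slope_b},
#'   \code{p_slope}, \code{p_slope_fdr}. Group A is the first factor level
#'   of \code{meta$group}.
#' @export
age_effects <- function(endpoints, meta) {
  stopifnot(all(c("subject", "metric", "value") %in% names(endpoints)),
            all(c("subject", "age", "group") %in% names(meta)))
  if ("day" %in% names(endpoints))
    endpoints <- stats::aggregate(value ~ subject + metric, endpoints, mean)
  meta$group <- factor(meta$group)
  stopifnot(nlevels(meta$group) == 2L)
  lv <- levels(meta$group)
  m <- merge(endpoints, meta, by = "subject")
  out <- lapply(split(m, m$metric), function(d) {
    a <- d[d$group == lv[1], ]; b <- d[d$group == lv[2], ]
    tt <- stats::t.test(a$value, b$value)
    sl <- tryCatch(slope_difference(a$age, a$value, b$age, b$value),
                   error = function(e) list(slope_a = NA_real_,
                                            slope_b = NA_real_, p = NA_real_))
    data.frame(metric = d$metric[1],
               mean_a = mean(a$value), sd_a = stats::sd(a$value),
               mean_b = mean(b$value), sd_b = stats::sd(b$value),
               cohens_d = cohens_d(a$value, b$value),
               p_mean = tt$p.value,
               slope_a = sl$slope_a, slope_b = sl$slope_b,
               p_slope = sl$p)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$p_mean_fdr <- fdr_adjust(res$p_mean)
  res$p_slope_fdr <- fdr_adjust(res$p_slope)
  res
}
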