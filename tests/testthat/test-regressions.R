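test_that("log-log OLS recovers exact power laws and handles edge cases", {
  x <- c(1, 2, 5, 10, 30)
  y <- 2 * sqrt(x)
  r <- log_ols(y, x)
  expect_equal(r$slope, 0.5)
  expect_equal(r$intercept, log(2))
  expect_equal(r$r2, 1)
  expect_equal(r$df_den, 3)

  rc <- log_ols(rep(4, 6), c(1, 2, 3, 4, 5, 6))
  expect_equal(rc$slope, 0)
  expect_equal(rc$r2, 0)

  expect_error(log_ols(c(-1, 2, 3), c(1, 2, 3)), "non-positive")
  expect_error(log_ols(c(1, 2), c(1, 2)), "at least 3")
})

test_that("log-log OLS recovers a generating slope at realistic noise", {
  sl <- vapply(1:100, function(s)
    with(gen_loglog_dataset(446, 3.783, 0.751, 0.30, seed = s),
         log_ols(y, x)$slope), numeric(1))
  # MC mean within 2 MC SEs of truth
  expect_lt(abs(mean(sl) - 0.751), 2 * sd(sl) / sqrt(length(sl)))
})

test_that("SMA slope satisfies its defining identities", {
  d <- gen_loglog_dataset(120, 4, 0.6, 0.5, seed = 5)
  ols <- log_ols(d$y, d$x)
  sma <- sma_fit(d$y, d$x)
  r <- sqrt(ols$r2)
  expect_equal(abs(sma$slope), abs(ols$slope) / r, tolerance = 1e-10)
  expect_gte(abs(sma$slope), abs(ols$slope))
  # line passes through the bivariate mean
  expect_equal(sma$intercept + sma$slope * mean(log(d$x)),
               mean(log(d$y)), tolerance = 1e-10)
  # perfect correlation: SMA = OLS
  x <- c(1, 3, 7, 20)
  expect_equal(sma_fit(5 * x^2, x)$slope, 2, tolerance = 1e-12)
  expect_error(sma_fit(c(2, 2, 2), c(1, 2, 3)), "zero variance")
})

test_that("separate-slopes interaction test behaves under null and alternative", {
  # same noiseless line in both groups: zero interaction coefficient
  x <- c(1, 2, 4, 8, 16, 32)
  y <- 3 * x^0.7
  cmp <- separate_slopes_test(c(y, y), c(x, x), rep(c("a", "b"), each = 6))
  expect_equal(unname(coef(cmp$model)["lx:groupsb"]), 0, tolerance = 1e-12)
  expect_equal(cmp$per_group$a$slope, cmp$per_group$b$slope)

  # the documented class structure (slopes 0.736 vs 0.367, n 231/212,
  # noise matched to r2 0.26/0.08) is detected in most replicates; the
  # analytic power of this design is ~0.88
  hits <- vapply(1:200, function(s) {
    a <- gen_loglog_dataset(231, 3.929, 0.736, 0.26, seed = s)
    b <- gen_loglog_dataset(212, 4.689, 0.367, 0.08, seed = s + 1e5)
    separate_slopes_test(c(a$y, b$y), c(a$x, b$x),
                         rep(c("mod", "low"), c(231, 212)))$interaction_p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.80)

  expect_warning(
    separate_slopes_test(c(y, y, 5, 6), c(x, x, 2, 3),
                         c(rep(c("a", "b"), each = 6), "c", "c"),
                         transform = "none"),
    "excluding")
  small <- suppressWarnings(
    separate_slopes_test(c(y, y, 5, 6), c(x, x, 2, 3),
                         c(rep(c("a", "b"), each = 6), "c", "c"),
                         transform = "none"))
  expect_equal(small$groups, c("a", "b"))
})

test_that("interaction-term type-I error is calibrated under a shared line", {
  p <- vapply(1:400, function(s) {
    a <- gen_loglog_dataset(100, 3.9, 0.7, 0.3, seed = s)
    b <- gen_loglog_dataset(100, 3.9, 0.7, 0.3, seed = s + 5e5)
    separate_slopes_test(c(a$y, b$y), c(a$x, b$x),
                         rep(1:2, each = 100))$interaction_p
  }, numeric(1))
  expect_true(abs(mean(p < 0.05) - 0.05) < 0.03)
})

test_that("N x P interaction model recovers noiseless generating coefficients", {
  set.seed(2)
  N <- exp(rnorm(60, log(20), 0.4))
  P <- exp(rnorm(60, log(0.9), 0.6))
  V <- exp(4.636 + 0.453 * log(N) - 0.546 * log(P) +
             0.321 * log(N) * log(P))
  # lm warns about the (intended) essentially perfect fit
  m <- suppressWarnings(np_interaction_model(V, N, P))
  expect_equal(unname(m$coefficients),
               c(4.636, 0.453, -0.546, 0.321), tolerance = 1e-10)
  expect_equal(m$r2, 1, tolerance = 1e-10)
  expect_equal(m$df_den, 56)

  # constant Ma column cannot be log-separated from the intercept
  expect_error(np_interaction_model(V, N, P, Ma = rep(100, 60)),
               "rank-deficient|collinear")
  # collinearity diagnostic reflects the generating correlation
  d <- gen_leaf_traits(5000, seed = 9)
  m2 <- np_interaction_model(d$Vcmax_mass, d$Nmass, d$Pmass)
  expect_equal(m2$nutrient_r2, 0.39, tolerance = 0.05)
})

test_that("threshold sweep reproduces the single-threshold test and class ordering", {
  d <- gen_leaf_traits(446, seed = 21)
  sw <- threshold_sweep(d$Vcmax_mass, d$Nmass, d$Pmass,
                        thresholds = c(0.7, 0.92, 1.1))
  one <- separate_slopes_test(d$Vcmax_mass, d$Nmass, p_class(d$Pmass, 0.92))
  row <- sw[sw$threshold == 0.92, ]
  expect_equal(row$slope_low, one$per_group$low$slope)
  expect_equal(row$slope_moderate, one$per_group$moderate$slope)
  expect_equal(row$interaction_p, one$interaction_p)
  # positive N x P interaction in the generator implies steeper
  # moderate-P slopes at every threshold
  expect_true(all(sw$slope_moderate > sw$slope_low))
  expect_error(threshold_sweep(d$Vcmax_mass, d$Nmass, d$Pmass, 99),
               "inside the observed P range")
})

test_that("fold change and class contrast match closed forms", {
  expect_equal(fold_change(0.736, 5, digits = 1), 3.3)
  expect_equal(fold_change(0.367, 5, digits = 1), 1.8)
  expect_equal(fold_change(0, 17), 1)
  # fold_change agrees with evaluating the fitted line at two points
  d <- gen_loglog_dataset(50, 3.9, 0.7, 0.6, seed = 3)
  r <- log_ols(d$y, d$x)
  pred <- function(x0) exp(r$intercept + r$slope * log(x0))
  expect_equal(fold_change(r$slope, 4), pred(4 * 7) / pred(7),
               tolerance = 1e-12)

  fit_mod <- list(intercept = 3.929, slope = 0.736)
  fit_low <- list(intercept = 4.689, slope = 0.367)
  expect_equal(class_contrast_at(20, fit_low, fit_mod), 41.259,
               tolerance = 1e-4)
  jm_mod <- list(intercept = 4.825, slope = 0.671)
  jm_low <- list(intercept = 5.366, slope = 0.382)
  expect_equal(class_contrast_at(20, jm_low, jm_mod), 38.371,
               tolerance = 1e-4)
  expect_equal(class_contrast_at(20, fit_low, fit_low), 0)
})

test_that("P classing is exhaustive, exclusive and uses the >= convention", {
  cls <- p_class(c(0.5, 0.92, 1.5))
  expect_equal(as.character(cls), c("low", "moderate", "moderate"))
  expect_true(all(!is.na(cls)))
})
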