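#' Log-log ordinary least-squares regression
#'
#' Fits `ln(y) ~ ln(x)` by OLS, the workhorse for power-law trait
#' relationships: a slope b and intercept a on the log scale correspond to
#' `y = exp(a) * x^b`.
#'
#' @param y,x Positive numeric vectors of equal length (n >= 3). Pairs with
#'   a missing value in either variable are dropped and counted.
#' @param transform `"ln"` (default) to natural-log transform both
#'   variables, `"none"` for a linear-scale fit.
#' @return An object of class `regression_result`: a list with `slope`,
#'   `intercept`, `r2`, `F`, `p`, `df_den`, `n`, `n_dropped`, `method`
#'   (`"OLS"`), `transform`, and the underlying `lm` fit.
#' @export
log_ols <- function(y, x, transform = c("ln", "none")) {
  transform <- match.arg(transform)
  ok <- is.finite(y) & is.finite(x)
  n_dropped <- sum(!ok)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 3) stop("need at least 3 complete observations")
  if (transform == "ln") {
    bad <- which(y <= 0 | x <= 0)
    if (length(bad))
      stop("non-positive values cannot be log-transformed (rows ",
           paste(utils::head(bad, 5), collapse = ", "),
           if (length(bad) > 5) ", ..." else "", ")")
    y <- log(y); x <- log(x)
  }
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  Fval <- if (sm$sigma == 0 || is.null(sm$fstatistic)) Inf else sm$fstatistic[[1]]
  df_den <- fit$df.residual
  pval <- if (is.finite(Fval)) pf(Fval, 1, df_den, lower.tail = FALSE) else 0
  r2 <- sm$r.squared
  slope <- unname(coef(fit)[2])
  if (var(fit$model$y) == 0) {  # constant response: a flat, featureless line
    Fval <- 0; pval <- 1; r2 <- 0; slope <- 0
  }
  structure(list(
    slope = slope, intercept = unname(coef(fit)[1]),
    r2 = r2, F = Fval, p = pval, df_den = df_den,
    n = length(y), n_dropped = n_dropped,
    method = "OLS", transform = transform, fit = fit
  ), class = "regression_result")
}

#' Standardised major axis (SMA) regression
#'
#' The symmetric line-fitting estimator used as a supporting approach when
#' both variables carry error: slope `sign(r) * sd(y) / sd(x)` with the
#' line through the bivariate mean, on the natural-log scale by default.
#' Its magnitude always satisfies `|b_SMA| = |b_OLS| / |r|`.
#'
#' @inheritParams log_ols
#' @return A `regression_result` with `method = "SMA"`. `r2`, `F`, `p` and
#'   `df_den` are those of the correlation (identical to OLS).
#' @export
sma_fit <- function(y, x, transform = c("ln", "none")) {
  transform <- match.arg(transform)
  ols <- log_ols(y, x, transform)
  ly <- ols$fit$model$y; lx <- ols$fit$model$x
  if (sd(lx) == 0 || sd(ly) == 0)
    stop("SMA undefined: zero variance in x or y")
  r <- stats::cor(lx, ly)
  slope <- sign(r) * sd(ly) / sd(lx)
  if (r == 0) slope <- sd(ly) / sd(lx)  # sign convention for r exactly 0
  intercept <- mean(ly) - slope * mean(lx)
  structure(list(
    slope = slope, intercept = intercept,
    r2 = ols$r2, F = ols$F, p = ols$p, df_den = ols$df_den,
    n = ols$n, n_dropped = ols$n_dropped,
    method = "SMA", transform = transform, fit = ols$fit
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("%s regression (%s scale): slope = %.4f, intercept = %.4f\n",
              x$method, if (x$transform == "ln") "natural-log" else "linear",
              x$slope, x$intercept))
  cat(sprintf("  r2 = %.3f, F = %.2f on 1 and %d df, p = %.3g, n = %d\n",
              x$r2, x$F, x$df_den, x$p, x$n))
  invisible(x)
}

#' Classify leaves into low- and moderate-P classes
#'
#' @param Pmass Leaf P concentration (mg g-1).
#' @param threshold Class boundary (mg g-1); `Pmass >= threshold` is
#'   `"moderate"`, below it `"low"`. The default 0.92 is the dataset-median
#'   convention for pan-tropical compilations.
#' @return A factor with levels `low`, `moderate`.
#' @export
p_class <- function(Pmass, threshold = 0.92) {
  stopifnot(threshold > 0)
  factor(ifelse(Pmass >= threshold, "moderate", "low"),
         levels = c("low", "moderate"))
}

#' Test for separate rather than parallel slopes across groups
#'
#' Fits the interaction model `ln(y) ~ ln(x) * group`; the F-test of the
#' interaction term is the test for separate slopes. Per-group lines are
#' fitted with [log_ols()] and returned alongside.
#'
#' @inheritParams log_ols
#' @param groups A factor (or coercible) with >= 2 levels; any level with
#'   fewer than 3 complete observations is excluded with a warning.
#' @return A list of class `slope_comparison`: `groups` (levels used),
#'   `per_group` (named list of `regression_result`), `interaction_p`,
#'   `interaction_F`, and `model` (the full `lm`).
#' @export
separate_slopes_test <- function(y, x, groups, transform = c("ln", "none")) {
  transform <- match.arg(transform)
  groups <- factor(groups)
  ok <- is.finite(y) & is.finite(x) & !is.na(groups)
  if (transform == "ln") ok <- ok & y > 0 & x > 0
  y <- y[ok]; x <- x[ok]; groups <- droplevels(groups[ok])
  counts <- table(groups)
  small <- names(counts)[counts < 3]
  if (length(small)) {
    warning("excluding group(s) with < 3 points: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    y <- y[keep]; x <- x[keep]; groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop("need at least 2 usable groups")
  ly <- if (transform == "ln") log(y) else y
  lx <- if (transform == "ln") log(x) else x
  full <- lm(ly ~ lx * groups)
  av <- anova(lm(ly ~ lx + groups), full)
  per_group <- lapply(levels(groups), function(g)
    log_ols(y[groups == g], x[groups == g], transform))
  names(per_group) <- levels(groups)
  structure(list(
    groups = levels(groups),
    per_group = per_group,
    interaction_F = av$F[2],
    interaction_p = av$`Pr(>F)`[2],
    model = full
  ), class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat("Separate-slopes test across", length(x$groups), "groups\n")
  for (g in x$groups)
    cat(sprintf("  %-10s slope = %.4f (n = %d, r2 = %.3f)\n",
                g, x$per_group[[g]]$slope, x$per_group[[g]]$n,
                x$per_group[[g]]$r2))
  cat(sprintf("  interaction F = %.2f, p = %.4g\n",
              x$interaction_F, x$interaction_p))
  invisible(x)
}

#' Multiple regression of a trait on leaf N, P and their interaction
#'
#' Fits `ln(y) ~ ln(N) + ln(P) + ln(N):ln(P)` (optionally `+ ln(Ma)`) by
#' OLS, the form used to provide biochemistry predictor functions for
#' terrestrial biosphere models. Reports all coefficients, the whole-model
#' F and p, r-squared, term-wise F-tests (Type I, in the stated order with
#' the interaction last), and the pairwise squared correlation between
#' `ln(N)` and `ln(P)` as a collinearity diagnostic.
#'
#' @param y Response trait (positive).
#' @param N,P Leaf N and P concentrations (mg g-1, positive).
#' @param Ma Optional leaf dry mass per area (g m-2); included as a
#'   covariate when supplied.
#' @return A list of class `np_model`: `coefficients` (named vector),
#'   `r2`, `F`, `p`, `df_den`, `n`, `term_tests` (anova table),
#'   `nutrient_r2` (squared lnN-lnP correlation), and `fit`.
#' @export
np_interaction_model <- function(y, N, P, Ma = NULL) {
  ok <- is.finite(y) & is.finite(N) & is.finite(P)
  if (!is.null(Ma)) ok <- ok & is.finite(Ma)
  y <- y[ok]; N <- N[ok]; P <- P[ok]
  if (!is.null(Ma)) Ma <- Ma[ok]
  if (any(y <= 0 | N <= 0 | P <= 0) || (!is.null(Ma) && any(Ma <= 0)))
    stop("all variables must be positive for log transformation")
  d <- data.frame(ly = log(y), lN = log(N), lP = log(P))
  form <- ly ~ lN + lP + lN:lP
  if (!is.null(Ma)) {
    d$lMa <- log(Ma)
    form <- ly ~ lN + lP + lMa + lN:lP
  }
  n_par <- length(attr(stats::terms(form), "term.labels")) + 1
  if (nrow(d) <= n_par + 2) stop("too few observations for the model")
  fit <- lm(form, data = d)
  if (fit$rank < n_par) {
    alias <- stats::alias(fit)$Complete
    stop("rank-deficient design; collinear term(s): ",
         paste(rownames(alias), collapse = ", "))
  }
  sm <- summary(fit)
  structure(list(
    coefficients = coef(fit),
    r2 = sm$r.squared,
    F = sm$fstatistic[[1]],
    p = pf(sm$fstatistic[[1]], sm$fstatistic[[2]], sm$fstatistic[[3]],
           lower.tail = FALSE),
    df_den = fit$df.residual,
    n = nrow(d),
    term_tests = anova(fit),
    nutrient_r2 = stats::cor(d$lN, d$lP)^2,
    fit = fit
  ), class = "np_model")
}

#' @export
print.np_model <- function(x, ...) {
  cat("N-P interaction model (natural-log scale)\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  r2 = %.3f, F = %.1f, p = %.3g, df_den = %d, n = %d\n",
              x$r2, x$F, x$p, x$df_den, x$n))
  cat(sprintf("  lnN-lnP squared correlation = %.3f\n", x$nutrient_r2))
  invisible(x)
}

#' Sweep the P-class threshold and refit class slopes
#'
#' For each candidate threshold, splits the data into low/moderate P
#' classes, fits per-class log-log OLS lines and the separate-slopes
#' interaction test. Thresholds that leave a class with fewer than
#' `min_n` points are flagged, not dropped.
#'
#' @inheritParams separate_slopes_test
#' @param P Leaf P concentration used for classing (mg g-1).
#' @param thresholds Numeric vector of candidate thresholds, strictly
#'   inside the observed range of `P`.
#' @param min_n Minimum per-class n below which a row is flagged.
#' @return A data.frame with one row per threshold: class slopes, ns,
#'   `interaction_p`, and a logical `flagged_small_class`.
#' @export
threshold_sweep <- function(y, x, P, thresholds, min_n = 10) {
  rng <- range(P, na.rm = TRUE)
  if (any(thresholds <= rng[1] | thresholds >= rng[2]))
    stop("thresholds must lie strictly inside the observed P range")
  rows <- lapply(thresholds, function(th) {
    cls <- p_class(P, th)
    cmp <- separate_slopes_test(y, x, cls)
    lo <- cmp$per_group[["low"]]; mo <- cmp$per_group[["moderate"]]
    data.frame(threshold = th,
               slope_low = lo$slope, n_low = lo$n,
               slope_moderate = mo$slope, n_moderate = mo$n,
               interaction_p = cmp$interaction_p,
               flagged_small_class = lo$n < min_n || mo$n < min_n)
  })
  do.call(rbind, rows)
}

#' Fold change implied by a log-log slope
#'
#' On a log-log line, multiplying x by `factor` multiplies y by
#' `factor^slope`.
#'
#' @param slope Log-log regression slope.
#' @param factor Multiplicative change in x (> 0).
#' @param digits Optional rounding of the returned fold change.
#' @return `factor^slope`, optionally rounded.
#' @export
fold_change <- function(slope, factor, digits = NULL) {
  stopifnot(factor > 0)
  fc <- factor^slope
  if (!is.null(digits)) fc <- round(fc, digits)
  fc
}

#' Percent difference between two log-scale fits at a reference x
#'
#' Evaluates two natural-log-scale lines at `x0` and returns the percent
#' increase from the first (e.g. low-P) to the second (e.g. moderate-P):
#' `100 * (exp(pred2 - pred1) - 1)`.
#'
#' @param x0 Reference x value on the original (unlogged) scale.
#' @param fit_low,fit_mod `regression_result` objects on the `ln` scale,
#'   or lists with `intercept` and `slope` on that scale.
#' @return Percent difference at `x0`.
#' @export
class_contrast_at <- function(x0, fit_low, fit_mod) {
  pred_l <- fit_low$intercept + fit_low$slope * log(x0)
  pred_m <- fit_mod$intercept + fit_mod$slope * log(x0)
  100 * (exp(pred_m - pred_l) - 1)
}
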