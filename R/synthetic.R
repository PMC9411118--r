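# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (is.null(seed) || !is.finite(seed)) stop("a seed is required")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Residual sd that makes the expected r2 of a fit equal `target_r2`,
# given the variance of the generating linear predictor.
.resid_sd_for_r2 <- function(var_fitted, target_r2) {
  stopifnot(target_r2 > 0, target_r2 <= 1)
  sqrt(var_fitted * (1 - target_r2) / target_r2)
}

#' Generate a synthetic species-site leaf trait table
#'
#' Emulates the statistical structure of a pan-tropical leaf trait
#' compilation: `(ln Nmass, ln Pmass)` bivariate normal with a chosen
#' squared correlation (default 0.39), photosynthetic responses generated
#' from a published coefficient set plus Gaussian log-scale residuals
#' calibrated so each response's expected r-squared matches the printed
#' value, and `Ma` from its own N-P interaction model. Defaults centre
#' `Nmass` on its dataset median of 20 mg g-1 and `Pmass` on 0.92 mg g-1,
#' with log-scale sds chosen so the P range spans roughly 50-fold at
#' n = 446.
#'
#' @param n Number of species-site rows (default 446).
#' @param seed RNG seed (required).
#' @param meanlog_N,sdlog_N Mean and sd of `ln Nmass` (defaults
#'   `log(20)`, 0.35).
#' @param meanlog_P,sdlog_P Mean and sd of `ln Pmass` (defaults
#'   `log(0.92)`, 0.63).
#' @param nutrient_r2 Target squared correlation between the logs
#'   (default 0.39; must be in `[0, 1)`).
#' @param set Generating coefficient set (see [np_coefficients()]);
#'   default `"table2"`, whose rows carry printed r-squared values used to
#'   calibrate residual noise.
#' @param continents Character vector of continent labels assigned
#'   uniformly at random (no continent effect is generated).
#' @return A data.frame with columns `species`, `site`, `continent`,
#'   `Nmass`, `Pmass`, `Ma`, `Vcmax_mass`, `Jmax_mass`, `Amass`,
#'   `Vcmax25`, `Jmax25`, `Anet` (area basis via `Ma`), `Narea`, `Parea`.
#' @export
gen_leaf_traits <- function(n = 446, seed,
                            meanlog_N = log(20), sdlog_N = 0.35,
                            meanlog_P = log(0.92), sdlog_P = 0.63,
                            nutrient_r2 = 0.39,
                            set = "table2",
                            continents = c("South America", "Africa",
                                           "Asia", "Australia")) {
  stopifnot(sdlog_N > 0, sdlog_P > 0)
  if (nutrient_r2 < 0 || nutrient_r2 >= 1)
    stop("nutrient_r2 must be in [0, 1)")
  co <- np_coefficients(set)
  .with_seed(seed, {
    rho <- sqrt(nutrient_r2)
    lN <- rnorm(n, meanlog_N, sdlog_N)
    lP <- meanlog_P + rho * sdlog_P / sdlog_N * (lN - meanlog_N) +
      sqrt(1 - rho^2) * sdlog_P * rnorm(n)
    gen_response <- function(cf) {
      lin <- cf["intercept"] + cf["lnN"] * lN + cf["lnP"] * lP
      if ("lnN_lnP" %in% names(cf)) lin <- lin + cf["lnN_lnP"] * lN * lP
      r2 <- if ("r2" %in% names(cf)) cf[["r2"]] else 1
      sdr <- if (r2 < 1) .resid_sd_for_r2(var(lin), r2) else 0
      exp(lin + rnorm(n, 0, sdr))
    }
    d <- data.frame(
      species = sprintf("sp%03d", seq_len(n)),
      site = sprintf("site%02d", rep_len(seq_len(max(1, n %/% 9)), n)),
      continent = sample(continents, n, replace = TRUE),
      Nmass = exp(lN), Pmass = exp(lP),
      stringsAsFactors = FALSE)
    d$Ma <- gen_response(np_coefficients("table2")$Ma)
    d$Vcmax_mass <- gen_response(co$Vcmax_mass)
    d$Jmax_mass <- gen_response(co$Jmax_mass)
    d$Amass <- if (!is.null(co$Amass)) gen_response(co$Amass)
      else d$Vcmax_mass * 0.3
    d$Vcmax25 <- mass_area_convert(d$Vcmax_mass, d$Ma)
    d$Jmax25 <- mass_area_convert(d$Jmax_mass, d$Ma)
    d$Anet <- mass_area_convert(d$Amass, d$Ma)
    d$Narea <- d$Nmass * d$Ma / 1000
    d$Parea <- d$Pmass * d$Ma / 1000
    d
  })
}

#' Generate a synthetic A-Ci curve from known FvCB parameters
#'
#' Forward-simulates [net_assimilation()] on a Ci grid and adds Gaussian
#' instrument noise on the linear scale. Stomatal conductance and light
#' are filled with configurable defaults that pass (or, if chosen low,
#' deliberately fail) the quality filters.
#'
#' @param biochem A [leaf_biochem()] object (true values at 25 C).
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @param Tleaf Leaf temperature (degrees C).
#' @param Ci_grid Ci values (umol mol-1), >= 5 points spanning low and
#'   high Ci.
#' @param noise_sd Additive noise sd (umol m-2 s-1).
#' @param kin A [kinetic_constants()] object.
#' @param gsw,PPFD Values recorded on every point.
#' @param ... Passed to [aci_curve()] (identifiers).
#' @return An [aci_curve()].
#' @export
gen_aci_curve <- function(biochem, seed = NULL, Tleaf = 25,
                          Ci_grid = c(50, 100, 150, 200, 250, 350, 500,
                                      700, 900, 1200, 1500),
                          noise_sd = 0, kin = kinetic_constants(),
                          gsw = 200, PPFD = 1800, ...) {
  if (length(Ci_grid) < 5) stop("Ci_grid needs at least 5 points")
  A <- net_assimilation(Ci_grid, biochem, kin, Tleaf)
  if (noise_sd > 0) {
    A <- .with_seed(seed, A + rnorm(length(A), 0, noise_sd))
  }
  aci_curve(Ci = Ci_grid, Anet = A, Tleaf = Tleaf, PPFD = PPFD, gsw = gsw,
            ...)
}

#' Generate (Vcmax, Jmax) pairs around a known linear relationship
#'
#' Vcmax is uniform on `Vcmax_range`; Jmax is the line plus Gaussian noise
#' whose sd is solved analytically so the expected r-squared equals
#' `target_r2`: `sd^2 = slope^2 * width^2 / 12 * (1 - r2) / r2`.
#'
#' @param n Number of pairs.
#' @param slope,intercept Generating line (linear scale).
#' @param target_r2 Target r-squared in (0, 1].
#' @param Vcmax_range Range of Vcmax (umol m-2 s-1).
#' @param seed RNG seed (required).
#' @return A data.frame with columns `Vcmax`, `Jmax`.
#' @export
gen_jv_dataset <- function(n, slope = 1.52, intercept = 17.5,
                           target_r2 = 0.82, Vcmax_range = c(10, 150),
                           seed) {
  stopifnot(n >= 3, target_r2 > 0, target_r2 <= 1)
  var_fitted <- slope^2 * diff(Vcmax_range)^2 / 12
  sdr <- .resid_sd_for_r2(var_fitted, target_r2)
  .with_seed(seed, {
    V <- runif(n, Vcmax_range[1], Vcmax_range[2])
    data.frame(Vcmax = V, Jmax = intercept + slope * V + rnorm(n, 0, sdr))
  })
}

#' Generate a power-law trait dataset with a known log-log line
#'
#' Draws `x` log-normally and sets `ln y = intercept + slope * ln x +`
#' Gaussian noise calibrated so the expected r-squared equals
#' `target_r2`. Used to study recovery of single-factor log-log slopes
#' and class-wise slope differences.
#'
#' @param n Number of observations.
#' @param intercept,slope Generating line on the natural-log scale.
#' @param target_r2 Expected r-squared in (0, 1].
#' @param meanlog_x,sdlog_x Log-scale mean and sd of x.
#' @param seed RNG seed (required).
#' @return A data.frame with columns `x`, `y` (both positive).
#' @export
gen_loglog_dataset <- function(n, intercept, slope, target_r2,
                               meanlog_x = log(20), sdlog_x = 0.35, seed) {
  stopifnot(n >= 3, target_r2 > 0, target_r2 <= 1)
  .with_seed(seed, {
    lx <- rnorm(n, meanlog_x, sdlog_x)
    var_fitted <- slope^2 * var(lx)
    sdr <- if (target_r2 < 1) .resid_sd_for_r2(var_fitted, target_r2) else 0
    ly <- intercept + slope * lx + rnorm(n, 0, sdr)
    data.frame(x = exp(lx), y = exp(ly))
  })
}
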