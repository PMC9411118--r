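#' Construct a table of canopy grid cells
#'
#' A desk-scale stand-in for a gridded tropical/subtropical forcing field:
#' each row is one cell with leaf stoichiometry, canopy structure and a
#' simple radiation/temperature climate. All defaults are package plumbing
#' choices, not published values, and every one is overridable.
#'
#' @param lat,lon Coordinates (degrees); `abs(lat)` must be <= 35, the
#'   tropical/subtropical domain.
#' @param Nmass,Pmass Leaf N and P (mg g-1).
#' @param Ma Leaf dry mass per area (g m-2).
#' @param LAI Leaf area index (m2 m-2, >= 0).
#' @param Tgrowth Growth (and assumed leaf) temperature (degrees C).
#' @param PPFD_peak Midday photosynthetic photon flux density
#'   (umol m-2 s-1).
#' @param Ca Atmospheric CO2 (umol mol-1).
#' @param CiCa Ratio of intercellular to atmospheric CO2 (0 < CiCa < 1).
#' @return A data.frame of class `canopy_cells`.
#' @export
canopy_cells <- function(lat, lon = 0, Nmass = 20, Pmass = 1, Ma = 100,
                         LAI = 5, Tgrowth = 25, PPFD_peak = 2000,
                         Ca = 400, CiCa = 0.7) {
  d <- data.frame(lat = lat, lon = lon, Nmass = Nmass, Pmass = Pmass,
                  Ma = Ma, LAI = LAI, Tgrowth = Tgrowth,
                  PPFD_peak = PPFD_peak, Ca = Ca, CiCa = CiCa)
  if (any(abs(d$lat) > 35)) stop("cells must lie within 35 degrees N/S")
  if (any(d$LAI < 0)) stop("LAI must be >= 0")
  if (any(d$CiCa <= 0 | d$CiCa >= 1)) stop("CiCa must be in (0, 1)")
  if (any(d$Nmass <= 0 | d$Pmass <= 0 | d$Ma <= 0))
    stop("Nmass, Pmass and Ma must be > 0")
  structure(d, class = c("canopy_cells", "data.frame"))
}

# Non-rectangular hyperbola for electron transport at absorbed light Q.
.nrh_j <- function(Q, Jmax, alpha = 0.3, theta = 0.7) {
  b <- alpha * Q + Jmax
  (b - sqrt(b^2 - 4 * theta * alpha * Q * Jmax)) / (2 * theta)
}

#' Annual gross primary productivity for one canopy cell
#'
#' A deliberately simple big-leaf engine: leaf Vcmax and Jmax are
#' predicted from (Nmass, Pmass) with [predict_biochem_mass()], converted
#' to an area basis with the cell's Ma, scaled to canopy totals with
#' Beer-law light absorption (`(1 - exp(-k LAI)) / k`), and gross
#' assimilation `min(Ac, Aj)` (no respiration term: GPP is gross) is
#' integrated over a sinusoidal 12-hour photoperiod at fixed `Ci/Ca` and
#' leaf temperature equal to the growth temperature, times 365 days.
#' Electron transport follows a non-rectangular hyperbola in absorbed
#' light. Deterministic: no randomness anywhere.
#'
#' @param cell One row of a [canopy_cells()] table (or a list with the
#'   same fields).
#' @param set Predictor coefficient set, see [np_coefficients()].
#' @param kin A [kinetic_constants()] object; its `Tgrowth` is overridden
#'   by the cell's.
#' @param k Canopy light-extinction coefficient (default 0.5).
#' @param alpha Quantum yield of electron transport (e- per photon,
#'   default 0.3).
#' @param theta Curvature of the light response (default 0.7).
#' @param n_steps Diurnal integration steps (default 48).
#' @return GPP in g C m-2 y-1.
#' @export
big_leaf_gpp <- function(cell, set = "methods", kin = kinetic_constants(),
                         k = 0.5, alpha = 0.3, theta = 0.7, n_steps = 48) {
  kin$Tgrowth <- cell$Tgrowth
  kin$deltaS_V <- 668.39 - 1.07 * kin$Tgrowth
  kin$deltaS_J <- 659.70 - 0.75 * kin$Tgrowth
  pred <- tryCatch(predict_biochem_mass(cell$Nmass, cell$Pmass, set),
                   error = function(e)
                     stop("cell (", cell$lat, ", ", cell$lon, "): ",
                          conditionMessage(e)))
  Vc25 <- mass_area_convert(pred$Vcmax_mass, cell$Ma)
  J25  <- mass_area_convert(pred$Jmax_mass, cell$Ma)
  # canopy scaling: big-leaf effective leaf area under Beer-law extinction
  Lc <- if (cell$LAI > 0) (1 - exp(-k * cell$LAI)) / k else 0

  Tleaf <- cell$Tgrowth
  Vc <- scale_to_leaf_temperature(Vc25, "Vcmax", kin, Tleaf)
  Jm <- scale_to_leaf_temperature(J25, "Jmax", kin, Tleaf)
  Kc <- scale_to_leaf_temperature(kin$Kc25, "Kc", kin, Tleaf)
  Ko <- scale_to_leaf_temperature(kin$Ko25, "Ko", kin, Tleaf)
  Gs <- scale_to_leaf_temperature(kin$GammaStar25, "GammaStar", kin, Tleaf)
  Km <- Kc * (1 + kin$O / Ko)
  Ci <- cell$CiCa * cell$Ca

  # sinusoidal 12-h photoperiod, midpoint rule over n_steps intervals
  h <- (seq_len(n_steps) - 0.5) * 12 / n_steps
  Q <- cell$PPFD_peak * sin(pi * h / 12)
  J <- .nrh_j(Q, Jm, alpha, theta)
  Ac <- Vc * (Ci - Gs) / (Ci + Km)
  Aj <- J * (Ci - Gs) / (4 * Ci + 8 * Gs)
  A_leaf <- pmax(pmin(Ac, Aj), 0)       # gross, umol m-2(leaf) s-1
  # daily canopy integral (umol m-2(ground) d-1), then annual g C m-2 y-1
  daily <- sum(A_leaf) * (12 * 3600 / n_steps) * Lc
  daily * 365 * 12.011e-6
}

#' Contrast P-limited and P-unlimited canopy photosynthesis
#'
#' Runs [big_leaf_gpp()] twice per cell: once with the observed leaf
#' Pmass, once with Pmass raised to the unlimited-P value `Nmass / 5`
#' (clamped so it is never below the observed Pmass). The P-acquisition
#' scalar [p_acquisition_scalar()] is reported per cell as a diagnostic
#' only; it feeds back on nothing.
#'
#' @param cells A [canopy_cells()] table (>= 1 row).
#' @inheritParams big_leaf_gpp
#' @return A list of class `scenario_result`: `cells` (per-cell
#'   data.frame with `gpp_limited`, `gpp_unlimited`,
#'   `fractional_reduction`, `p_acquisition`), `zonal` (per 2-degree band,
#'   from [zonal_aggregate()]), and totals-weighted summary fields
#'   `gpp_limited`, `gpp_unlimited`, `fractional_reduction`.
#' @export
scenario_compare <- function(cells, set = "methods",
                             kin = kinetic_constants(), ...) {
  if (nrow(cells) == 0) stop("need at least one cell")
  per <- as.data.frame(cells)
  res <- lapply(seq_len(nrow(per)), function(i) {
    cell <- as.list(per[i, ])
    g_lim <- big_leaf_gpp(cell, set, kin, ...)
    cell_unl <- cell
    cell_unl$Pmass <- max(cell$Pmass, unlimited_p_leaf(cell$Nmass))
    g_unl <- big_leaf_gpp(cell_unl, set, kin, ...)
    c(gpp_limited = g_lim, gpp_unlimited = g_unl)
  })
  res <- do.call(rbind, res)
  per$gpp_limited <- res[, "gpp_limited"]
  per$gpp_unlimited <- res[, "gpp_unlimited"]
  per$fractional_reduction <-
    ifelse(per$gpp_unlimited > 0, 1 - per$gpp_limited / per$gpp_unlimited, 0)
  per$p_acquisition <- p_acquisition_scalar(per$Nmass / per$Pmass)
  w <- cos(per$lat * pi / 180)
  g_lim <- sum(w * per$gpp_limited) / sum(w)
  g_unl <- sum(w * per$gpp_unlimited) / sum(w)
  structure(list(
    cells = per,
    zonal = zonal_aggregate(per),
    gpp_limited = g_lim,
    gpp_unlimited = g_unl,
    fractional_reduction = if (g_unl > 0) 1 - g_lim / g_unl else 0
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("GPP scenario contrast over %d cells\n", nrow(x$cells)))
  cat(sprintf("  area-weighted GPP: limited %.1f, unlimited %.1f g C m-2 y-1\n",
              x$gpp_limited, x$gpp_unlimited))
  cat(sprintf("  fractional reduction: %.3f\n", x$fractional_reduction))
  invisible(x)
}

#' Aggregate per-cell scenario results into 2-degree latitude bands
#'
#' Area-weighted (cosine-latitude) means of the limited and unlimited GPP
#' and their difference, per 2-degree latitudinal band.
#'
#' @param per_cell A data.frame with `lat`, `gpp_limited`,
#'   `gpp_unlimited`.
#' @param band_width Band width in degrees (default 2).
#' @return A data.frame with one row per occupied band: `lat_mid`,
#'   `gpp_limited`, `gpp_unlimited`, `gpp_difference`, `n_cells`.
#' @export
zonal_aggregate <- function(per_cell, band_width = 2) {
  band <- floor(per_cell$lat / band_width) * band_width
  groups <- split(per_cell, band)
  rows <- lapply(groups, function(g) {
    w <- cos(g$lat * pi / 180)
    data.frame(
      lat_mid = mean(unique(floor(g$lat / band_width)) * band_width) +
        band_width / 2,
      gpp_limited = sum(w * g$gpp_limited) / sum(w),
      gpp_unlimited = sum(w * g$gpp_unlimited) / sum(w),
      n_cells = nrow(g))
  })
  out <- do.call(rbind, rows)
  out$gpp_difference <- out$gpp_unlimited - out$gpp_limited
  rownames(out) <- NULL
  out[order(out$lat_mid), ]
}
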