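#' Predictor coefficient sets for Vcmax and Jmax from leaf N and P
#'
#' Two published coefficient sets are shipped as data in
#' `inst/extdata/np_coefficients.yaml`: the `"methods"` set (the mass- and
#' area-based equations used inside the land-surface model experiment,
#' fitted without the N x P interaction) and the `"table2"` set (the
#' full-dataset multiple-regression models including the interaction
#' term). The two differ: the interaction set gives a more pronounced leaf
#' P effect on canopy photosynthesis (by roughly 15 percent).
#'
#' @param set `"methods"` (default) or `"table2"`.
#' @return A named list of coefficient vectors with elements
#'   `Vcmax_mass`, `Jmax_mass` and, for the `"methods"` set, `Vcmax_area`
#'   and `Jmax_area`; each is `c(intercept, lnP, lnN)` or
#'   `c(intercept, lnN, lnP, lnN_lnP)` as recorded in the file.
#' @export
np_coefficients <- function(set = c("methods", "table2")) {
  set <- match.arg(set)
  path <- system.file("extdata", "np_coefficients.yaml", package = "phoslim")
  cfg <- yaml::read_yaml(path)
  if (!set %in% names(cfg)) stop("coefficient set '", set, "' not found")
  lapply(cfg[[set]], function(x) unlist(x))
}

#' Predict mass-based Vcmax and Jmax from leaf N and P concentrations
#'
#' Evaluates the mass-based predictor equations
#' `Vcmax_mass = exp(4.4490 + 0.3472 ln(Pmass) + 0.49078 ln(Nmass))` and
#' `Jmax_mass  = exp(5.4944 + 0.3735 ln(Pmass) + 0.4144 ln(Nmass))`
#' (`"methods"` set), or the interaction-model equivalents from the
#' `"table2"` set. Both are monotone increasing in each nutrient over the
#' observed trait range.
#'
#' @param Nmass,Pmass Leaf N and P concentrations (mg g-1, > 0);
#'   vectorised.
#' @param set Coefficient set, see [np_coefficients()].
#' @return A data.frame with columns `Vcmax_mass`, `Jmax_mass`
#'   (nmol g-1 s-1).
#' @export
predict_biochem_mass <- function(Nmass, Pmass, set = "methods") {
  if (any(!is.finite(Nmass)) || any(!is.finite(Pmass)) ||
      any(Nmass <= 0) || any(Pmass <= 0))
    stop("Nmass and Pmass must be finite and > 0")
  co <- np_coefficients(set)
  lN <- log(Nmass); lP <- log(Pmass)
  eval_one <- function(cf) {
    if ("lnN_lnP" %in% names(cf))
      exp(cf["intercept"] + cf["lnN"] * lN + cf["lnP"] * lP +
            cf["lnN_lnP"] * lN * lP)
    else
      exp(cf["intercept"] + cf["lnP"] * lP + cf["lnN"] * lN)
  }
  data.frame(Vcmax_mass = unname(eval_one(co$Vcmax_mass)),
             Jmax_mass = unname(eval_one(co$Jmax_mass)))
}

#' Predict area-based Vcmax and Jmax from area-based leaf N and P
#'
#' Evaluates `Vcmax = exp(4.308 + 0.298 ln(Parea) + 0.197 ln(Narea))` and
#' `Jmax = exp(5.139 + 0.325 ln(Parea) + 0.112 ln(Narea))`. These were
#' fitted to area-based data directly and are independent of the
#' mass-based equations; the package never chains the two silently.
#'
#' @param Narea,Parea Area-based leaf N and P (g m-2, > 0); vectorised.
#' @return A data.frame with columns `Vcmax`, `Jmax` (umol m-2 s-1).
#' @export
predict_biochem_area <- function(Narea, Parea) {
  if (any(!is.finite(Narea)) || any(!is.finite(Parea)) ||
      any(Narea <= 0) || any(Parea <= 0))
    stop("Narea and Parea must be finite and > 0")
  co <- np_coefficients("methods")
  eval_one <- function(cf)
    exp(cf["intercept"] + cf["lnP"] * log(Parea) + cf["lnN"] * log(Narea))
  data.frame(Vcmax = unname(eval_one(co$Vcmax_area)),
             Jmax = unname(eval_one(co$Jmax_area)))
}

#' Convert a rate between mass and area bases
#'
#' `area (umol m-2 s-1) = mass (nmol g-1 s-1) * Ma / 1000`, where `Ma` is
#' leaf dry mass per area in g m-2; the two directions are exact inverses.
#'
#' @param value Rate to convert.
#' @param Ma Leaf dry mass per area (g m-2, > 0).
#' @param direction `"mass_to_area"` or `"area_to_mass"`.
#' @return The rate on the other basis.
#' @export
mass_area_convert <- function(value, Ma,
                              direction = c("mass_to_area", "area_to_mass")) {
  direction <- match.arg(direction)
  if (any(!is.finite(Ma)) || any(Ma <= 0)) stop("Ma must be > 0")
  if (direction == "mass_to_area") value * Ma / 1000 else value * 1000 / Ma
}

#' Jmax from Vcmax by leaf-P class
#'
#' The linear Jmax-Vcmax relationships fitted to the two end-member leaf
#' P classes: `Jmax = 17.5 + 1.52 Vcmax` for low Pmass and
#' `Jmax = 12.8 + 1.79 Vcmax` for high Pmass, both at 25 C. The shallower
#' low-P line reflects a stronger P effect on electron-transport capacity
#' than on carboxylation.
#'
#' @param Vcmax Carboxylation capacity (umol m-2 s-1, >= 0); vectorised.
#' @param p_class `"low"` or `"high"`.
#' @return Jmax (umol m-2 s-1).
#' @export
jv_line <- function(Vcmax, p_class = c("low", "high")) {
  p_class <- match.arg(p_class)
  stopifnot(all(Vcmax >= 0))
  co <- jv_coefficients(p_class)
  co[["intercept"]] + co[["slope"]] * Vcmax
}

#' Coefficients of the class-specific Jmax-Vcmax lines
#'
#' @param p_class `"low"` or `"high"`.
#' @return Named vector with `intercept`, `slope`, `r2`, `n`.
#' @export
jv_coefficients <- function(p_class = c("low", "high")) {
  p_class <- match.arg(p_class)
  if (p_class == "low") c(intercept = 17.5, slope = 1.52, r2 = 0.82, n = 111)
  else c(intercept = 12.8, slope = 1.79, r2 = 0.71, n = 112)
}

#' Sigmoidal phosphorus-acquisition scalar
#'
#' `f(N:P) = 1 / (1 + exp(-(N:P)/2 + 10))`, a scalar in (0,1) applied to
#' plant P-acquisition processes (biochemical mineralisation and root
#' uptake). It rises sharply between N:P of 15 and 25 g g-1, the range
#' where plant communities shift from N- to P-limitation, with its
#' midpoint f = 0.5 exactly at N:P = 20.
#'
#' @param NtoP Plant N:P mass ratio (g N per g P, > 0); vectorised.
#' @return Scalar in (0, 1), strictly increasing in `NtoP`.
#' @export
p_acquisition_scalar <- function(NtoP) {
  if (any(!is.finite(NtoP)) || any(NtoP <= 0)) stop("NtoP must be > 0")
  1 / (1 + exp(-NtoP / 2 + 10))
}

#' Leaf P under unlimited P supply
#'
#' The P-unlimited diagnostic sets leaf P to the maximum consistent with
#' the minimum observed N:P ratio of 5 g N (g P)-1: `Pmass = Nmass / 5`.
#'
#' @param Nmass Leaf N concentration (mg g-1, > 0); vectorised.
#' @return Leaf P concentration (mg g-1) at N:P = 5.
#' @export
unlimited_p_leaf <- function(Nmass) {
  if (any(!is.finite(Nmass)) || any(Nmass <= 0)) stop("Nmass must be > 0")
  Nmass / 5
}

#' Predict leaf dry mass per area from leaf N and P
#'
#' Evaluates the full-dataset Ma multiple-regression model
#' `Ma = exp(6.484 - 0.598 ln(Nmass) + 0.461 ln(Pmass)
#'           - 0.214 ln(Nmass) ln(Pmass))` (g m-2).
#'
#' @param Nmass,Pmass Leaf N and P concentrations (mg g-1, > 0).
#' @return Ma (g m-2).
#' @export
predict_ma <- function(Nmass, Pmass) {
  if (any(Nmass <= 0) || any(Pmass <= 0)) stop("Nmass and Pmass must be > 0")
  co <- np_coefficients("table2")$Ma
  unname(exp(co["intercept"] + co["lnN"] * log(Nmass) +
               co["lnP"] * log(Pmass) +
               co["lnN_lnP"] * log(Nmass) * log(Pmass)))
}
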