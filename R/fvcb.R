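#' @importFrom stats coef lm optimize pf rnorm runif sd setNames var vcov anova
NULL

# Universal gas constant, J mol-1 K-1
.Rgas <- 8.314
.T25K <- 298.15

#' Kinetic and temperature-response constants for the FvCB model
#'
#' Bundles the Rubisco kinetic constants at 25 degrees C, their activation
#' energies, and the peaked temperature-response parameters for `Vcmax` and
#' `Jmax`, including the growth-temperature acclimation of the entropy
#' terms. Defaults are the widely used tobacco-derived kinetics
#' (Kc25 = 404.9 umol mol-1, Ko25 = 278.4 mmol mol-1,
#' GammaStar25 = 42.75 umol mol-1) and the meta-analysis acclimation forms
#' deltaS_V = 668.39 - 1.07 Tgrowth and deltaS_J = 659.70 - 0.75 Tgrowth
#' (J mol-1 K-1) with Ha_V = 71513, Ha_J = 49884 and Hd = 200000 J mol-1.
#'
#' @param Kc25 Michaelis constant of Rubisco for CO2 at 25 C (umol mol-1).
#' @param Ko25 Michaelis constant of Rubisco for O2 at 25 C (mmol mol-1).
#' @param GammaStar25 CO2 compensation point without day respiration at
#'   25 C (umol mol-1).
#' @param O Oxygen mole fraction (mmol mol-1).
#' @param Ea_Kc,Ea_Ko,Ea_GammaStar Arrhenius activation energies (J mol-1).
#' @param Ha_V,Ha_J Activation energies of the peaked response for Vcmax
#'   and Jmax (J mol-1).
#' @param Hd Deactivation energy shared by Vcmax and Jmax (J mol-1).
#' @param Ea_Rd Activation energy for day respiration (J mol-1).
#' @param Tgrowth Growth temperature (degrees C) controlling the entropy
#'   terms via the acclimation relations.
#' @param deltaS_V,deltaS_J Entropy terms (J mol-1 K-1); computed from
#'   `Tgrowth` when `NULL`.
#' @return An object of class `kinetic_constants` (a named list).
#' @export
kinetic_constants <- function(Kc25 = 404.9, Ko25 = 278.4, GammaStar25 = 42.75,
                              O = 210,
                              Ea_Kc = 79430, Ea_Ko = 36380, Ea_GammaStar = 37830,
                              Ha_V = 71513, Ha_J = 49884, Hd = 200000,
                              Ea_Rd = 46390,
                              Tgrowth = 25,
                              deltaS_V = NULL, deltaS_J = NULL) {
  if (is.null(deltaS_V)) deltaS_V <- 668.39 - 1.07 * Tgrowth
  if (is.null(deltaS_J)) deltaS_J <- 659.70 - 0.75 * Tgrowth
  kin <- list(Kc25 = Kc25, Ko25 = Ko25, GammaStar25 = GammaStar25, O = O,
              Ea_Kc = Ea_Kc, Ea_Ko = Ea_Ko, Ea_GammaStar = Ea_GammaStar,
              Ha_V = Ha_V, Ha_J = Ha_J, Hd = Hd, Ea_Rd = Ea_Rd,
              Tgrowth = Tgrowth, deltaS_V = deltaS_V, deltaS_J = deltaS_J)
  ener <- c(kin$Ea_Kc, kin$Ea_Ko, kin$Ea_GammaStar, kin$Ha_V, kin$Ha_J,
            kin$Hd, kin$Ea_Rd)
  if (any(!is.finite(unlist(kin))))
    stop("all kinetic constants must be finite")
  if (any(ener <= 0)) stop("activation/deactivation energies must be > 0")
  if (Kc25 <= 0 || Ko25 <= 0 || GammaStar25 <= 0 || O <= 0)
    stop("Kc25, Ko25, GammaStar25 and O must be > 0")
  # optimum of the peaked function must sit above 0 C
  if (deltaS_V <= 0 || deltaS_J <= 0 ||
      deltaS_V >= Hd / 273.15 || deltaS_J >= Hd / 273.15)
    stop("entropy terms must satisfy 0 < deltaS < Hd/273.15 K")
  structure(kin, class = "kinetic_constants")
}

#' Read kinetic constants from a YAML configuration file
#'
#' Any constant omitted from the file keeps its [kinetic_constants()]
#' default. Field names match the arguments of [kinetic_constants()].
#'
#' @param path Path to a YAML file.
#' @return A `kinetic_constants` object.
#' @export
read_kinetics <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(kinetic_constants))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown kinetic constant(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  do.call(kinetic_constants, vals)
}

#' Leaf biochemical capacities at 25 degrees C
#'
#' @param Vcmax25 Maximum Rubisco carboxylation rate (umol m-2 s-1).
#' @param Jmax25 Maximum electron-transport rate for RuBP regeneration
#'   (umol m-2 s-1).
#' @param Rd25 Day respiration (umol m-2 s-1).
#' @return An object of class `leaf_biochem`.
#' @export
leaf_biochem <- function(Vcmax25, Jmax25, Rd25 = 0) {
  stopifnot(is.finite(Vcmax25), is.finite(Jmax25), is.finite(Rd25))
  if (Vcmax25 <= 0 || Jmax25 <= 0) stop("Vcmax25 and Jmax25 must be > 0")
  if (Rd25 < 0) stop("Rd25 must be >= 0")
  structure(list(Vcmax25 = Vcmax25, Jmax25 = Jmax25, Rd25 = Rd25),
            class = "leaf_biochem")
}

.arrhenius_factor <- function(Ea, TleafK) {
  exp(Ea / .Rgas * (1 / .T25K - 1 / TleafK))
}

# Peaked (deactivating) response, normalised to 1 at 25 C.
.peaked_factor <- function(Ha, Hd, deltaS, TleafK) {
  .arrhenius_factor(Ha, TleafK) *
    (1 + exp((.T25K * deltaS - Hd) / (.T25K * .Rgas))) /
    (1 + exp((TleafK * deltaS - Hd) / (TleafK * .Rgas)))
}

.temp_factor <- function(which, kin, Tleaf) {
  TleafK <- Tleaf + 273.15
  switch(which,
    Vcmax     = .peaked_factor(kin$Ha_V, kin$Hd, kin$deltaS_V, TleafK),
    Jmax      = .peaked_factor(kin$Ha_J, kin$Hd, kin$deltaS_J, TleafK),
    Rd        = .arrhenius_factor(kin$Ea_Rd, TleafK),
    Kc        = .arrhenius_factor(kin$Ea_Kc, TleafK),
    Ko        = .arrhenius_factor(kin$Ea_Ko, TleafK),
    GammaStar = .arrhenius_factor(kin$Ea_GammaStar, TleafK),
    stop("unknown parameter class '", which, "'; expected one of ",
         "Vcmax, Jmax, Rd, Kc, Ko, GammaStar")
  )
}

#' Scale a rate from 25 degrees C to leaf temperature
#'
#' Arrhenius scaling for `Kc`, `Ko`, `GammaStar` and `Rd`; the peaked
#' (deactivating) response for `Vcmax` and `Jmax`, whose entropy terms
#' acclimate to the growth temperature stored in `kin`. The factor is
#' exactly 1 at 25 C.
#'
#' @param value25 Value at 25 C (>= 0).
#' @param which One of `"Vcmax"`, `"Jmax"`, `"Rd"`, `"Kc"`, `"Ko"`,
#'   `"GammaStar"`.
#' @param kin A [kinetic_constants()] object.
#' @param Tleaf Leaf temperature (degrees C).
#' @return The value at `Tleaf`.
#' @export
scale_to_leaf_temperature <- function(value25, which, kin, Tleaf) {
  stopifnot(all(value25 >= 0), all(is.finite(Tleaf)))
  value25 * .temp_factor(which, kin, Tleaf)
}

#' Normalise a rate measured at leaf temperature to 25 degrees C
#'
#' Exact inverse of [scale_to_leaf_temperature()]; the round trip is the
#' identity to machine precision.
#'
#' @inheritParams scale_to_leaf_temperature
#' @param value_at_T Value at `Tleaf` (>= 0).
#' @return The value at 25 C.
#' @export
normalize_to_25 <- function(value_at_T, which, kin, Tleaf) {
  stopifnot(all(value_at_T >= 0), all(is.finite(Tleaf)))
  f <- .temp_factor(which, kin, Tleaf)
  if (any(f < .Machine$double.xmin))
    stop("temperature scaling factor underflow at Tleaf = ", Tleaf)
  value_at_T / f
}

#' Net CO2 assimilation from the FvCB model
#'
#' Computes the light-saturated net assimilation rate as the minimum of the
#' Rubisco-limited rate `Ac = Vcmax (Ci - GammaStar) / (Ci + Km)`, with
#' `Km = Kc (1 + O/Ko)`, and the RuBP-regeneration-limited rate
#' `Aj = J (Ci - GammaStar) / (4 Ci + 8 GammaStar)`, minus day respiration.
#' At saturating light `J = Jmax`. All rate parameters and kinetic
#' constants are first scaled from 25 C to `Tleaf`. Mesophyll conductance
#' is assumed infinite, so `Ci` stands for the chloroplast CO2 mole
#' fraction.
#'
#' @param Ci Intercellular CO2 mole fraction (umol mol-1); vectorised.
#' @param biochem A [leaf_biochem()] object (values at 25 C).
#' @param kin A [kinetic_constants()] object.
#' @param Tleaf Leaf temperature (degrees C), scalar or one per `Ci`.
#' @return Net assimilation (umol m-2 s-1), same length as `Ci`.
#' @export
net_assimilation <- function(Ci, biochem, kin = kinetic_constants(),
                             Tleaf = 25) {
  if (any(!is.finite(Ci)) || any(Ci < 0))
    stop("Ci must be finite and non-negative")
  if (any(!is.finite(Tleaf)) || any(Tleaf < 0) || any(Tleaf > 50))
    stop("Tleaf must lie in [0, 50] degrees C")
  lim <- fvcb_limitations(Ci, biochem, kin, Tleaf)
  pmin(lim$Ac, lim$Aj) - lim$Rd
}

#' Component limitation rates of the FvCB model
#'
#' Returns the gross Rubisco-limited (`Ac`) and RuBP-regeneration-limited
#' (`Aj`) rates and day respiration (`Rd`), all at `Tleaf`.
#'
#' @inheritParams net_assimilation
#' @return A data.frame with columns `Ac`, `Aj`, `Rd`.
#' @export
fvcb_limitations <- function(Ci, biochem, kin = kinetic_constants(),
                             Tleaf = 25) {
  Vcmax <- scale_to_leaf_temperature(biochem$Vcmax25, "Vcmax", kin, Tleaf)
  Jmax  <- scale_to_leaf_temperature(biochem$Jmax25, "Jmax", kin, Tleaf)
  Rd    <- scale_to_leaf_temperature(biochem$Rd25, "Rd", kin, Tleaf)
  Kc    <- scale_to_leaf_temperature(kin$Kc25, "Kc", kin, Tleaf)
  Ko    <- scale_to_leaf_temperature(kin$Ko25, "Ko", kin, Tleaf)
  Gstar <- scale_to_leaf_temperature(kin$GammaStar25, "GammaStar", kin, Tleaf)
  Km <- Kc * (1 + kin$O / Ko)
  data.frame(
    Ac = Vcmax * (Ci - Gstar) / (Ci + Km),
    Aj = Jmax * (Ci - Gstar) / (4 * Ci + 8 * Gstar),
    Rd = rep_len(Rd, length(Ci))
  )
}
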