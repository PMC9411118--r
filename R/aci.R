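#' Construct an A-Ci curve
#'
#' One leaf's CO2-response series: per-point intercellular CO2, net
#' assimilation, leaf temperature, light level and stomatal conductance,
#' plus leaf/species/site identifiers.
#'
#' @param Ci Intercellular CO2 (umol mol-1), length >= 5, not all equal.
#' @param Anet Net assimilation (umol m-2 s-1).
#' @param Tleaf Leaf temperature (degrees C), scalar or per point.
#' @param PPFD Photosynthetic photon flux density (umol m-2 s-1).
#' @param gsw Stomatal conductance to water vapour (mmol H2O m-2 s-1).
#' @param leaf_id,species,site,continent Identifiers.
#' @return An object of class `aci_curve` (a data.frame of points with
#'   identifier attributes).
#' @export
aci_curve <- function(Ci, Anet, Tleaf = 25, PPFD = 1800, gsw = 200,
                      leaf_id = "leaf1", species = "sp1", site = "site1",
                      continent = NA_character_) {
  n <- length(Ci)
  if (n < 5) stop("an A-Ci curve needs at least 5 points")
  if (length(Anet) != n) stop("Ci and Anet lengths differ")
  if (any(!is.finite(Ci)) || any(Ci < 0)) stop("Ci must be non-negative")
  if (length(unique(Ci)) == 1) stop("Ci values must not all be equal")
  pts <- data.frame(Ci = Ci, Anet = Anet,
                    Tleaf = rep_len(Tleaf, n),
                    PPFD = rep_len(PPFD, n),
                    gsw = rep_len(gsw, n))
  structure(pts, class = c("aci_curve", "data.frame"),
            leaf_id = leaf_id, species = species, site = site,
            continent = continent)
}

#' Fit the FvCB model to an A-Ci curve
#'
#' Estimates `Vcmax25`, `Jmax25` and `Rd25` by bounded Levenberg-Marquardt
#' least squares on the forward model [net_assimilation()], with each
#' point's own leaf temperature handled by the temperature-response
#' machinery, so the returned parameters are already normalised to 25 C.
#' Three deterministic starting points are tried and the best optimum kept.
#' The relative standard error of `Vcmax25` (in percent) is derived from
#' the Jacobian-based covariance at the optimum and is the quantity the
#' curve-fit CV quality filter acts on.
#'
#' @param curve An [aci_curve()].
#' @param kin A [kinetic_constants()] object.
#' @return A list of class `fvcb_fit` with elements `biochem`
#'   ([leaf_biochem()] at 25 C), `rmse`, `cv_initial_slope` (percent),
#'   `n_points`, `converged`, and the curve identifiers.
#' @export
fit_aci <- function(curve, kin = kinetic_constants()) {
  if (!inherits(curve, "aci_curve")) stop("curve must be an aci_curve")
  if (nrow(curve) < 5) stop("an A-Ci curve needs at least 5 points")
  if (min(curve$Ci) >= 250 || max(curve$Ci) <= 400)
    warning("Ci range does not span both a low (<250) and high (>400 ",
            "umol mol-1) region; Vcmax and Jmax may not be identifiable")

  resid_fun <- function(p) {
    b <- list(Vcmax25 = p[1], Jmax25 = p[2], Rd25 = p[3])
    curve$Anet - net_assimilation(curve$Ci, b, kin, curve$Tleaf)
  }
  lower <- c(1, 2, 0)
  upper <- c(1000, 2000, 50)
  starts <- list(c(30, 60, 0.5), c(60, 120, 1), c(120, 240, 2))

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }

  ids <- attributes(curve)[c("leaf_id", "species", "site", "continent")]
  if (is.null(best)) {
    out <- list(biochem = NULL, rmse = NA_real_,
                cv_initial_slope = NA_real_, n_points = nrow(curve),
                converged = FALSE)
    return(structure(c(out, ids), class = "fvcb_fit"))
  }

  p <- best$par
  converged <- best$info %in% 1:4
  # Jacobian-based covariance; guard the noiseless case where the residual
  # variance estimate collapses to ~0.
  cv <- NA_real_
  se_v <- tryCatch(sqrt(diag(vcov(best)))[1], error = function(e) NA_real_)
  if (is.finite(se_v)) cv <- 100 * se_v / p[1]
  out <- list(
    biochem = leaf_biochem(p[1], p[2], p[3]),
    rmse = sqrt(best$deviance / nrow(curve)),
    cv_initial_slope = cv,
    n_points = nrow(curve),
    converged = converged
  )
  structure(c(out, ids), class = "fvcb_fit")
}

#' @export
print.fvcb_fit <- function(x, ...) {
  cat("FvCB fit (", x$leaf_id, "): ", sep = "")
  if (is.null(x$biochem)) {
    cat("did not converge\n")
  } else {
    cat(sprintf("Vcmax25 = %.2f, Jmax25 = %.2f, Rd25 = %.3f umol m-2 s-1\n",
                x$biochem$Vcmax25, x$biochem$Jmax25, x$biochem$Rd25))
    cat(sprintf("  rmse = %.3f, CV(Vcmax) = %.1f%%, n = %d, converged = %s\n",
                x$rmse, x$cv_initial_slope, x$n_points, x$converged))
  }
  invisible(x)
}

#' Quality-control filter for fitted leaves
#'
#' Applies the three inclusion rules used for gas-exchange compilations:
#' mean stomatal conductance must be at least 30 mmol H2O m-2 s-1 (lower
#' values indicate diffusional limitation confounding biochemical
#' interpretation), mass-based net photosynthesis must exceed
#' 20 nmol g-1 s-1, and the curve-fit CV of the initial slope must be
#' below 30 percent. A record missing any QC field is removed, never
#' silently kept. Each removed record is tagged with every rule it failed.
#'
#' @param records A data.frame with (at least) columns `gsw`
#'   (mmol m-2 s-1), `Amass` (nmol g-1 s-1) and `cv_initial_slope`
#'   (percent).
#' @param gsw_min Minimum mean stomatal conductance (default 30).
#' @param Amass_min Minimum mass-based assimilation, exclusive (default 20).
#' @param cv_max Maximum curve-fit CV in percent, exclusive (default 30).
#' @return A list with `kept` (rows passing all rules) and `removed`
#'   (failing rows with a `qc_reasons` column listing comma-separated tags
#'   among `LOW_GSW`, `LOW_AMASS`, `HIGH_CV`, `MISSING_FIELD`).
#' @export
qc_filter <- function(records, gsw_min = 30, Amass_min = 20, cv_max = 30) {
  needed <- c("gsw", "Amass", "cv_initial_slope")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("records lack QC column(s): ", paste(missing_cols, collapse = ", "))
  reasons <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    tags <- character(0)
    if (any(!is.finite(unlist(r[needed])))) tags <- c(tags, "MISSING_FIELD")
    if (is.finite(r$gsw) && r$gsw < gsw_min) tags <- c(tags, "LOW_GSW")
    if (is.finite(r$Amass) && r$Amass <= Amass_min) tags <- c(tags, "LOW_AMASS")
    if (is.finite(r$cv_initial_slope) && r$cv_initial_slope >= cv_max)
      tags <- c(tags, "HIGH_CV")
    paste(tags, collapse = ",")
  }, character(1))
  keep <- reasons == ""
  removed <- records[!keep, , drop = FALSE]
  if (nrow(removed)) removed$qc_reasons <- reasons[!keep]
  list(kept = records[keep, , drop = FALSE], removed = removed)
}

#' Species-at-site averaging
#'
#' Collapses QC-passed per-leaf records to one row per species-site
#' combination, the unit of analysis for the trait regressions: the
#' arithmetic mean of every numeric column over the leaves in the group,
#' with the group size reported as `n_leaves`. Mass- and area-based fields
#' are each averaged directly on their own basis; the stored `Ma` is the
#' group mean and the mass/area consistency identity is enforced per leaf,
#' not on group means.
#'
#' @param records A data.frame with columns `species` and `site`,
#'   optionally `continent`, plus numeric trait columns.
#' @return A data.frame with one row per species-site group.
#' @export
species_site_means <- function(records) {
  stopifnot(all(c("species", "site") %in% names(records)))
  key <- interaction(records$species, records$site, drop = TRUE, sep = "\r")
  num_cols <- names(records)[vapply(records, is.numeric, logical(1))]
  groups <- split(records, key)
  rows <- lapply(groups, function(g) {
    out <- data.frame(species = g$species[1], site = g$site[1],
                      stringsAsFactors = FALSE)
    if ("continent" %in% names(g)) {
      cc <- unique(g$continent[!is.na(g$continent)])
      if (length(cc) > 1)
        stop("conflicting continent labels within species-site group ",
             g$species[1], " / ", g$site[1])
      out$continent <- if (length(cc)) cc else NA_character_
    }
    for (cn in num_cols) out[[cn]] <- mean(g[[cn]])
    out$n_leaves <- nrow(g)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
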