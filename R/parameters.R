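#' First-order rate constants of the skin-surface mass balance
#'
#' Bundles the four first-order rate constants governing the skin-surface
#' compartment: release from the textile (`k_p`), transfer into the stratum
#' corneum (`k_sc`), inadvertent oral transfer (`k_o`) and wear-and-wash
#' removal (`k_ww`). Each constant is stored in its native unit; `k_sc` is
#' measured in diffusion-cell experiments per hour while the others are per
#' minute. The conversion to a single internal unit system (per minute)
#' happens exactly once, when a scenario is assembled for simulation.
#'
#' @param kp_per_min Release rate constant from textile to skin surface (1/min).
#' @param ksc_per_h Stratum-corneum transfer rate constant (1/h).
#' @param ko_per_min Inadvertent oral transfer rate constant (1/min).
#' @param kww_per_min Wear-and-wash removal rate constant (1/min).
#' @return An object of class `rate_constants`.
#' @examples
#' rate_constants(kp_per_min = 0.086, ksc_per_h = 1.8e-6)
#' @export
rate_constants <- function(kp_per_min = 0, ksc_per_h = 0,
                           ko_per_min = 0, kww_per_min = 0) {
  k <- c(kp_per_min = kp_per_min, ksc_per_h = ksc_per_h,
         ko_per_min = ko_per_min, kww_per_min = kww_per_min)
  if (any(!is.finite(k)) || any(k < 0)) {
    stop("all rate constants must be finite and >= 0", call. = FALSE)
  }
  structure(as.list(k), class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("First-order rate constants:\n")
  cat(sprintf("  k_p  = %g 1/min (textile release)\n", x$kp_per_min))
  cat(sprintf("  k_sc = %g 1/h   (stratum corneum)\n", x$ksc_per_h))
  cat(sprintf("  k_o  = %g 1/min (inadvertent oral)\n", x$ko_per_min))
  cat(sprintf("  k_ww = %g 1/min (wear and wash)\n", x$kww_per_min))
  invisible(x)
}

# Single point where k_sc leaves its native 1/h unit. Everything downstream
# works in ng, cm^2, min.
rates_per_min <- function(rates) {
  stopifnot(inherits(rates, "rate_constants"))
  c(kp = rates$kp_per_min,
    ksc = rates$ksc_per_h / 60,
    ko = rates$ko_per_min,
    kww = rates$kww_per_min)
}

#' Textile product in contact with skin
#'
#' Describes the donor side of the exposure model: a coated textile with a
#' given areal silver load, the skin contact area, and the fraction of the
#' load available for dermal transfer. The initial donor mass is
#' `m_p0 = areal_load * area * available_fraction` (ng).
#'
#' @param areal_load_ng_cm2 Areal Ag load of the textile (ng/cm^2).
#' @param area_cm2 Dermal contact area (cm^2).
#' @param available_fraction Fraction of the load available for transfer,
#'   in `[0, 1]`. Default 1 (all nanoparticles available).
#' @param label Optional product label.
#' @return An object of class `textile_product` with an `m_p0` field (ng).
#' @examples
#' textile_product(1530, 555, label = "AgCur face mask")
#' @export
textile_product <- function(areal_load_ng_cm2, area_cm2,
                            available_fraction = 1, label = "") {
  if (!is.finite(areal_load_ng_cm2) || areal_load_ng_cm2 < 0) {
    stop("areal_load_ng_cm2 must be >= 0", call. = FALSE)
  }
  if (!is.finite(area_cm2) || area_cm2 < 0) {
    stop("area_cm2 must be >= 0", call. = FALSE)
  }
  if (!is.finite(available_fraction) ||
      available_fraction < 0 || available_fraction > 1) {
    stop("available_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(areal_load_ng_cm2 = areal_load_ng_cm2,
         area_cm2 = area_cm2,
         available_fraction = available_fraction,
         m_p0 = areal_load_ng_cm2 * area_cm2 * available_fraction,
         label = as.character(label)),
    class = "textile_product")
}

#' @export
print.textile_product <- function(x, ...) {
  cat(sprintf("Textile product%s\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else ""))
  cat(sprintf("  areal load: %g ng/cm^2 over %g cm^2 (f_a = %g)\n",
              x$areal_load_ng_cm2, x$area_cm2, x$available_fraction))
  cat(sprintf("  initial donor mass m_p0 = %g ng\n", x$m_p0))
  invisible(x)
}

#' Skin permeation parameters from a diffusion-cell experiment
#'
#' Holds the median steady-state penetration flux, donor surface load and lag
#' time of a Franz-diffusion-cell measurement on a given skin preparation.
#' Dividing the flux by the donor load yields the first-order
#' stratum-corneum transfer rate constant (see [flux_to_rate_constant()]).
#'
#' @param flux_ng_cm2_h Median penetration flux (ng/cm^2/h).
#' @param donor_load_ug_cm2 Donor surface load (ug/cm^2); must be positive.
#' @param lag_time_h Lag time before steady-state flux (h), default 0.
#' @param condition Skin preparation, one of `"fresh"`, `"cryopreserved"`,
#'   `"glycerolized"`, `"intact"`, `"damaged"`.
#' @return An object of class `skin_permeation`.
#' @export
skin_permeation <- function(flux_ng_cm2_h, donor_load_ug_cm2,
                            lag_time_h = 0,
                            condition = c("fresh", "cryopreserved",
                                          "glycerolized", "intact",
                                          "damaged")) {
  condition <- match.arg(condition)
  if (!is.finite(flux_ng_cm2_h) || flux_ng_cm2_h < 0) {
    stop("flux must be >= 0", call. = FALSE)
  }
  if (!is.finite(donor_load_ug_cm2) || donor_load_ug_cm2 <= 0) {
    stop("donor load must be > 0", call. = FALSE)
  }
  if (!is.finite(lag_time_h) || lag_time_h < 0) {
    stop("lag time must be >= 0", call. = FALSE)
  }
  structure(
    list(flux_ng_cm2_h = flux_ng_cm2_h,
         donor_load_ug_cm2 = donor_load_ug_cm2,
         lag_time_h = lag_time_h,
         condition = condition),
    class = "skin_permeation")
}

#' Convert a penetration flux to a first-order rate constant
#'
#' The stratum-corneum transfer rate constant is the steady-state penetration
#' flux divided by the donor surface load, `k_sc = J / L`, with both expressed
#' per cm^2 so the area cancels. With `J` in ng/cm^2/h and `L` in ug/cm^2 the
#' result is `J / (1000 * L)` in 1/h.
#'
#' @param permeation A [skin_permeation()] object.
#' @return Rate constant `k_sc` (1/h), unrounded.
#' @examples
#' # fresh human skin graft: 0.2 ng/cm^2/h over a 113 ug/cm^2 donor load
#' flux_to_rate_constant(skin_permeation(0.2, 113))  # 1.77e-6 1/h
#' @export
flux_to_rate_constant <- function(permeation) {
  stopifnot(inherits(permeation, "skin_permeation"))
  permeation$flux_ng_cm2_h / (permeation$donor_load_ug_cm2 * 1000)
}

#' Exposed subject for risk characterisation
#'
#' @param bw_kg Body weight (kg). Default 60 kg, the standard adult reference
#'   weight used to normalise intake.
#' @param dnel_mg_kg_day Derived-no-effect level (mg/kg-bw/day). Default
#'   0.01, the lowest systemic DNEL for the general population.
#' @return An object of class `exposure_subject`.
#' @export
exposure_subject <- function(bw_kg = 60, dnel_mg_kg_day = 0.01) {
  if (!is.finite(bw_kg) || bw_kg <= 0) stop("bw_kg must be > 0", call. = FALSE)
  if (!is.finite(dnel_mg_kg_day) || dnel_mg_kg_day <= 0) {
    stop("dnel_mg_kg_day must be > 0", call. = FALSE)
  }
  structure(list(bw_kg = bw_kg, dnel_mg_kg_day = dnel_mg_kg_day),
            class = "exposure_subject")
}

#' Published skin permeation measurements for silver nanoparticles
#'
#' Median penetration fluxes of nanoscale silver measured in Franz diffusion
#' cells on human skin preparations in synthetic sweat, together with the
#' donor surface load, lag time, and the published first-order rate constant.
#' `ksc_computed_per_h` is the flux divided by the donor load
#' ([flux_to_rate_constant()]); it agrees with the published constant at two
#' significant figures for all rows except intact skin, where the published
#' 2.7e-7 differs slightly from the quotient 2.9e-7.
#'
#' @return A data.frame with one row per skin preparation: `condition`,
#'   `flux_ng_cm2_h`, `donor_load_ug_cm2`, `lag_time_h`,
#'   `ksc_published_per_h`, `ksc_computed_per_h`.
#' @export
skin_permeation_data <- function() {
  d <- data.frame(
    condition = c("fresh", "cryopreserved", "glycerolized",
                  "intact", "damaged"),
    flux_ng_cm2_h = c(0.2, 0.3, 3.8, 0.02, 0.10),
    donor_load_ug_cm2 = c(113, 113, 113, 70, 70),
    lag_time_h = c(8.2, 10.9, 6.3, 0, 0),
    ksc_published_per_h = c(1.8e-6, 2.7e-6, 34e-6, 0.27e-6, 1.4e-6),
    stringsAsFactors = FALSE)
  d$ksc_computed_per_h <- d$flux_ng_cm2_h / (d$donor_load_ug_cm2 * 1000)
  d
}

#' Stratum-corneum rate constant for a skin condition
#'
#' Looks up the published first-order stratum-corneum transfer constant for a
#' named skin preparation (see [skin_permeation_data()]).
#'
#' @param condition Skin preparation name.
#' @return `k_sc` in 1/h.
#' @export
ksc_for_condition <- function(condition = c("fresh", "cryopreserved",
                                            "glycerolized", "intact",
                                            "damaged")) {
  condition <- match.arg(condition)
  d <- skin_permeation_data()
  d$ksc_published_per_h[d$condition == condition]
}

#' Areal silver loads of the coated textile batches
#'
#' Measured Ag areal loads (ICP-MS) of the spray-coated textile batches for
#' the three coating families: curcumin-capped silver (AgCur) and silver in
#' quaternised hydroxyethylcellulose at two molar ratios (AgHEC6.4, AgHEC).
#'
#' @return A data.frame with `sample`, `family`, `load_ng_cm2`, `sd_ng_cm2`.
#' @export
textile_load_data <- function() {
  data.frame(
    sample = c("AgCurA", "AgCurB", "AgCurC", "AgCurC(P)", "AgCurD", "AgCurE",
               "AgHEC6.4A", "AgHEC6.4B", "AgHEC6.4C", "AgHEC6.4C(P)",
               "AgHEC6.4D", "AgHEC6.4E",
               "AgHECC", "AgHECC(P)", "AgHECD"),
    family = rep(c("AgCur", "AgHEC6.4", "AgHEC"), times = c(6, 6, 3)),
    load_ng_cm2 = c(849, 1444, 1530, 1147, 1957, 2258,
                    1149, 1222, 1538, 1529, 1861, 2651,
                    1311, 1406, 1574),
    sd_ng_cm2 = c(31, 203, 151, 165, 22, 14,
                  144, 49, 41, 82, 96, 399,
                  671, 318, 302),
    stringsAsFactors = FALSE)
}

#' Abrasion release measurements for unwashed textiles
#'
#' Silver mass transferred from each unwashed textile batch to a sweat-wetted
#' cotton receptor during a 10-second crock-meter abrasion, alongside the
#' batch's initial areal load. These are the inputs from which the
#' first-order abrasion release constants are estimated
#' (see [estimate_rate_constant()]).
#'
#' @return A data.frame with `sample`, `family`, `load_ng_cm2`,
#'   `release_ng_cm2`, `duration_min` (10 s = 1/6 min).
#' @export
abrasion_release_data <- function() {
  d <- textile_load_data()
  d$release_ng_cm2 <- c(17.6, 12.6, 19.1, 17.9, 27.6, 31.7,
                        25.0, 33.1, 34.1, 16.4, 40.7, 47.3,
                        35.9, 23.3, 49.7)
  d$duration_min <- 10 / 60
  d$sd_ng_cm2 <- NULL
  d
}

#' Scenario-level parameters for a textile coating family
#'
#' Family-average parameters used by the scenario builders: the mean areal
#' load of the batches and the family-mean abrasion release constant (both
#' rounded as published).
#'
#' @param family One of `"AgCur"`, `"AgHEC6.4"`, `"AgHEC"`.
#' @return A list with `load_ng_cm2` and `kp_per_min`.
#' @export
textile_family_params <- function(family = c("AgCur", "AgHEC6.4", "AgHEC")) {
  family <- match.arg(family)
  loads <- c(AgCur = 1530, AgHEC6.4 = 1658, AgHEC = 1430)
  kps <- c(AgCur = 0.086, AgHEC6.4 = 0.12, AgHEC = 0.15)
  list(family = family,
       load_ng_cm2 = unname(loads[family]),
       kp_per_min = unname(kps[family]))
}
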