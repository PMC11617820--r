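#' Discrete mouthing (oral transfer) event
#'
#' A hand-to-mouth or object-to-mouth contact that instantaneously transfers
#' a fraction of the skin-surface load on the mouthed contact area into the
#' oral compartment. With complete transfer and retention
#' (`transfer_efficiency = 1`, `f_ret = 1`) the whole load on the contact
#' area is ingested.
#'
#' @param time_min Event time (min from scenario start).
#' @param contact_area_cm2 Mouthed surface area (cm^2); e.g. 11.5 cm^2 for
#'   three adult fingertips.
#' @param transfer_efficiency Fraction of the contact-area load transferred
#'   per contact, in `[0, 1]`.
#' @param f_ret Retention (ingested) fraction, in `[0, 1]`; default 1,
#'   i.e. complete ingestion.
#' @param n_events Number of contacts represented by this event (default 1).
#' @return An object of class `oral_event`.
#' @export
oral_event <- function(time_min, contact_area_cm2, transfer_efficiency,
                       f_ret = 1, n_events = 1) {
  if (!is.finite(time_min) || time_min < 0) {
    stop("time_min must be >= 0", call. = FALSE)
  }
  if (!is.finite(contact_area_cm2) || contact_area_cm2 < 0) {
    stop("contact_area_cm2 must be >= 0", call. = FALSE)
  }
  if (transfer_efficiency < 0 || transfer_efficiency > 1) {
    stop("transfer_efficiency must be in [0, 1]", call. = FALSE)
  }
  if (f_ret < 0 || f_ret > 1) stop("f_ret must be in [0, 1]", call. = FALSE)
  if (n_events < 0) stop("n_events must be >= 0", call. = FALSE)
  structure(list(time_min = time_min,
                 contact_area_cm2 = contact_area_cm2,
                 transfer_efficiency = transfer_efficiency,
                 f_ret = f_ret, n_events = n_events),
            class = "oral_event")
}

#' Exposure scenario
#'
#' Declarative description of a wear scenario consumed by
#' [simulate_exposure()]: the textile product, its rate constants, when it is
#' worn, optional washing and mouthing events, and the exposed subject.
#'
#' @param product A [textile_product()].
#' @param rates A [rate_constants()].
#' @param wear_intervals List of `c(start, end)` pairs (min), non-overlapping
#'   and ordered within `[0, horizon]`. The release source is active only
#'   inside these intervals; the skin deposit persists after wear ends.
#' @param horizon_min Simulation horizon (min).
#' @param oral_events List of [oral_event()]s (optional).
#' @param wash_at_min Times (min) at which washing removes the entire
#'   skin-surface deposit (optional).
#' @param subject An [exposure_subject()].
#' @param label Scenario label.
#' @return An object of class `exposure_scenario`.
#' @export
exposure_scenario <- function(product, rates, wear_intervals, horizon_min,
                              oral_events = list(), wash_at_min = numeric(),
                              subject = exposure_subject(), label = "") {
  stopifnot(inherits(product, "textile_product"),
            inherits(rates, "rate_constants"),
            inherits(subject, "exposure_subject"))
  if (!is.finite(horizon_min) || horizon_min < 0) {
    stop("horizon_min must be >= 0", call. = FALSE)
  }
  if (!is.list(wear_intervals) || length(wear_intervals) == 0L) {
    stop("wear_intervals must be a non-empty list of c(start, end) pairs",
         call. = FALSE)
  }
  prev_end <- -Inf
  for (iv in wear_intervals) {
    if (length(iv) != 2L || iv[1L] > iv[2L]) {
      stop("each wear interval must be c(start, end) with start <= end",
           call. = FALSE)
    }
    if (iv[1L] < 0 || iv[2L] > horizon_min) {
      stop("wear intervals must lie within [0, horizon]", call. = FALSE)
    }
    if (iv[1L] < prev_end) {
      stop("wear intervals must be ordered and non-overlapping",
           call. = FALSE)
    }
    prev_end <- iv[2L]
  }
  if (!all(vapply(oral_events, inherits, logical(1), "oral_event"))) {
    stop("oral_events must be a list of oral_event objects", call. = FALSE)
  }
  structure(list(product = product, rates = rates,
                 wear_intervals = wear_intervals,
                 horizon_min = horizon_min,
                 oral_events = oral_events,
                 wash_at_min = wash_at_min,
                 subject = subject,
                 label = as.character(label)),
            class = "exposure_scenario")
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat(sprintf("Exposure scenario%s\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else ""))
  print(x$product)
  print(x$rates)
  ivs <- vapply(x$wear_intervals,
                function(iv) sprintf("[%g, %g]", iv[1], iv[2]), character(1))
  cat(sprintf("  wear (min): %s; horizon %g min\n",
              paste(ivs, collapse = ", "), x$horizon_min))
  if (length(x$oral_events)) {
    cat(sprintf("  %d oral event(s)\n", length(x$oral_events)))
  }
  if (length(x$wash_at_min)) {
    cat(sprintf("  washing at %s min\n",
                paste(x$wash_at_min, collapse = ", ")))
  }
  invisible(x)
}

#' Wear schedule with a single wear period
#'
#' A single wear interval `[0, wear_h]` inside a longer horizon. After wear
#' ends the remaining textile source is removed but the skin-surface deposit
#' is retained (no washing) and continues to feed absorption until the
#' horizon.
#'
#' @param horizon_h Total simulated duration (h).
#' @param wear_h Wear duration (h), `0 <= wear_h <= horizon_h`.
#' @return A list with one wear interval in minutes.
#' @export
wear_schedule <- function(horizon_h, wear_h = horizon_h) {
  if (!is.finite(horizon_h) || horizon_h < 0 ||
      !is.finite(wear_h) || wear_h < 0) {
    stop("durations must be >= 0", call. = FALSE)
  }
  if (wear_h > horizon_h) {
    stop("wear_h must not exceed horizon_h", call. = FALSE)
  }
  list(c(0, wear_h * 60))
}

#' Face-mask wear scenario
#'
#' An antimicrobial face mask with 555 cm^2 skin contact area, parameterised
#' by textile coating family (family-average areal load and abrasion release
#' constant, see [textile_family_params()]) and skin condition
#' (stratum-corneum constant from [skin_permeation_data()]).
#'
#' @param family Textile coating family (`"AgCur"`, `"AgHEC6.4"`, `"AgHEC"`).
#' @param skin_condition Skin preparation for `k_sc`.
#' @param wear_hours Wear duration (h), default 8.
#' @param horizon_hours Simulation horizon (h), default `wear_hours`.
#' @param subject An [exposure_subject()].
#' @return An [exposure_scenario()].
#' @examples
#' sim <- simulate_exposure(face_mask_scenario("AgCur", "fresh"))
#' sc_intake(sim)  # ~12 ng over 8 h
#' @export
face_mask_scenario <- function(family = c("AgCur", "AgHEC6.4", "AgHEC"),
                               skin_condition = "fresh",
                               wear_hours = 8,
                               horizon_hours = max(wear_hours, 8),
                               subject = exposure_subject()) {
  body_contact_scenario(family, skin_condition, area_cm2 = 555,
                        wear_hours = wear_hours,
                        horizon_hours = horizon_hours, subject = subject,
                        label = "face mask")
}

#' Full-body wear scenario
#'
#' Reasonable worst-case scenario: a full-body garment in contact with the
#' whole dermal surface, 20 000 cm^2 (2 m^2). Otherwise identical to
#' [face_mask_scenario()]; intakes scale exactly linearly with contact area.
#'
#' @inheritParams face_mask_scenario
#' @return An [exposure_scenario()].
#' @export
full_body_scenario <- function(family = c("AgCur", "AgHEC6.4", "AgHEC"),
                               skin_condition = "fresh",
                               wear_hours = 8,
                               horizon_hours = max(wear_hours, 8),
                               subject = exposure_subject()) {
  body_contact_scenario(family, skin_condition, area_cm2 = 20000,
                        wear_hours = wear_hours,
                        horizon_hours = horizon_hours, subject = subject,
                        label = "full body")
}

body_contact_scenario <- function(family, skin_condition, area_cm2,
                                  wear_hours, horizon_hours, subject,
                                  label) {
  fam <- textile_family_params(family)
  ksc <- ksc_for_condition(skin_condition)
  exposure_scenario(
    product = textile_product(fam$load_ng_cm2, area_cm2,
                              label = paste(fam$family, label)),
    rates = rate_constants(kp_per_min = fam$kp_per_min, ksc_per_h = ksc),
    wear_intervals = wear_schedule(horizon_hours, wear_hours),
    horizon_min = horizon_hours * 60,
    subject = subject,
    label = sprintf("%s %s, %s skin, %g-h wear",
                    fam$family, label, skin_condition, wear_hours))
}

#' Glove wear followed by finger mouthing
#'
#' Dermal phase on the hand surface (default 900 cm^2) during glove wear,
#' followed by a single inadvertent mouthing of the fingertips (default
#' 11.5 cm^2, three adult fingertips) at wear end, modelled as an
#' instantaneous fractional transfer of the skin-surface load on the mouthed
#' area into the oral compartment.
#'
#' @param family Textile coating family.
#' @param wear_hours Glove wear duration (h), default 1.
#' @param fingertip_area_cm2 Mouthed fingertip area (cm^2), default 11.5;
#'   must not exceed `hand_area_cm2`.
#' @param transfer_efficiency Hand-to-mouth transfer efficiency, default 0.1.
#' @param hand_area_cm2 Dermal contact area of the hands (cm^2), default 900.
#' @param skin_condition Skin preparation for the dermal route.
#' @param subject An [exposure_subject()].
#' @return An [exposure_scenario()] with one oral event at wear end.
#' @export
glove_mouthing_scenario <- function(family = "AgCur", wear_hours = 1,
                                    fingertip_area_cm2 = 11.5,
                                    transfer_efficiency = 0.1,
                                    hand_area_cm2 = 900,
                                    skin_condition = "fresh",
                                    subject = exposure_subject()) {
  if (fingertip_area_cm2 > hand_area_cm2) {
    stop("fingertip area must not exceed the hand contact area",
         call. = FALSE)
  }
  fam <- textile_family_params(family)
  exposure_scenario(
    product = textile_product(fam$load_ng_cm2, hand_area_cm2,
                              label = paste(fam$family, "gloves")),
    rates = rate_constants(kp_per_min = fam$kp_per_min,
                           ksc_per_h = ksc_for_condition(skin_condition)),
    wear_intervals = wear_schedule(wear_hours),
    horizon_min = wear_hours * 60,
    oral_events = list(oral_event(wear_hours * 60, fingertip_area_cm2,
                                  transfer_efficiency)),
    subject = subject,
    label = sprintf("%s gloves, %g-h wear + fingertip mouthing",
                    fam$family, wear_hours))
}

#' Indirect dermal load from contact with a contaminated surface
#'
#' Instant-application source: the mass transferred to skin from a
#' contaminated surface is the surface contamination times the contact area
#' times the transfer efficiency. Applied as an instantaneous addition to the
#' skin-surface compartment.
#'
#' @param surface_load_ng_cm2 Surface contamination (ng/cm^2).
#' @param contact_area_cm2 Dermal contact area (cm^2).
#' @param transfer_efficiency Fraction transferred per contact, in `[0, 1]`.
#' @return Transferred mass (ng).
#' @export
indirect_contact_load <- function(surface_load_ng_cm2, contact_area_cm2,
                                  transfer_efficiency) {
  if (surface_load_ng_cm2 < 0 || contact_area_cm2 < 0) {
    stop("surface load and contact area must be >= 0", call. = FALSE)
  }
  if (transfer_efficiency < 0 || transfer_efficiency > 1) {
    stop("transfer_efficiency must be in [0, 1]", call. = FALSE)
  }
  surface_load_ng_cm2 * contact_area_cm2 * transfer_efficiency
}

#' Sweat-immersion sport scenario
#'
#' A 60-minute sport activity wearing a T-shirt and trousers whose silver is
#' leached by sweat, with per-garment release constants estimated from
#' 30-minute sweat-immersion fractions (see
#' [immersion_constants_from_fractions()]). The garment silver masses are
#' not bundled with the package (they come from a supplementary parameter
#' table of the underlying study) and must be supplied in the config; the
#' builder fails with an explicit message otherwise.
#'
#' @param config A list with one entry per garment, each a list with
#'   `ag_mass_ng` (total garment Ag mass, ng), `kp_per_min`, and optionally
#'   `area_cm2` (dermal contact area).
#' @param duration_h Activity duration (h), default 1.
#' @param skin_condition Skin preparation for `k_sc`, default `"fresh"`.
#' @param subject An [exposure_subject()].
#' @return A list of [exposure_scenario()]s, one per garment.
#' @export
sport_scenario <- function(config, duration_h = 1, skin_condition = "fresh",
                           subject = exposure_subject()) {
  if (missing(config) || is.null(config) || length(config) == 0L) {
    stop(paste("sport_scenario requires per-garment Ag masses from the",
               "supplementary parameter table (not bundled); supply",
               "config = list(<garment> = list(ag_mass_ng =, kp_per_min =))"),
         call. = FALSE)
  }
  ksc <- ksc_for_condition(skin_condition)
  scenarios <- lapply(names(config), function(nm) {
    g <- config[[nm]]
    if (is.null(g$ag_mass_ng) || is.null(g$kp_per_min)) {
      stop(sprintf(
        "garment '%s' must supply ag_mass_ng and kp_per_min", nm),
        call. = FALSE)
    }
    area <- if (is.null(g$area_cm2)) 1 else g$area_cm2
    exposure_scenario(
      product = textile_product(g$ag_mass_ng / area, area, label = nm),
      rates = rate_constants(kp_per_min = g$kp_per_min, ksc_per_h = ksc),
      wear_intervals = wear_schedule(duration_h),
      horizon_min = duration_h * 60,
      subject = subject,
      label = sprintf("sport scenario: %s", nm))
  })
  names(scenarios) <- names(config)
  scenarios
}
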