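#' Convert a 1/e-squared beam diameter to a 1/e diameter
#'
#' For a circular TEM00 Gaussian beam the diameter at which irradiance falls
#' to 1/e of the axial value is the 1/e^2 diameter divided by sqrt(2).  Beam
#' profilers report the 1/e^2 width; peak radiant exposure is computed from
#' the 1/e width.
#'
#' @param d_1e2 1/e^2 beam diameter(s), micrometres. Must be non-negative.
#' @return 1/e diameter(s) in micrometres.
#' @examples
#' d1e_from_d1e2(98.25) # 69.47
#' @export
d1e_from_d1e2 <- function(d_1e2) {
  if (!is.numeric(d_1e2) || any(!is.finite(d_1e2)) || any(d_1e2 < 0)) {
    abort("`d_1e2` must be a finite non-negative numeric vector.")
  }
  d_1e2 / sqrt(2)
}

#' Describe a Gaussian beam waist
#'
#' A one-row tibble holding the beam geometry used by the dosimetry
#' functions: the 1/e^2 diameter, the derived 1/e diameter, the relative
#' diameter uncertainty, and optionally the beam-centre position along the
#' knife-edge scan axis.
#'
#' @param d_1e2_um 1/e^2 waist diameter, micrometres (> 0).
#' @param rel_u_d relative (fractional) uncertainty of the diameter, >= 0.
#' @param center_um beam-centre position along the scan axis, micrometres,
#'   or `NA` when not known.
#' @return A tibble with columns `d_1e2_um`, `d_1e_um`, `rel_u_d`,
#'   `center_um`.
#' @examples
#' beam_profile(98.25, rel_u_d = 0.035)
#' @export
beam_profile <- function(d_1e2_um, rel_u_d = 0, center_um = NA_real_) {
  if (!is.numeric(d_1e2_um) || length(d_1e2_um) != 1L ||
      !is.finite(d_1e2_um) || d_1e2_um <= 0) {
    abort("`d_1e2_um` must be a single positive number.")
  }
  if (!is.numeric(rel_u_d) || length(rel_u_d) != 1L || is.na(rel_u_d) ||
      rel_u_d < 0) {
    abort("`rel_u_d` must be a single non-negative number.")
  }
  tibble::tibble(
    d_1e2_um = d_1e2_um,
    d_1e_um = d1e_from_d1e2(d_1e2_um),
    rel_u_d = rel_u_d,
    center_um = as.numeric(center_um)
  )
}

radiant_exposure_tbl <- function(value, rel_u, convention) {
  tibble::tibble(value = value, rel_u = rel_u, convention = convention)
}

resolve_uncertainty <- function(rel_u_energy, rel_u_d,
                                mode = c("direct", "strict")) {
  mode <- match.arg(mode)
  d_term <- if (mode == "strict") 2 * rel_u_d else rel_u_d
  combine_relative_uncertainties(c(rel_u_energy, d_term))
}

#' Peak radiant exposure of a Gaussian pulse
#'
#' The on-axis (peak) radiant exposure of a TEM00 pulse is the pulse energy
#' divided by the area of the 1/e-diameter circle, `E / (pi (d_1e/2)^2)`;
#' equivalently `2E / (pi w^2)` with `w` the 1/e^2 radius.
#'
#' The returned relative uncertainty combines the energy and diameter terms
#' in quadrature.  `uncertainty_mode = "direct"` combines them as
#' `sqrt(u_E^2 + u_d^2)`, the convention used in published corneal-threshold
#' uncertainty budgets; `"strict"` applies the analytic sensitivity factor 2
#' to the diameter term (`H` scales as `d^-2`), giving
#' `sqrt(u_E^2 + (2 u_d)^2)`.
#'
#' @param energy_mj pulse energy, millijoules (>= 0).
#' @param beam a [beam_profile()] tibble.
#' @param rel_u_energy relative energy uncertainty (fraction).
#' @param uncertainty_mode `"direct"` (default) or `"strict"`; see Details.
#' @return A one-row tibble with columns `value` (J/cm^2), `rel_u`,
#'   `convention = "peak_1e"`.
#' @examples
#' peak_radiant_exposure(3.86, beam_profile(98.25)) # ~102 J/cm^2
#' @export
peak_radiant_exposure <- function(energy_mj, beam, rel_u_energy = 0,
                                  uncertainty_mode = c("direct", "strict")) {
  check_energy(energy_mj)
  check_beam(beam)
  d1e_cm <- beam$d_1e_um / UM_PER_CM
  area_cm2 <- pi * (d1e_cm / 2)^2
  value <- (energy_mj / MJ_PER_J) / area_cm2
  radiant_exposure_tbl(
    value,
    resolve_uncertainty(rel_u_energy, beam$rel_u_d, uncertainty_mode),
    "peak_1e"
  )
}

#' Fraction of a Gaussian beam's energy inside a circular aperture
#'
#' For a centred circular aperture of radius `R` over a Gaussian beam with
#' 1/e^2 radius `w = d_1e2/2`, the encircled-energy fraction is
#' `1 - exp(-2 R^2 / w^2)`.
#'
#' @param radius_um aperture radius, micrometres (>= 0, vectorised).
#' @param d_1e2_um beam 1/e^2 diameter, micrometres (> 0).
#' @return Fraction(s) in `[0, 1]`, nondecreasing in `radius_um`.
#' @examples
#' encircled_energy_fraction(49.125, 98.25) # 1 - exp(-2)
#' @export
encircled_energy_fraction <- function(radius_um, d_1e2_um) {
  if (any(!is.finite(radius_um)) || any(radius_um < 0)) {
    abort("`radius_um` must be finite and non-negative.")
  }
  if (!is.finite(d_1e2_um) || d_1e2_um <= 0) {
    abort("`d_1e2_um` must be a single positive number.")
  }
  w <- d_1e2_um / 2
  1 - exp(-2 * radius_um^2 / w^2)
}

#' Aperture-averaged radiant exposure
#'
#' The average radiant exposure over a circular limiting aperture: the
#' energy collected by the aperture divided by the aperture area.  ANSI
#' Z136.1 evaluates corneal exposures over a 1-mm-diameter limiting
#' aperture; when the beam is much smaller than the aperture this reduces
#' to total energy over aperture area.
#'
#' @inheritParams peak_radiant_exposure
#' @param aperture_mm aperture diameter, millimetres (> 0). Default 1.
#' @return A one-row tibble with columns `value` (J/cm^2), `rel_u`,
#'   `convention = "average_aperture"`.
#' @examples
#' average_radiant_exposure(3.86, beam_profile(98.25)) # ~0.49 J/cm^2
#' @export
average_radiant_exposure <- function(energy_mj, beam, aperture_mm = 1,
                                     rel_u_energy = 0,
                                     uncertainty_mode = c("direct", "strict")) {
  check_energy(energy_mj)
  check_beam(beam)
  if (!is.finite(aperture_mm) || aperture_mm <= 0) {
    abort("`aperture_mm` must be a single positive number.")
  }
  radius_um <- aperture_mm / 2 * 1e3
  frac <- encircled_energy_fraction(radius_um, beam$d_1e2_um)
  area_cm2 <- pi * (aperture_mm / MM_PER_CM / 2)^2
  value <- (energy_mj / MJ_PER_J) * frac / area_cm2
  radiant_exposure_tbl(
    value,
    resolve_uncertainty(rel_u_energy, beam$rel_u_d, uncertainty_mode),
    "average_aperture"
  )
}

#' Average radiant exposure over the 1/e^2 beam diameter
#'
#' Averaging a Gaussian beam's radiant exposure over its own 1/e^2 diameter
#' gives exactly half the peak value: the encircled energy within the 1/e^2
#' radius is `(1 - e^-2) E` and the area ratio works out to a factor of
#' one half of the peak.  This convention has been proposed as a
#' beam-diameter-aware way to state thresholds for beams smaller than the
#' limiting aperture.
#'
#' @param peak a one-row tibble from [peak_radiant_exposure()]
#'   (`convention` must be `"peak_1e"`).
#' @return A one-row tibble with `value = 0.5 * peak$value`, the same
#'   `rel_u`, and `convention = "average_1e2"`.
#' @export
average_over_1e2 <- function(peak) {
  if (!is.data.frame(peak) || !all(c("value", "rel_u", "convention") %in% names(peak))) {
    abort("`peak` must be a radiant-exposure tibble (value, rel_u, convention).")
  }
  if (!identical(peak$convention, "peak_1e")) {
    abort("`peak` must carry the \"peak_1e\" convention.")
  }
  radiant_exposure_tbl(0.5 * peak$value, peak$rel_u, "average_1e2")
}

#' Combine relative uncertainties in quadrature
#'
#' Root-sum-of-squares combination of independent relative uncertainty
#' components, `sqrt(sum(u_i^2))`.
#'
#' @param components numeric vector of fractional uncertainties (>= 0).
#' @return The combined fractional uncertainty.
#' @examples
#' combine_relative_uncertainties(c(0.02, 0.01))  # 0.022
#' combine_relative_uncertainties(c(0.022, 0.035)) # 0.041
#' @export
combine_relative_uncertainties <- function(components) {
  if (length(components) == 0L) return(0)
  if (any(!is.finite(components)) || any(components < 0)) {
    abort("All uncertainty components must be finite and non-negative.")
  }
  sqrt(sum(components^2))
}

#' Calibrate the reference-to-delivered energy ratio
#'
#' During exposures the delivered energy is inferred from a reference
#' detector via a ratio calibrated before and after each session.  This
#' returns the mean of the pairwise delivered/reference ratios and their
#' relative standard deviation (the session's calibration noise).
#'
#' @param reference reference-detector energies (> 0), length >= 1.
#' @param delivered simultaneously measured delivered energies, same length.
#' @return A one-row tibble with columns `ratio`, `rel_u` (NA when only one
#'   pair is available), and `n`.
#' @export
calibrate_energy_ratio <- function(reference, delivered) {
  if (length(reference) != length(delivered) || length(reference) < 1L) {
    abort("`reference` and `delivered` must be equal-length, length >= 1.")
  }
  if (any(!is.finite(reference)) || any(!is.finite(delivered)) ||
      any(reference <= 0) || any(delivered <= 0)) {
    abort("Energy readings must be finite and positive.")
  }
  r <- delivered / reference
  rel_u <- if (length(r) >= 2L) sd(r) / mean(r) else NA_real_
  tibble::tibble(ratio = mean(r), rel_u = rel_u, n = length(r))
}

#' Radiant-exposure summary for one pulse
#'
#' Computes all three radiant-exposure conventions (peak over the 1/e
#' diameter, average over a limiting aperture, average over the 1/e^2
#' diameter) for a delivered pulse energy and beam profile.
#'
#' @inheritParams average_radiant_exposure
#' @return A three-row tibble (one row per convention) with `value`,
#'   `rel_u`, `convention`.
#' @examples
#' dosimetry_summary(3.86, beam_profile(98.25, rel_u_d = 0.035),
#'                   rel_u_energy = 0.022)
#' @export
dosimetry_summary <- function(energy_mj, beam, aperture_mm = 1,
                              rel_u_energy = 0,
                              uncertainty_mode = c("direct", "strict")) {
  peak <- peak_radiant_exposure(energy_mj, beam, rel_u_energy,
                                uncertainty_mode)
  dplyr::bind_rows(
    peak,
    average_radiant_exposure(energy_mj, beam, aperture_mm, rel_u_energy,
                             uncertainty_mode),
    average_over_1e2(peak)
  )
}

check_energy <- function(energy_mj) {
  if (!is.numeric(energy_mj) || length(energy_mj) != 1L ||
      !is.finite(energy_mj) || energy_mj < 0) {
    abort("`energy_mj` must be a single non-negative number.")
  }
}

check_beam <- function(beam) {
  if (!is.data.frame(beam) || nrow(beam) != 1L ||
      !all(c("d_1e2_um", "d_1e_um", "rel_u_d") %in% names(beam))) {
    abort("`beam` must be a one-row tibble from beam_profile() or fit_knife_edge().")
  }
  if (beam$d_1e2_um <= 0) abort("Beam diameter must be positive.")
}
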