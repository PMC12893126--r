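#' Default pipeline configuration
#'
#' The analysis conventions as defaults rather than hard-code: the ANSI
#' Z136.1 MPE and limiting aperture, the confidence level, the uncertainty
#' combination mode, and the dose-log base.
#'
#' @param mpe maximum permissible exposure, J/cm^2 (1 at 1645 nm, ns
#'   pulses).
#' @param aperture_mm limiting-aperture diameter, mm (1 for the cornea).
#' @param confidence fiducial-limit confidence level (0.95).
#' @param uncertainty_mode `"direct"` or `"strict"`, see
#'   [peak_radiant_exposure()].
#' @param log_base dose-log base for the probit fit (10).
#' @param rel_u_energy relative energy uncertainty attached to dosimetry
#'   output (default 0.022).
#' @param target_ratio desired ED50/MPE safety margin (10).
#' @return A named list.
#' @export
pipeline_config <- function(mpe = 1, aperture_mm = 1, confidence = 0.95,
                            uncertainty_mode = "direct", log_base = 10,
                            rel_u_energy = 0.022, target_ratio = 10) {
  list(
    mpe = mpe, aperture_mm = aperture_mm, confidence = confidence,
    uncertainty_mode = uncertainty_mode, log_base = log_base,
    rel_u_energy = rel_u_energy, target_ratio = target_ratio
  )
}

#' Run the full threshold-analysis pipeline
#'
#' Orchestrates the analysis end to end: fit the probit threshold model to
#' the exposure records on whatever dose scale they carry, convert the
#' fitted ED50 into all three radiant-exposure conventions through the
#' session beam geometry, screen adequacy, compare against the MPE, and
#' (when depth measurements are supplied) fit the logarithmic depth-ratio
#' model.  Because the probit model is equivariant under a multiplicative
#' change of dose scale, running on pulse energies (mJ) or on peak radiant
#' exposures (J/cm^2) gives ED50s that agree exactly through the
#' beam-area factor.
#'
#' @param exposures exposure records (as from [read_exposure_table()] or
#'   [simulate_exposures()]); `dose_unit` must be `"mJ"` or `"J/cm2"`
#'   (peak convention).
#' @param sessions optional session table (`session_id`, `d_1e2_um`,
#'   optionally `d_1e2_sd_um`); when absent, `beam` must be given.
#' @param depths optional depth-measurement table.
#' @param beam optional [beam_profile()] overriding the session average.
#' @param config a [pipeline_config()] list.
#' @return An object of class `ldt_report`: a list with blocks `inputs`,
#'   `dosimetry`, `probit`, `depth` (may be `NULL`), `safety`, and
#'   `provenance`.  If the fit fails the adequacy screen the report is
#'   still produced, with `probit.adequate = FALSE`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' rep <- run_pipeline(simulate_exposures(cfg),
#'                     beam = beam_profile(cfg$beam_d1e2, rel_u_d = 0.035))
#' rep$probit$ed50
#' @export
run_pipeline <- function(exposures, sessions = NULL, depths = NULL,
                         beam = NULL, config = pipeline_config()) {
  if (!is.data.frame(exposures) || nrow(exposures) == 0L) {
    abort("`exposures` must be a non-empty data frame of exposure records.")
  }
  unit <- unique(exposures$dose_unit)
  if (length(unit) != 1L || !unit %in% c("mJ", "J/cm2")) {
    abort("`exposures$dose_unit` must be uniformly \"mJ\" or \"J/cm2\".")
  }
  if (is.null(beam)) {
    if (is.null(sessions)) {
      abort("Provide either a `sessions` table or a `beam` profile.")
    }
    rel_u <- if ("d_1e2_sd_um" %in% names(sessions)) {
      mean(sessions$d_1e2_sd_um / sessions$d_1e2_um)
    } else 0
    beam <- beam_profile(mean(sessions$d_1e2_um), rel_u_d = rel_u)
  }

  fit <- fit_probit(exposures, log_base = config$log_base)
  limits <- fieller_limits(fit, level = config$confidence)
  adq <- adequacy(fit, limits)

  # ED50 in both the energy and peak-radiant-exposure domains
  beam_area_cm2 <- pi * (beam$d_1e_um / UM_PER_CM / 2)^2
  if (unit == "mJ") {
    ed50_energy_mj <- fit$ed50
    scale_to_peak <- 1 / (MJ_PER_J * beam_area_cm2)
  } else {
    ed50_energy_mj <- fit$ed50 * beam_area_cm2 * MJ_PER_J
    scale_to_peak <- 1 / (MJ_PER_J * beam_area_cm2)
  }
  dosim <- dosimetry_summary(
    ed50_energy_mj, beam,
    aperture_mm = config$aperture_mm,
    rel_u_energy = config$rel_u_energy,
    uncertainty_mode = config$uncertainty_mode
  )
  ed50_peak <- dosim$value[dosim$convention == "peak_1e"]
  ed50_avg <- dosim$value[dosim$convention == "average_aperture"]

  depth_block <- NULL
  if (!is.null(depths)) {
    dfit <- fit_depth_response(depths)
    depth_block <- list(a = dfit$a, b = dfit$b,
                        r_squared = dfit$r_squared, n = dfit$n)
  }

  lim_scale <- if (unit == "mJ") scale_to_peak else 1
  report <- structure(
    list(
      inputs = list(
        n_exposures = nrow(exposures),
        n_lesions = sum(exposures$outcome),
        dose_min = min(exposures$dose),
        dose_max = max(exposures$dose),
        dose_unit = unit
      ),
      dosimetry = dosim,
      probit = list(
        ed50 = fit$ed50,
        ed50_unit = unit,
        ed50_energy_mj = ed50_energy_mj,
        ed50_peak_jcm2 = ed50_peak,
        slope = fit$beta1,
        fiducial_lower = limits$lower,
        fiducial_upper = limits$upper,
        fiducial_lower_peak_jcm2 = limits$lower * lim_scale,
        fiducial_upper_peak_jcm2 = limits$upper * lim_scale,
        confidence = config$confidence,
        slope_ok = adq$slope_ok,
        fiducial_ok = adq$fiducial_ok,
        adequate = adq$adequate,
        loglik = fit$loglik,
        n = fit$n
      ),
      depth = depth_block,
      safety = safety_comparison(ed50_peak, ed50_avg, mpe = config$mpe,
                                 target_ratio = config$target_ratio),
      provenance = list(
        package_version = as.character(utils::packageVersion("lasethresh")),
        beam_d_1e2_um = beam$d_1e2_um,
        log_base = config$log_base,
        uncertainty_mode = config$uncertainty_mode
      )
    ),
    class = "ldt_report"
  )
  report
}

#' @export
print.ldt_report <- function(x, ...) {
  cat("Laser damage threshold analysis report\n")
  cat(sprintf("  exposures: %d (%d lesions), dose %s\n",
              x$inputs$n_exposures, x$inputs$n_lesions, x$inputs$dose_unit))
  cat(sprintf("  ED50: %.4g %s  (peak %.4g J/cm2; 95%% fiducial %.4g-%.4g %s)\n",
              x$probit$ed50, x$probit$ed50_unit, x$probit$ed50_peak_jcm2,
              x$probit$fiducial_lower, x$probit$fiducial_upper,
              x$probit$ed50_unit))
  cat(sprintf("  slope: %.4g probits/decade; adequate: %s\n",
              x$probit$slope, x$probit$adequate))
  if (!is.null(x$depth)) {
    cat(sprintf("  depth model: ratio = %.3g + %.3g ln(dose), R^2 = %.3f\n",
                x$depth$a, x$depth$b, x$depth$r_squared))
  }
  cat("  safety ratios (ED50/MPE):\n")
  for (i in seq_len(nrow(x$safety))) {
    cat(sprintf("    %-17s %8.3g %s\n", x$safety$convention[i],
                x$safety$ratio[i],
                ifelse(x$safety$meets_target[i], "(meets target)", "")))
  }
  invisible(x)
}
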