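#' Lesion depth ratio
#'
#' Lesion depth divided by the adjacent full corneal thickness.  A ratio of
#' 1 means the lesion extends the full thickness of the cornea.
#'
#' @param lesion_depth_um lesion depth(s), micrometres (> 0).
#' @param corneal_thickness_um adjacent full corneal thickness, micrometres
#'   (>= lesion depth).
#' @return Ratio(s) in (0, 1].
#' @examples
#' depth_ratio(259, 377) # 0.687
#' @export
depth_ratio <- function(lesion_depth_um, corneal_thickness_um) {
  if (any(!is.finite(lesion_depth_um)) || any(lesion_depth_um <= 0)) {
    abort("`lesion_depth_um` must be finite and positive.")
  }
  if (any(!is.finite(corneal_thickness_um)) ||
      any(corneal_thickness_um < lesion_depth_um)) {
    abort("`corneal_thickness_um` must be finite and >= the lesion depth.")
  }
  lesion_depth_um / corneal_thickness_um
}

#' Logarithmic depth-ratio dose-response fit
#'
#' Ordinary least squares of the lesion depth ratio on the natural log of
#' dose, `ratio = a + b * ln(dose)`.  Lesion depth grows only
#' logarithmically with radiant exposure: each doubling of dose adds a
#' fixed `b * ln 2` to the predicted ratio.  The natural log is used; the
#' base only rescales `b`, not `r.squared` or predictions.  Fitted ratios
#' are not clipped to `[0, 1]`; out-of-range predictions are the caller's
#' signal that the model is extrapolating.
#'
#' @param data a data frame of depth measurements.
#' @param dose,lesion_depth,corneal_thickness columns (tidy-eval); defaults
#'   `dose_jcm2`, `lesion_depth_um`, `corneal_thickness_um`.  If `data`
#'   already has a `ratio` column it is used directly and the depth columns
#'   are ignored.
#' @return An object of class `depth_fit`: list with `a`, `b`,
#'   `r_squared`, `n`, the underlying `lm` in `model`, and the model frame
#'   `data` (columns `dose`, `ratio`).
#' @examples
#' cfg <- sim_config(seed = 7)
#' depths <- simulate_depth_measurements(cfg)
#' fit <- fit_depth_response(depths)
#' fit$r_squared
#' @export
fit_depth_response <- function(data, dose = dose_jcm2,
                               lesion_depth = lesion_depth_um,
                               corneal_thickness = corneal_thickness_um) {
  d <- dplyr::pull(data, {{ dose }})
  ratio <- if ("ratio" %in% names(data)) {
    data$ratio
  } else {
    depth_ratio(dplyr::pull(data, {{ lesion_depth }}),
                dplyr::pull(data, {{ corneal_thickness }}))
  }
  if (any(!is.finite(d)) || any(d <= 0)) {
    abort("Doses must be finite and positive.")
  }
  if (length(d) < 3L) abort("Need at least 3 depth measurements.")
  if (length(unique(d)) < 2L) {
    abort("All doses identical: the log-dose design matrix is rank deficient.")
  }
  df <- tibble::tibble(dose = d, ratio = ratio)
  model <- lm(ratio ~ log(dose), data = df)
  ss_res <- sum(stats::residuals(model)^2)
  ss_tot <- sum((df$ratio - mean(df$ratio))^2)
  structure(
    list(
      a = unname(coef(model)[1L]),
      b = unname(coef(model)[2L]),
      r_squared = 1 - ss_res / ss_tot,
      n = nrow(df),
      model = model,
      data = df
    ),
    class = "depth_fit"
  )
}

#' Predicted depth change when the dose doubles
#'
#' Under the logarithmic depth model, doubling the dose moves the predicted
#' ratio from `a + b ln(H)` to `a + b ln(2H)`.  This returns the new
#' predicted depth as a percentage of the old (so 100 means no change and
#' any increasing log model gives a value below 200 once the predicted
#' ratio is positive).
#'
#' @param fit a [fit_depth_response()] object.
#' @param reference_dose dose `H` at which the doubling is evaluated; the
#'   predicted ratio at `H` must be positive.
#' @return Percentage of the reference predicted depth, vectorised over
#'   `reference_dose`.
#' @export
predicted_depth_change_on_doubling <- function(fit, reference_dose) {
  stopifnot(inherits(fit, "depth_fit"))
  if (any(!is.finite(reference_dose)) || any(reference_dose <= 0)) {
    abort("`reference_dose` must be finite and positive.")
  }
  old <- fit$a + fit$b * log(reference_dose)
  if (any(old <= 0)) {
    abort("Predicted ratio at `reference_dose` is not positive; the doubling percentage is undefined there.")
  }
  100 * (fit$a + fit$b * log(2 * reference_dose)) / old
}

#' Safety-margin comparison against an MPE limit
#'
#' Compares threshold (ED50) radiant exposures against a maximum
#' permissible exposure (MPE).  ANSI Z136.1 guidance aims for a safety
#' margin of ED50/MPE = 10.  For small beams the peak and
#' aperture-averaged conventions can disagree by orders of magnitude, so
#' the comparison is reported per convention, including the
#' average-over-1/e^2 compromise (half the peak).
#'
#' @param ed50_peak ED50 as peak radiant exposure, J/cm^2.
#' @param ed50_avg ED50 averaged over the limiting aperture, J/cm^2.
#' @param mpe the MPE, J/cm^2; 1 for nanosecond corneal exposure at
#'   1645 nm.
#' @param target_ratio desired ED50/MPE margin, default 10.
#' @return A tibble with one row per convention: `convention`, `ed50`,
#'   `mpe`, `ratio`, `meets_target` (`ratio >= target_ratio`), and
#'   `target_ratio`.
#' @examples
#' safety_comparison(102, 0.49) # ratios ~102 and 0.49
#' @export
safety_comparison <- function(ed50_peak, ed50_avg, mpe = 1,
                              target_ratio = 10) {
  vals <- c(ed50_peak, ed50_avg, mpe, target_ratio)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All inputs must be finite and positive.")
  }
  ed50 <- c(peak_1e = ed50_peak,
            average_aperture = ed50_avg,
            average_1e2 = 0.5 * ed50_peak)
  tibble::tibble(
    convention = names(ed50),
    ed50 = unname(ed50),
    mpe = mpe,
    ratio = unname(ed50) / mpe,
    meets_target = unname(ed50) / mpe >= target_ratio,
    target_ratio = target_ratio
  )
}

#' @export
print.depth_fit <- function(x, ...) {
  cat("Logarithmic depth-ratio fit (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  ratio = %.4g + %.4g ln(dose),  R^2 = %.4f\n",
              x$a, x$b, x$r_squared))
  invisible(x)
}

#' Tidy a depth-ratio fit
#'
#' @param x a `depth_fit`.
#' @param ... unused.
#' @export
#' @method tidy depth_fit
tidy.depth_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$model))$coefficients
  tibble::tibble(
    term = c("(Intercept)", "log_dose"),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"])
  )
}

#' One-row summary of a depth-ratio fit
#'
#' @param x a `depth_fit`.
#' @param ... unused.
#' @export
#' @method glance depth_fit
glance.depth_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, r.squared = x$r_squared, n = x$n)
}
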