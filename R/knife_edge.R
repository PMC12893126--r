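#' Fit a Gaussian-beam waist to a knife-edge scan
#'
#' A knife edge translated across a Gaussian beam transmits the integrated
#' tail of the profile, so the recorded signal follows
#' `S(x) = S0 + (P/2) * erfc(s * sqrt(2) * (x - x0) / w)`
#' with `w` the 1/e^2 radius, `x0` the beam centre, `S0` a baseline offset,
#' `P` the total power (or energy) swing, and `s = +/-1` the scan direction.
#' The fit is Levenberg-Marquardt nonlinear least squares; starting values
#' come from the 10%/90% signal crossings (`w0 = |x90 - x10| / 1.28`) and
#' the direction is chosen from the sign of the endpoint difference, so the
#' fit is deterministic.
#'
#' @param scan a data frame with blade positions and transmitted signals;
#'   at least 6 rows, positions strictly monotone.
#' @param position,signal column names (tidy-eval) holding the blade
#'   position (micrometres) and transmitted signal. Defaults `position_um`,
#'   `signal`.
#' @return An object of class `knife_edge_fit`: a list with `beam` (a
#'   [beam_profile()] tibble whose `rel_u_d` is the fitted diameter's
#'   relative standard error), `w_um`, `x0_um`, `s0`, `power`, `direction`,
#'   `residual_sd`, `n`, and the fitted `model`.
#' @examples
#' scan <- simulate_knife_edge(w_um = 49.125, seed = 1)
#' fit <- fit_knife_edge(scan)
#' fit$beam$d_1e2_um
#' @export
fit_knife_edge <- function(scan, position = position_um, signal = signal) {
  pos <- dplyr::pull(scan, {{ position }})
  sig <- dplyr::pull(scan, {{ signal }})
  if (length(pos) < 6L) abort("Knife-edge scan needs at least 6 points.")
  d <- diff(pos)
  if (!(all(d > 0) || all(d < 0))) {
    abort("Blade positions must be strictly monotone.")
  }
  rng <- range(sig)
  if (diff(rng) <= 0) abort("Knife-edge signal has no dynamic range.")

  # work in position order; direction: does the signal rise or fall as the
  # blade position increases?
  ord <- order(pos)
  pos_o <- pos[ord]
  sig_o <- sig[ord]
  rising <- stats::cor(pos_o, sig_o) > 0
  # the model uses erfc, which falls with its argument; a rising scan needs
  # a negative sign on (x - x0)
  s <- if (rising) -1 else 1

  # monotone-trend sanity check: a smoothed scan should move consistently
  # in the scan direction
  sm <- stats::filter(sig_o, rep(1 / 3, 3), sides = 2)
  trend <- diff(sm[!is.na(sm)])
  if (mean(sign(trend) == ifelse(rising, 1, -1)) < 0.6) {
    abort("Scan does not show a monotone knife-edge transition; cannot fit.")
  }

  # starting values from the 10%/90% crossings
  f <- (sig_o - rng[1L]) / diff(rng)
  x10 <- approx_crossing(pos_o, f, 0.1)
  x90 <- approx_crossing(pos_o, f, 0.9)
  x50 <- approx_crossing(pos_o, f, 0.5)
  span <- abs(diff(range(pos)))
  # a centre start at floating-point noise breaks the numeric Jacobian
  # (its relative step underflows); snap it to exactly zero
  if (abs(x50) < 1e-9 * span) x50 <- 0
  w0 <- max(abs(x90 - x10) / 1.28, 1e-6 * span)

  df <- tibble::tibble(x = pos_o, y = sig_o)
  start <- list(s0 = rng[1L], p = diff(rng), x0 = x50, w = w0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ s0 + (p / 2) * erfc(s * sqrt(2) * (x - x0) / w),
      data = df, start = start,
      lower = c(-Inf, 0, -Inf, 1e-6 * span),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      abort(paste0(
        "Knife-edge fit failed to converge: ", conditionMessage(e),
        " [start: w0=", signif(w0, 4), " um, x0=", signif(x50, 4), " um]"
      ))
    }
  )
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 4))
  names(se) <- names(est)
  w_hat <- unname(est[["w"]])
  rel_u <- unname(se[["w"]]) / w_hat
  structure(
    list(
      beam = beam_profile(2 * w_hat,
                          rel_u_d = ifelse(is.na(rel_u), 0, rel_u),
                          center_um = unname(est[["x0"]])),
      w_um = w_hat,
      x0_um = unname(est[["x0"]]),
      s0 = unname(est[["s0"]]),
      power = unname(est[["p"]]),
      direction = if (rising) "rising" else "falling",
      residual_sd = sd(stats::residuals(fit)),
      n = length(pos),
      model = fit
    ),
    class = "knife_edge_fit"
  )
}

# complementary error function via the normal CDF
erfc <- function(z) 2 * pnorm(-z * sqrt(2))

# first crossing of a normalized signal through level `q`, by linear
# interpolation; falls back to the nearest point when the scan is noisy
approx_crossing <- function(x, f, q) {
  if (f[length(f)] < f[1L]) {
    x <- rev(x)
    f <- rev(f)
  }
  i <- which(f[-length(f)] <= q & f[-1L] >= q)
  if (length(i) == 0L) return(x[which.min(abs(f - q))])
  i <- i[1L]
  x[i] + (q - f[i]) * (x[i + 1L] - x[i]) / (f[i + 1L] - f[i])
}

#' @export
print.knife_edge_fit <- function(x, ...) {
  cat("Knife-edge beam fit (", x$n, " points, ", x$direction, " scan)\n",
      sep = "")
  cat(sprintf("  d(1/e^2) = %.2f um  (rel. SE %.2f%%)\n",
              x$beam$d_1e2_um, 100 * x$beam$rel_u_d))
  cat(sprintf("  centre   = %.2f um, baseline = %.4g, swing = %.4g\n",
              x$x0_um, x$s0, x$power))
  invisible(x)
}

#' @export
#' @method tidy knife_edge_fit
#' @rdname fit_knife_edge
#' @param x,object a `knife_edge_fit`.
#' @param ... unused.
tidy.knife_edge_fit <- function(x, ...) {
  est <- coef(x$model)
  se <- sqrt(diag(vcov(x$model)))
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se[names(est)])
  )
}

#' @export
#' @method glance knife_edge_fit
#' @rdname fit_knife_edge
glance.knife_edge_fit <- function(x, ...) {
  tibble::tibble(
    d_1e2_um = x$beam$d_1e2_um,
    rel_u_d = x$beam$rel_u_d,
    x0_um = x$x0_um,
    residual_sd = x$residual_sd,
    n = x$n
  )
}
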