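#' Plot a probit dose-response fit
#'
#' Outcomes (jittered 0/1 points) and the fitted response curve on a log
#' dose axis, with the ED50 and its fiducial limits marked.
#'
#' @param object a [fit_probit()] object.
#' @param level confidence level for the fiducial limits drawn.
#' @param ... unused.
#' @return A ggplot object.
#' @export
#' @method autoplot probit_fit
autoplot.probit_fit <- function(object, level = 0.95, ...) {
  dat <- object$data
  grid <- tibble::tibble(
    dose = exp(seq(log(min(dat$dose)), log(max(dat$dose)),
                   length.out = 200))
  )
  grid$p <- predict_probability(object, grid$dose)
  lim <- tryCatch(fieller_limits(object, level), error = function(e) NULL)
  unit <- if (is.na(object$dose_unit)) "dose" else
    paste0("dose (", object$dose_unit, ")")
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$dose)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$p)) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$outcome),
      position = ggplot2::position_jitter(width = 0, height = 0.02),
      alpha = 0.6
    ) +
    ggplot2::geom_vline(xintercept = object$ed50, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = unit, y = "lesion probability",
                  title = sprintf("ED50 = %.4g, slope = %.3g probits/decade",
                                  object$ed50, object$beta1)) +
    ggplot2::theme_minimal()
  if (!is.null(lim)) {
    p <- p + ggplot2::geom_vline(xintercept = c(lim$lower, lim$upper),
                                 linetype = "dotted")
  }
  p
}

#' Plot a logarithmic depth-ratio fit
#'
#' @param object a [fit_depth_response()] object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
#' @method autoplot depth_fit
autoplot.depth_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble::tibble(
    dose = exp(seq(log(min(dat$dose)), log(max(dat$dose)),
                   length.out = 100))
  )
  grid$ratio <- object$a + object$b * log(grid$dose)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$dose, y = .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "radiant exposure (J/cm²)",
                  y = "lesion depth / corneal thickness",
                  title = sprintf("ratio = %.3g + %.3g ln(dose), R² = %.3f",
                                  object$a, object$b, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a knife-edge scan and its fitted edge profile
#'
#' @param object a [fit_knife_edge()] object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
#' @method autoplot knife_edge_fit
autoplot.knife_edge_fit <- function(object, ...) {
  mf <- object$model$m$getEnv()
  dat <- tibble::tibble(position_um = mf$x, signal = mf$y)
  grid <- tibble::tibble(
    x = seq(min(dat$position_um), max(dat$position_um), length.out = 200)
  )
  grid$signal <- predict(object$model, newdata = grid)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$position_um,
                                    y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$x)) +
    ggplot2::labs(x = "blade position (µm)", y = "transmitted signal",
                  title = sprintf("d(1/e²) = %.2f µm",
                                  object$beam$d_1e2_um)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
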