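#' Fit a probit dose-response model to binary lesion outcomes
#'
#' Maximum-likelihood probit regression of a binary outcome on log dose,
#' `P(lesion) = Phi(beta0 + beta1 * log(dose))`.  This is the classical
#' quantal bioassay model: it assumes individual damage thresholds are
#' log-normally distributed, so the response probability is a normal CDF in
#' log dose.  The default logarithm base is 10, the convention of the
#' laser-bioeffects literature, so `beta1` is the probit slope in probits
#' per decade of dose; `log_base = exp(1)` is available.  Intercepts are on
#' the z-scale (no classical +5 offset), which changes only how the
#' intercept is reported, never ED50 or slope.
#'
#' Estimation is Fisher scoring on the exact log-likelihood with
#' step-halving, started from an ordinary least-squares line through
#' empirical-probit transforms of dose-binned response rates; convergence
#' at `|delta loglik| < 1e-10`.  The fit is deterministic: no random
#' initialisation, no seed.
#'
#' @param data a data frame with one row per exposure.
#' @param dose,outcome columns (tidy-eval) holding the positive dose and
#'   the 0/1 lesion outcome. Defaults `dose`, `outcome`.
#' @param dose_unit optional string recorded on the fit (e.g. `"J/cm2"`,
#'   `"mJ"`); taken from a `dose_unit` column when present.
#' @param log_base base of the dose logarithm; 10 (default) or any base > 1.
#' @param max_iter maximum scoring iterations.
#' @return An object of class `probit_fit`: a list with `beta0`, `beta1`,
#'   `ed50`, `log_ed50` (in `log_base` units), `vcov` (observed-information
#'   covariance of `(beta0, beta1)`), `loglik`, `n`, `converged`,
#'   `iterations`, `dose_unit`, `log_base`, and the model frame `data`.
#' @examples
#' records <- simulate_exposures(sim_config(seed = 1))
#' fit <- fit_probit(records)
#' fit$ed50
#' @export
fit_probit <- function(data, dose = dose, outcome = outcome,
                       dose_unit = NULL, log_base = 10, max_iter = 100L) {
  d <- dplyr::pull(data, {{ dose }})
  y <- dplyr::pull(data, {{ outcome }})
  if (is.null(dose_unit) && "dose_unit" %in% names(data)) {
    u <- unique(data$dose_unit)
    if (length(u) > 1L) {
      abort(paste0("Mixed dose units in data: ", paste(u, collapse = ", ")))
    }
    dose_unit <- u
  }
  if (any(!is.finite(d)) || any(d <= 0)) {
    abort("All doses must be finite and positive.")
  }
  if (!all(y %in% c(0, 1))) abort("Outcomes must be 0 or 1.")
  if (length(unique(d)) < 2L) abort("Need at least 2 distinct doses.")
  if (length(unique(y)) < 2L) {
    abort("Both outcome classes (lesion and no lesion) must be present.")
  }
  if (!is.finite(log_base) || log_base <= 1) abort("`log_base` must exceed 1.")

  x <- log(d, base = log_base)
  if (max(x[y == 0]) < min(x[y == 1]) || max(x[y == 1]) < min(x[y == 0])) {
    abort(paste(
      "Complete separation: the lesion and no-lesion doses do not overlap,",
      "so the maximum-likelihood probit slope is unbounded."
    ))
  }

  beta <- probit_start(x, y)
  ll <- probit_loglik(beta, x, y)
  converged <- FALSE
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    sc <- probit_score(beta, x, y)
    info <- probit_fisher_info(beta, x)
    step <- tryCatch(solve(info, sc), error = function(e) NULL)
    if (is.null(step)) {
      abort("Probit scoring step failed: singular information matrix.")
    }
    # step-halving keeps the likelihood nondecreasing
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ll_new <- probit_loglik(cand, x, y)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) {
        cand <- beta
        ll_new <- ll
        break
      }
    }
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < 1e-10) {
      beta <- cand
      ll <- ll_new
      converged <- TRUE
      break
    }
    beta <- cand
    ll <- ll_new
  }
  if (!converged) {
    abort(paste0(
      "Probit fit did not converge in ", max_iter, " iterations; ",
      "log-likelihood trace (last 5): ",
      paste(signif(tail(trace, 5), 8), collapse = ", ")
    ))
  }
  hess <- probit_obs_hessian(beta, x, y)
  vc <- tryCatch(solve(-hess), error = function(e) solve(probit_fisher_info(beta, x)))
  log_ed50 <- -beta[1L] / beta[2L]
  structure(
    list(
      beta0 = unname(beta[1L]),
      beta1 = unname(beta[2L]),
      ed50 = log_base^log_ed50,
      log_ed50 = unname(log_ed50),
      vcov = vc,
      loglik = unname(ll),
      n = length(y),
      converged = converged,
      iterations = it,
      dose_unit = dose_unit %||% NA_character_,
      log_base = log_base,
      data = tibble::tibble(dose = d, log_dose = x, outcome = y)
    ),
    class = "probit_fit"
  )
}

# log-likelihood via log CDFs for numerical stability in the tails
probit_loglik <- function(beta, x, y) {
  eta <- beta[1L] + beta[2L] * x
  sum(y * pnorm(eta, log.p = TRUE) + (1 - y) * pnorm(-eta, log.p = TRUE))
}

# inverse Mills ratio phi(eta)/Phi(eta), stable in the lower tail
mills <- function(eta) exp(dnorm(eta, log = TRUE) - pnorm(eta, log.p = TRUE))

probit_score <- function(beta, x, y) {
  eta <- beta[1L] + beta[2L] * x
  g <- ifelse(y == 1, mills(eta), -mills(-eta))
  c(sum(g), sum(g * x))
}

probit_fisher_info <- function(beta, x) {
  eta <- beta[1L] + beta[2L] * x
  w <- exp(2 * dnorm(eta, log = TRUE) -
             pnorm(eta, log.p = TRUE) - pnorm(-eta, log.p = TRUE))
  matrix(c(sum(w), sum(w * x), sum(w * x), sum(w * x^2)), 2L, 2L)
}

# observed Hessian of the log-likelihood;
# d2/deta2 log Phi(eta) = -lambda(eta) (lambda(eta) + eta)
probit_obs_hessian <- function(beta, x, y) {
  eta <- beta[1L] + beta[2L] * x
  h <- ifelse(
    y == 1,
    -mills(eta) * (mills(eta) + eta),
    -mills(-eta) * (mills(-eta) - eta)
  )
  matrix(c(sum(h), sum(h * x), sum(h * x), sum(h * x^2)), 2L, 2L)
}

# OLS through empirical probits of dose-binned response rates
probit_start <- function(x, y) {
  ux <- sort(unique(x))
  if (length(ux) > 5L) {
    br <- quantile(x, probs = seq(0, 1, length.out = 6), names = FALSE)
    grp <- cut(x, breaks = unique(br), include.lowest = TRUE)
  } else {
    grp <- factor(x)
  }
  xbar <- tapply(x, grp, mean)
  r <- tapply(y, grp, sum)
  n <- tapply(y, grp, length)
  p <- (r + 0.5) / (n + 1)  # shrunken rates keep probits finite
  z <- qnorm(p)
  keep <- is.finite(z) & is.finite(xbar)
  if (sum(keep) >= 2L) {
    cf <- coef(lm(z[keep] ~ xbar[keep]))
    if (is.finite(cf[2L]) && cf[2L] > 0) return(unname(cf))
  }
  c(-mean(x), 1)
}

#' Dose expected to produce a lesion with probability p
#'
#' Inverts the fitted probit model:
#' `ED_p = base^((qnorm(p) - beta0) / beta1)`.  `ed_p(fit, 0.5)` is the
#' ED50 exactly.
#'
#' @param fit a [fit_probit()] object.
#' @param p response probability (0 < p < 1), vectorised.
#' @return Dose(s) in the fit's dose units.
#' @export
ed_p <- function(fit, p) {
  stopifnot(inherits(fit, "probit_fit"))
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort("`p` must lie strictly between 0 and 1.")
  }
  fit$log_base^((qnorm(p) - fit$beta0) / fit$beta1)
}

#' Predicted lesion probability at a dose
#'
#' @param fit a [fit_probit()] object.
#' @param dose positive dose(s) in the fit's dose units.
#' @return Probabilities `Phi(beta0 + beta1 log(dose))`.
#' @export
predict_probability <- function(fit, dose) {
  stopifnot(inherits(fit, "probit_fit"))
  if (any(!is.finite(dose)) || any(dose <= 0)) {
    abort("`dose` must be finite and positive.")
  }
  pnorm(fit$beta0 + fit$beta1 * log(dose, base = fit$log_base))
}

#' Fieller fiducial limits for the ED50
#'
#' The ED50 on the log-dose scale is the ratio `-beta0/beta1`; its
#' confidence set from Fieller's theorem is the set of `theta` with
#' `(beta0 + beta1 theta)^2 <= q^2 Var(beta0 + beta1 theta)`, a quadratic
#' whose roots are back-transformed to dose units.  The covariance is the
#' fit's observed-information covariance.  Following the classical bioassay
#' (Finney) convention, when records share doses and the grouped Pearson
#' chi-square per degree of freedom exceeds 1, the covariance is inflated
#' by that heterogeneity factor and a t quantile replaces the normal one;
#' with all-distinct doses the plain normal quantile is used.
#'
#' @param fit a converged [fit_probit()] object.
#' @param level confidence level, default 0.95.
#' @return A one-row tibble with `lower`, `upper` (dose units), `level`,
#'   `g` (Fieller's g), `heterogeneity` (variance inflation applied), and
#'   `df` (`Inf` for the normal quantile).
#' @export
fieller_limits <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "probit_fit"))
  if (!is.finite(level) || level <= 0 || level >= 1) {
    abort("`level` must be in (0, 1).")
  }
  vc <- fit$vcov
  het <- heterogeneity_factor(fit)
  vc <- vc * het$factor
  q <- if (is.finite(het$df)) qt(1 - (1 - level) / 2, het$df) else
    qnorm(1 - (1 - level) / 2)

  b0 <- fit$beta0
  b1 <- fit$beta1
  v00 <- vc[1L, 1L]; v01 <- vc[1L, 2L]; v11 <- vc[2L, 2L]
  g <- q^2 * v11 / b1^2
  if (g >= 1) {
    abort(paste0(
      "Fieller g = ", signif(g, 4), " >= 1: the slope is not significantly ",
      "different from zero at this level and the fiducial interval is unbounded."
    ))
  }
  A <- b1^2 - q^2 * v11
  B <- b0 * b1 - q^2 * v01
  C <- b0^2 - q^2 * v00
  disc <- B^2 - A * C
  if (disc < 0) abort("Fieller discriminant negative; interval undefined.")
  roots <- sort((-B + c(-1, 1) * sqrt(disc)) / A)
  tibble::tibble(
    lower = fit$log_base^roots[1L],
    upper = fit$log_base^roots[2L],
    level = level,
    g = g,
    heterogeneity = het$factor,
    df = het$df
  )
}

# Finney-style heterogeneity: only meaningful when doses repeat
heterogeneity_factor <- function(fit) {
  dat <- fit$data
  grp <- dplyr::summarise(
    dplyr::group_by(dat, .data$log_dose),
    r = sum(.data$outcome), n = dplyr::n(), .groups = "drop"
  )
  k <- nrow(grp)
  if (k == fit$n || k <= 2L) {
    return(list(factor = 1, df = Inf, chisq = NA_real_))
  }
  p <- pnorm(fit$beta0 + fit$beta1 * grp$log_dose)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  chisq <- sum((grp$r - grp$n * p)^2 / (grp$n * p * (1 - p)))
  df <- k - 2L
  h <- chisq / df
  if (h > 1) list(factor = h, df = df, chisq = chisq)
  else list(factor = 1, df = Inf, chisq = chisq)
}

#' Adequacy screen for a fitted threshold
#'
#' A threshold fit is conventionally reported as adequate when the probit
#' slope exceeds 5 probits per decade and the 95% fiducial interval is
#' narrower than half the ED50.
#'
#' @param fit a converged [fit_probit()] object.
#' @param limits optionally, a precomputed [fieller_limits()] row.
#' @return A one-row tibble with `slope_ok`, `fiducial_ok`, `adequate`,
#'   plus the quantities screened (`slope`, `ed50`, `lower`, `upper`,
#'   `width`).
#' @export
adequacy <- function(fit, limits = NULL) {
  stopifnot(inherits(fit, "probit_fit"))
  if (is.null(limits)) limits <- fieller_limits(fit)
  width <- limits$upper - limits$lower
  tibble::tibble(
    slope = fit$beta1,
    ed50 = fit$ed50,
    lower = limits$lower,
    upper = limits$upper,
    width = width,
    slope_ok = fit$beta1 > 5,
    fiducial_ok = width < fit$ed50 / 2,
    adequate = fit$beta1 > 5 & width < fit$ed50 / 2
  )
}

#' @export
print.probit_fit <- function(x, ...) {
  cat("Probit dose-response fit (n = ", x$n, ", log base ",
      format(x$log_base), ")\n", sep = "")
  unit <- if (is.na(x$dose_unit)) "" else paste0(" ", x$dose_unit)
  cat(sprintf("  ED50  = %.4g%s\n", x$ed50, unit))
  cat(sprintf("  slope = %.4g probits per log-%s dose\n", x$beta1,
              format(x$log_base)))
  cat(sprintf("  loglik = %.4f (%d iterations)\n", x$loglik, x$iterations))
  invisible(x)
}

#' Tidy a probit fit
#'
#' @param x a `probit_fit`.
#' @param ... unused.
#' @return One row per coefficient with `term`, `estimate`, `std.error`.
#' @export
#' @method tidy probit_fit
tidy.probit_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  tibble::tibble(
    term = c("(Intercept)", "log_dose"),
    estimate = c(x$beta0, x$beta1),
    std.error = se
  )
}

#' One-row summary of a probit fit
#'
#' @param x a `probit_fit`.
#' @param ... unused.
#' @export
#' @method glance probit_fit
glance.probit_fit <- function(x, ...) {
  lim <- tryCatch(fieller_limits(x), error = function(e) {
    tibble::tibble(lower = NA_real_, upper = NA_real_)
  })
  tibble::tibble(
    ed50 = x$ed50,
    slope = x$beta1,
    fiducial_lower = lim$lower,
    fiducial_upper = lim$upper,
    logLik = x$loglik,
    n = x$n,
    converged = x$converged
  )
}

#' @export
predict.probit_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(predict_probability(object, object$data$dose))
  predict_probability(object, dplyr::pull(newdata, dose))
}
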