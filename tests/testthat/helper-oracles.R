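# Independent oracles used to validate the package's own estimators.
# These deliberately avoid the code paths they check.

# Brute-force probit MLE: dense grid over (log10 ED50, slope) -- a far
# less correlated parameterisation than (beta0, beta1) -- iteratively
# refined around the best cell, then polished with Nelder-Mead on the
# exact log-likelihood.  Independent of the package's scoring loop.
grid_mle_probit <- function(log_dose, outcome,
                            m_range = c(0.5, 3.5), b1_range = c(0.1, 40),
                            n_grid = 81, n_refine = 8) {
  ll_mb <- function(m, b1) {
    eta <- b1 * (log_dose - m)
    sum(outcome * pnorm(eta, log.p = TRUE) +
          (1 - outcome) * pnorm(-eta, log.p = TRUE))
  }
  for (r in seq_len(n_refine)) {
    ms <- seq(m_range[1], m_range[2], length.out = n_grid)
    b1s <- seq(b1_range[1], b1_range[2], length.out = n_grid)
    vals <- outer(ms, b1s, Vectorize(ll_mb))
    best <- arrayInd(which.max(vals), dim(vals))
    span_m <- diff(m_range) / (n_grid - 1)
    span_b <- diff(b1_range) / (n_grid - 1)
    m_range <- ms[best[1, 1]] + c(-2, 2) * span_m
    b1_range <- b1s[best[1, 2]] + c(-2, 2) * span_b
  }
  polish <- optim(
    c(mean(m_range), mean(b1_range)),
    function(th) -ll_mb(th[1], th[2]),
    method = "Nelder-Mead",
    control = list(reltol = 1e-15, maxit = 5000)
  )
  m <- polish$par[1]
  b1 <- polish$par[2]
  list(beta0 = -m * b1, beta1 = b1, loglik = -polish$value)
}

# Parametric-bootstrap ED50 percentile interval, refitting each draw with
# stats::glm (an implementation independent of the package's scoring loop).
bootstrap_ed50_limits <- function(fit, B = 10000, level = 0.95, seed = 99) {
  set.seed(seed)
  x <- fit$data$log_dose
  p <- pnorm(fit$beta0 + fit$beta1 * x)
  ed <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    yb <- rbinom(length(x), 1, p)
    if (length(unique(yb)) < 2L) next
    g <- tryCatch(
      suppressWarnings(glm(yb ~ x, family = binomial(link = "probit"))),
      error = function(e) NULL
    )
    if (is.null(g) || !g$converged) next
    cf <- coef(g)
    if (!is.finite(cf[2L]) || cf[2L] <= 0) next
    ed[b] <- 10^(-cf[1L] / cf[2L])
  }
  alpha <- 1 - level
  unname(quantile(ed, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))
}

# Encircled energy of a Gaussian profile H(r) = exp(-2 r^2 / w^2) by
# numeric radial integration (adaptive quadrature).
numeric_encircled_fraction <- function(R, w) {
  f <- function(r) r * exp(-2 * r^2 / w^2)
  inside <- stats::integrate(f, 0, R, rel.tol = 1e-12)$value
  total <- stats::integrate(f, 0, 10 * w, rel.tol = 1e-12)$value
  inside / total
}

fixture_path <- function() {
  system.file("extdata", "probit_fixture_12.csv", package = "lasethresh")
}

fixture_exposures <- function() read_exposure_table(fixture_path())
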