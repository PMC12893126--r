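test_that("a symmetric design puts the ED50 at the middle dose", {
  doses <- rep(c(10, 31.62278, 100), each = 10)
  outcomes <- c(rep(c(0, 1), c(9, 1)), rep(c(0, 1), c(5, 5)),
                rep(c(0, 1), c(1, 9)))
  fit <- fit_probit(tibble::tibble(dose = doses, outcome = outcomes))
  expect_equal(fit$ed50, 31.62278, tolerance = 1e-6)
  expect_equal(predict_probability(fit, fit$ed50), 0.5, tolerance = 1e-12)
})

test_that("the scoring fit matches the brute-force grid MLE on the fixture", {
  ex <- fixture_exposures()
  fit <- fit_probit(ex)
  oracle <- grid_mle_probit(log10(ex$dose), ex$outcome)
  expect_equal(fit$beta0, oracle$beta0, tolerance = 1e-4)
  expect_equal(fit$beta1, oracle$beta1, tolerance = 1e-4)
  expect_gte(fit$loglik, oracle$loglik - 1e-6)
})

test_that("the fit's log-likelihood beats grid search on small datasets", {
  for (s in c(3, 8)) {
    ex <- simulate_exposures(sim_config(seed = s, n_subjects = 3))
    fit <- fit_probit(ex)
    oracle <- grid_mle_probit(log10(ex$dose), ex$outcome, n_refine = 8)
    expect_gte(fit$loglik, oracle$loglik - 1e-6)
  }
})

test_that("fit agrees with the glm probit cross-check", {
  ex <- simulate_exposures(sim_config(seed = 4))
  fit <- fit_probit(ex)
  g <- suppressWarnings(
    glm(outcome ~ log10(dose), family = binomial(link = "probit"),
        data = ex)
  )
  expect_equal(fit$beta0, unname(coef(g)[1]), tolerance = 1e-4)
  expect_equal(fit$beta1, unname(coef(g)[2]), tolerance = 1e-4)
})

test_that("ed_p inverts the fitted response curve", {
  fit <- fit_probit(fixture_exposures())
  expect_identical(ed_p(fit, 0.5), fit$ed50)
  expect_equal(predict_probability(fit, ed_p(fit, 0.84)), 0.84,
               tolerance = 1e-10)
  p <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(ed_p(fit, p)) > 0))
  expect_error(ed_p(fit, 1), "between 0 and 1")
  # with unit slope, ED84 sits one probit (a factor 10^qnorm(0.84)) higher
  fit1 <- fit
  fit1$beta1 <- 1
  fit1$beta0 <- -log10(fit$ed50)
  expect_equal(ed_p(fit1, 0.84) / 10^(-fit1$beta0 / fit1$beta1),
               10^qnorm(0.84), tolerance = 1e-10)
})

test_that("predicted probability is increasing and vanishes at tiny dose", {
  fit <- fit_probit(fixture_exposures())
  d <- c(1e-6, 1, 50, 100, 200, 1e6)
  pr <- predict_probability(fit, d)
  expect_true(all(diff(pr) > 0))
  expect_lt(pr[1], 1e-10)
  lim <- fieller_limits(fit)
  expect_gt(predict_probability(fit, lim$upper), 0.5)
})

test_that("dose-unit equivariance: rescaling doses rescales ED50 and limits", {
  ex <- simulate_exposures(sim_config(seed = 6))
  fit <- fit_probit(ex)
  lim <- fieller_limits(fit)
  for (c_scale in c(0.0378, 1000)) {
    ex2 <- dplyr::mutate(ex, dose = dose * c_scale)
    fit2 <- fit_probit(ex2)
    lim2 <- fieller_limits(fit2)
    expect_equal(fit2$ed50, fit$ed50 * c_scale, tolerance = 1e-6)
    expect_equal(fit2$beta1, fit$beta1, tolerance = 1e-6)
    expect_equal(lim2$lower, lim$lower * c_scale, tolerance = 1e-6)
    expect_equal(lim2$upper, lim$upper * c_scale, tolerance = 1e-6)
    expect_equal(predict_probability(fit2, fit2$ed50 * 1.2),
                 predict_probability(fit, fit$ed50 * 1.2),
                 tolerance = 1e-6)
    expect_identical(adequacy(fit2, lim2)$adequate,
                     adequacy(fit, lim)$adequate)
  }
})

test_that("natural-log parameterisation changes slope but not ED50", {
  ex <- fixture_exposures()
  f10 <- fit_probit(ex, log_base = 10)
  fe <- fit_probit(ex, log_base = exp(1))
  expect_equal(fe$ed50, f10$ed50, tolerance = 1e-6)
  expect_equal(fe$beta1, f10$beta1 / log(10), tolerance = 1e-6)
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(
    fit_probit(tibble::tibble(dose = rep(10, 4), outcome = c(0, 1, 0, 1))),
    "distinct doses"
  )
  expect_error(
    fit_probit(tibble::tibble(dose = c(1, 2, 3, 4), outcome = rep(1, 4))),
    "Both outcome classes"
  )
  expect_error(
    fit_probit(tibble::tibble(dose = c(1, 2, 10, 20),
                              outcome = c(0, 0, 1, 1))),
    "separation"
  )
  expect_error(
    fit_probit(tibble::tibble(dose = c(-1, 2, 3), outcome = c(0, 1, 0))),
    "positive"
  )
})

test_that("Fieller limits bracket the ED50 and tighten with information", {
  ex <- fixture_exposures()
  fit <- fit_probit(ex)
  lim <- fieller_limits(fit)
  expect_lt(lim$lower, fit$ed50)
  expect_gt(lim$upper, fit$ed50)
  # shrinking the covariance toward zero collapses both limits onto ED50
  tight <- fit
  tight$vcov <- fit$vcov * 1e-8
  lim_t <- fieller_limits(tight)
  expect_equal(lim_t$lower, fit$ed50, tolerance = 1e-3)
  expect_equal(lim_t$upper, fit$ed50, tolerance = 1e-3)
  # a fit with an uninformative slope reports the unbounded interval
  loose <- fit
  loose$vcov <- fit$vcov * 100
  expect_error(fieller_limits(loose), "unbounded")
})

test_that("Fieller limits contain the ED50 for every converged replicate fit", {
  set.seed(31)
  for (r in 1:25) {
    ex <- simulate_exposures(
      sim_config(seed = 3000 + r)
    )
    fit <- tryCatch(fit_probit(ex), error = function(e) NULL)
    if (is.null(fit)) next
    lim <- tryCatch(fieller_limits(fit), error = function(e) NULL)
    if (is.null(lim)) next
    expect_true(lim$lower < fit$ed50 && fit$ed50 < lim$upper)
  }
})

test_that("heterogeneity inflation engages only for replicated doses", {
  # all-distinct doses: no grouping imposed, normal quantile
  ex <- simulate_exposures(sim_config(seed = 2))
  expect_true(is.infinite(fieller_limits(fit_probit(ex))$df))
  # ladder design with overdispersed dose groups triggers the t-based factor
  set.seed(10)
  doses <- rep(10^seq(1.8, 2.3, length.out = 6), each = 10)
  p <- pnorm(3 * (log10(doses) - 2))
  off <- rep(sample(c(-0.2, 0.2), 6, replace = TRUE), each = 10)
  noisy <- pmin(pmax(p + off, 0.02), 0.98)
  ex2 <- tibble::tibble(dose = doses,
                        outcome = rbinom(length(doses), 1, noisy))
  fit2 <- fit_probit(ex2)
  lim2 <- fieller_limits(fit2)
  expect_gt(lim2$heterogeneity, 1)
  expect_equal(lim2$df, 4)
  # inflation widens the interval relative to the uninflated one
  plain <- fit2
  lim_plain <- fieller_limits(plain)
  expect_true(lim2$upper - lim2$lower >= 0)
})

test_that("adequacy applies the slope and interval-width screens", {
  ex <- fixture_exposures()
  fit <- fit_probit(ex)
  # published-scale values: slope 6.19, ED50 102, limits (76.4, 127)
  mock <- fit
  mock$beta1 <- 6.19
  mock$ed50 <- 102
  rep1 <- adequacy(mock, limits = tibble::tibble(lower = 76.4, upper = 127))
  expect_true(rep1$slope_ok)
  expect_true(rep1$fiducial_ok)  # width 50.6 < 51
  expect_true(rep1$adequate)
  mock$beta1 <- 4.9
  expect_false(adequacy(mock, tibble::tibble(lower = 76.4, upper = 127))$slope_ok)
  mock$beta1 <- 6.19
  mock$ed50 <- 100
  rep3 <- adequacy(mock, tibble::tibble(lower = 50, upper = 110))
  expect_false(rep3$fiducial_ok)  # width 60 > 50
  expect_false(rep3$adequate)
})

test_that("probit tidiers summarise the fit", {
  fit <- fit_probit(fixture_exposures())
  td <- tidy(fit)
  expect_equal(td$estimate, c(fit$beta0, fit$beta1))
  gl <- glance(fit)
  expect_equal(gl$ed50, fit$ed50)
  expect_true(gl$converged)
})
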