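test_that("the joint MLE recovers the reliability on simulated data", {
  # At a = b = theta = 1 the model collapses onto the exponential baseline
  # and the individual shape parameters are not separately identified, so
  # recovery is asserted for R (the identified target quantity).
  d <- make_synthetic(2000, 2000, a = 1, b1 = 1, b2 = 1, theta = 1,
                      baseline = "exponential", par = 1, seed = 21)
  fit <- fit_egmo_ss(d$x, d$y, "exponential", method = "joint",
                     starts = 10, seed = 3)
  expect_true(fit$converged)
  se_R <- (fit$b1 * fit$b2 / (fit$b1 + fit$b2)^2) * sqrt(2 / 2000)
  expect_lt(abs(fit$R - 0.5), 3 * se_R)
  # the reported point satisfies the R identity exactly
  expect_identical(fit$R, fit$b1 / (fit$b1 + fit$b2))
})

test_that("plug-in fit is equivariant under swapping the two samples", {
  d <- make_synthetic(60, 50, a = 0.5, b1 = 1.5, b2 = 2.5, theta = 0.5,
                      baseline = "weibull", par = c(3.5, 1.5), seed = 13)
  f12 <- fit_egmo_ss(d$x, d$y, "weibull", method = "plugin", starts = 15)
  f21 <- fit_egmo_ss(d$y, d$x, "weibull", method = "plugin", starts = 15)
  expect_equal(f21$R, 1 - f12$R, tolerance = 1e-12)
  expect_true(f12$R > 0 && f12$R < 1)
})

test_that("multi-start fitting is reproducible for a fixed seed", {
  d <- make_synthetic(40, 40, a = 0.5, b1 = 0.5, b2 = 0.5, theta = 0.5,
                      baseline = "weibull", par = c(0.5, 0.5), seed = 2)
  f1 <- fit_egmo_ss(d$x, d$y, "weibull", starts = 8, seed = 5)
  f2 <- fit_egmo_ss(d$x, d$y, "weibull", starts = 8, seed = 5)
  expect_identical(f1$R, f2$R)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("asymptotic interval follows the closed-form half-width", {
  # b1 = b2, n = m = 50: half-width 1.96 * 0.25 * sqrt(2/50) = 0.098
  ci <- ci_asymp(list(b1 = 2, b2 = 2, n = 50, m = 50), level = 0.95)
  expect_equal(ci$upper - ci$lower, 2 * qnorm(0.975) * 0.25 * sqrt(2 / 50),
               tolerance = 1e-12)
  expect_equal((ci$lower + ci$upper) / 2, 0.5, tolerance = 1e-12)
  # tiny samples push the raw interval outside [0,1]; it is clipped
  ci2 <- ci_asymp(list(b1 = 1, b2 = 1, n = 2, m = 2), level = 0.99)
  expect_gte(ci2$lower, 0)
  expect_lte(ci2$upper, 1)
  expect_true(ci2$clipped)
  expect_error(ci_asymp(list(b1 = 1, b2 = 1, n = 5, m = 5), level = 1.2),
               "level")
})

test_that("percentile bootstrap is seed-reproducible and shrinks with n", {
  d <- make_synthetic(12, 12, a = 1, b1 = 1, b2 = 1, theta = 1,
                      baseline = "exponential", par = 1, seed = 31)
  fit <- fit_egmo_ss(d$x, d$y, "exponential", starts = 8)
  b1 <- ci_boot(d$x, d$y, "exponential", B = 100, seed = 7, fit = fit)
  b2 <- ci_boot(d$x, d$y, "exponential", B = 100, seed = 7, fit = fit)
  expect_identical(c(b1$lower, b1$upper), c(b2$lower, b2$upper))
  expect_error(ci_boot(d$x, d$y, "exponential", B = 50, fit = fit), "100")

  dbig <- make_synthetic(70, 70, a = 1, b1 = 1, b2 = 1, theta = 1,
                         baseline = "exponential", par = 1, seed = 32)
  fitb <- fit_egmo_ss(dbig$x, dbig$y, "exponential", starts = 8)
  bbig <- ci_boot(dbig$x, dbig$y, "exponential", B = 100, seed = 7, fit = fitb)
  expect_lt(bbig$upper - bbig$lower, b1$upper - b1$lower)
})

test_that("sub-model fits report the hierarchy honestly", {
  set.seed(41)
  x <- rweibull(400, 2, 1)
  fw <- fit_egmo_model(x, "W", starts = 5)
  expect_true(fw$converged)
  expect_lt(abs(fw$estimate[["shape"]] - 2), 3 * fw$se[["shape"]])
  expect_lt(abs(fw$estimate[["scale"]] - 1), 3 * fw$se[["scale"]])
  # AIC/BIC identities
  expect_equal(fw$aic, 2 * 2 - 2 * fw$loglik, tolerance = 1e-12)
  expect_equal(fw$bic, 2 * log(400) - 2 * fw$loglik, tolerance = 1e-12)
  expect_error(fit_egmo_model(x, "XYZ-W"), "unknown")
})
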