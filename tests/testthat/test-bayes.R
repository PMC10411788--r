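test_that("posterior hyper-quantities reduce to the profile denominators", {
  set.seed(3)
  x <- regmo(9, 0.7, 1.1, 1.8, "weibull", c(2.5, 1.2))
  y <- regmo(7, 0.7, 0.6, 1.8, "weibull", c(2.5, 1.2))
  hp <- posterior_hyper(x, y, 0.7, 1.8, "weibull", c(2.5, 1.2))
  pb <- profile_b(x, y, 0.7, 1.8, "weibull", c(2.5, 1.2))
  # with xi = 0, H1 and H2 are the negated profile denominators: b1hat = n/H1
  expect_equal(pb[["b1"]], length(x) / hp$H1, tolerance = 1e-12)
  expect_equal(pb[["b2"]], length(y) / hp$H2, tolerance = 1e-12)
  expect_true(hp$H1 > 0 && hp$H2 > 0)
  # a nonzero prior rate shifts H1 additively
  hp2 <- posterior_hyper(x, y, 0.7, 1.8, "weibull", c(2.5, 1.2),
                         prior = egmo_prior(xi = 2, eta = 3))
  expect_equal(hp2$H1 - hp$H1, 2, tolerance = 1e-12)
  # direct substitution for a single observation
  bl <- egmo_baseline("exponential")
  L1 <- egmoss:::.egmo_pieces(1.3, 0.9, 1.5, bl, 2)$L
  hp3 <- posterior_hyper(1.3, 2.1, 0.9, 1.5, "exponential", 2)
  L2 <- egmoss:::.egmo_pieces(2.1, 0.9, 1.5, bl, 2)$L
  expect_equal(hp3$H1, -L1, tolerance = 1e-12)
  expect_equal(hp3$H2, -L2, tolerance = 1e-12)
})

test_that("closed-form Bayes estimate matches its reductions and quadrature", {
  # exchangeable case: equal rates and shapes give exactly 1/2
  expect_equal(egmoss:::.gamma_ratio_mean(10, 2.5, 10, 2.5), 0.5,
               tolerance = 1e-12)
  # equal rates reduce to a Beta mean: alpha1/(alpha1+alpha2)
  expect_equal(egmoss:::.gamma_ratio_mean(2, 1, 3, 1), 0.4, tolerance = 1e-10)
  # general case against adaptive quadrature (both psi branches)
  for (hh in list(c(2.0, 0.5), c(0.5, 2.0))) {
    a1 <- 5; a2 <- 7; h1 <- hh[1]; h2 <- hh[2]
    psi <- 1 - h1 / h2; cc <- a1 + a2
    num <- integrate(function(w) w^a1 * (1 - w)^(a2 - 1) * (1 - psi * w)^(-cc),
                     0, 1, rel.tol = 1e-12)$value
    den <- integrate(function(w) w^(a1 - 1) * (1 - w)^(a2 - 1) * (1 - psi * w)^(-cc),
                     0, 1, rel.tol = 1e-12)$value
    expect_equal(egmoss:::.gamma_ratio_mean(a1, h1, a2, h2), num / den,
                 tolerance = 1e-8)
  }
  # the hypergeometric series itself against a direct high-precision sum
  direct <- sum(exp(lgamma(12 + 0:200) - lgamma(12) + lgamma(6 + 0:200) -
                    lgamma(6) - lgamma(13 + 0:200) + lgamma(13) -
                    lfactorial(0:200) + (0:200) * log(0.3)))
  expect_equal(hyp2f1(12, 6, 13, 0.3), direct, tolerance = 1e-10)
})

test_that("known-parameter sampler agrees with the closed form", {
  d <- make_synthetic(30, 25, a = 0.5, b1 = 1.5, b2 = 2.5, theta = 0.5,
                      baseline = "weibull", par = c(3.5, 1.5), seed = 3)
  cf <- bayes_closed_form(d$x, d$y, a = 0.5, theta = 0.5,
                          baseline = "weibull", par = c(3.5, 1.5))
  post <- quiet(egmo_ss_bayes(d$x, d$y, "weibull", egmo_prior(0, 0),
                              T = 10000, seed = 4,
                              init = list(b1 = 1, b2 = 1, a = 0.5,
                                          theta = 0.5, par = c(3.5, 1.5))))
  mcse <- sd(post$draws$R) / sqrt(post$T)
  expect_lt(abs(bayes_point(post) - cf), 5 * mcse)
  # every recorded R equals b1/(b1+b2) of its row
  expect_equal(post$draws$R,
               post$draws$b1 / (post$draws$b1 + post$draws$b2),
               tolerance = 1e-12)
})

test_that("chains are reproducible and the estimate is permutation-invariant", {
  d <- make_synthetic(20, 20, a = 0.5, b1 = 0.5, b2 = 0.5, theta = 0.5,
                      baseline = "weibull", par = c(0.5, 0.5), seed = 6)
  init <- list(b1 = 1, b2 = 1, a = 0.5, theta = 0.5, par = c(0.5, 0.5))
  p1 <- quiet(egmo_ss_bayes(d$x, d$y, "weibull", egmo_prior(2, 3), T = 300,
                            seed = 17, init = init))
  p2 <- quiet(egmo_ss_bayes(d$x, d$y, "weibull", egmo_prior(2, 3), T = 300,
                            seed = 17, init = init))
  expect_identical(p1$draws, p2$draws)
  expect_true(all(p1$acceptance >= 0 & p1$acceptance <= 1))
  p3 <- p1
  p3$draws <- p1$draws[sample(nrow(p1$draws)), ]
  expect_equal(bayes_point(p3), bayes_point(p1), tolerance = 1e-12)
})

test_that("credible intervals are nested across levels and need a long chain", {
  d <- make_synthetic(20, 20, a = 1, b1 = 1, b2 = 1, theta = 1,
                      baseline = "exponential", par = 1, seed = 8)
  post <- quiet(egmo_ss_bayes(d$x, d$y, "exponential", egmo_prior(0, 0),
                              T = 2000, seed = 9,
                              init = list(b1 = 1, b2 = 1, a = 1, theta = 1,
                                          par = 1)))
  c90 <- cred_int(post, 0.90)
  c95 <- cred_int(post, 0.95)
  expect_lte(c95$lower, c90$lower)
  expect_gte(c95$upper, c90$upper)
  expect_error(cred_int(post, 0.99999), "too short")
})

test_that("F-distribution interval matches product-gamma Monte Carlo", {
  n <- 10; m <- 12; H1 <- 3.3; H2 <- 2.2; e1 <- 1; e2 <- 2
  ci <- cred_int_F(n, m, H1, H2, eta1 = e1, eta2 = e2, level = 0.95)
  r <- rR_posterior(1e6, n, m, H1, H2, eta1 = e1, eta2 = e2, seed = 9)
  qs <- quantile(r, c(0.025, 0.975), names = FALSE)
  expect_lt(abs(ci$lower - qs[1]), 5e-4)   # 3-decimal agreement
  expect_lt(abs(ci$upper - qs[2]), 5e-4)
  # reciprocal F symmetry: equal shapes and rates give lower = 1 - upper
  cis <- cred_int_F(20, 20, 5, 5, level = 0.9)
  expect_equal(cis$lower, 1 - cis$upper, tolerance = 1e-12)
  expect_error(cred_int_F(0, 5, 1, 1, eta1 = 0), "positive")
})

test_that("F-interval covers the true R at its nominal rate (known parameters)", {
  # When the data truly come from the assumed model and the shared
  # parameters are known, coverage of the 95% interval should be near 95%.
  truth <- list(a = 0.5, b1 = 1.5, b2 = 2.5, theta = 0.5, par = c(3.5, 1.5))
  R0 <- true_R(truth$b1, truth$b2)
  hits <- 0L; reps <- 200L
  for (i in seq_len(reps)) {
    d <- make_synthetic(25, 25, truth$a, truth$b1, truth$b2, truth$theta,
                        "weibull", truth$par, seed = 1000 + i)
    hp <- posterior_hyper(d$x, d$y, truth$a, truth$theta, "weibull", truth$par)
    ci <- cred_int_F(25, 25, hp$H1, hp$H2, level = 0.95)
    if (ci$lower <= R0 && R0 <= ci$upper) hits <- hits + 1L
  }
  # binomial 3-sigma band around 0.95 with 200 replicates
  expect_gt(hits / reps, 0.95 - 3 * sqrt(0.95 * 0.05 / reps))
})
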