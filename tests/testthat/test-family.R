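test_that("family collapses to its baseline at a = b = theta = 1", {
  xx <- c(0.05, 0.3, 1, 2.7, 8)
  expect_equal(pegmo(xx, 1, 1, 1, "exponential", par = 2),
               pexp(xx, 2), tolerance = 1e-12)
  expect_equal(degmo(xx, 1, 1, 1, "exponential", par = 2),
               dexp(xx, 2), tolerance = 1e-12)
  expect_equal(pegmo(xx, 1, 1, 1, "weibull", par = c(1.7, 0.9)),
               pweibull(xx, 1.7, 0.9), tolerance = 1e-12)
  expect_equal(qegmo(1 - exp(-1), 1, 1, 1, "exponential", par = 1), 1,
               tolerance = 1e-9)
  us <- c(0.05, 0.5, 0.95)
  expect_equal(qegmo(us, 1, 1, 1, "weibull", par = c(1.7, 0.9)),
               qweibull(us, 1.7, 0.9), tolerance = 1e-12)
})

test_that("cdf has the correct limits, monotonicity and quadrature identity", {
  ps <- list(a = 0.5, b = 2, theta = 3, par = c(1.5, 1))
  expect_lt(pegmo(1e-12, ps$a, ps$b, ps$theta, "weibull", ps$par), 1e-8)
  expect_gt(pegmo(50, ps$a, ps$b, ps$theta, "weibull", ps$par), 1 - 1e-10)
  grid <- seq(0.05, 6, length.out = 120)
  Fv <- pegmo(grid, ps$a, ps$b, ps$theta, "weibull", ps$par)
  expect_true(all(diff(Fv) >= 0))
  # F(1) equals the integral of the density over (0, 1]
  Fq <- integrate(function(t) degmo(t, ps$a, ps$b, ps$theta, "weibull", ps$par),
                  0, 1, rel.tol = 1e-10)$value
  expect_equal(pegmo(1, ps$a, ps$b, ps$theta, "weibull", ps$par), Fq,
               tolerance = 1e-7)
  # density integrates to one
  total <- integrate(function(t) degmo(t, ps$a, ps$b, ps$theta, "weibull", ps$par),
                     0, Inf, rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-6)
  expect_true(all(degmo(grid, ps$a, ps$b, ps$theta, "weibull", ps$par) >= 0))
})

test_that("density is the derivative of the cdf (finite differences)", {
  for (ps in list(list(a = 0.5, b = 2, theta = 3, bl = "weibull", par = c(1.5, 1)),
                  list(a = 2, b = 0.4, theta = 0.2, bl = "exponential", par = 1.3))) {
    for (x in c(0.4, 1, 2.2)) {
      h <- 1e-5
      fd <- (pegmo(x + h, ps$a, ps$b, ps$theta, ps$bl, ps$par) -
             pegmo(x - h, ps$a, ps$b, ps$theta, ps$bl, ps$par)) / (2 * h)
      expect_equal(degmo(x, ps$a, ps$b, ps$theta, ps$bl, ps$par), fd,
                   tolerance = 1e-6)
    }
  }
})

test_that("quantile function inverts the cdf across the unit interval", {
  cfgs <- list(list(a = 0.5, b = 2.5, theta = 0.5, bl = "weibull", par = c(3.5, 1.5)),
               list(a = 1.6, b = 0.3, theta = 12, bl = "exponential", par = 0.7))
  us <- c(1e-4, 0.01, 0.5, 0.99, 1 - 1e-4)
  for (ps in cfgs) {
    q <- qegmo(us, ps$a, ps$b, ps$theta, ps$bl, ps$par)
    expect_equal(pegmo(q, ps$a, ps$b, ps$theta, ps$bl, ps$par), us,
                 tolerance = 1e-9)
  }
  # median agrees with a bisection root of F(x) - 1/2
  ps <- cfgs[[1]]
  root <- uniroot(function(t) pegmo(t, ps$a, ps$b, ps$theta, ps$bl, ps$par) - 0.5,
                  c(1e-6, 50), tol = 1e-12)$root
  expect_equal(qegmo(0.5, ps$a, ps$b, ps$theta, ps$bl, ps$par), root,
               tolerance = 1e-9)
})

test_that("the Weibull family with shape 1 equals the exponential family", {
  xx <- c(0.1, 0.5, 1.2, 3, 7)
  expect_equal(pegmo(xx, 0.5, 2, 3, "weibull", c(1, 2)),
               pegmo(xx, 0.5, 2, 3, "exponential", 0.5), tolerance = 1e-12)
  expect_equal(degmo(xx, 0.5, 2, 3, "weibull", c(1, 2)),
               degmo(xx, 0.5, 2, 3, "exponential", 0.5), tolerance = 1e-12)
})

test_that("random generation is seed-reproducible and distributed as the cdf", {
  set.seed(11); s1 <- regmo(5, 0.5, 1.5, 0.5, "weibull", c(3.5, 1.5))
  set.seed(11); s2 <- regmo(5, 0.5, 1.5, 0.5, "weibull", c(3.5, 1.5))
  expect_identical(s1, s2)
  # baseline collapse: mean of unit exponential draws within a CLT band
  set.seed(4); s <- regmo(5000, 1, 1, 1, "exponential", 1)
  expect_lt(abs(mean(s) - 1), 3 / sqrt(5000))
  # one-sample KS against the generating cdf below the 1% critical value
  set.seed(9); s <- regmo(5000, 0.5, 1.5, 0.5, "weibull", c(3.5, 1.5))
  D <- ks_fitted(s, function(v) pegmo(v, 0.5, 1.5, 0.5, "weibull", c(3.5, 1.5)))
  expect_lt(D$statistic, 1.63 / sqrt(5000))
})

test_that("invalid arguments are rejected", {
  expect_error(pegmo(-1, 1, 1, 1, "exponential", par = 1), "positive")
  expect_error(degmo(1, -1, 1, 1, "exponential", par = 1), "'a'")
  expect_error(pegmo(1, 1, 0, 1, "exponential", par = 1), "'b'")
  expect_error(pegmo(1, 1, 1, -2, "exponential", par = 1), "'theta'")
  expect_error(qegmo(1.2, 1, 1, 1, "exponential", par = 1), "inside")
  expect_error(qegmo(0, 1, 1, 1, "exponential", par = 1), "inside")
})
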