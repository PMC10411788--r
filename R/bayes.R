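#' Independent gamma priors for the stress-strength model
#'
#' Prior specification for (b1, b2, theta, a, baseline parameters), each
#' independently Gamma with shape \code{eta} and rate \code{xi} (the
#' posterior updates Gamma(n + eta1, H1) etc. fix this convention).
#' \code{xi = eta = 0} is the improper non-informative limit.
#'
#' @param xi rate parameters: scalar (recycled) or vector ordered as
#'   (b1, b2, theta, a, baseline...).
#' @param eta shape parameters, same layout.
#' @return object of class \code{egmo_prior}.
#' @export
egmo_prior <- function(xi = 0, eta = 0) {
  if (any(xi < 0) || any(eta < 0))
    stop("prior rates and shapes must be >= 0", call. = FALSE)
  structure(list(xi = xi, eta = eta), class = "egmo_prior")
}

# recycle prior vectors to 4 + l slots: b1, b2, theta, a, lambda_k
.prior_expand <- function(prior, l) {
  k <- 4 + l
  list(xi = rep_len(prior$xi, k), eta = rep_len(prior$eta, k))
}

#' Posterior hyper-quantities H1-H4
#'
#' The data- and parameter-dependent quantities entering the gamma full
#' conditionals: \eqn{H_1 = \xi_1 - \sum_i \log\{1 - r(x_i)^a\}},
#' \eqn{H_2} symmetrically for y, \eqn{H_3 = \xi_4 - \sum\log\bar G +
#' \sum\log(1-\bar\vartheta\bar G)} over both samples, and \eqn{H_4}
#' collecting the remaining baseline-dependent log terms.
#'
#' @inheritParams ss_loglik
#' @param prior an \code{\link{egmo_prior}}.
#' @return list with \code{H1}, \code{H2}, \code{H3}, \code{H4}.
#' @export
posterior_hyper <- function(x, y, a, theta, baseline = "weibull", par,
                            prior = egmo_prior()) {
  bl <- egmo_baseline(baseline)
  pe <- .prior_expand(prior, bl$npar)
  px <- .egmo_pieces(x, a, theta, bl, par)
  py <- .egmo_pieces(y, a, theta, bl, par)
  if (any(!is.finite(px$L)) || any(!is.finite(py$L)))
    stop("degenerate data: log{1 - r^a} undefined", call. = FALSE)
  H1 <- pe$xi[1] - sum(px$L)
  H2 <- pe$xi[2] - sum(py$L)
  # -sum log Gbar = +sum z
  H3 <- pe$xi[4] + sum(px$z) + sum(py$z) + sum(px$logD) + sum(py$logD)
  H4 <- sum(bl$logpdf(x, par)) + sum(px$z) - sum(px$logD) - sum(px$L) +
        sum(bl$logpdf(y, par)) + sum(py$z) - sum(py$logD) - sum(py$L)
  list(H1 = H1, H2 = H2, H3 = H3, H4 = H4)
}

# log target for the lambda_k Metropolis step: the exact full conditional
# from the two-sample likelihood times the gamma prior. (The printed
# marginal lambda^(eta-1) exp(-xi*lambda + H4) drops the lambda-dependence
# inside b1*H1 + b2*H2 + a*H3 - by the decomposition identity
# loglik(lambda) = -b1*H1 - b2*H2 - a*H3 + H4 + const - and is divergent
# as the baseline scale shrinks, so it cannot be used as an MH target.)
.lambda_logtarget <- function(x, y, a, b1, b2, theta, bl, par, eta5, xi5) {
  if (any(par <= 0)) return(-Inf)
  px <- .egmo_pieces(x, a, theta, bl, par)
  py <- .egmo_pieces(y, a, theta, bl, par)
  pr <- sum((eta5 - 1) * log(par)) - sum(xi5 * par)
  ll <- sum(bl$logpdf(x, par)) - (a - 1) * sum(px$z) -
    (a + 1) * sum(px$logD) + (b1 - 1) * sum(px$L) +
    sum(bl$logpdf(y, par)) - (a - 1) * sum(py$z) -
    (a + 1) * sum(py$logD) + (b2 - 1) * sum(py$L)
  pr + ll
}

# exact full-conditional log densities for theta and a (mode = "exact")
.theta_logtarget <- function(x, y, a, b1, b2, theta, bl, par, eta3, xi3) {
  if (theta <= 0) return(-Inf)
  px <- .egmo_pieces(x, a, theta, bl, par)
  py <- .egmo_pieces(y, a, theta, bl, par)
  a * (length(x) + length(y)) * log(theta) -
    (a + 1) * (sum(px$logD) + sum(py$logD)) +
    (b1 - 1) * sum(px$L) + (b2 - 1) * sum(py$L) +
    (eta3 - 1) * log(theta) - xi3 * theta
}

.a_logtarget <- function(x, y, a, b1, b2, theta, bl, par, eta4, xi4) {
  if (a <= 0) return(-Inf)
  px <- .egmo_pieces(x, a, theta, bl, par)
  py <- .egmo_pieces(y, a, theta, bl, par)
  nm <- length(x) + length(y)
  nm * log(a) + a * nm * log(theta) - (a - 1) * (sum(px$z) + sum(py$z)) -
    (a + 1) * (sum(px$logD) + sum(py$logD)) +
    (b1 - 1) * sum(px$L) + (b2 - 1) * sum(py$L) +
    (eta4 - 1) * log(a) - xi4 * a
}

#' Gibbs-within-Metropolis-Hastings sampler for the stress-strength model
#'
#' Draws a Markov chain over (b1, b2, theta, a, baseline parameters) and
#' records R = b1/(b1+b2) at every sweep.
#'
#' @details In \code{mode = "paper"} the sweep cycles the printed
#' conditionals literally: b1 ~ Gamma(n+eta1, H1), b2 ~ Gamma(m+eta2, H2),
#' theta ~ Gamma(a(n+m)+eta3, xi3), a ~ Gamma(n+m+eta4, H3), and each
#' baseline parameter by a Gaussian random-walk Metropolis step on its
#' printed marginal. These conditionals drop likelihood factors that depend
#' on theta and a, so the chain is not a sampler of the exact joint
#' posterior; it is provided because published estimates were produced with
#' it. \code{mode = "exact"} replaces the theta, a and baseline updates by
#' Metropolis steps on the exact full conditionals.
#'
#' When \code{xi3 = 0} the printed theta-conditional Gamma(., 0) is
#' improper; theta is then held fixed at its initial value (the known-
#' parameter reduction) and a message is emitted. With a fully improper
#' prior (all rates and shapes 0) the printed pseudo-conditionals for a and
#' the baseline parameters are degenerate as well (the chain collapses
#' along a -> 0 with the baseline scale), so the sampler reduces to the
#' known-parameter Case II form: (theta, a, lambda) stay at their initial
#' joint-MLE values and only b1, b2 are Gibbs-sampled. Updates whose gamma
#' rate is non-positive are skipped for that sweep. Proposal scales are adapted
#' towards a 20-45 percent acceptance rate during the first
#' \code{min(T/2, 1000)} sweeps; all \code{T} draws are recorded and the
#' posterior mean uses the full chain unless \code{burnin} is set.
#'
#' @inheritParams ss_loglik
#' @param prior an \code{\link{egmo_prior}}.
#' @param T chain length (>= 100).
#' @param seed integer seed (chains are reproducible).
#' @param mode \code{"paper"} (default) or \code{"exact"}.
#' @param init optional converged \code{egmo_ss_fit} (joint method) or named
#'   list with \code{b1}, \code{b2}, \code{a}, \code{theta}, \code{par};
#'   fitted internally when missing.
#' @param burnin number of initial sweeps discarded by summaries.
#' @param prop_sd optional vector of initial random-walk proposal sds for
#'   the baseline parameters (default: 10 percent of the initial values).
#' @param starts multi-start count for the internal initial fit.
#' @param sample_baseline if FALSE the baseline parameters are held at
#'   their initial values and only (b1, b2, theta, a) are updated - the
#'   reading under which the prior specifies four (rate, shape) pairs and
#'   the baseline is treated as known, as in the fully non-informative
#'   reduction.
#' @return object of class \code{egmo_ss_post}: \code{draws} (data.frame
#'   with one row per sweep: b1, b2, theta, a, baseline..., R),
#'   \code{acceptance} rates, \code{skipped} update counts, plus the
#'   configuration.
#' @export
egmo_ss_bayes <- function(x, y, baseline = "weibull", prior = egmo_prior(),
                          T = 1000, seed = 1, mode = c("paper", "exact"),
                          init = NULL, burnin = 0, prop_sd = NULL,
                          starts = 50, sample_baseline = TRUE) {
  mode <- match.arg(mode)
  if (T < 100) stop("T must be at least 100", call. = FALSE)
  bl <- egmo_baseline(baseline)
  l <- bl$npar
  pe <- .prior_expand(prior, l)
  n <- length(x); m <- length(y)

  if (is.null(init))
    init <- fit_egmo_ss(x, y, bl, method = "joint", starts = starts,
                        seed = seed)
  if (inherits(init, "egmo_ss_fit")) {
    if (!init$converged) stop("initial fit did not converge", call. = FALSE)
    if (init$method != "joint")
      stop("init must be a joint fit (shared parameters) or a named list",
           call. = FALSE)
    init <- list(b1 = init$b1, b2 = init$b2, a = init$a,
                 theta = init$theta, par = unname(init$par))
  }
  a <- init$a; theta <- init$theta; par <- init$par
  b1 <- init$b1; b2 <- init$b2

  # Fully improper priors: the printed pseudo-conditionals for a and the
  # baseline parameters are degenerate (the chain collapses along a -> 0,
  # scale -> 0), so the only well-defined version of the printed procedure
  # is its known-parameter reduction: hold (theta, a, lambda) at the
  # initial (joint MLE) values and Gibbs-sample b1, b2 alone.
  case2 <- mode == "paper" && all(pe$xi == 0) && all(pe$eta == 0)
  if (case2)
    message("fully non-informative prior: known-parameter (Case II) ",
            "reduction; shared parameters held at their initial values")
  theta_fixed <- case2 || (mode == "paper" && pe$xi[3] == 0)
  if (theta_fixed && !case2)
    message("xi3 = 0: printed theta-conditional is improper; ",
            "theta held at its initial value")
  if (is.null(prop_sd)) prop_sd <- pmax(0.1 * abs(par), 1e-3)
  sd_th <- max(0.1 * theta, 1e-3)
  sd_a <- max(0.1 * a, 1e-3)

  warm <- min(floor(T / 2), 1000)
  batch <- 50L
  acc <- numeric(l); acc_batch <- numeric(l)
  acc_th <- acc_a <- 0; accb_th <- accb_a <- 0
  skipped <- c(b = 0L, theta = 0L, a = 0L)
  draws <- matrix(NA_real_, T, 4 + l + 1)
  colnames(draws) <- c("b1", "b2", "theta", "a", bl$par_names, "R")
  eta5 <- pe$eta[5:(4 + l)]; xi5 <- pe$xi[5:(4 + l)]

  set.seed(seed)
  for (t in seq_len(T)) {
    hp <- tryCatch(
      posterior_hyper(x, y, a, theta, bl, par, prior),
      error = function(e) NULL)
    if (!is.null(hp) && hp$H1 > 0 && hp$H2 > 0) {
      b1 <- stats::rgamma(1, shape = n + pe$eta[1], rate = hp$H1)
      b2 <- stats::rgamma(1, shape = m + pe$eta[2], rate = hp$H2)
    } else skipped["b"] <- skipped["b"] + 1L

    if (!theta_fixed) {
      if (mode == "paper") {
        theta <- stats::rgamma(1, shape = a * (n + m) + pe$eta[3],
                               rate = pe$xi[3])
      } else {
        thp <- theta + stats::rnorm(1, 0, sd_th)
        if (thp > 0) {
          lr <- .theta_logtarget(x, y, a, b1, b2, thp, bl, par,
                                 pe$eta[3], pe$xi[3]) -
                .theta_logtarget(x, y, a, b1, b2, theta, bl, par,
                                 pe$eta[3], pe$xi[3])
          if (is.finite(lr) && log(stats::runif(1)) < lr) {
            theta <- thp; acc_th <- acc_th + 1; accb_th <- accb_th + 1
          }
        }
      }
    }

    if (case2) {
      # shared parameters fixed; nothing to update
    } else if (mode == "paper") {
      hp <- tryCatch(
        posterior_hyper(x, y, a, theta, bl, par, prior),
        error = function(e) NULL)
      if (!is.null(hp) && hp$H3 > 0) {
        a <- stats::rgamma(1, shape = n + m + pe$eta[4], rate = hp$H3)
      } else skipped["a"] <- skipped["a"] + 1L
    } else {
      ap <- a + stats::rnorm(1, 0, sd_a)
      if (ap > 0) {
        lr <- .a_logtarget(x, y, ap, b1, b2, theta, bl, par,
                           pe$eta[4], pe$xi[4]) -
              .a_logtarget(x, y, a, b1, b2, theta, bl, par,
                           pe$eta[4], pe$xi[4])
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          a <- ap; acc_a <- acc_a + 1; accb_a <- accb_a + 1
        }
      }
    }

    for (k in (if (case2 || !sample_baseline) integer(0) else seq_len(l))) {
      parp <- par
      parp[k] <- par[k] + stats::rnorm(1, 0, prop_sd[k])
      if (parp[k] > 0) {
        lr <- .lambda_logtarget(x, y, a, b1, b2, theta, bl, parp,
                                eta5, xi5) -
              .lambda_logtarget(x, y, a, b1, b2, theta, bl, par,
                                eta5, xi5)
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          par <- parp
          acc[k] <- acc[k] + 1; acc_batch[k] <- acc_batch[k] + 1
        }
      }
    }

    if (t <= warm && t %% batch == 0) {
      rate <- acc_batch / batch
      prop_sd <- prop_sd * ifelse(rate > 0.45, 2, ifelse(rate < 0.2, 0.5, 1))
      acc_batch[] <- 0
      if (mode == "exact") {
        rt <- accb_th / batch; ra <- accb_a / batch
        sd_th <- sd_th * if (rt > 0.45) 2 else if (rt < 0.2) 0.5 else 1
        sd_a <- sd_a * if (ra > 0.45) 2 else if (ra < 0.2) 0.5 else 1
        accb_th <- accb_a <- 0
      }
    }
    draws[t, ] <- c(b1, b2, theta, a, par, b1 / (b1 + b2))
  }
  structure(list(
    draws = as.data.frame(draws), T = T, burnin = burnin,
    acceptance = stats::setNames(acc / T, bl$par_names),
    skipped = skipped, mode = mode, prior = prior, seed = seed,
    baseline = bl$name, n = n, m = m, theta_fixed = theta_fixed,
    case2 = case2
  ), class = "egmo_ss_post")
}

#' @export
print.egmo_ss_post <- function(x, ...) {
  cat(sprintf("EGMO posterior chain (%s mode, %s baseline): T = %d\n",
              x$mode, x$baseline, x$T))
  cat(sprintf("  Bayes estimate of R (squared-error loss): %.4f\n",
              bayes_point(x)))
  cat("  baseline-parameter MH acceptance:",
      paste(sprintf("%s %.2f", names(x$acceptance), x$acceptance),
            collapse = ", "), "\n")
  invisible(x)
}

#' Squared-error-loss Bayes estimate of R
#'
#' The posterior mean, approximated by the average of the recorded R draws
#' (after any burn-in configured on the chain).
#'
#' @param post an \code{egmo_ss_post}.
#' @return scalar estimate in (0, 1).
#' @export
bayes_point <- function(post) {
  r <- post$draws$R
  if (post$burnin > 0) r <- r[-seq_len(post$burnin)]
  mean(r)
}

#' Empirical credible interval from the R chain
#'
#' Empirical (eps/2, 1-eps/2) quantiles of the sorted R draws (R's default
#' type-7 sample quantiles).
#'
#' @param post an \code{egmo_ss_post}.
#' @param level credible level (1 - eps).
#' @return an \code{egmo_interval}.
#' @export
cred_int <- function(post, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0,1)", call. = FALSE)
  r <- post$draws$R
  if (post$burnin > 0) r <- r[-seq_len(post$burnin)]
  if (length(r) * (1 - level) / 2 < 1)
    stop("chain too short for this level", call. = FALSE)
  qs <- stats::quantile(sort(r), c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(list(lower = qs[1], upper = qs[2], level = level,
                 method = "credible-empirical"),
            class = "egmo_interval")
}

#' F-distribution credible interval for R (known shared parameters)
#'
#' With shared parameters known, 2 H1 b1 ~ chi-squared(2(n+eta1)) and
#' 2 H2 b2 ~ chi-squared(2(m+eta2)) a posteriori, so
#' \eqn{R = [1 + (b_2/b_1)]^{-1}} has the closed-form interval
#' \deqn{\Big[\big(1 + \kappa F_{1-\epsilon/2}\big)^{-1},\;
#'       \big(1 + \kappa F_{\epsilon/2}\big)^{-1}\Big],\quad
#'   \kappa = \frac{(m+\eta_2)H_1}{(n+\eta_1)H_2},}
#' with F quantiles on (2(m+eta2), 2(n+eta1)) degrees of freedom.
#'
#' @param n,m sample sizes.
#' @param H1,H2 posterior rates (see \code{\link{posterior_hyper}}).
#' @param eta1,eta2 prior shapes for b1, b2.
#' @param level credible level (1 - eps).
#' @return an \code{egmo_interval}.
#' @export
cred_int_F <- function(n, m, H1, H2, eta1 = 0, eta2 = 0, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0,1)", call. = FALSE)
  if (n + eta1 <= 0 || m + eta2 <= 0)
    stop("posterior shapes must be positive", call. = FALSE)
  if (H1 <= 0 || H2 <= 0) stop("H1, H2 must be positive", call. = FALSE)
  kap <- (m + eta2) * H1 / ((n + eta1) * H2)
  eps <- 1 - level
  ends <- sort(1 / (1 + kap * stats::qf(c(1 - eps / 2, eps / 2),
                                        2 * (m + eta2), 2 * (n + eta1))))
  structure(list(lower = ends[1], upper = ends[2], level = level,
                 method = "credible-F"), class = "egmo_interval")
}

#' Draws of R from the product-gamma posterior (known shared parameters)
#'
#' Convenience generator for the known-parameter reduction: b1 ~
#' Gamma(n+eta1, H1), b2 ~ Gamma(m+eta2, H2) independently, returning
#' R = b1/(b1+b2).
#'
#' @param T number of draws.
#' @inheritParams cred_int_F
#' @param seed integer seed.
#' @return numeric vector of T draws.
#' @export
rR_posterior <- function(T, n, m, H1, H2, eta1 = 0, eta2 = 0, seed = 1) {
  set.seed(seed)
  b1 <- stats::rgamma(T, shape = n + eta1, rate = H1)
  b2 <- stats::rgamma(T, shape = m + eta2, rate = H2)
  b1 / (b1 + b2)
}

#' Gauss hypergeometric function 2F1 (series evaluation)
#'
#' Log-scale evaluation of \eqn{{}_2F_1(A, B; C; z)} by its power series,
#' valid for \eqn{0 \le z < 1} with positive parameters (the only regime the
#' closed-form Bayes estimator needs after the Pfaff transformation).
#'
#' @param A,B,C parameters (positive).
#' @param z argument in [0, 1).
#' @param log return the logarithm.
#' @param tol,maxit series control.
#' @return the (log) function value.
#' @export
hyp2f1 <- function(A, B, C, z, log = FALSE, tol = 1e-13, maxit = 100000L) {
  if (z < 0 || z >= 1) stop("series requires 0 <= z < 1", call. = FALSE)
  if (z == 0) return(if (log) 0 else 1)
  lterm <- 0            # log of current term (k = 0)
  lsum <- 0
  for (k in 0:(maxit - 1)) {
    lratio <- base::log(A + k) + base::log(B + k) -
      base::log(C + k) - base::log(k + 1) + base::log(z)
    lterm <- lterm + lratio
    lsum <- lsum + log1p(exp(lterm - lsum))
    # stop once terms are decreasing and negligible relative to the sum
    if (lratio < 0 && lterm - lsum < base::log(tol)) {
      return(if (log) lsum else exp(lsum))
    }
  }
  stop("2F1 series did not converge", call. = FALSE)
}

# posterior mean of b1/(b1+b2), b1 ~ Gamma(a1, rate h1), b2 ~ Gamma(a2, h2)
# via 2F1 with psi = 1 - h1/h2; quadrature fallback on numerical failure
.gamma_ratio_mean <- function(a1, h1, a2, h2) {
  psi <- 1 - h1 / h2
  cc <- a1 + a2
  val <- tryCatch({
    if (abs(psi) < 1e-12) {
      a1 / cc
    } else if (psi > 0) {
      exp(a1 * log1p(-psi) + base::log(a1 / cc) +
            hyp2f1(cc, a1 + 1, cc + 1, psi, log = TRUE))
    } else {
      # Pfaff: 2F1(c, a1+1; c+1; psi) = (1-psi)^(-a2) 2F1(c, a2; c+1; psi/(psi-1))
      exp(base::log(a1 / cc) - a2 * log1p(-psi) +
            hyp2f1(cc, a2, cc + 1, psi / (psi - 1), log = TRUE))
    }
  }, error = function(e) NA_real_)
  if (!is.na(val) && val > 0 && val < 1) return(val)
  message("2F1 evaluation failed; falling back to quadrature")
  num <- stats::integrate(function(w)
    exp((a1) * base::log(w) + (a2 - 1) * log1p(-w) - cc * log1p(-psi * w)),
    0, 1, rel.tol = 1e-10)$value
  den <- stats::integrate(function(w)
    exp((a1 - 1) * base::log(w) + (a2 - 1) * log1p(-w) - cc * log1p(-psi * w)),
    0, 1, rel.tol = 1e-10)$value
  num / den
}

#' Closed-form Bayes estimate of R with known shared parameters
#'
#' With (a, theta, baseline) known, the posteriors of b1 and b2 are
#' independent gammas and the posterior mean of R = b1/(b1+b2) has a closed
#' form in the Gauss hypergeometric function:
#' \deqn{\hat R_B = (1-\psi)^{n+\eta_1}\frac{n+\eta_1}{c}\,
#'   {}_2F_1(c,\, n+\eta_1+1;\, c+1;\, \psi),}
#' with \eqn{c = n+\eta_1+m+\eta_2} and \eqn{\psi = 1 - H_1/H_2}; for
#' \eqn{\psi < 0} the Pfaff transformation maps the series into the unit
#' interval. Falls back to adaptive quadrature if the series fails.
#'
#' @inheritParams posterior_hyper
#' @return scalar posterior mean of R.
#' @export
bayes_closed_form <- function(x, y, a, theta, baseline = "weibull", par,
                              prior = egmo_prior()) {
  bl <- egmo_baseline(baseline)
  pe <- .prior_expand(prior, bl$npar)
  hp <- posterior_hyper(x, y, a, theta, bl, par, prior)
  if (hp$H1 <= 0 || hp$H2 <= 0) stop("H1, H2 must be positive", call. = FALSE)
  .gamma_ratio_mean(length(x) + pe$eta[1], hp$H1,
                    length(y) + pe$eta[2], hp$H2)
}
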