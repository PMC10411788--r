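#' @title The exponentiated generalized Marshall-Olkin (EGMO-G) family
#'
#' @description Density, distribution function, quantile function and random
#' generation for the EGMO-G distribution with cdf
#' \deqn{F(x) = \{1 - [\vartheta \bar G(x) / (1 - \bar\vartheta \bar G(x))]^a\}^b,}
#' where \eqn{\bar G} is the baseline survival function,
#' \eqn{\bar\vartheta = 1 - \vartheta}, and \eqn{a, b, \vartheta > 0}.
#' \eqn{a = b = \vartheta = 1} recovers the baseline distribution; values of
#' \eqn{\vartheta} above 1 (tilting mass to the right) are allowed, in which
#' case \eqn{\bar\vartheta < 0} and the denominator \eqn{1-\bar\vartheta\bar G}
#' exceeds 1.
#'
#' All computation is carried out on the log scale: the Marshall-Olkin
#' denominator is evaluated as \eqn{G + \vartheta\bar G} (a sum of
#' non-negative terms for every \eqn{\vartheta > 0}), and
#' \eqn{\log\{1 - r^a\}} uses \code{expm1}/series guards so that exponents
#' \eqn{b - 1 < 0} remain stable when \eqn{r \to 1}.
#'
#' @param x vector of positive quantiles.
#' @param p vector of probabilities in (0,1).
#' @param n number of draws.
#' @param a,b,theta EGMO shape parameters, all positive.
#' @param baseline baseline name or \code{\link{egmo_baseline}} object.
#' @param par baseline parameter vector (Weibull: shape, scale;
#'   exponential: rate).
#' @param log,log.p logical; return log densities / log probabilities.
#' @param lower.tail logical; if FALSE, probabilities are P(X > x).
#'
#' @return \code{degmo} the density, \code{pegmo} the cdf, \code{qegmo} the
#'   quantile function, \code{regmo} a vector of draws.
#' @name egmo
NULL

.egmo_check <- function(a, b, theta, par) {
  if (!is.finite(a) || a <= 0) stop("'a' must be a positive real", call. = FALSE)
  if (!is.finite(b) || b <= 0) stop("'b' must be a positive real", call. = FALSE)
  if (!is.finite(theta) || theta <= 0) stop("'theta' must be a positive real", call. = FALSE)
  if (any(!is.finite(par)) || any(par <= 0)) stop("baseline parameters must be positive", call. = FALSE)
  invisible(TRUE)
}

# log(1 - exp(al)) for al < 0, with the canonical log(2) crossover:
# above it expm1 keeps the cancellation accurate, below it exp(al) is
# already exact relative to 1. The deep tail returns -exp(al) directly so
# the result stays a nonzero negative number down to al ~ -745 (callers
# test its sign to detect support-boundary degeneracy).
.log1mexp <- function(al) {
  out <- al
  hi <- al > -0.6931472
  mid <- !hi & al > -37
  out[hi] <- log(-expm1(al[hi]))
  out[mid] <- log1p(-exp(al[mid]))
  out[!hi & !mid] <- -exp(al[!hi & !mid])
  out
}

# shared building blocks: z = baseline cumulative hazard, L = log{1 - r^a}
.egmo_pieces <- function(x, a, theta, bl, par) {
  z <- pmax(bl$cumhaz(x, par), 1e-300)
  S <- exp(-z)
  G <- -expm1(-z)
  D <- G + theta * S                   # = 1 - (1-theta) * Gbar, always > 0
  # r = theta*S/D = 1 - G/D; log1p keeps precision when G/D -> 0 (r -> 1)
  logr <- log1p(-G / D)
  list(z = z, S = S, G = G, D = D, logD = log(D), logr = logr,
       L = .log1mexp(pmin(a * logr, -1e-320)))
}

#' @rdname egmo
#' @export
degmo <- function(x, a, b, theta, baseline = "weibull", par, log = FALSE) {
  bl <- egmo_baseline(baseline)
  .egmo_check(a, b, theta, par)
  if (any(x <= 0)) stop("'x' must be positive", call. = FALSE)
  pc <- .egmo_pieces(x, a, theta, bl, par)
  ld <- base::log(a) + base::log(b) + a * base::log(theta) +
    bl$logpdf(x, par) - (a - 1) * pc$z - (a + 1) * pc$logD + (b - 1) * pc$L
  if (log) ld else exp(ld)
}

#' @rdname egmo
#' @export
pegmo <- function(x, a, b, theta, baseline = "weibull", par,
                  lower.tail = TRUE, log.p = FALSE) {
  bl <- egmo_baseline(baseline)
  .egmo_check(a, b, theta, par)
  if (any(x <= 0)) stop("'x' must be positive", call. = FALSE)
  pc <- .egmo_pieces(x, a, theta, bl, par)
  logF <- b * pc$L
  if (lower.tail) {
    if (log.p) logF else exp(logF)
  } else {
    lf <- .log1mexp(pmin(logF, -1e-300))
    if (log.p) lf else exp(lf)
  }
}

#' @rdname egmo
#' @details The quantile function inverts the cdf in closed form: with
#' \eqn{t = (1 - u^{1/b})^{1/a}} the baseline survival target is
#' \eqn{\bar G^* = t / (\vartheta + \bar\vartheta t)} and
#' \eqn{Q(u) = Q_G(1 - \bar G^*)}.
#' @export
qegmo <- function(p, a, b, theta, baseline = "weibull", par) {
  bl <- egmo_baseline(baseline)
  .egmo_check(a, b, theta, par)
  if (any(p <= 0 | p >= 1)) stop("'p' must be inside (0, 1)", call. = FALSE)
  # t = (1 - p^(1/b))^(1/a) and 1 - t, each on its stable path
  w <- .log1mexp(log(p) / b) / a
  t <- exp(w)
  omt <- -expm1(w)                       # 1 - t, no cancellation
  den <- t + theta * omt                 # = theta + (1-theta)t, positive sum
  sf_target <- t / den
  cdf_target <- theta * omt / den        # = 1 - sf_target, stable
  # invert through whichever baseline tail retains relative precision
  ifelse(sf_target < 0.5,
         bl$quantile_sf(sf_target, par),
         bl$quantile(cdf_target, par))
}

#' @rdname egmo
#' @export
regmo <- function(n, a, b, theta, baseline = "weibull", par) {
  qegmo(stats::runif(n), a, b, theta, baseline = baseline, par = par)
}
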