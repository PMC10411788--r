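#' Baseline distributions for the EGMO-G construction
#'
#' The EGMO-G family is built on top of a parent ("baseline") distribution G
#' with density g, survival function Gbar = 1 - G and quantile function.
#' A baseline is represented as a list of vectorised closures over a named
#' parameter vector, so that new baselines can be plugged in by the user.
#'
#' Built-in baselines:
#' \describe{
#'   \item{\code{"weibull"}}{parameters \code{c(shape, scale)} (gamma, beta);
#'     survival \eqn{\exp\{-(x/\beta)^\gamma\}}.}
#'   \item{\code{"exponential"}}{parameter \code{c(rate)} (lambda); survival
#'     \eqn{\exp(-\lambda x)}.}
#' }
#'
#' @param name baseline name, one of \code{"weibull"}, \code{"exponential"},
#'   or a \code{egmo_baseline} object which is returned unchanged.
#' @return an object of class \code{egmo_baseline}: a list with elements
#'   \code{name}, \code{par_names}, \code{npar}, and functions
#'   \code{logpdf(x, par)}, \code{cdf(x, par)}, \code{sf(x, par)} (survival),
#'   \code{cumhaz(x, par)} (-log survival), \code{quantile(p, par)} and its survival-scale companion
#'   \code{quantile_sf(s, par)},
#'   \code{dsf(x, par)} (n x npar matrix of partial derivatives of the
#'   survival function w.r.t. the parameters) and \code{dlogpdf(x, par)}
#'   (n x npar matrix of partials of log g), plus \code{start_box(x)} giving
#'   data-adaptive multi-start bounds on the log-parameter scale.
#' @export
egmo_baseline <- function(name) {
  if (inherits(name, "egmo_baseline")) return(name)
  name <- match.arg(name, c("weibull", "exponential"))
  b <- switch(name,
    weibull = list(
      name = "weibull",
      par_names = c("shape", "scale"),
      npar = 2L,
      # explicit form: dweibull()'s C code emits NaN warnings at the extreme
      # shape/scale combinations a box-constrained optimizer visits
      logpdf = function(x, par) {
        lr <- log(x / par[2])
        ld <- log(par[1] / par[2]) + (par[1] - 1) * lr - exp(par[1] * lr)
        ld[!is.finite(ld)] <- -Inf
        ld
      },
      cdf = function(x, par) stats::pweibull(x, par[1], par[2]),
      sf = function(x, par) stats::pweibull(x, par[1], par[2], lower.tail = FALSE),
      cumhaz = function(x, par) (x / par[2])^par[1],
      quantile = function(p, par) stats::qweibull(p, par[1], par[2]),
      quantile_sf = function(s, par)
        stats::qweibull(s, par[1], par[2], lower.tail = FALSE),
      dsf = function(x, par) {
        z <- (x / par[2])^par[1]
        S <- exp(-z)
        cbind(shape = -S * z * log(x / par[2]),
              scale = S * z * par[1] / par[2])
      },
      dlogpdf = function(x, par) {
        z <- (x / par[2])^par[1]
        cbind(shape = 1 / par[1] + (1 - z) * log(x / par[2]),
              scale = (par[1] / par[2]) * (z - 1))
      },
      start_box = function(x) {
        q <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
        rbind(shape = log(c(1e-2, 1e2)),
              scale = log(c(q[1] / 3, q[2] * 3)))
      }
    ),
    exponential = list(
      name = "exponential",
      par_names = "rate",
      npar = 1L,
      logpdf = function(x, par) stats::dexp(x, par[1], log = TRUE),
      cdf = function(x, par) stats::pexp(x, par[1]),
      sf = function(x, par) stats::pexp(x, par[1], lower.tail = FALSE),
      cumhaz = function(x, par) par[1] * x,
      quantile = function(p, par) stats::qexp(p, par[1]),
      quantile_sf = function(s, par)
        stats::qexp(s, par[1], lower.tail = FALSE),
      dsf = function(x, par) cbind(rate = -x * exp(-par[1] * x)),
      dlogpdf = function(x, par) cbind(rate = 1 / par[1] - x),
      start_box = function(x) rbind(rate = log(c(1e-2, 1e2) / mean(x)))
    )
  )
  structure(b, class = "egmo_baseline")
}

#' @export
print.egmo_baseline <- function(x, ...) {
  cat("EGMO baseline:", x$name, "- parameters:",
      paste(x$par_names, collapse = ", "), "\n")
  invisible(x)
}
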