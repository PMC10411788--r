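#' Delta-method asymptotic confidence interval for R
#'
#' Computes the large-sample interval
#' \deqn{\hat R \pm z_{1-\delta/2}\,
#'   \frac{\hat b_1 \hat b_2}{(\hat b_1+\hat b_2)^2}\sqrt{1/n + 1/m},}
#' clipped to [0, 1].
#'
#' @param fit an \code{egmo_ss_fit} (either method), or a list with elements
#'   \code{b1}, \code{b2}, \code{n}, \code{m}.
#' @param level confidence level (1 - delta).
#' @return an \code{egmo_interval}: list with \code{lower}, \code{upper},
#'   \code{level}, \code{method}, and \code{clipped} flag.
#' @export
ci_asymp <- function(fit, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0,1)", call. = FALSE)
  b1 <- fit$b1; b2 <- fit$b2
  R <- b1 / (b1 + b2)
  half <- stats::qnorm(1 - (1 - level) / 2) * (b1 * b2 / (b1 + b2)^2) *
    sqrt(1 / fit$n + 1 / fit$m)
  raw <- c(R - half, R + half)
  structure(list(lower = max(0, raw[1]), upper = min(1, raw[2]),
                 level = level, method = "asymptotic",
                 clipped = raw[1] < 0 || raw[2] > 1),
            class = "egmo_interval")
}

#' Percentile bootstrap confidence interval for R
#'
#' Resamples x and y independently with replacement B times, refits the
#' model (warm-started from the full-data estimate) and returns the
#' empirical (delta/2, 1-delta/2) percentiles of the bootstrap
#' \eqn{\hat R^*} values. Resamples whose refit fails are redrawn; an
#' error is raised if more than 20 percent fail.
#'
#' @inheritParams fit_egmo_ss
#' @param B number of bootstrap resamples (>= 100).
#' @param level confidence level.
#' @param fit optional pre-computed full-data \code{egmo_ss_fit} used as
#'   warm start; fitted internally when missing.
#' @return an \code{egmo_interval} with the bootstrap \code{R_star} draws
#'   attached.
#' @export
ci_boot <- function(x, y, baseline = "weibull", B = 1000, level = 0.95,
                    seed = 1, method = c("joint", "plugin"), fit = NULL,
                    starts = 50) {
  method <- match.arg(method)
  if (B < 100) stop("B must be at least 100", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0,1)", call. = FALSE)
  bl <- egmo_baseline(baseline)
  if (is.null(fit))
    fit <- fit_egmo_ss(x, y, bl, method = method, starts = starts, seed = seed)
  if (!fit$converged) stop("full-data fit did not converge", call. = FALSE)
  warm <- .warm_point(fit, bl)
  set.seed(seed)
  Rs <- numeric(B)
  fails <- 0L
  i <- 1L
  while (i <= B) {
    xb <- sample(x, replace = TRUE)
    yb <- sample(y, replace = TRUE)
    r <- tryCatch(.refit_R(xb, yb, bl, method, warm), error = function(e) NA_real_)
    if (is.na(r)) {
      fails <- fails + 1L
      if (fails > 0.2 * B)
        stop("more than 20% of bootstrap refits failed", call. = FALSE)
      next
    }
    Rs[i] <- r
    i <- i + 1L
  }
  qs <- stats::quantile(sort(Rs), c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(list(lower = qs[1], upper = qs[2], level = level,
                 method = "bootstrap", B = B, n_failed = fails,
                 R_star = Rs, seed = seed),
            class = "egmo_interval")
}

.warm_point <- function(fit, bl) {
  if (fit$method == "joint") {
    list(joint = log(c(fit$a, fit$theta, fit$par)))
  } else {
    list(x = log(c(fit$fit_x$estimate[c("a", "theta")],
                   fit$fit_x$estimate[bl$par_names])),
         y = log(c(fit$fit_y$estimate[c("a", "theta")],
                   fit$fit_y$estimate[bl$par_names])))
  }
}

# single local refit from the warm start (bootstrap workhorse)
.refit_R <- function(x, y, bl, method, warm) {
  n <- length(x); m <- length(y)
  if (method == "joint") {
    objfn <- function(p) {
      a <- exp(p[1]); th <- exp(p[2]); par <- exp(p[-(1:2)])
      SLx <- sum(.egmo_pieces(x, a, th, bl, par)$L)
      SLy <- sum(.egmo_pieces(y, a, th, bl, par)$L)
      if (!is.finite(SLx) || !is.finite(SLy) || SLx >= 0 || SLy >= 0) return(1e10)
      b1 <- min(max(-n / SLx, 1e-2), 1e2); b2 <- min(max(-m / SLy, 1e-2), 1e2)
      v <- ss_loglik(x, y, b1, b2, a, th, bl, par)
      if (!is.finite(v)) 1e10 else -v
    }
    box <- rbind(.SHAPE_BOX, .SHAPE_BOX, bl$start_box(c(x, y)))
    o <- stats::optim(pmin(pmax(warm$joint, box[, 1]), box[, 2]), objfn,
                      method = "L-BFGS-B", lower = box[, 1], upper = box[, 2],
                      control = list(maxit = 500))
    a <- exp(o$par[1]); th <- exp(o$par[2]); par <- exp(o$par[-(1:2)])
    bb <- profile_b(x, y, a, th, bl, par)
    b1 <- min(max(bb[[1]], 1e-2), 1e2); b2 <- min(max(bb[[2]], 1e-2), 1e2)
    b1 / (b1 + b2)
  } else {
    bfor <- function(s, w) {
      objfn <- function(p) {
        a <- exp(p[1]); th <- exp(p[2]); par <- exp(p[-(1:2)])
        SL <- sum(.egmo_pieces(s, a, th, bl, par)$L)
        if (!is.finite(SL) || SL >= 0) return(1e10)
        b <- min(max(-length(s) / SL, 1e-2), 1e2)
        v <- sum(degmo(s, a, b, th, bl, par, log = TRUE))
        if (!is.finite(v)) 1e10 else -v
      }
      box <- rbind(.SHAPE_BOX, .SHAPE_BOX, bl$start_box(s))
      o <- stats::optim(pmin(pmax(w, box[, 1]), box[, 2]), objfn,
                        method = "L-BFGS-B", lower = box[, 1],
                        upper = box[, 2], control = list(maxit = 500))
      a <- exp(o$par[1]); th <- exp(o$par[2]); par <- exp(o$par[-(1:2)])
      SL <- sum(.egmo_pieces(s, a, th, bl, par)$L)
      min(max(-length(s) / SL, 1e-2), 1e2)
    }
    b1 <- bfor(x, warm$x); b2 <- bfor(y, warm$y)
    b1 / (b1 + b2)
  }
}

#' @export
print.egmo_interval <- function(x, ...) {
  cat(sprintf("%d%% %s interval for R: [%.4f, %.4f]\n",
              round(100 * x$level), x$method, x$lower, x$upper))
  invisible(x)
}
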