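#' Kolmogorov-Smirnov statistic against a fitted cdf
#'
#' Computes \eqn{D = \sup_x |F_n(x) - \hat F(x)|} at the order statistics,
#' evaluating both one-sided jumps of the empirical cdf (ties contribute
#' through cumulative counts, as in the usual step ecdf). The p-value uses
#' the asymptotic Kolmogorov distribution,
#' \eqn{P(\sqrt n D > t) = 2\sum_{k\ge1} (-1)^{k-1} e^{-2k^2t^2}},
#' with the estimated parameters plugged in (no small-sample or
#' estimation-effect correction).
#'
#' @param x numeric sample.
#' @param cdf vectorised fitted cdf.
#' @return list with \code{statistic} and \code{p.value}.
#' @export
ks_fitted <- function(x, cdf) {
  if (!length(x)) stop("empty sample", call. = FALSE)
  n <- length(x)
  xs <- sort(x)
  Fv <- cdf(xs)
  D <- max(abs(seq_len(n) / n - Fv), abs((seq_len(n) - 1) / n - Fv))
  t <- sqrt(n) * D
  k <- seq_len(101)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  list(statistic = D, p.value = min(1, max(0, p)))
}

#' Compare the EGMO family against its nested sub-models on one sample
#'
#' Fits every requested sub-model by multi-start maximum likelihood and
#' tabulates log-likelihood, AIC, BIC, and the Kolmogorov-Smirnov statistic
#' with its (naive asymptotic) p-value, sorted by AIC.
#'
#' @param x positive sample.
#' @param family baseline family, \code{"weibull"} or \code{"exponential"}.
#' @param models character vector of model names; defaults to the full
#'   hierarchy for the chosen family.
#' @param starts,seed multi-start configuration passed to
#'   \code{\link{fit_egmo_model}}.
#' @return a data.frame of class \code{egmo_gof_table} (one row per model,
#'   AIC-sorted, minimum flagged) with the fitted \code{egmo_fit} objects in
#'   \code{attr(, "fits")}.
#' @export
egmo_compare <- function(x, family = c("weibull", "exponential"),
                         models = NULL, starts = 50, seed = 1) {
  family <- match.arg(family)
  suf <- toupper(substr(family, 1, 1))
  if (is.null(models))
    models <- paste0(c("EGMO-", "EG-", "GMO-", "EMO-", "G-", "MO-", ""), suf)
  fits <- lapply(models, function(mm) {
    tryCatch(fit_egmo_model(x, mm, starts = starts, seed = seed),
             error = function(e) structure(list(model = mm, converged = FALSE,
                                                error = conditionMessage(e)),
                                           class = "egmo_fit"))
  })
  ok <- vapply(fits, `[[`, TRUE, "converged")
  tab <- data.frame(
    model = models,
    k = vapply(fits, function(f) if (f$converged) length(f$estimate) else NA_integer_, 0L),
    loglik = vapply(fits, function(f) if (f$converged) f$loglik else NA_real_, 0),
    aic = vapply(fits, function(f) if (f$converged) f$aic else NA_real_, 0),
    bic = vapply(fits, function(f) if (f$converged) f$bic else NA_real_, 0),
    ks = vapply(fits, function(f) if (f$converged) f$ks else NA_real_, 0),
    ks_p = vapply(fits, function(f) if (f$converged) f$ks_p else NA_real_, 0),
    boundary = vapply(fits, function(f) isTRUE(f$boundary), TRUE),
    converged = ok
  )
  ord <- order(tab$aic)
  tab <- tab[ord, ]
  tab$best_aic <- FALSE
  if (any(ok)) tab$best_aic[which.min(tab$aic)] <- TRUE
  rownames(tab) <- NULL
  attr(tab, "fits") <- stats::setNames(fits[ord], tab$model)
  class(tab) <- c("egmo_gof_table", "data.frame")
  tab
}

#' @export
print.egmo_gof_table <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  df$ks <- round(df$ks, digits); df$ks_p <- round(df$ks_p, digits)
  df$loglik <- round(df$loglik, 3); df$aic <- round(df$aic, 3)
  df$bic <- round(df$bic, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Death and recovery rates from epidemic count series
#'
#' Elementwise rates \code{deaths/confirmed} and \code{recovered/confirmed}.
#'
#' @param confirmed,recovered,deaths equal-length count vectors;
#'   \code{confirmed} must be positive.
#' @return data.frame with columns \code{death_rate} and
#'   \code{recovery_rate}.
#' @export
compute_rates <- function(confirmed, recovered, deaths) {
  if (length(unique(c(length(confirmed), length(recovered), length(deaths)))) != 1)
    stop("count vectors must have equal length", call. = FALSE)
  if (any(confirmed <= 0))
    stop("confirmed counts must be positive", call. = FALSE)
  data.frame(death_rate = deaths / confirmed,
             recovery_rate = recovered / confirmed)
}
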