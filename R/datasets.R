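#' Packaged application datasets
#'
#' Verbatim copies of the two application datasets, shipped as plain CSV
#' under \code{inst/extdata} so that every analysis is reproducible offline:
#' \describe{
#'   \item{\code{"fiber_20mm"} (alias \code{"fiber_1"})}{breaking strengths
#'     of 69 single carbon fibres at 20 mm gauge length.}
#'   \item{\code{"fiber_10mm"} (alias \code{"fiber_2"})}{breaking strengths
#'     of 63 single carbon fibres at 10 mm gauge length.}
#'   \item{\code{"covid_saudi"} (alias \code{"covid"})}{45 daily rows of
#'     (confirmed, recovered, deaths) COVID-19 counts for Saudi Arabia,
#'     1 April - 15 May 2020, with the derived \code{death_rate} and
#'     \code{recovery_rate} columns appended (see
#'     \code{\link{compute_rates}}).}
#' }
#' The derived series are also loadable directly as single samples under
#' the names \code{"covid_death_rate"} and \code{"covid_recovery_rate"}
#' (useful from the command line).
#'
#' @param name dataset name or alias (case-insensitive).
#' @return a numeric vector for the fibre datasets; a data.frame for the
#'   COVID table.
#' @export
egmo_data <- function(name) {
  key <- switch(tolower(name),
    fiber_20mm = , fiber_1 = "fiber_20mm",
    fiber_10mm = , fiber_2 = "fiber_10mm",
    covid_saudi = , covid = "covid_saudi",
    covid_death_rate = , covid_recovery_rate = "covid_saudi",
    stop("unknown dataset '", name, "'", call. = FALSE))
  path <- system.file("extdata", paste0(key, ".csv"), package = "egmoss",
                      mustWork = TRUE)
  df <- utils::read.csv(path)
  if (key == "covid_saudi") {
    tab <- cbind(df, compute_rates(df$confirmed, df$recovered, df$deaths))
    switch(tolower(name),
           covid_death_rate = tab$death_rate,
           covid_recovery_rate = tab$recovery_rate,
           tab)
  } else {
    df$strength
  }
}

#' Generate a synthetic stress-strength dataset with known truth
#'
#' Draws a stress sample of size n from EGMO-G(a, b1, theta, baseline) and an
#' independent strength sample of size m from EGMO-G(a, b2, theta, baseline)
#' by inversion, together with the true reliability
#' \eqn{R = b_1/(b_1+b_2)}.
#'
#' @param n,m sample sizes.
#' @param a,b1,b2,theta EGMO parameters (a, theta shared between samples).
#' @param baseline,par baseline specification.
#' @param seed integer seed.
#' @return list with \code{x}, \code{y}, \code{true_R} and the generating
#'   parameters.
#' @export
make_synthetic <- function(n, m, a, b1, b2, theta, baseline = "weibull",
                           par, seed = 1) {
  set.seed(seed)
  x <- regmo(n, a, b1, theta, baseline, par)
  y <- regmo(m, a, b2, theta, baseline, par)
  list(x = x, y = y, true_R = true_R(b1, b2),
       params = list(a = a, b1 = b1, b2 = b2, theta = theta,
                     baseline = baseline, par = par, seed = seed))
}

#' Read a single-column numeric sample from CSV or whitespace text
#'
#' Accepts either a one-column CSV (with or without header) or a plain
#' whitespace/newline-separated list of numbers.
#'
#' @param path file path.
#' @return numeric vector.
#' @export
read_sample <- function(path) {
  first <- readLines(path, n = 1)
  tok1 <- strsplit(trimws(first), "[,[:space:]]+")[[1]][1]
  has_header <- suppressWarnings(is.na(as.numeric(tok1)))
  vals <- if (grepl(",", first)) {
    utils::read.csv(path, header = has_header)[[1]]
  } else {
    scan(path, what = numeric(), quiet = TRUE, skip = as.integer(has_header))
  }
  v <- as.numeric(vals)
  if (any(!is.finite(v))) stop("non-numeric values in ", path, call. = FALSE)
  v
}
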