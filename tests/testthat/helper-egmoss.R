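# shared fixtures and a lazy cache so expensive fits are computed once
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}
quiet <- function(expr) suppressMessages(expr)

fiber1 <- egmo_data("fiber_1")
fiber2 <- egmo_data("fiber_2")
covid <- egmo_data("covid")

fiber_plugin <- function() cached("fiber_plugin",
  fit_egmo_ss(fiber1, fiber2, "weibull", method = "plugin"))
fiber_joint <- function() cached("fiber_joint",
  fit_egmo_ss(fiber1, fiber2, "weibull", method = "joint"))
covid_plugin <- function() cached("covid_plugin",
  fit_egmo_ss(covid$death_rate, covid$recovery_rate, "exponential",
              method = "plugin"))
covid_joint <- function() cached("covid_joint",
  fit_egmo_ss(covid$death_rate, covid$recovery_rate, "exponential",
              method = "joint"))
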