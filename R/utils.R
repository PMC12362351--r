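#' @keywords internal
logit <- function(p) log(p / (1 - p))

#' @keywords internal
inv_logit <- function(x) 1 / (1 + exp(-x))

# trapezoidal rule on an irregular grid
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# linear-interpolation quantiles (type 7): the convention used for all
# cohort band summaries in this package
#' @keywords internal
band_quantiles <- function(x, probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE, na.rm = TRUE)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic per-stage seed derivation from one master seed; keeps
# derived seeds in 32-bit integer range
#' @keywords internal
derive_seed <- function(seed, stage) {
  offsets <- c(generate = 101L, fit = 211L, vpop = 307L,
               sensitivity = 401L, classify = 503L, noise = 601L,
               draw = 701L, restart = 809L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483587)
}
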