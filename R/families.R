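# Candidate decline-model families. Every family is parameterised so that
# A is the value at day 0 and k > 0 means functional decline; the Weibull
# adds a shape b and collapses to the exponential at b = 1.

.FAMILIES <- c("linear", "exponential", "harmonic", "weibull")
.FAMILY_CODE <- c(linear = 0L, exponential = 1L, harmonic = 2L, weibull = 3L)

.family_code <- function(family) {
  family <- match.arg(family, .FAMILIES)
  .FAMILY_CODE[[family]]
}

#' Candidate trajectory model families
#'
#' The four parametric decline models used for longitudinal clinical
#' variables, all sharing the interpretation `A` = baseline value at day 0
#' and `k` = rate of disease progression (per day):
#'
#' * linear: `A - k * t`
#' * exponential: `A * exp(-k * t)`
#' * harmonic: `A / (1 + k * t)`
#' * weibull: `A * exp(-(k * t)^b)`, shape `b`; equals the exponential
#'   when `b = 1`.
#'
#' @return Character vector of family names.
#' @export
trajectory_families <- function() .FAMILIES

#' Number of curve parameters of a model family
#'
#' @param family One of [trajectory_families()].
#' @return 2 for linear/exponential/harmonic, 3 for weibull.
#' @export
family_arity <- function(family) {
  family <- match.arg(family, .FAMILIES)
  if (family == "weibull") 3L else 2L
}

#' Evaluate a trajectory model
#'
#' @param family One of [trajectory_families()].
#' @param A Baseline value at day 0.
#' @param k Progression rate per day.
#' @param b Weibull shape (ignored for other families; default 1).
#' @param t Days since trial start (vector, `t >= 0`).
#' @return Model values at `t`.
#' @examples
#' model_value("exponential", A = 40, k = 0.004, t = c(0, 173))
#' @export
model_value <- function(family, A, k, b = 1, t) {
  family <- match.arg(family, .FAMILIES)
  stopifnot(is.numeric(t), all(t >= 0))
  v <- .curve_values_cpp(.family_code(family), A, k,
                         if (is.null(b) || is.na(b)) 1 else b, t)
  if (family == "harmonic" && anyNA(v))
    stop("harmonic model undefined: 1 + k*t <= 0 for some t", call. = FALSE)
  if (family == "weibull" && anyNA(v))
    stop("weibull model undefined for k*t < 0", call. = FALSE)
  v
}

#' Simulate a subject's series from a planted trajectory
#'
#' Evaluates the model curve at the given visit days and adds i.i.d.
#' Gaussian measurement noise, truncating below at 0 (clinical scores and
#' laboratory concentrations have a floor at zero).
#'
#' @inheritParams model_value
#' @param times Visit days, nonnegative and sorted.
#' @param noise_sd Gaussian noise standard deviation (`>= 0`), in the
#'   variable's units.
#' @return Numeric vector of simulated values, one per time.
#' @export
plant_trajectory <- function(family, A, k, b = 1, times, noise_sd = 0) {
  stopifnot(is.numeric(times), all(times >= 0), !is.unsorted(times))
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0)
    stop("noise_sd must be a single nonnegative number", call. = FALSE)
  y <- model_value(family, A, k, b, times)
  if (noise_sd > 0) y <- y + rnorm(length(times), 0, noise_sd)
  pmax(y, 0)
}
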