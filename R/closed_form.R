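# Closed-form asymptotic predictors of annual genetic gain, genetic lag and
# time lag for the two-tier honeybee gene-flow model.

.new_prediction <- function(mating, p, q, s1, s2, dB, D, T, divergent) {
  structure(
    list(mating = mating, p = p, q = q, s1 = s1, s2 = s2,
         dB = dB, dP = dB, D = D, T = T, divergent = divergent),
    class = "asymptotic_prediction"
  )
}

#' Asymptotic response to selection under uncontrolled mating
#'
#' Closed-form long-run values for free aerial mating of breeding queens:
#' annual genetic gain \eqn{\Delta B = \Delta P = \frac{p+q}{3+3q} S_1},
#' genetic lag \eqn{D = S_1 / (1+q)} and time lag \eqn{T = 3/(p+q)} years.
#' With `p = q = 0` the two tiers are genetically disconnected: the gain is
#' zero and the time lag diverges (flagged, not an error, so grid sweeps over
#' the unit square complete).
#'
#' @param p probability that a free-mating drone has a breeding-colony dam.
#' @param q proportion of passive queens with a breeding-population dam.
#' @param s1 genetic selection differential for breeding-queen production.
#' @return An `asymptotic_prediction` with elements `dB`, `dP`, `D`, `T` and a
#'   `divergent` flag.
#' @export
#' @examples
#' predict_uncontrolled(p = 1, q = 1, s1 = 1) # gain 1/3, lag 0.5, time lag 1.5
predict_uncontrolled <- function(p, q, s1) {
  .check_prob(p, "p"); .check_prob(q, "q")
  stopifnot(is.finite(s1))
  dB <- (p + q) / (3 + 3 * q) * s1
  D <- s1 / (1 + q)
  divergent <- (p + q) == 0
  T <- if (divergent) Inf else 3 / (p + q)
  .new_prediction("uncontrolled", p, q, s1, NULL, dB, D, T, divergent)
}

#' Asymptotic response to selection under controlled mating
#'
#' Closed-form long-run values when breeding queens mate on isolated mating
#' stations: annual gain \eqn{\Delta B = \Delta P = (S_1+S_2)/5} — the
#' Rendel–Robertson ratio of summed selection differentials to the summed
#' maternal (2-year) and paternal (3-year) generation intervals — genetic lag
#' \deqn{D = \frac{6}{p+2q-pq}\cdot\frac{S_1+S_2}{5} - \frac{p}{p+2q-pq} S_1,}
#' and time lag \eqn{T = D / \Delta B}. When `p + 2q - pq = 0` the passive
#' population receives no genetic inflow and lag and time lag diverge
#' (flagged).
#'
#' @inheritParams predict_uncontrolled
#' @param s2 genetic selection differential for the production of
#'   drone-producing queens.
#' @return An `asymptotic_prediction`.
#' @export
#' @examples
#' predict_controlled(p = 1, q = 1, s1 = 1, s2 = 1) # gain 0.4, lag 0.7
predict_controlled <- function(p, q, s1, s2) {
  .check_prob(p, "p"); .check_prob(q, "q")
  stopifnot(is.finite(s1), is.finite(s2))
  dB <- (s1 + s2) / 5
  den <- p + 2 * q - p * q
  divergent <- den == 0
  if (divergent) {
    D <- Inf
    T <- Inf
  } else {
    D <- 6 / den * (s1 + s2) / 5 - p / den * s1
    T <- if (s1 + s2 == 0) time_lag(D, dB) else 6 / den - 5 * p / den * s1 / (s1 + s2)
  }
  .new_prediction("controlled", p, q, s1, s2, dB, D, T, divergent)
}

#' Asymptotic prediction for a scenario object
#'
#' Dispatches to [predict_uncontrolled()] or [predict_controlled()] according
#' to the scenario's mating system.
#'
#' @param params a [scenario_params()] object (constant-parameter mode).
#' @return An `asymptotic_prediction`.
#' @export
predict_asymptote <- function(params) {
  stopifnot(inherits(params, "scenario_params"))
  if (params$mating == "controlled") {
    predict_controlled(params$p, params$q, params$s1, params$s2)
  } else {
    predict_uncontrolled(params$p, params$q, params$s1)
  }
}

#' Expected genetic selection differential from intensity, accuracy and spread
#'
#' For colony true breeding values that are normally distributed with standard
#' deviation `sigma` and estimated with accuracy `rho`, truncation selection
#' with standardized intensity `i` yields an expected genetic selection
#' differential \eqn{S = i \rho \sigma}. Note that `sigma` is the standard
#' deviation of colony values, which in general differs from the additive
#' genetic standard deviation and shrinks under sustained selection; it is an
#' input here, not derived.
#'
#' @param i selection intensity (standardized mean of the selected fraction),
#'   non-negative.
#' @param rho accuracy of breeding-value estimation in \[0, 1\].
#' @param sigma standard deviation of colony true breeding values,
#'   non-negative.
#' @return The expected selection differential in breeding-value units.
#' @export
selection_differential <- function(i, rho, sigma) {
  stopifnot("i must be >= 0" = is.finite(i) && i >= 0,
            "rho must be in [0, 1]" = is.finite(rho) && rho >= 0 && rho <= 1,
            "sigma must be >= 0" = is.finite(sigma) && sigma >= 0)
  i * rho * sigma
}

#' Time lag between the breeding and passive populations
#'
#' Years by which the passive population trails the breeding population:
#' `D / dB`, with the conventions that a zero lag gives a zero time lag and a
#' positive lag with zero gain never closes (`Inf`).
#'
#' @param D asymptotic genetic lag (breeding-value units).
#' @param dB asymptotic annual gain (breeding-value units per year),
#'   non-negative.
#' @return Time lag in years.
#' @export
time_lag <- function(D, dB) {
  stopifnot(dB >= 0)
  if (dB == 0) {
    if (D == 0) 0 else Inf
  } else {
    D / dB
  }
}

#' @export
print.asymptotic_prediction <- function(x, ...) {
  cat("Asymptotic selection response (", x$mating, " mating)\n", sep = "")
  cat(sprintf("  p = %g, q = %g, S1 = %g%s\n", x$p, x$q, x$s1,
              if (is.null(x$s2)) "" else sprintf(", S2 = %g", x$s2)))
  cat(sprintf("  annual gain  dB = dP = %.6g\n", x$dB))
  cat(sprintf("  genetic lag  D  = %.6g%s\n", x$D,
              if (x$divergent) "  (divergent)" else ""))
  cat(sprintf("  time lag     T  = %.6g years%s\n", x$T,
              if (!is.finite(x$T)) "  (divergent)" else ""))
  invisible(x)
}

#' @export
as.list.asymptotic_prediction <- function(x, ...) {
  list(mating = x$mating, p = x$p, q = x$q, s1 = x$s1, s2 = x$s2,
       dB = x$dB, dP = x$dP, D = x$D, T = x$T, divergent = x$divergent)
}
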