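#' Deterministic gene-flow scenario parameters
#'
#' Bundles the parameters of the deterministic two-tier gene-flow model: the
#' mating system of the breeding population, the probability `p` that a sire
#' drone in a free mating comes from a breeding colony, the proportion `q` of
#' passive queens whose dam queen belongs to the breeding population, and the
#' genetic selection differentials `s1` (dams of breeding queens) and `s2`
#' (dams of drone-producing queens, controlled mating only).
#'
#' All four parameters may alternatively be supplied as per-year series
#' (`p_t`, `q_t`, `s1_t`, `s2_t`), in which case the recursion steps evaluate
#' the time-varying form of the recursions term by term. Series are indexed by
#' simulation year (year 1 = first year with selection); lags reaching into
#' pre-start years are clamped to the year-1 value, which reproduces the
#' constant-parameter recursion exactly when a constant series is supplied.
#'
#' @param mating `"uncontrolled"` (free aerial mating) or `"controlled"`
#'   (isolated mating stations / insemination) for the breeding population.
#'   Passive queens always mate freely.
#' @param p probability in \[0, 1\] that a drone in a free mating has a dam
#'   from a breeding colony.
#' @param q proportion in \[0, 1\] of passive queens with a breeding-population
#'   dam queen.
#' @param s1 genetic selection differential of colonies selected to produce
#'   breeding queens, in breeding-value units.
#' @param s2 genetic selection differential of colonies selected to produce
#'   drone-producing queens; required iff `mating = "controlled"`.
#' @param p_t,q_t,s1_t,s2_t optional numeric vectors giving per-year values
#'   overriding the constants; each must cover every simulated year.
#' @return An object of class `scenario_params`.
#' @seealso [iterate_gene_flow()], [predict_asymptote()]
#' @export
#' @examples
#' scenario_params("uncontrolled", p = 0.5, q = 0.5, s1 = 1)
scenario_params <- function(mating = c("uncontrolled", "controlled"),
                            p, q, s1, s2 = NULL,
                            p_t = NULL, q_t = NULL, s1_t = NULL, s2_t = NULL) {
  mating <- match.arg(mating)
  .check_prob(p, "p")
  .check_prob(q, "q")
  stopifnot("s1 must be a finite number" = is.numeric(s1) && length(s1) == 1L && is.finite(s1))
  if (mating == "controlled") {
    if (is.null(s2)) {
      stop("scenario_params: 's2' is required under controlled mating", call. = FALSE)
    }
    stopifnot("s2 must be a finite number" = is.numeric(s2) && length(s2) == 1L && is.finite(s2))
  } else if (!is.null(s2)) {
    stop("scenario_params: 's2' is only meaningful under controlled mating", call. = FALSE)
  }
  for (nm in c("p_t", "q_t")) {
    v <- get(nm)
    if (!is.null(v) && (any(!is.finite(v)) || any(v < 0 | v > 1))) {
      stop("scenario_params: '", nm, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(mating = mating, p = p, q = q, s1 = s1, s2 = s2,
         series = list(p = p_t, q = q_t, s1 = s1_t, s2 = s2_t)),
    class = "scenario_params"
  )
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop("scenario_params: '", name, "' must be a probability in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.scenario_params <- function(x, ...) {
  cat("Gene-flow scenario (", x$mating, " mating)\n", sep = "")
  cat(sprintf("  p  = %-8g q  = %g\n", x$p, x$q))
  if (is.null(x$s2)) {
    cat(sprintf("  S1 = %g\n", x$s1))
  } else {
    cat(sprintf("  S1 = %-8g S2 = %g\n", x$s1, x$s2))
  }
  if (any(!vapply(x$series, is.null, logical(1L)))) {
    cat("  time-varying series:",
        paste(names(x$series)[!vapply(x$series, is.null, logical(1L))], collapse = ", "),
        "\n")
  }
  invisible(x)
}

# Per-year parameter lookup; years before the start clamp to the year-1 value,
# so a constant series reproduces the constant-parameter recursion exactly.
.param_at <- function(params, name, t) {
  v <- params$series[[name]]
  if (is.null(v)) {
    val <- params[[name]]
    if (is.null(val)) stop("parameter '", name, "' is not set", call. = FALSE)
    return(val)
  }
  v[[max(1L, min(length(v), t))]]
}

.has_series <- function(params) {
  any(!vapply(params$series, is.null, logical(1L)))
}

#' Pre-start state of the gene-flow recursions
#'
#' The deepest recursion term looks four years back, so the iteration needs a
#' short history of pre-start mean breeding values. The default is the
#' unselected base population: all pre-start means zero, with selection acting
#' from year 1 onward.
#'
#' @param depth number of pre-start years to carry (at least 5).
#' @param B,P pre-start mean true breeding values of breeding and passive
#'   colonies; scalars are recycled over the `depth` years.
#' @return A data frame with columns `year` (`1 - depth` to `0`), `B`, `P`,
#'   of class `initial_state`.
#' @export
initial_state <- function(depth = 5L, B = 0, P = 0) {
  depth <- as.integer(depth)
  if (depth < 5L) stop("initial_state: depth must be at least 5 years", call. = FALSE)
  out <- data.frame(year = seq.int(1L - depth, 0L),
                    B = rep_len(as.numeric(B), depth),
                    P = rep_len(as.numeric(P), depth))
  class(out) <- c("initial_state", "data.frame")
  out
}
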