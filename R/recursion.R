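# Year-by-year gene-flow recursions for mean true breeding values.
#
# Bookkeeping conventions: a colony is labelled by the birth/mating year of its
# queen; worker groups receive their breeding values in equal parts from their
# queen and from the drones she mated with; the queen-dam generation interval is
# two years, free-mating drones come from two-year-old dams, and the
# station-drone path adds a three-year interval between drone-producing queens
# and the queens they serve.

.lag_value <- function(history, var, year) {
  i <- match(year, history$year)
  if (is.na(i) || is.na(history[[var]][i])) {
    stop("insufficient history: no value of ", var, " for year ", year, call. = FALSE)
  }
  history[[var]][i]
}

#' One recursion step for breeding colonies under uncontrolled mating
#'
#' Computes the mean true breeding value of year-`t` breeding colonies from
#' lagged breeding/passive means. In constant-parameter mode this is
#' \deqn{B_t = \tfrac12 B_{t-2} + \tfrac{p+q-pq}{2} B_{t-4}
#'           + \tfrac{(1-p)(1-q)}{2} P_{t-4} + \tfrac{1+p}{2} S_1,}
#' the grouped form of the path-by-path recursion; with time-varying series the
#' path-by-path form is evaluated term by term
#' (\eqn{p_t}, \eqn{q_{t-2}}, \eqn{S_{1,t-2}}, \eqn{S_{1,t-4}}).
#'
#' @param history data frame with columns `year`, `B`, `P` supplying at least
#'   years `t-4` to `t-1`.
#' @param params a [scenario_params()] object.
#' @param t the year being computed.
#' @return The scalar mean breeding value \eqn{B_t}.
#' @export
step_breeding_uncontrolled <- function(history, params, t) {
  stopifnot(inherits(params, "scenario_params"))
  B2 <- .lag_value(history, "B", t - 2L)
  B4 <- .lag_value(history, "B", t - 4L)
  P4 <- .lag_value(history, "P", t - 4L)
  if (.has_series(params)) {
    p_t <- .param_at(params, "p", t)
    q_l2 <- .param_at(params, "q", t - 2L)
    s1_l2 <- .param_at(params, "s1", t - 2L)
    s1_l4 <- .param_at(params, "s1", t - 4L)
    (B2 + s1_l2) / 2 +
      p_t * (B4 + s1_l4) / 2 +
      (1 - p_t) * (q_l2 * B4 + (1 - q_l2) * P4) / 2
  } else {
    p <- params$p; q <- params$q; s1 <- params$s1
    B2 / 2 + (p + q - p * q) / 2 * B4 + (1 - p) * (1 - q) / 2 * P4 + (1 + p) / 2 * s1
  }
}

#' One recursion step for passive colonies
#'
#' Passive queens are reared from an unselected breeding colony with
#' probability `q` and from a passive colony otherwise; their mates follow the
#' free-mating drone path regardless of how the breeding population mates.
#' Constant-parameter form:
#' \deqn{P_t = \tfrac{q}{2} B_{t-2} + \tfrac{p+q-pq}{2} B_{t-4}
#'           + \tfrac{1-q}{2} P_{t-2} + \tfrac{(1-p)(1-q)}{2} P_{t-4}
#'           + \tfrac{p}{2} S_1.}
#'
#' @inheritParams step_breeding_uncontrolled
#' @return The scalar mean breeding value \eqn{P_t}.
#' @export
step_passive <- function(history, params, t) {
  stopifnot(inherits(params, "scenario_params"))
  B2 <- .lag_value(history, "B", t - 2L)
  B4 <- .lag_value(history, "B", t - 4L)
  P2 <- .lag_value(history, "P", t - 2L)
  P4 <- .lag_value(history, "P", t - 4L)
  if (.has_series(params)) {
    p_t <- .param_at(params, "p", t)
    q_t <- .param_at(params, "q", t)
    q_l2 <- .param_at(params, "q", t - 2L)
    s1_l4 <- .param_at(params, "s1", t - 4L)
    (q_t * B2 + (1 - q_t) * P2) / 2 +
      p_t * (B4 + s1_l4) / 2 +
      (1 - p_t) * (q_l2 * B4 + (1 - q_l2) * P4) / 2
  } else {
    p <- params$p; q <- params$q; s1 <- params$s1
    q / 2 * B2 + (p + q - p * q) / 2 * B4 + (1 - q) / 2 * P2 +
      (1 - p) * (1 - q) / 2 * P4 + p / 2 * s1
  }
}

#' One recursion step for breeding colonies under controlled mating
#'
#' With mating stations the paternal path runs through drone-producing queens
#' whose common dam is a selected colony three years older than the mated
#' queen, so the breeding population is decoupled from the passive one:
#' \deqn{B_t = \tfrac12 B_{t-2} + \tfrac12 B_{t-3} + \tfrac{S_1 + S_2}{2}.}
#'
#' @inheritParams step_breeding_uncontrolled
#' @return The scalar mean breeding value \eqn{B_t}.
#' @export
step_breeding_controlled <- function(history, params, t) {
  stopifnot(inherits(params, "scenario_params"))
  if (is.null(params$s2) && is.null(params$series$s2)) {
    stop("controlled mating requires the selection differential 's2'", call. = FALSE)
  }
  B2 <- .lag_value(history, "B", t - 2L)
  B3 <- .lag_value(history, "B", t - 3L)
  if (.has_series(params)) {
    s1_l2 <- .param_at(params, "s1", t - 2L)
    s2_l3 <- .param_at(params, "s2", t - 3L)
    (B2 + s1_l2) / 2 + (B3 + s2_l3) / 2
  } else {
    B2 / 2 + B3 / 2 + (params$s1 + params$s2) / 2
  }
}

#' Iterate the gene-flow recursions forward
#'
#' Deterministic forward driver. Breeding-colony means follow the step matching
#' the scenario's mating system, passive-colony means always follow
#' [step_passive()]. Annual gains and the genetic lag are derived as exact
#' differences of the `B`/`P` series.
#'
#' Under uncontrolled mating all lags in the recursions are even, so from a
#' parity-symmetric start the even-year and odd-year sub-chains coincide and
#' the annual first difference `dB` oscillates permanently between 0 and twice
#' the asymptotic gain. Convergence detection therefore uses the parity-robust
#' two-year mean gain \eqn{(B_t - B_{t-2})/2} (see [trajectory_asymptotes()]);
#' the genetic lag `D` converges annually in all scenarios.
#'
#' @param params a [scenario_params()] object.
#' @param n_years number of years to simulate (at least 1).
#' @param init pre-start state, see [initial_state()].
#' @param tol convergence tolerance: the trajectory is flagged converged at the
#'   first year where both the two-year mean gain and the lag change by less
#'   than `tol` (gain against the previous year, lag against two years back).
#' @return A data frame of class `bee_trajectory` with columns `year`, `B`,
#'   `P`, `dB`, `dP`, `D` and attributes `params`, `convergence_year` (`NA` if
#'   the tolerance was never met).
#' @export
#' @examples
#' tr <- iterate_gene_flow(scenario_params("uncontrolled", 1, 1, 1), 60)
#' trajectory_asymptotes(tr)$dB # ~ 1/3
iterate_gene_flow <- function(params, n_years, init = initial_state(), tol = 1e-9) {
  stopifnot(inherits(params, "scenario_params"))
  n_years <- as.integer(n_years)
  if (n_years < 1L) stop("n_years must be at least 1", call. = FALSE)
  if (!all(c("year", "B", "P") %in% names(init))) {
    stop("init must have columns year, B, P", call. = FALSE)
  }
  depth <- nrow(init)
  if (depth < 5L || !identical(init$year, seq.int(1L - depth, 0L))) {
    stop("init must cover consecutive pre-start years down to at least year -4",
         call. = FALSE)
  }
  controlled <- params$mating == "controlled"
  if (controlled && is.null(params$s2) && is.null(params$series$s2)) {
    stop("controlled mating requires the selection differential 's2'", call. = FALSE)
  }
  tv <- .has_series(params)
  if (tv) {
    for (nm in c("p", "q", "s1", if (controlled) "s2")) {
      v <- params$series[[nm]]
      if (!is.null(v) && length(v) < n_years) {
        stop("time-varying series '", nm, "' must cover every simulated year",
             call. = FALSE)
      }
    }
  }

  off <- depth                         # vector index of year 0 is `off`
  B <- c(init$B, numeric(n_years))
  P <- c(init$P, numeric(n_years))
  for (t in seq_len(n_years)) {
    i <- off + t
    if (tv) {
      p_t <- .param_at(params, "p", t)
      q_t <- .param_at(params, "q", t)
      q_l2 <- .param_at(params, "q", t - 2L)
      s1_l2 <- .param_at(params, "s1", t - 2L)
      s1_l4 <- .param_at(params, "s1", t - 4L)
      drone_side <- p_t * (B[i - 4L] + s1_l4) / 2 +
        (1 - p_t) * (q_l2 * B[i - 4L] + (1 - q_l2) * P[i - 4L]) / 2
      B[i] <- if (controlled) {
        (B[i - 2L] + s1_l2) / 2 + (B[i - 3L] + .param_at(params, "s2", t - 3L)) / 2
      } else {
        (B[i - 2L] + s1_l2) / 2 + drone_side
      }
      P[i] <- (q_t * B[i - 2L] + (1 - q_t) * P[i - 2L]) / 2 + drone_side
    } else {
      p <- params$p; q <- params$q; s1 <- params$s1
      B[i] <- if (controlled) {
        B[i - 2L] / 2 + B[i - 3L] / 2 + (s1 + params$s2) / 2
      } else {
        B[i - 2L] / 2 + (p + q - p * q) / 2 * B[i - 4L] +
          (1 - p) * (1 - q) / 2 * P[i - 4L] + (1 + p) / 2 * s1
      }
      P[i] <- q / 2 * B[i - 2L] + (p + q - p * q) / 2 * B[i - 4L] +
        (1 - q) / 2 * P[i - 2L] + (1 - p) * (1 - q) / 2 * P[i - 4L] + p / 2 * s1
    }
  }

  yr <- seq_len(n_years)
  i <- off + yr
  out <- data.frame(year = yr,
                    B = B[i], P = P[i],
                    dB = B[i] - B[i - 1L],
                    dP = P[i] - P[i - 1L],
                    D = B[i] - P[i])
  # parity-robust convergence: two-year mean gain settles and lag settles
  g <- (B[i] - B[i - 2L]) / 2
  conv <- NA_integer_
  if (n_years >= 3L) {
    dD <- abs(out$D[3:n_years] - out$D[1:(n_years - 2L)])
    dg <- abs(g[3:n_years] - g[2:(n_years - 1L)])
    hit <- which(dg < tol & dD < tol)
    if (length(hit)) conv <- hit[1L] + 2L
  }
  attr(out, "params") <- params
  attr(out, "convergence_year") <- conv
  class(out) <- c("bee_trajectory", "data.frame")
  out
}

#' Asymptotic gains and lag read off an iterated trajectory
#'
#' Extracts the late-year annual gains and genetic lag from a trajectory in a
#' parity-robust way: gains as the two-year mean \eqn{(X_n - X_{n-2})/2}
#' (identical to the annual difference once the trajectory has converged under
#' controlled mating, and the correct annual rate when the uncontrolled
#' first differences alternate between the two parity chains), and the lag as
#' the mean of the last two years.
#'
#' @param trajectory a `bee_trajectory` from [iterate_gene_flow()].
#' @return A list with elements `dB`, `dP`, `D`.
#' @export
trajectory_asymptotes <- function(trajectory) {
  stopifnot(inherits(trajectory, "bee_trajectory"), nrow(trajectory) >= 3L)
  n <- nrow(trajectory)
  list(dB = (trajectory$B[n] - trajectory$B[n - 2L]) / 2,
       dP = (trajectory$P[n] - trajectory$P[n - 2L]) / 2,
       D = mean(trajectory$D[c(n - 1L, n)]))
}

#' @export
print.bee_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat("Gene-flow trajectory: ", nrow(x), " years (", p$mating, " mating)\n", sep = "")
  cv <- attr(x, "convergence_year")
  if (!is.na(cv)) cat("  converged (tol criterion) at year", cv, "\n")
  a <- trajectory_asymptotes(x)
  cat(sprintf("  late-year gain %.6g, lag %.6g\n", a$dB, a$D))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ... [", nrow(x) - 6L, " more years]\n", sep = "")
  invisible(x)
}
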