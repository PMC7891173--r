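# Predicted-versus-simulated comparison: reconstruction of passive colony
# means from queen means, window averaging of realized gains and lags, and
# regression of simulated on predicted values.

#' Reconstruct the mean passive colony value from queen means
#'
#' When passive worker groups are not tracked directly, the mean passive
#' colony (worker-group) value of year `t` can be reconstructed from the mean
#' queen values of both tiers: half from the passive queens of year `t`, half
#' from the drones they mated with, whose dams are breeding queens with
#' probability `p` and are 1 to 3 years old uniformly:
#' \deqn{\bar P_t = \tfrac12 \bar P^Q_t + \tfrac12\Big(\tfrac{p}{3}
#'   \sum_{i=1}^{3} \bar B^Q_{t-i} + \tfrac{1-p}{3} \sum_{i=1}^{3}
#'   \bar P^Q_{t-i}\Big).}
#'
#' @param b_q,p_q numeric vectors of mean breeding- and passive-queen breeding
#'   values, indexed by `years`.
#' @param p probability that a free-mating drone has a breeding-colony dam.
#' @param t year to reconstruct (queen means for `t-3` to `t` must be
#'   available).
#' @param years integer years labelling `b_q`/`p_q` (default: positions).
#' @return The reconstructed mean passive colony value for year `t`.
#' @export
reconstruct_passive_mean <- function(b_q, p_q, p, t, years = seq_along(b_q)) {
  .check_prob(p, "p")
  stopifnot(length(b_q) == length(years), length(p_q) == length(years))
  need <- t - 0:3
  i <- match(need, years)
  if (anyNA(i)) {
    stop("reconstruct_passive_mean: queen means missing for year(s) ",
         paste(need[is.na(i)], collapse = ", "), call. = FALSE)
  }
  lag <- i[2:4]
  p_q[i[1L]] / 2 + (p / 3 * sum(b_q[lag]) + (1 - p) / 3 * sum(p_q[lag])) / 2
}

#' Average a yearly series over a reporting window
#'
#' @param x numeric series indexed by `years`.
#' @param years integer years labelling `x` (default: positions).
#' @param window years to average over (default 8 to 17, the window in which
#'   realized selection differentials have stabilized on a 20-year horizon).
#' @return The arithmetic mean of `x` over `window`.
#' @export
window_average <- function(x, years = seq_along(x), window = 8:17) {
  stopifnot(length(x) == length(years))
  i <- match(window, years)
  if (anyNA(i)) {
    stop("window_average: series does not cover year(s) ",
         paste(window[is.na(i)], collapse = ", "), call. = FALSE)
  }
  mean(x[i])
}

#' Regress simulated against predicted values
#'
#' The headline statistics are the least-squares slope through the origin of
#' simulated on predicted values and the squared Pearson correlation; the
#' with-intercept ordinary least-squares fit is reported alongside.
#'
#' @param predicted,simulated paired numeric vectors (at least 3 pairs).
#' @param labels optional labels for the pairs (data frame or vector),
#'   carried into the records table.
#' @return A list of class `validation_report`: `records`, `slope` (through
#'   the origin), `r_squared` (squared Pearson correlation; `NA` and flagged
#'   when the predictions have zero variance), `slope_ols`, `intercept_ols`,
#'   `n`.
#' @export
compare_predictions <- function(predicted, simulated, labels = NULL) {
  stopifnot(length(predicted) == length(simulated))
  keep <- is.finite(predicted) & is.finite(simulated)
  predicted <- predicted[keep]; simulated <- simulated[keep]
  if (length(predicted) < 3L) {
    stop("compare_predictions: need at least 3 finite pairs", call. = FALSE)
  }
  records <- data.frame(predicted = predicted, simulated = simulated)
  if (!is.null(labels)) {
    labels <- as.data.frame(labels)[keep, , drop = FALSE]
    records <- cbind(labels, records)
  }
  zero_var <- stats::var(predicted) == 0
  r2 <- if (zero_var) NA_real_ else stats::cor(predicted, simulated)^2
  fit <- stats::lm(simulated ~ predicted)
  structure(
    list(records = records,
         slope = sum(predicted * simulated) / sum(predicted^2),
         r_squared = r2, zero_variance = zero_var,
         slope_ols = unname(stats::coef(fit)[2L]),
         intercept_ols = unname(stats::coef(fit)[1L]),
         n = length(predicted)),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Predicted vs simulated genetic progress:", x$n, "paired values\n")
  if (x$zero_variance) {
    cat("  R^2 undefined: predictions have zero variance\n")
  } else {
    cat(sprintf("  slope through origin = %.4f, R^2 = %.4f\n", x$slope, x$r_squared))
  }
  cat(sprintf("  OLS fit: slope %.4f, intercept %.4f\n", x$slope_ols, x$intercept_ols))
  invisible(x)
}

#' @export
plot.validation_report <- function(x, ...) {
  r <- x$records
  graphics::plot(r$predicted, r$simulated,
                 xlab = "predicted", ylab = "simulated",
                 main = "Predicted vs simulated genetic progress", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

# window-averaged realized quantities of one simulation, per replicate,
# on the component given (aggregate/total)
.sim_window_stats <- function(sim, window = 8:17, component = NULL) {
  s <- sim$summary
  if (is.null(component)) {
    component <- if (sim$config$genetics == "aggregate") "aggregate" else "total"
  }
  s <- s[s$component == component, ]
  reps <- sort(unique(s$replicate))
  out <- lapply(reps, function(r) {
    sr <- s[s$replicate == r, ]
    sr <- sr[order(sr$year), ]
    dB <- diff(sr$B); dP <- diff(sr$P)
    yr_d <- sr$year[-1L]
    data.frame(
      replicate = r,
      dB = window_average(dB, yr_d, window),
      dP = window_average(dP, yr_d, window),
      D = window_average(sr$B - sr$P, sr$year, window),
      S1 = window_average(sr$S1, sr$year, window),
      S2 = if (all(is.na(sr$S2))) NA_real_ else
        window_average(sr$S2, sr$year, window)
    )
  })
  do.call(rbind, out)
}

#' Reduced validation study: simulator versus closed-form predictors
#'
#' Runs the individual-based simulator over a grid of scenarios, averages the
#' realized annual gains, genetic lags and selection differentials over a
#' reporting window, predicts each scenario's gains and lag from the
#' closed-form formulas using the *realized* selection differentials, and
#' regresses simulated on predicted values. The scenario grid is a scaled-down
#' version of the full simulation study (desk-scale runtime); the informative
#' statistic is the pooled squared correlation and near-unit slope, not any
#' particular scenario's value.
#'
#' @param sizes population sizes per tier (used for both tiers:
#'   `n_breeding = n_passive`).
#' @param q_values passive-dam migration proportions to cover.
#' @param mating mating systems to cover (one or both).
#' @param replicates replicates per scenario.
#' @param years horizon per replicate.
#' @param window reporting window (years) for averaging.
#' @param seed master seed; scenario seeds are derived deterministically.
#' @param ... further arguments passed to [sim_config()] (e.g. `rho`,
#'   `n_stations`).
#' @return A list of class `validation_study`: `records` (one row per
#'   scenario and quantity with predicted and simulated values), `report`
#'   (pooled [compare_predictions()] result), `by_quantity` (reports per
#'   quantity), `window`.
#' @export
run_validation_study <- function(sizes = c(250L, 500L),
                                 q_values = c(0.5, 0.75, 1),
                                 mating = c("uncontrolled", "controlled"),
                                 replicates = 10L, years = 20L,
                                 window = 8:17, seed = 1L, ...) {
  mating <- match.arg(mating, several.ok = TRUE)
  grid <- expand.grid(n = sizes, q = q_values, mating = mating,
                      stringsAsFactors = FALSE)
  set.seed(seed)
  grid$seed <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  rec <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cfg <- sim_config(n_breeding = g$n, n_passive = g$n, mating = g$mating,
                      q = g$q, years = years, replicates = replicates,
                      seed = g$seed, ...)
    sim <- simulate_breeding(cfg)
    w <- .sim_window_stats(sim, window = window)
    s1 <- mean(w$S1)
    pred <- if (g$mating == "controlled") {
      predict_controlled(cfg$p_drone, g$q, s1, mean(w$S2))
    } else {
      predict_uncontrolled(cfg$p_drone, g$q, s1)
    }
    rec[[i]] <- data.frame(
      n = g$n, q = g$q, mating = g$mating,
      quantity = c("dB", "dP", "D"),
      predicted = c(pred$dB, pred$dP, pred$D),
      simulated = c(mean(w$dB), mean(w$dP), mean(w$D)),
      sim_se = c(stats::sd(w$dB), stats::sd(w$dP), stats::sd(w$D)) /
        sqrt(nrow(w)),
      s1_realized = s1,
      s2_realized = if (g$mating == "controlled") mean(w$S2) else NA_real_
    )
  }
  records <- do.call(rbind, rec)
  report <- compare_predictions(records$predicted, records$simulated,
                                labels = records[c("n", "q", "mating", "quantity")])
  by_q <- lapply(split(records, records$quantity), function(r) {
    compare_predictions(r$predicted, r$simulated)
  })
  structure(list(records = records, report = report, by_quantity = by_q,
                 window = window),
            class = "validation_study")
}

#' @export
print.validation_study <- function(x, ...) {
  cat("Reduced validation study:", nrow(x$records) / 3, "scenarios, window",
      min(x$window), "-", max(x$window), "\n")
  print(x$report)
  for (nm in names(x$by_quantity)) {
    r <- x$by_quantity[[nm]]
    cat(sprintf("  %-2s: slope %.3f, R^2 %.4f\n", nm, r$slope, r$r_squared))
  }
  invisible(x)
}
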