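# How fast each recursion approaches its asymptote: characteristic roots of
# the homogeneous lag polynomial, per-year contraction factors, and the first
# year within a tolerance of the fixed point. This makes quantitative the
# observation that with little queen migration (small q) the lag recursion
# under controlled mating converges so slowly that a 20-year horizon never
# reaches the asymptote.

#' Linear-recurrence specification of a gene-flow quantity
#'
#' The four scalar recursions implied by the model, written as
#' \eqn{X_k = \sum_j \phi_j X_{k-j} + c} on their natural step:
#' \describe{
#'   \item{`lag_uncontrolled`}{\eqn{D_t = \frac{1-q}{2} D_{t-2} + \frac{S_1}{2}},
#'     a 2-year step.}
#'   \item{`lag_controlled`}{\eqn{D_t = \frac{1-q}{2} D_{t-2} +
#'     \frac{(1-p)(1-q)}{2} D_{t-4} + \frac{6-5p}{10} S_1 + \frac35 S_2},
#'     2-year steps.}
#'   \item{`gain_uncontrolled`}{\eqn{\Delta B_t = -\Delta B_{t-1} -
#'     \tfrac12 \Delta B_{t-2} - \tfrac12 \Delta B_{t-3} + \frac{p+q}{1+q} S_1},
#'     annual steps. Its root \eqn{x=-1} is a parity oscillation between the
#'     even- and odd-year sub-chains: it never decays but does not move the
#'     two-year mean gain, and is flagged structural.}
#'   \item{`gain_controlled`}{\eqn{\Delta B_t = -\Delta B_{t-1} -
#'     \tfrac12 \Delta B_{t-2} + \frac{S_1+S_2}{2}}, annual steps.}
#' }
#' Note that the homogeneous part of both gain recursions is parameter-free;
#' only the lag recursions slow down as `p` and `q` shrink.
#'
#' @param name which recursion, see Details.
#' @param p,q gene-flow probabilities in \[0, 1\].
#' @param s1,s2 selection differentials (only the intercept and asymptote
#'   depend on them); `s2` is required for the controlled-mating recursions.
#' @return A list of class `recursion_spec` with elements `name`, `ar`
#'   (coefficients \eqn{\phi_j}), `step_years`, `intercept`, `asymptote`
#'   (`Inf` when the recursion does not contract), and `structural_roots`
#'   (roots excluded from the transient modulus, with the reason).
#' @export
recursion_spec <- function(name = c("lag_uncontrolled", "gain_uncontrolled",
                                    "gain_controlled", "lag_controlled"),
                           p, q, s1 = 1, s2 = NULL) {
  name <- match.arg(name)
  .check_prob(p, "p"); .check_prob(q, "q")
  controlled <- name %in% c("gain_controlled", "lag_controlled")
  if (controlled && is.null(s2)) {
    stop("recursion_spec: 's2' is required for the controlled-mating recursions",
         call. = FALSE)
  }
  spec <- switch(name,
    lag_uncontrolled = list(
      ar = (1 - q) / 2, step_years = 2L,
      intercept = s1 / 2, asymptote = s1 / (1 + q),
      structural_roots = NULL),
    lag_controlled = {
      den <- p + 2 * q - p * q
      list(ar = c((1 - q) / 2, (1 - p) * (1 - q) / 2), step_years = 2L,
           intercept = (6 - 5 * p) / 10 * s1 + 3 / 5 * s2,
           asymptote = if (den == 0) Inf else
             6 / den * (s1 + s2) / 5 - p / den * s1,
           structural_roots = NULL)
    },
    gain_uncontrolled = list(
      ar = c(-1, -1 / 2, -1 / 2), step_years = 1L,
      intercept = (p + q) / (1 + q) * s1,
      asymptote = (p + q) / (3 + 3 * q) * s1,
      structural_roots = list(value = -1 + 0i,
                              reason = "parity oscillation of the even/odd year chains")),
    gain_controlled = list(
      ar = c(-1, -1 / 2), step_years = 1L,
      intercept = (s1 + s2) / 2,
      asymptote = (s1 + s2) / 5,
      structural_roots = NULL)
  )
  structure(c(list(name = name, p = p, q = q, s1 = s1, s2 = s2), spec),
            class = "recursion_spec")
}

#' Characteristic roots and per-year contraction factor of a recursion
#'
#' Roots of the homogeneous characteristic polynomial
#' \eqn{x^k - \phi_1 x^{k-1} - \dots - \phi_k}, found as eigenvalues of the
#' companion matrix. Structural roots (the parity root of the uncontrolled
#' gain recursion) are identified and excluded from the dominant transient
#' modulus; roots of recursions on a 2-year step are converted to a per-year
#' factor by square root so all recursions are comparable per year.
#'
#' @param spec a [recursion_spec()].
#' @param tol modulus tolerance used to match structural roots.
#' @return A list of class `recursion_roots`: `roots` (complex, per step),
#'   `step_years`, `transient_roots`, `dominant_modulus_per_step`,
#'   `dominant_modulus_per_year`, `contracting` (logical), and the spec.
#' @export
characteristic_roots <- function(spec, tol = 1e-8) {
  stopifnot(inherits(spec, "recursion_spec"))
  k <- length(spec$ar)
  roots <- if (k == 1L) {
    as.complex(spec$ar)
  } else {
    comp <- rbind(spec$ar, cbind(diag(k - 1L), 0))
    eigen(comp, only.values = TRUE)$values
  }
  transient <- roots
  if (!is.null(spec$structural_roots)) {
    drop <- abs(transient - spec$structural_roots$value) < tol
    if (!any(drop)) {
      stop("expected structural root ", format(spec$structural_roots$value),
           " not found", call. = FALSE)
    }
    transient <- transient[!drop]
  }
  m_step <- if (length(transient)) max(Mod(transient)) else 0
  m_year <- m_step^(1 / spec$step_years)
  structure(
    list(spec = spec, roots = roots, transient_roots = transient,
         step_years = spec$step_years,
         dominant_modulus_per_step = m_step,
         dominant_modulus_per_year = m_year,
         contracting = m_step < 1 - tol),
    class = "recursion_roots"
  )
}

#' @export
print.recursion_roots <- function(x, ...) {
  cat("Characteristic roots of", x$spec$name,
      sprintf("(p = %g, q = %g)\n", x$spec$p, x$spec$q))
  cat("  roots (per ", x$step_years, "-year step): ",
      paste(format(x$roots, digits = 4), collapse = ", "), "\n", sep = "")
  cat(sprintf("  dominant transient modulus: %.4f per step, %.4f per year%s\n",
              x$dominant_modulus_per_step, x$dominant_modulus_per_year,
              if (x$contracting) "" else "  (not contracting)"))
  invisible(x)
}

#' Years until a gene-flow quantity is within a tolerance of its asymptote
#'
#' Iterates the model from the unselected zero state and reports the first
#' year at which the chosen quantity (genetic lag, or annual gain measured as
#' the two-year mean) is within `eps` of its closed-form asymptote, together
#' with the analytic per-year contraction factor from the characteristic
#' roots and the empirical geometric rate fitted to the late-year distances.
#'
#' @param params a [scenario_params()] object.
#' @param eps positive tolerance on the distance to the asymptote.
#' @param quantity `"lag"` (default) or `"gain"`.
#' @param max_years iteration horizon used to search for the crossing.
#' @return A list of class `convergence_report`: `quantity`, `asymptote`,
#'   `dominant_root_modulus` (per year), `years_to_eps` (`Inf` if the
#'   recursion does not contract or the horizon was insufficient),
#'   `empirical_rate` (per-year geometric rate fitted over late years; `NA`
#'   when the transient dies too fast to fit), `eps`, and the root report.
#' @export
years_to_converge <- function(params, eps = 1e-6,
                              quantity = c("lag", "gain"),
                              max_years = 2000L) {
  stopifnot(inherits(params, "scenario_params"), eps > 0)
  quantity <- match.arg(quantity)
  controlled <- params$mating == "controlled"
  spec_name <- paste0(quantity, "_", params$mating)
  spec <- recursion_spec(spec_name, p = params$p, q = params$q,
                         s1 = params$s1, s2 = params$s2)
  roots <- characteristic_roots(spec)

  if (!is.finite(spec$asymptote)) {
    rep <- list(quantity = quantity, asymptote = Inf,
                dominant_root_modulus = roots$dominant_modulus_per_year,
                years_to_eps = Inf, empirical_rate = NA_real_,
                eps = eps, roots = roots, params = params)
    class(rep) <- "convergence_report"
    return(rep)
  }

  traj <- iterate_gene_flow(params, max_years)
  dist <- if (quantity == "lag") {
    abs(traj$D - spec$asymptote)
  } else {
    g <- c(NA, NA, (traj$B[-(1:2)] - traj$B[seq_len(nrow(traj) - 2L)]) / 2)
    abs(g - spec$asymptote)
  }
  hit <- which(dist < eps)
  years_to_eps <- if (length(hit)) hit[1L] else Inf
  if (!length(hit) && roots$contracting) {
    warning("horizon of ", max_years, " years insufficient to reach eps = ", eps)
  }

  # empirical per-year geometric rate over late years, above float noise
  emp <- NA_real_
  noise_floor <- 1e-9 * max(1, abs(spec$asymptote))
  usable <- which(is.finite(dist) & dist > noise_floor)
  usable <- usable[usable > 10L]
  if (length(usable) >= 8L && roots$contracting) {
    u <- utils::tail(usable, 60L)
    fit <- stats::lm(log(dist[u]) ~ u)
    emp <- exp(unname(stats::coef(fit)[2L]))
  }
  rep <- list(quantity = quantity, asymptote = spec$asymptote,
              dominant_root_modulus = roots$dominant_modulus_per_year,
              years_to_eps = years_to_eps, empirical_rate = emp,
              eps = eps, roots = roots, params = params)
  class(rep) <- "convergence_report"
  rep
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("Convergence of the ", x$quantity, " recursion (",
      x$params$mating, " mating, p = ", x$params$p, ", q = ", x$params$q, ")\n",
      sep = "")
  cat(sprintf("  asymptote: %.6g;  dominant per-year modulus: %.4f\n",
              x$asymptote, x$dominant_root_modulus))
  cat(sprintf("  first year within eps = %g: %s\n", x$eps,
              if (is.finite(x$years_to_eps)) x$years_to_eps else "never (horizon/contraction)"))
  if (is.finite(x$empirical_rate)) {
    cat(sprintf("  empirical per-year rate (late years): %.4f\n", x$empirical_rate))
  }
  invisible(x)
}
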