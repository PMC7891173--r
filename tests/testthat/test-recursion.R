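test_that("zero state with zero selection is a fixed point of every step", {
  h <- history_df()
  for (params in list(unc(0.3, 0.7, 0), ctl(0.3, 0.7, 0, 0))) {
    if (params$mating == "uncontrolled") {
      expect_identical(step_breeding_uncontrolled(h, params, 1L), 0)
    } else {
      expect_identical(step_breeding_controlled(h, params, 1L), 0)
    }
    expect_identical(step_passive(h, params, 1L), 0)
  }
})

test_that("constant terms of the uncontrolled steps match the grouped recursion", {
  h <- history_df()
  # only the (1+p)/2 * S1 term survives a zero history
  expect_equal(step_breeding_uncontrolled(h, unc(1, 0, 1), 1L), 1.0)
  expect_equal(step_breeding_uncontrolled(h, unc(0.4, 0.8, 2), 1L), (1 + 0.4) / 2 * 2)
  # passive: only p/2 * S1 survives
  expect_equal(step_passive(h, unc(1, 0.3, 1), 1L), 0.5)
  expect_equal(step_passive(h, unc(0.6, 0.9, 2), 1L), 0.6)
})

test_that("with q = 1 the passive step draws its maternal path from B_{t-2} only", {
  params <- unc(0.4, 1, 0)
  base <- history_df(-4:0)
  base$B[base$year == -2] <- 3
  p0 <- step_passive(base, params, 0L + 0L)
  # maternal weight on B_{t-2} is 1/2
  expect_equal(step_passive(base, params, 0L), 3 / 2 +
                 step_passive(history_df(), params, 0L))
  # and P_{t-2} is irrelevant
  perturbed <- base
  perturbed$P[perturbed$year == -2] <- 99
  expect_equal(step_passive(perturbed, params, 0L), p0)
})

test_that("path-by-path and grouped uncontrolled recursions agree on random states", {
  set.seed(41)
  for (rep in 1:100) {
    p <- runif(1); q <- runif(1); s1 <- rnorm(1)
    h <- history_df(-4:0, B = rnorm(5), P = rnorm(5))
    grouped <- unc(p, q, s1)
    termwise <- scenario_params("uncontrolled", p = p, q = q, s1 = s1,
                                p_t = rep(p, 5), q_t = rep(q, 5),
                                s1_t = rep(s1, 5))
    expect_equal(step_breeding_uncontrolled(h, termwise, 1L),
                 step_breeding_uncontrolled(h, grouped, 1L))
    expect_equal(step_passive(h, termwise, 1L),
                 step_passive(h, grouped, 1L))
  }
})

test_that("controlled step: constants and the self-consistent linear trajectory", {
  h <- history_df()
  expect_identical(step_breeding_controlled(h, ctl(0.5, 0.5, 0, 0), 1L), 0)
  expect_equal(step_breeding_controlled(h, ctl(0.5, 0.5, 1, 1), 1L), 1.0)
  # B_t = a t with a = (S1+S2)/5 satisfies the recursion exactly:
  # a t = a(t-2)/2 + a(t-3)/2 + (S1+S2)/2
  s1 <- 0.8; s2 <- 1.7; a <- (s1 + s2) / 5
  t <- 30L
  h <- history_df((t - 5):(t - 1), B = a * ((t - 5):(t - 1)))
  expect_equal(step_breeding_controlled(h, ctl(0.2, 0.9, s1, s2), t), a * t)
})

test_that("missing lags and invalid parameters fail loudly", {
  expect_error(step_breeding_uncontrolled(history_df(-2:0), unc(0.5, 0.5), 1L),
               "insufficient history")
  expect_error(step_passive(history_df(-2:0), unc(0.5, 0.5), 1L),
               "insufficient history")
  expect_error(scenario_params("uncontrolled", p = 1.2, q = 0, s1 = 1),
               "'p'")
  expect_error(scenario_params("uncontrolled", p = 0, q = -0.1, s1 = 1),
               "'q'")
  expect_error(scenario_params("controlled", p = 0.5, q = 0.5, s1 = 1),
               "'s2'")
  expect_error(step_breeding_controlled(history_df(), unc(0.5, 0.5), 1L),
               "s2")
})

test_that("iterate reproduces the exported step functions", {
  params <- unc(0.35, 0.65, 1.2)
  tr <- iterate_gene_flow(params, 8)
  h <- rbind(history_df(), data.frame(year = tr$year, B = tr$B, P = tr$P))
  for (t in 5:8) {
    expect_equal(tr$B[t], step_breeding_uncontrolled(h[h$year < t, ], params, t))
    expect_equal(tr$P[t], step_passive(h[h$year < t, ], params, t))
  }
  paramsc <- ctl(0.35, 0.65, 1.2, 0.7)
  trc <- iterate_gene_flow(paramsc, 8)
  hc <- rbind(history_df(), data.frame(year = trc$year, B = trc$B, P = trc$P))
  for (t in 5:8) {
    expect_equal(trc$B[t], step_breeding_controlled(hc[hc$year < t, ], paramsc, t))
  }
})

test_that("trajectory gains and lag are exact difference identities", {
  tr <- iterate_gene_flow(unc(0.3, 0.8, 1.5), 40)
  expect_equal(tr$dB, c(tr$B[1], diff(tr$B)))
  expect_equal(tr$dP, c(tr$P[1], diff(tr$P)))
  expect_equal(tr$D, tr$B - tr$P)
})

test_that("long-run anchors: gains and lags converge to the printed values", {
  # p = q = 1: annual gain S1/3
  a <- trajectory_asymptotes(iterate_gene_flow(unc(1, 1, 1), 60))
  expect_equal(a$dB, 1 / 3, tolerance = 1e-6)
  # controlled, S1 = S2 = 1: annual gain 2/5
  ac <- trajectory_asymptotes(iterate_gene_flow(ctl(1, 1, 1, 1), 60))
  expect_equal(ac$dB, 0.4, tolerance = 1e-6)
  # disconnected tiers: lag -> S1, gain -> 0
  a0 <- trajectory_asymptotes(iterate_gene_flow(unc(0, 0, 1), 120))
  expect_equal(a0$D, 1, tolerance = 1e-9)
  expect_equal(a0$dB, 0, tolerance = 1e-9)
})

test_that("zero selection conserves the zero state over time", {
  tr <- iterate_gene_flow(unc(0.6, 0.4, 0), 30)
  expect_true(all(tr$B == 0) && all(tr$P == 0))
  trc <- iterate_gene_flow(ctl(0.6, 0.4, 0, 0), 30)
  expect_true(all(trc$B == 0) && all(trc$P == 0))
})

test_that("the lag from the full trajectory equals the direct lag recursion", {
  # D_t = (1-q)/2 D_{t-2} + S1/2 under uncontrolled mating, to machine precision
  set.seed(99)
  for (rep in 1:5) {
    p <- runif(1); q <- runif(1); s1 <- runif(1, 0.5, 2)
    tr <- iterate_gene_flow(unc(p, q, s1), 30)
    D <- numeric(32) # years -1, 0 are zero; index t + 2
    for (t in 1:30) D[t + 2] <- (1 - q) / 2 * D[t] + s1 / 2
    expect_equal(tr$D, D[3:32])
  }
})

test_that("uncontrolled fixed points hold over the (p, q) grid", {
  # D -> S1/(1+q); two-year mean gains -> (p+q)/(3+3q) S1.  All lags in the
  # uncontrolled recursions are even, so from the parity-symmetric zero start
  # the annual first difference alternates between the two year-parity chains
  # and only the two-year mean converges.
  grid <- seq(0, 1, by = 0.1)
  for (p in grid) for (q in grid) {
    a <- trajectory_asymptotes(iterate_gene_flow(unc(p, q, 1), 150))
    expect_equal(a$D, 1 / (1 + q), tolerance = 1e-9)
    expect_equal(a$dB, (p + q) / (3 + 3 * q), tolerance = 1e-9)
    expect_equal(a$dP, (p + q) / (3 + 3 * q), tolerance = 1e-9)
  }
})

test_that("annual gains of the two tiers become parallel whenever p + q > 0", {
  for (pq in list(c(0.1, 0), c(0, 0.1), c(0.5, 0.5), c(1, 1))) {
    tr <- iterate_gene_flow(unc(pq[1], pq[2], 1), 300)
    gap <- abs(tr$dB - tr$dP)
    expect_lt(gap[300], 1e-10)
  }
  trc <- iterate_gene_flow(ctl(0.5, 0.5, 1, 1), 300)
  expect_lt(abs(trc$dB[300] - trc$dP[300]), 1e-10)
})

test_that("controlled fixed points hold wherever the lag recursion contracts", {
  grid <- seq(0, 1, by = 0.2)
  for (p in grid) for (q in grid) {
    if (p + 2 * q - p * q == 0) next
    a <- trajectory_asymptotes(iterate_gene_flow(ctl(p, q, 1, 1), 3000))
    pred <- predict_controlled(p, q, 1, 1)
    expect_equal(a$dB, 0.4, tolerance = 1e-9)
    expect_equal(a$D, pred$D, tolerance = 1e-7)
  }
})

test_that("time-varying series must cover the horizon and are honoured", {
  params <- scenario_params("uncontrolled", p = 0.5, q = 0.5, s1 = 1,
                            s1_t = rep(1, 5))
  expect_error(iterate_gene_flow(params, 10), "every simulated year")
  # switching selection off after year 5 freezes the breeding mean's growth
  n <- 40
  off <- scenario_params("uncontrolled", p = 1, q = 1, s1 = 1,
                         s1_t = c(rep(1, 5), rep(0, n - 5)))
  tr <- iterate_gene_flow(off, n)
  expect_lt(abs(trajectory_asymptotes(tr)$dB), 1e-3)
  expect_gt(tr$B[n], 0)
})
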