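test_that("sim_config validates its inputs", {
  expect_error(sim_config(q = 1.2), "'q'")
  expect_error(sim_config(drones_per_mating = 25), "between 1 and 20")
  expect_error(sim_config(mating = "controlled", n_stations = 0), "n_stations")
  expect_error(sim_config(genetics = "maternal_direct", r_md = -1.2), "r_md")
  cfg <- sim_config(n_breeding = 400, n_passive = 1200)
  expect_equal(cfg$p_drone, 0.25)
})

test_that("base population is centred and the same seed reproduces it exactly", {
  cfg <- sim_config(n_breeding = 500, n_passive = 100, seed = 11)
  set.seed(11); s1 <- init_population(cfg)
  for (y in as.character(-3:0)) {
    expect_lt(abs(mean(s1$breeding[[y]]$queen)), 4 / sqrt(500))
  }
  set.seed(11); s2 <- init_population(cfg)
  expect_identical(s1$breeding, s2$breeding)
  expect_identical(s1$passive, s2$passive)
})

test_that("truncation selection realizes the order-statistics differential", {
  set.seed(5)
  v <- rnorm(1e5, sd = 2)
  top <- select_colonies(v, n_select = 1e4, rho = 1)
  expect_equal(top$differential, 1.755 * sd(v), tolerance = 0.02)
  # random selection: differential is noise around zero
  rnd <- select_colonies(v, n_select = 1e4, rho = 0)
  expect_lt(abs(rnd$differential), 4 * sd(v) / sqrt(1e4))
  # selecting everything changes nothing
  all_sel <- select_colonies(v, n_select = 1e5, rho = 1)
  expect_equal(all_sel$differential, 0)
  expect_error(select_colonies(v, n_select = 0), "n_select")
  expect_error(select_colonies(numeric(0), 1), "empty")
})

test_that("direct and maternal components carry the configured correlation", {
  cfg <- sim_config(n_breeding = 30000, n_passive = 1, drones_per_mating = 1,
                    genetics = "maternal_direct", r_md = -0.53, seed = 2)
  set.seed(2)
  state <- init_population(cfg)
  q <- state$breeding[["0"]]$queen
  expect_identical(colnames(q), c("direct", "maternal"))
  expect_equal(cor(q[, "direct"], q[, "maternal"]), -0.53, tolerance = 0.05)
  # total variance scaled to sigma_a^2
  expect_equal(var(rowSums(q)), 1, tolerance = 0.05)
})

test_that("free-mating drones come from the breeding tier at rate N_b/(N_b+N_p)", {
  sim <- quick_sim(n = 600, years = 3, replicates = 2, seed = 21)
  rp <- sim$summary$realized_p[sim$summary$year >= 1]
  expect_true(all(abs(rp - 0.5) < 4 * sqrt(0.25 / (1200 * 12))))
})

test_that("colony means are exactly half queen mean plus half sire mean", {
  sim <- quick_sim(n = 150, years = 6, replicates = 2, seed = 31,
                   genetics = "maternal_direct")
  s <- sim$summary
  expect_equal(s$B, (s$B_Q + s$B_S) / 2)
  expect_equal(s$P, (s$P_Q + s$P_S) / 2)
  # total component is the sum of direct and maternal
  tot <- s[s$component == "total", ]
  dir <- s[s$component == "direct", ]
  mat <- s[s$component == "maternal", ]
  expect_equal(tot$B, dir$B + mat$B)
})

test_that("a full run is reproducible byte for byte and spans the horizon", {
  cfg <- sim_config(n_breeding = 120, n_passive = 120, years = 8,
                    replicates = 2, seed = 17)
  sim1 <- simulate_breeding(cfg)
  sim2 <- simulate_breeding(cfg)
  expect_identical(sim1$summary, sim2$summary)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_sim_summary(sim1, f1); write_sim_summary(sim2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_equal(sum(sim1$summary$year >= 1) / 2, 8) # 8 years per replicate
  expect_setequal(unique(sim1$summary$replicate), 1:2)
})

test_that("realized selection differentials stabilize after the early years", {
  sim <- simulate_breeding(sim_config(n_breeding = 500, n_passive = 500,
                                      years = 20, replicates = 3, seed = 23))
  w <- sim$summary[sim$summary$year %in% 8:17, ]
  for (r in 1:3) {
    s1 <- w$S1[w$replicate == r]
    expect_lt(sd(s1), 0.25 * mean(s1))
  }
})

test_that("the passive tier's reproduction code is blind to the mating system", {
  # the passive routine receives only cohorts, never the mating flag
  expect_false("mating" %in% names(formals(beeflow:::.breed_passive)))
  # and a controlled run records S2 while an uncontrolled one does not
  simc <- quick_sim(n = 150, years = 8, replicates = 1, seed = 41,
                    mating = "controlled", n_stations = 5)
  expect_true(any(is.finite(simc$summary$S2)))
  simu <- quick_sim(n = 150, years = 8, replicates = 1, seed = 41)
  expect_true(all(is.na(simu$summary$S2)))
})

test_that("simulated gains track the gene-flow prediction with realized differentials", {
  sim <- simulate_breeding(sim_config(n_breeding = 300, n_passive = 300,
                                      q = 0.5, years = 20, replicates = 10,
                                      seed = 13))
  w <- win_stats(sim)
  pred <- predict_uncontrolled(0.5, 0.5, mean(w$S1))
  z <- (mean(w$dB) - pred$dB) / (sd(w$dB) / sqrt(nrow(w)))
  expect_lt(abs(z), 3)

  simc <- simulate_breeding(sim_config(n_breeding = 300, n_passive = 300,
                                       mating = "controlled", n_stations = 10,
                                       q = 0.5, years = 20, replicates = 10,
                                       seed = 14))
  wc <- win_stats(simc)
  zc <- (mean(wc$dB) - (mean(wc$S1) + mean(wc$S2)) / 5) /
    (sd(wc$dB) / sqrt(nrow(wc)))
  expect_lt(abs(zc), 3)
})
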