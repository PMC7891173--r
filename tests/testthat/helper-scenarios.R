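# shared fixtures: all built in code, no stored data

unc <- function(p, q, s1 = 1) scenario_params("uncontrolled", p = p, q = q, s1 = s1)
ctl <- function(p, q, s1 = 1, s2 = 1) {
  scenario_params("controlled", p = p, q = q, s1 = s1, s2 = s2)
}

# history data frame from named year -> (B, P) values; unnamed years are zero
history_df <- function(years = -4:0, B = 0, P = 0) {
  data.frame(year = years, B = rep_len(B, length(years)),
             P = rep_len(P, length(years)))
}

quick_sim <- function(..., n = 200L, years = 12L, replicates = 2L, seed = 1L) {
  simulate_breeding(sim_config(n_breeding = n, n_passive = n, years = years,
                               replicates = replicates, seed = seed, ...))
}

# per-replicate window stats of a bee_sim (internal helper, re-exported here
# for test readability)
win_stats <- function(sim, window = 8:17) beeflow:::.sim_window_stats(sim, window)
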