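# shared fixtures for the test suite (all built in code)

base <- base_params()

# discount factors under the all-years convention, for closed-form oracles
df_base <- (1 + base$discount_rate)^-(1:2)

# closed-form yearly utility means for the base-case branches, used as
# independent oracles for the engine's exact piecewise-linear integration
resp_year1_mean <- function(u0, inc, onset, yl = 365) {
  # flat at u0+inc all year, minus the triangle lost during the onset ramp
  (u0 + inc) - inc * onset / (2 * yl)
}
ll_resp_year1_mean <- function(u0, inc_ll, a_day = 56, yl = 365) {
  (a_day * u0 + (yl - a_day) * (u0 + inc_ll)) / yl
}

# fine-grid trapezoid oracle for discounted QALYs of a trajectory; the
# trajectory's own knots are merged into the grid (the trapezoid rule only
# converges past a kink or step when the grid lands on it)
qaly_trapezoid <- function(traj, params, n_per_year = 20001) {
  yl <- params$year_length_days
  df <- discount_factors(params)
  total <- 0
  for (y in seq_len(params$horizon_years)) {
    a <- (y - 1) * yl; b <- y * yl
    ts <- sort(unique(c(seq(a, b, length.out = n_per_year),
                        traj$time[traj$time > a & traj$time < b])))
    us <- trajectory_utility(traj, ts)
    total <- total + df[y] * sum(diff(ts) * (us[-1] + us[-length(us)]) / 2) / yl
  }
  total
}

expect_arm_close <- function(sim_row, arm_result, n_se = 3) {
  expect_lt(abs(sim_row$qaly_mean - arm_result$qaly_total),
            n_se * sim_row$qaly_se + 1e-12)
  expect_lt(abs(sim_row$cost_mean - arm_result$cost_total),
            n_se * sim_row$cost_se + 1e-12)
}
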