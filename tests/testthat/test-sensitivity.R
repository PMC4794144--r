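test_that("one-way analysis ranks by NMB span and handles dominance ends", {
  tor <- one_way(base, top = Inf)
  expect_true(!is.unsorted(rev(tor$nmb_span)))
  # retreatment interval: ICER in the right region at the low bound,
  # dominant at the high bound
  rt <- tor[tor$parameter_path == "costs.t_retreat_days", ]
  expect_gt(rt$icer_low, 5000)
  expect_lt(rt$icer_low, 12000)
  expect_equal(rt$result_high, "dominant")
  # a degenerate range has zero span and sorts last
  rng <- param_ranges(base)
  deg <- rng[rng$parameter_path == "costs.gp_visit_cost", ]
  deg$low <- deg$high <- deg$base
  tor_deg <- one_way(base, ranges = rbind(rng, deg), top = Inf)
  expect_equal(tor_deg$nmb_span[nrow(tor_deg)], 0)
  expect_equal(tor_deg$parameter_path[nrow(tor_deg)], "costs.gp_visit_cost")
})

test_that("threshold solving hits the target ICER and returns NA when unreachable", {
  x20 <- threshold_solve(base, "costs.t_retreat_days", 20000)
  expect_equal(x20, 77.43, tolerance = 0.01)  # relative
  # plugging the solution back reproduces the target ICER to < GBP 1/QALY
  ce <- evaluate_model(set_param(base, "costs.t_retreat_days", x20))
  expect_lt(abs(ce$icer - 20000), 1)
  x30 <- threshold_solve(base, "costs.t_retreat_days", 30000)
  expect_equal(x30, 60.46, tolerance = 0.01)
  expect_lt(x30, x20)  # tighter threshold needs faster retreatment
  # capsaicin response probability cannot push the ICER to the threshold
  # anywhere the patch still gains QALYs
  expect_true(is.na(threshold_solve(base, "therapies.capsaicin.p_response", 20000)))
  expect_true(is.na(threshold_solve(base, "therapies.pregabalin.u_increment", 20000)))
  # threshold table covers the leading parameters at both thresholds
  tt <- threshold_table(base, top = 4)
  expect_equal(nrow(tt), 4)
  expect_true(all(c("wtp_20000", "wtp_30000") %in% names(tt)))
})

test_that("zero pregabalin drug cost yields a five-figure ICER, not dominance", {
  ce <- evaluate_model(set_param(base, "costs.pregabalin_cost_per_tablet", 0))
  expect_equal(ce$quadrant, "NE")
  expect_gt(ce$icer, 12000)
  expect_lt(ce$icer, 25000)
})

test_that("PSA distribution fits respect domain bounds", {
  specs <- psa_dist_specs(base)
  expect_true(all(specs$family %in% c("beta", "gamma", "normal")))
  expect_false("discount_rate" %in% specs$parameter_path)
  # pregabalin response is sampled around its observed trial mean
  expect_equal(specs$mean[specs$parameter_path == "therapies.pregabalin.p_response"],
               0.5451)
  set.seed(99)
  for (j in seq_len(nrow(specs))) {
    x <- pnpcea:::draw_spec(specs[j, ], 500)
    if (specs$family[j] == "beta") expect_true(all(x >= 0 & x <= 1))
    if (specs$family[j] == "gamma") expect_true(all(x >= 0))
    if (specs$se[j] > 0)
      expect_lt(abs(mean(x) - specs$mean[j]), 5 * specs$se[j] / sqrt(500))
  }
})

test_that("PSA is seeded, rejects invalid draws, and degenerates to the base case", {
  specs <- psa_dist_specs(base)
  a <- run_psa(base, n = 300, seed = 11, specs = specs)
  b <- run_psa(base, n = 300, seed = 11, specs = specs)
  expect_identical(a$draws, b$draws)
  expect_identical(a$ceac, b$ceac)
  expect_true(all(a$ceac$probability >= 0 & a$ceac$probability <= 1))
  # CEAC at zero willingness-to-pay is the fraction of cost-saving draws
  expect_equal(a$ceac$probability[a$ceac$wtp == 0],
               mean(a$draws$delta_cost < 0))
  # all-degenerate distributions reproduce the deterministic base case
  # (the pregabalin response mean is pinned back to the equalized base-case
  # value, since the PSA deliberately samples it around the observed rate)
  d_specs <- specs
  d_specs$se <- 0
  d_specs$mean[d_specs$parameter_path == "therapies.pregabalin.p_response"] <-
    base$therapies$pregabalin$p_response
  d <- run_psa(base, n = 5, seed = 1, specs = d_specs)
  ce <- evaluate_model(base)
  expect_equal(d$draws$delta_cost, rep(ce$delta_cost, 5))
  expect_equal(d$draws$delta_qaly, rep(ce$delta_qaly, 5))
  # the gamma onset-time draws occasionally exceed the assessment window
  # and must be redrawn, not silently accepted
  big <- run_psa(base, n = 2000, seed = 3)
  expect_gt(big$n_rejected, 0)
  expect_true(all(is.finite(big$draws$delta_cost)))
})

test_that("CEAC is the empirical NMB-crossing distribution for QALY-gaining draws", {
  psa <- run_psa(base, n = 400, seed = 21)
  pos <- psa$draws[psa$draws$delta_qaly > 0, ]
  # restricted to QALY-gaining draws the curve is non-decreasing in wtp
  grid <- seq(0, 50000, by = 500)
  curve_pos <- vapply(grid, function(l) mean(l * pos$delta_qaly - pos$delta_cost > 0),
                      numeric(1))
  expect_true(!is.unsorted(curve_pos))
  # and equals the ECDF of the per-draw break-even willingness-to-pay
  breakeven <- pos$delta_cost / pos$delta_qaly
  expect_equal(curve_pos, vapply(grid, function(l) mean(breakeven < l), numeric(1)))
})

test_that("PSA means are stable across seeds within Monte Carlo error", {
  a <- run_psa(base, n = 1500, seed = 101)
  b <- run_psa(base, n = 1500, seed = 202)
  se_q <- sqrt(stats::var(a$draws$delta_qaly) / 1500 +
                 stats::var(b$draws$delta_qaly) / 1500)
  se_c <- sqrt(stats::var(a$draws$delta_cost) / 1500 +
                 stats::var(b$draws$delta_cost) / 1500)
  expect_lt(abs(a$mean_delta_qaly - b$mean_delta_qaly), 3 * se_q)
  expect_lt(abs(a$mean_delta_cost - b$mean_delta_cost), 3 * se_c)
})
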