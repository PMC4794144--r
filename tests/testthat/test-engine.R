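test_that("branch probabilities are a proper distribution in every arm", {
  for (arm in c("capsaicin", "pregabalin")) {
    br <- arm_branches(arm, base)
    expect_equal(sum(br$probability), 1, tolerance = 1e-12)
    expect_true(all(br$probability >= 0))
  }
  # response is conditional on not discontinuing
  br <- arm_branches("pregabalin", base)
  expect_equal(br$probability[br$kind == "responder"], (1 - 0.085) * 0.5567)
  expect_equal(sum(br$probability[grepl("^discontinuer", br$kind)]), 0.085)
  # property over random parameter sets
  for (s in 1:25) {
    p <- generate_random_params(s)
    for (arm in c("capsaicin", "pregabalin"))
      expect_equal(sum(arm_branches(arm, p)$probability), 1, tolerance = 1e-12)
  }
})

test_that("branch trajectories follow the assumed utility time-courses", {
  tr <- build_trajectory("capsaicin", "responder", base)
  expect_equal(tr$time[1:2], c(0, 7.5))
  expect_equal(tr$utility[1:2], c(0.57, 0.57 + 0.2284))
  expect_equal(trajectory_utility(tr, c(400, 730)), rep(0.7984, 2))  # constant after onset
  # last-line response steps in immediately after the assessment
  ll <- build_trajectory("pregabalin", "nonresponder_LLresp", base)
  expect_equal(trajectory_utility(ll, 55), 0.57)
  expect_equal(trajectory_utility(ll, 57), 0.57 + 0.2284)
  # last-line non-response stays at baseline
  nr <- build_trajectory("capsaicin", "nonresponder_LLnonresp", base)
  expect_equal(trajectory_utility(nr, c(0, 100, 730)), rep(0.57, 3))
  # zero effect means flat trajectories on every branch
  p0 <- base
  for (nm in names(p0$therapies)) p0$therapies[[nm]]$u_increment <- 0
  for (k in pnpcea:::BRANCH_KINDS) {
    t0 <- build_trajectory("capsaicin", k, p0)
    expect_equal(range(trajectory_utility(t0, seq(0, 730, by = 7))),
                 c(0.57, 0.57))
  }
  # onset later than the assessment cannot be classified as response
  expect_error(
    build_trajectory("pregabalin", "responder",
                     modifyList(base, list(assessment_days = 30))),
    "onset")
})

test_that("discounted QALY integration matches closed-form oracles", {
  # constant utility of 1: geometric sum of discount factors
  flat <- structure(list(time = 0, utility = 1), class = "pnp_trajectory")
  expect_equal(integrate_qaly(flat, base), sum(1.035^-(1:2)), tolerance = 1e-12)
  p_r0 <- set_param(base, "discount_rate", 0)
  expect_equal(integrate_qaly(flat, p_r0), 2)  # undiscounted identity
  # capsaicin responder: yearly means from the ramp-triangle closed form
  tr <- build_trajectory("capsaicin", "responder", base)
  y1 <- resp_year1_mean(0.57, 0.2284, 7.5)
  expect_equal(integrate_qaly(tr, base),
               y1 * df_base[1] + 0.7984 * df_base[2], tolerance = 1e-12)
  expect_equal(integrate_qaly(tr, base), 1.51444, tolerance = 1e-5)
  # last-line responder branch, closed form for the step at day 56
  ll <- build_trajectory("capsaicin", "nonresponder_LLresp", base)
  expect_equal(integrate_qaly(ll, base),
               ll_resp_year1_mean(0.57, 0.2284) * df_base[1] + 0.7984 * df_base[2],
               tolerance = 1e-8)
})

test_that("exact integration agrees with a fine-grid trapezoid oracle", {
  set.seed(42)
  for (rep in 1:8) {
    p <- generate_random_params(rep + 300)
    arm <- sample(c("capsaicin", "pregabalin"), 1)
    kind <- sample(pnpcea:::BRANCH_KINDS, 1)
    traj <- build_trajectory(arm, kind, p)
    expect_lt(abs(integrate_qaly(traj, p) - qaly_trapezoid(traj, p)), 1e-9)
  }
  # include a waning trajectory, the most segmented shape
  pw <- base
  pw$waning <- list(loss_fraction = 0.39, recovery_days = 14)
  tw <- build_trajectory("capsaicin", "responder", pw)
  expect_lt(abs(integrate_qaly(tw, pw) - qaly_trapezoid(tw, pw)), 1e-9)
})

test_that("QALYs are monotone in discount rate and utility increments", {
  rates <- c(0, 0.015, 0.035, 0.06, 0.1)
  q_by_rate <- vapply(rates, function(r) {
    evaluate_arm("capsaicin", set_param(base, "discount_rate", r))$qaly_total
  }, numeric(1))
  expect_true(all(diff(q_by_rate) < 0))
  incs <- seq(0, 0.26, length.out = 6)
  q_by_inc <- vapply(incs, function(u) {
    evaluate_arm("capsaicin",
                 set_param(base, "therapies.capsaicin.u_increment", u))$qaly_total
  }, numeric(1))
  expect_true(all(diff(q_by_inc) > 0))
})

test_that("branch costing follows the stated accrual conventions", {
  dc <- derived_costs(base)
  # pregabalin-arm expected visit cost: only AE discontinuers see GP + specialist
  preg <- evaluate_arm("pregabalin", base)
  expect_equal(preg$cost_visits, 0.085 * (45 + 125) * df_base[1], tolerance = 1e-12)
  expect_equal(round(preg$cost_visits), 14)
  expect_equal(evaluate_arm("capsaicin", base)$cost_visits, 0)
  # capsaicin responder, one undiscounted year: continuous application rate
  p1 <- set_param(set_param(base, "discount_rate", 0), "horizon_years", 1)
  cs <- branch_costs("capsaicin", "responder", p1)
  expect_equal(cs[["index"]], dc$capsaicin_per_application * 365 / 179,
               tolerance = 1e-12)
  # non-responders get exactly one application
  cs_nr <- branch_costs("capsaicin", "nonresponder_LLnonresp", base)
  expect_equal(cs_nr[["index"]], dc$capsaicin_per_application * df_base[1])
  # last-line drug cost accrues regardless of last-line response status
  expect_equal(branch_costs("capsaicin", "nonresponder_LLresp", base)[["lastline"]],
               branch_costs("capsaicin", "nonresponder_LLnonresp", base)[["lastline"]])
  expect_equal(cs_nr[["lastline"]],
               361.35 * (309 / 365) * df_base[1] + 361.35 * df_base[2])
  # pregabalin non-responders pay the assessment-period fraction only
  expect_equal(branch_costs("pregabalin", "nonresponder_LLresp", base)[["index"]],
               839.50 * 56 / 365 * df_base[1])
})

test_that("arm totals are component sums and equalized arms tie exactly", {
  for (arm in c("capsaicin", "pregabalin")) {
    r <- evaluate_arm(arm, base)
    expect_identical(r$cost_total,
                     r$cost_index_therapy + r$cost_lastline + r$cost_visits)
    expect_true(r$qaly_total >= 0 && r$qaly_total <= base$horizon_years)
  }
  # all efficacy/timing/utility/tolerability parameters zeroed: arms tie on QALYs
  p0 <- base
  for (nm in names(p0$therapies)) {
    p0$therapies[[nm]]$p_response <- 0
    p0$therapies[[nm]]$p_discontinue_ae <- 0
    p0$therapies[[nm]]$u_increment <- 0
  }
  expect_equal(evaluate_arm("capsaicin", p0)$qaly_total,
               evaluate_arm("pregabalin", p0)$qaly_total, tolerance = 1e-15)
  # expected values are linear in branch probabilities: weighted branch
  # detail reproduces the totals
  r <- evaluate_arm("pregabalin", base)
  expect_equal(sum(r$branches$probability * r$branches$qaly), r$qaly_total)
})

test_that("setting discontinuation to zero leaves the capsaicin arm bit-identical", {
  p <- set_param(base, "therapies.pregabalin.p_discontinue_ae", 0)
  expect_identical(evaluate_arm("capsaicin", p), evaluate_arm("capsaicin", base))
  expect_false(isTRUE(all.equal(evaluate_arm("pregabalin", p)$qaly_total,
                                evaluate_arm("pregabalin", base)$qaly_total)))
})

test_that("incremental comparison classifies every quadrant correctly", {
  mk <- function(cost, qaly, arm = "x")
    structure(list(arm = arm, cost_total = cost, qaly_total = qaly),
              class = "pnp_arm_result")
  # plain ICER arithmetic
  ce <- compare_arms(mk(1100, 1.05), mk(1000, 1.00))
  expect_equal(ce$icer, 100 / 0.05)
  expect_equal(ce$quadrant, "NE")
  # dominance
  expect_equal(compare_arms(mk(900, 1.1), mk(1000, 1.0))$label, "dominant")
  expect_equal(compare_arms(mk(1100, 0.9), mk(1000, 1.0))$label, "dominated")
  # south-west: ratio reported with quadrant label, not dominance
  sw <- compare_arms(mk(990, 0.99), mk(1000, 1.00))
  expect_equal(sw$icer, 1000)
  expect_equal(sw$quadrant, "SW")
  # zero QALY difference never yields a ratio
  zq <- compare_arms(mk(1100, 1.0), mk(1000, 1.0))
  expect_true(is.na(zq$icer))
  expect_match(zq$label, "no QALY difference")
  # net monetary benefit at the base case
  ce_base <- evaluate_model(base)
  expect_equal(nmb(ce_base, 20000),
               20000 * ce_base$delta_qaly - ce_base$delta_cost)
})

test_that("waning reshapes the capsaicin responder trajectory as specified", {
  pw <- base
  pw$waning <- list(loss_fraction = 0.39, recovery_days = 14)
  tr <- build_trajectory("capsaicin", "responder", pw)
  full <- 0.57 + 0.2284
  low <- 0.57 + 0.2284 * (1 - 0.39)
  # full effect holds up to the assessment day of cycle 1
  expect_equal(trajectory_utility(tr, c(7.5, 30, 56)), rep(full, 3))
  # linear decline reaches 61% of the increment at the retreatment day
  expect_equal(trajectory_utility(tr, 179), low)
  expect_equal(trajectory_utility(tr, (56 + 179) / 2), (full + low) / 2)
  # recovery completes within two weeks of retreatment, then holds
  expect_equal(trajectory_utility(tr, 193), full)
  expect_equal(trajectory_utility(tr, 220), full)
  # second cycle declines again
  expect_equal(trajectory_utility(tr, 358), low)
  # pregabalin responders are unaffected by waning
  expect_equal(unclass(build_trajectory("pregabalin", "responder", pw)),
               unclass(build_trajectory("pregabalin", "responder", base)))
})

test_that("the alternative discounting convention leaves year 1 undiscounted", {
  p_alt <- base
  p_alt$options$discounting <- "after_first"
  expect_equal(discount_factors(p_alt), c(1, 1.035^-1))
  expect_equal(discount_factors(base), 1.035^-(1:2))
  flat <- structure(list(time = 0, utility = 1), class = "pnp_trajectory")
  expect_equal(integrate_qaly(flat, p_alt), 1 + 1.035^-1)
})
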