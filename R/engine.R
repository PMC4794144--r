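# Deterministic expected-value evaluation of the decision tree.
#
# Each arm resolves into five terminal branches at the 8-week assessment:
# responder; non-responder with/without last-line response; discontinuer
# (intolerable AEs) with/without last-line response. Utility over time on a
# branch is piecewise linear; QALYs and costs are accrued per model year and
# discounted with year-indexed factors.

BRANCH_KINDS <- c("responder",
                  "nonresponder_LLresp", "nonresponder_LLnonresp",
                  "discontinuer_LLresp", "discontinuer_LLnonresp")

#' Terminal branches of one arm
#'
#' Response probability is conditional on not discontinuing; discontinuers
#' and non-responders both split by the last-line response probability.
#'
#' @param arm `"capsaicin"` or `"pregabalin"`.
#' @param params A `pnp_params`.
#' @return `data.frame` with columns `arm`, `kind`, `probability`
#'   (summing to 1).
#' @export
arm_branches <- function(arm, params) {
  th <- params$therapies[[arm]]
  if (is.null(th)) stop("unknown arm: ", arm, call. = FALSE)
  p_ll <- params$therapies$last_line$p_response
  pd <- th$p_discontinue_ae
  pr <- th$p_response
  prob <- c(
    responder               = (1 - pd) * pr,
    nonresponder_LLresp     = (1 - pd) * (1 - pr) * p_ll,
    nonresponder_LLnonresp  = (1 - pd) * (1 - pr) * (1 - p_ll),
    discontinuer_LLresp     = pd * p_ll,
    discontinuer_LLnonresp  = pd * (1 - p_ll)
  )
  data.frame(arm = arm, kind = names(prob), probability = unname(prob),
             stringsAsFactors = FALSE)
}

#' Utility trajectory for a terminal branch
#'
#' Responders ramp linearly from the baseline utility to baseline +
#' increment over the median time to onset, then stay there. Non-responders
#' and discontinuers stay at baseline until the assessment day; those who
#' then respond to last-line therapy step immediately to baseline + the
#' last-line increment, the rest remain at baseline. With waning active,
#' capsaicin responders cycle over the retreatment interval: full effect
#' until the assessment day of each cycle, linear decline to
#' `1 - loss_fraction` of the increment by cycle end, recovery to full over
#' `recovery_days` after retreatment.
#'
#' @param arm `"capsaicin"` or `"pregabalin"`.
#' @param kind One of the five terminal branch kinds (see [arm_branches()]).
#' @param params A `pnp_params`.
#' @return Object of class `pnp_trajectory`: a list with `time` (days,
#'   strictly increasing from 0) and `utility` breakpoints; piecewise
#'   linear between breakpoints, constant after the last.
#' @export
build_trajectory <- function(arm, kind, params) {
  u0 <- params$baseline_utility
  th <- params$therapies[[arm]]
  if (is.null(th)) stop("unknown arm: ", arm, call. = FALSE)
  if (!kind %in% BRANCH_KINDS) stop("unknown branch kind: ", kind, call. = FALSE)
  a_day <- params$assessment_days
  h_days <- params$horizon_years * params$year_length_days

  if (kind == "responder") {
    if (th$t_onset_days > a_day)
      stop("t_onset_days exceeds assessment_days: response onset must ",
           "complete before response is classified", call. = FALSE)
    full <- u0 + th$u_increment
    if (arm == "capsaicin" && !is.null(params$waning) && th$u_increment > 0) {
      w <- params$waning
      tr <- params$costs$t_retreat_days
      low <- u0 + th$u_increment * (1 - w$loss_fraction)
      tt <- 0; uu <- u0
      s <- 0
      while (s < h_days) {
        if (s == 0) {
          if (th$t_onset_days > 0) { tt <- c(tt, th$t_onset_days); uu <- c(uu, full) }
          else uu[1] <- full
        } else {
          rec_end <- min(s + w$recovery_days, s + a_day)
          tt <- c(tt, rec_end); uu <- c(uu, full)
        }
        decline_start <- s + a_day
        if (decline_start < s + tr) {
          tt <- c(tt, decline_start, s + tr)
          uu <- c(uu, full, low)
        } else {
          tt <- c(tt, s + tr); uu <- c(uu, low)
        }
        s <- s + tr
      }
      keep <- !duplicated(tt)
      traj <- list(time = tt[keep], utility = uu[keep])
    } else {
      if (th$t_onset_days > 0)
        traj <- list(time = c(0, th$t_onset_days), utility = c(u0, full))
      else
        traj <- list(time = 0, utility = full)
    }
  } else if (kind %in% c("nonresponder_LLresp", "discontinuer_LLresp")) {
    u_ll <- u0 + params$therapies$last_line$u_increment
    # step at the assessment day: last-line response is immediate
    eps <- 1e-9
    traj <- list(time = c(0, a_day, a_day + eps), utility = c(u0, u0, u_ll))
  } else {
    traj <- list(time = 0, utility = u0)
  }
  stopifnot(all(diff(traj$time) > 0), all(traj$utility >= 0 & traj$utility <= 1))
  structure(traj, class = "pnp_trajectory")
}

#' Evaluate a trajectory at arbitrary times
#'
#' @param traj A `pnp_trajectory`.
#' @param t Numeric vector of times in days.
#' @return Utility values (constant extrapolation beyond the breakpoints).
#' @export
trajectory_utility <- function(traj, t) {
  if (length(traj$time) == 1) return(rep(traj$utility, length(t)))
  stats::approx(traj$time, traj$utility, xout = t, rule = 2)$y
}

# exact integral of the piecewise-linear trajectory over [a, b]
pl_integral <- function(traj, a, b) {
  if (b <= a) return(0)
  knots <- traj$time[traj$time > a & traj$time < b]
  ts <- c(a, knots, b)
  us <- trajectory_utility(traj, ts)
  sum(diff(ts) * (us[-length(us)] + us[-1]) / 2)
}

#' Year-indexed discount factors
#'
#' Under the default `"all_years"` convention year y receives
#' (1+r)^-y for y = 1..H; under `"after_first"` year 1 is undiscounted and
#' year y receives (1+r)^-(y-1).
#'
#' @param params A `pnp_params`.
#' @return Numeric vector of length `horizon_years`.
#' @export
discount_factors <- function(params) {
  y <- seq_len(params$horizon_years)
  r <- params$discount_rate
  if (params$options$discounting == "all_years") (1 + r)^(-y) else (1 + r)^(-(y - 1))
}

#' Discounted QALYs of a utility trajectory
#'
#' QALY = sum over model years of the discount factor times the exact
#' integral of the piecewise-linear utility over that year divided by the
#' year length. No time grid is involved; integration is exact on the
#' segments.
#'
#' @param traj A `pnp_trajectory`.
#' @param params A `pnp_params`.
#' @return Discounted QALYs (scalar).
#' @export
integrate_qaly <- function(traj, params) {
  yl <- params$year_length_days
  df <- discount_factors(params)
  yr <- vapply(seq_len(params$horizon_years), function(y) {
    pl_integral(traj, (y - 1) * yl, y * yl) / yl
  }, numeric(1))
  sum(df * yr)
}

#' Discounted cost components of a terminal branch
#'
#' Costing conventions:
#' * capsaicin responders incur the per-application cost at the continuous
#'   rate `year_length_days / t_retreat_days` applications per year, every
#'   model year;
#' * capsaicin non-responders and discontinuers incur exactly one
#'   application, in year 1;
#' * pregabalin responders incur the full per-annum drug cost every year;
#'   pregabalin non-responders (and discontinuers, times the
#'   `discontinuer_drug_fraction` option) incur the assessment-period
#'   fraction of it in year 1 only;
#' * all non-responder/discontinuer branches incur last-line drug cost
#'   from the assessment day: the remaining-year fraction in year 1 and
#'   the full per-annum cost in later years, regardless of last-line
#'   response;
#' * discontinuers incur one GP plus one pain-specialist visit in year 1.
#'
#' @param arm `"capsaicin"` or `"pregabalin"`.
#' @param kind Terminal branch kind.
#' @param params A `pnp_params`.
#' @return Named numeric vector: `index` (index-therapy drug/application
#'   cost), `lastline`, `visits` — discounted GBP.
#' @export
branch_costs <- function(arm, kind, params) {
  dc <- derived_costs(params)
  df <- discount_factors(params)
  yl <- params$year_length_days
  a_day <- params$assessment_days
  is_disc <- grepl("^discontinuer", kind)
  is_resp <- kind == "responder"

  index <- 0
  if (arm == "capsaicin") {
    per_app <- dc$capsaicin_per_application
    if (is_resp) {
      index <- per_app * (yl / params$costs$t_retreat_days) * sum(df)
    } else {
      index <- per_app * df[1]
    }
    if (isTRUE(params$anesthesia) && params$options$anesthesia_mode == "first") {
      # "first"-application variant: anesthesia charged once, at entry
      index <- index + dc$anesthesia_per_application * df[1]
    }
  } else if (arm == "pregabalin") {
    pa <- dc$pregabalin_per_annum
    if (is_resp) {
      index <- pa * sum(df)
    } else {
      frac <- a_day / yl
      if (is_disc) frac <- frac * params$options$discontinuer_drug_fraction
      index <- pa * frac * df[1]
    }
  } else stop("unknown arm: ", arm, call. = FALSE)

  lastline <- 0
  if (!is_resp) {
    ll <- dc$lastline_per_annum
    lastline <- ll * ((yl - a_day) / yl) * df[1] +
      if (params$horizon_years > 1) ll * sum(df[-1]) else 0
  }

  visits <- if (is_disc) dc$visit_cost * df[1] else 0
  c(index = unname(index), lastline = unname(lastline), visits = unname(visits))
}

#' Evaluate one treatment arm
#'
#' Probability-weighted, discounted expectation over the five terminal
#' branches of the decision tree.
#'
#' @param arm `"capsaicin"` or `"pregabalin"`.
#' @param params A `pnp_params`.
#' @return Object of class `pnp_arm_result`: per-patient expected
#'   discounted cost components (`cost_index_therapy`, `cost_lastline`,
#'   `cost_visits`, `cost_total`), `qaly_total`, and a per-branch detail
#'   `data.frame` (`branches`).
#' @export
evaluate_arm <- function(arm, params) {
  br <- arm_branches(arm, params)
  stopifnot(abs(sum(br$probability) - 1) < 1e-12)
  detail <- do.call(rbind, lapply(seq_len(nrow(br)), function(i) {
    kind <- br$kind[i]
    traj <- build_trajectory(arm, kind, params)
    cs <- branch_costs(arm, kind, params)
    data.frame(kind = kind, probability = br$probability[i],
               qaly = integrate_qaly(traj, params),
               cost_index = cs[["index"]], cost_lastline = cs[["lastline"]],
               cost_visits = cs[["visits"]], stringsAsFactors = FALSE)
  }))
  w <- detail$probability
  out <- list(
    arm = arm,
    cost_index_therapy = sum(w * detail$cost_index),
    cost_lastline = sum(w * detail$cost_lastline),
    cost_visits = sum(w * detail$cost_visits),
    qaly_total = sum(w * detail$qaly),
    branches = detail
  )
  out$cost_total <- out$cost_index_therapy + out$cost_lastline + out$cost_visits
  class(out) <- "pnp_arm_result"
  out
}

#' Incremental cost-effectiveness comparison
#'
#' Computes incremental cost and QALYs of `a` versus `b` and classifies the
#' result: `"dominant"` (cheaper and more effective), `"dominated"` (more
#' costly and less effective), an ICER with its cost-effectiveness-plane
#' quadrant otherwise, or `"no QALY difference"` when the QALY delta is
#' exactly zero.
#'
#' @param a,b `pnp_arm_result` objects evaluated under the same parameters
#'   (`a` is the intervention, `b` the comparator).
#' @return Object of class `pnp_ce_result` with `delta_cost`, `delta_qaly`,
#'   `icer` (`NA` under dominance or zero QALY delta), `label`, `quadrant`,
#'   and the two arm results.
#' @export
compare_arms <- function(a, b) {
  dc <- a$cost_total - b$cost_total
  dq <- a$qaly_total - b$qaly_total
  if (dq > 0 && dc < 0) {
    label <- "dominant"; icer <- NA_real_; quad <- "SE"
  } else if (dq < 0 && dc > 0) {
    label <- "dominated"; icer <- NA_real_; quad <- "NW"
  } else if (dq == 0) {
    label <- "no QALY difference"; icer <- NA_real_
    quad <- if (dc == 0) "origin" else if (dc > 0) "N" else "S"
  } else {
    icer <- dc / dq
    quad <- if (dq > 0) "NE" else "SW"
    label <- sprintf("ICER %.0f (%s)", icer, quad)
  }
  structure(list(delta_cost = dc, delta_qaly = dq, icer = icer,
                 label = label, quadrant = quad,
                 intervention = a, comparator = b),
            class = "pnp_ce_result")
}

#' Evaluate both arms and compare
#'
#' Convenience wrapper: capsaicin 8% patch versus pregabalin under one
#' parameter set.
#'
#' @param params A `pnp_params`.
#' @return A `pnp_ce_result`.
#' @export
evaluate_model <- function(params = base_params()) {
  compare_arms(evaluate_arm("capsaicin", params),
               evaluate_arm("pregabalin", params))
}

#' Net monetary benefit
#'
#' @param ce A `pnp_ce_result`.
#' @param wtp Willingness-to-pay threshold, GBP per QALY.
#' @return `wtp * delta_qaly - delta_cost` (GBP).
#' @export
nmb <- function(ce, wtp) wtp * ce$delta_qaly - ce$delta_cost

#' @export
print.pnp_arm_result <- function(x, ...) {
  cat(sprintf("Arm: %s\n", x$arm))
  cat(sprintf("  index therapy cost  GBP %8.2f\n", x$cost_index_therapy))
  cat(sprintf("  last-line cost      GBP %8.2f\n", x$cost_lastline))
  cat(sprintf("  GP/specialist cost  GBP %8.2f\n", x$cost_visits))
  cat(sprintf("  total cost          GBP %8.2f\n", x$cost_total))
  cat(sprintf("  total QALYs         %12.4f\n", x$qaly_total))
  invisible(x)
}

#' @export
print.pnp_ce_result <- function(x, ...) {
  cat(sprintf("%s vs %s\n", x$intervention$arm, x$comparator$arm))
  cat(sprintf("  incremental cost : GBP %.2f\n", x$delta_cost))
  cat(sprintf("  incremental QALYs: %.4f\n", x$delta_qaly))
  if (is.na(x$icer)) cat(sprintf("  result           : %s\n", x$label))
  else cat(sprintf("  ICER             : GBP %.0f per QALY (%s quadrant)\n",
                   x$icer, x$quadrant))
  invisible(x)
}
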