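# Named scenario analyses and the structural (time-horizon) sweep.

#' Scenario definition
#'
#' A scenario is a named set of parameter-path overrides plus optional
#' structural flags (waning on, topical anesthesia on). Applying a scenario
#' never mutates the base parameters.
#'
#' @param name Scenario label.
#' @param overrides Named list mapping dotted parameter paths (see
#'   [set_param()]) to replacement values. A value may also be a function
#'   of the base `pnp_params`, evaluated at application time (used to copy
#'   one arm's value onto the other).
#' @param waning `NULL` or a waning record to enable.
#' @param anesthesia Logical; enable topical anesthesia costing.
#' @return Object of class `pnp_scenario`.
#' @export
scenario <- function(name, overrides = list(), waning = NULL, anesthesia = FALSE) {
  structure(list(name = name, overrides = overrides, waning = waning,
                 anesthesia = anesthesia),
            class = "pnp_scenario")
}

#' Built-in scenario registry
#'
#' The seven named scenarios of the analysis:
#' \describe{
#'   \item{difference_in_clinical_efficacy}{pregabalin response restored to
#'     its observed trial value (54.51%) instead of the equalized base-case
#'     rate.}
#'   \item{equal_time_to_response}{pregabalin onset set to the capsaicin
#'     7.5 days.}
#'   \item{no_discontinuation}{pregabalin AE discontinuation set to 0%.}
#'   \item{equal_response_utilities}{pregabalin response-utility increment
#'     set to the capsaicin value.}
#'   \item{all_equalized}{all four differences removed at once; the QALY
#'     delta is then exactly zero.}
#'   \item{waning}{39% of the capsaicin response increment lost linearly
#'     between retreatments, restored within two weeks of retreatment.}
#'   \item{topical_anesthesia}{lidocaine cream + occlusive film charged
#'     with capsaicin applications.}
#' }
#'
#' @return Named list of `pnp_scenario` objects.
#' @export
scenario_registry <- function() {
  cap <- function(field) function(p) p$therapies$capsaicin[[field]]
  list(
    difference_in_clinical_efficacy = scenario(
      "difference_in_clinical_efficacy",
      overrides = list("therapies.pregabalin.p_response" =
                         function(p) p$therapies$pregabalin$p_response_observed)),
    equal_time_to_response = scenario(
      "equal_time_to_response",
      overrides = list("therapies.pregabalin.t_onset_days" = cap("t_onset_days"))),
    no_discontinuation = scenario(
      "no_discontinuation",
      overrides = list("therapies.pregabalin.p_discontinue_ae" = 0)),
    equal_response_utilities = scenario(
      "equal_response_utilities",
      overrides = list("therapies.pregabalin.u_increment" = cap("u_increment"))),
    all_equalized = scenario(
      "all_equalized",
      overrides = list(
        "therapies.pregabalin.p_response" = cap("p_response"),
        "therapies.pregabalin.t_onset_days" = cap("t_onset_days"),
        "therapies.pregabalin.p_discontinue_ae" = 0,
        "therapies.pregabalin.u_increment" = cap("u_increment"))),
    waning = scenario(
      "waning", waning = list(loss_fraction = 0.39, recovery_days = 14)),
    topical_anesthesia = scenario("topical_anesthesia", anesthesia = TRUE)
  )
}

#' Apply a scenario to a parameter set
#'
#' @param s A `pnp_scenario` or the name of a registry scenario.
#' @param params Base `pnp_params` (untouched).
#' @return A new, validated `pnp_params`.
#' @export
apply_scenario <- function(s, params) {
  if (is.character(s)) {
    reg <- scenario_registry()
    if (!s %in% names(reg)) stop("unknown scenario: ", s, call. = FALSE)
    s <- reg[[s]]
  }
  out <- params
  for (path in names(s$overrides)) {
    v <- s$overrides[[path]]
    if (is.function(v)) v <- v(params)
    out <- set_param(out, path, v)
  }
  if (!is.null(s$waning)) out$waning <- s$waning
  if (isTRUE(s$anesthesia)) out$anesthesia <- TRUE
  validate_params(out)
}

#' Run one scenario
#'
#' @param s A `pnp_scenario` or registry scenario name.
#' @param params Base `pnp_params`.
#' @return List with `name`, both `pnp_arm_result`s and the `pnp_ce_result`.
#' @export
run_scenario <- function(s, params = base_params()) {
  p2 <- apply_scenario(s, params)
  ce <- evaluate_model(p2)
  nm <- if (is.character(s)) s else s$name
  list(name = nm, capsaicin = ce$intervention, pregabalin = ce$comparator,
       ce = ce)
}

#' Run the full scenario suite
#'
#' Base case plus the seven registry scenarios, one row each, in the layout
#' of the scenario results table (arm costs and QALYs, increments,
#' ICER/dominance).
#'
#' @param params Base `pnp_params`.
#' @return `data.frame`, one row per scenario.
#' @export
run_scenarios <- function(params = base_params()) {
  runs <- c(list(list(name = "base_case",
                      ce = evaluate_model(params))),
            lapply(names(scenario_registry()),
                   function(nm) run_scenario(nm, params)))
  do.call(rbind, lapply(runs, function(r) {
    ce <- r$ce
    data.frame(
      scenario = r$name,
      cost_capsaicin = ce$intervention$cost_total,
      cost_pregabalin = ce$comparator$cost_total,
      qaly_capsaicin = ce$intervention$qaly_total,
      qaly_pregabalin = ce$comparator$qaly_total,
      delta_cost = ce$delta_cost,
      delta_qaly = ce$delta_qaly,
      icer = ce$icer,
      result = ce$label,
      stringsAsFactors = FALSE
    )
  }))
}

#' Structural analysis: time-horizon sweep
#'
#' Re-evaluates both arms for each horizon, with constant extrapolation of
#' health-state utilities and costs beyond year 1 and year-indexed
#' discounting.
#'
#' @param params Base `pnp_params`.
#' @param years Integer vector of horizons (each >= 1).
#' @return `data.frame`, one row per horizon with arm totals, increments
#'   and ICER/dominance.
#' @export
horizon_sweep <- function(params = base_params(), years = 1:10) {
  stopifnot(all(years >= 1), all(years == round(years)))
  do.call(rbind, lapply(years, function(h) {
    ce <- evaluate_model(set_param(params, "horizon_years", h))
    data.frame(horizon_years = h,
               cost_capsaicin = ce$intervention$cost_total,
               cost_pregabalin = ce$comparator$cost_total,
               qaly_capsaicin = ce$intervention$qaly_total,
               qaly_pregabalin = ce$comparator$qaly_total,
               delta_cost = ce$delta_cost, delta_qaly = ce$delta_qaly,
               icer = ce$icer, result = ce$label, stringsAsFactors = FALSE)
  }))
}
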