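#' Therapy profile
#'
#' Bundle of efficacy, tolerability and timing parameters for one treatment
#' strategy in the decision tree.
#'
#' @param name One of `"capsaicin"`, `"pregabalin"`, `"last_line"`.
#' @param p_response Probability of response (>= 30% reduction in the
#'   24-hour average numeric pain rating scale score) at the 8-week
#'   assessment, conditional on not discontinuing.
#' @param p_discontinue_ae Probability of discontinuation due to intolerable
#'   adverse events before the assessment.
#' @param t_onset_days Median time to onset of response in days; utility
#'   ramps linearly from baseline to the response level over this period.
#' @param u_increment Additive utility gain on response (change from the
#'   baseline no-response utility).
#' @param p_response_observed Optional observed response probability kept
#'   alongside an equalized base-case value (used by the clinical-efficacy
#'   scenario); defaults to `p_response`.
#'
#' @return A list of class `pnp_therapy`.
#' @export
therapy_profile <- function(name, p_response, p_discontinue_ae = 0,
                            t_onset_days = 0, u_increment = 0,
                            p_response_observed = NULL) {
  out <- list(
    name = name,
    p_response = p_response,
    p_discontinue_ae = p_discontinue_ae,
    t_onset_days = t_onset_days,
    u_increment = u_increment,
    p_response_observed = if (is.null(p_response_observed)) p_response else p_response_observed
  )
  class(out) <- "pnp_therapy"
  out
}

#' Unit costs and resource-use inputs
#'
#' All monetary values are GBP (2013/14 prices). The capsaicin
#' per-application cost is derived, never stored: patch acquisition
#' (unit cost x mean patches per treatment) plus nurse time (hourly rate x
#' contact hours) plus a pair of nitrile gloves, plus optional topical
#' anesthesia when that scenario is switched on.
#'
#' @param patch_unit_cost GBP per capsaicin patch.
#' @param mean_patches_per_treatment Mean number of patches used per
#'   treatment (fractional). Held at full precision 1.3830 so that the
#'   acquisition cost per treatment works out exactly.
#' @param nurse_hourly_rate GBP per hour for the applying (band 6) nurse.
#' @param nurse_contact_hours Patient contact time per application, hours.
#' @param gloves_cost GBP per pair of nitrile gloves.
#' @param anesthesia_cost_per_application GBP for lidocaine 4% cream plus
#'   occlusive film; charged only when the anesthesia scenario is active.
#' @param pregabalin_cost_per_tablet,pregabalin_doses_per_day Pregabalin
#'   tablet price (flat across strengths) and daily dosing frequency.
#' @param lastline_cost_per_tablet,lastline_doses_per_day Last-line therapy
#'   (duloxetine proxy) tablet price and daily dosing frequency.
#' @param gp_visit_cost,specialist_visit_cost GBP per GP consultation and
#'   per pain-specialist follow-up visit (incurred once by discontinuers).
#' @param t_retreat_days Mean time between capsaicin retreatments among
#'   responders, days.
#'
#' @return A list of class `pnp_costs`.
#' @export
cost_inputs <- function(patch_unit_cost = 210,
                        mean_patches_per_treatment = 1.3830,
                        nurse_hourly_rate = 119,
                        nurse_contact_hours = 0.5,
                        gloves_cost = 0.06,
                        anesthesia_cost_per_application = 34.19,
                        pregabalin_cost_per_tablet = 1.15,
                        pregabalin_doses_per_day = 2,
                        lastline_cost_per_tablet = 0.99,
                        lastline_doses_per_day = 1,
                        gp_visit_cost = 45,
                        specialist_visit_cost = 125,
                        t_retreat_days = 179) {
  out <- list(
    patch_unit_cost = patch_unit_cost,
    mean_patches_per_treatment = mean_patches_per_treatment,
    nurse_hourly_rate = nurse_hourly_rate,
    nurse_contact_hours = nurse_contact_hours,
    gloves_cost = gloves_cost,
    anesthesia_cost_per_application = anesthesia_cost_per_application,
    pregabalin_cost_per_tablet = pregabalin_cost_per_tablet,
    pregabalin_doses_per_day = pregabalin_doses_per_day,
    lastline_cost_per_tablet = lastline_cost_per_tablet,
    lastline_doses_per_day = lastline_doses_per_day,
    gp_visit_cost = gp_visit_cost,
    specialist_visit_cost = specialist_visit_cost,
    t_retreat_days = t_retreat_days
  )
  class(out) <- "pnp_costs"
  out
}

#' Full model parameter set
#'
#' The defaults ARE the base case: equalized 55.67% response in both arms
#' (non-inferiority assumption; the observed pregabalin 54.51% is retained
#' for the clinical-efficacy scenario), 8.5% pregabalin discontinuation,
#' onset of response at 7.5 / 36 days, baseline utility 0.57 with
#' response increments 0.2284 (capsaicin, also assumed for last-line
#' response) and 0.1989 (pregabalin), 20% last-line response, 3.5% annual
#' discounting over a 2-year horizon with an 8-week (56-day) response
#' assessment.
#'
#' @param baseline_utility Utility of the no-response health state.
#' @param therapies Named list of three [therapy_profile()] records:
#'   `capsaicin`, `pregabalin`, `last_line`.
#' @param costs A [cost_inputs()] record.
#' @param discount_rate Annual discount rate applied to costs and QALYs.
#' @param horizon_years Model time horizon in whole years (>= 1).
#' @param assessment_days Day of the response assessment (8 weeks = 56).
#' @param year_length_days Days per model year (365).
#' @param waning `NULL`, or `list(loss_fraction =, recovery_days =)` to
#'   switch on waning of the capsaicin response between retreatments:
#'   the utility increment declines linearly from the assessment day of
#'   each retreatment cycle to `1 - loss_fraction` of its value at cycle
#'   end, then recovers to full over `recovery_days`.
#' @param anesthesia Logical; charge topical anesthesia with capsaicin
#'   applications (scenario analysis only).
#' @param options List of modelling-convention switches:
#'   `discounting` (`"all_years"`: every model year y gets factor
#'   (1+r)^-y; `"after_first"`: year 1 undiscounted),
#'   `anesthesia_mode` (`"all"` applications or `"first"` only), and
#'   `discontinuer_drug_fraction` (fraction of the assessment-period index
#'   drug cost charged to discontinuers).
#'
#' @return A validated list of class `pnp_params`.
#' @seealso [load_config()], [derived_costs()], [evaluate_arm()]
#' @export
model_params <- function(baseline_utility = 0.57,
                         therapies = list(
                           capsaicin = therapy_profile("capsaicin",
                             p_response = 0.5567, p_discontinue_ae = 0,
                             t_onset_days = 7.5, u_increment = 0.2284),
                           pregabalin = therapy_profile("pregabalin",
                             p_response = 0.5567, p_discontinue_ae = 0.085,
                             t_onset_days = 36, u_increment = 0.1989,
                             p_response_observed = 0.5451),
                           last_line = therapy_profile("last_line",
                             p_response = 0.20, p_discontinue_ae = 0,
                             t_onset_days = 0, u_increment = 0.2284)
                         ),
                         costs = cost_inputs(),
                         discount_rate = 0.035,
                         horizon_years = 2,
                         assessment_days = 56,
                         year_length_days = 365,
                         waning = NULL,
                         anesthesia = FALSE,
                         options = list()) {
  opts <- list(discounting = "all_years",
               anesthesia_mode = "all",
               discontinuer_drug_fraction = 1)
  opts[names(options)] <- options
  params <- list(
    baseline_utility = baseline_utility,
    therapies = therapies,
    costs = costs,
    discount_rate = discount_rate,
    horizon_years = horizon_years,
    assessment_days = assessment_days,
    year_length_days = year_length_days,
    waning = waning,
    anesthesia = anesthesia,
    options = opts
  )
  class(params) <- "pnp_params"
  validate_params(params)
}

#' Validate a parameter set
#'
#' Checks every structural invariant (probabilities in \[0,1\], utilities in
#' \[0,1\], non-negative costs and times, onset completing before the
#' assessment, positive retreatment interval) and fails with the offending
#' field named.
#'
#' @param params A `pnp_params` object (or plain list with its structure).
#' @return The validated `pnp_params`, invisibly usable in a pipe.
#' @export
validate_params <- function(params) {
  fail <- function(field, msg) {
    stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
  }
  chk_prob <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      fail(field, "must be a probability in [0, 1]")
  }
  chk_nonneg <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0)
      fail(field, "must be a single non-negative number")
  }
  chk_prob(params$baseline_utility, "baseline_utility")
  if (!is.numeric(params$discount_rate) || params$discount_rate < 0)
    fail("discount_rate", "must be >= 0")
  if (!is.numeric(params$horizon_years) || params$horizon_years < 1 ||
      params$horizon_years != round(params$horizon_years))
    fail("horizon_years", "must be an integer >= 1")
  if (params$assessment_days <= 0 || params$assessment_days >= params$year_length_days)
    fail("assessment_days", "must lie strictly inside the first model year")
  for (nm in c("capsaicin", "pregabalin", "last_line")) {
    th <- params$therapies[[nm]]
    if (is.null(th)) fail(paste0("therapies.", nm), "missing therapy profile")
    chk_prob(th$p_response, paste0("therapies.", nm, ".p_response"))
    chk_prob(th$p_discontinue_ae, paste0("therapies.", nm, ".p_discontinue_ae"))
    chk_nonneg(th$t_onset_days, paste0("therapies.", nm, ".t_onset_days"))
    chk_nonneg(th$u_increment, paste0("therapies.", nm, ".u_increment"))
    if (params$baseline_utility + th$u_increment > 1 + 1e-12)
      fail(paste0("therapies.", nm, ".u_increment"),
           "baseline utility plus increment exceeds 1")
    if (nm != "last_line" && th$t_onset_days > params$assessment_days)
      fail(paste0("therapies.", nm, ".t_onset_days"),
           "response onset must complete before the 8-week assessment")
  }
  cost_fields <- setdiff(names(params$costs), "t_retreat_days")
  for (nm in cost_fields) chk_nonneg(params$costs[[nm]], paste0("costs.", nm))
  if (!is.numeric(params$costs$t_retreat_days) || params$costs$t_retreat_days <= 0)
    fail("costs.t_retreat_days", "must be > 0")
  if (!is.null(params$waning)) {
    chk_prob(params$waning$loss_fraction, "waning.loss_fraction")
    chk_nonneg(params$waning$recovery_days, "waning.recovery_days")
  }
  if (!params$options$discounting %in% c("all_years", "after_first"))
    fail("options.discounting", "must be 'all_years' or 'after_first'")
  if (!params$options$anesthesia_mode %in% c("all", "first"))
    fail("options.anesthesia_mode", "must be 'all' or 'first'")
  chk_prob(params$options$discontinuer_drug_fraction,
           "options.discontinuer_drug_fraction")
  params
}

#' Base-case parameter set
#'
#' @return The base-case `pnp_params` (identical to `model_params()` with
#'   all defaults).
#' @export
base_params <- function() model_params()

# ---- config file I/O --------------------------------------------------------

config_template <- function() {
  # canonical nesting of the YAML config; used for schema checking
  list(
    baseline_utility = NULL,
    therapies = list(
      capsaicin = list(p_response = NULL, p_discontinue_ae = NULL,
                       t_onset_days = NULL, u_increment = NULL,
                       p_response_observed = NULL),
      pregabalin = list(p_response = NULL, p_discontinue_ae = NULL,
                        t_onset_days = NULL, u_increment = NULL,
                        p_response_observed = NULL),
      last_line = list(p_response = NULL, p_discontinue_ae = NULL,
                       t_onset_days = NULL, u_increment = NULL,
                       p_response_observed = NULL)
    ),
    costs = as.list(unclass(cost_inputs()))[names(cost_inputs())],
    discount_rate = NULL, horizon_years = NULL, assessment_days = NULL,
    year_length_days = NULL, waning = NULL, anesthesia = NULL,
    options = list(discounting = NULL, anesthesia_mode = NULL,
                   discontinuer_drug_fraction = NULL)
  )
}

#' Load a model configuration file
#'
#' Reads a YAML configuration whose keys mirror the model's parameter
#' tables, validates every invariant, and returns a `pnp_params`. Unknown
#' keys are reported with a warning (and ignored); missing required fields
#' raise an error naming the field. Optional blocks (`waning`,
#' `anesthesia`, `options`, `p_response_observed`) may be omitted.
#'
#' @param path Path to a YAML config, e.g. the bundled base case
#'   `system.file("extdata", "base_case.yaml", package = "pnpcea")`.
#' @return A validated `pnp_params`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)

  known_top <- names(config_template())
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown))
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "),
            call. = FALSE)

  req <- function(x, field) {
    if (is.null(x)) stop("config is missing required field `", field, "`",
                         call. = FALSE)
    x
  }
  therapies <- list()
  for (nm in c("capsaicin", "pregabalin", "last_line")) {
    t_raw <- req(raw$therapies[[nm]], paste0("therapies.", nm))
    known <- names(config_template()$therapies[[nm]])
    bad <- setdiff(names(t_raw), known)
    if (length(bad))
      warning("ignoring unknown keys under therapies.", nm, ": ",
              paste(bad, collapse = ", "), call. = FALSE)
    therapies[[nm]] <- therapy_profile(
      name = nm,
      p_response = req(t_raw$p_response, paste0("therapies.", nm, ".p_response")),
      p_discontinue_ae = req(t_raw$p_discontinue_ae,
                             paste0("therapies.", nm, ".p_discontinue_ae")),
      t_onset_days = req(t_raw$t_onset_days, paste0("therapies.", nm, ".t_onset_days")),
      u_increment = req(t_raw$u_increment, paste0("therapies.", nm, ".u_increment")),
      p_response_observed = t_raw$p_response_observed
    )
  }
  c_raw <- req(raw$costs, "costs")
  known_costs <- names(cost_inputs())
  bad <- setdiff(names(c_raw), known_costs)
  if (length(bad))
    warning("ignoring unknown keys under costs: ", paste(bad, collapse = ", "),
            call. = FALSE)
  for (nm in known_costs) req(c_raw[[nm]], paste0("costs.", nm))
  costs <- do.call(cost_inputs, c_raw[known_costs])

  model_params(
    baseline_utility = req(raw$baseline_utility, "baseline_utility"),
    therapies = therapies,
    costs = costs,
    discount_rate = req(raw$discount_rate, "discount_rate"),
    horizon_years = req(raw$horizon_years, "horizon_years"),
    assessment_days = req(raw$assessment_days, "assessment_days"),
    year_length_days = req(raw$year_length_days, "year_length_days"),
    waning = raw$waning,
    anesthesia = isTRUE(raw$anesthesia),
    options = if (is.null(raw$options)) list() else raw$options
  )
}

#' Write a parameter set to a YAML config
#'
#' Inverse of [load_config()]: `load_config(write_config(p, f))` restores
#' `p` exactly.
#'
#' @param params A `pnp_params`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  out <- strip(params)
  out$therapies <- lapply(out$therapies, function(th) th[setdiff(names(th), "name")])
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

# ---- derived costs ----------------------------------------------------------

#' Derived cost summary
#'
#' Computes the costs the model actually charges from the unit inputs:
#' capsaicin acquisition per treatment (patch price x mean patches), the
#' full per-application cost (acquisition + nurse time + gloves, plus
#' anesthesia when active), and annual drug costs (tablet price x doses
#' per day x days per year).
#'
#' @param params A `pnp_params`.
#' @return A list with elements `capsaicin_acquisition_per_treatment`,
#'   `capsaicin_per_application`, `anesthesia_per_application`,
#'   `pregabalin_per_annum`, `lastline_per_annum`, `visit_cost`.
#' @export
derived_costs <- function(params) {
  cc <- params$costs
  acq <- cc$patch_unit_cost * cc$mean_patches_per_treatment
  per_app <- acq + cc$nurse_hourly_rate * cc$nurse_contact_hours + cc$gloves_cost
  anes <- if (isTRUE(params$anesthesia)) cc$anesthesia_cost_per_application else 0
  list(
    capsaicin_acquisition_per_treatment = acq,
    capsaicin_per_application = per_app + if (params$options$anesthesia_mode == "all") anes else 0,
    anesthesia_per_application = anes,
    pregabalin_per_annum = cc$pregabalin_cost_per_tablet *
      cc$pregabalin_doses_per_day * params$year_length_days,
    lastline_per_annum = cc$lastline_cost_per_tablet *
      cc$lastline_doses_per_day * params$year_length_days,
    visit_cost = cc$gp_visit_cost + cc$specialist_visit_cost
  )
}

# ---- parameter paths --------------------------------------------------------

#' Get / set a parameter by dotted path
#'
#' Parameters are addressed by dotted paths such as
#' `"therapies.pregabalin.p_response"` or `"costs.t_retreat_days"`, the
#' addressing scheme used by scenarios, sensitivity ranges and the PSA.
#'
#' @param params A `pnp_params`.
#' @param path Dotted parameter path.
#' @param value Replacement value (for `set_param`).
#' @return `get_param` returns the value; `set_param` returns a new,
#'   re-validated `pnp_params` (the input is untouched).
#' @export
get_param <- function(params, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  x <- params
  for (k in keys) {
    if (!is.list(x) || is.null(x[[k]]))
      stop("unknown parameter path: ", path, call. = FALSE)
    x <- x[[k]]
  }
  x
}

#' @rdname get_param
#' @export
set_param <- function(params, path, value) {
  get_param(params, path)  # errors on unknown path
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  params[[keys]] <- value
  validate_params(params)
}

# ---- sensitivity ranges -----------------------------------------------------

#' Plausible parameter ranges for sensitivity analysis
#'
#' One row per varied parameter with its base value and low/high bounds:
#' the 95% confidence interval where one is reported, otherwise +/-25% of
#' the point estimate. Probabilities are expressed as probabilities (not
#' percent). Capsaicin discontinuation is fixed at zero and therefore not
#' listed.
#'
#' @param params A `pnp_params` (bounds for +/-25% rows scale with it).
#' @return A `data.frame` with columns `parameter_path`, `label`, `base`,
#'   `low`, `high`, `source` (`"95% CI"` or `"+/-25%"`), `family`
#'   (distribution family used in the PSA), and `psa_base` (the mean used
#'   when sampling: identical to `base` except for pregabalin response,
#'   which is sampled around its observed trial value).
#' @export
param_ranges <- function(params = base_params()) {
  p25 <- function(x) c(0.75 * x, 1.25 * x)
  rows <- list(
    list("therapies.capsaicin.p_response", "Responders with capsaicin 8% patch",
         0.499, 0.615, "95% CI", "beta", NA),
    list("therapies.pregabalin.p_response", "Responders with pregabalin",
         0.487, 0.604, "95% CI", "beta",
         params$therapies$pregabalin$p_response_observed),
    list("therapies.last_line.p_response", "Responders with last-line therapy",
         0.15, 0.45, "95% CI", "beta", NA),
    list("therapies.pregabalin.p_discontinue_ae",
         "Intolerable adverse events with pregabalin", 0.052, 0.118,
         "95% CI", "beta", NA),
    list("therapies.capsaicin.t_onset_days", "Time to onset, capsaicin 8% patch",
         6, 10, "95% CI", "gamma", NA),
    list("therapies.pregabalin.t_onset_days", "Time to onset, pregabalin",
         22, 50, "95% CI", "gamma", NA),
    list("costs.t_retreat_days", "Time to capsaicin 8% patch retreatment",
         117, 241, "95% CI", "gamma", NA),
    list("baseline_utility", "Baseline/no-response utility",
         0.55, 0.58, "95% CI", "beta", NA),
    list("therapies.capsaicin.u_increment",
         "Utilities for response with capsaicin 8% patch", 0.20, 0.26,
         "95% CI", "normal", NA),
    list("therapies.pregabalin.u_increment",
         "Utilities for response with pregabalin", 0.17, 0.23,
         "95% CI", "normal", NA),
    list("therapies.last_line.u_increment",
         "Utilities for response with last-line therapy", 0.20, 0.26,
         "95% CI", "normal", NA),
    list("costs.mean_patches_per_treatment",
         "Number of capsaicin 8% patches per treatment", 1.26, 1.51,
         "95% CI", "gamma", NA),
    list("costs.nurse_contact_hours", "Grade 6 nurse time",
         0.25, 1.0, "95% CI", "gamma", NA),
    list("costs.nurse_hourly_rate", "Unit cost of grade 6 nurse", NA, NA,
         "+/-25%", "gamma", NA),
    list("costs.patch_unit_cost", "Acquisition cost per patch", NA, NA,
         "+/-25%", "gamma", NA),
    list("costs.gloves_cost", "Pair of nitrile gloves", 0.05, 0.08,
         "95% CI", "gamma", NA),
    list("costs.pregabalin_cost_per_tablet", "Pregabalin cost per tablet",
         NA, NA, "+/-25%", "gamma", NA),
    list("costs.lastline_cost_per_tablet", "Cost per tablet of last-line therapy",
         0.74, 1.24, "95% CI", "gamma", NA),
    list("costs.gp_visit_cost", "GP consultation", 34, 66, "95% CI", "gamma", NA),
    list("costs.specialist_visit_cost", "Pain specialist follow-up visit",
         90, 171, "95% CI", "gamma", NA),
    list("discount_rate", "Discount rate", 0.015, 0.06, "95% CI", "gamma", NA)
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    base <- get_param(params, r[[1]])
    lo <- r[[3]]; hi <- r[[4]]
    if (is.na(lo)) { b <- p25(base); lo <- b[1]; hi <- b[2] }
    data.frame(parameter_path = r[[1]], label = r[[2]],
               base = base, low = lo, high = hi, source = r[[5]],
               family = r[[6]],
               psa_base = if (is.na(r[[7]])) base else r[[7]],
               stringsAsFactors = FALSE)
  }))
  # guard: low <= base <= high must hold for every row
  stopifnot(all(out$low <= out$base + 1e-12), all(out$base <= out$high + 1e-12))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export the resolved parameter table
#'
#' Writes the base/low/high parameter table (see [param_ranges()]) as CSV.
#'
#' @param params A `pnp_params`.
#' @param file Output CSV path.
#' @return The table, invisibly.
#' @export
export_param_table <- function(params, file) {
  tab <- param_ranges(params)
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(tab)
}

#' @export
print.pnp_params <- function(x, ...) {
  cat("Decision-tree cost-utility model parameters\n")
  cat(sprintf("  horizon: %d years | discount: %.1f%% (%s) | assessment day %g\n",
              x$horizon_years, 100 * x$discount_rate, x$options$discounting,
              x$assessment_days))
  cat(sprintf("  baseline utility: %.4f\n", x$baseline_utility))
  for (nm in names(x$therapies)) {
    th <- x$therapies[[nm]]
    cat(sprintf("  %-10s p_resp=%.4f p_disc=%.3f onset=%gd u_inc=%.4f\n",
                nm, th$p_response, th$p_discontinue_ae, th$t_onset_days,
                th$u_increment))
  }
  dc <- derived_costs(x)
  cat(sprintf("  capsaicin/application GBP %.2f | pregabalin/yr GBP %.2f | last-line/yr GBP %.2f\n",
              dc$capsaicin_per_application, dc$pregabalin_per_annum,
              dc$lastline_per_annum))
  if (!is.null(x$waning))
    cat(sprintf("  waning: %.0f%% loss, %g-day recovery\n",
                100 * x$waning$loss_fraction, x$waning$recovery_days))
  if (isTRUE(x$anesthesia)) cat("  topical anesthesia: on\n")
  invisible(x)
}
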