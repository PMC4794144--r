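# One-way deterministic sensitivity analysis (tornado), threshold solving,
# and seeded probabilistic sensitivity analysis with CEAC.

#' One-way deterministic sensitivity analysis
#'
#' Each parameter is set in turn to its low and high plausible bound (see
#' [param_ranges()]) with everything else at base values; the incremental
#' comparison is recorded at each end. Parameters are ranked by the
#' absolute span of incremental net monetary benefit at the given
#' willingness-to-pay, a metric that remains defined when one end of a bar
#' crosses a dominance boundary (a raw ICER span does not).
#'
#' @param params Base `pnp_params`.
#' @param ranges Range table, defaulting to [param_ranges()].
#' @param wtp Willingness-to-pay used for the ranking, GBP/QALY.
#' @param top Number of leading parameters to keep (`Inf` for all).
#' @return `data.frame` of class `pnp_tornado`, ranked by descending NMB
#'   span: parameter, bounds, ICER or dominance label at each bound, NMB at
#'   each bound, span.
#' @export
one_way <- function(params = base_params(), ranges = param_ranges(params),
                    wtp = 20000, top = 10) {
  eval_at <- function(path, value) {
    ce <- evaluate_model(set_param(params, path, value))
    list(icer = ce$icer, label = ce$label, nmb = nmb(ce, wtp))
  }
  rows <- lapply(seq_len(nrow(ranges)), function(i) {
    r <- ranges[i, ]
    lo <- eval_at(r$parameter_path, r$low)
    hi <- eval_at(r$parameter_path, r$high)
    data.frame(parameter_path = r$parameter_path, label = r$label,
               base = r$base, low = r$low, high = r$high,
               icer_low = lo$icer, result_low = lo$label,
               icer_high = hi$icer, result_high = hi$label,
               nmb_low = lo$nmb, nmb_high = hi$nmb,
               nmb_span = abs(hi$nmb - lo$nmb), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$nmb_span), ]
  rownames(out) <- NULL
  out <- utils::head(out, top)
  class(out) <- c("pnp_tornado", class(out))
  out
}

# generous "plausible" solving bounds per parameter, wider than the
# one-way ranges (threshold values may fall outside a 95% CI)
plausible_bounds <- function(params, path) {
  base <- get_param(params, path)
  if (grepl("p_response|p_discontinue", path)) return(c(0, 1))
  if (grepl("u_increment", path)) return(c(0, 1 - params$baseline_utility))
  if (path == "baseline_utility") return(c(0, 1))
  if (path == "discount_rate") return(c(0, 0.2))
  if (grepl("t_onset", path)) return(c(0, params$assessment_days))
  if (path == "costs.t_retreat_days") return(c(5, 10 * base))
  c(0, max(20 * base, 1))  # costs, counts, hours
}

#' Threshold analysis: solve a parameter for a target ICER
#'
#' Finds the value of one parameter at which the ICER of capsaicin versus
#' pregabalin equals the willingness-to-pay threshold, i.e. the root of
#' `delta_cost - wtp * delta_qaly`, restricted to the region where the
#' intervention gains QALYs (an ICER target is only meaningful in the
#' north-east quadrant of the cost-effectiveness plane). The root is
#' bracketed on a grid — monotonicity of the objective over the valid
#' region is checked numerically and multiple crossings raise an error
#' suggesting a bracket split — then polished by bisection to a relative
#' tolerance of 1e-8. Returns `NA` when no crossing exists within the
#' plausible bounds.
#'
#' @param params Base `pnp_params`.
#' @param path Dotted parameter path.
#' @param wtp Target ICER, GBP/QALY.
#' @param lower,upper Plausible bounds; sensible per-type defaults are used
#'   when omitted.
#' @param n_grid Number of bracketing grid points.
#' @return The solved parameter value, or `NA_real_`.
#' @export
threshold_solve <- function(params, path, wtp, lower = NULL, upper = NULL,
                            n_grid = 61) {
  b <- plausible_bounds(params, path)
  if (is.null(lower)) lower <- b[1]
  if (is.null(upper)) upper <- b[2]
  stopifnot(lower < upper)

  obj <- function(x) {
    ce <- evaluate_model(set_param(params, path, x))
    c(g = ce$delta_cost - wtp * ce$delta_qaly, dq = ce$delta_qaly)
  }
  xs <- seq(lower, upper, length.out = n_grid)
  vals <- vapply(xs, obj, numeric(2))
  valid <- vals["dq", ] > 1e-12
  g <- vals["g", ]

  crossings <- which(valid[-n_grid] & valid[-1] &
                       g[-n_grid] * g[-1] <= 0 & g[-n_grid] != g[-1])
  if (length(crossings) == 0) return(NA_real_)
  if (length(crossings) > 1)
    stop("objective is non-monotone over the bracket (multiple ICER ",
         "crossings); split the bracket and solve each part", call. = FALSE)
  i <- crossings[1]
  root <- stats::uniroot(function(x) obj(x)[["g"]], c(xs[i], xs[i + 1]),
                         tol = 1e-8 * max(abs(xs[i]), abs(xs[i + 1]), 1))$root
  root
}

#' Threshold table for the leading tornado parameters
#'
#' @param params Base `pnp_params`.
#' @param wtps Target thresholds, GBP/QALY.
#' @param top Number of parameters (ranked as in [one_way()]).
#' @return `data.frame`: parameter, base value, solved value per threshold
#'   (`NA` when the target ICER cannot be reached within plausible bounds).
#' @export
threshold_table <- function(params = base_params(), wtps = c(20000, 30000),
                            top = 10) {
  tor <- one_way(params, top = top)
  out <- data.frame(parameter_path = tor$parameter_path, label = tor$label,
                    base = tor$base, stringsAsFactors = FALSE)
  for (w in wtps) {
    out[[paste0("wtp_", w)]] <- vapply(tor$parameter_path, function(p) {
      tryCatch(threshold_solve(params, p, w), error = function(e) NA_real_)
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}

# ---- probabilistic sensitivity analysis -------------------------------------

#' Distribution specifications for the PSA
#'
#' Method-of-moments fits per parameter: beta for probabilities and the
#' baseline utility, gamma for costs, times and counts, normal for utility
#' increments (redrawn while outside \[0, 1 - baseline\]). The standard
#' error is `(high - low) / (2 * 1.96)` whether the range is a reported
#' 95% CI or the +/-25% convention. Parameters with a degenerate range
#' (low == high) keep their base value; the discount rate is held fixed in
#' the PSA (it is varied deterministically instead).
#'
#' @param params Base `pnp_params`.
#' @param ranges Range table, defaulting to [param_ranges()]. The
#'   pregabalin response is sampled around its observed trial mean (the
#'   `psa_base` column) rather than the equalized base-case value.
#' @return `data.frame` of class `pnp_dist_specs` with family and fitted
#'   shape columns.
#' @export
psa_dist_specs <- function(params = base_params(), ranges = param_ranges(params)) {
  ranges <- ranges[ranges$parameter_path != "discount_rate", ]
  se <- (ranges$high - ranges$low) / (2 * 1.96)
  m <- ranges$psa_base
  out <- data.frame(parameter_path = ranges$parameter_path,
                    label = ranges$label, family = ranges$family,
                    mean = m, se = se, stringsAsFactors = FALSE)
  v <- se^2
  # beta: a+b = m(1-m)/v - 1
  nu <- ifelse(out$family == "beta" & v > 0, m * (1 - m) / v - 1, NA)
  out$shape1 <- ifelse(out$family == "beta", m * nu, NA)
  out$shape2 <- ifelse(out$family == "beta", (1 - m) * nu, NA)
  out$shape <- ifelse(out$family == "gamma" & v > 0, m^2 / v, NA)
  out$rate <- ifelse(out$family == "gamma" & v > 0, m / v, NA)
  bad <- out$family == "beta" & v > 0 & (out$shape1 <= 0 | out$shape2 <= 0)
  if (any(bad))
    stop("beta method-of-moments failed for: ",
         paste(out$parameter_path[bad], collapse = ", "), call. = FALSE)
  class(out) <- c("pnp_dist_specs", class(out))
  out
}

# draw n values for one spec row; degenerate ranges return the mean
draw_spec <- function(spec, n) {
  if (spec$se == 0) return(rep(spec$mean, n))
  switch(spec$family,
    beta = stats::rbeta(n, spec$shape1, spec$shape2),
    gamma = stats::rgamma(n, shape = spec$shape, rate = spec$rate),
    normal = stats::rnorm(n, spec$mean, spec$se),
    stop("unknown distribution family: ", spec$family, call. = FALSE))
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` independent parameter sets from the distribution
#' specifications, pushes each through the deterministic cohort engine,
#' and summarizes the cost-effectiveness plane and acceptability curve.
#' Draws that produce an invalid parameter set (e.g. a normal utility
#' increment below zero) are rejected and redrawn; the count is reported.
#' Identical seeds give identical results.
#'
#' @param params Base `pnp_params`.
#' @param n Number of Monte Carlo draws.
#' @param seed RNG seed.
#' @param wtp_grid Willingness-to-pay grid for the CEAC (GBP/QALY).
#' @param specs Distribution table, defaulting to [psa_dist_specs()].
#' @return Object of class `pnp_psa`: `draws` (`data.frame` of
#'   `delta_cost`, `delta_qaly`), `mean_delta_cost`, `mean_delta_qaly`,
#'   `ceac` (`wtp`, `probability` = fraction of draws with positive net
#'   monetary benefit), `n_draws`, `seed`, `n_rejected`.
#' @export
run_psa <- function(params = base_params(), n = 10000, seed = 1,
                    wtp_grid = seq(0, 50000, by = 500),
                    specs = psa_dist_specs(params)) {
  stopifnot(n >= 1)
  set.seed(seed)
  k <- nrow(specs)
  draws <- matrix(NA_real_, n, k, dimnames = list(NULL, specs$parameter_path))
  for (j in seq_len(k)) draws[, j] <- draw_spec(specs[j, ], n)

  n_rejected <- 0L
  dc <- dq <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      p_i <- tryCatch({
        p <- params
        for (j in seq_len(k))
          p[[strsplit(specs$parameter_path[j], ".", fixed = TRUE)[[1]]]] <-
            unname(draws[i, j])
        validate_params(p)
      }, error = function(e) NULL)
      if (!is.null(p_i)) break
      n_rejected <- n_rejected + 1L
      draws[i, ] <- vapply(seq_len(k), function(j) draw_spec(specs[j, ], 1),
                           numeric(1))
    }
    ce <- evaluate_model(p_i)
    dc[i] <- ce$delta_cost
    dq[i] <- ce$delta_qaly
  }
  ceac <- data.frame(
    wtp = wtp_grid,
    probability = vapply(wtp_grid, function(l) mean(l * dq - dc > 0), numeric(1))
  )
  structure(list(draws = data.frame(delta_cost = dc, delta_qaly = dq),
                 mean_delta_cost = mean(dc), mean_delta_qaly = mean(dq),
                 ceac = ceac, n_draws = n, seed = seed,
                 n_rejected = n_rejected),
            class = "pnp_psa")
}

#' Probability of cost-effectiveness at a threshold
#'
#' @param psa A `pnp_psa`.
#' @param wtp Willingness-to-pay, GBP/QALY.
#' @return Fraction of PSA draws with positive net monetary benefit.
#' @export
prob_cost_effective <- function(psa, wtp) {
  with(psa$draws, mean(wtp * delta_qaly - delta_cost > 0))
}

#' @export
print.pnp_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d draws (seed %s)\n",
              x$n_draws, format(x$seed)))
  cat(sprintf("  mean incremental cost : GBP %.2f\n", x$mean_delta_cost))
  cat(sprintf("  mean incremental QALYs: %.4f\n", x$mean_delta_qaly))
  for (w in c(20000, 30000))
    cat(sprintf("  P(cost-effective at GBP %d/QALY): %.1f%%\n",
                w, 100 * prob_cost_effective(x, w)))
  if (x$n_rejected > 0)
    cat(sprintf("  rejected/redrawn parameter sets: %d\n", x$n_rejected))
  invisible(x)
}
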