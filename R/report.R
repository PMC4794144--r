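# CSV report writers in the published table layouts, run orchestration for
# the command-line front-end, and run manifests.

round_money <- function(x) round(x, 0)
round_qaly <- function(x) round(x, 3)

#' Base-case results table
#'
#' Two-arm cost breakdown, QALY totals and the incremental column in the
#' base-case table layout. Monetary values are rounded to whole pounds and
#' QALYs to three decimals for display; pass `raw = TRUE` for full
#' precision.
#'
#' @param ce A `pnp_ce_result` (see [evaluate_model()]).
#' @param raw Keep full precision instead of display rounding.
#' @return `data.frame` with columns `quantity`, `capsaicin`, `pregabalin`,
#'   `incremental`.
#' @export
base_case_table <- function(ce, raw = FALSE) {
  a <- ce$intervention; b <- ce$comparator
  out <- data.frame(
    quantity = c("Capsaicin 8% patch cost", "Pregabalin cost",
                 "Last-line therapy cost", "GP/pain specialist visits",
                 "Total cost", "Total QALYs"),
    capsaicin = c(a$cost_index_therapy, 0, a$cost_lastline, a$cost_visits,
                  a$cost_total, a$qaly_total),
    pregabalin = c(0, b$cost_index_therapy, b$cost_lastline, b$cost_visits,
                   b$cost_total, b$qaly_total),
    incremental = c(a$cost_index_therapy, -b$cost_index_therapy,
                    a$cost_lastline - b$cost_lastline,
                    a$cost_visits - b$cost_visits,
                    ce$delta_cost, ce$delta_qaly),
    stringsAsFactors = FALSE)
  if (!raw) {
    money <- out$quantity != "Total QALYs"
    out[money, 2:4] <- round_money(out[money, 2:4])
    out[!money, 2:4] <- round_qaly(out[!money, 2:4])
  }
  out <- rbind(out, data.frame(quantity = "ICER", capsaicin = NA,
                               pregabalin = NA, incremental = NA))
  attr(out, "result") <- ce$label
  out
}

write_with_raw <- function(df_display, df_raw, file) {
  utils::write.csv(df_display, file, row.names = FALSE, na = "")
  raw_file <- sub("(\\.csv)?$", "_raw.csv", file)
  utils::write.csv(df_raw, raw_file, row.names = FALSE, na = "")
  c(file, raw_file)
}

#' Run a named analysis and write its outputs
#'
#' Orchestrates one command — the interface also used by the bundled
#' command-line script (`system.file("cli", "pnpcea.R", package =
#' "pnpcea")`). Every run writes its CSV outputs plus a `manifest.json`
#' recording config, command, seed, package version, timestamp and output
#' files, sufficient to reproduce the run.
#'
#' @param command One of `"base"`, `"scenarios"`, `"horizons"`, `"dsa"`,
#'   `"threshold"`, `"psa"`, `"validate-oracle"`.
#' @param params A `pnp_params` (or path to a YAML config).
#' @param outdir Output directory, created if needed.
#' @param seed Seed for stochastic commands.
#' @param n Draw count (`psa`) or patients per arm (`validate-oracle`).
#' @param wtp Willingness-to-pay for ranking/thresholds, GBP/QALY.
#' @return Invisibly, the list of files written.
#' @export
run_report <- function(command, params = base_params(), outdir = ".",
                       seed = 1, n = 10000, wtp = 20000) {
  if (is.character(params)) params <- load_config(params)
  commands <- c("base", "scenarios", "horizons", "dsa", "threshold", "psa",
                "validate-oracle")
  if (!command %in% commands)
    stop("unknown command '", command, "'; expected one of: ",
         paste(commands, collapse = ", "), call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(outdir, f)
  files <- character()

  if (command == "base") {
    ce <- evaluate_model(params)
    files <- write_with_raw(base_case_table(ce), base_case_table(ce, raw = TRUE),
                            fp("base_case.csv"))
    message(sprintf("base case: %s (dC = %.2f, dQ = %.4f)",
                    ce$label, ce$delta_cost, ce$delta_qaly))
  } else if (command == "scenarios") {
    tab <- run_scenarios(params)
    disp <- tab
    disp[c("cost_capsaicin", "cost_pregabalin", "delta_cost", "icer")] <-
      lapply(disp[c("cost_capsaicin", "cost_pregabalin", "delta_cost", "icer")],
             round_money)
    disp[c("qaly_capsaicin", "qaly_pregabalin", "delta_qaly")] <-
      lapply(disp[c("qaly_capsaicin", "qaly_pregabalin", "delta_qaly")],
             round_qaly)
    files <- write_with_raw(disp, tab, fp("scenarios.csv"))
  } else if (command == "horizons") {
    tab <- horizon_sweep(params)
    files <- write_with_raw(tab, tab, fp("horizons.csv"))
  } else if (command == "dsa") {
    tab <- one_way(params, wtp = wtp)
    files <- write_with_raw(as.data.frame(tab), as.data.frame(tab),
                            fp("tornado.csv"))
  } else if (command == "threshold") {
    tab <- threshold_table(params)
    files <- write_with_raw(tab, tab, fp("threshold.csv"))
  } else if (command == "psa") {
    psa <- run_psa(params, n = n, seed = seed)
    utils::write.csv(psa$draws, fp("psa_draws.csv"), row.names = FALSE)
    utils::write.csv(psa$ceac, fp("ceac.csv"), row.names = FALSE)
    files <- c(fp("psa_draws.csv"), fp("ceac.csv"))
    message(sprintf("PSA: P(CE at GBP %d/QALY) = %.1f%%", wtp,
                    100 * prob_cost_effective(psa, wtp)))
  } else if (command == "validate-oracle") {
    sim <- simulate_cohort(params, n = n, seed = seed)
    eng <- do.call(rbind, lapply(c("capsaicin", "pregabalin"), function(a) {
      r <- evaluate_arm(a, params)
      data.frame(arm = a, engine_qaly = r$qaly_total, engine_cost = r$cost_total)
    }))
    tab <- merge(sim$summary, eng, by = "arm")
    tab$qaly_z <- (tab$qaly_mean - tab$engine_qaly) / tab$qaly_se
    tab$cost_z <- (tab$cost_mean - tab$engine_cost) / tab$cost_se
    utils::write.csv(tab, fp("oracle_validation.csv"), row.names = FALSE)
    files <- fp("oracle_validation.csv")
  }

  manifest <- list(
    command = command, seed = seed, n = n, wtp = wtp,
    package_version = as.character(utils::packageVersion("pnpcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = basename(files)
  )
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(files, fp("manifest.json")))
}
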