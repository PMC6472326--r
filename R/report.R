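# Indicator reporting: cumulative and long-run tables mirroring the
# economic / nutrition-biomarker-health / demographic-environment blocks.

#' Summarize a scenario into cumulative and long-run indicator tables
#'
#' For every indicator the table reports the cumulative (sum over periods)
#' and long-run (horizon-year) scenario-minus-baseline difference, in
#' absolute units and as a percentage of the corresponding baseline
#' aggregate.  Stock-like indicators (shares, the cholesterol ratio,
#' population, hectares, CPI) are reported long-run only; flow indicators
#' cumulate.
#'
#' @param result a `scenario_result`.
#' @return a data frame with columns `indicator`, `cumulative`,
#'   `cumulative_pct`, `longrun`, `longrun_pct`.
#' @export
report_indicators <- function(result) {
  d <- result$delta
  b <- result$baseline_indicators
  hz <- nrow(d)
  pct <- function(num, den) ifelse(abs(den) > 0, num / den * 100, NA_real_)
  data.frame(
    indicator = colnames(d),
    cumulative = colSums(d),
    cumulative_pct = pct(colSums(d), colSums(b)),
    longrun = d[hz, ],
    longrun_pct = pct(d[hz, ], b[hz, ]),
    row.names = NULL
  )
}

#' Write scenario outputs to a results directory
#'
#' Emits the tidy trajectory (period x variable x value for scenario,
#' baseline and difference), the indicator summary table, and a JSON
#' manifest recording the tax rate and options.
#'
#' @param result a `scenario_result`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_scenario_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traj <- tidy_trajectory(result)
  p1 <- file.path(dir, "trajectory.csv")
  utils::write.csv(traj, p1, row.names = FALSE)
  p2 <- file.path(dir, "indicators.csv")
  utils::write.csv(report_indicators(result), p2, row.names = FALSE)
  p3 <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(tax_rate = result$tax_rate,
                            closure = result$opts$closure_variant,
                            health_feedback = result$opts$health_feedback,
                            target = result$opts$target,
                            periods = nrow(result$indicators)),
                       p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}

#' Tidy long-format trajectory of a scenario result
#'
#' @param result a `scenario_result`.
#' @return data frame with `period`, `variable`, `scenario`, `baseline`,
#'   `delta`.
#' @export
tidy_trajectory <- function(result) {
  ind <- result$indicators
  base <- result$baseline_indicators
  periods <- as.integer(rownames(ind))
  out <- expand.grid(period = periods, variable = colnames(ind),
                     stringsAsFactors = FALSE)
  out$scenario <- as.numeric(ind[cbind(match(out$period, periods),
                                       match(out$variable, colnames(ind)))])
  out$baseline <- as.numeric(base[cbind(match(out$period, periods),
                                        match(out$variable,
                                              colnames(base)))])
  out$delta <- out$scenario - out$baseline
  out
}
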