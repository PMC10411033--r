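# Report assembly: assessment tables (one row per tier per coil),
# difference histograms with the quantile marker, and JSON/CSV export.

fmt_or_dash <- function(x, digits) {
  ifelse(is.na(x), "-", formatC(round(x, digits), format = "f",
                                digits = digits))
}

#' Render an assessment report table
#'
#' One row per assessment with the columns of a tier-assessment summary:
#' tier, the three uncertainty percentages, safety factor, buffer,
#' simulated and corrected pSAR, and the power limits. Percentages are
#' printed to 0 decimals, safety factors / pSAR / power to 1, matching the
#' report precision; the JSON carries full precision plus provenance.
#'
#' @param assessments a `tier_assessment` or list of them.
#' @param uncertainty_results optional list of
#'   `modeling_uncertainty_result`s included in the JSON.
#' @param fit_reports optional list of [fit_gamma()]/[psar_population()]
#'   outputs included in the JSON.
#' @return object of class `assessment_report` with elements `table`
#'   (formatted data.frame), `numeric` (unformatted data.frame) and `json`
#'   (list ready for serialization).
#' @export
render_report <- function(assessments, uncertainty_results = NULL,
                          fit_reports = NULL) {
  if (inherits(assessments, "tier_assessment")) assessments <- list(assessments)
  if (!length(assessments))
    stop("render_report(): at least one assessment required")
  stopifnot(all(vapply(assessments, inherits, TRUE, "tier_assessment")))
  units <- unique(vapply(assessments, `[[`, "", "units"))
  if (length(units) != 1L)
    stop("render_report(): inconsistent units across assessments: ",
         paste(units, collapse = ", "))
  num <- do.call(rbind, lapply(assessments, function(a) {
    b <- a$budget
    data.frame(
      label = a$label,
      tier = a$tier,
      modeling_pct = if (is.null(b)) NA_real_ else 100 * b$modeling,
      intersubject_pct = if (is.null(b)) NA_real_ else 100 * b$intersubject,
      power_monitoring_pct = if (is.null(b)) NA_real_
                             else 100 * b$power_monitoring,
      safety_factor = a$safety_factor,
      buffer = if (a$tier == 2) a$config$buffer else NA_real_,
      simulated_psar = if (a$tier == 1) NA_real_ else a$config$psar_sim_mean,
      corrected_psar = a$corrected_psar,
      total_power_limit_W = a$total_power_limit,
      per_channel_power_limit_W = a$per_channel_power_limit,
      stringsAsFactors = FALSE)
  }))
  tab <- data.frame(
    label = num$label,
    tier = num$tier,
    modeling = fmt_or_dash(num$modeling_pct, 0),
    intersubject = fmt_or_dash(num$intersubject_pct, 0),
    power_monitoring = fmt_or_dash(num$power_monitoring_pct, 0),
    safety_factor = fmt_or_dash(num$safety_factor, 1),
    buffer = fmt_or_dash(num$buffer, 0),
    simulated_psar = fmt_or_dash(num$simulated_psar, 1),
    corrected_psar = fmt_or_dash(num$corrected_psar, 1),
    total_power_limit_W = fmt_or_dash(num$total_power_limit_W, 1),
    per_channel_power_limit_W = fmt_or_dash(num$per_channel_power_limit_W, 2),
    stringsAsFactors = FALSE)
  json <- list(
    units = units,
    rows = lapply(assessments, function(a) {
      list(label = a$label, tier = a$tier,
           budget = if (is.null(a$budget)) NULL else
             list(modeling = a$budget$modeling,
                  intersubject = a$budget$intersubject,
                  power_monitoring = a$budget$power_monitoring,
                  modeling_source = a$budget$modeling_source,
                  provenance = a$budget$provenance),
           total_relative_uncertainty = a$total_relative_uncertainty,
           safety_factor = a$safety_factor,
           final_safety_factor = a$final_safety_factor,
           corrected_psar = a$corrected_psar,
           total_power_limit_W = a$total_power_limit,
           per_channel_power_limit_W = a$per_channel_power_limit,
           multiplicative_safety_factor = a$multiplicative_safety_factor,
           rounding_mode = a$config$rounding_mode,
           audit = a$audit)
    }),
    modeling_uncertainty = uncertainty_results,
    fits = fit_reports)
  structure(list(table = tab, numeric = num, json = json),
            class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write a report to CSV and/or JSON
#'
#' @param report an `assessment_report` from [render_report()].
#' @param csv,json output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, csv = NULL, json = NULL) {
  stopifnot(inherits(report, "assessment_report"))
  if (!is.null(csv))
    utils::write.csv(report$table, csv, row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(json))
    jsonlite::write_json(report$json, json, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  invisible(c(csv = csv, json = json))
}

#' Histogram summary of a difference map
#'
#' Bin counts of the pooled voxel-wise differences plus the modeling-
#' uncertainty quantile marker (the red-line statistic on difference
#' histograms). Counts sum to the number of pooled voxels.
#'
#' @param diffs a `diff_map`, numeric values, or list of these (pooled).
#' @param n_bins number of equal-width bins >= 1.
#' @param quantile quantile for the marker (default 0.999).
#' @return list with `breaks`, `counts`, `mids`, `n`, `quantile`, `marker`
#'   (the clamped modeling uncertainty) and `marker_raw`.
#' @export
histogram_summary <- function(diffs, n_bins = 50, quantile = 0.999) {
  if (n_bins < 1) stop("histogram_summary(): n_bins must be >= 1")
  mu <- modeling_uncertainty(diffs, quantile = quantile)
  pool_one <- function(d) {
    if (inherits(d, "diff_map")) d$diff[d$mask]
    else as.numeric(d)[!is.na(as.numeric(d))]
  }
  x <- if (is.list(diffs) && !inherits(diffs, "diff_map"))
    unlist(lapply(diffs, pool_one), use.names = FALSE)
  else pool_one(diffs)
  rng <- range(x)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  list(breaks = h$breaks, counts = h$counts, mids = h$mids,
       n = length(x), quantile = quantile,
       marker = as.numeric(mu), marker_raw = attr(mu, "raw"))
}
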