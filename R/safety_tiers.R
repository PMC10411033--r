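# Uncertainty propagation, safety factors, tier logic and power limits.
#
# Three uncorrelated relative uncertainties (modeling, intersubject,
# power monitoring) combine by root-sum-of-squares into the total relative
# uncertainty u; the safety factor is 1 + u. Tier 2 (B1-only validation)
# multiplies the safety factor by an additional buffer (default 2) because
# the controlled quantity (SAR/temperature) itself is not validated.
# Tier 1 performs no simulation at all: all RF power is assumed deposited
# in 10 g of tissue.

#' Construct an uncertainty budget
#'
#' The three relative uncertainties entering the safety factor, as
#' fractions (0.64 = 64%), each with a provenance note.
#'
#' @param modeling modeling uncertainty (simulation-vs-measurement 99.9%
#'   voxel statistic), fraction >= 0. May be a
#'   `modeling_uncertainty_result`, in which case its final value and
#'   modality provenance are used.
#' @param intersubject intersubject variation fraction >= 0.
#' @param power_monitoring relative power-monitoring uncertainty >= 0.
#' @param modeling_source character vector of modalities the modeling term
#'   was derived from (subset of `"B1"`, `"SAR"`, `"TEMP"`), or
#'   `"unspecified"`. Tier 3 refuses budgets whose modeling term comes from
#'   B1 mapping alone.
#' @param provenance named character notes (measured / literature / vendor).
#' @return object of class `uncertainty_budget`.
#' @export
uncertainty_budget <- function(modeling, intersubject, power_monitoring,
                               modeling_source = "unspecified",
                               provenance = NULL) {
  if (inherits(modeling, "modeling_uncertainty_result")) {
    mods <- unique(modeling$per_comparison$modality)
    if (!all(is.na(mods))) modeling_source <- mods[!is.na(mods)]
    modeling <- modeling$final
  }
  terms <- c(modeling = modeling, intersubject = intersubject,
             power_monitoring = power_monitoring)
  if (any(!is.finite(terms)) || any(terms < 0))
    stop("uncertainty_budget(): all terms must be finite fractions >= 0")
  structure(list(modeling = unname(modeling),
                 intersubject = unname(intersubject),
                 power_monitoring = unname(power_monitoring),
                 modeling_source = modeling_source,
                 provenance = provenance),
            class = "uncertainty_budget")
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat(sprintf(paste0("<uncertainty_budget> modeling %.0f%% (%s), ",
                     "intersubject %.0f%%, power monitoring %.0f%%\n"),
              100 * x$modeling, paste(x$modeling_source, collapse = "+"),
              100 * x$intersubject, 100 * x$power_monitoring))
  invisible(x)
}

budget_terms <- function(budget) {
  stopifnot(inherits(budget, "uncertainty_budget"))
  c(budget$modeling, budget$intersubject, budget$power_monitoring)
}

#' Combine uncertainties by root-sum-of-squares
#'
#' The three sources are uncorrelated, so the relative uncertainties add in
#' quadrature: `sqrt(modeling^2 + intersubject^2 + power_monitoring^2)`.
#'
#' @param budget an [uncertainty_budget()].
#' @return total relative uncertainty (fraction).
#' @export
combine_uncertainties <- function(budget) {
  sqrt(sum(budget_terms(budget)^2))
}

#' Safety factor from the total relative uncertainty
#'
#' `1 + total_uncertainty`: scaling the simulated peak SAR by this factor
#' makes underestimation of the true peak SAR acceptably unlikely.
#'
#' @param total_uncertainty fraction >= 0.
#' @return safety factor >= 1 (full precision; rounding happens in
#'   [run_tier_assessment()] under `rounding_mode = "paper"`).
#' @export
safety_factor <- function(total_uncertainty) {
  if (!is.numeric(total_uncertainty) || any(total_uncertainty < 0))
    stop("safety_factor(): total uncertainty must be >= 0")
  1 + total_uncertainty
}

#' Apply the tier-2 buffer
#'
#' Tier 2 validates only B1+, not the controlled quantity, so its safety
#' factor is multiplied by an additional buffer (default 2; the choice is a
#' site/regulatory decision). Tiers 1 and 3 pass through unchanged.
#'
#' @param sf safety factor >= 1.
#' @param tier 1, 2 or 3.
#' @param buffer multiplicative margin >= 1.
#' @return final safety factor.
#' @export
apply_buffer <- function(sf, tier, buffer = 2) {
  if (sf < 1) stop("apply_buffer(): safety factor must be >= 1")
  if (!tier %in% 1:3) stop("apply_buffer(): tier must be 1, 2 or 3")
  if (buffer < 1) stop("apply_buffer(): buffer must be >= 1")
  if (tier == 2) sf * buffer else sf
}

#' Corrected peak SAR
#'
#' `pSAR_corrected = pSAR_simulated * final_safety_factor`, at the same
#' power normalization as the simulated value.
#'
#' @param psar_sim_mean mean simulated peak SAR in W/kg (> 0).
#' @param final_sf final safety factor (buffer included) (> 0).
#' @return corrected peak SAR in W/kg.
#' @export
corrected_psar <- function(psar_sim_mean, final_sf) {
  if (!is.numeric(psar_sim_mean) || psar_sim_mean <= 0 ||
      !is.numeric(final_sf) || final_sf <= 0)
    stop("corrected_psar(): inputs must be > 0")
  psar_sim_mean * final_sf
}

#' Average power limits from the corrected peak SAR
#'
#' The corrected pSAR corresponds to `reference_power` W total input, so the
#' admissible total average power is `sar_limit / corrected_psar *
#' reference_power`, split equally over the channels.
#'
#' @param corrected_psar corrected peak SAR in W/kg (> 0).
#' @param sar_limit local 10-g SAR limit in W/kg (20 for first level
#'   controlled mode, head and trunk).
#' @param reference_power total input power in W the simulation is
#'   normalized to.
#' @param n_channels number of transmit channels.
#' @return list with `total` and `per_channel` average power limits in W.
#' @export
power_limit <- function(corrected_psar, sar_limit = 20, reference_power = 8,
                        n_channels = 8) {
  vals <- c(corrected_psar, sar_limit, reference_power, n_channels)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("power_limit(): all inputs must be > 0")
  total <- sar_limit / corrected_psar * reference_power
  list(total = total, per_channel = total / n_channels)
}

#' Tier-1 power limit
#'
#' Tier 1 performs no simulation: all RF power is assumed to be dissipated
#' in a single 10-g averaging mass, so 1 W per channel on an n-channel
#' array implies a worst-case SAR of `n / 0.010 kg` W/kg and the admissible
#' total power is `sar_limit * averaging_mass`.
#'
#' @param sar_limit local SAR limit in W/kg.
#' @param n_channels number of transmit channels.
#' @param averaging_mass averaging mass in kg (default 0.010 = 10 g).
#' @return list with `total` and `per_channel` limits in W and
#'   `implied_sar_1w_per_channel` in W/kg.
#' @export
tier1_limit <- function(sar_limit = 20, n_channels = 8,
                        averaging_mass = 0.010) {
  vals <- c(sar_limit, n_channels, averaging_mass)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("tier1_limit(): all inputs must be > 0")
  total <- sar_limit * averaging_mass
  list(total = total, per_channel = total / n_channels,
       implied_sar_1w_per_channel = n_channels / averaging_mass)
}

#' Multiplicative safety-factor comparator
#'
#' The conventional propagation multiplies the per-source factors:
#' `prod(1 + term_i)`. It ignores the stochastic independence of the
#' sources and is always at least as conservative as the
#' root-sum-of-squares factor; both are reported for comparison.
#'
#' @param budget an [uncertainty_budget()].
#' @return multiplicative safety factor.
#' @export
multiplicative_safety_factor <- function(budget) {
  prod(1 + budget_terms(budget))
}

#' Tier assessment configuration
#'
#' @param tier validation tier 1, 2 or 3.
#' @param n_channels number of transmit channels.
#' @param reference_power total input power in W the simulated pSAR is
#'   normalized to.
#' @param psar_sim_mean mean simulated peak SAR in W/kg; required for tiers
#'   2-3, must be absent for tier 1.
#' @param buffer tier-2 buffer >= 1 (ignored for tiers 1 and 3).
#' @param sar_limit local 10-g SAR limit in W/kg; default 20 (first level
#'   controlled mode, head and trunk); 10 for normal mode.
#' @param averaging_mass tier-1 averaging mass in kg.
#' @param chain_efficiency optional multiplicative transmit-chain
#'   efficiency applied to the reference power (default 1: losses between
#'   power monitoring and coil are not modeled).
#' @param rounding_mode `"paper"` (report-precision chain: safety factor
#'   and corrected pSAR rounded to one decimal before downstream use) or
#'   `"full_precision"`.
#' @param label free-text coil/scenario label for reports.
#' @return object of class `tier_config`.
#' @export
tier_config <- function(tier, n_channels = 8, reference_power = 8,
                        psar_sim_mean = NULL, buffer = 2, sar_limit = 20,
                        averaging_mass = 0.010, chain_efficiency = 1,
                        rounding_mode = c("paper", "full_precision"),
                        label = "") {
  rounding_mode <- match.arg(rounding_mode)
  if (!tier %in% 1:3) stop("tier_config(): tier must be 1, 2 or 3")
  if (tier == 1 && !is.null(psar_sim_mean))
    stop("tier_config(): tier 1 uses no simulation; psar_sim_mean must be ",
         "absent")
  if (tier > 1 && (is.null(psar_sim_mean) || psar_sim_mean <= 0))
    stop("tier_config(): tiers 2-3 require a positive psar_sim_mean")
  if (buffer < 1) stop("tier_config(): buffer must be >= 1")
  vals <- c(n_channels, reference_power, sar_limit, averaging_mass,
            chain_efficiency)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("tier_config(): numeric parameters must be > 0")
  structure(list(tier = as.integer(tier), n_channels = as.integer(n_channels),
                 reference_power = reference_power,
                 psar_sim_mean = psar_sim_mean, buffer = buffer,
                 sar_limit = sar_limit, averaging_mass = averaging_mass,
                 chain_efficiency = chain_efficiency,
                 rounding_mode = rounding_mode, label = label),
            class = "tier_config")
}

round1 <- function(x) round(x, 1)

#' Run a complete tier assessment
#'
#' Executes the full chain: combine the uncertainty budget, form the safety
#' factor, apply the tier-2 buffer, correct the simulated peak SAR and
#' derive the power limits (or, for tier 1, the all-power-in-10-g limit).
#' Both the full-precision chain and the report-precision ("paper") chain —
#' safety factor and corrected pSAR rounded to one decimal before being
#' used downstream — are computed; `rounding_mode` selects which one fills
#' the headline fields.
#'
#' @param config a [tier_config()].
#' @param budget an [uncertainty_budget()]; required for tiers 2-3, ignored
#'   for tier 1.
#' @return object of class `tier_assessment` with fields
#'   `total_relative_uncertainty`, `safety_factor`, `final_safety_factor`,
#'   `corrected_psar`, `total_power_limit`, `per_channel_power_limit`,
#'   `multiplicative_safety_factor` and an `audit` list holding both
#'   precision chains and all inputs.
#' @export
run_tier_assessment <- function(config, budget = NULL) {
  stopifnot(inherits(config, "tier_config"))
  if (config$tier == 1) {
    lim <- tier1_limit(config$sar_limit, config$n_channels,
                       config$averaging_mass)
    out <- list(
      tier = 1L, label = config$label, units = "W/kg",
      total_relative_uncertainty = NA_real_,
      safety_factor = NA_real_, final_safety_factor = NA_real_,
      corrected_psar = NA_real_,
      total_power_limit = lim$total,
      per_channel_power_limit = lim$per_channel,
      implied_sar_1w_per_channel = lim$implied_sar_1w_per_channel,
      multiplicative_safety_factor = NA_real_,
      budget = NULL, config = config,
      audit = list(mode = "tier1", limits = lim))
    return(structure(out, class = "tier_assessment"))
  }
  if (is.null(budget))
    stop("run_tier_assessment(): tiers 2-3 require an uncertainty budget")
  stopifnot(inherits(budget, "uncertainty_budget"))
  if (config$tier == 3 &&
      !"unspecified" %in% budget$modeling_source &&
      !any(c("SAR", "TEMP") %in% budget$modeling_source))
    stop("run_tier_assessment(): tier 3 requires the modeling uncertainty ",
         "to include a SAR/temperature comparison; budget provides only ",
         paste(budget$modeling_source, collapse = "+"))
  u <- combine_uncertainties(budget)
  chain <- function(sf) {
    final <- apply_buffer(sf, config$tier, config$buffer)
    corr <- corrected_psar(config$psar_sim_mean, final)
    list(sf = sf, final = final, corr = corr)
  }
  run_limits <- function(corr) power_limit(
    corr, config$sar_limit,
    config$reference_power * config$chain_efficiency, config$n_channels)
  full <- chain(safety_factor(u))
  full$limits <- run_limits(full$corr)
  pap <- chain(round1(safety_factor(u)))
  pap$corr <- round1(pap$corr)
  pap$limits <- run_limits(pap$corr)
  pap$limits <- lapply(pap$limits, round1)
  use <- if (config$rounding_mode == "paper") pap else full
  structure(list(
    tier = config$tier, label = config$label, units = "W/kg",
    total_relative_uncertainty = u,
    safety_factor = use$sf,
    final_safety_factor = use$final,
    corrected_psar = use$corr,
    total_power_limit = use$limits$total,
    per_channel_power_limit = use$limits$per_channel,
    implied_sar_1w_per_channel = NA_real_,
    multiplicative_safety_factor = multiplicative_safety_factor(budget),
    budget = budget, config = config,
    audit = list(mode = config$rounding_mode,
                 full_precision = full, paper = pap,
                 rss_vs_multiplicative = c(
                   rss = safety_factor(u),
                   multiplicative = multiplicative_safety_factor(budget)))),
    class = "tier_assessment")
}

#' @export
print.tier_assessment <- function(x, ...) {
  cat(sprintf("<tier_assessment> tier %d%s\n", x$tier,
              if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  if (x$tier == 1) {
    cat(sprintf("  all power in %g g of tissue; implied SAR at 1 W/channel: %g W/kg\n",
                1000 * x$config$averaging_mass, x$implied_sar_1w_per_channel))
  } else {
    cat(sprintf("  total uncertainty %.1f%%; safety factor %.2g (final %.2g)\n",
                100 * x$total_relative_uncertainty, x$safety_factor,
                x$final_safety_factor))
    cat(sprintf("  corrected pSAR %.3g W/kg (simulated %.3g W/kg at %g W)\n",
                x$corrected_psar, x$config$psar_sim_mean,
                x$config$reference_power))
  }
  cat(sprintf("  power limit: %.3g W total, %.3g W/channel (SAR limit %g W/kg)\n",
              x$total_power_limit, x$per_channel_power_limit,
              x$config$sar_limit))
  invisible(x)
}
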