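# Simulation-vs-measurement validation: voxel-wise normalized difference
# maps and the 99.9%-of-voxels modeling uncertainty.
#
# The difference maps are normalized by the in-mask *peak* of the simulated
# map (not voxel-wise ratios): peak SAR sets the safe operating limits, so
# deviations are expressed relative to the quantity that matters.

check_comparable <- function(meas, sim, modality) {
  stopifnot(inherits(meas, "field_map"), inherits(sim, "field_map"))
  if (meas$modality != modality || sim$modality != modality)
    stop("expected two ", modality, " maps (got ", meas$modality, " / ",
         sim$modality, ")")
  if (!same_grid(meas, sim))
    stop("measured and simulated maps are on different grids; ",
         "resample the simulation to the measurement grid first ",
         "(resample_to_grid())")
  if (!is.null(meas$norm_power) && !is.null(sim$norm_power) &&
      abs(meas$norm_power - sim$norm_power) > 1e-6 * sim$norm_power)
    stop("maps are normalized to different input powers (",
         meas$norm_power, " W vs ", sim$norm_power, " W)")
  invisible(TRUE)
}

new_diff_map <- function(diff, mask, modality, convention = NULL) {
  diff[!mask] <- NaN
  structure(list(diff = diff, mask = mask, modality = modality,
                 convention = convention),
            class = "diff_map")
}

#' @export
print.diff_map <- function(x, ...) {
  v <- x$diff[x$mask]
  cat(sprintf("<diff_map> %s%s, %d voxels, range [%.4f, %.4f]\n",
              x$modality,
              if (is.null(x$convention)) "" else paste0(" (", x$convention, ")"),
              length(v), min(v), max(v)))
  invisible(x)
}

#' Voxel-wise normalized SAR difference map
#'
#' `diff(x) = (SAR_meas(x) - SAR_sim(x)) / max_in-mask(SAR_sim)`, defined on
#' the intersection of the two masks.
#'
#' @param meas,sim `SAR` [field_map()]s on the same grid and power
#'   normalization (resample the simulation first if needed).
#' @return a `diff_map` object (signed fractions).
#' @export
diff_map_sar <- function(meas, sim) {
  check_comparable(meas, sim, "SAR")
  mask <- meas$mask & sim$mask
  if (!any(mask)) stop("diff_map_sar(): empty intersection mask")
  ref <- mask_max(sim)
  new_diff_map((meas$values - sim$values) / ref, mask, "SAR")
}

#' Voxel-wise normalized B1+ difference map
#'
#' Default (`squared`) convention compares transmit efficiencies:
#' `(|B1_meas|^2 - |B1_sim|^2) / max(|B1_sim|)^2`, consistent with SAR being
#' quadratic in B1. The `linear` convention
#' `(B1_meas - B1_sim) / max(B1_sim)` is retained for magnitude-map
#' difference figures.
#'
#' @param meas,sim `B1` [field_map()]s on the same grid and power
#'   normalization.
#' @param convention `"squared"` (default) or `"linear"`.
#' @return a `diff_map` object.
#' @export
diff_map_b1 <- function(meas, sim, convention = c("squared", "linear")) {
  convention <- match.arg(convention)
  check_comparable(meas, sim, "B1")
  mask <- meas$mask & sim$mask
  if (!any(mask)) stop("diff_map_b1(): empty intersection mask")
  ref <- mask_max(sim)
  d <- if (convention == "squared")
    (meas$values^2 - sim$values^2) / ref^2
  else
    (meas$values - sim$values) / ref
  new_diff_map(d, mask, "B1", convention)
}

#' Modeling uncertainty from difference maps
#'
#' The positive error not exceeded in a given fraction of voxels (default
#' 99.9%): the nearest-rank empirical quantile (value at index
#' `ceiling(q * N)` of the ascending sort) of the pooled signed differences.
#' The maximum over all voxels is deliberately not used — the far tail is
#' poorly sampled and contaminated by edge artifacts. A negative quantile
#' (simulation over-predicts everywhere) is clamped to 0 for the budget;
#' the raw value is kept in the `"raw"` attribute.
#'
#' @param diffs a `diff_map`, a numeric vector/array of signed fractions, or
#'   a list of these (pooled).
#' @param quantile voxel fraction in (0, 1); default 0.999.
#' @return clamped uncertainty as a single number with attributes `raw`,
#'   `n_voxels` and `quantile`.
#' @export
modeling_uncertainty <- function(diffs, quantile = 0.999) {
  if (!is.numeric(quantile) || length(quantile) != 1L ||
      quantile <= 0 || quantile >= 1)
    stop("modeling_uncertainty(): quantile must be in (0, 1)")
  pool_one <- function(d) {
    if (inherits(d, "diff_map")) d$diff[d$mask]
    else as.numeric(d)[!is.na(as.numeric(d))]
  }
  x <- if (is.list(diffs) && !inherits(diffs, "diff_map"))
    unlist(lapply(diffs, pool_one), use.names = FALSE)
  else pool_one(diffs)
  if (!length(x)) stop("modeling_uncertainty(): empty difference pool")
  raw <- unname(stats::quantile(x, probs = quantile, type = 1, names = FALSE))
  structure(max(raw, 0), raw = raw, n_voxels = length(x), quantile = quantile)
}

#' Worst-case aggregation of per-comparison modeling uncertainties
#'
#' When several RF shims and modalities are validated, the final modeling
#' uncertainty is the maximum over all comparisons. Tier 2 requires at least
#' one B1 comparison; tier 3 additionally requires a SAR (or
#' thermometry-derived) comparison.
#'
#' @param results data.frame with columns `shim`, `modality`, `uncertainty`
#'   (fractions), or a named numeric vector (names used as labels).
#' @param tier optional tier level 2 or 3 enforcing modality requirements.
#' @param quantile the quantile the per-comparison values were computed at
#'   (metadata only).
#' @return object of class `modeling_uncertainty_result` with elements
#'   `final`, `which` (row attaining the max), `per_comparison`, `quantile`.
#' @export
worst_case_uncertainty <- function(results, tier = NULL, quantile = 0.999) {
  if (is.numeric(results) && !is.data.frame(results)) {
    results <- data.frame(
      shim = if (is.null(names(results))) paste0("comparison", seq_along(results))
             else names(results),
      modality = NA_character_,
      uncertainty = as.numeric(results))
  }
  stopifnot(is.data.frame(results),
            all(c("shim", "modality", "uncertainty") %in% names(results)))
  if (nrow(results) == 0L)
    stop("worst_case_uncertainty(): at least one comparison required")
  if (any(results$uncertainty < 0))
    stop("worst_case_uncertainty(): uncertainties must be >= 0 (clamped)")
  if (!is.null(tier)) {
    mods <- unique(results$modality[!is.na(results$modality)])
    if (tier >= 2 && !("B1" %in% mods))
      stop("tier ", tier, " validation requires a B1 comparison")
    if (tier >= 3 && !any(c("SAR", "TEMP") %in% mods))
      stop("tier 3 validation requires a SAR (thermometry) comparison in ",
           "addition to B1; only B1 data present")
  }
  k <- which.max(results$uncertainty)
  structure(list(final = results$uncertainty[k],
                 which = results[k, , drop = FALSE],
                 per_comparison = results,
                 quantile = quantile,
                 tier = tier),
            class = "modeling_uncertainty_result")
}

#' @export
print.modeling_uncertainty_result <- function(x, ...) {
  cat(sprintf("<modeling_uncertainty_result> final = %.1f%% (%s, %s) over %d comparisons\n",
              100 * x$final, x$which$shim, x$which$modality,
              nrow(x$per_comparison)))
  invisible(x)
}

# global mean-structure similarity between two maps over a mask
ssim_global <- function(a, b, mask) {
  x <- a[mask]; y <- b[mask]
  c1 <- (0.01 * 360)^2; c2 <- (0.03 * 360)^2
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  cxy <- stats::cov(x, y)
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

wrap_deg <- function(x) ((x + 180) %% 360) - 180

#' Align simulated channel phases to measured relative phase maps
#'
#' Measured per-channel transmit phases carry arbitrary constant offsets
#' relative to the simulation. For each channel the constant offset in
#' [0, 360) maximizing a similarity score between the measured and the
#' offset simulated relative phase map is found by grid search.
#'
#' @param meas_phase list of per-channel measured relative phase maps in
#'   degrees (matrices).
#' @param sim_fields list of per-channel simulated complex field maps (or
#'   phase maps in degrees, if real-valued).
#' @param mask logical grid restricting the comparison; default all voxels.
#' @param step grid-search step in degrees.
#' @param objective `"cosine"` (mean cosine of the wrapped phase difference;
#'   default, continuous across the +-180 branch cut) or `"ssim"` (global
#'   structural-similarity index on the wrapped difference-free maps).
#' @return numeric vector of per-channel offsets in degrees in [0, 360),
#'   with attribute `score` (per-channel objective at the optimum).
#' @export
align_channel_phases <- function(meas_phase, sim_fields, mask = NULL,
                                 step = 1, objective = c("cosine", "ssim")) {
  objective <- match.arg(objective)
  if (length(meas_phase) != length(sim_fields))
    stop("align_channel_phases(): channel-count mismatch (",
         length(meas_phase), " measured vs ", length(sim_fields),
         " simulated)")
  thetas <- seq(0, 360 - step, by = step)
  offsets <- numeric(length(meas_phase))
  scores <- numeric(length(meas_phase))
  for (ch in seq_along(meas_phase)) {
    pm <- meas_phase[[ch]]
    sf <- sim_fields[[ch]]
    ps <- if (is.complex(sf)) Arg(sf) * 180 / pi else sf
    m <- if (is.null(mask)) array(TRUE, dim = dim(pm)) else mask
    score <- if (objective == "cosine") {
      vapply(thetas, function(th) {
        d <- wrap_deg(pm - ps - th)
        mean(cos(d[m] * pi / 180))
      }, 1)
    } else {
      vapply(thetas, function(th)
        ssim_global(pm, wrap_deg(ps + th), m), 1)
    }
    k <- which.max(score)
    offsets[ch] <- thetas[k]
    scores[ch] <- score[k]
  }
  structure(offsets %% 360, score = scores, objective = objective)
}
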