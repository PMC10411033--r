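# Seedable synthetic generators: multichannel phantom field maps, perturbed
# "measurements", heating curves and gamma pSAR populations.
#
# The field model is a geometric surrogate, not an EM solution: each channel
# contributes a complex field peaked at its position on the phantom
# boundary, decaying exponentially into the phantom with a smooth
# propagation-like phase. The pipeline statistics are agnostic to the field
# physics, so this is sufficient to exercise every stage.

#' Elliptical phantom mask
#'
#' @param shape grid shape `c(nrow, ncol)`.
#' @param semiaxes ellipse semi-axes in voxels; default 0.42 of the shape.
#' @return logical matrix.
#' @export
phantom_mask <- function(shape, semiaxes = 0.42 * shape) {
  ctr <- (shape + 1) / 2
  r <- outer(((seq_len(shape[1]) - ctr[1]) / semiaxes[1])^2,
             ((seq_len(shape[2]) - ctr[2]) / semiaxes[2])^2, `+`)
  r <= 1
}

#' Generate per-channel synthetic transmit fields
#'
#' Emulates an n-channel dipole array around an elliptical phantom: channel
#' c sits on the phantom boundary at angle `2*pi*(c-1)/n`; its B1+ surrogate
#' has magnitude `exp(-d/decay_length)` (d = distance from the channel in
#' mm) and a smooth propagation phase `-2*pi*d/wavelength`. An E-field
#' surrogate with a shorter decay provides the SAR basis. `gain_jitter`
#' adds seeded per-channel amplitude variation.
#'
#' @param shape grid shape `c(nrow, ncol)`.
#' @param spacing voxel size in mm (per axis).
#' @param n_channels number of channels >= 1.
#' @param semiaxes phantom semi-axes in voxels.
#' @param decay_length B1 magnitude decay length in mm.
#' @param wavelength phase wavelength in mm.
#' @param gain_jitter sd of the per-channel relative amplitude jitter.
#' @param seed RNG seed (generators are deterministic given seed).
#' @return object of class `synth_channel_fields`: lists `b1` and `e`
#'   of per-channel complex matrices (zero outside the phantom), plus
#'   `mask`, `spacing` and the generator parameters. Recorded phantom
#'   metadata mimics a PVP phantom (eps_r = 37, sigma = 0.4 S/m).
#' @export
synth_channel_fields <- function(shape = c(50, 80), spacing = c(3, 3),
                                 n_channels = 8, semiaxes = 0.42 * shape,
                                 decay_length = 60, wavelength = 120,
                                 gain_jitter = 0, seed = 1) {
  shape <- as.integer(shape)
  if (n_channels < 1) stop("synth_channel_fields(): n_channels must be >= 1")
  if (any(semiaxes > shape / 2))
    stop("synth_channel_fields(): phantom does not fit the grid")
  spacing <- rep_len(spacing, 2L)
  mask <- phantom_mask(shape, semiaxes)
  ctr <- (shape + 1) / 2
  set.seed(seed)
  gains <- 1 + stats::rnorm(n_channels, 0, gain_jitter)
  ang <- 2 * pi * (seq_len(n_channels) - 1) / n_channels
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  b1 <- vector("list", n_channels)
  e <- vector("list", n_channels)
  for (ch in seq_len(n_channels)) {
    pos <- ctr + 1.05 * semiaxes * c(cos(ang[ch]), sin(ang[ch]))
    d <- sqrt(((rows - pos[1]) * spacing[1])^2 +
              ((cols - pos[2]) * spacing[2])^2)
    phase <- -2 * pi * d / wavelength
    bb <- gains[ch] * exp(-d / decay_length) * exp(1i * phase)
    ee <- gains[ch] * exp(-d / (0.8 * decay_length)) * exp(1i * phase)
    bb[!mask] <- 0 + 0i
    ee[!mask] <- 0 + 0i
    b1[[ch]] <- bb
    e[[ch]] <- ee
  }
  structure(list(b1 = b1, e = e, mask = mask, spacing = spacing,
                 n_channels = n_channels, shape = shape,
                 phantom = list(eps_r = 37, sigma_S_per_m = 0.4),
                 params = list(semiaxes = semiaxes,
                               decay_length = decay_length,
                               wavelength = wavelength,
                               gain_jitter = gain_jitter, seed = seed)),
            class = "synth_channel_fields")
}

#' Named RF shim phase vectors
#'
#' The four validation shims: all-zero phases (`"zero"`), alternating
#' 0/180 (`"alt180"`), and hotspots on the left/right phantom side
#' produced by phase focusing on a lateral target (`"left"`, `"right"`),
#' plus `"cp"` (circularly polarized: phase increment 360/n) and seeded
#' `"random"`.
#'
#' @param fields a [synth_channel_fields()].
#' @param shim shim name.
#' @param seed seed for `"random"`.
#' @return numeric vector of per-channel phases in degrees.
#' @export
shim_phases <- function(fields,
                        shim = c("zero", "alt180", "left", "right",
                                 "cp", "random"),
                        seed = 1) {
  shim <- match.arg(shim)
  n <- fields$n_channels
  focus <- function(frac_col) {
    # conjugate-phase focusing on a target voxel
    ctr <- (fields$shape + 1) / 2
    target <- c(round(ctr[1]), round(ctr[2] + frac_col * fields$shape[2] / 4))
    ph <- vapply(fields$b1, function(b) Arg(b[target[1], target[2]]), 1)
    -ph * 180 / pi
  }
  switch(shim,
         zero = rep(0, n),
         alt180 = rep(c(0, 180), length.out = n),
         left = focus(-1),
         right = focus(1),
         cp = (seq_len(n) - 1) * 360 / n,
         random = { set.seed(seed); stats::runif(n, 0, 360) })
}

#' Combine channel fields under an RF shim
#'
#' Coherent sum of `sqrt(power) * exp(i*phase)`-weighted channel fields.
#' The B1+ magnitude map is `|sum|` of the B1 surrogates; the SAR map is
#' `|sum|^2` of the E surrogates. The result is normalized to
#' `sum(powers)` W total input power.
#'
#' @param fields a [synth_channel_fields()].
#' @param phases per-channel phases in degrees.
#' @param powers per-channel input powers in W.
#' @return list with `b1` and `sar` [field_map()]s.
#' @export
combine_shim <- function(fields, phases, powers = rep(1, fields$n_channels)) {
  stopifnot(inherits(fields, "synth_channel_fields"))
  n <- fields$n_channels
  if (length(phases) != n || length(powers) != n)
    stop("combine_shim(): phases and powers must have one entry per channel")
  if (any(powers < 0)) stop("combine_shim(): powers must be >= 0")
  w <- sqrt(powers) * exp(1i * phases * pi / 180)
  sum_w <- function(maps) Reduce(`+`, Map(function(m, wi) wi * m, maps, as.list(w)))
  b1 <- Mod(sum_w(fields$b1))
  sar <- Mod(sum_w(fields$e))^2
  np <- sum(powers)
  if (np <= 0) np <- NULL   # zero-drive maps carry no power normalization
  list(
    b1 = field_map(b1, spacing = fields$spacing, modality = "B1",
                   mask = fields$mask, norm_power = np),
    sar = field_map(sar, spacing = fields$spacing, modality = "SAR",
                    mask = fields$mask, norm_power = np))
}

# white noise smoothed to a correlation length, unit in-mask variance
correlated_noise <- function(shape, mask, corr_length) {
  noise <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
  if (corr_length > 0) {
    size <- 2L * as.integer(ceiling(3 * corr_length)) + 1L
    size <- min(size, 2L * (min(shape) %/% 2L) - 1L)
    w <- gaussian_kernel_1d(size, corr_length)
    full <- array(TRUE, dim = shape)
    noise <- smooth_slice(noise, full, w)
  }
  s <- stats::sd(noise[mask])
  if (s > 0) noise <- noise / s
  noise
}

#' Perturb a map into a synthetic "measurement"
#'
#' `meas = map * (1 + scale_error) + noise`, where the noise is a smooth
#' Gaussian random field (white noise smoothed to `corr_length` voxels)
#' scaled so its in-mask standard deviation is `corr_noise_sigma` times the
#' in-mask maximum of the input. This is the error structure the
#' 99.9%-voxel statistic has to detect. SAR maps are clamped at zero
#' (a measured SAR cannot be negative).
#'
#' @param map a [field_map()].
#' @param scale_error global relative scale error (fraction).
#' @param corr_noise_sigma noise sd as a fraction of the in-mask maximum.
#' @param corr_length noise correlation length in voxels.
#' @param seed RNG seed.
#' @param clamp clamp negative values to 0 for B1/SAR maps (default TRUE).
#' @return perturbed `field_map` with the same grid, mask and modality.
#' @export
perturb_measurement <- function(map, scale_error = 0, corr_noise_sigma = 0,
                                corr_length = 2, seed = 1, clamp = TRUE) {
  stopifnot(inherits(map, "field_map"))
  if (corr_noise_sigma < 0 || corr_length < 0)
    stop("perturb_measurement(): noise parameters must be >= 0")
  vals <- map$values * (1 + scale_error)
  if (corr_noise_sigma > 0) {
    set.seed(seed)
    noise <- correlated_noise(dim(map$values)[1:2], map$mask, corr_length)
    vals <- vals + corr_noise_sigma * mask_max(map) * noise
  }
  if (clamp && map$modality %in% c("B1", "SAR")) vals <- pmax(vals, 0)
  new_field_map(vals, map)
}

#' Generate a synthetic heating series
#'
#' `T(x, t) = T0 + (SAR(x)/Cp) * t + N(0, noise_sigma)` per frame, the
#' linear early-phase heating regime (heating experiments run ~6 min with
#' the fit done on the first minute). An optional saturation time constant
#' `tau` replaces the linear ramp by `(SAR/Cp) * tau * (1 - exp(-t/tau))`
#' to emulate conduction losses at later times.
#'
#' @param sar_map `SAR` [field_map()] driving the heating.
#' @param Cp specific heat capacity in J/(kg K).
#' @param duration total heating time in s.
#' @param frame_interval time between frames in s.
#' @param noise_sigma temperature noise sd in K.
#' @param T0 starting temperature in degC.
#' @param tau saturation time constant in s; `Inf` (default) = purely
#'   linear heating.
#' @param seed RNG seed.
#' @return a [temperature_series()] with frames at `0, dt, 2*dt, ...`.
#' @export
synth_temperature_series <- function(sar_map, Cp = 4000, duration = 60,
                                     frame_interval = 5, noise_sigma = 0,
                                     T0 = 20, tau = Inf, seed = 1) {
  stopifnot(inherits(sar_map, "field_map"))
  if (duration <= 0 || Cp <= 0)
    stop("synth_temperature_series(): duration and Cp must be > 0")
  times <- seq(0, duration, by = frame_interval)
  rate <- sar_map$values / Cp
  rate[!sar_map$mask] <- 0
  set.seed(seed)
  frames <- lapply(times, function(t) {
    ramp <- if (is.finite(tau)) rate * tau * (1 - exp(-t / tau)) else rate * t
    v <- T0 + ramp
    if (noise_sigma > 0)
      v <- v + matrix(stats::rnorm(length(v), 0, noise_sigma), nrow(v), ncol(v))
    field_map(v, spacing = sar_map$spacing, modality = "TEMP",
              mask = sar_map$mask)
  })
  temperature_series(frames, times, Cp = Cp)
}

#' Draw a synthetic pSAR population
#'
#' i.i.d. gamma draws emulating a peak-SAR histogram over body models and
#' RF shims. Defaults `shape = 4, scale = 0.575` give a mean of 2.3 W/kg,
#' matching a prostate-shimmed 7 T body-array population.
#'
#' @param gamma_shape,gamma_scale gamma parameters (> 0).
#' @param n number of draws >= 1.
#' @param seed RNG seed.
#' @return numeric vector of pSAR samples in W/kg.
#' @export
synth_psar_population <- function(gamma_shape = 4, gamma_scale = 0.575,
                                  n = 1000, seed = 1) {
  if (gamma_shape <= 0 || gamma_scale <= 0)
    stop("synth_psar_population(): gamma parameters must be > 0")
  if (n < 1) stop("synth_psar_population(): n must be >= 1")
  set.seed(seed)
  stats::rgamma(n, shape = gamma_shape, scale = gamma_scale)
}
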