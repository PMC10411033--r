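# PRFS-thermometry to SAR conversion.
#
# At RF heating onset and short time scales, temperature rises linearly with
# SAR * t / Cp (heat conduction is negligible in the first minute), so the
# per-voxel OLS slope of T(t) times the specific heat capacity recovers SAR.

#' Construct a temperature time series
#'
#' An ordered stack of temperature frames on a common grid, with acquisition
#' times and the phantom's specific heat capacity.
#'
#' @param frames list of `TEMP` [field_map()]s sharing shape, spacing, mask.
#' @param times acquisition time of each frame in s, strictly increasing,
#'   `times[1] >= 0`. Time 0 is RF-on.
#' @param Cp specific heat capacity in J/(kg K); 4000 for the
#'   polyvinylpyrrolidone phantom used in validation experiments.
#' @return object of class `temperature_series`.
#' @export
temperature_series <- function(frames, times, Cp = 4000) {
  if (!length(frames) || !all(vapply(frames, inherits, TRUE, "field_map")))
    stop("temperature_series(): frames must be a list of field_map objects")
  if (length(times) != length(frames))
    stop("temperature_series(): one acquisition time per frame required")
  times <- as.numeric(times)
  if (times[1L] < 0) stop("temperature_series(): times must start at >= 0")
  if (any(diff(times) <= 0))
    stop("temperature_series(): times must be strictly increasing")
  if (!is.numeric(Cp) || Cp <= 0)
    stop("temperature_series(): Cp must be > 0")
  ref <- frames[[1L]]
  ok <- vapply(frames, function(f)
    identical(dim(f$values), dim(ref$values)) &&
      all(abs(f$spacing - ref$spacing) < 1e-9) &&
      identical(f$mask, ref$mask), TRUE)
  if (!all(ok))
    stop("temperature_series(): all frames must share shape, spacing and mask")
  structure(list(frames = frames, times = times, Cp = Cp),
            class = "temperature_series")
}

#' @export
print.temperature_series <- function(x, ...) {
  cat(sprintf("<temperature_series> %d frames over [%g, %g] s, Cp = %g J/(kg K)\n",
              length(x$frames), x$times[1L], x$times[length(x$times)], x$Cp))
  invisible(x)
}

series_window <- function(series, fit_window) {
  if (is.null(fit_window)) fit_window <- c(series$times[1L], series$times[1L] + 60)
  if (length(fit_window) != 2L || fit_window[1L] >= fit_window[2L])
    stop("fit_window must be an increasing time interval c(t0, t1)")
  sel <- which(series$times >= fit_window[1L] - 1e-9 &
               series$times <= fit_window[2L] + 1e-9)
  if (length(sel) < 2L)
    stop("need at least 2 frames inside the fit window (found ",
         length(sel), ")")
  sel
}

# per-voxel OLS slope and R^2 of T(t), vectorized over the grid
fit_slopes <- function(series, sel, smooth, kernel_size, sigma) {
  frames <- series$frames[sel]
  if (smooth) frames <- lapply(frames, gaussian_smooth,
                               kernel_size = kernel_size, sigma = sigma)
  t <- series$times[sel]
  tc <- t - mean(t)
  sxx <- sum(tc^2)
  dmv <- dim(frames[[1L]]$values)
  acc_ty <- array(0, dim = dmv)   # sum tc_i * T_i
  acc_y <- array(0, dim = dmv)
  acc_yy <- array(0, dim = dmv)
  for (i in seq_along(frames)) {
    v <- frames[[i]]$values
    v[!frames[[i]]$mask] <- 0
    acc_ty <- acc_ty + tc[i] * v
    acc_y <- acc_y + v
    acc_yy <- acc_yy + v^2
  }
  n <- length(t)
  slope <- acc_ty / sxx
  sstot <- acc_yy - acc_y^2 / n
  ssreg <- slope^2 * sxx
  list(slope = slope, sstot = sstot, ssreg = ssreg, n = n)
}

#' Estimate a SAR map from a temperature time series
#'
#' Per in-mask voxel, SAR = Cp times the ordinary-least-squares slope of
#' T(t) over the fit window (default: the first 60 s after RF-on, where
#' heating is linear). Optionally each frame is first smoothed with the
#' mask-aware 3x3 Gaussian kernel to suppress spurious artifacts, as done
#' before fitting in the validation experiments.
#'
#' @param series a [temperature_series()].
#' @param fit_window `c(t0, t1)` in s; default first 60 s from the first
#'   frame.
#' @param smooth smooth each frame with [gaussian_smooth()] first.
#' @param kernel_size,sigma smoothing parameters.
#' @return a `SAR` [field_map()] (W/kg). Noisy voxels with negligible
#'   heating can fit slightly negative; they are reported as-is and can be
#'   screened with [linearity_check()].
#' @export
sar_from_temperature <- function(series, fit_window = NULL, smooth = TRUE,
                                 kernel_size = 3L, sigma = 0.8) {
  stopifnot(inherits(series, "temperature_series"))
  sel <- series_window(series, fit_window)
  fit <- fit_slopes(series, sel, smooth, kernel_size, sigma)
  sar <- series$Cp * fit$slope
  ref <- series$frames[[1L]]
  sar[!ref$mask] <- NaN
  field_map(sar, spacing = ref$spacing, modality = "SAR", mask = ref$mask,
            validate = FALSE)
}

#' Coefficient of determination of the voxel-wise heating fit
#'
#' R-squared of the per-voxel linear fit over the window; used to verify
#' that the chosen window sits in the linear part of the heating curve.
#' Voxels with zero temperature variance get R-squared 1 when the fit is
#' exact (flat line) — a constant series is perfectly linear.
#'
#' @inheritParams sar_from_temperature
#' @param threshold voxels with R-squared below this are flagged in the
#'   `flagged` attribute (fraction of in-mask voxels).
#' @return an `R2` [field_map()] with attribute `flagged`.
#' @export
linearity_check <- function(series, fit_window = NULL, smooth = FALSE,
                            kernel_size = 3L, sigma = 0.8, threshold = 0.9) {
  stopifnot(inherits(series, "temperature_series"))
  sel <- series_window(series, fit_window)
  fit <- fit_slopes(series, sel, smooth, kernel_size, sigma)
  r2 <- ifelse(fit$sstot > 1e-12 * fit$n, pmin(fit$ssreg / fit$sstot, 1), 1)
  ref <- series$frames[[1L]]
  r2[!ref$mask] <- NaN
  out <- field_map(r2, spacing = ref$spacing, modality = "R2",
                   mask = ref$mask, validate = FALSE)
  attr(out, "flagged") <- mean(r2[ref$mask] < threshold)
  out
}
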