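# Intersubject variation from populations of peak local SAR values.
#
# pSAR varies across body models and RF shim settings. A two-parameter gamma
# distribution is fitted to the sample (right-skewed, positive support); the
# 99.9% quantile of the fit (pSAR99) relative to the sample mean gives the
# intersubject-variation term of the uncertainty budget. For small model
# databases the conservative max/min ratio is used instead.

#' Maximum-likelihood gamma fit
#'
#' Two-parameter gamma fit (location fixed at 0) by profile-likelihood
#' Newton iteration on the shape (Minka's closed-form initialisation), or
#' method of moments. With `method = "mle"` the moment fit is also computed
#' and a `moment_disagreement` flag is set when the two shapes differ by
#' more than 5%.
#'
#' @param samples positive numeric vector, length >= 10.
#' @param method `"mle"` (default) or `"moments"`.
#' @param tol,max_iter Newton convergence controls.
#' @return list with `shape`, `scale`, `method`, `converged`, `iterations`,
#'   `loglik`, `moments` (the moment estimates) and `moment_disagreement`.
#' @export
fit_gamma <- function(samples, method = c("mle", "moments"),
                      tol = 1e-10, max_iter = 100L) {
  method <- match.arg(method)
  x <- as.numeric(samples)
  if (length(x) < 10L)
    stop("fit_gamma(): at least 10 samples required (got ", length(x), ")")
  if (any(!is.finite(x)) || any(x <= 0))
    stop("fit_gamma(): all samples must be finite and > 0")
  if (stats::sd(x) < 1e-12 * mean(x))
    stop("fit_gamma(): degenerate sample (zero variance); a gamma ",
         "distribution cannot be fitted")
  mx <- mean(x)
  vx <- stats::var(x)
  mom <- list(shape = mx^2 / vx, scale = vx / mx)
  if (method == "moments") {
    k <- mom$shape; theta <- mom$scale
    converged <- TRUE; it <- 0L
  } else {
    s <- log(mx) - mean(log(x))
    k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      f <- log(k) - digamma(k) - s
      fp <- 1 / k - trigamma(k)
      step <- f / fp
      k_new <- k - step
      if (k_new <= 0) k_new <- k / 2
      if (abs(k_new - k) < tol * k) { k <- k_new; converged <- TRUE; break }
      k <- k_new
    }
    if (!converged)
      stop("fit_gamma(): Newton iteration did not converge after ",
           max_iter, " steps (last shape = ", signif(k, 6),
           ", profile gradient = ", signif(log(k) - digamma(k) - s, 3), ")")
    theta <- mx / k
  }
  ll <- sum(stats::dgamma(x, shape = k, scale = theta, log = TRUE))
  list(shape = k, scale = theta, method = method,
       converged = converged, iterations = it, loglik = ll,
       moments = mom,
       moment_disagreement = abs(k - mom$shape) > 0.05 * mom$shape)
}

#' Gamma quantile of peak SAR (pSAR99)
#'
#' The pSAR value not expected to be exceeded in `quantile` (default 99.9%)
#' of examinations: the inverse gamma CDF at the quantile.
#'
#' @param gamma_shape,gamma_scale fitted gamma parameters (> 0), or a list
#'   from [fit_gamma()] as first argument.
#' @param quantile probability in (0, 1); default 0.999.
#' @return quantile in W/kg.
#' @export
psar99 <- function(gamma_shape, gamma_scale = NULL, quantile = 0.999) {
  if (is.list(gamma_shape)) {
    gamma_scale <- gamma_shape$scale
    gamma_shape <- gamma_shape$shape
  }
  if (!is.numeric(quantile) || quantile <= 0 || quantile >= 1)
    stop("psar99(): quantile must be in (0, 1)")
  if (gamma_shape <= 0 || gamma_scale <= 0)
    stop("psar99(): gamma parameters must be > 0")
  stats::qgamma(quantile, shape = gamma_shape, scale = gamma_scale)
}

#' Intersubject variation from the gamma fit
#'
#' Relative spread of peak SAR over subjects and shims:
#' `pSAR99 / mean(pSAR) - 1` (a fraction; multiply by 100 for percent).
#'
#' @param psar99 fitted 99.9% quantile in W/kg.
#' @param mean_psar arithmetic mean of the pSAR samples in W/kg.
#' @return fraction >= -1.
#' @export
intersubject_variation_gamma <- function(psar99, mean_psar) {
  if (!is.numeric(psar99) || !is.numeric(mean_psar) ||
      psar99 <= 0 || mean_psar <= 0)
    stop("intersubject_variation_gamma(): inputs must be > 0")
  psar99 / mean_psar - 1
}

#' Intersubject variation by the max/min ratio
#'
#' Conservative small-database alternative: `max(samples)/min(samples) - 1`.
#' Used when too few body models are available for a stable gamma fit.
#'
#' @param samples positive numeric vector, length >= 2.
#' @return fraction >= 0.
#' @export
intersubject_variation_minmax <- function(samples) {
  x <- as.numeric(samples)
  if (length(x) < 2L)
    stop("intersubject_variation_minmax(): at least 2 samples required")
  if (any(!is.finite(x)) || any(x <= 0))
    stop("intersubject_variation_minmax(): all samples must be > 0")
  max(x) / min(x) - 1
}

#' Bundle a pSAR sample with its gamma fit
#'
#' Fits the gamma distribution, computes the sample mean, the fitted-
#' distribution mean, pSAR99 and the intersubject variation, and returns
#' them as one object.
#'
#' @param samples positive pSAR values in W/kg.
#' @param labels optional per-sample source labels (body model / RF shim).
#' @param quantile quantile for pSAR99 (default 0.999).
#' @param method gamma fitting method, see [fit_gamma()].
#' @return object of class `psar_population`.
#' @export
psar_population <- function(samples, labels = NULL, quantile = 0.999,
                            method = "mle") {
  fit <- fit_gamma(samples, method = method)
  mean_psar <- mean(samples)     # sample mean, not the fitted mean
  q99 <- psar99(fit, quantile = quantile)
  structure(list(
    samples = as.numeric(samples),
    labels = labels,
    gamma_shape = fit$shape,
    gamma_scale = fit$scale,
    fit = fit,
    mean_psar = mean_psar,
    fitted_mean = fit$shape * fit$scale,
    psar99 = q99,
    quantile = quantile,
    intersubject_variation = intersubject_variation_gamma(q99, mean_psar)),
    class = "psar_population")
}

#' @export
print.psar_population <- function(x, ...) {
  cat(sprintf(paste0(
    "<psar_population> n = %d, gamma(shape = %.3g, scale = %.3g)\n",
    "  mean pSAR = %.3g W/kg (fitted %.3g), pSAR%g = %.3g W/kg\n",
    "  intersubject variation = %.0f%%\n"),
    length(x$samples), x$gamma_shape, x$gamma_scale,
    x$mean_psar, x$fitted_mean, 100 * x$quantile, x$psar99,
    100 * x$intersubject_variation))
  invisible(x)
}

#' Read pSAR samples from a delimited text file
#'
#' Single-column CSV/TSV of pSAR values in W/kg, with optional `model` and
#' `shim` label columns (header row detected automatically).
#'
#' @param path CSV/TSV file.
#' @param column name or index of the value column; default the first
#'   numeric column.
#' @return numeric vector with optional `labels` attribute.
#' @export
read_psar_samples <- function(path, column = NULL) {
  if (!file.exists(path)) stop("read_psar_samples(): no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  has_header <- !grepl("^[0-9.+eE \t,-]+$", first)
  df <- utils::read.table(path, header = has_header, sep = sep,
                          stringsAsFactors = FALSE)
  if (is.null(column)) {
    numcols <- which(vapply(df, is.numeric, TRUE))
    if (!length(numcols)) stop("read_psar_samples(): no numeric column in ", path)
    column <- numcols[1L]
  }
  x <- df[[column]]
  lab <- df[setdiff(names(df), names(df)[column])]
  if (ncol(lab)) attr(x, "labels") <- lab
  x
}
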