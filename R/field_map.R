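# Field-map data model: scalar values on a regular voxel grid.
#
# A field_map is the common container for the three map modalities handled
# by the safety-assessment pipeline:
#   B1   -- B1+ magnitude in uT, non-negative
#   SAR  -- 10-g averaged SAR in W/kg, non-negative inside the mask
#   TEMP -- temperature in degC (or K differences)
# plus the derived "R2" goodness-of-fit maps produced by linearity_check().

FIELD_MODALITIES <- c("B1", "SAR", "TEMP", "R2")

#' Construct a field map
#'
#' A field map holds scalar values on a regular 2D or 3D voxel grid together
#' with the per-axis voxel spacing (mm), an in-phantom mask, the map modality
#' and, for simulated maps, the total input power the map is normalized to.
#'
#' @param values numeric matrix or 3D array. `NaN`/`NA` voxels are masked out.
#' @param spacing per-axis voxel size in mm, all > 0 (recycled to the rank).
#' @param modality one of `"B1"`, `"SAR"`, `"TEMP"`, `"R2"`.
#' @param mask logical array of the same shape; default: all finite voxels.
#' @param norm_power total input power in W the map is normalized to
#'   (`NULL` for temperature maps).
#' @param validate check modality-specific invariants (non-negative B1/SAR
#'   inside the mask). Internal callers that legitimately produce small
#'   negatives (noisy thermometry fits) disable this.
#' @return an object of class `field_map`.
#' @export
field_map <- function(values, spacing = rep(1, length(dim(values))),
                      modality = c("SAR", "B1", "TEMP", "R2"),
                      mask = NULL, norm_power = NULL, validate = TRUE) {
  modality <- match.arg(modality)
  if (is.null(dim(values))) values <- as.matrix(values)
  dm <- dim(values)
  if (!(length(dm) %in% c(2L, 3L)))
    stop("field_map(): values must be a 2D or 3D grid")
  storage.mode(values) <- "double"
  spacing <- rep_len(as.numeric(spacing), length(dm))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("field_map(): spacing entries must be finite and > 0")
  finite <- is.finite(values)
  if (is.null(mask)) {
    mask <- finite
  } else {
    if (!identical(dim(mask), dm))
      stop("field_map(): mask and values must have identical shape")
    mask <- mask & finite
  }
  storage.mode(mask) <- "logical"
  if (validate && modality %in% c("B1", "SAR") && any(values[mask] < 0))
    stop("field_map(): negative values inside the mask are invalid for a ",
         modality, " map")
  if (!is.null(norm_power)) {
    norm_power <- as.numeric(norm_power)
    if (length(norm_power) != 1L || !is.finite(norm_power) || norm_power <= 0)
      stop("field_map(): norm_power must be a single positive number")
  }
  structure(
    list(values = values, spacing = spacing, mask = mask,
         modality = modality, norm_power = norm_power),
    class = "field_map")
}

new_field_map <- function(values, template, modality = template$modality,
                          mask = template$mask, norm_power = template$norm_power) {
  field_map(values, spacing = template$spacing, modality = modality,
            mask = mask, norm_power = norm_power, validate = FALSE)
}

#' @export
print.field_map <- function(x, ...) {
  units <- c(B1 = "uT", SAR = "W/kg", TEMP = "degC", R2 = "")[x$modality]
  cat(sprintf("<field_map> %s [%s], %s voxels, spacing %s mm\n",
              x$modality, units, paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  inm <- x$values[x$mask]
  cat(sprintf("  mask: %d/%d voxels; in-mask range [%.4g, %.4g]\n",
              sum(x$mask), length(x$mask),
              if (length(inm)) min(inm) else NA, if (length(inm)) max(inm) else NA))
  if (!is.null(x$norm_power))
    cat(sprintf("  normalized to %.4g W total input power\n", x$norm_power))
  invisible(x)
}

#' In-mask values of a field map
#' @param map a `field_map`.
#' @return numeric vector of the values inside the mask.
#' @export
mask_values <- function(map) {
  stopifnot(inherits(map, "field_map"))
  map$values[map$mask]
}

#' In-mask maximum of a field map
#'
#' The normalization reference used by the difference maps; errors if the
#' mask is empty or the maximum is not finite and positive.
#' @param map a `field_map`.
#' @param require_positive error unless the maximum is > 0.
#' @return scalar maximum.
#' @export
mask_max <- function(map, require_positive = TRUE) {
  v <- mask_values(map)
  if (!length(v)) stop("mask_max(): empty mask")
  m <- max(v)
  if (require_positive && (!is.finite(m) || m <= 0))
    stop("mask_max(): in-mask maximum must be finite and > 0 to serve as a ",
         "normalization reference")
  m
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    length(a$spacing) == length(b$spacing) &&
    all(abs(a$spacing - b$spacing) <= tol * a$spacing)
}

# ---- readers / writers ----------------------------------------------------

#' Read a field map from disk
#'
#' Supported formats: whitespace/comma-delimited text matrices (2D slices)
#' and NIfTI-1 (`.nii`/`.nii.gz`). `NaN` cells are masked out. Negative
#' values in a B1 or SAR map are rejected.
#'
#' @param path input file.
#' @param format `"tsv"` or `"nifti"`; default guessed from the extension.
#' @param modality map modality (see [field_map()]).
#' @param spacing per-axis voxel size in mm; for NIfTI the header value is
#'   used unless overridden here.
#' @param norm_power total input power in W the map is normalized to.
#' @param mask_path optional 0/1 map in the same format restricting the mask.
#' @return a [field_map()].
#' @export
read_field_map <- function(path, format = NULL,
                           modality = c("SAR", "B1", "TEMP"),
                           spacing = NULL, norm_power = NULL,
                           mask_path = NULL) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("read_field_map(): no such file: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else "tsv"
  }
  format <- match.arg(format, c("tsv", "nifti"))
  if (format == "nifti") {
    values <- read_nifti(path)
    if (is.null(spacing)) spacing <- attr(values, "spacing")
    attr(values, "spacing") <- NULL
  } else {
    values <- read_text_matrix(path)
    if (is.null(spacing)) spacing <- c(1, 1)
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- if (grepl("\\.nii(\\.gz)?$", mask_path)) read_nifti(mask_path)
         else read_text_matrix(mask_path)
    attr(m, "spacing") <- NULL
    if (!identical(dim(m), dim(values)))
      stop("read_field_map(): mask shape does not match map shape")
    mask <- m != 0
  }
  field_map(values, spacing = spacing, modality = modality,
            mask = mask, norm_power = norm_power)
}

read_text_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("read_field_map(): ", path, " is empty")
  split_row <- function(l) {
    parts <- strsplit(trimws(l), "[,\t ]+")[[1L]]
    suppressWarnings(as.numeric(parts))
  }
  rows <- lapply(lines, split_row)
  ncols <- unique(vapply(rows, length, 1L))
  if (length(ncols) != 1L)
    stop("read_field_map(): non-rectangular matrix in ", path,
         " (row lengths ", paste(ncols, collapse = ", "), ")")
  do.call(rbind, rows)
}

#' Write a field map to disk
#'
#' Inverse of [read_field_map()]: text matrices for 2D maps (out-of-mask
#' voxels written as `NaN`) or NIfTI-1.
#'
#' @param map a `field_map`.
#' @param path output file; `.nii`/`.nii.gz` selects NIfTI.
#' @param format `"tsv"` or `"nifti"`; default guessed from the extension.
#' @param digits significant digits for the text format.
#' @return `path`, invisibly.
#' @export
write_field_map <- function(map, path, format = NULL, digits = 10) {
  stopifnot(inherits(map, "field_map"))
  if (is.null(format)) {
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else "tsv"
  }
  format <- match.arg(format, c("tsv", "nifti"))
  values <- map$values
  values[!map$mask] <- NaN
  if (format == "nifti") {
    write_nifti(values, path, spacing = map$spacing)
  } else {
    if (length(dim(values)) != 2L)
      stop("write_field_map(): text format supports 2D maps only")
    txt <- apply(values, 1L, function(r)
      paste(formatC(r, digits = digits, format = "g"), collapse = "\t"))
    writeLines(txt, path)
  }
  invisible(path)
}

# ---- grid preprocessing ---------------------------------------------------

#' Downsample a field map onto a coarser grid
#'
#' Simulated maps are reduced to the (lower) resolution of the measured maps
#' before voxel-wise comparison. Two methods: `block_average` (integer
#' reduction factors; a target voxel is the mean of its source block) and
#' `linear` interpolation at the target voxel centers. Upsampling is
#' refused. Grids are voxel-centered and share the physical origin of the
#' field of view; maps are assumed pre-registered.
#'
#' @param map a `field_map`.
#' @param factor integer reduction factor per axis (scalar recycled);
#'   shorthand for a target grid of shape `dim/factor`, spacing
#'   `spacing*factor`.
#' @param target alternatively, a list with elements `shape` and `spacing`.
#' @param method `"block_average"` or `"linear"`; default block averaging
#'   for integer factors, linear otherwise.
#' @return a `field_map` on the target grid. The mask keeps only target
#'   voxels whose contributing source voxels are all in-mask.
#' @export
resample_to_grid <- function(map, factor = NULL, target = NULL, method = NULL) {
  stopifnot(inherits(map, "field_map"))
  dm <- dim(map$values)
  if (!is.null(factor)) {
    factor <- rep_len(as.numeric(factor), length(dm))
    target <- list(shape = as.integer(round(dm / factor)),
                   spacing = map$spacing * factor)
  }
  if (is.null(target))
    stop("resample_to_grid(): supply `factor` or `target`")
  shape <- as.integer(target$shape)
  spacing <- rep_len(as.numeric(target$spacing), length(dm))
  if (length(shape) != length(dm))
    stop("resample_to_grid(): target rank does not match map rank")
  if (any(spacing < map$spacing * (1 - 1e-9)))
    stop("resample_to_grid(): upsampling requested (target spacing ",
         "finer than source); only downsampling to the measurement grid ",
         "is supported")
  f <- spacing / map$spacing
  integer_factor <- all(abs(f - round(f)) < 1e-9) &&
    all(round(f) * shape == dm)
  if (is.null(method))
    method <- if (integer_factor) "block_average" else "linear"
  method <- match.arg(method, c("block_average", "linear"))
  if (method == "block_average") {
    if (!integer_factor)
      stop("resample_to_grid(): block_average needs integer reduction ",
           "factors that divide the grid evenly; use method = \"linear\"")
    out <- block_average(map$values, map$mask, as.integer(round(f)))
  } else {
    out <- linear_resample(map$values, map$mask, dm, shape)
  }
  field_map(out$values, spacing = spacing, modality = map$modality,
            mask = out$mask, norm_power = map$norm_power, validate = FALSE)
}

block_average <- function(values, mask, f) {
  dm <- dim(values)
  nd <- length(dm)
  shape <- dm %/% f
  # reshape to (f1, s1, f2, s2[, f3, s3]) and reduce over the f axes
  interleaved <- as.vector(rbind(seq_len(nd) * 2 - 1, seq_len(nd) * 2))
  dims6 <- as.vector(rbind(f, shape))
  v <- array(values, dim = dims6)
  m <- array(mask, dim = dims6)
  reduce <- function(a, fun) apply(a, seq_len(nd) * 2, fun)
  vin <- v; vin[!m] <- 0
  cnt <- reduce(m, sum)
  sm <- reduce(vin, sum)
  vals <- ifelse(cnt > 0, sm / cnt, NaN)
  msk <- cnt == prod(f)
  list(values = array(vals, dim = shape), mask = array(msk, dim = shape))
}

linear_resample <- function(values, mask, dm, shape) {
  nd <- length(dm)
  # target voxel centers expressed in source voxel indices (0-based)
  ax <- lapply(seq_len(nd), function(k) {
    x <- ((seq_len(shape[k]) - 0.5) * dm[k] / shape[k]) - 0.5
    pmin(pmax(x, 0), dm[k] - 1)
  })
  lo <- lapply(seq_len(nd), function(k)
    pmax(pmin(floor(ax[[k]]), dm[k] - 2), 0))
  w <- lapply(seq_len(nd), function(k) ax[[k]] - lo[[k]])
  vin <- values; vin[!mask] <- 0
  out <- array(0, dim = shape)
  outm <- array(TRUE, dim = shape)
  corners <- expand.grid(rep(list(0:1), nd))
  idx_grid <- function(k, corner) lo[[k]] + 1 + corner   # 1-based source index
  for (ci in seq_len(nrow(corners))) {
    corner <- as.integer(corners[ci, ])
    wgt <- Reduce(function(a, b) outer(a, b),
                  lapply(seq_len(nd), function(k)
                    if (corner[k] == 1) w[[k]] else 1 - w[[k]]))
    idx <- as.matrix(expand.grid(lapply(seq_len(nd), function(k)
      idx_grid(k, corner[k]))))
    vsub <- array(vin[idx], dim = shape)
    msub <- array(mask[idx], dim = shape)
    out <- out + array(wgt, dim = shape) * vsub
    outm <- outm & msub
  }
  out[!outm] <- NaN
  list(values = out, mask = outm)
}

shift_array <- function(a, off, fill = FALSE) {
  dm <- dim(a)
  nd <- length(dm)
  src <- vector("list", nd)
  dst <- vector("list", nd)
  for (k in seq_len(nd)) {
    o <- off[k]
    if (abs(o) >= dm[k]) return(array(fill, dim = dm))
    if (o >= 0) { src[[k]] <- seq_len(dm[k] - o); dst[[k]] <- src[[k]] + o }
    else { src[[k]] <- seq(1 - o, dm[k]); dst[[k]] <- src[[k]] + o }
  }
  out <- array(fill, dim = dm)
  arg_dst <- c(list(out), dst, list(value = do.call(`[`, c(list(a), src))))
  do.call(`[<-`, arg_dst)
}

#' Erode a phantom mask
#'
#' Removes voxels within Chebyshev distance `depth` of the mask boundary
#' (edge voxels of the phantom are dominated by partial-volume artifacts in
#' measured maps). Voxels outside the grid count as background, so a full
#' mask loses a border of width `depth`.
#'
#' @param mask logical 2D/3D array (or a `field_map`, whose mask is used).
#' @param depth non-negative integer erosion depth in voxels.
#' @return logical array of the same shape.
#' @export
erode_mask <- function(mask, depth = 1L) {
  if (inherits(mask, "field_map")) mask <- mask$mask
  stopifnot(is.logical(mask), !is.null(dim(mask)))
  depth <- as.integer(depth)
  if (depth < 0L) stop("erode_mask(): depth must be >= 0")
  nd <- length(dim(mask))
  offsets <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  out <- mask
  for (i in seq_len(depth)) {
    acc <- out
    for (r in seq_len(nrow(offsets))) {
      o <- offsets[r, ]
      if (all(o == 0)) next
      acc <- acc & shift_array(out, o, fill = FALSE)
    }
    out <- acc
  }
  out
}

gaussian_kernel_1d <- function(size, sigma) {
  if (size %% 2L != 1L) stop("gaussian_smooth(): kernel_size must be odd")
  if (sigma <= 0) stop("gaussian_smooth(): sigma must be > 0")
  h <- (size - 1L) / 2L
  w <- exp(-((-h:h)^2) / (2 * sigma^2))
  w / sum(w)
}

smooth_slice <- function(v, m, w) {
  h <- (length(w) - 1L) / 2L
  num <- array(0, dim = dim(v))
  den <- array(0, dim = dim(v))
  vin <- v; vin[!m] <- 0
  mnum <- m * 1
  for (i in -h:h) for (j in -h:h) {
    wij <- w[i + h + 1L] * w[j + h + 1L]
    num <- num + wij * shift_array(vin, c(i, j), fill = 0)
    den <- den + wij * shift_array(mnum, c(i, j), fill = 0)
  }
  out <- ifelse(den > 0, num / den, NaN)
  out[!m] <- NaN
  out
}

#' Mask-aware Gaussian smoothing
#'
#' 2D discrete convolution with a truncated, renormalized Gaussian kernel,
#' applied per slice for 3D maps. Only in-mask voxels contribute: the kernel
#' weights are renormalized over the in-mask support, so phantom-edge voxels
#' are not dragged toward the background. Thermometry maps are smoothed with
#' the default 3x3 kernel before SAR fitting.
#'
#' @param map a `field_map` (or plain matrix).
#' @param kernel_size odd kernel width in voxels (default 3).
#' @param sigma Gaussian sigma in voxels; default 0.8 (a standard choice for
#'   a 3x3 support; the value is recorded in reports).
#' @return smoothed object of the same class.
#' @export
gaussian_smooth <- function(map, kernel_size = 3L, sigma = 0.8) {
  plain <- !inherits(map, "field_map")
  if (plain) map <- field_map(as.matrix(map), modality = "TEMP")
  w <- gaussian_kernel_1d(as.integer(kernel_size), sigma)
  dm <- dim(map$values)
  if (kernel_size > min(dm[1:2]))
    stop("gaussian_smooth(): kernel larger than the map")
  if (length(dm) == 2L) {
    out <- smooth_slice(map$values, map$mask, w)
  } else {
    out <- map$values
    for (s in seq_len(dm[3L]))
      out[, , s] <- smooth_slice(map$values[, , s], map$mask[, , s], w)
  }
  if (plain) return(out)
  new_field_map(out, map)
}
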