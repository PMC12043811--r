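#' Z-score normalization of an image volume
#'
#' Subtracts the mean and divides by the (sample) standard deviation so the
#' output has mean 0 and SD 1. Used for T2W and DWI sequences. Statistics are
#' computed over all voxels by default; supply `mask` to restrict them (e.g.
#' to the prostate gland) while still transforming every voxel.
#'
#' @param vol `image_volume` (or 3D array, unit spacing assumed).
#' @param mask optional binary volume/array on the same grid; statistics are
#'   computed over `mask != 0` voxels only.
#' @return `image_volume` with standardized intensities.
#' @export
zscore_normalize <- function(vol, mask = NULL) {
  vol <- as_volume(vol)
  sel <- if (is.null(mask)) vol$values else {
    m <- as_volume(mask)
    stop_unless_same_grid(vol, m, "volume and mask")
    vol$values[m$values != 0]
  }
  if (length(sel) < 2L) stop("need at least 2 voxels to standardize")
  mu <- mean(sel)
  sdv <- stats::sd(sel)
  if (!is.finite(sdv) || sdv == 0) {
    stop("degenerate input: volume has zero variance (constant intensities)")
  }
  image_volume((vol$values - mu) / sdv, vol$spacing, vol$origin)
}

#' ADC normalization: percentile clipping followed by Z-scoring
#'
#' Clips intensities to the 0.5 and 99.5 percentiles of the input (linear
#' interpolation quantiles), then subtracts the mean and divides by the
#' standard deviation of the clipped volume. This is the normalization used
#' for ADC maps, whose extreme values are acquisition artefacts rather than
#' tissue signal.
#'
#' @inheritParams zscore_normalize
#' @param probs length-2 clipping probabilities, default `c(0.005, 0.995)`.
#' @return `image_volume`.
#' @export
adc_normalize <- function(vol, probs = c(0.005, 0.995), mask = NULL) {
  vol <- as_volume(vol)
  if (length(probs) != 2L || any(probs < 0) || any(probs > 1) ||
      probs[1] >= probs[2]) {
    stop("'probs' must be increasing probabilities in [0, 1]")
  }
  sel <- if (is.null(mask)) vol$values else {
    m <- as_volume(mask)
    stop_unless_same_grid(vol, m, "volume and mask")
    vol$values[m$values != 0]
  }
  if (length(unique(as.vector(sel))) < 2L) {
    stop("degenerate input: volume has zero variance (constant intensities)")
  }
  bounds <- stats::quantile(sel, probs = probs, names = FALSE, type = 7)
  clipped <- pmin(pmax(vol$values, bounds[1]), bounds[2])
  zscore_normalize(image_volume(clipped, vol$spacing, vol$origin), mask = mask)
}

#' Assemble a preprocessed biparametric MRI stack
#'
#' Resamples DWI and ADC onto the T2W grid (trilinear), Z-scores T2W and DWI,
#' and applies [adc_normalize()] to ADC, returning the three sequences as a
#' single multi-channel stack in fixed channel order (t2w, dwi, adc).
#'
#' @param t2w,dwi,adc `image_volume` inputs (DWI/ADC may be on other grids).
#' @param mask optional gland mask on the T2W grid used to restrict
#'   normalization statistics (default `NULL`: all voxels).
#' @return An object of class `bpmri_stack`: list with elements `t2w`,
#'   `dwi`, `adc`, all on the T2W grid.
#' @export
build_stack <- function(t2w, dwi, adc, mask = NULL) {
  t2w <- as_volume(t2w)
  dwi <- resample_to_reference(as_volume(dwi), t2w, "linear")
  adc <- resample_to_reference(as_volume(adc), t2w, "linear")
  out <- list(
    t2w = zscore_normalize(t2w, mask = mask),
    dwi = zscore_normalize(dwi, mask = mask),
    adc = adc_normalize(adc, mask = mask)
  )
  class(out) <- "bpmri_stack"
  out
}

#' @export
print.bpmri_stack <- function(x, ...) {
  d <- dim(x$t2w$values)
  cat(sprintf("<bpmri_stack> channels t2w, dwi, adc on %d x %d x %d grid\n",
              d[1], d[2], d[3]))
  invisible(x)
}
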