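#' 3D image volume with physical geometry
#'
#' Lightweight container for a 3D scalar lattice (T2W/DWI/ADC intensities,
#' masks, or detector probability maps) together with its voxel spacing and
#' origin in millimetres. Voxel `(i, j, k)` (1-based) is centred at world
#' coordinate `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param values numeric 3D array of voxel values.
#' @param spacing numeric length-3, voxel size in mm per axis; strictly
#'   positive.
#' @param origin numeric length-3, world coordinate (mm) of the first voxel
#'   centre.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("'values' must be a 3D array")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("'spacing' must be 3 strictly positive finite values (mm)")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("'origin' must be 3 finite values (mm)")
  }
  if (any(!is.finite(values))) stop("'values' must be finite")
  structure(
    list(values = values, spacing = spacing, origin = origin),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<image_volume> %d x %d x %d voxels, spacing %s mm, range [%.4g, %.4g]\n",
    d[1], d[2], d[3], paste(format(x$spacing), collapse = " x "),
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$values)

#' Physical volume of one voxel in mm^3
#' @param vol an `image_volume`.
#' @return scalar, mm^3.
#' @export
voxel_volume <- function(vol) prod(as_volume(vol)$spacing)

# Coerce arrays (unit spacing) and image_volume objects to image_volume.
as_volume <- function(x, spacing = c(1, 1, 1)) {
  if (inherits(x, "image_volume")) return(x)
  if (is.array(x) && length(dim(x)) == 3L) return(image_volume(x, spacing))
  stop("expected an image_volume or a 3D array")
}

same_grid <- function(a, b, tol = 1e-8) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_unless_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) {
    stop(sprintf("grid mismatch: %s must share shape, spacing and origin", what))
  }
  invisible(TRUE)
}

#' Resample a volume onto the grid of a reference volume
#'
#' Maps every voxel centre of the reference grid into the moving volume's
#' continuous index space and interpolates. This is the co-registration step
#' used to bring DWI/ADC sequences onto the T2W grid; masks must use
#' `mode = "nearest"` so that the output value set is a subset of the input's.
#' Coordinates falling outside the moving volume are clamped to its edge.
#'
#' @param moving `image_volume` to resample.
#' @param reference `image_volume` whose grid defines the output.
#' @param mode `"linear"` (trilinear, for intensities) or `"nearest"`
#'   (for masks and label maps).
#' @return `image_volume` on the reference grid.
#' @export
resample_to_reference <- function(moving, reference,
                                  mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  moving <- as_volume(moving)
  reference <- as_volume(reference)
  dref <- dim(reference$values)
  if (any(dref < 1L)) stop("zero-sized reference grid")
  dmov <- dim(moving$values)

  # continuous (1-based) index of each reference voxel centre in moving space
  ci <- lapply(1:3, function(ax) {
    w <- reference$origin[ax] + (seq_len(dref[ax]) - 1) * reference$spacing[ax]
    idx <- (w - moving$origin[ax]) / moving$spacing[ax] + 1
    pmin(pmax(idx, 1), dmov[ax])
  })

  expand_axis <- function(v, ax) {
    switch(ax,
      rep(v, times = dref[2] * dref[3]),
      rep(rep(v, each = dref[1]), times = dref[3]),
      rep(v, each = dref[1] * dref[2])
    )
  }

  if (mode == "nearest") {
    ix <- expand_axis(round(ci[[1]]), 1)
    iy <- expand_axis(round(ci[[2]]), 2)
    iz <- expand_axis(round(ci[[3]]), 3)
    lin <- ix + (iy - 1) * dmov[1] + (iz - 1) * dmov[1] * dmov[2]
    out <- moving$values[lin]
  } else {
    # per-axis floor index and fractional part (floor clamped so i0+1 valid)
    f0 <- vector("list", 3)
    fr <- vector("list", 3)
    for (ax in 1:3) {
      lo <- pmin(floor(ci[[ax]]), dmov[ax] - 1)
      lo <- pmax(lo, 1)
      if (dmov[ax] == 1L) lo <- rep(1, dref[ax])
      f0[[ax]] <- lo
      fr[[ax]] <- ci[[ax]] - lo
    }
    x0 <- expand_axis(f0[[1]], 1); fx <- expand_axis(fr[[1]], 1)
    y0 <- expand_axis(f0[[2]], 2); fy <- expand_axis(fr[[2]], 2)
    z0 <- expand_axis(f0[[3]], 3); fz <- expand_axis(fr[[3]], 3)
    nx <- dmov[1]; nxy <- dmov[1] * dmov[2]
    out <- numeric(prod(dref))
    for (dz in 0:1) {
      wz <- if (dz == 0) 1 - fz else fz
      if (dmov[3] == 1L && dz == 1) next
      for (dy in 0:1) {
        wy <- if (dy == 0) 1 - fy else fy
        if (dmov[2] == 1L && dy == 1) next
        for (dx in 0:1) {
          wx <- if (dx == 0) 1 - fx else fx
          if (dmov[1] == 1L && dx == 1) next
          lin <- (x0 + dx) + (y0 + dy - 1) * nx + (z0 + dz - 1) * nxy
          out <- out + wx * wy * wz * moving$values[lin]
        }
      }
    }
  }
  image_volume(array(out, dref), reference$spacing, reference$origin)
}
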