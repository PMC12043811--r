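#' Label connected components of a 3D binary mask
#'
#' Breadth-first labeling of foreground voxels under 6-, 18- or
#' 26-neighbourhood connectivity (26 = faces, edges and corners, the default
#' used for lesion-candidate extraction). Labels are assigned in array scan
#' order of each component's first voxel, so the result is deterministic.
#'
#' @param mask logical/numeric 3D array (or `image_volume`); non-zero is
#'   foreground.
#' @param connectivity 6, 18 or 26.
#' @return integer 3D array of the same shape; 0 = background, components
#'   numbered from 1.
#' @export
label_components <- function(mask, connectivity = 26L) {
  if (inherits(mask, "image_volume")) mask <- mask$values
  if (!is.array(mask) || length(dim(mask)) != 3L) stop("'mask' must be 3D")
  d <- dim(mask)
  pd <- d + 2L
  pm <- array(FALSE, pd)
  pm[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask != 0
  pm <- as.vector(pm)
  offs <- neighbour_offsets(connectivity, pd)
  lab <- integer(length(pm))
  seeds <- which(pm)
  nlab <- 0L
  for (s in seeds) {
    if (lab[s] != 0L) next
    nlab <- nlab + 1L
    lab[s] <- nlab
    frontier <- s
    while (length(frontier)) {
      nb <- rep(frontier, each = length(offs)) + offs
      nb <- nb[pm[nb] & lab[nb] == 0L]
      if (length(nb)) {
        nb <- unique(nb)
        lab[nb] <- nlab
        frontier <- nb
      } else frontier <- integer(0)
    }
  }
  out <- array(lab, pd)[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
  array(as.integer(out), d)
}

# linear-index offsets of the chosen neighbourhood in a padded array
neighbour_offsets <- function(connectivity, pd) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("connectivity must be 6, 18 or 26")
  }
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  ord <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
    "6" = ord == 1L, "18" = ord >= 1L & ord <= 2L, "26" = ord >= 1L
  )
  g <- g[keep, ]
  as.integer(g$dx + g$dy * pd[1] + g$dz * pd[1] * pd[2])
}
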