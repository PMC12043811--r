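#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)` between two binary masks on the same grid.
#' When both masks are empty the score is undefined and `NA` is returned
#' (callers should exclude such cases from averages).
#'
#' @param pred,gt binary volumes/arrays on a common grid.
#' @return numeric in `[0, 1]`, or `NA` if both masks are empty.
#' @export
dice <- function(pred, gt) {
  a <- mask_values(pred); b <- mask_values(gt)
  if (!identical(dim(a), dim(b))) stop("masks must share a grid")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(NA_real_)
  2 * sum(a & b) / (na + nb)
}

mask_values <- function(x) {
  v <- if (inherits(x, "image_volume")) x$values else x
  if (!is.array(v) || length(dim(v)) != 3L) stop("expected a 3D mask")
  v != 0
}

# boundary voxels: mask voxels with at least one background 6-neighbour
# (array faces count as background); returns n x 3 matrix of mm coordinates
surface_coords <- function(mask, spacing) {
  d <- dim(mask)
  pd <- d + 2L
  pm <- array(FALSE, pd)
  pm[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  interior <- pm
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    shifted <- array(FALSE, pd)
    src <- lapply(1:3, function(ax) {
      i <- seq_len(pd[ax]) - off[ax]
      pmin(pmax(i, 1L), pd[ax])
    })
    shifted <- pm[src[[1]], src[[2]], src[[3]]]
    # voxels whose neighbour in this direction is background are boundary
    interior <- interior & shifted
  }
  boundary <- pm & !interior
  idx <- which(boundary, arr.ind = TRUE)
  sweep(idx - 2L, 2, spacing, "*")  # back to 0-based unpadded, then mm
}

# for each row of a, distance (mm) to the nearest row of b
directed_min_dists <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(apply(d2, 1, min), 0))
}

surface_distance_sets <- function(a, b, spacing) {
  a <- mask_values(a); b <- mask_values(b)
  if (!identical(dim(a), dim(b))) stop("masks must share a grid")
  if (!any(a) || !any(b)) stop("surface distances need two non-empty masks")
  sa <- surface_coords(a, spacing)
  sb <- surface_coords(b, spacing)
  list(ab = directed_min_dists(sa, sb), ba = directed_min_dists(sb, sa))
}

#' Hausdorff distance between mask surfaces (mm)
#'
#' Classical (maximum) symmetric Hausdorff distance between the boundary
#' voxels of two masks, computed in physical units. `percentile < 1` gives
#' the robust variant (e.g. 0.95 for HD95).
#'
#' @param a,b non-empty binary volumes/arrays on a common grid.
#' @param spacing voxel spacing in mm (taken from `a` if it is an
#'   `image_volume`).
#' @param percentile quantile of the directed distances, default 1 (max).
#' @return distance in mm.
#' @export
hausdorff <- function(a, b, spacing = NULL, percentile = 1) {
  spacing <- resolve_spacing(a, spacing)
  s <- surface_distance_sets(a, b, spacing)
  if (percentile >= 1) {
    max(max(s$ab), max(s$ba))
  } else {
    max(stats::quantile(s$ab, percentile, names = FALSE),
        stats::quantile(s$ba, percentile, names = FALSE))
  }
}

#' Average symmetric surface distance (mm)
#'
#' Mean of the two directed average surface distances between the boundary
#' voxels of the masks.
#'
#' @inheritParams hausdorff
#' @return distance in mm.
#' @export
assd <- function(a, b, spacing = NULL) {
  spacing <- resolve_spacing(a, spacing)
  s <- surface_distance_sets(a, b, spacing)
  (mean(s$ab) + mean(s$ba)) / 2
}

resolve_spacing <- function(a, spacing) {
  if (is.null(spacing)) {
    if (inherits(a, "image_volume")) a$spacing else c(1, 1, 1)
  } else as.numeric(spacing)
}

#' Relative volume difference
#'
#' `(|pred| - |gt|) / |gt|` as a signed fraction: positive when the
#' prediction over-segments. Set `absolute = TRUE` for the magnitude (the
#' "relative absolute volume difference" reported in quality assessments).
#'
#' @param pred,gt binary volumes/arrays; `gt` must be non-empty.
#' @param absolute return `abs()` of the signed fraction.
#' @return numeric fraction.
#' @export
ravd <- function(pred, gt, absolute = FALSE) {
  a <- mask_values(pred); b <- mask_values(gt)
  if (!identical(dim(a), dim(b))) stop("masks must share a grid")
  if (!any(b)) stop("ground-truth mask is empty")
  out <- (sum(a) - sum(b)) / sum(b)
  if (absolute) abs(out) else out
}

#' Pooled lesion-level recall and precision
#'
#' Recall pools hit ground-truth lesions over annotated aggressive lesions
#' across cases; precision pools hit candidates over retained candidates.
#' Accepts a list of `case_detection` objects or a data.frame with columns
#' `n_annotated`, `n_gt_hit` and optionally `n_detected`,
#' `n_hit_candidates` (the latter defaults to `n_gt_hit`), so published
#' count tables can be fed in directly.
#'
#' @param detections list of `case_detection` or data.frame of counts.
#' @param digits decimals for the rounded view (half-even), default 2.
#' @return list with `recall`, `precision`, `recall_rounded`,
#'   `precision_rounded` and the pooled `totals`.
#' @export
pooled_recall_precision <- function(detections, digits = 2) {
  df <- detection_table(detections)
  if (any(is.na(df$n_gt_hit))) {
    stop("per-case hit counts (n_gt_hit) are required for pooled recall")
  }
  tot <- list(
    n_annotated = sum(df$n_annotated),
    n_gt_hit = sum(df$n_gt_hit),
    n_detected = sum(df$n_detected),
    n_hit_candidates = sum(df$n_hit_candidates)
  )
  recall <- if (tot$n_annotated > 0) tot$n_gt_hit / tot$n_annotated else {
    warning("no annotated lesions: recall undefined")
    NA_real_
  }
  precision <- if (tot$n_detected > 0) {
    tot$n_hit_candidates / tot$n_detected
  } else {
    warning("no retained candidates: precision undefined")
    NA_real_
  }
  list(recall = recall, precision = precision,
       recall_rounded = round(recall, digits),
       precision_rounded = round(precision, digits),
       totals = tot)
}

#' Per-case detection count table
#'
#' @param detections list of `case_detection` objects or a compatible
#'   data.frame.
#' @return data.frame with one row per case.
#' @export
detection_table <- function(detections) {
  if (is.data.frame(detections)) {
    df <- detections
    if (is.null(df$n_annotated)) stop("need a column n_annotated")
    if (is.null(df$n_gt_hit) && is.null(df$n_detected)) {
      stop("need a column n_gt_hit or n_detected")
    }
    if (is.null(df$n_gt_hit)) df$n_gt_hit <- NA_integer_
    if (is.null(df$n_detected)) df$n_detected <- df$n_gt_hit
    if (is.null(df$n_hit_candidates)) df$n_hit_candidates <- df$n_gt_hit
    if (is.null(df$case_id)) df$case_id <- seq_len(nrow(df))
    return(df)
  }
  if (inherits(detections, "case_detection")) detections <- list(detections)
  data.frame(
    case_id = vapply(detections, function(d) as.character(d$case_id),
                     character(1)),
    n_annotated = vapply(detections, `[[`, integer(1), "n_annotated"),
    n_detected = vapply(detections, `[[`, integer(1), "n_detected"),
    n_gt_hit = vapply(detections, `[[`, integer(1), "n_gt_hit"),
    n_hit_candidates = vapply(detections, `[[`, integer(1),
                              "n_hit_candidates"),
    case_probability = vapply(detections, `[[`, numeric(1),
                              "case_probability"),
    empty_aggressive = vapply(detections, `[[`, logical(1),
                              "empty_aggressive")
  )
}

#' Connected-component size analysis of lesion label maps
#'
#' Tabulates per-lesion voxel counts and physical volumes over a list of
#' cases and flags cases whose aggressive label map is empty despite an
#' aggressive case grade (annotation defects).
#'
#' @param cases list of `study_case` objects, or a list of instance-label
#'   (or binary) arrays.
#' @param aggressive_only restrict to lesions with ISUP >= 2 (only
#'   meaningful for `study_case` input).
#' @return list with `sizes` (data.frame: case_id, label, isup, n_voxels,
#'   volume_mm3) and `empty_aggressive` (case ids).
#' @export
component_analysis <- function(cases, aggressive_only = TRUE) {
  rows <- list()
  empty_aggressive <- character(0)
  for (i in seq_along(cases)) {
    x <- cases[[i]]
    if (inherits(x, "study_case")) {
      id <- x$case_id
      les <- if (aggressive_only) aggressive_instance_map(x) else {
        x$lesions$values
      }
      vv <- prod(x$lesions$spacing)
      isup <- x$lesion_isup
      if (isTRUE(x$case_isup >= 2) && !any(les > 0)) {
        empty_aggressive <- c(empty_aggressive, id)
      }
    } else {
      id <- as.character(i)
      les <- if (inherits(x, "image_volume")) x$values else x
      vv <- if (inherits(x, "image_volume")) prod(x$spacing) else 1
      if (all(les %in% c(0, 1))) les <- label_components(les)
      isup <- NULL
    }
    labs <- sort(unique(as.vector(les[les > 0])))
    if (length(labs)) {
      cnt <- as.integer(table(factor(les[les > 0], levels = labs)))
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = id, label = as.integer(labs),
        isup = if (is.null(isup)) NA_integer_ else {
          as.integer(isup[as.character(labs)])
        },
        n_voxels = cnt, volume_mm3 = cnt * vv
      )
    }
  }
  sizes <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(case_id = character(0), label = integer(0),
               isup = integer(0), n_voxels = integer(0),
               volume_mm3 = numeric(0))
  }
  list(sizes = sizes, empty_aggressive = empty_aggressive)
}

#' Stratify per-case scores by lesion size
#'
#' Median split on lesion volume: cases with volume `<= median` form the
#' "below" group, the rest "above" (ties go below). Returns the per-group
#' score distributions and means; significance testing is left to the
#' caller.
#'
#' @param scores numeric per-case scores (e.g. Dice).
#' @param volumes numeric per-case lesion volumes (same length).
#' @return list with `median_volume`, `below`, `above`, `mean_below`,
#'   `mean_above`, `group` (factor aligned to input).
#' @export
stratify_by_size <- function(scores, volumes) {
  if (length(scores) != length(volumes) || length(scores) < 2L) {
    stop("need >= 2 paired scores and volumes")
  }
  med <- stats::median(volumes)
  grp <- factor(ifelse(volumes <= med, "below", "above"),
                levels = c("below", "above"))
  list(
    median_volume = med,
    below = scores[grp == "below"], above = scores[grp == "above"],
    mean_below = mean(scores[grp == "below"], na.rm = TRUE),
    mean_above = mean(scores[grp == "above"], na.rm = TRUE),
    group = grp
  )
}

#' Cohort stratification table
#'
#' Counts and proportions of cases by ISUP grade within cohort and split,
#' plus scanner-manufacturer counts — the descriptive table accompanying a
#' multi-centre cohort.
#'
#' @param meta data.frame with columns `case_id`, `isup` (0..5) and
#'   optionally `cohort`, `split`, `scanner`.
#' @param digits decimals for proportions (half-even rounding), default 2.
#' @return object of class `cohort_table`: list with `isup` (data.frame of
#'   counts/proportions per cohort x split x ISUP) and `scanner` counts.
#' @export
cohort_table <- function(meta, digits = 2) {
  stopifnot(is.data.frame(meta), "isup" %in% names(meta))
  if (any(!meta$isup %in% 0:5)) stop("unknown ISUP grade (must be 0..5)")
  if (is.null(meta$cohort)) meta$cohort <- "cohort"
  if (is.null(meta$split)) meta$split <- "all"
  groups <- unique(meta[, c("cohort", "split")])
  out <- list()
  for (r in seq_len(nrow(groups))) {
    sub <- meta[meta$cohort == groups$cohort[r] &
                  meta$split == groups$split[r], ]
    cnt <- as.integer(table(factor(sub$isup, levels = 0:5)))
    out[[r]] <- data.frame(
      cohort = groups$cohort[r], split = groups$split[r], isup = 0:5,
      n = cnt, proportion = round(cnt / nrow(sub), digits)
    )
  }
  isup_tab <- do.call(rbind, out)
  scanner_tab <- if (!is.null(meta$scanner)) {
    as.data.frame(table(cohort = meta$cohort, scanner = meta$scanner),
                  responseName = "n")
  } else NULL
  structure(list(isup = isup_tab, scanner = scanner_tab,
                 n_total = nrow(meta)),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d cases\n", x$n_total))
  print(x$isup, row.names = FALSE)
  invisible(x)
}
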