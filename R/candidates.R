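#' Configuration of the lesion-candidate extraction pipeline
#'
#' Holds the four decision thresholds of the candidate-selection procedure.
#' All default to 0.10: voxels below 10% probability are clipped when forming
#' soft blobs; candidates whose confidence (maximum probability inside the
#' blob) is below 10% are discarded; hard blobs with less than 10% of their
#' volume inside the prostate gland are classified as extra-prostatic
#' negatives; and a matched candidate counts as a true detection only with at
#' least 10% intersection with its assigned ground-truth lesion. All
#' comparisons are inclusive (`>=`).
#'
#' @param voxel_threshold probability threshold forming the soft-blob support.
#' @param confidence_threshold minimum candidate confidence.
#' @param gland_overlap_threshold minimum fraction of the candidate inside
#'   the gland.
#' @param hit_threshold minimum intersection fraction for a detection.
#' @param connectivity component connectivity (6, 18 or 26).
#' @param hit_denominator `"lesion"` (default; intersection divided by the
#'   ground-truth lesion volume) or `"candidate"`.
#' @return object of class `detection_config`.
#' @export
detection_config <- function(voxel_threshold = 0.10,
                             confidence_threshold = 0.10,
                             gland_overlap_threshold = 0.10,
                             hit_threshold = 0.10,
                             connectivity = 26L,
                             hit_denominator = c("lesion", "candidate")) {
  thr <- c(voxel_threshold, confidence_threshold,
           gland_overlap_threshold, hit_threshold)
  if (any(thr <= 0) || any(thr >= 1)) {
    stop("all thresholds must lie strictly inside (0, 1)")
  }
  if (!as.integer(connectivity) %in% c(6L, 18L, 26L)) {
    stop("connectivity must be 6, 18 or 26")
  }
  structure(list(
    voxel_threshold = voxel_threshold,
    confidence_threshold = confidence_threshold,
    gland_overlap_threshold = gland_overlap_threshold,
    hit_threshold = hit_threshold,
    connectivity = as.integer(connectivity),
    hit_denominator = match.arg(hit_denominator)
  ), class = "detection_config")
}

#' Threshold a probability map into a soft-blob support
#'
#' @param map `image_volume` (or array) with values in `[0, 1]`.
#' @param t voxel threshold in (0, 1); voxels with probability `>= t` are
#'   kept.
#' @return logical 3D array.
#' @export
threshold_map <- function(map, t = 0.10) {
  map <- as_volume(map)
  if (length(t) != 1L || !is.finite(t) || t <= 0 || t >= 1) {
    stop("'t' must be a single value in (0, 1)")
  }
  if (min(map$values) < 0 || max(map$values) > 1) {
    stop("probability map values must lie in [0, 1]")
  }
  map$values >= t
}

#' Extract lesion candidates from a thresholded probability map
#'
#' Connected components of the support become candidates; each carries its
#' voxel support (linear indices), confidence (maximum probability within
#' the component) and physical volume.
#'
#' @param support logical array from [threshold_map()].
#' @param map the probability map the support came from.
#' @param connectivity component connectivity (default 26).
#' @return object of class `lesion_candidates`: list of candidates plus grid
#'   metadata. Each candidate has `id`, `voxels`, `confidence`,
#'   `volume_mm3`, `gland_fraction`, `matched_gt`, `gt_overlap`,
#'   `hit_fraction`, `status`, `hit`.
#' @export
extract_candidates <- function(support, map, connectivity = 26L) {
  map <- as_volume(map)
  if (!identical(dim(support), dim(map$values))) {
    stop("support and map must share a grid")
  }
  lab <- label_components(support, connectivity)
  n <- max(lab)
  vv <- prod(map$spacing)
  cands <- vector("list", n)
  if (n > 0) {
    idx_by_lab <- split(which(lab > 0), lab[lab > 0])
    for (i in seq_len(n)) {
      vox <- idx_by_lab[[as.character(i)]]
      cands[[i]] <- list(
        id = i, voxels = vox,
        confidence = max(map$values[vox]),
        volume_mm3 = length(vox) * vv,
        gland_fraction = NA_real_, matched_gt = NA_integer_,
        gt_overlap = 0L, hit_fraction = NA_real_,
        status = "extracted", hit = FALSE
      )
    }
  }
  structure(list(candidates = cands, dim = dim(map$values),
                 spacing = map$spacing),
            class = "lesion_candidates")
}

#' @export
print.lesion_candidates <- function(x, ...) {
  cat(sprintf("<lesion_candidates> %d candidate(s)\n", length(x$candidates)))
  if (length(x$candidates)) print(candidate_table(x))
  invisible(x)
}

#' Tabulate candidates
#'
#' @param cands `lesion_candidates` or `case_detection`.
#' @return data.frame with one row per candidate.
#' @export
candidate_table <- function(cands) {
  if (inherits(cands, "case_detection")) cands <- cands$candidates
  cl <- cands$candidates
  data.frame(
    id = vapply(cl, `[[`, integer(1), "id"),
    n_voxels = vapply(cl, function(c) length(c$voxels), integer(1)),
    confidence = vapply(cl, `[[`, numeric(1), "confidence"),
    volume_mm3 = vapply(cl, `[[`, numeric(1), "volume_mm3"),
    gland_fraction = vapply(cl, `[[`, numeric(1), "gland_fraction"),
    matched_gt = vapply(cl, `[[`, integer(1), "matched_gt"),
    hit_fraction = vapply(cl, `[[`, numeric(1), "hit_fraction"),
    status = vapply(cl, `[[`, character(1), "status"),
    hit = vapply(cl, `[[`, logical(1), "hit")
  )
}

#' Confidence filter
#'
#' Candidates whose confidence is below `t` are marked `below_confidence`
#' and take no further part in the pipeline.
#'
#' @param cands `lesion_candidates`.
#' @param t confidence threshold; kept iff confidence `>= t`.
#' @return `lesion_candidates` with updated statuses.
#' @export
filter_confidence <- function(cands, t = 0.10) {
  stopifnot(inherits(cands, "lesion_candidates"))
  cands$candidates <- lapply(cands$candidates, function(c) {
    if (c$status == "extracted" && c$confidence < t) {
      c$status <- "below_confidence"
    }
    c
  })
  cands
}

#' Prostate-gland overlap filter
#'
#' Computes, for each surviving candidate, the fraction of its voxels lying
#' inside the gland mask; candidates with fraction below `t` are marked
#' `extra_prostatic` (they sit almost entirely outside the prostate), the
#' rest become `retained`.
#'
#' @param cands `lesion_candidates`.
#' @param gland_mask binary volume/array on the candidate grid.
#' @param t gland-overlap threshold; retained iff fraction `>= t`.
#' @return `lesion_candidates` with gland fractions and statuses filled in.
#' @export
filter_gland_overlap <- function(cands, gland_mask, t = 0.10) {
  stopifnot(inherits(cands, "lesion_candidates"))
  g <- if (inherits(gland_mask, "image_volume")) gland_mask$values else gland_mask
  if (!identical(dim(g), cands$dim)) stop("gland mask grid mismatch")
  gl <- as.vector(g != 0)
  if (!any(gl)) warning("empty gland mask: all candidates extra-prostatic")
  cands$candidates <- lapply(cands$candidates, function(c) {
    if (c$status %in% c("extracted", "retained")) {
      c$gland_fraction <- mean(gl[c$voxels])
      c$status <- if (c$gland_fraction >= t) "retained" else "extra_prostatic"
    }
    c
  })
  cands
}

# overlap (voxel-count) matrix between retained candidates and ground-truth
# instances; rows = candidates (by list position), cols = instance labels
overlap_matrix <- function(cand_list, gt, labels) {
  ov <- matrix(0L, nrow = length(cand_list), ncol = length(labels),
               dimnames = list(NULL, labels))
  for (i in seq_along(cand_list)) {
    vals <- gt[cand_list[[i]]$voxels]
    vals <- vals[vals > 0]
    if (length(vals)) {
      tb <- table(vals)
      ov[i, names(tb)[names(tb) %in% colnames(ov)]] <-
        as.integer(tb[names(tb) %in% colnames(ov)])
    }
  }
  ov
}

#' Match candidates to ground-truth lesions by linear sum assignment
#'
#' Finds the one-to-one assignment of retained candidates to annotated
#' lesions maximizing the total voxel overlap (a maximum-weight bipartite
#' matching, equivalent to the linear sum assignment problem on negative
#' overlaps). Pairs with zero overlap are never matched; unmatched
#' candidates are false-positive candidates and unmatched lesions misses.
#'
#' @param cands `lesion_candidates` (only `retained` candidates enter).
#' @param gt_instance_map integer instance-label volume/array on the same
#'   grid (0 background, positive labels per lesion).
#' @return `lesion_candidates` with `matched_gt`/`gt_overlap` set on matched
#'   candidates, plus attribute `"unmatched_gt"` (labels of missed lesions).
#' @export
assign_candidates <- function(cands, gt_instance_map) {
  stopifnot(inherits(cands, "lesion_candidates"))
  gt <- if (inherits(gt_instance_map, "image_volume")) {
    gt_instance_map$values
  } else gt_instance_map
  if (!identical(dim(gt), cands$dim)) stop("ground-truth grid mismatch")
  gt <- as.vector(gt)
  labels <- sort(unique(gt[gt > 0]))
  ret <- which(vapply(cands$candidates, function(c) c$status == "retained",
                      logical(1)))
  if (length(ret) == 0L || length(labels) == 0L) {
    attr(cands, "unmatched_gt") <- labels
    return(cands)
  }
  ov <- overlap_matrix(cands$candidates[ret], gt, labels)
  m <- max_weight_matching(ov)
  for (k in seq_len(nrow(m))) {
    ci <- ret[m$row[k]]
    cands$candidates[[ci]]$matched_gt <- as.integer(labels[m$col[k]])
    cands$candidates[[ci]]$gt_overlap <- unname(ov[m$row[k], m$col[k]])
  }
  attr(cands, "unmatched_gt") <-
    setdiff(labels, labels[m$col])
  cands
}

# maximum-weight bipartite matching on a non-negative integer weight matrix;
# returns data.frame(row, col) of matched pairs with positive weight
max_weight_matching <- function(w) {
  pos <- which(w > 0, arr.ind = TRUE)
  if (nrow(pos) == 0L) return(data.frame(row = integer(0), col = integer(0)))
  nr <- nrow(w); nc <- ncol(w)
  edges <- as.vector(t(cbind(pos[, 1], pos[, 2] + nr)))
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nr), rep(TRUE, nc)), edges = edges
  )
  mm <- igraph::max_bipartite_match(g, weights = w[pos])
  mate <- mm$matching[seq_len(nr)]
  matched <- which(!is.na(mate))
  data.frame(row = matched, col = mate[matched] - nr)
}

#' Score hits for matched candidates
#'
#' A matched candidate is a hit iff its intersection with its assigned
#' lesion, divided by that lesion's volume (or the candidate's, see
#' `denominator`), reaches `t_hit`; a ground-truth lesion counts as detected
#' iff its assigned candidate is a hit. Only the assigned pair is consulted,
#' regardless of overlap with any other lesion in the case.
#'
#' @param cands `lesion_candidates` after [assign_candidates()].
#' @param gt_instance_map instance-label volume/array.
#' @param t_hit hit threshold; hit iff fraction `>= t_hit`.
#' @param denominator `"lesion"` or `"candidate"`.
#' @return `lesion_candidates` with `hit_fraction`/`hit` filled; attribute
#'   `"detected_gt"` lists labels of detected lesions.
#' @export
score_hits <- function(cands, gt_instance_map, t_hit = 0.10,
                       denominator = c("lesion", "candidate")) {
  denominator <- match.arg(denominator)
  gt <- if (inherits(gt_instance_map, "image_volume")) {
    gt_instance_map$values
  } else gt_instance_map
  gt <- as.vector(gt)
  gt_sizes <- table(gt[gt > 0])
  detected <- integer(0)
  cands$candidates <- lapply(cands$candidates, function(c) {
    if (c$status == "retained" && !is.na(c$matched_gt)) {
      den <- if (denominator == "lesion") {
        as.integer(gt_sizes[as.character(c$matched_gt)])
      } else length(c$voxels)
      c$hit_fraction <- c$gt_overlap / den
      c$hit <- c$hit_fraction >= t_hit
    }
    c
  })
  hits <- vapply(cands$candidates,
                 function(c) isTRUE(c$hit), logical(1))
  detected <- vapply(cands$candidates[hits], `[[`, integer(1), "matched_gt")
  attr(cands, "detected_gt") <- sort(detected)
  cands
}

#' Run the full candidate-extraction and matching pipeline on one case
#'
#' Composes thresholding, connected components, the confidence filter, the
#' gland-overlap filter, linear-sum-assignment matching and hit scoring.
#' Only aggressive ground-truth lesions (ISUP >= 2) enter the ground truth;
#' lower-grade annotations are removed from the instance map before
#' matching.
#'
#' @param case `study_case` (needs `gland`, `lesions`, `lesion_isup`).
#' @param map probability map (`image_volume` on the case grid).
#' @param cfg `detection_config`.
#' @return object of class `case_detection` with fields `case_id`,
#'   `candidates`, `n_annotated`, `n_detected` (retained candidates),
#'   `n_gt_hit`, `case_probability` (max retained confidence, 0 if none),
#'   `detected_mask` (union of retained candidates), `empty_aggressive`
#'   (TRUE when the case is graded aggressive but its aggressive label map
#'   is empty).
#' @export
run_detection <- function(case, map, cfg = detection_config()) {
  stopifnot(inherits(case, "study_case"), inherits(cfg, "detection_config"))
  map <- as_volume(map)
  stop_unless_same_grid(case$lesions, map, "lesion map and probability map")
  stop_unless_same_grid(case$gland, map, "gland mask and probability map")

  agg <- aggressive_instance_map(case)
  labels <- sort(unique(as.vector(agg[agg > 0])))

  support <- threshold_map(map, cfg$voxel_threshold)
  cands <- extract_candidates(support, map, cfg$connectivity)
  cands <- filter_confidence(cands, cfg$confidence_threshold)
  cands <- filter_gland_overlap(cands, case$gland,
                                cfg$gland_overlap_threshold)
  cands <- assign_candidates(cands, agg)
  cands <- score_hits(cands, agg, cfg$hit_threshold, cfg$hit_denominator)

  ret <- Filter(function(c) c$status == "retained", cands$candidates)
  det_mask <- array(FALSE, cands$dim)
  for (c in ret) det_mask[c$voxels] <- TRUE
  structure(list(
    case_id = case$case_id,
    candidates = cands,
    n_annotated = length(labels),
    n_detected = length(ret),
    n_gt_hit = length(attr(cands, "detected_gt")),
    n_hit_candidates = sum(vapply(ret, function(c) isTRUE(c$hit), logical(1))),
    case_probability = if (length(ret)) {
      max(vapply(ret, `[[`, numeric(1), "confidence"))
    } else 0,
    detected_mask = det_mask,
    empty_aggressive = isTRUE(case$case_isup >= 2) && length(labels) == 0L
  ), class = "case_detection")
}

# instance map restricted to aggressive (ISUP >= 2) lesions
aggressive_instance_map <- function(case) {
  les <- case$lesions$values
  isup <- case$lesion_isup
  agg_labels <- as.integer(names(isup)[isup >= 2])
  out <- array(0L, dim(les))
  if (length(agg_labels)) {
    keep <- les %in% agg_labels
    out[keep] <- as.integer(les[keep])
  }
  out
}

#' @export
print.case_detection <- function(x, ...) {
  cat(sprintf(
    "<case_detection> %s: %d annotated aggressive lesion(s), %d retained candidate(s), %d detected, case probability %.3f%s\n",
    x$case_id, x$n_annotated, x$n_detected, x$n_gt_hit, x$case_probability,
    if (x$empty_aggressive) " [empty aggressive label]" else ""
  ))
  invisible(x)
}
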