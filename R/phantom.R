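#' Phantom cohort configuration
#'
#' Defines the synthetic study conditions: an ellipsoidal prostate gland,
#' 0-4 blob lesions per case with a right-skewed (log-normal) size
#' distribution, per-lesion ISUP grades, and bpMRI intensity contrasts.
#' The two cohort styles mirror the observation that one cohort's lesions
#' run larger than the other's: `"PNet-like"` draws equivalent-sphere radii
#' around 7 mm, `"PI-CAI-like"` around 5 mm. The default ISUP distribution
#' uses the published training-cohort proportions
#' (0.52, 0.22, 0.14, 0.07, 0.02, 0.03 for grades 0-5).
#'
#' @param dim grid size in voxels per axis.
#' @param spacing voxel spacing in mm.
#' @param gland_semiaxes gland ellipsoid semi-axes in mm.
#' @param gland_jitter relative per-axis jitter of the semi-axes.
#' @param lesion_count_probs probabilities for 0..4 lesions per case.
#' @param lesion_radius_meanlog,lesion_radius_sdlog log-normal parameters
#'   of the equivalent-sphere lesion radius (mm); defaults depend on
#'   `style`.
#' @param style `"PNet-like"` or `"PI-CAI-like"` cohort tag.
#' @param isup_probs probabilities over ISUP grades 0..5 (per lesion).
#' @param contrasts list of per-sequence intensity triples
#'   `c(background, gland_offset, lesion_offset)` for `t2w`, `dwi`, `adc`.
#' @param noise_sd per-sequence additive Gaussian noise SD (t2w, dwi, adc).
#' @param coarse_dwi_adc generate DWI/ADC on a 2x coarser in-plane grid to
#'   exercise resampling (default TRUE).
#' @param min_separation_mm minimum physical separation (mm) between the
#'   voxel sets of distinct lesions, chosen so that distinct detection
#'   blobs cannot coalesce into one candidate at the default thresholds.
#' @param containment minimum fraction of each lesion inside the gland.
#' @param seed default master seed for [make_cohort()].
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(dim = c(64L, 64L, 32L),
                           spacing = c(1.5, 1.5, 3.0),
                           gland_semiaxes = c(24, 20, 18),
                           gland_jitter = 0.1,
                           lesion_count_probs = c(0.4, 0.3, 0.15, 0.1, 0.05),
                           lesion_radius_meanlog = NULL,
                           lesion_radius_sdlog = 0.35,
                           style = c("PNet-like", "PI-CAI-like"),
                           isup_probs = c(0.52, 0.22, 0.14, 0.07, 0.02, 0.03),
                           contrasts = list(t2w = c(1.0, 0.6, -0.5),
                                            dwi = c(0.5, 0.3, 1.0),
                                            adc = c(1800, -400, -600)),
                           noise_sd = c(0.08, 0.08, 60),
                           coarse_dwi_adc = TRUE,
                           min_separation_mm = 8,
                           containment = 0.9,
                           seed = 1L) {
  style <- match.arg(style)
  if (is.null(lesion_radius_meanlog)) {
    lesion_radius_meanlog <- if (style == "PNet-like") log(7) else log(5)
  }
  check_probs <- function(p, what, len) {
    if (length(p) != len || any(p < 0) || any(p > 1) ||
        abs(sum(p) - 1) > 1e-8) {
      stop(sprintf("'%s' must be %d probabilities summing to 1", what, len))
    }
  }
  check_probs(lesion_count_probs, "lesion_count_probs", 5L)
  check_probs(isup_probs, "isup_probs", 6L)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  if (any(gland_semiaxes <= 0)) stop("gland semi-axes must be positive")
  if (gland_jitter < 0 || gland_jitter >= 1) {
    stop("gland_jitter must lie in [0, 1)")
  }
  half_extent <- (dim - 1) * spacing / 2
  if (any((1 + gland_jitter) * gland_semiaxes > half_extent - spacing)) {
    stop("configuration error: gland does not fit the grid")
  }
  structure(list(
    dim = as.integer(dim), spacing = as.numeric(spacing),
    gland_semiaxes = gland_semiaxes, gland_jitter = gland_jitter,
    lesion_count_probs = lesion_count_probs,
    lesion_radius_meanlog = lesion_radius_meanlog,
    lesion_radius_sdlog = lesion_radius_sdlog,
    style = style, isup_probs = isup_probs,
    contrasts = contrasts, noise_sd = noise_sd,
    coarse_dwi_adc = coarse_dwi_adc,
    min_separation_mm = min_separation_mm,
    containment = containment, seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Simulated-detector operating characteristics
#'
#' Stand-in for a trained voxel-probability detector: each aggressive
#' lesion is independently detected with probability `sensitivity` and, if
#' detected, covered by a probability blob whose peak is drawn from a Beta
#' confidence distribution; false-positive blobs appear at Poisson rates
#' inside and outside the gland.
#'
#' @param sensitivity per-lesion detection probability in `[0, 1]`.
#' @param conf_shape Beta shape parameters of the detected-lesion
#'   confidence distribution.
#' @param conf_fixed optional fixed confidence (overrides `conf_shape`).
#' @param fp_rate_inside,fp_rate_outside expected false-positive blob
#'   counts per case, inside / outside the gland.
#' @param fp_conf_shape Beta shape parameters for false-positive peaks.
#' @param fp_conf_fixed optional fixed false-positive confidence.
#' @param blur_sd spatial decay SD of blob edges, mm.
#' @param coverage fraction of each detected lesion's voxels guaranteed to
#'   receive the full peak probability.
#' @param nonaggressive_blobs also emit low-confidence blobs on ISUP-1
#'   lesions (default off; detectors are trained on aggressive lesions
#'   only).
#' @return object of class `operating_characteristics`.
#' @export
operating_characteristics <- function(sensitivity = 0.8,
                                      conf_shape = c(8, 2),
                                      conf_fixed = NULL,
                                      fp_rate_inside = 0.5,
                                      fp_rate_outside = 0.5,
                                      fp_conf_shape = c(2, 5),
                                      fp_conf_fixed = NULL,
                                      blur_sd = 1.5,
                                      coverage = 0.9,
                                      nonaggressive_blobs = FALSE) {
  if (sensitivity < 0 || sensitivity > 1) {
    stop("sensitivity must lie in [0, 1]")
  }
  if (fp_rate_inside < 0 || fp_rate_outside < 0) {
    stop("false-positive rates must be >= 0")
  }
  for (v in c(conf_fixed, fp_conf_fixed)) {
    if (!is.null(v) && (v < 0 || v > 1)) {
      stop("fixed confidences must lie in [0, 1]")
    }
  }
  if (coverage <= 0 || coverage > 1) stop("coverage must lie in (0, 1]")
  structure(list(
    sensitivity = sensitivity, conf_shape = conf_shape,
    conf_fixed = conf_fixed, fp_rate_inside = fp_rate_inside,
    fp_rate_outside = fp_rate_outside, fp_conf_shape = fp_conf_shape,
    fp_conf_fixed = fp_conf_fixed, blur_sd = blur_sd,
    coverage = coverage, nonaggressive_blobs = nonaggressive_blobs
  ), class = "operating_characteristics")
}

#' Simulated radiologist reading model
#'
#' A radiologist recommending follow-up biopsies with the given
#' sensitivity (probability of recommending when the case harbours
#' aggressive disease) and specificity (probability of not recommending
#' otherwise). The defaults emulate high-sensitivity, modest-specificity
#' PI-RADS-driven referral.
#'
#' @param sensitivity,specificity probabilities in `[0, 1]`.
#' @return object of class `radiologist_model`.
#' @export
radiologist_model <- function(sensitivity = 0.91, specificity = 0.35) {
  if (any(c(sensitivity, specificity) < 0) ||
      any(c(sensitivity, specificity) > 1)) {
    stop("sensitivity and specificity must lie in [0, 1]")
  }
  structure(list(sensitivity = sensitivity, specificity = specificity),
            class = "radiologist_model")
}

# counter-based seed splitting: one master seed deterministically yields
# independent per-case, per-stream seeds (all < 2^31 - 1)
derive_seed <- function(master, counter, stream = 0L) {
  as.integer((as.numeric(master) * 48271 + as.numeric(counter) * 30269 +
                as.numeric(stream) * 24251 + 11) %% 2147483647)
}

# quadratic form ((p - centre) / semiaxes)^2 summed, over the whole grid
ellipsoid_q <- function(dim, spacing, origin, centre, semiaxes) {
  qax <- lapply(1:3, function(ax) {
    w <- origin[ax] + (seq_len(dim[ax]) - 1) * spacing[ax]
    ((w - centre[ax]) / semiaxes[ax])^2
  })
  q <- array(0, dim)
  q <- q + qax[[1]]
  q <- q + rep(rep(qax[[2]], each = dim[1]), times = dim[3])
  q <- q + rep(qax[[3]], each = dim[1] * dim[2])
  q
}

# mm coordinates of linear voxel indices
voxel_coords <- function(idx, dim, spacing, origin) {
  idx0 <- idx - 1L
  i <- idx0 %% dim[1]
  j <- (idx0 %/% dim[1]) %% dim[2]
  k <- idx0 %/% (dim[1] * dim[2])
  cbind(origin[1] + i * spacing[1],
        origin[2] + j * spacing[2],
        origin[3] + k * spacing[3])
}

#' Generate one synthetic study case
#'
#' Builds a gland mask (jittered ellipsoid, a single connected component),
#' places 0-4 non-overlapping ellipsoidal lesions at least 90% inside the
#' gland, grades each lesion, and synthesizes T2W/DWI/ADC intensities with
#' per-sequence contrasts and Gaussian noise. DWI and ADC are produced on a
#' 2x coarser in-plane grid when `config$coarse_dwi_adc` is set, so the
#' preprocessing stage has real resampling work to do. Deterministic given
#' `(config, case_seed)`.
#'
#' @param config a [phantom_config()].
#' @param case_seed integer seed for this case.
#' @param case_id case identifier (default derived from the seed).
#' @param with_intensity generate intensity volumes (set `FALSE` for
#'   detection-only studies; geometry and grades are unchanged).
#' @return object of class `study_case`.
#' @export
make_case <- function(config, case_seed,
                      case_id = sprintf("case_%d", case_seed),
                      with_intensity = TRUE) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$dim; sp <- config$spacing; org <- c(0, 0, 0)
  withr::with_seed(case_seed, {
    centre <- org + (d - 1) * sp / 2
    axes <- config$gland_semiaxes *
      (1 + stats::runif(3, -config$gland_jitter, config$gland_jitter))
    qg <- ellipsoid_q(d, sp, org, centre, axes)
    gland <- qg <= 1

    n_lesions <- sample.int(5L, 1L, prob = config$lesion_count_probs) - 1L
    interior <- which(qg <= 0.6)
    lesions <- array(0L, d)
    lesion_vox <- list()
    placed <- 0L
    for (li in seq_len(n_lesions)) {
      r_eq <- stats::rlnorm(1, config$lesion_radius_meanlog,
                            config$lesion_radius_sdlog)
      ax_jit <- stats::runif(3, 0.8, 1.2)
      vox <- NULL
      r_try <- r_eq
      repeat {
        ok <- FALSE
        for (attempt in 1:40) {
          ci <- interior[sample.int(length(interior), 1L)]
          cc <- as.vector(voxel_coords(ci, d, sp, org))
          radii <- pmax(r_try * ax_jit, 1.01 * sp)
          ql <- ellipsoid_q(d, sp, org, cc, radii)
          cand <- which(ql <= 1)
          if (!length(cand)) next
          if (mean(gland[cand]) < config$containment) next
          if (length(lesion_vox) &&
              !separated(cand, lesion_vox, d, sp,
                         config$min_separation_mm)) next
          vox <- cand; ok <- TRUE; break
        }
        if (ok || r_try < 1.05 * min(sp)) break
        r_try <- r_try * 0.75  # shrink and retry
      }
      if (is.null(vox)) {
        # deterministic fallback: single-voxel lesion at the interior
        # voxel farthest from all placed lesions (placement never fails)
        vox <- farthest_interior_voxel(interior, lesion_vox, d, sp)
      }
      placed <- placed + 1L
      lesions[vox] <- placed
      lesion_vox[[placed]] <- vox
    }
    isup <- if (placed > 0) {
      stats::setNames(sample(0:5, placed, replace = TRUE,
                             prob = config$isup_probs),
                      as.character(seq_len(placed)))
    } else stats::setNames(integer(0), character(0))
    scanner <- sample(c("Siemens", "Philips", "GE"), 1L,
                      prob = c(0.6, 0.3, 0.1))

    seqs <- list(t2w = NULL, dwi = NULL, adc = NULL)
    if (with_intensity) {
      lesion_any <- lesions > 0
      for (sq in names(seqs)) {
        ct <- config$contrasts[[sq]]
        clean <- array(ct[1], d) + ct[2] * gland + ct[3] * lesion_any
        nsd <- config$noise_sd[match(sq, names(seqs))]
        if (sq == "t2w" || !config$coarse_dwi_adc) {
          vals <- clean + array(stats::rnorm(prod(d), 0, nsd), d)
          seqs[[sq]] <- image_volume(vals, sp, org)
        } else {
          cd <- c(ceiling(d[1] / 2), ceiling(d[2] / 2), d[3])
          ref <- image_volume(array(0, cd), c(2 * sp[1], 2 * sp[2], sp[3]),
                              org)
          coarse <- resample_to_reference(image_volume(clean, sp, org),
                                          ref, "linear")
          coarse$values <- coarse$values +
            array(stats::rnorm(prod(cd), 0, nsd), cd)
          seqs[[sq]] <- coarse
        }
      }
    }
    structure(list(
      case_id = case_id,
      t2w = seqs$t2w, dwi = seqs$dwi, adc = seqs$adc,
      gland = image_volume(gland + 0, sp, org),
      lesions = image_volume(lesions, sp, org),
      lesion_isup = isup,
      case_isup = if (placed > 0) max(isup) else 0L,
      cohort = config$style,
      scanner = scanner,
      gland_params = list(centre = centre, semiaxes = axes)
    ), class = "study_case")
  })
}

# physical (mm) separation between a candidate voxel set and all
# previously placed lesions
separated <- function(cand, lesion_vox, d, sp, min_sep_mm) {
  a <- voxel_coords(cand, d, sp, c(0, 0, 0))
  for (vox in lesion_vox) {
    b <- voxel_coords(vox, d, sp, c(0, 0, 0))
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    if (min(d2) < min_sep_mm^2) return(FALSE)
  }
  TRUE
}

farthest_interior_voxel <- function(interior, lesion_vox, d, sp) {
  if (!length(lesion_vox)) return(interior[1L])
  a <- voxel_coords(interior, d, sp, c(0, 0, 0))
  b <- voxel_coords(unlist(lesion_vox), d, sp, c(0, 0, 0))
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  interior[which.max(apply(d2, 1, min))]
}

#' @export
print.study_case <- function(x, ...) {
  cat(sprintf(
    "<study_case> %s (%s, %s): case ISUP %d, %d lesion(s)%s\n",
    x$case_id, x$cohort, x$scanner, x$case_isup, length(x$lesion_isup),
    if (length(x$lesion_isup)) {
      sprintf(" [grades %s]", paste(x$lesion_isup, collapse = ", "))
    } else ""
  ))
  invisible(x)
}

#' Is a case aggressive?
#'
#' @param case a `study_case`.
#' @return TRUE iff the case-level ISUP grade (maximum over lesions, 0 when
#'   none) is at least 2.
#' @export
is_aggressive <- function(case) isTRUE(case$case_isup >= 2)

sample_conf <- function(fixed, shape) {
  if (!is.null(fixed)) fixed else stats::rbeta(1, shape[1], shape[2])
}

#' Simulate a detector probability map for a case
#'
#' Each aggressive (ISUP >= 2) lesion is detected independently with
#' probability `oc$sensitivity`; a detected lesion receives a probability
#' blob whose peak equals the sampled confidence over the central
#' `oc$coverage` fraction of its voxels, decaying (Gaussian, SD
#' `oc$blur_sd` mm) outside the lesion. False-positive blobs are placed at
#' Poisson-distributed counts: inside blobs are centred well within the
#' gland, outside blobs are placed clear of the gland and clipped to its
#' exterior, so they carry zero gland overlap. Values are truncated to
#' `[0, 1]`. Deterministic given `(case, oc, map_seed)`.
#'
#' @param case a `study_case`.
#' @param oc an [operating_characteristics()].
#' @param map_seed integer seed.
#' @return probability map as an `image_volume` on the case grid.
#' @export
make_probability_map <- function(case, oc, map_seed) {
  stopifnot(inherits(case, "study_case"),
            inherits(oc, "operating_characteristics"))
  d <- dim(case$lesions$values); sp <- case$lesions$spacing
  org <- case$lesions$origin
  les <- case$lesions$values
  map <- array(0, d)
  withr::with_seed(map_seed, {
    for (lab in seq_along(case$lesion_isup)) {
      grade <- case$lesion_isup[[lab]]
      eligible <- grade >= 2 ||
        (oc$nonaggressive_blobs && grade >= 1)
      if (!eligible) next
      if (stats::runif(1) >= oc$sensitivity) next
      conf <- sample_conf(oc$conf_fixed, oc$conf_shape)
      if (grade < 2) conf <- conf * 0.3  # sub-threshold-ish low grade blob
      vox <- which(les == lab)
      map <- add_lesion_blob(map, vox, conf, d, sp, org, oc)
    }
    n_in <- stats::rpois(1, oc$fp_rate_inside)
    n_out <- stats::rpois(1, oc$fp_rate_outside)
    if (n_in + n_out > 0) {
      gp <- case$gland_params
      qg <- ellipsoid_q(d, sp, org, gp$centre, gp$semiaxes)
      deep <- which(qg <= 0.5)
      for (k in seq_len(n_in)) {
        conf <- sample_conf(oc$fp_conf_fixed, oc$fp_conf_shape)
        r <- stats::rlnorm(1, log(4), 0.3)
        ci <- deep[sample.int(length(deep), 1L)]
        map <- add_fp_blob(map, ci, conf, r, d, sp, org)
      }
      for (k in seq_len(n_out)) {
        conf <- sample_conf(oc$fp_conf_fixed, oc$fp_conf_shape)
        r <- stats::rlnorm(1, log(4), 0.3)
        if (conf <= 0.02) next
        d_max <- r * sqrt(2 * log(conf / 0.02))
        q_out <- ellipsoid_q(d, sp, org, gp$centre,
                             gp$semiaxes + d_max + 2)
        far <- which(q_out > 1)
        if (!length(far)) next
        ci <- far[sample.int(length(far), 1L)]
        # clip the blob to the gland exterior so it stays fully
        # extra-prostatic
        map <- add_fp_blob(map, ci, conf, r, d, sp, org,
                           exclude = which(qg <= 1))
      }
    }
  })
  image_volume(pmin(pmax(map, 0), 1), sp, org)
}

# full-peak core over `coverage` of the lesion, soft Gaussian halo outside
add_lesion_blob <- function(map, vox, conf, d, sp, org, oc) {
  coords <- voxel_coords(vox, d, sp, org)
  centroid <- colMeans(coords)
  dist_c <- sqrt(rowSums(sweep(coords, 2, centroid)^2))
  n_core <- max(1L, ceiling(oc$coverage * length(vox)))
  core <- vox[order(dist_c)[seq_len(n_core)]]
  ring <- setdiff(vox, core)
  map[core] <- pmax(map[core], conf)
  if (length(ring)) map[ring] <- pmax(map[ring], conf * 0.7)
  # halo: bounding box expanded by 3 SD of the spatial blur
  halo_idx <- bbox_indices(vox, d, ceiling(3 * oc$blur_sd / sp))
  halo_idx <- setdiff(halo_idx, vox)
  if (length(halo_idx)) {
    hc <- voxel_coords(halo_idx, d, sp, org)
    dmin <- apply(
      outer(rowSums(hc^2), rowSums(coords^2), "+") - 2 * hc %*% t(coords),
      1, min
    )
    dmin <- sqrt(pmax(dmin, 0))
    map[halo_idx] <- pmax(map[halo_idx],
                          conf * 0.7 * exp(-dmin^2 / (2 * oc$blur_sd^2)))
  }
  map
}

add_fp_blob <- function(map, centre_idx, conf, r, d, sp, org,
                        exclude = NULL) {
  cc <- as.vector(voxel_coords(centre_idx, d, sp, org))
  reach <- ceiling(2.5 * r / sp)
  idx <- bbox_indices(centre_idx, d, reach)
  if (!is.null(exclude)) idx <- setdiff(idx, exclude)
  if (!length(idx)) return(map)
  pc <- voxel_coords(idx, d, sp, org)
  dd2 <- rowSums(sweep(pc, 2, cc)^2)
  map[idx] <- pmax(map[idx], conf * exp(-0.5 * dd2 / r^2))
  map
}

# linear indices of the voxel bounding box around a voxel set, expanded by
# `pad` voxels per axis (vector of 3)
bbox_indices <- function(vox, d, pad) {
  idx0 <- vox - 1L
  i <- idx0 %% d[1]; j <- (idx0 %/% d[1]) %% d[2]; k <- idx0 %/% (d[1] * d[2])
  rng <- function(v, p, n) max(0L, min(v) - p):min(n - 1L, max(v) + p)
  ii <- rng(i, pad[1], d[1]); jj <- rng(j, pad[2], d[2])
  kk <- rng(k, pad[3], d[3])
  grid <- expand.grid(i = ii, j = jj, k = kk)
  as.integer(grid$i + grid$j * d[1] + grid$k * d[1] * d[2] + 1L)
}

#' Simulate a radiologist biopsy recommendation
#'
#' Bernoulli read: recommends with probability `sensitivity` for an
#' aggressive case and `1 - specificity` otherwise. Deterministic given the
#' seed; vectorized over cases.
#'
#' @param case_is_aggressive logical vector.
#' @param model a [radiologist_model()].
#' @param seed integer seed.
#' @return logical vector of biopsy recommendations.
#' @export
simulate_radiologist <- function(case_is_aggressive, model, seed) {
  stopifnot(inherits(model, "radiologist_model"))
  withr::with_seed(seed, {
    u <- stats::runif(length(case_is_aggressive))
    ifelse(case_is_aggressive, u < model$sensitivity,
           u < 1 - model$specificity)
  })
}

#' Generate a full synthetic cohort
#'
#' Cases, probability maps and radiologist reads for `n_cases` patients.
#' Per-case seeds are split deterministically from the master seed with a
#' counter-based scheme (stable across runs and platforms), so the whole
#' bundle is reproducible from `(config, oc, rad, n_cases, seed)`.
#'
#' @param config a [phantom_config()].
#' @param oc an [operating_characteristics()].
#' @param rad a [radiologist_model()].
#' @param n_cases number of cases (>= 1).
#' @param seed master seed (default `config$seed`).
#' @param with_intensity generate intensity volumes (see [make_case()]).
#' @return object of class `pca_cohort`: list with `cases`, `maps`,
#'   `radiologist` (data.frame `case_id`, `recommend_biopsy`), and the
#'   generating configuration.
#' @export
make_cohort <- function(config, oc = operating_characteristics(),
                        rad = radiologist_model(), n_cases,
                        seed = config$seed, with_intensity = TRUE) {
  if (n_cases < 1) stop("n_cases must be >= 1")
  cases <- vector("list", n_cases)
  maps <- vector("list", n_cases)
  reads <- logical(n_cases)
  for (i in seq_len(n_cases)) {
    id <- sprintf("case_%04d", i)
    cases[[i]] <- make_case(config, derive_seed(seed, i, 1L), case_id = id,
                            with_intensity = with_intensity)
    maps[[i]] <- make_probability_map(cases[[i]], oc,
                                      derive_seed(seed, i, 2L))
    reads[i] <- simulate_radiologist(is_aggressive(cases[[i]]), rad,
                                     derive_seed(seed, i, 3L))
  }
  structure(list(
    cases = cases, maps = maps,
    radiologist = data.frame(
      case_id = vapply(cases, `[[`, character(1), "case_id"),
      recommend_biopsy = reads
    ),
    config = config, oc = oc, rad_model = rad,
    seed = as.integer(seed), n_cases = as.integer(n_cases)
  ), class = "pca_cohort")
}

#' @export
print.pca_cohort <- function(x, ...) {
  n_agg <- sum(vapply(x$cases, is_aggressive, logical(1)))
  cat(sprintf("<pca_cohort> %d cases (%d aggressive), style %s, seed %d\n",
              x$n_cases, n_agg, x$config$style, x$seed))
  invisible(x)
}
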