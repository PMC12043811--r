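nifti_path <- function(dir, name) file.path(dir, paste0(name, ".nii.gz"))

write_nifti_volume <- function(vol, path, datatype = "auto") {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

read_nifti_volume <- function(path, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  vals <- array(as.vector(img), dim(img))
  image_volume(vals, RNifti::pixdim(img)[1:3], origin)
}

#' Write a study case to a directory
#'
#' Persists the case in the on-disk layout `t2w/dwi/adc/gland/lesions`
#' (+ optional `prob`) as NIfTI, with ISUP grades and tags in a
#' `meta.json` sidecar. The round trip through [read_case()] is lossless
#' for voxels, spacing, instance labels and grades.
#'
#' @param case a `study_case`.
#' @param dir output directory (created if needed).
#' @param prob optional probability map (`image_volume`) saved alongside.
#' @return `dir`, invisibly.
#' @export
write_case <- function(case, dir, prob = NULL) {
  stopifnot(inherits(case, "study_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sq in c("t2w", "dwi", "adc")) {
    if (!is.null(case[[sq]])) {
      write_nifti_volume(case[[sq]], nifti_path(dir, sq))
    }
  }
  write_nifti_volume(case$gland, nifti_path(dir, "gland"),
                     datatype = "uint8")
  write_nifti_volume(case$lesions, nifti_path(dir, "lesions"),
                     datatype = "int16")
  if (!is.null(prob)) write_nifti_volume(prob, nifti_path(dir, "prob"))
  meta <- list(
    case_id = case$case_id,
    cohort = case$cohort,
    scanner = case$scanner,
    case_isup = case$case_isup,
    lesion_isup = as.list(case$lesion_isup),
    aggressive = is_aggressive(case)
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a study case from a directory
#'
#' Validates the layout written by [write_case()]: mandatory files must be
#' present, the gland and lesion maps must share the T2W grid, lesion
#' labels must be integers matching the sidecar, and ISUP grades must lie
#' in 0..5.
#'
#' @param dir case directory.
#' @return a `study_case` (plus element `prob` when a probability map was
#'   stored).
#' @export
read_case <- function(dir) {
  need <- c("gland", "lesions")
  for (f in need) {
    if (!file.exists(nifti_path(dir, f))) {
      stop(sprintf("missing mandatory file '%s.nii.gz' in %s", f, dir))
    }
  }
  if (!file.exists(file.path(dir, "meta.json"))) {
    stop(sprintf("missing meta.json in %s", dir))
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  vols <- list()
  for (sq in c("t2w", "dwi", "adc")) {
    p <- nifti_path(dir, sq)
    vols[[sq]] <- if (file.exists(p)) read_nifti_volume(p) else NULL
  }
  gland <- read_nifti_volume(nifti_path(dir, "gland"))
  lesions <- read_nifti_volume(nifti_path(dir, "lesions"))
  stop_unless_same_grid(gland, lesions, "gland and lesion maps")
  if (!is.null(vols$t2w)) {
    stop_unless_same_grid(vols$t2w, lesions, "t2w and lesion maps")
  }
  if (any(lesions$values != round(lesions$values))) {
    stop("lesion map must carry integer instance labels")
  }
  lesions$values <- array(as.integer(lesions$values), dim(lesions$values))
  isup <- unlist(meta$lesion_isup)
  if (length(isup) && (any(isup < 0) || any(isup > 5))) {
    stop("ISUP grades in meta.json must lie in 0..5")
  }
  labs <- sort(unique(lesions$values[lesions$values > 0]))
  if (!setequal(as.character(labs), names(isup))) {
    stop("lesion instance labels do not match meta.json ISUP entries")
  }
  isup <- if (length(labs)) {
    v <- isup[as.character(labs)]
    storage.mode(v) <- "integer"
    v
  } else stats::setNames(integer(0), character(0))
  out <- structure(list(
    case_id = meta$case_id,
    t2w = vols$t2w, dwi = vols$dwi, adc = vols$adc,
    gland = gland, lesions = lesions,
    lesion_isup = isup,
    case_isup = as.integer(meta$case_isup),
    cohort = meta$cohort, scanner = meta$scanner,
    gland_params = NULL
  ), class = "study_case")
  p <- nifti_path(dir, "prob")
  if (file.exists(p)) out$prob <- read_nifti_volume(p)
  out
}

#' Write a cohort to disk
#'
#' One subdirectory per case (NIfTI volumes + `meta.json`) and a
#' cohort-level `radiologist.csv` with the per-case biopsy
#' recommendations.
#'
#' @param cohort a `pca_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pca_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(cohort$n_cases)) {
    write_case(cohort$cases[[i]],
               file.path(dir, cohort$cases[[i]]$case_id),
               prob = cohort$maps[[i]])
  }
  utils::write.csv(cohort$radiologist, file.path(dir, "radiologist.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort from disk
#'
#' @param dir directory written by [write_cohort()].
#' @return a `pca_cohort` (configuration slots are `NULL`; geometry,
#'   grades, maps and reads are restored).
#' @export
read_cohort <- function(dir) {
  rad_path <- file.path(dir, "radiologist.csv")
  if (!file.exists(rad_path)) stop("missing radiologist.csv")
  rad <- utils::read.csv(rad_path)
  case_dirs <- sort(list.dirs(dir, recursive = FALSE))
  cases <- list(); maps <- list()
  for (cd in case_dirs) {
    cs <- read_case(cd)
    maps[[length(maps) + 1L]] <- cs$prob
    cs$prob <- NULL
    cases[[length(cases) + 1L]] <- cs
  }
  structure(list(
    cases = cases, maps = maps, radiologist = rad,
    config = NULL, oc = NULL, rad_model = NULL,
    seed = NA_integer_, n_cases = length(cases)
  ), class = "pca_cohort")
}

#' End-to-end pipeline configuration
#'
#' @param out_dir run output directory.
#' @param n_cases cohort size for synthetic runs.
#' @param seed master seed; every source of randomness flows from it.
#' @param phantom,oc,rad generators for synthetic runs.
#' @param detection a [detection_config()].
#' @param digits report rounding (decimals).
#' @param with_intensity generate and preprocess intensity volumes.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, n_cases = 20L, seed = 1L,
                       phantom = phantom_config(),
                       oc = operating_characteristics(),
                       rad = radiologist_model(),
                       detection = detection_config(),
                       digits = 2, with_intensity = FALSE) {
  structure(list(out_dir = out_dir, n_cases = as.integer(n_cases),
                 seed = as.integer(seed), phantom = phantom, oc = oc,
                 rad = rad, detection = detection, digits = digits,
                 with_intensity = with_intensity),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::serializeJSON(
    config[setdiff(names(config), "out_dir")])), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic evaluation pipeline
#'
#' Generates a cohort, runs candidate extraction and matching on every
#' case, computes segmentation metrics on the retained-candidate masks,
#' simulates the triage protocol, and writes `detection.csv`,
#' `metrics.csv`, `triage_records.csv`, `triage_summary.json` and
#' `run_log.txt` to the output directory. Fully deterministic given the
#' seed; every report embeds the seed and a configuration hash.
#'
#' @param config a [run_config()].
#' @return list with `cohort`, `detections`, `metrics`, `triage`, and the
#'   output paths, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE)
    })
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)

  cohort <- stage("generate", make_cohort(
    config$phantom, config$oc, config$rad, config$n_cases,
    seed = config$seed, with_intensity = config$with_intensity
  ))
  if (config$with_intensity) {
    stage("preprocess", for (cs in cohort$cases) {
      invisible(build_stack(cs$t2w, cs$dwi, cs$adc))
    })
  }
  detections <- stage("detect", lapply(seq_len(cohort$n_cases), function(i) {
    run_detection(cohort$cases[[i]], cohort$maps[[i]], config$detection)
  }))
  det_df <- detection_table(detections)

  metrics_df <- stage("metrics", {
    rows <- lapply(seq_len(cohort$n_cases), function(i) {
      cs <- cohort$cases[[i]]
      dt <- detections[[i]]
      gt <- aggressive_instance_map(cs) > 0
      pred <- dt$detected_mask
      has_both <- any(gt) && any(pred)
      data.frame(
        case_id = cs$case_id,
        dice = if (any(gt) || any(pred)) dice(pred, gt) else NA_real_,
        hausdorff_mm = if (has_both) {
          hausdorff(pred, gt, cs$lesions$spacing)
        } else NA_real_,
        assd_mm = if (has_both) assd(pred, gt, cs$lesions$spacing) else {
          NA_real_
        },
        ravd = if (any(gt)) ravd(pred, gt) else NA_real_
      )
    })
    do.call(rbind, rows)
  })

  triage <- stage("triage", simulate_protocol(detections,
                                              cohort$radiologist))
  pooled <- pooled_recall_precision(detections, digits = config$digits)

  paths <- list(
    detection = file.path(config$out_dir, "detection.csv"),
    metrics = file.path(config$out_dir, "metrics.csv"),
    triage_records = file.path(config$out_dir, "triage_records.csv"),
    triage_summary = file.path(config$out_dir, "triage_summary.json"),
    log = file.path(config$out_dir, "run_log.txt")
  )
  utils::write.csv(det_df, paths$detection, row.names = FALSE)
  utils::write.csv(metrics_df, paths$metrics, row.names = FALSE)
  utils::write.csv(triage$records, paths$triage_records, row.names = FALSE)
  jsonlite::write_json(list(
    seed = config$seed, config_hash = hash, n_cases = triage$n_cases,
    categories = as.list(stats::setNames(triage$category_counts,
                                         triage$categories)),
    category_pct = as.list(stats::setNames(triage$category_pct,
                                           triage$categories)),
    avoided_biopsies = triage$avoided_biopsies,
    dangerous_avoidances = triage$dangerous_avoidances,
    biopsies_radiologist = triage$biopsies_radiologist,
    biopsies_hybrid = triage$biopsies_hybrid,
    pooled_recall = pooled$recall_rounded,
    pooled_precision = pooled$precision_rounded
  ), paths$triage_summary, auto_unbox = TRUE, digits = NA)
  writeLines(c(
    sprintf("seed: %d", config$seed),
    sprintf("config_hash: %s", hash),
    sprintf("n_cases: %d", cohort$n_cases),
    sprintf("pooled_recall: %s", format(pooled$recall)),
    sprintf("pooled_precision: %s", format(pooled$precision))
  ), paths$log)
  invisible(list(cohort = cohort, detections = detections,
                 metrics = metrics_df, triage = triage,
                 pooled = pooled, paths = paths, config_hash = hash))
}
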