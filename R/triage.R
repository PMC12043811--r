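#' The six biopsy-recommendation categories
#'
#' @return character vector of category levels, in reporting order.
#' @export
triage_categories <- function() {
  c("correct_avoided", "correct", "overestimate",
    "overestimate_unnecessary", "underestimate", "dangerous_underestimate")
}

#' Categorize a case by annotated vs detected lesion counts
#'
#' Assigns each `(n_annotated, n_detected)` pair to exactly one of six
#' categories: `correct_avoided` (no lesions, none detected — an
#' unnecessary biopsy avoided), `correct` (lesions present, count matched),
#' `overestimate` (lesions present, count overestimated),
#' `overestimate_unnecessary` (no lesions but some detected — an
#' unnecessary biopsy recommended), `underestimate` (two or more lesions,
#' between one and fewer than present detected), and
#' `dangerous_underestimate` (lesions present but none detected — a
#' necessary biopsy avoided). The literal category definitions only cover
#' the missed-everything case for two or more lesions; a missed solitary
#' lesion is assigned `dangerous_underestimate` by default since it too
#' avoids a necessary biopsy. With `strict = TRUE` that pair is returned as
#' `NA` and should be reported separately.
#'
#' @param n_annotated,n_detected non-negative integer vectors (recycled).
#' @param strict keep the literal definitions, leaving `(1, 0)`
#'   uncategorized (`NA`).
#' @return factor with levels [triage_categories()].
#' @export
categorize <- function(n_annotated, n_detected, strict = FALSE) {
  n <- as.integer(n_annotated); d <- as.integer(n_detected)
  if (any(is.na(n)) || any(is.na(d)) || any(n < 0) || any(d < 0)) {
    stop("counts must be non-negative integers")
  }
  k <- max(length(n), length(d))
  n <- rep_len(n, k); d <- rep_len(d, k)
  out <- character(k)
  out[n == 0 & d == 0] <- "correct_avoided"
  out[n == 0 & d > 0] <- "overestimate_unnecessary"
  out[n >= 1 & d == n] <- "correct"
  out[n >= 1 & d > n] <- "overestimate"
  out[n >= 2 & d >= 1 & d < n] <- "underestimate"
  out[n >= 2 & d == 0] <- "dangerous_underestimate"
  out[n == 1 & d == 0] <- if (strict) NA_character_ else {
    "dangerous_underestimate"
  }
  factor(out, levels = triage_categories())
}

#' CAD biopsy recommendation for a case
#'
#' The CAD recommends a biopsy iff at least one candidate was retained
#' (equivalently, iff the case probability reaches the confidence
#' threshold). Ground truth plays no role: the recommendation is made at
#' decision time.
#'
#' @param det a `case_detection`, a list of them, or an integer vector of
#'   retained-candidate counts.
#' @return logical vector.
#' @export
cad_recommendation <- function(det) {
  if (inherits(det, "case_detection")) return(det$n_detected >= 1L)
  if (is.list(det)) {
    return(vapply(det, function(d) d$n_detected >= 1L, logical(1)))
  }
  as.integer(det) >= 1L
}

#' Hybrid radiologist + CAD biopsy decision
#'
#' A biopsy is performed iff both the radiologist and the CAD recommend
#' it: a radiologist "no" is final, and a CAD "no" vetoes a radiologist
#' "yes". The hybrid can therefore only remove biopsies relative to the
#' radiologist alone.
#'
#' @param radiologist,cad logical vectors (recycled).
#' @return logical vector.
#' @export
hybrid_decision <- function(radiologist, cad) {
  as.logical(radiologist) & as.logical(cad)
}

#' Simulate the hybrid biopsy-triage protocol over a cohort
#'
#' Builds per-case triage records (category, radiologist/CAD/hybrid
#' decisions) and cohort summaries: category frequencies, biopsies avoided
#' (radiologist yes, CAD no, truth negative), dangerous avoidances
#' (radiologist yes, CAD no, truth positive), and biopsy counts under the
#' radiologist alone versus the hybrid protocol.
#'
#' @param detections list of `case_detection` objects or a data.frame with
#'   `case_id`, `n_annotated`, `n_detected`.
#' @param radiologist data.frame with `case_id` and logical
#'   `recommend_biopsy`.
#' @param truth optional data.frame with `case_id` and logical
#'   `aggressive`; defaults to `n_annotated >= 1`.
#' @param strict passed to [categorize()].
#' @return object of class `triage_summary`; its `records` element holds
#'   the per-case table.
#' @export
simulate_protocol <- function(detections, radiologist, truth = NULL,
                              strict = FALSE) {
  det <- detection_table(detections)
  det$case_id <- as.character(det$case_id)
  radiologist$case_id <- as.character(radiologist$case_id)
  if (!setequal(det$case_id, radiologist$case_id) ||
      anyDuplicated(det$case_id) || anyDuplicated(radiologist$case_id)) {
    stop("case ids of detections and radiologist reads do not match")
  }
  rad <- radiologist$recommend_biopsy[match(det$case_id,
                                            radiologist$case_id)]
  agg <- if (is.null(truth)) det$n_annotated >= 1L else {
    truth$case_id <- as.character(truth$case_id)
    if (!setequal(det$case_id, truth$case_id)) {
      stop("case ids of truth table do not match detections")
    }
    truth$aggressive[match(det$case_id, truth$case_id)]
  }
  cad <- cad_recommendation(det$n_detected)
  hybrid <- hybrid_decision(rad, cad)
  records <- data.frame(
    case_id = det$case_id,
    n_annotated = det$n_annotated,
    n_detected = det$n_detected,
    category = categorize(det$n_annotated, det$n_detected, strict = strict),
    aggressive = agg,
    radiologist = rad,
    cad = cad,
    hybrid = hybrid
  )
  n <- nrow(records)
  cat_counts <- table(records$category, useNA = "no")
  summary <- structure(list(
    records = records,
    n_cases = n,
    category_counts = as.integer(cat_counts),
    category_pct = relative_frequencies(as.integer(cat_counts), n),
    categories = names(cat_counts),
    n_uncategorized = sum(is.na(records$category)),
    avoided_biopsies = sum(rad & !cad & !agg),
    dangerous_avoidances = sum(rad & !cad & agg),
    unnecessary_cad_recommendations = sum(cad & !agg),
    biopsies_radiologist = sum(rad),
    biopsies_hybrid = sum(hybrid)
  ), class = "triage_summary")
  summary
}

#' @export
print.triage_summary <- function(x, ...) {
  cat(sprintf("<triage_summary> %d cases\n", x$n_cases))
  tab <- data.frame(category = x$categories, n = x$category_counts,
                    pct = x$category_pct)
  print(tab, row.names = FALSE)
  if (x$n_uncategorized > 0) {
    cat(sprintf("  uncategorized (strict mode): %d\n", x$n_uncategorized))
  }
  cat(sprintf(
    "  biopsies: radiologist alone %d, hybrid %d; avoided unnecessary %d (%.2f%%); dangerous avoidances %d\n",
    x$biopsies_radiologist, x$biopsies_hybrid, x$avoided_biopsies,
    relative_frequencies(x$avoided_biopsies, x$n_cases), x$dangerous_avoidances
  ))
  invisible(x)
}

#' Relative frequency as a percentage
#'
#' `100 * count / denominator`, rounded half-even to the requested number
#' of decimals (reports quote one or two).
#'
#' @param count numeric count(s).
#' @param denominator positive denominator (cohort size).
#' @param digits decimals, default 2.
#' @return numeric percentage(s).
#' @export
relative_frequencies <- function(count, denominator, digits = 2) {
  if (length(denominator) != 1L || !is.finite(denominator) ||
      denominator < 1) {
    stop("denominator must be a single value >= 1")
  }
  round(100 * count / denominator, digits)
}
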