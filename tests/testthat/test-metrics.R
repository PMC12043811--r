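test_that("dice handles identity, disjoint, partial and degenerate masks", {
  d <- c(6, 6, 2)
  a <- array(FALSE, d); a[1:10] <- TRUE
  b <- array(FALSE, d); b[6:15] <- TRUE
  expect_equal(dice(a, a), 1.0)
  expect_equal(dice(a, array(FALSE, d)), 0)
  expect_equal(dice(a, b), 0.5)  # |A| = |B| = 10, overlap 5
  expect_equal(dice(a, b), dice(b, a))
  expect_true(is.na(dice(array(FALSE, d), array(FALSE, d))))
})

test_that("surface distances reproduce closed-form separations", {
  d <- c(8, 4, 4)
  a <- array(FALSE, d); a[2, 2, 2] <- TRUE
  b <- array(FALSE, d); b[5, 2, 2] <- TRUE  # 3 voxels apart on axis 1
  sp <- c(2, 1, 1)
  expect_equal(hausdorff(a, b, sp), 6)
  expect_equal(assd(a, b, sp), 6)
  expect_equal(hausdorff(a, a, sp), 0)
  expect_equal(assd(a, a, sp), 0)
  expect_error(hausdorff(a, array(FALSE, d), sp), "non-empty")
})

test_that("surface distances agree with a brute-force all-pairs oracle", {
  set.seed(20)
  for (rep in 1:12) {
    a <- random_mask(); b <- random_mask()
    sp <- c(sample(c(0.5, 1, 2), 1), 1, sample(c(1, 3), 1))
    want <- naive_surface_metrics(a, b, sp)
    expect_equal(hausdorff(a, b, sp), want$hd, tolerance = 1e-9)
    expect_equal(assd(a, b, sp), want$assd, tolerance = 1e-9)
    # symmetry and ordering invariants
    expect_equal(hausdorff(a, b, sp), hausdorff(b, a, sp), tolerance = 1e-12)
    expect_equal(assd(a, b, sp), assd(b, a, sp), tolerance = 1e-12)
    expect_gte(hausdorff(a, b, sp) + 1e-12, assd(a, b, sp))
  }
})

test_that("relative volume difference is a signed fraction anchored on truth", {
  d <- c(12, 10, 1)
  gt <- array(FALSE, d); gt[1:100] <- TRUE
  over <- array(FALSE, d); over[1:110] <- TRUE
  under <- array(FALSE, d); under[1:90] <- TRUE
  expect_equal(ravd(gt, gt), 0)
  expect_equal(ravd(over, gt), 0.10)
  expect_equal(ravd(under, gt), -0.10)
  expect_equal(ravd(under, gt, absolute = TRUE), 0.10)
  expect_error(ravd(gt, array(FALSE, d)), "empty")
})

test_that("pooled recall reproduces published count arithmetic", {
  # hold-out counts per ISUP grade: detected (15, 9, 5, 2) of (23, 9, 5, 2)
  holdout <- data.frame(n_annotated = c(23, 9, 5, 2),
                        n_gt_hit = c(15, 9, 5, 2))
  pr <- pooled_recall_precision(holdout)
  expect_equal(pr$recall, 31 / 39)
  expect_equal(pr$recall_rounded, 0.79)

  # prospective: 21 of 21 lesions found
  pr2 <- pooled_recall_precision(data.frame(n_annotated = 21, n_gt_hit = 21))
  expect_equal(pr2$recall_rounded, 1.00)

  expect_warning(
    pr0 <- pooled_recall_precision(data.frame(n_annotated = c(3, 2),
                                              n_gt_hit = c(0, 0))),
    "precision undefined"
  )
  expect_equal(pr0$recall, 0)
})

test_that("pooled recall equals the annotation-weighted mean of case recalls", {
  set.seed(21)
  for (rep in 1:10) {
    n_ann <- sample(0:4, 12, replace = TRUE)
    n_hit <- vapply(n_ann, function(n) if (n == 0) 0L else {
      sample(0:n, 1)
    }, integer(1))
    df <- data.frame(n_annotated = n_ann, n_gt_hit = n_hit)
    pr <- pooled_recall_precision(df)
    with_ann <- n_ann > 0
    weighted <- sum((n_hit[with_ann] / n_ann[with_ann]) * n_ann[with_ann]) /
      sum(n_ann[with_ann])
    expect_equal(pr$recall, weighted)
    expect_true(pr$recall >= 0 && pr$recall <= 1)
  }
})

test_that("precision pools hit candidates over retained candidates", {
  df <- data.frame(n_annotated = c(2, 1), n_gt_hit = c(2, 0),
                   n_detected = c(5, 3), n_hit_candidates = c(2, 0))
  pr <- pooled_recall_precision(df)
  expect_equal(pr$precision, 2 / 8)
  expect_equal(pr$recall, 2 / 3)
})

test_that("component analysis sizes match a flood-fill oracle and flag empties", {
  m <- array(0L, c(10, 6, 2))
  m[1:5, 1, 1] <- 1L
  m[1:7, 4, 2] <- 2L
  res <- component_analysis(list(m))
  expect_identical(sort(res$sizes$n_voxels), c(5L, 7L))

  set.seed(22)
  bin <- array(runif(8 * 8 * 4) < 0.3, c(8, 8, 4))
  res2 <- component_analysis(list(bin + 0))
  want <- flood_fill_label(bin)
  expect_identical(sort(res2$sizes$n_voxels),
                   sort(as.integer(table(want[want > 0]))))

  # an aggressive-graded case with an empty aggressive label map is flagged
  cfg <- tiny_config(lesion_count_probs = c(1, 0, 0, 0, 0))
  cs <- make_case(cfg, 30, with_intensity = FALSE)
  cs$case_isup <- 2L
  res3 <- component_analysis(list(cs))
  expect_identical(res3$empty_aggressive, cs$case_id)
  expect_identical(nrow(res3$sizes), 0L)
})

test_that("size stratification splits at the median with ties below", {
  s <- stratify_by_size(scores = c(0.2, 0.4, 0.6, 0.8, 0.9),
                        volumes = c(10, 20, 30, 40, 50))
  expect_equal(s$median_volume, 30)
  expect_identical(length(s$below), 3L)  # tie at the median goes below
  expect_identical(length(s$above), 2L)
  expect_lte(abs(length(s$below) - length(s$above)), 1L)

  tied <- stratify_by_size(c(0.1, 0.2, 0.3), c(7, 7, 7))
  expect_identical(length(tied$below), 3L)
  expect_identical(length(tied$above), 0L)

  # larger lesions constructed to score higher
  big <- stratify_by_size(scores = c(0.1, 0.2, 0.7, 0.9),
                          volumes = c(5, 6, 50, 60))
  expect_gt(big$mean_above, big$mean_below)
})

test_that("cohort table reproduces published ISUP proportions", {
  counts <- c(442, 192, 118, 61, 15, 29)
  meta <- data.frame(
    case_id = seq_len(sum(counts)),
    isup = rep(0:5, counts),
    cohort = "ProstateNet", split = "train"
  )
  tab <- cohort_table(meta)
  expect_identical(tab$isup$n, as.integer(counts))
  expect_equal(tab$isup$proportion[tab$isup$isup == 0], 0.52)
  expect_lte(abs(sum(tab$isup$proportion) - 1), 0.02)

  single <- cohort_table(data.frame(case_id = 1, isup = 3))
  expect_equal(single$isup$proportion[single$isup$isup == 3], 1.0)

  expect_error(cohort_table(data.frame(case_id = 1, isup = 7)),
               "unknown ISUP")
})
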