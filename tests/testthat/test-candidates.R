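test_that("probability-map thresholding is inclusive and exhaustive", {
  zero <- image_volume(array(0, c(4, 4, 2)), c(1, 1, 1))
  expect_false(any(threshold_map(zero, 0.1)))

  one <- array(0, c(4, 4, 2))
  one[2, 2, 1] <- 0.10
  expect_identical(sum(threshold_map(image_volume(one, c(1, 1, 1)), 0.10)), 1L)

  set.seed(10)
  m <- array(runif(6 * 6 * 3), c(6, 6, 3))
  sup <- threshold_map(image_volume(m, c(1, 1, 1)), 0.37)
  for (i in seq_along(m)) expect_identical(sup[i], m[i] >= 0.37)

  expect_error(threshold_map(zero, 0), "in \\(0, 1\\)")
  expect_error(threshold_map(zero, 1), "in \\(0, 1\\)")
})

test_that("connected-component labeling agrees with a flood-fill oracle", {
  set.seed(11)
  for (conn in c(26L, 6L)) {
    for (rep in 1:8) {
      m <- array(runif(8 * 8 * 5) < 0.35, c(8, 8, 5))
      got <- label_components(m, conn)
      want <- flood_fill_label(m, conn)
      # same partition: every component maps one-to-one
      expect_identical(max(got), max(want))
      expect_true(all((got > 0) == (want > 0)))
      for (l in seq_len(max(got))) {
        expect_identical(length(unique(want[got == l])), 1L)
      }
    }
  }
})

test_that("candidate extraction yields disjoint components with max confidence", {
  m <- array(0, c(10, 4, 2))
  m[2:3, 2, 1] <- c(0.2, 0.5)
  m[3, 3, 1] <- 0.3
  m[8:9, 2, 1] <- 0.4
  map <- image_volume(m, c(1, 2, 3))
  cands <- extract_candidates(threshold_map(map, 0.1), map)
  expect_identical(length(cands$candidates), 2L)
  confs <- sort(vapply(cands$candidates, `[[`, numeric(1), "confidence"))
  expect_equal(confs, c(0.4, 0.5))
  vox <- lapply(cands$candidates, `[[`, "voxels")
  expect_identical(length(intersect(vox[[1]], vox[[2]])), 0L)
  # volume = count x voxel volume
  sizes <- sort(vapply(cands$candidates, `[[`, numeric(1), "volume_mm3"))
  expect_equal(sizes, c(2, 3) * 6)
})

test_that("confidence filter partitions candidates and is monotone", {
  m <- array(0, c(12, 4, 1))
  m[2:3, 2, 1] <- 0.08
  m[8:9, 2, 1] <- 0.5
  map <- image_volume(m, c(1, 1, 1))
  cands <- extract_candidates(threshold_map(map, 0.05), map)
  out <- filter_confidence(cands, 0.10)
  st <- vapply(out$candidates, `[[`, character(1), "status")
  cf <- vapply(out$candidates, `[[`, numeric(1), "confidence")
  expect_identical(st[which.min(cf)], "below_confidence")
  expect_identical(st[which.max(cf)], "extracted")

  expect_identical(length(filter_confidence(extract_candidates(
    threshold_map(image_volume(array(0, c(3, 3, 1)), c(1, 1, 1)), 0.1),
    image_volume(array(0, c(3, 3, 1)), c(1, 1, 1))), 0.1)$candidates), 0L)

  set.seed(12)
  for (rep in 1:5) {
    m <- array(runif(8 * 8 * 3) * (runif(8 * 8 * 3) < 0.3), c(8, 8, 3))
    map <- image_volume(m, c(1, 1, 1))
    cands <- extract_candidates(threshold_map(map, 0.05), map)
    kept <- vapply(seq(0.05, 0.9, by = 0.05), function(t) {
      sum(vapply(filter_confidence(cands, t)$candidates,
                 function(c) c$status == "extracted", logical(1)))
    }, numeric(1))
    expect_true(all(diff(kept) <= 0))
  }
})

test_that("gland-overlap filter uses the candidate-volume denominator inclusively", {
  d <- c(40, 4, 1)
  gland <- array(0, d); gland[1:10, , 1] <- 1
  cands <- make_candidates(
    list(which(gland > 0)[1:6],              # fully inside
         which(gland == 0)[1:6],             # fully outside
         c(which(gland > 0)[1:3], which(gland == 0)[1:27])),  # 3 of 30
    c(0.5, 0.5, 0.5), d, status = "extracted")
  out <- filter_gland_overlap(cands, gland, 0.10)
  st <- vapply(out$candidates, `[[`, character(1), "status")
  fr <- vapply(out$candidates, `[[`, numeric(1), "gland_fraction")
  expect_equal(fr, c(1.0, 0.0, 0.10))
  expect_identical(st, c("retained", "extra_prostatic", "retained"))

  expect_warning(filter_gland_overlap(cands, array(0, d), 0.10), "empty gland")
})

test_that("assignment maximizes total overlap, never matching zero-overlap pairs", {
  # overlap matrix [[5, 1], [2, 4]]: optimum pairs (c1, g1), (c2, g2), total 9
  d <- c(30, 6, 1)
  gt <- array(0L, d)
  gt[1:6, 1, 1] <- 1L
  gt[1:6, 3, 1] <- 2L
  c1 <- c(which(gt == 1L)[1:5], which(gt == 2L)[1])
  c2 <- c(which(gt == 1L)[6], setdiff(which(gt == 2L), which(gt == 2L)[1])[1:4])
  c2 <- c(c2, which(gt == 0L)[1])  # padding voxel outside both lesions
  cands <- make_candidates(list(c1, c2), c(0.9, 0.8), d)
  out <- assign_candidates(cands, gt)
  expect_identical(out$candidates[[1]]$matched_gt, 1L)
  expect_identical(out$candidates[[2]]$matched_gt, 2L)
  expect_identical(out$candidates[[1]]$gt_overlap + 0L +
                     out$candidates[[2]]$gt_overlap, 9L)

  # single candidate over single lesion
  cands1 <- make_candidates(list(which(gt == 1L)[1:3]), 0.7, d)
  out1 <- assign_candidates(cands1, gt)
  expect_identical(out1$candidates[[1]]$matched_gt, 1L)
  expect_identical(attr(out1, "unmatched_gt"), 2L)

  # a candidate with no overlap stays unmatched
  cands0 <- make_candidates(list(which(gt == 0L)[1:4]), 0.7, d)
  out0 <- assign_candidates(cands0, gt)
  expect_true(is.na(out0$candidates[[1]]$matched_gt))
})

test_that("assignment equals the brute-force permutation optimum", {
  set.seed(13)
  for (rep in 1:40) {
    nc <- sample(1:4, 1); ng <- sample(1:4, 1)
    d <- c(nc * 12L, ng * 3L, 1L)
    gt <- array(0L, d)
    for (g in seq_len(ng)) gt[1:10, g * 2, 1] <- g
    sets <- lapply(seq_len(nc), function(ci) {
      vox <- integer(0)
      for (g in seq_len(ng)) {
        k <- sample(0:6, 1)
        if (k > 0) vox <- c(vox, which(gt == g)[seq_len(k)])
      }
      base <- which(gt == 0L)
      c(vox, base[(ci - 1) * 3 + 1:3])  # distinct filler voxels
    })
    ov <- matrix(0L, nc, ng)
    for (ci in seq_len(nc)) for (g in seq_len(ng)) {
      ov[ci, g] <- sum(gt[sets[[ci]]] == g)
    }
    cands <- make_candidates(sets, runif(nc, 0.3, 0.9), d)
    out <- assign_candidates(cands, gt)
    total <- sum(vapply(out$candidates, `[[`, integer(1), "gt_overlap"))
    expect_identical(as.numeric(total), brute_force_assignment(ov))
  }
})

test_that("hit scoring anchors on the assigned lesion's volume", {
  d <- c(50, 4, 1)
  gt <- array(0L, d)
  gt[1:40, 1, 1] <- 1L
  full <- make_candidates(list(which(gt == 1L)), 0.9, d)
  full <- assign_candidates(full, gt)
  full <- score_hits(full, gt, 0.10)
  expect_equal(full$candidates[[1]]$hit_fraction, 1.0)
  expect_true(full$candidates[[1]]$hit)
  expect_identical(attr(full, "detected_gt"), 1L)

  # 2 of 40 lesion voxels covered: fraction 0.05 < 0.10, lesion missed
  partial <- make_candidates(list(c(which(gt == 1L)[1:2], which(gt == 0L)[1])),
                             0.9, d)
  partial <- assign_candidates(partial, gt)
  partial <- score_hits(partial, gt, 0.10)
  expect_equal(partial$candidates[[1]]$hit_fraction, 0.05)
  expect_false(partial$candidates[[1]]$hit)
  expect_identical(length(attr(partial, "detected_gt")), 0L)

  # candidate-volume denominator is the configurable alternative
  alt <- score_hits(assign_candidates(
    make_candidates(list(c(which(gt == 1L)[1:2], which(gt == 0L)[1])), 0.9, d),
    gt), gt, 0.10, denominator = "candidate")
  expect_equal(alt$candidates[[1]]$hit_fraction, 2 / 3)
  expect_true(alt$candidates[[1]]$hit)
})

test_that("full detection run fills every field and handles empty cases", {
  cfg <- tiny_config(lesion_count_probs = c(1, 0, 0, 0, 0))
  cs <- make_case(cfg, 7, with_intensity = FALSE)
  zero_map <- image_volume(array(0, dim(cs$lesions$values)),
                           cs$lesions$spacing)
  det <- run_detection(cs, zero_map)
  expect_identical(det$n_detected, 0L)
  expect_identical(det$n_annotated, 0L)
  expect_identical(det$n_gt_hit, 0L)
  expect_identical(det$case_probability, 0)
  expect_false(det$empty_aggressive)

  cfg2 <- all_aggressive_config(2L)
  cs2 <- make_case(cfg2, 8, with_intensity = FALSE)
  map2 <- make_probability_map(cs2, perfect_oc(), 9)
  det2 <- run_detection(cs2, map2)
  expect_identical(det2$n_annotated, 2L)
  expect_identical(det2$n_gt_hit, 2L)
  expect_equal(det2$case_probability, 0.9)
  expect_identical(sum(det2$detected_mask),
                   sum(vapply(det2$candidates$candidates, function(c) {
                     if (c$status == "retained") length(c$voxels) else 0L
                   }, integer(1))))
})

test_that("detection counts are invariant to ground-truth relabeling", {
  cfg <- all_aggressive_config(3L)
  cs <- make_case(cfg, 14, with_intensity = FALSE)
  map <- make_probability_map(cs, perfect_oc(sensitivity = 0.9), 15)
  det <- run_detection(cs, map)

  perm <- c(3L, 1L, 2L)
  cs2 <- cs
  les <- cs$lesions$values
  relab <- les
  for (l in 1:3) relab[les == l] <- perm[l]
  cs2$lesions$values <- relab
  cs2$lesion_isup <- setNames(rep(2L, 3), as.character(1:3))
  det2 <- run_detection(cs2, map)
  expect_identical(det$n_annotated, det2$n_annotated)
  expect_identical(det$n_detected, det2$n_detected)
  expect_identical(det$n_gt_hit, det2$n_gt_hit)
  expect_equal(det$case_probability, det2$case_probability)
})

test_that("raising a filter threshold never increases detections or hits", {
  # the voxel threshold is excluded: raising it can split one connected
  # component into two, which legitimately raises the candidate count
  cfg <- all_aggressive_config(2L)
  cs <- make_case(cfg, 16, with_intensity = FALSE)
  oc <- operating_characteristics(sensitivity = 1, fp_rate_inside = 1,
                                  fp_rate_outside = 1)
  map <- make_probability_map(cs, oc, 17)
  base <- run_detection(cs, map)
  for (par in c("confidence_threshold", "gland_overlap_threshold",
                "hit_threshold")) {
    args <- list(0.3)
    names(args) <- par
    det_hi <- run_detection(cs, map, do.call(detection_config, args))
    expect_lte(det_hi$n_detected, base$n_detected)
    expect_lte(det_hi$n_gt_hit, base$n_gt_hit)
  }
  # the soft-blob support itself does shrink monotonically
  sup_lo <- threshold_map(map, 0.10)
  sup_hi <- threshold_map(map, 0.30)
  expect_true(all(sup_lo[sup_hi]))
})
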