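# Independent oracles used to cross-check the package implementations.
# Deliberately written in a different style (explicit stacks / double
# loops) so they share no code path with the functions under test.

# stack-based flood fill labeling
flood_fill_label <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(nb))
  nb <- nb[if (connectivity == 6) ord == 1 else if (connectivity == 18) {
    ord >= 1 & ord <= 2
  } else ord >= 1, , drop = FALSE]
  cur <- 0L
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!mask[i, j, k] || lab[i, j, k] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j, k))
    lab[i, j, k] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (r in seq_len(nrow(nb))) {
        q <- p + nb[r, ]
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- cur
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# maximum total overlap over all injective candidate -> lesion assignments
# (zero-overlap pairs contribute nothing and are allowed to stay unmatched)
brute_force_assignment <- function(ov) {
  nr <- nrow(ov); nc <- ncol(ov)
  best <- 0
  rec <- function(row, used, total) {
    if (row > nr) {
      best <<- max(best, total)
      return(invisible())
    }
    rec(row + 1L, used, total)  # leave this candidate unmatched
    for (col in seq_len(nc)) {
      if (!used[col] && ov[row, col] > 0) {
        used[col] <- TRUE
        rec(row + 1L, used, total + ov[row, col])
        used[col] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, nc), 0)
  best
}

# boundary voxels by per-voxel 6-neighbour inspection
naive_boundary <- function(mask) {
  d <- dim(mask)
  out <- NULL
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!mask[i, j, k]) next
    bdry <- FALSE
    for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                     c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      q <- c(i, j, k) + off
      if (any(q < 1) || any(q > d) || !mask[q[1], q[2], q[3]]) {
        bdry <- TRUE
        break
      }
    }
    if (bdry) out <- rbind(out, c(i, j, k))
  }
  out
}

# all-pairs surface distances, O(n * m) double loop
naive_surface_metrics <- function(a, b, spacing) {
  sa <- sweep(naive_boundary(a) - 1, 2, spacing, "*")
  sb <- sweep(naive_boundary(b) - 1, 2, spacing, "*")
  mins_ab <- numeric(nrow(sa))
  for (i in seq_len(nrow(sa))) {
    best <- Inf
    for (j in seq_len(nrow(sb))) {
      best <- min(best, sqrt(sum((sa[i, ] - sb[j, ])^2)))
    }
    mins_ab[i] <- best
  }
  mins_ba <- numeric(nrow(sb))
  for (j in seq_len(nrow(sb))) {
    best <- Inf
    for (i in seq_len(nrow(sa))) {
      best <- min(best, sqrt(sum((sb[j, ] - sa[i, ])^2)))
    }
    mins_ba[j] <- best
  }
  list(hd = max(max(mins_ab), max(mins_ba)),
       assd = (mean(mins_ab) + mean(mins_ba)) / 2)
}

# random compact-ish binary mask for metric tests
random_mask <- function(d = c(8, 8, 6), p = 0.3) {
  m <- array(runif(prod(d)) < p, d)
  if (!any(m)) m[ceiling(d[1] / 2), ceiling(d[2] / 2), ceiling(d[3] / 2)] <- TRUE
  m
}

# construct a lesion_candidates object directly from voxel index sets
make_candidates <- function(voxel_sets, confidences, dim, spacing = c(1, 1, 1),
                            status = "retained") {
  cands <- lapply(seq_along(voxel_sets), function(i) {
    list(id = i, voxels = voxel_sets[[i]], confidence = confidences[i],
         volume_mm3 = length(voxel_sets[[i]]) * prod(spacing),
         gland_fraction = NA_real_, matched_gt = NA_integer_,
         gt_overlap = 0L, hit_fraction = NA_real_,
         status = status, hit = FALSE)
  })
  structure(list(candidates = cands, dim = as.integer(dim),
                 spacing = spacing),
            class = "lesion_candidates")
}
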