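# Independent oracles used across the suite. These re-derive expected values
# by the most direct route available (explicit flood fill, exhaustive grid
# search, direct formula evaluation) and deliberately share no code with the
# implementation paths they check.

# Connected-component labelling by explicit BFS flood fill over an index
# queue. mask: logical (y, x, z) array. Returns integer label array.
oracle_flood_fill <- function(mask, mode = c("slice", "volume"),
                              connectivity = NULL) {
  mode <- match.arg(mode)
  connectivity <- if (is.null(connectivity)) {
    if (mode == "slice") 8 else 26
  } else connectivity
  d <- dim(mask)
  offs <- list()
  for (dy in -1:1) for (dx in -1:1) for (dz in -1:1) {
    if (dy == 0 && dx == 0 && dz == 0) next
    if (mode == "slice" && dz != 0) next
    man <- abs(dy) + abs(dx) + abs(dz)
    keep <- switch(as.character(connectivity),
                   "4" = man == 1 && dz == 0, "8" = dz == 0,
                   "6" = man == 1, "26" = TRUE)
    if (keep) offs[[length(offs) + 1L]] <- c(dy, dx, dz)
  }
  labels <- array(0L, dim = d)
  nxt <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    labels[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      co <- arrayInd(cur, d)
      for (o in offs) {
        y <- co[1] + o[1]; x <- co[2] + o[2]; z <- co[3] + o[3]
        if (y < 1 || y > d[1] || x < 1 || x > d[2] || z < 1 || z > d[3]) next
        if (!mask[y, x, z]) next
        idx <- y + (x - 1L) * d[1] + (z - 1L) * d[1] * d[2]
        if (labels[idx] == 0L) {
          labels[idx] <- nxt
          queue <- c(queue, idx)
        }
      }
    }
  }
  labels
}

# Exhaustive grid search for the normalized 4PL: minimizes SSE over a
# (log10_ic50, hill_slope) grid, coarse then refined around the best cell.
oracle_4pl_gridsearch <- function(conc_nM, response_pct,
                                  l_range = c(-10, -4), h_range = c(0.2, 4)) {
  sse <- function(l, h) {
    x <- log10(conc_nM) - 9
    pred <- 100 / (1 + 10^((x - l) * h))
    sum((response_pct - pred)^2)
  }
  ls <- seq(l_range[1], l_range[2], length.out = 61)
  hs <- seq(h_range[1], h_range[2], length.out = 39)
  for (pass in 1:3) {
    grid <- expand.grid(l = ls, h = hs)
    grid$sse <- mapply(sse, grid$l, grid$h)
    best <- grid[which.min(grid$sse), ]
    dl <- diff(ls[1:2]); dh <- diff(hs[1:2])
    ls <- seq(best$l - dl, best$l + dl, length.out = 21)
    hs <- seq(max(1e-3, best$h - dh), best$h + dh, length.out = 21)
  }
  list(log10_ic50 = best$l, hill_slope = best$h, sse = best$sse)
}

# Direct Pearson chi-square statistic on a contingency table
oracle_chisq <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# Per-pixel brute-force depth projection: max and argmax over z via apply()
oracle_projection <- function(arr) {
  list(intensity = apply(arr, c(1, 2), max),
       z_index = apply(arr, c(1, 2), which.max))
}

# Ramped-threshold score evaluated directly, returning the winning threshold
oracle_ramp_optimum <- function(img, t_grid) {
  v <- as.vector(img)
  area <- sapply(t_grid, function(T) sum(v >= T))
  mn <- sapply(t_grid, function(T) if (any(v >= T)) mean(v[v >= T]) else NA)
  nrm <- function(x) {
    r <- range(x, na.rm = TRUE)
    if (diff(r) == 0) return(ifelse(is.na(x), NA, 0))
    (x - r[1]) / diff(r)
  }
  score <- nrm(mn) - nrm(area)
  score[area == 0] <- NA
  t_grid[which.max(score)]
}

# match detected particles to ground-truth objects by dominant voxel overlap
match_particles_to_truth <- function(particles, truth) {
  vapply(seq_len(nrow(particles)), function(i) {
    ov <- vapply(truth$voxels,
                 function(v) length(intersect(v, particles$voxels[[i]])), 1L)
    truth$class[which.max(ov)]
  }, character(1))
}

# precision/recall/F1 of the dead-vs-alive particle classification against
# truth labels ("dead-fragment" is the positive class)
classification_f1 <- function(pred_class, true_class) {
  tp <- sum(pred_class == "dead" & true_class == "dead-fragment")
  fp <- sum(pred_class == "dead" & true_class == "alive")
  fn <- sum(pred_class == "alive" & true_class == "dead-fragment")
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
}
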