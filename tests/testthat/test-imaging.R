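make_two_level <- function(dims = c(20, 20, 3), fg_frac = 0.1, bg = 10, fg = 200,
                           seed = 1) {
  withr::with_seed(seed, {
    arr <- array(bg, dim = dims)
    n_fg <- round(prod(dims) * fg_frac)
    fg_idx <- sample(prod(dims), n_fg)
    arr[fg_idx] <- fg
    list(arr = arr, fg_idx = sort(fg_idx))
  })
}

test_that("binarization uses the inclusive >= convention", {
  arr <- array(50, dim = c(4, 4, 2, 1, 1))
  stk <- image_stack(arr)
  expect_false(any(binarize_channel(stk, 1, 51)$mask))
  expect_true(all(binarize_channel(stk, 1, 50)$mask))
  expect_error(binarize_channel(stk, "nope", 10), class = "organoidr_unknown_channel")
})

test_that("mask at the midpoint of the snr gap recovers ground-truth foreground", {
  p <- organoid_sim_params(n_alive = 18, n_dead = 4, snr = 10, seed = 21)
  res <- make_organoid_stack(p)
  mid <- p$bg_level * (1 + p$snr) / 2
  mask <- binarize_channel(res$stack, "H2B", mid)
  expect_identical(sort(which(mask$mask)), sort(unlist(res$truth$voxels)))
})

test_that("diagonal touch merges under 8- but not 4-connectivity", {
  m <- array(FALSE, dim = c(4, 4, 1))
  m[1, 1, 1] <- TRUE; m[2, 2, 1] <- TRUE
  bm <- binary_mask_from_array(m)
  expect_equal(nrow(find_particles(bm, "slice", 8)), 1)
  expect_equal(nrow(find_particles(bm, "slice", 4)), 2)
  expect_equal(nrow(find_particles(binary_mask_from_array(array(FALSE, c(3, 3, 1))),
                                   "slice")), 0)
  expect_error(find_particles(bm, "slice", 26), class = "organoidr_bad_connectivity")
  expect_error(find_particles(bm, "volume", 8), class = "organoidr_bad_connectivity")
})

test_that("connected components match the flood-fill oracle on random masks", {
  for (seed in 1:8) {
    dims <- c(14, 12, 3)
    m <- withr::with_seed(seed, array(runif(prod(dims)) < 0.35, dim = dims))
    bm <- binary_mask_from_array(m)
    for (case in list(list("slice", 4), list("slice", 8),
                      list("volume", 6), list("volume", 26))) {
      pt <- find_particles(bm, case[[1]], case[[2]])
      lab <- oracle_flood_fill(m, case[[1]], case[[2]])
      if (case[[1]] == "volume") {
        expect_equal(nrow(pt), max(lab))
      } else {
        per_slice <- vapply(seq_len(dims[3]), function(z) {
          lz <- oracle_flood_fill(m[, , z, drop = FALSE], "slice", case[[2]])
          max(lz)
        }, 1L)
        expect_equal(nrow(pt), sum(per_slice))
      }
      # identical partition: particle voxel sets = oracle label classes
      impl_sets <- lapply(pt$voxels, sort)
      if (case[[1]] == "volume") {
        oracle_sets <- lapply(seq_len(max(lab)), function(l) sort(which(lab == l)))
        expect_setequal(sapply(impl_sets, paste, collapse = ","),
                        sapply(oracle_sets, paste, collapse = ","))
      }
    }
  }
})

test_that("size classification uses the boundary-is-alive convention", {
  pt <- tibble::tibble(particle_id = 1:3, slice = NA_integer_, n_px = c(10L, 9L, 30L),
                       y = 1, x = 1, z = 1, y_min = 1L, y_max = 1L, x_min = 1L,
                       x_max = 1L, z_min = 1L, z_max = 1L,
                       voxels = list(1L, 2L, 3L))
  class(pt) <- c("particle_set", class(pt))
  cls <- classify_particles(pt, 10)
  expect_equal(cls$class, c("alive", "dead", "alive"))
})

test_that("alive/dead classification recovers ground truth on synthetic stacks", {
  p <- organoid_sim_params(n_alive = 15, n_dead = 5, alive_radius_px = 5,
                           fragment_radius_px = 1.5, seed = 3)
  res <- make_organoid_stack(p)
  mid <- p$bg_level * (1 + p$snr) / 2
  pt <- find_particles(binarize_channel(res$stack, "H2B", mid), "volume")
  cutoff <- default_size_cutoff(dplyr::filter(pt, n_px > 50))
  cls <- classify_particles(pt, cutoff)
  true_class <- match_particles_to_truth(cls, res$truth)
  expect_gte(classification_f1(cls$class, true_class), 0.95)
})

test_that("lower-half quantification partitions foreground and halves symmetric organoids", {
  d <- c(8, 8, 10)
  ma <- array(FALSE, d); md <- array(FALSE, d)
  # organoid spanning slices 1..10, alive columns mirrored in z
  ma[3, 3, ] <- TRUE
  md[5, 5, c(1, 10)] <- TRUE
  q <- quantify_lower_half(ma, md)
  expect_equal(q$z_lo, 1); expect_equal(q$z_hi, 5)
  expect_equal(q$alive_px, 5)  # half of the 10 alive voxels
  expect_equal(q$dead_px, 1)   # half of the 2 dead voxels
  expect_equal(q$alive_px + q$dead_px, sum((ma | md)[, , 1:5]))
  # all foreground in bottom half -> lower-half totals equal full totals
  ma2 <- array(FALSE, d); ma2[2, 2, 1:5] <- TRUE
  md2 <- array(FALSE, d); md2[6, 6, 3] <- TRUE
  q2 <- quantify_lower_half(ma2, md2, z_extent = c(1, 10))
  expect_equal(q2$alive_px, 5)
  expect_equal(q2$dead_px, 1)
  expect_error(quantify_lower_half(ma, md, z_extent = c(0, 11)),
               class = "organoidr_bad_argument")
  expect_error(quantify_lower_half(ma, ma), "disjoint")
})

test_that("partition identity holds on simulated stacks", {
  p <- organoid_sim_params(n_alive = 10, n_dead = 3, seed = 11)
  res <- make_organoid_stack(p)
  mid <- p$bg_level * (1 + p$snr) / 2
  mask <- binarize_channel(res$stack, "H2B", mid)
  pt <- classify_particles(find_particles(mask, "volume"), 40)
  d <- dim(mask$mask)
  ma <- array(FALSE, d); md <- array(FALSE, d)
  ma[unlist(pt$voxels[pt$class == "alive"])] <- TRUE
  md[unlist(pt$voxels[pt$class == "dead"])] <- TRUE
  q <- quantify_lower_half(ma, md)
  total <- sum(mask$mask[, , q$z_lo:q$z_hi])
  expect_equal(q$alive_px + q$dead_px, total)
})

test_that("depth projection equals per-pixel brute force with lowest-z ties", {
  p <- organoid_sim_params(n_alive = 8, n_dead = 2, seed = 13,
                           stack_shape = c(64, 64, 10))
  res <- make_organoid_stack(p)
  arr <- stack_channel(res$stack, "H2B")
  pr <- depth_coded_projection(res$stack, "H2B")
  orc <- oracle_projection(arr)
  expect_equal(pr$intensity, orc$intensity)
  expect_equal(pr$z_index, array(orc$z_index, dim = dim(arr)[1:2]))
  # two identical planes: tie resolves to z = 1
  two <- image_stack(array(rep(as.vector(arr[, , 1]), 2), dim = c(dim(arr)[1:2], 2)))
  pr2 <- depth_coded_projection(two, 1)
  expect_true(all(pr2$z_index == 1L))
  # single plane projects to itself
  one <- image_stack(arr[, , 1, drop = TRUE])
  pr1 <- depth_coded_projection(one, 1)
  expect_equal(pr1$intensity, arr[, , 1])
})

test_that("quadrant montage assembles when a transmitted channel is present", {
  arr <- array(runif(16 * 16 * 3 * 2, 0, 100), dim = c(16, 16, 3, 2, 1))
  stk <- image_stack(arr, channels = c("H2B", "TL"))
  pr <- depth_coded_projection(stk, "H2B", transmitted = "TL")
  expect_equal(dim(pr$quadrants), c(32, 32, 3))
  expect_equal(pr$quadrants[1:16, 1:16, ], pr$rgb)
})

test_that("ramped-threshold optimum matches its brute-force definition", {
  # two-level noiseless image: returned threshold separates bg from fg exactly
  tl <- make_two_level(seed = 4)
  grid <- seq(0, 210, by = 5)
  rs <- ramp_threshold_optimum(tl$arr, grid)
  expect_gt(rs$threshold, 10)
  expect_lte(rs$threshold, 200)
  expect_identical(which(tl$arr >= rs$threshold), tl$fg_idx)
  expect_equal(rs$threshold, oracle_ramp_optimum(tl$arr, grid))
  # Gaussian-mixture images: argmax equals direct evaluation of the score
  for (seed in 1:6) {
    img <- withr::with_seed(seed, c(rnorm(900, 30, 4), rnorm(100, 150, 20)))
    g <- seq(min(img), max(img), length.out = 40)
    expect_equal(ramp_threshold_optimum(img, g)$threshold,
                 oracle_ramp_optimum(img, g))
  }
  expect_error(ramp_threshold_optimum(array(7, dim = c(5, 5))),
               class = "organoidr_degenerate_image")
})

test_that("area curve is non-increasing and mean curve non-decreasing in T", {
  for (seed in 1:10) {
    img <- withr::with_seed(seed, runif(400, 0, 100)^2)
    crv <- ramp_threshold_optimum(img, seq(min(img), max(img), length.out = 25))$curves
    expect_true(all(diff(crv$area) <= 0))
    ok <- !is.na(crv$mean_intensity)
    expect_true(all(diff(crv$mean_intensity[ok]) >= -1e-9))
  }
})

test_that("PI/H2B death ratio matches the true dead-voxel fraction and pools counts", {
  p <- organoid_sim_params(n_alive = 12, n_dead = 8, snr = 8, seed = 17)
  res <- make_organoid_stack(p)
  mid <- p$bg_level * (1 + p$snr) / 2
  dr <- pi_h2b_death_ratio(res$stack, t_h2b = mid, t_pi = mid)
  truth_frac <- sum(res$truth$n_vox[res$truth$class == "dead-fragment"]) /
    sum(res$truth$n_vox)
  expect_equal(dr$ratio, truth_frac, tolerance = 0.02)
  # scale invariance: duplicating the field leaves the ratio unchanged
  arr <- res$stack$data
  big <- array(0, dim = dim(arr) + c(0, dim(arr)[2], 0, 0, 0))
  big[, seq_len(dim(arr)[2]), , , ] <- arr
  big[, dim(arr)[2] + seq_len(dim(arr)[2]), , , ] <- arr
  stk2 <- image_stack(big, channels = res$stack$channels)
  dr2 <- pi_h2b_death_ratio(stk2, t_h2b = mid, t_pi = mid)
  expect_equal(dr2$ratio, dr$ratio)
  expect_equal(dr2$pi_px, 2 * dr$pi_px)
  # PI below threshold -> ratio 0; empty H2B -> failure
  dr0 <- pi_h2b_death_ratio(res$stack, t_h2b = mid, t_pi = 1e6)
  expect_equal(dr0$ratio, 0)
  expect_error(pi_h2b_death_ratio(res$stack, t_h2b = 1e6, t_pi = mid),
               class = "organoidr_empty_mask")
})

test_that("tiff round-trip preserves voxel data and calibration", {
  p <- organoid_sim_params(stack_shape = c(40, 40, 8), n_alive = 3, n_dead = 1,
                           seed = 8)
  res <- make_organoid_stack(p)
  path <- tempfile(fileext = ".tif")
  write_stack_tiff(res$stack, path)
  rt <- read_stack_tiff(path)
  expect_equal(rt$data, round(res$stack$data))
  expect_equal(rt$channels, res$stack$channels)
  expect_equal(rt$z_step_um, res$stack$z_step_um)
  unlink(c(path, paste0(path, ".json")))
})
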