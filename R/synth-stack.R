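#' Simulation parameters for a synthetic organoid stack
#'
#' Defines the geometry and photometry of a simulated H2B-reporter organoid
#' field. Live nuclei are rendered as compact bright blobs; each dead cell is
#' shattered into several small fragments scattered within one nucleus
#' diameter of the death site, the morphology that histone-reporter nuclei
#' show upon apoptosis. An optional propidium-iodide (PI) channel marks only
#' the dead fragments.
#'
#' Background is fixed at 100 intensity units with additive Gaussian noise of
#' sd 5; foreground blob peaks are `snr * 100` with a Gaussian radial profile
#' (`sigma = radius`), so every ground-truth voxel stays above the midpoint
#' between background and peak for any `snr > 1`.
#'
#' @param stack_shape Integer vector `(x, y, z)` of voxels per axis.
#' @param pixel_size_um Microns per xy pixel.
#' @param z_step_um Microns between z planes.
#' @param n_alive,n_dead Counts of live nuclei and dead cells.
#' @param alive_radius_px Mean live-nucleus radius in pixels.
#' @param alive_radius_sd Spread (sd) of live-nucleus radii.
#' @param fragment_radius_px Dead-fragment radius in pixels; must be smaller
#'   than `alive_radius_px`.
#' @param fragments_per_dead Number of fragments a dead nucleus shatters into.
#' @param snr Foreground peak / background intensity ratio; must exceed 1.
#' @param pi_channel Render a PI channel in which only dead fragments exceed
#'   background?
#' @param seed Integer RNG seed; identical parameters + seed reproduce the
#'   stack bit for bit.
#' @return A validated parameter list of class `organoid_sim_params`.
#' @export
organoid_sim_params <- function(stack_shape = c(96L, 96L, 12L),
                                pixel_size_um = 1, z_step_um = 2,
                                n_alive = 20L, n_dead = 5L,
                                alive_radius_px = 5, alive_radius_sd = 0.5,
                                fragment_radius_px = 1.5,
                                fragments_per_dead = 4L,
                                snr = 5, pi_channel = TRUE, seed = 1L) {
  stack_shape <- as.integer(stack_shape)
  if (length(stack_shape) != 3L || any(!is.finite(stack_shape)) || any(stack_shape <= 0L)) {
    stop_organoidr("`stack_shape` must be three positive integers (x, y, z)",
                   "organoidr_bad_params")
  }
  for (nm in c("n_alive", "n_dead", "fragments_per_dead")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v < 0 || v != round(v)) {
      stop_organoidr(sprintf("`%s` must be a non-negative integer", nm),
                     "organoidr_bad_params")
    }
  }
  assert_scalar_number(alive_radius_px, "alive_radius_px", lower = 0.5)
  assert_scalar_number(alive_radius_sd, "alive_radius_sd", lower = 0)
  assert_scalar_number(fragment_radius_px, "fragment_radius_px", lower = 0.25)
  if (fragment_radius_px >= alive_radius_px) {
    stop_organoidr("`fragment_radius_px` must be smaller than `alive_radius_px`",
                   "organoidr_bad_params")
  }
  assert_scalar_number(snr, "snr")
  if (snr <= 1) stop_organoidr("`snr` must exceed 1", "organoidr_bad_params")
  assert_scalar_number(pixel_size_um, "pixel_size_um", lower = 1e-9)
  assert_scalar_number(z_step_um, "z_step_um", lower = 1e-9)
  structure(
    list(stack_shape = stack_shape, pixel_size_um = pixel_size_um,
         z_step_um = z_step_um, n_alive = as.integer(n_alive),
         n_dead = as.integer(n_dead), alive_radius_px = alive_radius_px,
         alive_radius_sd = alive_radius_sd,
         fragment_radius_px = fragment_radius_px,
         fragments_per_dead = as.integer(fragments_per_dead), snr = snr,
         pi_channel = isTRUE(pi_channel), seed = as.integer(seed),
         bg_level = 100, noise_sd = 5),
    class = "organoid_sim_params"
  )
}

# z anisotropy: one z step expressed in xy pixels
z_ratio <- function(params) params$z_step_um / params$pixel_size_um

MAX_PLACEMENT_RETRIES <- 1000L

# sample one blob center of radius r, rejecting overlap with existing objects.
# objects: data.frame with cy, cx, cz, r. Returns c(cy, cx, cz).
place_blob <- function(objects, r, dims_yxz, zr, near = NULL, near_dist = NULL,
                       fallback_global = FALSE) {
  ny <- dims_yxz[1]; nx <- dims_yxz[2]; nz <- dims_yxz[3]
  rz <- r / zr
  lo_z <- min(1 + rz, (nz + 1) / 2); hi_z <- max(nz - rz, (nz + 1) / 2)
  lo_y <- min(1 + r, (ny + 1) / 2); hi_y <- max(ny - r, (ny + 1) / 2)
  lo_x <- min(1 + r, (nx + 1) / 2); hi_x <- max(nx - r, (nx + 1) / 2)
  for (i in seq_len(MAX_PLACEMENT_RETRIES)) {
    if (is.null(near)) {
      cand <- c(runif(1, lo_y, hi_y), runif(1, lo_x, hi_x), runif(1, lo_z, hi_z))
    } else {
      # uniform in a ball of radius near_dist around `near` (anisotropy-aware)
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      d <- near_dist * runif(1)^(1 / 3)
      cand <- near + c(u[1] * d, u[2] * d, u[3] * d / zr)
      cand[1] <- min(max(cand[1], lo_y), hi_y)
      cand[2] <- min(max(cand[2], lo_x), hi_x)
      cand[3] <- min(max(cand[3], lo_z), hi_z)
    }
    if (nrow(objects) == 0L) return(cand)
    dy <- objects$cy - cand[1]
    dx <- objects$cx - cand[2]
    dz <- (objects$cz - cand[3]) * zr
    sep <- sqrt(dy^2 + dx^2 + dz^2)
    # margin > the 26-connectivity diagonal reach (1,1,1 voxel steps, z scaled)
    # so voxel sets of distinct objects are never even diagonally adjacent
    if (all(sep > objects$r + r + sqrt(2 + zr^2) + 0.1)) return(cand)
  }
  if (!is.null(near) && fallback_global) {
    # daughters/fragments may drift away from a locally crowded site
    return(place_blob(objects, r, dims_yxz, zr))
  }
  stop_organoidr(
    sprintf("could not place a blob of radius %.2g after %d retries (overcrowded field)",
            r, MAX_PLACEMENT_RETRIES),
    "organoidr_overcrowded")
}

# voxels of a blob: linear indices into (ny, nx, nz) plus squared scaled distance
blob_voxels <- function(center, r, dims_yxz, zr) {
  cy <- center[1]; cx <- center[2]; cz <- center[3]
  ys <- max(1L, ceiling(cy - r)):min(dims_yxz[1], floor(cy + r))
  xs <- max(1L, ceiling(cx - r)):min(dims_yxz[2], floor(cx + r))
  zs <- max(1L, ceiling(cz - r / zr)):min(dims_yxz[3], floor(cz + r / zr))
  g <- expand.grid(y = ys, x = xs, z = zs)
  d2 <- (g$y - cy)^2 + (g$x - cx)^2 + ((g$z - cz) * zr)^2
  keep <- d2 <= r^2
  g <- g[keep, , drop = FALSE]
  list(
    idx = g$y + (g$x - 1L) * dims_yxz[1] + (g$z - 1L) * dims_yxz[1] * dims_yxz[2],
    d2 = d2[keep],
    yxz = g
  )
}

# place the full object population for one field; RNG state is the caller's
populate_field <- function(params) {
  dims <- params$stack_shape[c(2, 1, 3)]  # (y, x, z)
  zr <- z_ratio(params)
  objects <- tibble(id = integer(), class = character(),
                    cy = numeric(), cx = numeric(), cz = numeric(), r = numeric(),
                    parent = integer())
  next_id <- 1L
  for (i in seq_len(params$n_alive)) {
    r <- max(1, rnorm(1, params$alive_radius_px, params$alive_radius_sd))
    ctr <- place_blob(objects, r, dims, zr)
    objects <- bind_rows(objects, tibble(
      id = next_id, class = "alive", cy = ctr[1], cx = ctr[2], cz = ctr[3],
      r = r, parent = NA_integer_))
    next_id <- next_id + 1L
  }
  for (i in seq_len(params$n_dead)) {
    site <- place_blob(objects, params$alive_radius_px, dims, zr)
    objects <- shatter_at(objects, site, params, dims, zr,
                          next_ids = next_id + seq_len(params$fragments_per_dead) - 1L,
                          parent = NA_integer_)
    next_id <- next_id + params$fragments_per_dead
  }
  objects
}

# add dead fragments scattered within one nucleus diameter of `site`
shatter_at <- function(objects, site, params, dims, zr, next_ids, parent) {
  for (k in seq_along(next_ids)) {
    ctr <- place_blob(objects, params$fragment_radius_px, dims, zr,
                      near = site, near_dist = 2 * params$alive_radius_px)
    objects <- bind_rows(objects, tibble(
      id = next_ids[k], class = "dead-fragment",
      cy = ctr[1], cx = ctr[2], cz = ctr[3],
      r = params$fragment_radius_px, parent = parent))
  }
  objects
}

# render one frame (all channels) from an object table; consumes RNG for noise
render_frame <- function(objects, params) {
  dims <- params$stack_shape[c(2, 1, 3)]
  zr <- z_ratio(params)
  bg <- params$bg_level
  peak <- (params$snr - 1) * bg
  h2b <- array(pmax(0, bg + rnorm(prod(dims), 0, params$noise_sd)), dim = dims)
  pi_arr <- if (params$pi_channel) {
    array(pmax(0, bg + rnorm(prod(dims), 0, params$noise_sd)), dim = dims)
  } else NULL
  vox <- vector("list", nrow(objects))
  for (i in seq_len(nrow(objects))) {
    bv <- blob_voxels(c(objects$cy[i], objects$cx[i], objects$cz[i]),
                      objects$r[i], dims, zr)
    gain <- peak * exp(-bv$d2 / (2 * objects$r[i]^2))
    h2b[bv$idx] <- h2b[bv$idx] + gain
    if (!is.null(pi_arr) && objects$class[i] == "dead-fragment") {
      pi_arr[bv$idx] <- pi_arr[bv$idx] + gain
    }
    vox[[i]] <- bv
  }
  list(h2b = h2b, pi = pi_arr, vox = vox)
}

truth_from_objects <- function(objects, vox, n_alive, n_dead) {
  tr <- tibble(
    object_id = objects$id,
    class = objects$class,
    y = map_dbl(vox, ~ if (length(.x$idx)) mean(.x$yxz$y) else NA_real_),
    x = map_dbl(vox, ~ if (length(.x$idx)) mean(.x$yxz$x) else NA_real_),
    z = map_dbl(vox, ~ if (length(.x$idx)) mean(.x$yxz$z) else NA_real_),
    n_vox = map_int(vox, ~ length(.x$idx)),
    voxels = map(vox, "idx")
  )
  attr(tr, "n_alive_true") <- n_alive
  attr(tr, "n_dead_true") <- n_dead
  tr
}

#' Generate one synthetic organoid stack with ground truth
#'
#' Renders live nuclei and dead-cell fragments into an H2B channel (plus an
#' optional PI channel marking only dead fragments) and returns the per-object
#' ground truth used by downstream recovery tests: object class, centroid and
#' the exact voxel set of every object. Object voxel sets are pairwise
#' disjoint by construction (rejection-sampled placement; the call fails
#' loudly if the field is too crowded to place all objects).
#'
#' @param params An [organoid_sim_params()].
#' @return A list with elements `stack` (an [image_stack()]) and `truth`
#'   (a tibble: `object_id`, `class` (`"alive"` / `"dead-fragment"`), centroid
#'   `y`, `x`, `z`, `n_vox`, and a `voxels` list-column of linear indices into
#'   the `(y, x, z)` array; attributes `n_alive_true`, `n_dead_true`).
#' @export
make_organoid_stack <- function(params) {
  stopifnot(inherits(params, "organoid_sim_params"))
  withr::with_seed(params$seed, {
    objects <- populate_field(params)
    fr <- render_frame(objects, params)
  })
  nch <- if (params$pi_channel) 2L else 1L
  d <- dim(fr$h2b)
  arr <- array(0, dim = c(d, nch, 1L))
  arr[, , , 1L, 1L] <- fr$h2b
  if (nch == 2L) arr[, , , 2L, 1L] <- fr$pi
  stk <- image_stack(arr, channels = c("H2B", "PI")[seq_len(nch)],
                     pixel_size_um = params$pixel_size_um,
                     z_step_um = params$z_step_um)
  truth <- truth_from_objects(objects, fr$vox, params$n_alive, params$n_dead)
  list(stack = stk, truth = truth)
}

#' Schedule of mitosis / apoptosis events for a simulated time-lapse
#'
#' @param time_min Numeric vector of event times, minutes from movie start.
#' @param event_type Character vector, `"mitosis"` or `"apoptosis"`.
#' @param object_id Integer ids of the affected (parent) objects.
#' @return A tibble of class `event_schedule`, sorted by time.
#' @export
event_schedule <- function(time_min = numeric(), event_type = character(),
                           object_id = integer()) {
  if (length(time_min) != length(event_type) ||
      length(time_min) != length(object_id)) {
    stop_organoidr("schedule columns must have equal length", "organoidr_bad_schedule")
  }
  if (any(time_min < 0)) {
    stop_organoidr("event times must be >= 0", "organoidr_bad_schedule")
  }
  bad <- setdiff(unique(event_type), c("mitosis", "apoptosis"))
  if (length(bad)) {
    stop_organoidr(sprintf("unknown event type(s): %s", paste(bad, collapse = ", ")),
                   "organoidr_bad_schedule")
  }
  sched <- tibble(time_min = as.numeric(time_min),
                  event_type = as.character(event_type),
                  object_id = as.integer(object_id))
  sched <- arrange(sched, .data$time_min)
  dup <- sched |> filter(.data$event_type == "apoptosis") |> count(.data$object_id) |> filter(n > 1)
  if (nrow(dup)) {
    stop_organoidr("an object can undergo apoptosis at most once", "organoidr_bad_schedule")
  }
  class(sched) <- c("event_schedule", class(sched))
  sched
}

#' Simulate a time-lapse movie driven by an event schedule
#'
#' Starts from a field placed per `params` (live-nucleus ids `1..n_alive`) and
#' replays the schedule: at each mitosis the parent blob is replaced by two
#' daughter blobs placed beside it; at each apoptosis the blob shatters into
#' `fragments_per_dead` fragments. Frames are rendered every
#' `frame_interval_min` minutes; a frame at time *t* reflects all events with
#' time <= *t*.
#'
#' @param params An [organoid_sim_params()] (initial `n_dead` cells are
#'   rendered as fragments already present at t = 0).
#' @param schedule An [event_schedule()]; every referenced object must exist
#'   and be alive when its event fires.
#' @param frame_interval_min Minutes between frames.
#' @param duration_min Total movie length; must cover the latest event.
#' @return A list: `stack` (an [image_stack()] with a time axis), `event_log`
#'   (the realized schedule, chronologically sorted, with daughter ids),
#'   `frame_truth` (tibble: `frame`, `time_min`, `n_alive`, `n_dead_cells`).
#' @export
make_timelapse <- function(params, schedule, frame_interval_min = 15,
                           duration_min = 150) {
  stopifnot(inherits(params, "organoid_sim_params"))
  if (!inherits(schedule, "event_schedule")) {
    schedule <- event_schedule(schedule$time_min, schedule$event_type, schedule$object_id)
  }
  assert_scalar_number(frame_interval_min, "frame_interval_min", lower = 1e-9)
  assert_scalar_number(duration_min, "duration_min", lower = 0)
  if (nrow(schedule) && max(schedule$time_min) > duration_min) {
    stop_organoidr("`duration_min` must cover the latest scheduled event",
                   "organoidr_bad_schedule")
  }
  dims <- params$stack_shape[c(2, 1, 3)]
  zr <- z_ratio(params)
  frame_times <- seq(0, duration_min, by = frame_interval_min)
  nf <- length(frame_times)
  # apoptosis before mitosis at equal times; stable within type
  ord <- order(schedule$time_min, match(schedule$event_type, c("apoptosis", "mitosis")))
  sched <- schedule[ord, ]

  frames_h2b <- vector("list", nf)
  frames_pi <- vector("list", nf)
  frame_truth <- tibble(frame = integer(), time_min = numeric(),
                        n_alive = integer(), n_dead_cells = integer())
  log_rows <- list()

  withr::with_seed(params$seed, {
    objects <- populate_field(params)
    next_id <- if (nrow(objects)) max(objects$id) + 1L else 1L
    n_dead_cells <- params$n_dead
    ei <- 1L
    for (fi in seq_len(nf)) {
      while (ei <= nrow(sched) && sched$time_min[ei] <= frame_times[fi]) {
        pid <- sched$object_id[ei]
        row <- which(objects$id == pid & objects$class == "alive")
        if (length(row) != 1L) {
          stop_organoidr(sprintf("event %d references unknown or non-alive object id %d",
                                 ei, pid), "organoidr_unknown_object")
        }
        ctr <- c(objects$cy[row], objects$cx[row], objects$cz[row])
        r <- objects$r[row]
        objects <- objects[-row, ]
        if (sched$event_type[ei] == "mitosis") {
          for (k in 1:2) {
            dctr <- place_blob(objects, r, dims, zr, near = ctr, near_dist = 3 * r,
                               fallback_global = TRUE)
            objects <- bind_rows(objects, tibble(
              id = next_id, class = "alive", cy = dctr[1], cx = dctr[2],
              cz = dctr[3], r = r, parent = pid))
            next_id <- next_id + 1L
          }
        } else {
          objects <- shatter_at(objects, ctr, params, dims, zr,
                                next_ids = next_id + seq_len(params$fragments_per_dead) - 1L,
                                parent = pid)
          next_id <- next_id + params$fragments_per_dead
          n_dead_cells <- n_dead_cells + 1L
        }
        log_rows[[length(log_rows) + 1L]] <- tibble(
          time_min = sched$time_min[ei], event_type = sched$event_type[ei],
          object_id = pid)
        ei <- ei + 1L
      }
      fr <- render_frame(objects, params)
      frames_h2b[[fi]] <- fr$h2b
      frames_pi[[fi]] <- fr$pi
      frame_truth <- bind_rows(frame_truth, tibble(
        frame = fi, time_min = frame_times[fi],
        n_alive = sum(objects$class == "alive"),
        n_dead_cells = n_dead_cells))
    }
  })

  nch <- if (params$pi_channel) 2L else 1L
  arr <- array(0, dim = c(dims, nch, nf))
  for (fi in seq_len(nf)) {
    arr[, , , 1L, fi] <- frames_h2b[[fi]]
    if (nch == 2L) arr[, , , 2L, fi] <- frames_pi[[fi]]
  }
  stk <- image_stack(arr, channels = c("H2B", "PI")[seq_len(nch)],
                     pixel_size_um = params$pixel_size_um,
                     z_step_um = params$z_step_um,
                     frame_interval_min = frame_interval_min)
  event_log <- if (length(log_rows)) bind_rows(log_rows) else
    tibble(time_min = numeric(), event_type = character(), object_id = integer())
  list(stack = stk, event_log = event_log, frame_truth = frame_truth)
}
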