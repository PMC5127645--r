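#' Threshold one channel into a binary mask
#'
#' A voxel is foreground iff its intensity is greater than or equal to the
#' threshold (inclusive convention, fixed for determinism).
#'
#' @param stack An [image_stack()].
#' @param channel Channel name or index.
#' @param threshold Intensity threshold.
#' @param frame Time frame, default 1.
#' @return A `binary_mask`: list with `mask` (logical `(y, x, z)` array),
#'   `threshold`, `channel`.
#' @export
binarize_channel <- function(stack, channel, threshold, frame = 1L) {
  arr <- stack_channel(stack, channel, frame)
  assert_scalar_number(threshold, "threshold")
  structure(list(mask = arr >= threshold, threshold = threshold,
                 channel = channel),
            class = "binary_mask")
}

binary_mask_from_array <- function(mask, threshold = NA_real_, channel = NA) {
  stopifnot(is.logical(mask), length(dim(mask)) %in% c(2L, 3L))
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  structure(list(mask = mask, threshold = threshold, channel = channel),
            class = "binary_mask")
}

# neighbor offsets for the supported connectivities
conn_offsets <- function(mode, connectivity) {
  if (mode == "slice") {
    if (!connectivity %in% c(4, 8)) {
      stop_organoidr("2D connectivity must be 4 or 8", "organoidr_bad_connectivity")
    }
    off <- expand.grid(dy = -1:1, dx = -1:1, dz = 0L)
    off <- off[!(off$dy == 0 & off$dx == 0), ]
    if (connectivity == 4) off <- off[abs(off$dy) + abs(off$dx) == 1, ]
  } else {
    if (!connectivity %in% c(6, 26)) {
      stop_organoidr("3D connectivity must be 6 or 26", "organoidr_bad_connectivity")
    }
    off <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
    off <- off[!(off$dy == 0 & off$dx == 0 & off$dz == 0), ]
    if (connectivity == 6) off <- off[abs(off$dy) + abs(off$dx) + abs(off$dz) == 1, ]
  }
  # half neighborhood suffices for undirected adjacency
  off[off$dz > 0 | (off$dz == 0 & (off$dx > 0 | (off$dx == 0 & off$dy > 0))), ]
}

# label foreground of a logical (y, x, z) array via graph components
label_components <- function(mask, offsets) {
  d <- dim(mask)
  fg <- which(mask)
  labels <- integer(length(fg))
  if (!length(fg)) return(list(fg = fg, labels = labels))
  idmap <- array(0L, dim = d)
  idmap[fg] <- seq_along(fg)
  co <- arrayInd(fg, d)
  edges <- list()
  for (i in seq_len(nrow(offsets))) {
    ny <- co[, 1] + offsets$dy[i]
    nx <- co[, 2] + offsets$dx[i]
    nz <- co[, 3] + offsets$dz[i]
    ok <- ny >= 1L & ny <= d[1] & nx >= 1L & nx <= d[2] & nz >= 1L & nz <= d[3]
    if (!any(ok)) next
    nid <- idmap[cbind(ny[ok], nx[ok], nz[ok])]
    hit <- nid > 0L
    if (any(hit)) {
      edges[[length(edges) + 1L]] <- cbind(which(ok)[hit], nid[hit])
    }
  }
  if (length(edges)) {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
    labels <- igraph::components(g)$membership[seq_along(fg)]
  } else {
    labels <- seq_along(fg)
  }
  list(fg = fg, labels = as.integer(labels))
}

#' Detect particles (connected components) in a binary mask
#'
#' Either per z-slice in 2D (the per-slice operation used when marking dead
#' pixels slice by slice) or over the whole volume in 3D.
#'
#' @param mask A `binary_mask` (from [binarize_channel()]).
#' @param mode `"slice"` (per-plane 2D labelling) or `"volume"` (3D).
#' @param connectivity 4 or 8 in slice mode (default 8); 6 or 26 in volume
#'   mode (default 26).
#' @return A tibble of class `particle_set`: `particle_id`, `slice` (`NA` in
#'   volume mode), `n_px`, centroids `y`/`x`/`z`, bounding box columns, and a
#'   `voxels` list-column of linear indices into the `(y, x, z)` array.
#' @export
find_particles <- function(mask, mode = c("slice", "volume"), connectivity = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  mode <- match.arg(mode)
  connectivity <- connectivity %||% if (mode == "slice") 8 else 26
  offsets <- conn_offsets(mode, connectivity)
  d <- dim(mask$mask)
  rows <- list()
  pid <- 0L

  collect <- function(fg, labels, slice) {
    if (!length(fg)) return(NULL)
    co <- arrayInd(fg, d)
    split_idx <- split(seq_along(fg), labels)
    purrr::map(split_idx, function(ii) {
      pid <<- pid + 1L
      tibble(
        particle_id = pid, slice = slice, n_px = length(ii),
        y = mean(co[ii, 1]), x = mean(co[ii, 2]), z = mean(co[ii, 3]),
        y_min = min(co[ii, 1]), y_max = max(co[ii, 1]),
        x_min = min(co[ii, 2]), x_max = max(co[ii, 2]),
        z_min = min(co[ii, 3]), z_max = max(co[ii, 3]),
        voxels = list(fg[ii]))
    })
  }

  if (mode == "volume") {
    lab <- label_components(mask$mask, offsets)
    rows <- collect(lab$fg, lab$labels, NA_integer_)
  } else {
    for (z in seq_len(d[3])) {
      sl <- array(FALSE, dim = d)
      sl[, , z] <- mask$mask[, , z]
      lab <- label_components(sl, offsets)
      rows <- c(rows, collect(lab$fg, lab$labels, z))
    }
  }
  out <- if (length(rows)) bind_rows(rows) else tibble(
    particle_id = integer(), slice = integer(), n_px = integer(),
    y = numeric(), x = numeric(), z = numeric(),
    y_min = integer(), y_max = integer(), x_min = integer(), x_max = integer(),
    z_min = integer(), z_max = integer(), voxels = list())
  class(out) <- c("particle_set", class(out))
  attr(out, "stack_dim") <- d
  attr(out, "mode") <- mode
  attr(out, "connectivity") <- connectivity
  out
}

#' Classify particles as alive nuclei or dead fragments by size
#'
#' Apoptotic nuclei shatter into fragments much smaller than intact nuclei,
#' so a particle is labelled `"dead"` iff its pixel count is strictly below
#' the size cutoff (a particle exactly at the cutoff is `"alive"`).
#'
#' @param particles A `particle_set` from [find_particles()].
#' @param size_cutoff_px Positive size cutoff in pixels/voxels; see
#'   [default_size_cutoff()] for the data-driven default.
#' @return The particle set with a `class` column (`"alive"` / `"dead"`).
#' @export
classify_particles <- function(particles, size_cutoff_px) {
  stopifnot(inherits(particles, "particle_set"))
  assert_scalar_number(size_cutoff_px, "size_cutoff_px", lower = 1e-9)
  out <- mutate(particles,
                class = if_else(.data$n_px < size_cutoff_px, "dead", "alive"))
  attr(out, "size_cutoff_px") <- size_cutoff_px
  out
}

#' Data-driven alive/dead size cutoff
#'
#' Half the median particle size of a vehicle (all-alive) reference field.
#' The untreated condition carries essentially only intact nuclei, so half
#' its median particle area separates nuclei from apoptotic fragments.
#'
#' @param vehicle_particles A `particle_set` measured on a vehicle condition.
#' @return Cutoff in pixels.
#' @export
default_size_cutoff <- function(vehicle_particles) {
  stopifnot(inherits(vehicle_particles, "particle_set"))
  if (!nrow(vehicle_particles)) {
    stop_organoidr("vehicle particle set is empty", "organoidr_bad_argument")
  }
  median(vehicle_particles$n_px) / 2
}

#' Integrate alive/dead pixel areas over the lower half of an organoid
#'
#' Sums alive and dead foreground areas over the slices forming the lower
#' half of the organoid's own z-extent (bottom-anchored,
#' `max(1, floor(n_slices / 2))` slices), the part of the volume with the
#' best image quality. The two masks must be congruent and disjoint; alive +
#' dead pixel counts equal total foreground in the analyzed slices by
#' construction.
#'
#' @param mask_alive,mask_dead `binary_mask` objects (or logical arrays) that
#'   partition the thresholded foreground.
#' @param z_extent Integer `c(z_lo, z_hi)` of the organoid's z-range; default
#'   is the z-support of the combined mask.
#' @param organoid_id,timepoint Identifiers carried into the output.
#' @return A one-row tibble of class `viability_quant`: `organoid_id`,
#'   `timepoint`, `alive_px`, `dead_px`, `z_lo`, `z_hi` (analyzed range).
#' @export
quantify_lower_half <- function(mask_alive, mask_dead, z_extent = NULL,
                                organoid_id = NA_character_,
                                timepoint = NA_real_) {
  ma <- if (inherits(mask_alive, "binary_mask")) mask_alive$mask else mask_alive
  md <- if (inherits(mask_dead, "binary_mask")) mask_dead$mask else mask_dead
  if (!identical(dim(ma), dim(md))) {
    stop_organoidr("alive and dead masks must be congruent", "organoidr_bad_argument")
  }
  if (any(ma & md)) {
    stop_organoidr("alive and dead masks must be disjoint", "organoidr_bad_argument")
  }
  d <- dim(ma)
  if (is.null(z_extent)) {
    support <- which(apply(ma | md, 3, any))
    if (!length(support)) {
      stop_organoidr("masks are empty; no z-extent to analyze", "organoidr_empty_mask")
    }
    z_extent <- range(support)
  }
  z_extent <- as.integer(z_extent)
  if (length(z_extent) != 2L || z_extent[1] > z_extent[2] ||
      z_extent[1] < 1L || z_extent[2] > d[3]) {
    stop_organoidr("`z_extent` outside the stack", "organoidr_bad_argument")
  }
  n_slices <- z_extent[2] - z_extent[1] + 1L
  n_lower <- max(1L, n_slices %/% 2L)
  zs <- z_extent[1]:(z_extent[1] + n_lower - 1L)
  out <- tibble(
    organoid_id = organoid_id, timepoint = timepoint,
    alive_px = sum(ma[, , zs, drop = FALSE]),
    dead_px = sum(md[, , zs, drop = FALSE]),
    z_lo = zs[1], z_hi = zs[length(zs)])
  class(out) <- c("viability_quant", class(out))
  out
}
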