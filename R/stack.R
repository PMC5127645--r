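#' Multi-channel 3D(+time) image stack
#'
#' Container for confocal voxel data. Data are stored as a 5-D numeric array
#' with dimensions `(y, x, z, channel, time)`; z index 1 is the bottom plane
#' (closest to the vessel floor). Physical calibration is carried as microns
#' per xy pixel and microns between z planes.
#'
#' @param data Numeric array. Accepted shapes: `(y, x)`, `(y, x, z)`,
#'   `(y, x, z, channel)` or `(y, x, z, channel, time)`; lower-dimensional
#'   input is promoted with singleton axes.
#' @param channels Character vector of channel names, e.g. `c("H2B", "PI")`.
#' @param pixel_size_um Microns per pixel in xy.
#' @param z_step_um Microns between consecutive z planes.
#' @param frame_interval_min Minutes between time frames (`NA` for a single
#'   timepoint).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, channels = NULL, pixel_size_um = 1, z_step_um = 1,
                        frame_interval_min = NA_real_) {
  if (!is.numeric(data)) {
    stop_organoidr("`data` must be a numeric array", "organoidr_bad_argument")
  }
  if (is.null(dim(data))) dim(data) <- c(length(data), 1L)
  nd <- length(dim(data))
  if (nd < 2L || nd > 5L) {
    stop_organoidr("`data` must have between 2 and 5 dimensions", "organoidr_bad_argument")
  }
  dim(data) <- c(dim(data), rep(1L, 5L - nd))
  if (any(dim(data) <= 0L)) {
    stop_organoidr("all stack dimensions must be positive", "organoidr_bad_stack")
  }
  if (min(data) < 0) {
    stop_organoidr("voxel intensities must be >= 0", "organoidr_bad_stack")
  }
  nc <- dim(data)[4]
  if (is.null(channels)) channels <- paste0("ch", seq_len(nc))
  if (length(channels) != nc) {
    stop_organoidr("`channels` length must match the channel axis", "organoidr_bad_argument")
  }
  assert_scalar_number(pixel_size_um, "pixel_size_um", lower = 1e-9)
  assert_scalar_number(z_step_um, "z_step_um", lower = 1e-9)
  structure(
    list(data = data, channels = channels,
         pixel_size_um = pixel_size_um, z_step_um = z_step_um,
         frame_interval_min = frame_interval_min),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_stack> %d x %d px, %d z-planes, channels: %s, %d frame(s)\n",
    d[1], d[2], d[3], paste(x$channels, collapse = ", "), d[5]))
  cat(sprintf("  calibration: %.3g um/px (xy), %.3g um/plane (z)\n",
              x$pixel_size_um, x$z_step_um))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' Extract one channel of one frame as a 3D array
#'
#' @param stack An [image_stack()].
#' @param channel Channel name or index.
#' @param frame Time frame index (1-based), default 1.
#' @return Numeric `(y, x, z)` array.
#' @export
stack_channel <- function(stack, channel = 1L, frame = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  ci <- resolve_channel(stack, channel)
  d <- dim(stack$data)
  if (frame < 1L || frame > d[5]) {
    stop_organoidr(sprintf("frame %s outside 1..%d", frame, d[5]), "organoidr_bad_argument")
  }
  arr <- stack$data[, , , ci, frame]
  dim(arr) <- d[1:3]
  arr
}

resolve_channel <- function(stack, channel) {
  if (is.character(channel)) {
    ci <- match(channel, stack$channels)
    if (is.na(ci)) {
      stop_organoidr(sprintf("unknown channel '%s' (have: %s)", channel,
                             paste(stack$channels, collapse = ", ")),
                     "organoidr_unknown_channel")
    }
    return(ci)
  }
  ci <- as.integer(channel)
  if (ci < 1L || ci > length(stack$channels)) {
    stop_organoidr(sprintf("channel index %d outside 1..%d", ci, length(stack$channels)),
                   "organoidr_unknown_channel")
  }
  ci
}

#' Write an image stack as multi-page 16-bit TIFF with a JSON sidecar
#'
#' Pages are ordered time-major, then z, then channel (TZCYX). Intensities are
#' rounded to integers and must fit in 16 bits. Calibration and axis metadata
#' go to `<path>.json` so [read_stack_tiff()] can restore the exact object.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  if (max(stack$data) > 65535) {
    stop_organoidr("intensities exceed 16-bit range", "organoidr_bad_stack")
  }
  pages <- list()
  k <- 1L
  for (t in seq_len(d[5])) for (z in seq_len(d[3])) for (c in seq_len(d[4])) {
    pages[[k]] <- round(stack$data[, , z, c, t]) / 65535
    dim(pages[[k]]) <- d[1:2]
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(
    shape_yxzct = d, channels = stack$channels,
    pixel_size_um = stack$pixel_size_um, z_step_um = stack$z_step_um,
    frame_interval_min = stack$frame_interval_min, page_order = "TZC"
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stack written by [write_stack_tiff()]
#'
#' @param path TIFF path; `<path>.json` must exist alongside.
#' @return An [image_stack()].
#' @export
read_stack_tiff <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) {
    stop_organoidr(sprintf("metadata sidecar not found: %s", meta_path),
                   "organoidr_io_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$shape_yxzct)
  arr <- array(0, dim = d)
  k <- 1L
  for (t in seq_len(d[5])) for (z in seq_len(d[3])) for (c in seq_len(d[4])) {
    arr[, , z, c, t] <- round(pages[[k]] * 65535)
    k <- k + 1L
  }
  image_stack(arr, channels = meta$channels,
              pixel_size_um = meta$pixel_size_um, z_step_um = meta$z_step_um,
              frame_interval_min = meta$frame_interval_min %||% NA_real_)
}
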