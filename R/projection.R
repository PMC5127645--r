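#' Depth-coded maximum-intensity z-projection
#'
#' Projects a 3D channel to 2D: per xy pixel, intensity is the maximum over
#' z and hue encodes the z-position of that maximum (ties resolved to the
#' lowest z plane). The hue comes from `lut`, a palette over normalized depth.
#' When a transmitted-light channel is given, a four-quadrant montage frame
#' is also returned (depth-coded projection, transmitted light, grayscale
#' projection, and their blend).
#'
#' @param stack An [image_stack()] with at least one z-plane.
#' @param channel Channel to project, default `"H2B"`.
#' @param frame Time frame index.
#' @param lut Function mapping normalized depth in `[0, 1]` to a color; the
#'   default spans blue (bottom) to red (top).
#' @param transmitted Optional transmitted-light channel name/index for the
#'   quadrant montage.
#' @return A list of class `depth_projection`: `intensity` (max projection
#'   matrix), `z_index` (1-based argmax matrix), `rgb` (`(y, x, 3)` array in
#'   `[0, 1]`), and optionally `quadrants` (`(2y, 2x, 3)` montage).
#' @export
depth_coded_projection <- function(stack, channel = 1L, frame = 1L,
                                   lut = NULL, transmitted = NULL) {
  arr <- stack_channel(stack, channel, frame)
  d <- dim(arr)
  nz <- d[3]
  lut <- lut %||% function(u) grDevices::hsv(h = 0.7 * (1 - u), s = 1, v = 1)
  proj <- arr[, , 1]
  zidx <- array(1L, dim = d[1:2])
  if (nz > 1L) {
    for (z in 2:nz) {
      plane <- arr[, , z]
      better <- plane > proj  # strict: ties stay at the lowest z
      proj[better] <- plane[better]
      zidx[better] <- z
    }
  }
  depth_norm <- if (nz > 1L) (zidx - 1) / (nz - 1) else array(0, dim = d[1:2])
  cols <- grDevices::col2rgb(lut(as.vector(depth_norm))) / 255
  rng <- range(proj)
  val <- if (diff(rng) > 0) (proj - rng[1]) / diff(rng) else array(0, dim = d[1:2])
  rgb <- array(0, dim = c(d[1:2], 3L))
  for (k in 1:3) rgb[, , k] <- matrix(cols[k, ], d[1], d[2]) * as.vector(val)
  out <- list(intensity = proj, z_index = zidx, rgb = rgb,
              channel = channel, lut = lut)
  if (!is.null(transmitted)) {
    tl <- stack_channel(stack, transmitted, frame)
    tl2 <- apply(tl, c(1, 2), max)
    tl_rng <- range(tl2)
    tl_n <- if (diff(tl_rng) > 0) (tl2 - tl_rng[1]) / diff(tl_rng) else tl2 * 0
    gray <- array(rep(val, 3L), dim = c(d[1:2], 3L))
    tl_rgb <- array(rep(tl_n, 3L), dim = c(d[1:2], 3L))
    blend <- pmin(1, 0.5 * tl_rgb + rgb)
    quad <- array(0, dim = c(2L * d[1], 2L * d[2], 3L))
    quad[seq_len(d[1]), seq_len(d[2]), ] <- rgb
    quad[seq_len(d[1]), d[2] + seq_len(d[2]), ] <- tl_rgb
    quad[d[1] + seq_len(d[1]), seq_len(d[2]), ] <- gray
    quad[d[1] + seq_len(d[1]), d[2] + seq_len(d[2]), ] <- blend
    out$quadrants <- quad
  }
  structure(out, class = "depth_projection")
}

#' Write a depth-coded projection (or its quadrant montage) as PNG
#'
#' @param projection A `depth_projection`.
#' @param path Output PNG path.
#' @param quadrants Write the four-quadrant montage instead of the plain
#'   projection (requires that it was rendered).
#' @return `path`, invisibly.
#' @export
write_projection_png <- function(projection, path, quadrants = FALSE) {
  stopifnot(inherits(projection, "depth_projection"))
  img <- if (quadrants) {
    if (is.null(projection$quadrants)) {
      stop_organoidr("projection has no quadrant montage (no transmitted channel given)",
                     "organoidr_bad_argument")
    }
    projection$quadrants
  } else projection$rgb
  grDevices::png(path, width = dim(img)[2], height = dim(img)[1])
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::plot.new()
  graphics::rasterImage(img, 0, 0, 1, 1, interpolate = FALSE)
  invisible(path)
}
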