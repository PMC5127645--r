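#' Auto-threshold by ramped threshold scan
#'
#' Scans candidate thresholds and, per threshold `T`, measures the foreground
#' surface `area(T)` (count of pixels >= `T`) and its `mean(T)` intensity.
#' Both curves are min-max normalized to `[0, 1]` over the grid and the
#' optimum combines the highest mean signal with the most confined surface:
#' `score(T) = norm_mean(T) - norm_area(T)`, maximized over the grid (ties
#' resolved to the lowest threshold). Thresholds that select no pixel are
#' excluded (their mean is undefined).
#'
#' Note the score's domain of validity: it is designed for images whose
#' intensity distribution is close to two-level (confined bright surfaces on
#' a dark background, as in high-laser-power endpoint acquisitions). On
#' images with a long continuous intensity tail the normalized mean keeps
#' rising with the threshold and the optimum drifts toward the top of the
#' range; use [midpoint_threshold()] or an explicit threshold there.
#'
#' @param img Numeric array (any dimensionality) of one channel.
#' @param t_grid Candidate thresholds; at least 3 distinct values. Default:
#'   64 values spanning the intensity range of `img`.
#' @return A list of class `ramp_scan`: `threshold` (the optimum), and
#'   `curves`, a tibble `(threshold, area, mean_intensity, score)` for
#'   diagnostics.
#' @export
ramp_threshold_optimum <- function(img, t_grid = NULL) {
  v <- as.vector(img)
  if (!length(v)) stop_organoidr("empty image", "organoidr_bad_argument")
  rng <- range(v)
  if (diff(rng) == 0) {
    stop_organoidr("image is constant; ramped threshold scan is degenerate",
                   "organoidr_degenerate_image")
  }
  t_grid <- t_grid %||% seq(rng[1], rng[2], length.out = 64)
  t_grid <- sort(unique(t_grid))
  if (length(t_grid) < 3L) {
    stop_organoidr("`t_grid` needs at least 3 distinct values", "organoidr_bad_argument")
  }
  area <- map_dbl(t_grid, ~ sum(v >= .x))
  mean_int <- map_dbl(t_grid, ~ if (any(v >= .x)) mean(v[v >= .x]) else NA_real_)
  ok <- area > 0
  if (sum(ok) < 2L || diff(range(area[ok])) == 0) {
    stop_organoidr("area curve is degenerate over the threshold grid",
                   "organoidr_degenerate_image")
  }
  norm01 <- function(x) {
    r <- range(x, na.rm = TRUE)
    if (diff(r) == 0) return(ifelse(is.na(x), NA_real_, 0)) # flat curve carries no signal
    (x - r[1]) / diff(r)
  }
  score <- norm01(mean_int) - norm01(area)
  score[!ok] <- NA_real_
  best <- which(score == max(score, na.rm = TRUE))[1]  # ties -> lowest T
  structure(
    list(threshold = t_grid[best],
         curves = tibble(threshold = t_grid, area = area,
                         mean_intensity = mean_int, score = score)),
    class = "ramp_scan")
}

#' Simple midpoint intensity threshold
#'
#' Midpoint between the median intensity (which in a sparse fluorescence
#' image estimates the background level) and the maximum. Robust for
#' bright-blob-on-dark-background images where the ramped-threshold score is
#' not appropriate (see the note in [ramp_threshold_optimum()]); used as the
#' default thresholding rule of the imaging pipeline.
#'
#' @param img Numeric array of one channel.
#' @return Scalar threshold.
#' @export
midpoint_threshold <- function(img) {
  v <- as.vector(img)
  if (!length(v) || diff(range(v)) == 0) {
    stop_organoidr("image is empty or constant", "organoidr_degenerate_image")
  }
  (median(v) + max(v)) / 2
}

#' PI/H2B surface ratio: the quantitative measure for cell death
#'
#' Thresholds the nuclear (H2B) and propidium-iodide channels over the whole
#' stack and returns the ratio of PI-positive to H2B-positive pixel counts.
#' Counts are pooled over all organoids in the field before the division
#' (ratio of summed counts, not mean of per-organoid ratios). The PI mask is
#' deliberately not constrained to the H2B mask, so the ratio may marginally
#' exceed 1 on pathological input.
#'
#' @param stack An [image_stack()] with both channels.
#' @param t_h2b,t_pi Thresholds for the two channels, or `"auto"` to derive
#'   each from [ramp_threshold_optimum()] on that channel.
#' @param h2b_channel,pi_channel Channel names/indices.
#' @param frame Time frame index.
#' @return A one-row tibble of class `death_ratio`: `pi_px`, `h2b_px`,
#'   `ratio`, `t_h2b`, `t_pi`.
#' @export
pi_h2b_death_ratio <- function(stack, t_h2b = "auto", t_pi = "auto",
                               h2b_channel = "H2B", pi_channel = "PI",
                               frame = 1L) {
  h2b <- stack_channel(stack, h2b_channel, frame)
  pi_arr <- stack_channel(stack, pi_channel, frame)
  if (identical(t_h2b, "auto")) t_h2b <- ramp_threshold_optimum(h2b)$threshold
  if (identical(t_pi, "auto")) t_pi <- ramp_threshold_optimum(pi_arr)$threshold
  assert_scalar_number(t_h2b, "t_h2b")
  assert_scalar_number(t_pi, "t_pi")
  h2b_px <- sum(h2b >= t_h2b)
  pi_px <- sum(pi_arr >= t_pi)
  if (h2b_px == 0L) {
    stop_organoidr("no H2B-positive pixels at this threshold; death ratio undefined",
                   "organoidr_empty_mask")
  }
  out <- tibble(pi_px = pi_px, h2b_px = h2b_px, ratio = pi_px / h2b_px,
                t_h2b = t_h2b, t_pi = t_pi)
  class(out) <- c("death_ratio", class(out))
  out
}
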