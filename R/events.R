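#' Validate an event log of marked mitoses and apoptoses
#'
#' @param log Data frame with columns `time_min` (>= 0), `event_type`
#'   (`"mitosis"` / `"apoptosis"`), and optionally `organoid_id`.
#' @return The log as a tibble with `organoid_id` filled in.
#' @export
as_event_log <- function(log) {
  log <- as_tibble(log)
  if (!all(c("time_min", "event_type") %in% names(log))) {
    stop_organoidr("event log needs `time_min` and `event_type` columns",
                   "organoidr_bad_log")
  }
  if (any(log$time_min < 0)) {
    stop_organoidr("event times must be >= 0", "organoidr_bad_log")
  }
  bad <- setdiff(unique(log$event_type), c("mitosis", "apoptosis"))
  if (length(bad)) {
    stop_organoidr(sprintf("unknown event type(s): %s", paste(bad, collapse = ", ")),
                   "organoidr_bad_log")
  }
  if (!"organoid_id" %in% names(log)) log$organoid_id <- 1L
  log
}

#' Reconstruct a relative cell-count trajectory from chronologically ranked events
#'
#' Chronological ranking of the marked mitotic and apoptotic events
#' reconstructs the organoid's size evolution over time: starting from `n0`,
#' the count steps +1 at every mitosis and -1 at every apoptosis. Events at
#' identical times are ordered apoptosis first (fixed convention), then by
#' input order. A count that would drop below zero signals an inconsistent
#' log and raises an error.
#'
#' @param log An event log (see [as_event_log()]); pass one organoid at a
#'   time or a pooled log if a pooled trajectory is wanted.
#' @param n0 Starting cell count (>= 1).
#' @return A tibble of class `count_trajectory`: `time_min`, `count`, with a
#'   leading row at time 0 holding `n0` (attribute `n0`).
#' @export
reconstruct_trajectory <- function(log, n0) {
  log <- as_event_log(log)
  if (!is.numeric(n0) || length(n0) != 1L || n0 < 1 || n0 != round(n0)) {
    stop_organoidr("`n0` must be a positive integer", "organoidr_bad_argument")
  }
  log <- log[order(log$time_min,
                   match(log$event_type, c("apoptosis", "mitosis"))), ]
  delta <- ifelse(log$event_type == "mitosis", 1L, -1L)
  counts <- n0 + cumsum(delta)
  if (any(counts < 0)) {
    stop_organoidr("inconsistent log: cell count would drop below 0",
                   "organoidr_inconsistent_log")
  }
  out <- bind_rows(
    tibble(time_min = 0, count = as.integer(n0)),
    tibble(time_min = log$time_min, count = as.integer(counts)))
  class(out) <- c("count_trajectory", class(out))
  attr(out, "n0") <- as.integer(n0)
  out
}

#' Per-window mitosis and apoptosis rates
#'
#' Bins events into half-open windows `[k*w, (k+1)*w)` (an event exactly on a
#' boundary belongs to the later window) and divides the counts by the number
#' of organoids scored.
#'
#' @param log An event log.
#' @param window_min Window width in minutes (> 0).
#' @param n_organoids Number of organoids the log covers (> 0).
#' @return A tibble: `window`, `t_start_min`, `t_end_min`, `mitosis_n`,
#'   `apoptosis_n`, `mitosis_per_organoid`, `apoptosis_per_organoid`.
#' @export
event_rates <- function(log, window_min, n_organoids) {
  log <- as_event_log(log)
  assert_scalar_number(window_min, "window_min", lower = 1e-9)
  if (!is.numeric(n_organoids) || length(n_organoids) != 1L || n_organoids <= 0) {
    stop_organoidr("`n_organoids` must be positive", "organoidr_bad_argument")
  }
  win <- floor(log$time_min / window_min)
  n_win <- if (nrow(log)) max(win) + 1L else 0L
  out <- tibble(window = seq_len(n_win) - 1L) |>
    mutate(t_start_min = .data$window * window_min,
           t_end_min = (.data$window + 1) * window_min,
           mitosis_n = map_int(.data$window,
             ~ sum(win == .x & log$event_type == "mitosis")),
           apoptosis_n = map_int(.data$window,
             ~ sum(win == .x & log$event_type == "apoptosis")),
           mitosis_per_organoid = .data$mitosis_n / n_organoids,
           apoptosis_per_organoid = .data$apoptosis_n / n_organoids)
  out
}

#' Growth speed of a count trajectory by linear fitting
#'
#' Ordinary least-squares slope of cell count versus time over a window,
#' typically the first or second half of the recording. The step trajectory
#' is sampled at its change points within the window plus the window
#' endpoints (count at an endpoint is the value after all events at or
#' before it).
#'
#' @param traj A `count_trajectory` from [reconstruct_trajectory()].
#' @param window Numeric `c(t_lo, t_hi)` in minutes; default the whole
#'   trajectory.
#' @return A one-row tibble: `slope_cells_per_h`, `se_cells_per_h`,
#'   `n_points`, `t_lo_min`, `t_hi_min`.
#' @export
fit_growth_speed <- function(traj, window = NULL) {
  stopifnot(inherits(traj, "count_trajectory"))
  window <- window %||% range(traj$time_min)
  if (length(window) != 2L || window[1] >= window[2]) {
    stop_organoidr("`window` must be c(t_lo, t_hi) with t_lo < t_hi",
                   "organoidr_bad_argument")
  }
  # right-continuous step function; simultaneous events collapse to the
  # post-event count at that time
  agg <- traj |>
    group_by(.data$time_min) |>
    summarise(count = dplyr::last(.data$count), .groups = "drop") |>
    arrange(.data$time_min)
  sf <- if (nrow(agg) > 1L) {
    stats::stepfun(agg$time_min[-1], agg$count, right = FALSE)
  } else {
    function(t) rep(agg$count[1], length(t))
  }
  inner <- agg$time_min[agg$time_min > window[1] & agg$time_min < window[2]]
  tt <- sort(unique(c(window, inner)))
  yy <- sf(tt)
  if (length(tt) < 2L) {
    stop_organoidr("fewer than 2 trajectory points in the window",
                   "organoidr_bad_argument")
  }
  fit <- lm(yy ~ I(tt / 60))
  # summary.lm warns on perfect (zero-residual) fits; those are legitimate here
  sm <- suppressWarnings(summary(fit))$coefficients
  se <- if (nrow(sm) > 1L && !is.na(sm[2, 2])) sm[2, 2] else NA_real_
  tibble(slope_cells_per_h = unname(coef(fit)[2]), se_cells_per_h = se,
         n_points = length(tt), t_lo_min = window[1], t_hi_min = window[2])
}

#' Growth speeds over the first and second half of a recording
#'
#' @param traj A `count_trajectory`.
#' @param duration_min Total recording length; default the last event time.
#' @return Two-row tibble (one row per half) as from [fit_growth_speed()],
#'   with a `half` column.
#' @export
growth_speed_halves <- function(traj, duration_min = NULL) {
  stopifnot(inherits(traj, "count_trajectory"))
  duration_min <- duration_min %||% max(traj$time_min)
  mid <- duration_min / 2
  bind_rows(
    mutate(fit_growth_speed(traj, c(0, mid)), half = "first"),
    mutate(fit_growth_speed(traj, c(mid, duration_min)), half = "second"))
}
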