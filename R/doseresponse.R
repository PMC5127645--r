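#' Normalize raw plate signals to percent viability
#'
#' Maps the vehicle (DMSO) mean to 100% and the multi-drug signal plateau at
#' high concentrations to 0%: `v = 100 * (raw - B) / (V - B)`. `V` is the
#' mean of the vehicle wells; the baseline `B` is either given explicitly or
#' estimated as the mean of the `k` wells with the highest total
#' concentration (default k = 3). Replicate wells at identical
#' `(conc_a, conc_b)` are averaged after normalization; values are not
#' clipped. The zero-concentration cell `(0, 0)` of the returned matrix is
#' the normalized vehicle mean (100 by construction).
#'
#' @param reads A `plate_reads` tibble (columns `conc_a_nM`, `conc_b_nM`,
#'   `signal`, `role`), e.g. from [make_plate_reads()] or read from CSV.
#' @param baseline `"plateau_wells"` (estimate from the most-inhibited wells)
#'   or a numeric baseline signal.
#' @param k Number of highest-total-concentration wells averaged for the
#'   plateau estimate.
#' @return A tibble of class `dose_matrix`: `conc_a_nM`, `conc_b_nM`,
#'   `viability_pct`, one row per grid cell, with normalization constants in
#'   attributes `vehicle_mean` and `baseline`.
#' @export
normalize_viability <- function(reads, baseline = "plateau_wells", k = 3L) {
  reads <- as_tibble(reads)
  need <- c("conc_a_nM", "conc_b_nM", "signal", "role")
  if (!all(need %in% names(reads))) {
    stop_organoidr(sprintf("plate reads need columns: %s", paste(need, collapse = ", ")),
                   "organoidr_bad_reads")
  }
  veh <- reads$signal[reads$role == "vehicle"]
  if (!length(veh)) {
    stop_organoidr("no vehicle wells; cannot anchor 100%", "organoidr_bad_reads")
  }
  V <- mean(veh)
  treated <- filter(reads, .data$role == "treated")
  if (identical(baseline, "plateau_wells")) {
    top <- treated |>
      arrange(desc(.data$conc_a_nM + .data$conc_b_nM)) |>
      dplyr::slice_head(n = k)
    B <- mean(top$signal)
  } else {
    assert_scalar_number(baseline, "baseline")
    B <- baseline
  }
  if (V <= B) {
    stop_organoidr("vehicle mean does not exceed the baseline plateau (assay failed)",
                   "organoidr_assay_failure")
  }
  norm <- bind_rows(
    treated |> mutate(viability_pct = 100 * (.data$signal - B) / (V - B)),
    reads |> filter(.data$role == "vehicle") |>
      mutate(conc_a_nM = 0, conc_b_nM = 0,
             viability_pct = 100 * (.data$signal - B) / (V - B)))
  out <- norm |>
    group_by(.data$conc_a_nM, .data$conc_b_nM) |>
    summarise(viability_pct = mean(.data$viability_pct), .groups = "drop") |>
    arrange(.data$conc_a_nM, .data$conc_b_nM)
  class(out) <- c("dose_matrix", class(out))
  attr(out, "vehicle_mean") <- V
  attr(out, "baseline") <- B
  out
}

#' Spread a dose matrix (or Bliss matrix) into a numeric grid
#'
#' @param m A `dose_matrix` or `bliss_matrix`.
#' @return A numeric matrix, rows = `conc_a_nM`, columns = `conc_b_nM`,
#'   dimnames carrying the concentrations.
#' @export
as_grid <- function(m) {
  value_col <- if (inherits(m, "bliss_matrix")) "bliss_score" else "viability_pct"
  a <- sort(unique(m$conc_a_nM))
  b <- sort(unique(m$conc_b_nM))
  g <- matrix(NA_real_, length(a), length(b),
              dimnames = list(format(a, trim = TRUE), format(b, trim = TRUE)))
  g[cbind(match(m$conc_a_nM, a), match(m$conc_b_nM, b))] <- m[[value_col]]
  g
}

grid_to_tbl <- function(g, a, b, value_col) {
  out <- tidyr::expand_grid(conc_a_nM = a, conc_b_nM = b)
  out[[value_col]] <- g[cbind(match(out$conc_a_nM, a), match(out$conc_b_nM, b))]
  out
}

#' Bliss-independence excess over a full dose matrix
#'
#' For each combination cell, the fractional inhibitions of the two
#' monotherapies `fA = 1 - v(a, 0)/100` and `fB = 1 - v(0, b)/100` (clamped
#' to `[0, 1]`) predict an independent combined inhibition
#' `fA + fB - fA * fB`; the Bliss score is the observed combined inhibition
#' minus that expectation. Positive scores mark combinations whose effect
#' exceeds the additive expectation. Monotherapy rows/columns score 0 by
#' construction.
#'
#' @param matrix A `dose_matrix` containing the zero-concentration row and
#'   column (the monotherapies).
#' @return A tibble of class `bliss_matrix`: `conc_a_nM`, `conc_b_nM`,
#'   `bliss_score`.
#' @export
bliss_excess <- function(matrix) {
  stopifnot(inherits(matrix, "dose_matrix"))
  a <- sort(unique(matrix$conc_a_nM))
  b <- sort(unique(matrix$conc_b_nM))
  if (!(0 %in% a) || !(0 %in% b)) {
    stop_organoidr("dose matrix must contain the zero-concentration row and column",
                   "organoidr_missing_monotherapy")
  }
  g <- as_grid(matrix)
  clamp01 <- function(x) pmin(1, pmax(0, x))
  fA <- clamp01(1 - g[, 1] / 100)   # column b = 0
  fB <- clamp01(1 - g[1, ] / 100)   # row a = 0
  expected <- outer(fA, fB, function(x, y) x + y - x * y)
  observed <- clamp01(1 - g / 100)
  score <- observed - expected
  score[1, ] <- 0
  score[, 1] <- 0
  out <- grid_to_tbl(score, a, b, "bliss_score")
  class(out) <- c("bliss_matrix", class(out))
  out
}

#' Smooth a dose or Bliss matrix with a moving average
#'
#' Each cell is replaced by the mean of its `window x window` neighborhood on
#' the concentration grid; the window shrinks at the edges. `window = 1` is
#' the identity.
#'
#' @param m A `dose_matrix` or `bliss_matrix`.
#' @param window Odd positive integer, default 3.
#' @return Object of the same class with smoothed values.
#' @export
smooth_matrix <- function(m, window = 3L) {
  if (!inherits(m, "dose_matrix") && !inherits(m, "bliss_matrix")) {
    stop_organoidr("`m` must be a dose_matrix or bliss_matrix", "organoidr_bad_argument")
  }
  if (window < 1 || window %% 2 == 0) {
    stop_organoidr("`window` must be an odd positive integer", "organoidr_bad_argument")
  }
  value_col <- if (inherits(m, "bliss_matrix")) "bliss_score" else "viability_pct"
  g <- as_grid(m)
  h <- (window - 1L) %/% 2L
  sm <- g
  for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g))) {
    ii <- max(1L, i - h):min(nrow(g), i + h)
    jj <- max(1L, j - h):min(ncol(g), j + h)
    sm[i, j] <- mean(g[ii, jj])
  }
  a <- sort(unique(m$conc_a_nM)); b <- sort(unique(m$conc_b_nM))
  out <- grid_to_tbl(sm, a, b, value_col)
  class(out) <- class(m)
  for (at in c("vehicle_mean", "baseline")) attr(out, at) <- attr(m, at)
  out
}

#' Extract monotherapy or fixed-ratio diagonal curves from a dose matrix
#'
#' Monotherapy modes return the zero-concentration row/column of the matrix
#' (the horizontal and vertical lines of the heat map). Diagonal mode returns
#' the fixed-ratio combination cells where
#' `log10(conc_b) = log10(conc_a) + ratio_offset_logdecades` (offset 0 is the
#' equimolar diagonal); its concentration axis is the reference drug A and
#' the offset is recorded, so a combination IC50 fitted on the curve is
#' reported on the reference axis.
#'
#' @param matrix A `dose_matrix`.
#' @param mode `"row_a_mono"`, `"col_b_mono"` or `"fixed_ratio_diagonal"`.
#' @param ratio_offset_logdecades Log10 offset of drug B relative to drug A
#'   on the diagonal (e.g. -2 when drug B runs two decades lower).
#' @param tol Relative matching tolerance on the log grid.
#' @return A tibble: `conc_nM` (reference axis), `viability_pct`, `mode`,
#'   `ratio_offset_logdecades` (`NA` for monotherapies).
#' @export
extract_curve <- function(matrix,
                          mode = c("row_a_mono", "col_b_mono", "fixed_ratio_diagonal"),
                          ratio_offset_logdecades = 0, tol = 1e-6) {
  stopifnot(inherits(matrix, "dose_matrix"))
  mode <- match.arg(mode)
  if (mode == "row_a_mono") {
    cur <- matrix |> filter(.data$conc_b_nM == 0, .data$conc_a_nM > 0)
    return(tibble(conc_nM = cur$conc_a_nM, viability_pct = cur$viability_pct,
                  mode = mode, ratio_offset_logdecades = NA_real_))
  }
  if (mode == "col_b_mono") {
    cur <- matrix |> filter(.data$conc_a_nM == 0, .data$conc_b_nM > 0)
    return(tibble(conc_nM = cur$conc_b_nM, viability_pct = cur$viability_pct,
                  mode = mode, ratio_offset_logdecades = NA_real_))
  }
  cmb <- matrix |> filter(.data$conc_a_nM > 0, .data$conc_b_nM > 0)
  hit <- abs(log10(cmb$conc_b_nM) - log10(cmb$conc_a_nM) -
               ratio_offset_logdecades) < tol
  cur <- cmb[hit, ]
  if (!nrow(cur)) {
    stop_organoidr(sprintf("no grid cells at diagonal offset %g log decades",
                           ratio_offset_logdecades),
                   "organoidr_bad_offset")
  }
  cur <- arrange(cur, .data$conc_a_nM)
  tibble(conc_nM = cur$conc_a_nM, viability_pct = cur$viability_pct,
         mode = mode, ratio_offset_logdecades = ratio_offset_logdecades)
}
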