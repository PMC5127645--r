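#' Concentration-grid presets used in the study designs this package targets
#'
#' * `"fig3b"` — 14 log-spaced concentrations, 5 nM to 5 uM (full 14 x 14
#'   two-drug matrix design).
#' * `"fig4"` — 22 log-spaced concentrations, 5 nM to 20 uM.
#' * `"fig9d"` — 9 log-spaced concentrations, 5 nM to 20 uM.
#'
#' @param preset One of `"fig3b"`, `"fig4"`, `"fig9d"`.
#' @return Numeric vector of concentrations in nM, strictly increasing.
#' @export
conc_preset <- function(preset = c("fig3b", "fig4", "fig9d")) {
  preset <- match.arg(preset)
  switch(preset,
    fig3b = 10^seq(log10(5), log10(5000), length.out = 14),
    fig4  = 10^seq(log10(5), log10(20000), length.out = 22),
    fig9d = 10^seq(log10(5), log10(20000), length.out = 9))
}

#' Parameters of one simulated drug (normalized 4PL truth)
#'
#' @param log10_ic50 log10 of the IC50 in molar (e.g. -7 is 100 nM).
#' @param hill_slope Hill slope, positive = response falls with dose.
#' @return A named list of class `drug_truth`.
#' @export
drug_truth <- function(log10_ic50, hill_slope = 1) {
  assert_scalar_number(log10_ic50, "log10_ic50")
  assert_scalar_number(hill_slope, "hill_slope", lower = 1e-6)
  structure(list(log10_ic50 = log10_ic50, hill_slope = hill_slope),
            class = "drug_truth")
}

#' Simulate raw plate-reader signals from a known dose-response surface
#'
#' Builds a full two-drug matrix (all combinations of `c(0, conc_a_nM)` and
#' `c(0, conc_b_nM)`, the zero row/column being the monotherapies) plus
#' dedicated vehicle wells. The fractional viability of a well is the 4PL
#' value for monotherapy wells and the Bliss-independent product of the two
#' single-drug viabilities minus `bliss_excess` for combination wells; the
#' raw signal is `plateau + v * (vehicle - plateau)` under multiplicative
#' lognormal noise of coefficient of variation `noise_cv`.
#'
#' @param drug_a,drug_b [drug_truth()] objects (set `drug_b = NULL` for a
#'   single-drug plate with `conc_b_nM = numeric()`).
#' @param conc_a_nM,conc_b_nM Positive concentration grids in nM.
#' @param bliss_excess Scalar synergy excess (on the fractional-inhibition
#'   scale) subtracted from the independent combination viability; applied to
#'   combination wells only. May also be a matrix
#'   `length(conc_a_nM) x length(conc_b_nM)`.
#' @param vehicle_signal,plateau_signal Raw assay units at 100% and 0%
#'   viability; `vehicle_signal` must exceed `plateau_signal`.
#' @param noise_cv Coefficient of variation of the lognormal noise (>= 0;
#'   0 = noiseless). Noise is mean-one.
#' @param n_vehicle Number of vehicle wells.
#' @param n_replicates Technical replicates of every treated well.
#' @param seed Integer RNG seed.
#' @return A tibble of class `plate_reads`: `well`, `conc_a_nM`, `conc_b_nM`,
#'   `signal`, `role` (`"treated"` / `"vehicle"`), `replicate`.
#' @export
make_plate_reads <- function(drug_a, drug_b = NULL,
                             conc_a_nM = conc_preset("fig3b"),
                             conc_b_nM = conc_preset("fig3b"),
                             bliss_excess = 0,
                             vehicle_signal = 10000, plateau_signal = 500,
                             noise_cv = 0, n_vehicle = 8L, n_replicates = 1L,
                             seed = 1L) {
  stopifnot(inherits(drug_a, "drug_truth"))
  if (!is.null(drug_b)) stopifnot(inherits(drug_b, "drug_truth"))
  if (any(conc_a_nM <= 0) || any(conc_b_nM <= 0)) {
    stop_organoidr("concentration grids must be strictly positive (zero rows are added internally)",
                   "organoidr_bad_params")
  }
  if (vehicle_signal <= plateau_signal) {
    stop_organoidr("`vehicle_signal` must exceed `plateau_signal`", "organoidr_bad_params")
  }
  assert_scalar_number(noise_cv, "noise_cv", lower = 0)
  if (is.null(drug_b) && length(conc_b_nM)) {
    stop_organoidr("`conc_b_nM` must be empty when `drug_b` is NULL", "organoidr_bad_params")
  }
  conc_a_nM <- sort(unique(conc_a_nM))
  conc_b_nM <- sort(unique(conc_b_nM))
  grid <- expand.grid(conc_a_nM = c(0, conc_a_nM),
                      conc_b_nM = c(0, conc_b_nM))
  grid <- grid[!(grid$conc_a_nM == 0 & grid$conc_b_nM == 0), , drop = FALSE]

  va <- fourpl_frac(grid$conc_a_nM, drug_a$log10_ic50, drug_a$hill_slope)
  vb <- if (is.null(drug_b)) rep(1, nrow(grid)) else
    fourpl_frac(grid$conc_b_nM, drug_b$log10_ic50, drug_b$hill_slope)
  v <- va * vb
  combo <- grid$conc_a_nM > 0 & grid$conc_b_nM > 0
  if (is.matrix(bliss_excess)) {
    if (!all(dim(bliss_excess) == c(length(conc_a_nM), length(conc_b_nM)))) {
      stop_organoidr("`bliss_excess` matrix must be length(conc_a) x length(conc_b)",
                     "organoidr_bad_params")
    }
    ia <- match(grid$conc_a_nM, conc_a_nM)
    ib <- match(grid$conc_b_nM, conc_b_nM)
    exc <- ifelse(combo, bliss_excess[cbind(ia, ib)], 0)
  } else {
    assert_scalar_number(bliss_excess, "bliss_excess", lower = -1, upper = 1)
    exc <- ifelse(combo, bliss_excess, 0)
  }
  v <- v - exc

  treated <- tibble(
    conc_a_nM = rep(grid$conc_a_nM, times = n_replicates),
    conc_b_nM = rep(grid$conc_b_nM, times = n_replicates),
    viability = rep(v, times = n_replicates),
    role = "treated",
    replicate = rep(seq_len(n_replicates), each = nrow(grid)))
  vehicle <- tibble(conc_a_nM = 0, conc_b_nM = 0, viability = 1,
                    role = "vehicle", replicate = seq_len(n_vehicle))
  wells <- bind_rows(treated, vehicle)
  mean_signal <- plateau_signal + wells$viability * (vehicle_signal - plateau_signal)

  noise <- if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    withr::with_seed(seed, rlnorm(nrow(wells), meanlog = -sdlog^2 / 2, sdlog = sdlog))
  } else rep(1, nrow(wells))

  out <- wells |>
    mutate(signal = mean_signal * noise,
           well = sprintf("W%03d", row_number())) |>
    select("well", "conc_a_nM", "conc_b_nM", "signal", "role", "replicate")
  class(out) <- c("plate_reads", class(out))
  attr(out, "truth") <- list(drug_a = drug_a, drug_b = drug_b,
                             bliss_excess = bliss_excess,
                             vehicle_signal = vehicle_signal,
                             plateau_signal = plateau_signal,
                             noise_cv = noise_cv, seed = seed)
  out
}
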