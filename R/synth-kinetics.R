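#' Simulate an alamarBlue (resazurin) fluorescence kinetic read
#'
#' The reduction of resazurin by viable cells raises fluorescence linearly in
#' time until the reagent saturates; the read is
#' `RFU(t) = background + true_viability * slope * min(t, saturation_t) + noise`,
#' so the read at t = 0 is pure background.
#'
#' @param true_viability Fraction of viable signal relative to an untreated
#'   well (0..1 scale, values above 1 allowed).
#' @param background_rfu Background fluorescence at t = 0 (units RFU).
#' @param slope_rfu_per_h Linear-phase slope of a fully viable well (RFU/h);
#'   must be non-negative.
#' @param saturation_t_h Time (hours) at which the assay saturates.
#' @param read_times_h Non-decreasing read times starting at 0 (hours).
#' @param noise_sd Additive Gaussian read noise (RFU).
#' @param seed Integer RNG seed.
#' @param role `"treated"` or `"vehicle"` tag carried on the series.
#' @return A tibble of class `kinetics_series`: `time_h`, `rfu`.
#' @export
make_ab_kinetics <- function(true_viability, background_rfu = 100,
                             slope_rfu_per_h = 200, saturation_t_h = 1.5,
                             read_times_h = seq(0, 2, by = 0.25),
                             noise_sd = 0, seed = 1L, role = "treated") {
  assert_scalar_number(true_viability, "true_viability", lower = 0)
  assert_scalar_number(background_rfu, "background_rfu", lower = 0)
  assert_scalar_number(slope_rfu_per_h, "slope_rfu_per_h", lower = 0)
  assert_scalar_number(saturation_t_h, "saturation_t_h", lower = 1e-9)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (length(read_times_h) < 1L || read_times_h[1] != 0 ||
      any(diff(read_times_h) < 0)) {
    stop_organoidr("`read_times_h` must be non-decreasing and start at 0",
                   "organoidr_bad_params")
  }
  noise <- if (noise_sd > 0) {
    withr::with_seed(seed, rnorm(length(read_times_h), 0, noise_sd))
  } else rep(0, length(read_times_h))
  out <- tibble(
    time_h = as.numeric(read_times_h),
    rfu = background_rfu + true_viability * slope_rfu_per_h *
      pmin(read_times_h, saturation_t_h) + noise)
  class(out) <- c("kinetics_series", class(out))
  attr(out, "role") <- role
  attr(out, "truth") <- list(true_viability = true_viability,
                             background_rfu = background_rfu,
                             slope_rfu_per_h = slope_rfu_per_h,
                             saturation_t_h = saturation_t_h,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate an EdU x DNA flow-cytometry sample with known phase fractions
#'
#' G1 cells sit at the 2N DNA peak with background EdU; S cells span 2N..4N
#' DNA with high EdU (incorporated during the pulse); G2 cells sit at 4N with
#' background EdU. Signals carry multiplicative lognormal noise of
#' coefficient of variation `cv`.
#'
#' @param n Number of cells.
#' @param fractions Length-3 numeric `(G1, S, G2)` summing to 1.
#' @param dna_2n DNA signal at the 2N peak (arbitrary units).
#' @param edu_neg,edu_pos EdU signal of negative / positive cells.
#' @param cv Coefficient of variation of the signal noise.
#' @param seed Integer RNG seed.
#' @return A tibble of class `cellcycle_sample`: `cell`, `dna`, `edu`,
#'   `true_phase`.
#' @export
make_cellcycle_sample <- function(n = 5000L, fractions = c(0.6, 0.25, 0.15),
                                  dna_2n = 100, edu_neg = 50, edu_pos = 1000,
                                  cv = 0.05, seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop_organoidr("`fractions` must be three non-negative numbers summing to 1",
                   "organoidr_bad_params")
  }
  assert_scalar_number(cv, "cv", lower = 0)
  counts <- c(floor(n * fractions[1]), floor(n * fractions[2]))
  counts <- c(counts, n - sum(counts))
  sdlog <- sqrt(log(1 + cv^2))
  withr::with_seed(seed, {
    phase <- rep(c("G1", "S", "G2"), counts)
    dna_mu <- c(rep(dna_2n, counts[1]),
                runif(counts[2], dna_2n * 1.05, dna_2n * 1.95),
                rep(dna_2n * 2, counts[3]))
    edu_mu <- c(rep(edu_neg, counts[1]),
                rep(edu_pos, counts[2]),
                rep(edu_neg, counts[3]))
    dna <- dna_mu * rlnorm(n, -sdlog^2 / 2, sdlog)
    edu <- edu_mu * rlnorm(n, -sdlog^2 / 2, sdlog)
  })
  out <- tibble(cell = seq_len(n), dna = dna, edu = edu, true_phase = phase)
  class(out) <- c("cellcycle_sample", class(out))
  attr(out, "fractions_true") <- setNames(counts / n, c("G1", "S", "G2"))
  out
}
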