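noiseless_matrix <- function(la = -7.5, ha = 1, lb = -7, hb = 1.2,
                             grid = conc_preset("fig3b")) {
  reads <- make_plate_reads(drug_truth(la, ha), drug_truth(lb, hb),
                            conc_a_nM = grid, conc_b_nM = grid,
                            noise_cv = 0, seed = 1)
  normalize_viability(reads, baseline = 500)
}

test_that("normalization maps vehicle to 100, plateau to 0 and midpoints linearly", {
  reads <- tibble::tibble(
    well = sprintf("W%d", 1:7),
    conc_a_nM = c(10, 100, 1000, 1000, 1000, 0, 0),
    conc_b_nM = 0,
    signal = c(10000, 5250, 500, 500, 500, 10000, 10000),
    role = c(rep("treated", 5), "vehicle", "vehicle"))
  dm <- normalize_viability(reads)  # plateau from the 3 highest-conc wells
  v <- function(a) dm$viability_pct[dm$conc_a_nM == a & dm$conc_b_nM == 0]
  expect_equal(v(0), 100)
  expect_equal(v(10), 100, tolerance = 1e-9)
  expect_equal(v(100), 50, tolerance = 0.5)
  expect_equal(v(1000), 0, tolerance = 1e-9)
})

test_that("replicate wells average after normalization and failures are explicit", {
  reads <- tibble::tibble(
    conc_a_nM = c(10, 10, 0), conc_b_nM = 0,
    signal = c(8000, 6000, 10000),
    role = c("treated", "treated", "vehicle"))
  dm <- normalize_viability(reads, baseline = 0)
  expect_equal(dm$viability_pct[dm$conc_a_nM == 10], 70)
  expect_error(normalize_viability(dplyr::mutate(reads, role = "treated")),
               class = "organoidr_bad_reads")
  expect_error(normalize_viability(reads, baseline = 20000),
               class = "organoidr_assay_failure")
})

test_that("noiseless round-trip recovers the generating 4PL surface and parameters", {
  dm <- noiseless_matrix()
  g <- as_grid(dm)
  a <- sort(unique(dm$conc_a_nM)); b <- sort(unique(dm$conc_b_nM))
  expect_lt(max(abs(g - 100 * outer(fourpl_frac(a, -7.5, 1),
                                    fourpl_frac(b, -7, 1.2)))), 1e-9)
  mono <- extract_curve(dm, "row_a_mono")
  fit <- fit_dose_response(mono$conc_nM, mono$viability_pct)
  expect_true(fit$converged)
  expect_equal(fit$log10_ic50, -7.5, tolerance = 1e-6)
  expect_equal(fit$hill_slope, 1, tolerance = 1e-6)
  monob <- extract_curve(dm, "col_b_mono")
  fitb <- fit_dose_response(monob$conc_nM, monob$viability_pct)
  expect_equal(fitb$log10_ic50, -7, tolerance = 1e-6)
  expect_equal(fitb$hill_slope, 1.2, tolerance = 1e-6)
})

test_that("fitted curve passes through 50% at the fitted IC50", {
  dm <- noiseless_matrix()
  mono <- extract_curve(dm, "row_a_mono")
  fit <- fit_dose_response(mono$conc_nM, mono$viability_pct)
  expect_equal(predict(fit, 10^(fit$log10_ic50 + 9)), 50, tolerance = 1e-9)
})

test_that("noisy fits agree with the exhaustive grid-search oracle", {
  grid <- conc_preset("fig3b")
  reads <- make_plate_reads(drug_truth(-7, 1.3), NULL, conc_a_nM = grid,
                            conc_b_nM = numeric(), noise_cv = 0.05, seed = 1)
  dm <- normalize_viability(reads, baseline = 500)
  mono <- extract_curve(dm, "row_a_mono")
  fit <- fit_dose_response(mono$conc_nM, mono$viability_pct)
  orc <- oracle_4pl_gridsearch(mono$conc_nM, mono$viability_pct)
  expect_equal(fit$log10_ic50, orc$log10_ic50, tolerance = 0.02)
  expect_lte(fit$rss, orc$sse + 1e-6)
  expect_equal(fit$log10_ic50, -7, tolerance = 0.1)
})

test_that("degenerate fits fail with diagnostics", {
  expect_error(fit_dose_response(c(1, 10, 100, 1000), rep(80, 4)),
               class = "organoidr_flat_response")
  expect_error(fit_dose_response(c(1, 10, 100), c(90, 50, 10)),
               "4 distinct")
})

test_that("delta IC50 is a log-scale difference with antisymmetry", {
  dm <- noiseless_matrix()
  mono <- extract_curve(dm, "row_a_mono")
  f1 <- fit_dose_response(mono$conc_nM, mono$viability_pct)
  expect_equal(delta_ic50(f1, f1), 0)
  # 1 uM vs 10 nM is +2 decades
  v2 <- 100 * fourpl_frac(mono$conc_nM, -6, 1)
  v3 <- 100 * fourpl_frac(mono$conc_nM, -8, 1)
  f2 <- fit_dose_response(mono$conc_nM, v2)
  f3 <- fit_dose_response(mono$conc_nM, v3)
  expect_equal(delta_ic50(f2, f3), 2, tolerance = 1e-6)
  expect_equal(delta_ic50(f3, f2), -delta_ic50(f2, f3))
  bad <- f2; bad$converged <- FALSE
  expect_error(delta_ic50(bad, f3), class = "organoidr_unconverged_fit")
})

test_that("Bliss scores are zero under independence and recover injected excess", {
  dm <- noiseless_matrix()
  bl <- bliss_excess(dm)
  expect_lt(max(abs(bl$bliss_score)), 1e-9)
  # direct-formula oracle on a random 4x4-plus-monotherapy matrix
  set.seed(5)
  a <- c(0, 10, 100, 1000, 10000); b <- c(0, 20, 200, 2000, 20000)
  vals <- matrix(runif(25, 0, 100), 5, 5); vals[1, 1] <- 100
  m <- tidyr::expand_grid(conc_a_nM = a, conc_b_nM = b)
  m$viability_pct <- vals[cbind(match(m$conc_a_nM, a), match(m$conc_b_nM, b))]
  class(m) <- c("dose_matrix", class(m))
  bl2 <- bliss_excess(m)
  for (i in 2:5) for (j in 2:5) {
    fA <- min(1, max(0, 1 - vals[i, 1] / 100))
    fB <- min(1, max(0, 1 - vals[1, j] / 100))
    obs <- min(1, max(0, 1 - vals[i, j] / 100))
    direct <- obs - (fA + fB - fA * fB)
    got <- bl2$bliss_score[bl2$conc_a_nM == a[i] & bl2$conc_b_nM == b[j]]
    expect_equal(got, direct, tolerance = 1e-12)
  }
  expect_true(all(bl2$bliss_score[bl2$conc_a_nM == 0 | bl2$conc_b_nM == 0] == 0))
  # injected synergy comes back at cells where the excess is observable
  for (delta in c(0.1, 0.3)) {
    reads <- make_plate_reads(drug_truth(-7.5, 1), drug_truth(-7, 1),
                              bliss_excess = delta, noise_cv = 0, seed = 2)
    bld <- bliss_excess(normalize_viability(reads, baseline = 500))
    truth_v <- outer(fourpl_frac(sort(unique(bld$conc_a_nM)), -7.5, 1),
                     fourpl_frac(sort(unique(bld$conc_b_nM)), -7, 1))
    gb <- as_grid(bld)
    observable <- truth_v >= delta & row(truth_v) > 1 & col(truth_v) > 1
    expect_lt(max(abs(gb[observable] - delta)), 1e-9)
  }
  # missing monotherapy axes
  m2 <- dplyr::filter(dm, conc_a_nM > 0)
  class(m2) <- class(dm)
  expect_error(bliss_excess(m2), class = "organoidr_missing_monotherapy")
})

test_that("moving-average smoothing is identity at w=1, exact on 3x3, and bounded", {
  dm <- noiseless_matrix(grid = conc_preset("fig9d"))
  expect_equal(as_grid(smooth_matrix(dm, 1)), as_grid(dm))
  sm <- smooth_matrix(dm, 3)
  g <- as_grid(dm); gs <- as_grid(sm)
  expect_equal(gs[2, 2], mean(g[1:3, 1:3]))
  expect_gte(min(gs), min(g)); expect_lte(max(gs), max(g))
  # constants are fixed points
  cm <- dplyr::mutate(dm, viability_pct = 42)
  class(cm) <- class(dm)
  expect_true(all(as_grid(smooth_matrix(cm, 3)) == 42))
  expect_error(smooth_matrix(dm, 2), "odd")
  # smoothing a Bliss matrix keeps its class and value column
  bls <- smooth_matrix(bliss_excess(dm), 3)
  expect_s3_class(bls, "bliss_matrix")
})

test_that("curve extraction returns monotherapies and offset diagonals on the grid", {
  dm <- noiseless_matrix()
  expect_equal(nrow(extract_curve(dm, "row_a_mono")), 14)
  expect_equal(nrow(extract_curve(dm, "col_b_mono")), 14)
  diag0 <- extract_curve(dm, "fixed_ratio_diagonal", 0)
  expect_equal(nrow(diag0), 14)
  expect_equal(diag0$conc_nM, sort(unique(dm$conc_a_nM[dm$conc_a_nM > 0])))
  # the fig3b grid spans 3 decades in 13 steps: a -2 decade offset is not on
  # the grid, but an offset of exactly 2 grid steps down is representable
  step <- diff(log10(conc_preset("fig3b")))[1]
  diag_off <- extract_curve(dm, "fixed_ratio_diagonal", -2 * step)
  expect_equal(nrow(diag_off), 12)
  expect_error(extract_curve(dm, "fixed_ratio_diagonal", -0.123),
               class = "organoidr_bad_offset")
  # monotherapy row equals the generating single-drug 4PL
  mono <- extract_curve(dm, "row_a_mono")
  expect_equal(mono$viability_pct, 100 * fourpl_frac(mono$conc_nM, -7.5, 1),
               tolerance = 1e-9)
})

test_that("tidy and glance expose fit parameters in broom shape", {
  dm <- noiseless_matrix()
  mono <- extract_curve(dm, "row_a_mono")
  fit <- fit_dose_response(mono$conc_nM, mono$viability_pct)
  td <- tidy(fit)
  expect_equal(td$term, c("log10_ic50", "hill_slope"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$ic50_nM, 10^(gl$log10_ic50 + 9))
})
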