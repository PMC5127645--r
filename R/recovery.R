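#' alamarBlue kinetic viability, normalized to vehicle
#'
#' Viability is the maximum fluorescence within the linear range of the
#' assay, corrected for the background read at t = 0, normalized to the
#' vehicle well. The linear range is the longest contiguous read window
#' (>= `min_len` reads) whose least-squares line reaches a coefficient of
#' determination of at least `r2_min`; ties go to the earliest window, and a
#' zero-variance (flat) window counts as perfectly linear.
#'
#' @param series,vehicle_series `kinetics_series` tibbles (`time_h`, `rfu`),
#'   at least 4 reads each.
#' @param r2_min Linear-range R-squared rule, default 0.99.
#' @param min_len Minimum window length in reads, default 3.
#' @return A one-row tibble: `viability_pct`, `treated_rfu` and
#'   `vehicle_rfu` (background-corrected RFUmax), linear-range bounds of the
#'   treated series `t_lin_lo_h`, `t_lin_hi_h`.
#' @export
ab_viability <- function(series, vehicle_series, r2_min = 0.99, min_len = 3L) {
  for (s in list(series, vehicle_series)) {
    if (!all(c("time_h", "rfu") %in% names(s)) || nrow(s) < 4L) {
      stop_organoidr("each kinetics series needs >= 4 reads with time_h and rfu",
                     "organoidr_bad_argument")
    }
  }
  lin_t <- linear_range(series, r2_min, min_len)
  lin_v <- linear_range(vehicle_series, r2_min, min_len)
  treated_max <- series$rfu[lin_t[2]] - series$rfu[1]
  vehicle_max <- vehicle_series$rfu[lin_v[2]] - vehicle_series$rfu[1]
  if (vehicle_max <= 0) {
    stop_organoidr("vehicle series shows no signal increase; normalization undefined",
                   "organoidr_assay_failure")
  }
  tibble(viability_pct = 100 * treated_max / vehicle_max,
         treated_rfu = treated_max, vehicle_rfu = vehicle_max,
         t_lin_lo_h = series$time_h[lin_t[1]],
         t_lin_hi_h = series$time_h[lin_t[2]])
}

# longest contiguous window with R^2 >= r2_min; returns c(start, end) indices
linear_range <- function(series, r2_min, min_len) {
  n <- nrow(series)
  t <- series$time_h
  y <- series$rfu
  best <- NULL
  for (len in n:min_len) {
    for (start in 1:(n - len + 1)) {
      ii <- start:(start + len - 1)
      sst <- sum((y[ii] - mean(y[ii]))^2)
      r2 <- if (sst == 0) 1 else {
        fit <- lm(y[ii] ~ t[ii])
        1 - sum(stats::resid(fit)^2) / sst
      }
      if (r2 >= r2_min) { best <- c(start, start + len - 1L); break }
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) {
    stop_organoidr(sprintf("no window of >= %d reads reaches R^2 >= %g", min_len, r2_min),
                   "organoidr_no_linear_range")
  }
  best
}

#' Caliper tumor-volume series with percent change from baseline
#'
#' Volume from the two caliper axes by the ellipsoid approximation
#' `V = D * d^2 / 2` with `D` the major and `d` the minor axis (the pair is
#' canonicalized by swapping, so entry order does not matter). Percent
#' change at day *t* is `100 * (V(t) - V(0)) / V(0)` against each animal's
#' day-0 baseline.
#'
#' @param measurements Data frame: `animal`, `day`, `d1_mm`, `d2_mm`, and
#'   optionally `group`. Every animal must have a day-0 measurement.
#' @return A tibble of class `tumor_series`: input columns plus `d_major_mm`,
#'   `d_minor_mm`, `volume_mm3`, `baseline_mm3`, `pct_change`.
#' @export
tumor_series <- function(measurements) {
  m <- as_tibble(measurements)
  need <- c("animal", "day", "d1_mm", "d2_mm")
  if (!all(need %in% names(m))) {
    stop_organoidr(sprintf("caliper table needs columns: %s", paste(need, collapse = ", ")),
                   "organoidr_bad_argument")
  }
  if (!"group" %in% names(m)) m$group <- "all"
  m <- m |>
    mutate(d_major_mm = pmax(.data$d1_mm, .data$d2_mm),
           d_minor_mm = pmin(.data$d1_mm, .data$d2_mm),
           volume_mm3 = .data$d_major_mm * .data$d_minor_mm^2 / 2)
  if (any(m$volume_mm3 <= 0)) {
    stop_organoidr("caliper measurements must give positive volumes",
                   "organoidr_bad_argument")
  }
  base <- m |> filter(.data$day == 0) |>
    select("animal", baseline_mm3 = "volume_mm3")
  missing <- setdiff(unique(m$animal), base$animal)
  if (length(missing)) {
    stop_organoidr(sprintf("animal(s) without day-0 baseline: %s",
                           paste(missing, collapse = ", ")),
                   "organoidr_missing_baseline")
  }
  out <- m |>
    left_join(base, by = "animal") |>
    mutate(pct_change = 100 * (.data$volume_mm3 - .data$baseline_mm3) /
             .data$baseline_mm3) |>
    arrange(.data$group, .data$animal, .data$day)
  class(out) <- c("tumor_series", class(out))
  out
}

#' Per-group mean and sd of tumor percent change by day
#'
#' @param ts A `tumor_series`.
#' @return Tibble: `group`, `day`, `n`, `mean_pct_change`, `sd_pct_change`.
#' @export
tumor_group_summary <- function(ts) {
  stopifnot(inherits(ts, "tumor_series"))
  ts |>
    group_by(.data$group, .data$day) |>
    summarise(n = dplyr::n(), mean_pct_change = mean(.data$pct_change),
              sd_pct_change = sd(.data$pct_change), .groups = "drop")
}

#' Compare tumor growth between groups
#'
#' Reports both a per-day two-sample Student's t test of percent change
#' against the reference group and an overall two-way (group x day) ANOVA,
#' labelling which test produced each p value.
#'
#' @param ts A `tumor_series` with >= 2 groups.
#' @param reference Reference (e.g. vehicle) group name.
#' @return Tibble: `group`, `day` (`NA` for the ANOVA row), `test`,
#'   `p_value`.
#' @export
tumor_group_tests <- function(ts, reference) {
  stopifnot(inherits(ts, "tumor_series"))
  groups <- setdiff(unique(ts$group), reference)
  if (!reference %in% ts$group || !length(groups)) {
    stop_organoidr("need a reference group and at least one other group",
                   "organoidr_bad_argument")
  }
  rows <- list()
  for (g in groups) {
    days <- sort(intersect(ts$day[ts$group == g], ts$day[ts$group == reference]))
    for (d in setdiff(days, 0)) {
      a <- ts$pct_change[ts$group == g & ts$day == d]
      b <- ts$pct_change[ts$group == reference & ts$day == d]
      if (length(a) >= 2 && length(b) >= 2) {
        rows[[length(rows) + 1L]] <- tibble(
          group = g, day = d, test = "t_test",
          p_value = t.test(a, b)$p.value)
      }
    }
    sub <- ts |> filter(.data$group %in% c(g, reference), .data$day != 0)
    if (length(unique(sub$day)) > 1) {
      an <- summary(aov(pct_change ~ group * factor(day), data = sub))[[1]]
      rows[[length(rows) + 1L]] <- tibble(
        group = g, day = NA_real_, test = "two_way_anova_group",
        p_value = an[trimws(rownames(an)) == "group", "Pr(>F)"])
    }
  }
  bind_rows(rows)
}

#' Estimate EdU / DNA gates from a reference sample
#'
#' The 2N position is the dominant DNA density mode; 4N is twice that. The
#' G1 gate closes at 1.25x the 2N peak and the G2 gate opens at 1.75x
#' (cells between are intermediate-DNA and stay unassigned). The EdU
#' threshold is the midpoint of a 2-means split of log EdU signal.
#'
#' @param sample A data frame with `dna` and `edu` columns.
#' @return List: `edu_threshold`, `dna_g1_upper`, `dna_g2_lower`,
#'   `dna_2n_peak`.
#' @export
estimate_cellcycle_gates <- function(sample) {
  if (!all(c("dna", "edu") %in% names(sample)) || !nrow(sample)) {
    stop_organoidr("sample needs non-empty `dna` and `edu` columns",
                   "organoidr_bad_argument")
  }
  den <- density(sample$dna)
  peak2n <- den$x[which.max(den$y)]
  km <- kmeans(log10(pmax(sample$edu, 1e-9)), centers = 2, nstart = 5)
  edu_thr <- 10^mean(km$centers)
  list(edu_threshold = edu_thr,
       dna_g1_upper = 1.25 * peak2n,
       dna_g2_lower = 1.75 * peak2n,
       dna_2n_peak = peak2n)
}

#' Classify cells into G1 / S / G2 from EdU x DNA signals
#'
#' EdU incorporation takes precedence: any cell at or above the EdU
#' threshold is S phase regardless of DNA content; remaining cells are G1 at
#' or below the 2N gate, G2 at or above the 4N gate, and unassigned in
#' between. Phase fractions plus the unassigned fraction sum to 1 exactly.
#'
#' @param sample Data frame with `dna` and `edu` columns.
#' @param gates Gate list as from [estimate_cellcycle_gates()]; default
#'   estimates the gates from `sample` itself.
#' @return An object of class `cellcycle_fit`: `cells` (per-cell tibble with
#'   a `phase` column), `fractions` (named G1/S/G2/unassigned), `counts`,
#'   `gates`.
#' @export
cellcycle_classify <- function(sample, gates = NULL) {
  if (!all(c("dna", "edu") %in% names(sample)) || !nrow(sample)) {
    stop_organoidr("sample needs non-empty `dna` and `edu` columns",
                   "organoidr_bad_argument")
  }
  gates <- gates %||% estimate_cellcycle_gates(sample)
  if (gates$dna_g1_upper >= gates$dna_g2_lower) {
    stop_organoidr("gates must satisfy 2N upper < 4N lower", "organoidr_bad_argument")
  }
  phase <- dplyr::case_when(
    sample$edu >= gates$edu_threshold ~ "S",
    sample$dna <= gates$dna_g1_upper ~ "G1",
    sample$dna >= gates$dna_g2_lower ~ "G2",
    TRUE ~ "unassigned")
  if (all(phase == "unassigned")) {
    stop_organoidr("all cells unassigned; gates do not match the sample",
                   "organoidr_bad_gates")
  }
  counts <- setNames(
    vapply(c("G1", "S", "G2", "unassigned"), function(p) sum(phase == p), 1L),
    c("G1", "S", "G2", "unassigned"))
  structure(
    list(cells = mutate(as_tibble(sample), phase = phase),
         fractions = counts / length(phase), counts = counts, gates = gates),
    class = "cellcycle_fit")
}

#' @export
print.cellcycle_fit <- function(x, ...) {
  f <- x$fractions * 100
  cat(sprintf("<cellcycle_fit> G1 %.1f%% | S %.1f%% | G2 %.1f%% (unassigned %.1f%%), n = %d\n",
              f["G1"], f["S"], f["G2"], f["unassigned"], sum(x$counts)))
  invisible(x)
}

#' Chi-square comparison of two phase distributions
#'
#' Pearson chi-square (no continuity correction) on the 2 x 3 contingency
#' table of assigned G1/S/G2 counts of a sample versus a reference.
#'
#' @param fit,reference `cellcycle_fit` objects.
#' @return Tibble: `statistic`, `df`, `p_value`.
#' @export
cellcycle_compare <- function(fit, reference) {
  stopifnot(inherits(fit, "cellcycle_fit"), inherits(reference, "cellcycle_fit"))
  tab <- rbind(fit$counts[c("G1", "S", "G2")],
               reference$counts[c("G1", "S", "G2")])
  ct <- chisq.test(tab, correct = FALSE)
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value)
}
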