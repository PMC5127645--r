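#' Validated run configuration for the demonstration pipelines
#'
#' Collects every tunable of a pipeline run into one object; unknown keys
#' are rejected and every applied value (including defaults) is echoed into
#' the run manifest, so a run is reproducible from its manifest alone.
#'
#' @param pipeline `"drugrelease"` or `"plate"`.
#' @param seed Integer seed driving all simulated inputs.
#' @param out_dir Output directory (`NULL` = return results only).
#' @param ... Pipeline-specific overrides. For `"drugrelease"`:
#'   `n_organoids`, `timepoints` (days), `scenario` (`"arrest"` or
#'   `"death"`), `n_alive0`, `snr`, `stack_shape`, `cutoff` (`"auto"` or
#'   pixels). For `"plate"`: `preset` (see [conc_preset()]), `lines` (named
#'   list, each `list(drug_a = drug_truth, drug_b = drug_truth)`),
#'   `bliss_excess`, `noise_cv`, `n_replicates`, `baseline`,
#'   `smooth_window`, `diagonal_offset`.
#' @return A list of class `run_config` with all defaults resolved.
#' @export
run_config <- function(pipeline = c("drugrelease", "plate"), seed = 1L,
                       out_dir = NULL, ...) {
  pipeline <- match.arg(pipeline)
  defaults <- if (pipeline == "drugrelease") {
    list(n_organoids = 3L, timepoints = c(-3, 0, 3, 7), scenario = "arrest",
         n_alive0 = 16L, snr = 5, stack_shape = c(72L, 72L, 10L),
         cutoff = "auto")
  } else {
    list(preset = "fig3b",
         lines = list(
           parental = list(drug_a = drug_truth(-7.5, 1), drug_b = drug_truth(-7, 1)),
           kras = list(drug_a = drug_truth(-5.5, 1), drug_b = drug_truth(-7, 1))),
         bliss_excess = 0, noise_cv = 0, n_replicates = 1L,
         baseline = "plateau_wells", smooth_window = 3L, diagonal_offset = 0)
  }
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop_organoidr(sprintf("unknown config key(s) for pipeline '%s': %s",
                           pipeline, paste(unknown, collapse = ", ")),
                   "organoidr_bad_config")
  }
  cfg <- utils::modifyList(defaults, overrides)
  cfg$pipeline <- pipeline
  cfg$seed <- as.integer(seed)
  cfg$out_dir <- out_dir
  structure(cfg, class = "run_config")
}

# run a stage, relabelling any failure with the stage name
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("[stage %s] %s", stage, conditionMessage(e)),
                 class = c("organoidr_stage_error", "organoidr_error"))
  })
}

manifest_of <- function(config, extra = list()) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # path of the manifest itself; keeps reruns byte-identical
  cfg$lines <- if (!is.null(cfg$lines)) {
    purrr::map(cfg$lines, ~ purrr::map(.x, unclass))
  }
  c(list(package = "organoidr",
         version = as.character(utils::packageVersion("organoidr"))),
    cfg[!vapply(cfg, is.null, TRUE)], extra)
}

write_outputs <- function(out_dir, tables, manifest) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  purrr::iwalk(tables, function(tbl, nm) {
    readr::write_csv(tbl, file.path(out_dir, paste0(nm, ".csv")))
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

# the paired design re-images the same organoid across days: the field is
# placed once per organoid; in the death scenario half of its nuclei are
# replaced by fragment clusters at their own positions from the second
# timepoint onward, in arrest nothing changes but the acquisition noise
organoid_states <- function(config, o) {
  params <- organoid_sim_params(
    stack_shape = config$stack_shape, n_alive = config$n_alive0, n_dead = 0L,
    snr = config$snr, pi_channel = FALSE, seed = derive_seed(config$seed, o))
  dims <- params$stack_shape[c(2, 1, 3)]
  zr <- z_ratio(params)
  objects0 <- withr::with_seed(params$seed, populate_field(params))
  if (config$scenario == "arrest") {
    return(list(params = params, states = list(objects0, objects0)))
  }
  if (config$scenario != "death") {
    stop_organoidr(sprintf("unknown scenario '%s'", config$scenario),
                   "organoidr_bad_config")
  }
  kill <- objects0$id[seq_len(config$n_alive0 %/% 2L)]
  objects1 <- withr::with_seed(derive_seed(config$seed, o * 13L + 7L), {
    obj <- objects0
    next_id <- max(obj$id) + 1L
    for (pid in kill) {
      row <- which(obj$id == pid)
      site <- c(obj$cy[row], obj$cx[row], obj$cz[row])
      obj <- obj[-row, ]
      obj <- shatter_at(obj, site, params, dims, zr,
                        next_ids = next_id + seq_len(params$fragments_per_dead) - 1L,
                        parent = pid)
      next_id <- next_id + params$fragments_per_dead
    }
    obj
  })
  list(params = params, states = list(objects0, objects1))
}

#' End-to-end drug & release imaging pipeline on synthetic stacks
#'
#' Simulates the paired multi-day organoid imaging design (same organoids
#' re-imaged across timepoints), then runs the full quantification chain per
#' stack: auto-threshold the H2B channel, detect 3D particles, classify them
#' alive/dead by size (cutoff estimated from the pre-treatment timepoint
#' unless overridden), and integrate alive/dead pixel areas over the lower
#' half of each organoid's z-extent. Per-organoid series are normalized to
#' the alive area prior to treatment.
#'
#' @param config A [run_config()] with `pipeline = "drugrelease"`.
#' @return A list: `viability` (tibble: organoid, timepoint day, alive_px,
#'   dead_px, z-range, alive_norm, dead_norm), `cutoff_px`, `manifest`.
#'   Tables and manifest are also written to `config$out_dir` if set.
#' @export
run_drugrelease_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"), config$pipeline == "drugrelease")
  n_tp <- length(config$timepoints)
  if (n_tp < 2L) {
    stop_organoidr("need stacks for >= 2 timepoints", "organoidr_bad_config")
  }
  quants <- list()
  cutoff <- if (identical(config$cutoff, "auto")) NULL else config$cutoff
  mask_dim <- config$stack_shape[c(2, 1, 3)]
  for (o in seq_len(config$n_organoids)) {
    st <- with_stage("synth", organoid_states(config, o))
    for (k in seq_len(n_tp)) {
      objects <- st$states[[min(k, 2L)]]
      h2b <- with_stage("synth", withr::with_seed(
        derive_seed(config$seed, o * 101L + k),
        render_frame(objects, st$params)$h2b))
      particles <- with_stage("quantify", {
        mask <- binary_mask_from_array(h2b >= midpoint_threshold(h2b),
                                       threshold = midpoint_threshold(h2b))
        find_particles(mask, mode = "volume")
      })
      if (is.null(cutoff)) cutoff <- default_size_cutoff(particles)
      qrow <- with_stage("quantify", {
        cls <- classify_particles(particles, cutoff)
        ma <- array(FALSE, mask_dim); md <- array(FALSE, mask_dim)
        ma[unlist(cls$voxels[cls$class == "alive"])] <- TRUE
        md[unlist(cls$voxels[cls$class == "dead"])] <- TRUE
        mutate(
          quantify_lower_half(ma, md, organoid_id = sprintf("org%02d", o),
                              timepoint = config$timepoints[k]),
          n_alive_particles = sum(cls$class == "alive"),
          n_dead_particles = sum(cls$class == "dead"))
      })
      quants[[length(quants) + 1L]] <- qrow
    }
  }
  viability <- bind_rows(quants) |>
    group_by(.data$organoid_id) |>
    mutate(alive_norm = .data$alive_px / .data$alive_px[1],
           dead_norm = .data$dead_px / .data$alive_px[1]) |>
    ungroup()
  manifest <- manifest_of(config, list(cutoff_px_applied = cutoff))
  write_outputs(config$out_dir, list(viability = viability), manifest)
  list(viability = viability, cutoff_px = cutoff, manifest = manifest)
}

#' End-to-end plate pipeline: normalization, IC50 / delta IC50, Bliss
#'
#' For each simulated organoid line: generates raw plate reads from its
#' ground-truth dose-response surface, normalizes them to percent viability,
#' fits monotherapy and fixed-ratio diagonal curves, computes the
#' Bliss-excess matrix and a moving-average-smoothed heat-map matrix. The
#' delta IC50 table compares every line to the first (reference) line on the
#' log10 scale, per curve.
#'
#' @param config A [run_config()] with `pipeline = "plate"`.
#' @return A list: `matrices` (per line: `dose_matrix`, `bliss`,
#'   `smoothed`), `fits` (tibble of per-line per-curve fit parameters),
#'   `delta_ic50` (tibble vs the reference line), `manifest`.
#' @export
run_plate_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"), config$pipeline == "plate")
  grid <- conc_preset(config$preset)
  if (!length(config$lines)) {
    stop_organoidr("config$lines is empty", "organoidr_bad_config")
  }
  matrices <- list()
  fit_rows <- list()
  fits <- list()
  for (ln in names(config$lines)) {
    spec_ln <- config$lines[[ln]]
    reads <- with_stage("synth", make_plate_reads(
      drug_a = spec_ln$drug_a, drug_b = spec_ln$drug_b,
      conc_a_nM = grid, conc_b_nM = grid,
      bliss_excess = config$bliss_excess, noise_cv = config$noise_cv,
      n_replicates = config$n_replicates,
      seed = derive_seed(config$seed, match(ln, names(config$lines)))))
    if (!nrow(filter(reads, .data$role == "treated"))) {
      stop_organoidr("[stage normalize] no treated wells", "organoidr_stage_error")
    }
    dm <- with_stage("normalize", normalize_viability(reads, baseline = config$baseline))
    bl <- with_stage("bliss", bliss_excess(dm))
    sm <- with_stage("smooth", smooth_matrix(dm, config$smooth_window))
    matrices[[ln]] <- list(dose_matrix = dm, bliss = bl, smoothed = sm)
    for (curve in c("row_a_mono", "col_b_mono", "fixed_ratio_diagonal")) {
      cur <- with_stage("curve", extract_curve(
        dm, curve, ratio_offset_logdecades = config$diagonal_offset))
      fit <- with_stage("fit", fit_dose_response(cur$conc_nM, cur$viability_pct))
      fits[[paste(ln, curve, sep = ".")]] <- fit
      fit_rows[[length(fit_rows) + 1L]] <- mutate(
        glance(fit), line = ln, curve = curve, .before = 1)
    }
  }
  fits_tbl <- bind_rows(fit_rows)
  ref <- names(config$lines)[1]
  delta <- fits_tbl |>
    filter(.data$line != ref) |>
    dplyr::rowwise() |>
    mutate(delta_log10_ic50 = delta_ic50(
      fits[[paste(.data$line, .data$curve, sep = ".")]],
      fits[[paste(ref, .data$curve, sep = ".")]])) |>
    ungroup() |>
    select("line", "curve", "delta_log10_ic50") |>
    mutate(reference = ref)
  manifest <- manifest_of(config, list(grid_nM = grid))
  tables <- list(fits = fits_tbl, delta_ic50 = delta)
  for (ln in names(matrices)) {
    tables[[paste0("dose_matrix_", ln)]] <- matrices[[ln]]$dose_matrix
    tables[[paste0("bliss_", ln)]] <- matrices[[ln]]$bliss
    tables[[paste0("smoothed_", ln)]] <- matrices[[ln]]$smoothed
  }
  write_outputs(config$out_dir, tables, manifest)
  list(matrices = matrices, fits = fits_tbl, delta_ic50 = delta,
       fit_objects = fits, manifest = manifest)
}
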