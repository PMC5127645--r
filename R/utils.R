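# internal helpers shared across modules

# stop with a classed condition so pipelines can map failures to stages
stop_organoidr <- function(msg, class) {
  rlang::abort(msg, class = c(class, "organoidr_error"))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_organoidr(sprintf("`%s` must be a single finite number", name),
                   "organoidr_bad_argument")
  }
  if (x < lower || x > upper) {
    stop_organoidr(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x),
                   "organoidr_bad_argument")
  }
  invisible(x)
}

# seeds derived from a user seed for independent sub-streams; kept < 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 7919) %% 2147483629)
}

#' Fractional viability under the normalized four-parameter logistic
#'
#' `v = 1 / (1 + 10^((x - log10_ic50) * hill_slope))` with
#' `x = log10(concentration in molar)`; asymptotes 1 (no drug) and 0
#' (saturating drug), positive Hill slope = descending response. This is the
#' ground-truth surface the plate simulator samples from and the model
#' [fit_dose_response()] fits (on the percent scale).
#'
#' @param conc_nM Concentrations in nM; zero returns 1.
#' @param log10_ic50 log10 IC50 in molar.
#' @param hill_slope Positive Hill slope.
#' @return Fractional viabilities in `[0, 1]`.
#' @export
fourpl_frac <- function(conc_nM, log10_ic50, hill_slope) {
  v <- numeric(length(conc_nM))
  pos <- conc_nM > 0
  x <- log10(conc_nM[pos]) - 9
  v[pos] <- 1 / (1 + 10^((x - log10_ic50) * hill_slope))
  v[!pos] <- 1
  v
}
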