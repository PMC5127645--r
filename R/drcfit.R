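#' Fit a log(inhibitor) vs normalized-response curve (variable slope)
#'
#' Least-squares fit of the normalized four-parameter logistic with
#' asymptotes fixed at 100% and 0%:
#' \deqn{y = 100 / (1 + 10^{(x - \log_{10} IC_{50}) \cdot h})}
#' where `x` is log10 concentration (molar) and the Hill slope `h > 0` gives
#' a descending response. Fitting uses Levenberg-Marquardt least squares
#' with multi-start initialization (log IC50 started across the observed
#' concentration range, several slope starts); the best converged start by
#' residual sum of squares wins.
#'
#' @param conc_nM Concentrations in nM; zero-concentration points are
#'   dropped (at least 4 distinct positive concentrations required).
#' @param response_pct Normalized responses in percent.
#' @return An object of class `drc_fit`: `log10_ic50` (log10 molar),
#'   `hill_slope`, `rss`, `n_points`, `converged`, and the fitted data.
#'   Broom-style [tidy()] and [glance()] methods are provided.
#' @export
fit_dose_response <- function(conc_nM, response_pct) {
  keep <- conc_nM > 0 & is.finite(response_pct)
  conc_nM <- conc_nM[keep]
  response_pct <- response_pct[keep]
  if (length(unique(conc_nM)) < 4L) {
    stop_organoidr("need at least 4 distinct positive concentrations",
                   "organoidr_bad_argument")
  }
  if (diff(range(response_pct)) == 0) {
    stop_organoidr("all responses identical; dose-response fit is undefined",
                   "organoidr_flat_response")
  }
  x <- log10(conc_nM) - 9
  y <- response_pct
  starts <- tidyr::expand_grid(
    l = quantile(x, c(0.2, 0.5, 0.8), names = FALSE),
    h = c(0.5, 1, 2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ 100 / (1 + 10^((x - l) * h)),
        start = list(l = starts$l[i], h = starts$h[i]),
        lower = c(l = min(x) - 6, h = 1e-3),
        upper = c(l = max(x) + 6, h = 50),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(
      list(log10_ic50 = NA_real_, hill_slope = NA_real_, rss = NA_real_,
           n_points = length(x), converged = FALSE,
           data = tibble(conc_nM = conc_nM, response_pct = y)),
      class = "drc_fit"))
  }
  cf <- coef(best$fit)
  structure(
    list(log10_ic50 = unname(cf["l"]), hill_slope = unname(cf["h"]),
         rss = best$rss, n_points = length(x),
         converged = best$fit$convInfo$isConv %||% TRUE,
         data = tibble(conc_nM = conc_nM, response_pct = y)),
    class = "drc_fit")
}

#' Predict the fitted response at given concentrations
#'
#' @param object A `drc_fit`.
#' @param conc_nM Concentrations in nM (zero maps to the upper asymptote).
#' @param ... Unused.
#' @return Numeric responses in percent.
#' @export
predict.drc_fit <- function(object, conc_nM, ...) {
  100 * fourpl_frac(conc_nM, object$log10_ic50, object$hill_slope)
}

#' @export
print.drc_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<drc_fit> not converged\n")
    return(invisible(x))
  }
  cat(sprintf("<drc_fit> log10 IC50 = %.4f (IC50 = %.3g nM), Hill slope = %.3f\n",
              x$log10_ic50, 10^(x$log10_ic50 + 9), x$hill_slope))
  cat(sprintf("  n = %d points, RSS = %.4g\n", x$n_points, x$rss))
  invisible(x)
}

#' @rdname fit_dose_response
#' @param x A `drc_fit`.
#' @param ... Unused.
#' @export
tidy.drc_fit <- function(x, ...) {
  tibble(term = c("log10_ic50", "hill_slope"),
         estimate = c(x$log10_ic50, x$hill_slope))
}

#' @rdname fit_dose_response
#' @export
glance.drc_fit <- function(x, ...) {
  tibble(log10_ic50 = x$log10_ic50, hill_slope = x$hill_slope,
         ic50_nM = 10^(x$log10_ic50 + 9), rss = x$rss,
         n_points = x$n_points, converged = x$converged)
}

#' Differential IC50 between two fitted lines
#'
#' `delta = log10 IC50(mutant) - log10 IC50(wild-type)`; positive values mean
#' the mutant line is more resistant (needs more drug for the same effect).
#'
#' @param fit_mut,fit_wt Converged `drc_fit` objects.
#' @return Numeric, log10 decades.
#' @export
delta_ic50 <- function(fit_mut, fit_wt) {
  stopifnot(inherits(fit_mut, "drc_fit"), inherits(fit_wt, "drc_fit"))
  if (!isTRUE(fit_mut$converged) || !isTRUE(fit_wt$converged)) {
    stop_organoidr("both fits must have converged", "organoidr_unconverged_fit")
  }
  fit_mut$log10_ic50 - fit_wt$log10_ic50
}
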