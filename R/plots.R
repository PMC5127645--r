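# ggplot2 methods for the package's result types; all headless-safe

#' @describeIn normalize_viability Heat map of the viability matrix (red =
#'   0% ATP, green = 100%).
#' @param object A `dose_matrix`.
#' @param ... Unused.
#' @export
autoplot.dose_matrix <- function(object, ...) {
  ggplot2::ggplot(conc_factor(object),
                  ggplot2::aes(.data$conc_a, .data$conc_b,
                               fill = .data$viability_pct)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "red", high = "green",
                                 limits = c(0, 100), oob = scales_squish) +
    ggplot2::labs(x = "drug A (nM)", y = "drug B (nM)",
                  fill = "viability (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @describeIn bliss_excess Diverging heat map of Bliss scores (red =
#'   synergy).
#' @param object A `bliss_matrix`.
#' @param ... Unused.
#' @export
autoplot.bliss_matrix <- function(object, ...) {
  ggplot2::ggplot(conc_factor(object),
                  ggplot2::aes(.data$conc_a, .data$conc_b,
                               fill = .data$bliss_score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0) +
    ggplot2::labs(x = "drug A (nM)", y = "drug B (nM)", fill = "Bliss excess") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

conc_factor <- function(m) {
  mutate(as_tibble(m),
         conc_a = factor(signif(.data$conc_a_nM, 3)),
         conc_b = factor(signif(.data$conc_b_nM, 3)))
}

# minimal squish so we need not depend on the scales package directly
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}

#' @describeIn fit_dose_response Fitted curve over the data points (log10
#'   concentration axis).
#' @param object A `drc_fit`.
#' @export
autoplot.drc_fit <- function(object, ...) {
  dat <- object$data
  xr <- range(log10(dat$conc_nM))
  grid <- tibble(conc_nM = 10^seq(xr[1], xr[2], length.out = 200))
  grid$response_pct <- predict(object, grid$conc_nM)
  ggplot2::ggplot(dat, ggplot2::aes(.data$conc_nM, .data$response_pct)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, color = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (nM)", y = "viability (%)") +
    ggplot2::theme_minimal()
}

#' @describeIn reconstruct_trajectory Step plot of the reconstructed cell
#'   count over time.
#' @param object A `count_trajectory`.
#' @param ... Unused.
#' @export
autoplot.count_trajectory <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$time_min / 60, .data$count)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (h)", y = "relative cell count") +
    ggplot2::theme_minimal()
}

#' @describeIn make_ab_kinetics Fluorescence-versus-time read with the
#'   linear phase visible.
#' @param object A `kinetics_series`.
#' @export
autoplot.kinetics_series <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$time_h, .data$rfu)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "fluorescence (RFU)") +
    ggplot2::theme_minimal()
}

#' @describeIn depth_coded_projection Render the projection as a ggplot
#'   raster.
#' @param object A `depth_projection`.
#' @param ... Unused.
#' @export
autoplot.depth_projection <- function(object, ...) {
  img <- object$rgb
  ggplot2::ggplot() +
    ggplot2::annotation_raster(
      grDevices::rgb(img[, , 1], img[, , 2], img[, , 3]) |>
        matrix(nrow = dim(img)[1]),
      xmin = 0, xmax = dim(img)[2], ymin = 0, ymax = dim(img)[1]) +
    ggplot2::coord_fixed(xlim = c(0, dim(img)[2]), ylim = c(0, dim(img)[1]),
                         expand = FALSE) +
    ggplot2::theme_void()
}
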