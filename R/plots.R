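#' Plot a dose-response fit
#'
#' Replicate values, the fitted regression line and the shaded mean-response
#' confidence band over the concentration range.
#'
#' @param object A `dose_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dose_fit <- function(object, ...) {
  grid <- tibble::tibble(
    concentration = seq(min(object$data$concentration),
                        max(object$data$concentration), length.out = 80))
  band <- dplyr::bind_cols(grid, tibble::as_tibble(suppressWarnings(
    stats::predict(object$model, newdata = grid, interval = "confidence",
                   level = object$conf_level))))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$concentration, y = .data$value)) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(y = .data$fit, ymin = .data$lwr,
                                      ymax = .data$upr),
                         alpha = 0.2) +
    ggplot2::geom_line(data = band, ggplot2::aes(y = .data$fit)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression("concentration ("*mu*g/cm^2*")"),
                  y = "bead pixels per cell")
}

#' Plot endmember spectra
#'
#' @param object An `endmember_set`.
#' @param ... Unused.
#' @return A ggplot object, one facet per endmember.
#' @export
autoplot.endmember_set <- function(object, ...) {
  df <- as_tibble(object) %>%
    dplyr::mutate(panel = paste0("EM", .data$endmember, " (", .data$label, ")"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavenumber, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = expression("wavenumber (cm"^-1*")"),
                  y = "intensity (a.u.)")
}

#' Plot abundance maps
#'
#' @param object An `abundance_stack`.
#' @param ... Unused.
#' @return A ggplot object, faceted by endmember and z plane.
#' @export
autoplot.abundance_stack <- function(object, ...) {
  df <- as_tibble(object) %>%
    dplyr::mutate(panel = paste0("EM", .data$endmember, " (", .data$label, ")"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$abundance)) +
    ggplot2::geom_raster() +
    ggplot2::facet_grid(z ~ panel) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "abundance")
}

#' Plot a band-intensity image
#'
#' @param object A `band_image`.
#' @param ... Unused.
#' @return A ggplot object, one facet per z plane.
#' @export
autoplot.band_image <- function(object, ...) {
  df <- purrr::imap_dfr(object$images, function(img, z) {
    tibble::tibble(
      x = rep(seq_len(nrow(img)), times = ncol(img)),
      y = rep(seq_len(ncol(img)), each = nrow(img)),
      z = z,
      intensity = as.vector(img))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~z) +
    ggplot2::scale_fill_viridis_c(option = "magma") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("band %g +/- %g cm-1", object$center, object$width / 2),
      x = NULL, y = NULL, fill = "intensity")
}
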