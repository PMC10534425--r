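# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @noRd
map_to_df <- function(m, value = "value") {
  df <- data.frame(col = rep(seq_len(ncol(m)), each = nrow(m)) - 1,
                   row = rep(seq_len(nrow(m)), ncol(m)) - 1,
                   value = as.numeric(m))
  names(df)[3] <- value
  df
}

#' Plot a demodulation result
#'
#' DC, AC and wrapped-phase maps side by side.
#'
#' @param object An `sfdi_demod`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sfdi_demod <- function(object, ...) {
  df <- rbind(cbind(map_to_df(object$i_dc), channel = "I_DC"),
              cbind(map_to_df(object$i_ac), channel = "I_AC"),
              cbind(map_to_df(object$phase_wrapped), channel = "phase (wrapped)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel, scales = "free") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "u (px)", y = "v (px)", fill = NULL)
}

#' Plot field-averaged diffuse reflectance against spatial frequency
#'
#' @param object An `sfdi_reflectance`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sfdi_reflectance <- function(object, ...) {
  n_f <- dim(object$r_ac)[3]
  df <- do.call(rbind, lapply(seq_len(n_f), function(k) {
    data.frame(f = mean(object$f_corr[, , k], na.rm = TRUE),
               r = mean(object$r_ac[, , k], na.rm = TRUE),
               r_sd = stats::sd(object$r_ac[, , k], na.rm = TRUE))
  }))
  df <- rbind(data.frame(f = 0, r = mean(object$r_dc, na.rm = TRUE),
                         r_sd = stats::sd(object$r_dc, na.rm = TRUE)), df)
  ggplot2::ggplot(df, ggplot2::aes(.data$f, .data$r)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$r - .data$r_sd,
                                          ymax = .data$r + .data$r_sd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "corrected spatial frequency (1/mm)",
                  y = "diffuse reflectance R_SFD")
}

#' Plot optical-property maps
#'
#' @param object An `sfdi_property_map` from [invert_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sfdi_property_map <- function(object, ...) {
  df <- rbind(cbind(map_to_df(object$mu_a), parameter = "mu_a (1/mm)"),
              cbind(map_to_df(object$mu_s_prime), parameter = "mu_s' (1/mm)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "bin", y = "bin", fill = NULL)
}

#' Plot the MTF look-up profile of one pixel
#'
#' Corrected reference intensity against distance, one curve per stored
#' frequency node, for a chosen pixel.
#'
#' @param lut An [build_mtf_lut()] result.
#' @param pixel `c(row, col)` 1-based matrix indices; default: center pixel.
#' @return A ggplot object.
#' @export
plot_mtf_profile <- function(lut, pixel = NULL) {
  pixel <- pixel %||% ceiling(lut$dims / 2)
  i <- pixel[1] + (pixel[2] - 1) * lut$dims[1]
  df <- do.call(rbind, lapply(seq_len(lut$n_f), function(k) {
    data.frame(l = lut$l_nodes[i, ],
               value = lut$ac_nodes[i, , k],
               f = sprintf("f = %.3g 1/mm", lut$f_nominal_ac[k]))
  }))
  df <- rbind(df, data.frame(l = lut$l_nodes[i, ], value = lut$dc_nodes[i, ],
                             f = "DC"))
  ggplot2::ggplot(df, ggplot2::aes(.data$l, .data$value, color = .data$f)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "distance l (mm)", y = "corrected reference intensity",
                  color = NULL)
}
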