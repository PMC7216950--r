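# ggplot2 autoplot methods for the main result types.

#' Plot a slice profile
#'
#' Magnitude and phase of the transverse magnetization across the slice.
#'
#' @param object A `slice_profile`.
#' @param zlim Plotted z range in metres (default plus/minus 2 slice
#'   thicknesses around the centre).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.slice_profile <- function(object, zlim = NULL, ...) {
  zlim <- zlim %||% (2 * profile_fwhm(object) * c(-1, 1))
  df <- tibble(z = object$z, magnitude = Mod(object$mxy),
               phase = Arg(object$mxy)) |>
    dplyr::filter(.data$z >= zlim[1], .data$z <= zlim[2]) |>
    tidyr::pivot_longer(c("magnitude", "phase"), names_to = "component")
  ggplot2::ggplot(df, ggplot2::aes(.data$z * 1e3, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "z (mm)", y = NULL,
                  title = sprintf("Slice profile, flip %.0f deg, G_slice %+.3g mT/m",
                                  attr(object, "alpha") * 180 / pi,
                                  attr(object, "g_slice")))
}

#' Plot a dephasing factor
#'
#' @param object A `dephasing_factor`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dephasing_factor <- function(object, ...) {
  ggplot2::ggplot(tibble(te = object$te * 1e3, f = Mod(object$f)),
                  ggplot2::aes(.data$te, .data$f)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "TE (ms)", y = "|F(t)|",
                  title = sprintf("%s, G_z = %.3g uT/m", attr(object, "model"),
                                  attr(object, "gz")))
}

#' Plot a T2* spectrum
#'
#' @param object An `mwf_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mwf_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t2star * 1e3, .data$amplitude)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$t2star * 1e3, yend = 0)) +
    ggplot2::geom_vline(xintercept = attr(object, "cutoff") * 1e3,
                        linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "T2* (ms)", y = "amplitude",
                  title = sprintf("MWF = %.1f%%", 100 * attr(object, "mwf")))
}

#' Plot a sensitivity sweep table
#'
#' @param data A tibble from [sensitivity_sweep()].
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(data) {
  xvar <- switch(data$sweep[1],
                 phase = "alpha", b1 = "xi", lambda = "lambda",
                 lambda_gz = "gz", t1 = "tr_t1")
  col <- intersect(c("polarity", "alpha", "ernst_fraction"), names(data))[1]
  ggplot2::ggplot(data, ggplot2::aes(.data[[xvar]], .data$rmse,
                                     colour = factor(.data[[col]]))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = xvar, y = "RMSE (%)", colour = col)
}
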