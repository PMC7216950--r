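# Per-voxel inputs for the dephasing correction: field offset, through-slice
# gradient, normalized transmit field, and navigator phase correction.
#
# Volumes are plain R arrays; the echo dimension is last; the slice axis is
# the third array axis. Field offsets are carried in rad/s; conversion to
# gradient units uses the package gyromagnetic ratio.

#' Temporal phase unwrapping along the echo dimension
#'
#' Removes plus/minus 2 pi jumps between consecutive echoes per voxel
#' (spatial unwrapping is assumed to have been done upstream).
#'
#' @param phase Array with echoes on the last dimension, in radians.
#' @return Array of the same shape.
#' @export
unwrap_echo_phase <- function(phase) {
  d <- dim(phase)
  if (is.null(d)) {
    dp <- diff(phase)
    return(phase[1] + c(0, cumsum(dp - 2 * pi * round(dp / (2 * pi)))))
  }
  ne <- d[length(d)]
  m <- matrix(phase, ncol = ne)
  u <- m
  for (j in 2:ne) {
    dp <- m[, j] - m[, j - 1]
    u[, j] <- u[, j - 1] + dp - 2 * pi * round(dp / (2 * pi))
  }
  array(u, d)
}

#' Field-offset map from multi-echo phase
#'
#' Per-voxel frequency offset (rad/s) from the unwrapped phase evolution
#' over echoes: an ordinary least-squares slope of phase versus echo time
#' over the first `n_echoes` echoes (default 6), or the two-point difference
#' `(phi_3 - phi_1)/(TE_3 - TE_1)` with `method = "two_echo"`.
#'
#' @param phase Array (spatial dims x echoes) of unwrapped phase in radians.
#' @param te Echo times in seconds (length = last dim of `phase`).
#' @param n_echoes Number of leading echoes used in the linear fit.
#' @param method `"ols"` (default) or `"two_echo"`.
#' @return Array of frequency offsets in rad/s with the spatial dimensions
#'   of `phase`.
#' @export
fit_delta_omega0 <- function(phase, te, n_echoes = 6,
                             method = c("ols", "two_echo")) {
  method <- match.arg(method)
  d <- dim(phase)
  ne <- if (is.null(d)) length(phase) else d[length(d)]
  if (length(te) != ne) {
    abort("`te` length must match the echo dimension.",
          class = "dephasr_invalid_argument")
  }
  m <- matrix(phase, ncol = ne)
  if (method == "two_echo") {
    if (ne < 3) abort("two-echo method needs at least 3 echoes.",
                      class = "dephasr_invalid_argument")
    slope <- (m[, 3] - m[, 1]) / (te[3] - te[1])
  } else {
    if (ne < n_echoes) {
      abort(sprintf("requested %d echoes but only %d available.", n_echoes, ne),
            class = "dephasr_invalid_argument")
    }
    tt <- te[seq_len(n_echoes)]
    tc <- tt - mean(tt)
    mm <- m[, seq_len(n_echoes), drop = FALSE]
    slope <- as.vector(mm %*% tc) / sum(tc^2)
  }
  if (is.null(d) || length(d) == 1) slope else array(slope, d[-length(d)])
}

#' Through-slice gradient map from a field map
#'
#' Central difference of the frequency-offset map along the slice axis
#' (third array dimension), single-sided at the first and last slice,
#' converted to field-gradient units:
#' `G_z = (d omega / d z) / gamma`, returned in microtesla per metre.
#'
#' @param delta_omega0 3D array of field offsets in rad/s.
#' @param slice_spacing Centre-to-centre slice distance in metres.
#' @return 3D array of through-slice gradients in microtesla/m.
#' @export
gz_map_from_fieldmap <- function(delta_omega0, slice_spacing) {
  d <- dim(delta_omega0)
  if (is.null(d) || length(d) != 3 || d[3] < 2) {
    abort("need a 3D field map with at least 2 slices.",
          class = "dephasr_invalid_argument")
  }
  ns <- d[3]
  grad <- array(NA_real_, d)
  grad[, , 1] <- (delta_omega0[, , 2] - delta_omega0[, , 1]) / slice_spacing
  grad[, , ns] <- (delta_omega0[, , ns] - delta_omega0[, , ns - 1]) / slice_spacing
  if (ns > 2) {
    for (i in 2:(ns - 1)) {
      grad[, , i] <- 0.5 * (delta_omega0[, , i + 1] - delta_omega0[, , i - 1]) /
        slice_spacing
    }
  }
  grad / .gamma * 1e6 # rad/s/m -> T/m -> uT/m
}

#' Normalize a transmit-field map
#'
#' `xi = measured / nominal`, clipped to the range covered by the simulated
#' profile grid; the number of clipped voxels is reported as an attribute
#' and a message.
#'
#' @param b1_map Array of measured flip angles or B1 amplitudes.
#' @param nominal Nominal (prescribed) value of the same quantity.
#' @param clip_range Allowed `xi` range (default `c(0.5, 1.5)`, the default
#'   [xi_profile_grid()] span).
#' @return Array of `xi` with attribute `n_clipped`.
#' @export
normalize_b1 <- function(b1_map, nominal, clip_range = c(0.5, 1.5)) {
  if (!is.numeric(nominal) || nominal <= 0) {
    abort("`nominal` must be positive.", class = "dephasr_invalid_argument")
  }
  xi <- b1_map / nominal
  clipped <- which(!is.na(xi) & (xi < clip_range[1] | xi > clip_range[2]))
  xi[xi < clip_range[1]] <- clip_range[1]
  xi[xi > clip_range[2]] <- clip_range[2]
  if (length(clipped) > 0) {
    rlang::inform(sprintf("normalize_b1: clipped %d voxels to [%g, %g].",
                          length(clipped), clip_range[1], clip_range[2]))
  }
  structure(xi, n_clipped = length(clipped))
}

#' Navigator phase series
#'
#' Mean navigator phase per phase-encoding line and channel: the angle of
#' the complex sum over the central 25 percent of the navigator readout
#' samples.
#'
#' @param nav_readout Complex array (lines x channels x readout) of
#'   navigator echo samples.
#' @param te_navi Navigator echo time in seconds.
#' @return A `navigator_series` list with `phi` (lines x channels, rad) and
#'   `te_navi`.
#' @export
navigator_series <- function(nav_readout, te_navi) {
  d <- dim(nav_readout)
  if (is.null(d) || length(d) != 3) {
    abort("`nav_readout` must be lines x channels x readout.",
          class = "dephasr_invalid_argument")
  }
  nr <- d[3]
  centre <- seq(floor(nr * 0.375) + 1, ceiling(nr * 0.625))
  phi <- apply(nav_readout[, , centre, drop = FALSE], c(1, 2),
               function(v) Arg(sum(v)))
  structure(list(phi = matrix(phi, d[1], d[2]), te_navi = te_navi),
            class = "navigator_series")
}

#' Navigator-echo phase correction of raw k-space lines
#'
#' Removes line-to-line physiological phase fluctuations: each acquired
#' phase-encoding line is multiplied by
#' `exp(-i (phi_n - phi_1) TE / TE_navi)` per channel and echo, where
#' `phi_n` is the mean navigator phase of line `n` and `phi_1` the reference
#' phase of the first line. The measured phase difference is scaled with
#' the echo time to account for phase accumulation after excitation.
#'
#' @param kspace Complex array (lines x channels x echoes x readout).
#' @param nav A `navigator_series` (or a list with `phi` and `te_navi`);
#'   `phi` may be a vector (single channel) or a lines x channels matrix.
#' @param te Echo times in seconds (length = echo dimension).
#' @return Corrected array of the same shape.
#' @export
navigator_correct <- function(kspace, nav, te) {
  d <- dim(kspace)
  if (is.null(d) || length(d) != 4) {
    abort("`kspace` must be lines x channels x echoes x readout.",
          class = "dephasr_invalid_argument")
  }
  phi <- nav$phi
  if (is.null(dim(phi))) phi <- matrix(phi, ncol = 1)
  if (nrow(phi) != d[1] || ncol(phi) != d[2]) {
    missing <- setdiff(seq_len(d[1]), seq_len(nrow(phi)))
    abort(paste0("navigator phase missing for lines: ",
                 paste(missing, collapse = ", ")),
          class = "dephasr_invalid_argument")
  }
  if (length(te) != d[3]) {
    abort("`te` length must match the echo dimension.",
          class = "dephasr_invalid_argument")
  }
  dphi <- sweep(phi, 2, phi[1, ], "-") # lines x channels
  out <- kspace
  for (e in seq_len(d[3])) {
    corr <- exp(-1i * dphi * te[e] / nav$te_navi) # lines x channels
    out[, , e, ] <- kspace[, , e, , drop = FALSE] *
      array(corr, c(d[1], d[2], 1, d[4]))
  }
  out
}

#' Assemble the per-voxel field-map bundle
#'
#' Convenience constructor holding the three per-voxel inputs of the
#' correction plus the slice geometry.
#'
#' @param delta_omega0 3D array, rad/s.
#' @param gz 3D array, microtesla/m.
#' @param xi 3D array, dimensionless.
#' @param slice_spacing Centre-to-centre slice distance (m).
#' @return A `field_maps` list.
#' @export
field_maps <- function(delta_omega0 = NULL, gz, xi, slice_spacing) {
  structure(list(delta_omega0 = delta_omega0, gz = gz, xi = xi,
                 slice_spacing = slice_spacing),
            class = "field_maps")
}
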