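# Fast per-voxel evaluation of dephasing factors.
#
# Voxel-wise fitting needs |F(te; G_z, xi)| for ~1e5 voxels. F is a linear
# functional of the complex slice profile, so interpolating F linearly over
# the xi profile nodes is mathematically identical to interpolating the
# profile itself; over G_z the factor is smooth on a few-uT/m scale. The
# lookup therefore tabulates complex F on (xi node) x (G_z node) and
# bilinearly interpolates, with the slice scaling lambda(G_z) folded into
# each G_z node.

trim_profile_support <- function(profile, tol = 1e-7, pad = 20L) {
  m <- Mod(profile$mxy)
  keep <- which(m > tol * max(m))
  i1 <- max(1L, min(keep) - pad)
  i2 <- min(length(m), max(keep) + pad)
  i1:i2
}

# complex F rows for one profile over gz nodes (trapezoid on trimmed support)
factor_rows_for_profile <- function(profile, gz_nodes, te, g_slice,
                                    apply_lambda = TRUE) {
  idx <- trim_profile_support(profile)
  z <- profile$z[idx]
  w <- rep(1, length(z)); w[1] <- 0.5; w[length(w)] <- 0.5
  wm <- w * profile$mxy[idx]
  f0 <- sum(wm)
  out <- matrix(NA_complex_, length(gz_nodes), length(te))
  for (j in seq_along(gz_nodes)) {
    gz <- gz_nodes[j]
    lam <- if (apply_lambda) lambda_factor(g_slice, gz) else 1
    # lambda by coordinate scaling == time rescaling t -> t/lambda (exact)
    f <- as.vector(crossprod(exp(1i * .gamma * gz * 1e-6 * outer(z, te / lam)),
                             wm))
    out[j, ] <- f / f0
  }
  out
}

#' Tabulated dephasing factors for voxel-wise fitting
#'
#' Precomputes complex dephasing factors on a grid of transmit-field scales
#' (the [xi_profile_grid()] nodes) and through-slice gradients, for bilinear
#' per-voxel interpolation with [lookup_f_mag()]. The slice-scaling factor
#' `lambda = G_slice/(G_slice + G_z)` is applied at each gradient node for
#' the S4 model; the S2/S3 models tabulate a single profile over gradients
#' only.
#'
#' @param source A `slice_profile` (models S2/S3) or an [xi_profile_grid()]
#'   (model S4).
#' @param gz_range Gradient range to cover, microtesla/m.
#' @param te Echo times in seconds.
#' @param model Signal model, one of `"S2"`, `"S3"`, `"S4"`.
#' @param gz_step Gradient node spacing in microtesla/m (default 5).
#' @return A `dephasing_lookup` object.
#' @export
dephasing_lookup <- function(source, gz_range, te, model = "S4", gz_step = 5) {
  gz_nodes <- seq(floor(gz_range[1] / gz_step) * gz_step,
                  ceiling(gz_range[2] / gz_step) * gz_step, by = gz_step)
  if (length(gz_nodes) == 1) gz_nodes <- c(gz_nodes, gz_nodes + gz_step)
  if (model == "S4") {
    stopifnot(inherits(source, "xi_profile_grid"))
    g_slice <- source$g_slice
    xi_nodes <- source$xi
    f <- array(NA_complex_, c(length(xi_nodes), length(gz_nodes), length(te)))
    for (i in seq_along(xi_nodes)) {
      f[i, , ] <- factor_rows_for_profile(source$profiles[[i]], gz_nodes, te,
                                          g_slice, apply_lambda = TRUE)
    }
  } else if (model %in% c("S2", "S3")) {
    stopifnot(inherits(source, "slice_profile"))
    g_slice <- attr(source, "g_slice")
    prof <- source
    if (model == "S2") prof$mxy <- complex(real = Mod(prof$mxy))
    xi_nodes <- 1
    f <- array(factor_rows_for_profile(prof, gz_nodes, te, g_slice,
                                       apply_lambda = FALSE),
               c(1, length(gz_nodes), length(te)))
  } else {
    abort(sprintf("no lookup needed for model %s.", model),
          class = "dephasr_invalid_argument")
  }
  structure(list(xi = xi_nodes, gz = gz_nodes, te = te, f = f,
                 model = model, g_slice = g_slice),
            class = "dephasing_lookup")
}

#' Interpolated dephasing-factor magnitudes per voxel
#'
#' Bilinear interpolation of the tabulated complex factors over
#' (`xi`, `gz`), magnitude taken after interpolation. Vectorized over
#' voxels.
#'
#' @param lookup A [dephasing_lookup()].
#' @param gz Vector of per-voxel gradients (microtesla/m).
#' @param xi Vector of per-voxel transmit scales (recycled if length 1).
#' @return Matrix `length(gz)` x `length(te)` of `|F|`.
#' @export
lookup_f_mag <- function(lookup, gz, xi = 1) {
  nv <- length(gz)
  xi <- rep_len(xi, nv)
  xs <- lookup$xi; gs <- lookup$gz
  if (any(gz < gs[1] - 1e-9 | gz > gs[length(gs)] + 1e-9)) {
    abort("gz outside the tabulated range.", class = "dephasr_range_error")
  }
  nxi <- length(xs)
  fm <- matrix(lookup$f, nxi * length(gs), length(lookup$te))
  ig <- pmin(pmax(findInterval(gz, gs), 1L), length(gs) - 1L)
  wg <- (gz - gs[ig]) / (gs[ig + 1] - gs[ig])
  if (nxi == 1) {
    f <- (1 - wg) * fm[ig, , drop = FALSE] + wg * fm[ig + 1, , drop = FALSE]
    return(Mod(f))
  }
  xi <- pmin(pmax(xi, xs[1]), xs[nxi])
  ix <- pmin(pmax(findInterval(xi, xs), 1L), nxi - 1L)
  wx <- (xi - xs[ix]) / (xs[ix + 1] - xs[ix])
  id <- function(i, j) i + (j - 1L) * nxi
  f <- (1 - wx) * (1 - wg) * fm[id(ix, ig), , drop = FALSE] +
    wx * (1 - wg) * fm[id(ix + 1L, ig), , drop = FALSE] +
    (1 - wx) * wg * fm[id(ix, ig + 1L), , drop = FALSE] +
    wx * wg * fm[id(ix + 1L, ig + 1L), , drop = FALSE]
  Mod(f)
}
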