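# Myelin water fraction from a multi-exponential T2* spectrum.
#
# The F-corrected magnitude decay is expanded onto M = 200 decaying
# exponentials on a log-spaced T2* grid by nonnegative least squares
# (unregularized); the myelin water fraction is the spectral weight below
# the 25 ms cutoff.

#' Default T2* spectral grid
#'
#' 200 relaxation times, log-spaced from 1.5 to 300 ms.
#'
#' @param m Number of components.
#' @param range Length-2 range in seconds.
#' @return Numeric vector of T2* values (s), strictly increasing.
#' @export
t2star_spectrum_grid <- function(m = 200, range = c(1.5e-3, 0.3)) {
  exp(seq(log(range[1]), log(range[2]), length.out = m))
}

#' Myelin water fraction by nonnegative least squares
#'
#' Corrects the measured magnitudes for through-slice dephasing by dividing
#' by `|F(t)|`, excluding echoes where `|F|` falls below `floor` (near
#' signal nulls the division amplifies noise), then solves the nonnegative
#' least-squares problem onto decaying exponentials over `t2_grid`. The MWF
#' is the amplitude fraction with T2* below `cutoff`.
#'
#' @param series An [echo_series()].
#' @param f Optional dephasing factor: a `dephasing_factor`, or a numeric
#'   vector of `|F|` per echo. `NULL` fits the uncorrected decay.
#' @param t2_grid Spectral grid in seconds (default
#'   [t2star_spectrum_grid()]).
#' @param cutoff Myelin-water cutoff in seconds (default 25 ms).
#' @param floor Exclusion threshold on `|F|` (default 0.05).
#' @return An `mwf_spectrum` tibble with columns `t2star`, `amplitude`, and
#'   attributes `mwf`, `cutoff`, `n_excluded`, `flagged`.
#' @export
#' @examples
#' te <- 2.37e-3 + 2.2e-3 * (0:26)
#' y <- 0.15 * exp(-te / 0.010) + 0.85 * exp(-te / 0.060)
#' attr(fit_mwf(echo_series(te, y)), "mwf")
fit_mwf <- function(series, f = NULL, t2_grid = t2star_spectrum_grid(),
                    cutoff = 0.025, floor = 0.05) {
  stopifnot(inherits(series, "echo_series"))
  te <- series$te
  y <- series$magnitude
  fmag <- if (is.null(f)) {
    rep(1, length(te))
  } else if (inherits(f, "dephasing_factor")) {
    if (nrow(f) != length(te) || max(abs(f$te - te)) > 1e-12) {
      abort("`f` must be on the series echo grid.",
            class = "dephasr_invalid_argument")
    }
    Mod(f$f)
  } else {
    as.numeric(f)
  }
  keep <- fmag >= floor
  n_excl <- sum(!keep)
  if (!any(keep) || sum(keep) < 3) {
    out <- new_mwf_spectrum(t2_grid, rep(NA_real_, length(t2_grid)),
                            NA_real_, cutoff, n_excl, flagged = TRUE)
    return(out)
  }
  tk <- te[keep]
  yk <- y[keep] / fmag[keep]
  a <- exp(-outer(tk, 1 / t2_grid))
  s <- pracma::lsqnonneg(a, yk)$x
  tot <- sum(s)
  mwf <- if (tot > 0) sum(s[t2_grid < cutoff]) / tot else NA_real_
  new_mwf_spectrum(t2_grid, s, mwf, cutoff, n_excl, flagged = !is.finite(mwf))
}

new_mwf_spectrum <- function(t2_grid, s, mwf, cutoff, n_excluded, flagged) {
  out <- tibble(t2star = t2_grid, amplitude = s)
  class(out) <- c("mwf_spectrum", class(out))
  attr(out, "mwf") <- mwf
  attr(out, "cutoff") <- cutoff
  attr(out, "n_excluded") <- n_excluded
  attr(out, "flagged") <- flagged
  out
}

#' @export
print.mwf_spectrum <- function(x, ...) {
  cat(sprintf("<mwf_spectrum> MWF = %.3g%% (cutoff %.0f ms, %d echoes excluded%s)\n",
              100 * attr(x, "mwf"), attr(x, "cutoff") * 1e3,
              attr(x, "n_excluded"),
              if (isTRUE(attr(x, "flagged"))) ", flagged" else ""))
  invisible(x)
}

#' @export
glance.mwf_spectrum <- function(x, ...) {
  tibble(mwf = attr(x, "mwf"), cutoff = attr(x, "cutoff"),
         n_excluded = attr(x, "n_excluded"), flagged = attr(x, "flagged"))
}

#' Voxel-wise MWF mapping
#'
#' Applies [fit_mwf()] per foreground voxel, with the dephasing correction
#' evaluated from a [dephasing_lookup()].
#'
#' @param volume 4D magnitude array (x, y, slice, echo).
#' @param maps A [field_maps()] (ignored when `lookup` is `NULL`).
#' @param lookup A `dephasing_lookup` for the correction model, or `NULL`
#'   for uncorrected fitting.
#' @param te Echo times (s).
#' @param mask Logical 3D array; default: any nonzero echo.
#' @param ... Passed to [fit_mwf()].
#' @return List with `mwf` (3D array), `n_flagged`, and the mask.
#' @export
fit_mwf_map <- function(volume, maps = NULL, lookup = NULL, te,
                        mask = NULL, ...) {
  d <- dim(volume)
  sp <- d[1:3]
  if (is.null(mask)) mask <- apply(volume != 0, 1:3, any)
  vox <- which(mask)
  ymat <- matrix(volume, prod(sp), d[4])[vox, , drop = FALSE]
  fmat <- if (is.null(lookup)) {
    matrix(1, length(vox), d[4])
  } else {
    lookup_f_mag(lookup, maps$gz[vox], maps$xi[vox])
  }
  out <- array(NA_real_, sp)
  flagged <- 0L
  for (k in seq_along(vox)) {
    sp_fit <- fit_mwf(echo_series(te, ymat[k, ]), f = fmat[k, ], ...)
    out[vox[k]] <- attr(sp_fit, "mwf")
    flagged <- flagged + isTRUE(attr(sp_fit, "flagged"))
  }
  list(mwf = out, n_flagged = flagged, mask = mask)
}
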