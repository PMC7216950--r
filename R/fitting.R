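# R2* estimation under the nested signal models S1-S4.
#
# S(t) = S0 exp(-R2* t) |F_model(t)|. The least-squares problem is solved by
# variable projection: S0 enters linearly and is profiled out, leaving a 1D
# minimization over R2* in [0, r2star_max], solved by Brent search and
# seeded/initialized from a log-linear fit of the leading echoes.

#' Multi-echo series container
#'
#' @param te Echo times in seconds, strictly increasing.
#' @param magnitude Nonnegative signal magnitudes, same length as `te`.
#' @param protocol Optional named list describing the acquisition (pulse
#'   config, `alpha` in rad, signed `g_slice` in mT/m, `tr`, `t1`).
#' @return An `echo_series` tibble.
#' @export
echo_series <- function(te, magnitude, protocol = list()) {
  if (any(diff(te) <= 0)) {
    abort("`te` must be strictly increasing.", class = "dephasr_invalid_argument")
  }
  if (any(magnitude < 0)) {
    abort("`magnitude` must be nonnegative.", class = "dephasr_invalid_argument")
  }
  out <- tibble(te = te, magnitude = magnitude)
  class(out) <- c("echo_series", class(out))
  attr(out, "protocol") <- protocol
  out
}

# |F| for a voxel under a given model; source is a slice_profile,
# xi_profile_grid, or dephasing_lookup
model_f_mag <- function(model, te, gz, xi, source, g_slice = NULL) {
  if (model == "S1") return(rep(1, length(te)))
  if (inherits(source, "dephasing_lookup")) {
    return(as.vector(lookup_f_mag(source, gz, xi)))
  }
  if (model %in% c("S2", "S3")) {
    stopifnot(inherits(source, "slice_profile"))
    fmod <- if (model == "S2") "F2" else "F3"
    return(Mod(dephasing_factor(source, gz, te, fmod)$f))
  }
  if (model == "S4") {
    stopifnot(inherits(source, "xi_profile_grid"))
    prof <- profile_at_xi(source, xi)
    lam <- lambda_factor(g_slice %||% source$g_slice, gz)
    return(Mod(dephasing_factor(prof, gz, te, "F4", lambda = lam)$f))
  }
  abort(sprintf("unknown model '%s'.", model), class = "dephasr_invalid_argument")
}

# log-linear R2* over the first n echoes of the (F-corrected) magnitudes
r2star_loglin <- function(te, y, n = 6L) {
  n <- min(n, length(te))
  keep <- which(y[seq_len(n)] > 0)
  if (length(keep) < 2) return(0)
  tt <- te[keep]; ly <- log(y[keep])
  tc <- tt - mean(tt)
  max(0, -sum(tc * (ly - mean(ly))) / sum(tc^2))
}

# variable-projection fit; returns c(s0, r2star, rss, bound)
fit_r2star_core <- function(te, y, fmag, r2star_max = 2000, tol = 1e-8) {
  gss <- function(r) exp(-r * te) * fmag
  rss <- function(r) {
    g <- gss(r)
    s0 <- sum(y * g) / sum(g * g)
    if (!is.finite(s0) || s0 < 0) s0 <- 0
    sum((y - s0 * g)^2)
  }
  opt <- optimize(rss, c(0, r2star_max), tol = tol)
  r <- opt$minimum
  # Brent never samples the interval ends; snap if the edge is better
  if (rss(0) <= opt$objective) r <- 0
  g <- gss(r)
  s0 <- max(0, sum(y * g) / sum(g * g))
  bound <- r <= tol * 10 || r >= r2star_max - 1e-6 * r2star_max
  c(s0 = s0, r2star = r, rss = sum((y - s0 * g)^2), bound = as.numeric(bound))
}

#' Fit R2* to a multi-echo series under a dephasing model
#'
#' Nonlinear least squares of `S0 exp(-R2* t) |F(t)|` against the measured
#' magnitudes. `S0` is profiled out analytically (it enters linearly) and
#' `R2*` is found by Brent search on `[0, r2star_max]`, seeded by a
#' log-linear fit of the first six echoes. The dephasing factor is built
#' from `profile_source` according to the model: `"S1"` no correction,
#' `"S2"` magnitude-only profile, `"S3"` complex profile, `"S4"` complex
#' profile at the voxel's B1 scale with slice scaling
#' `lambda = G_slice/(G_slice+G_z)`.
#'
#' @param series An [echo_series()].
#' @param model `"S1"`, `"S2"`, `"S3"`, or `"S4"`.
#' @param gz Voxel through-slice gradient in microtesla/m.
#' @param xi Voxel transmit-field scale.
#' @param profile_source `slice_profile` (S2/S3), [xi_profile_grid()] or
#'   [dephasing_lookup()] (S4); ignored for S1.
#' @param r2star_max Upper bound of the search, s^-1 (default 2000).
#' @return An object of class `r2star_fit` with elements `s0`, `r2star`
#'   (s^-1), `residual_norm`, `model`, `convergence`, `bound_active`, and
#'   the data/factor used. Supports [tidy()] and [glance()].
#' @export
#' @examples
#' te <- acquisition_te_grid()
#' fit <- fit_r2star(echo_series(te, 3 * exp(-20 * te)), "S1")
#' glance(fit)
fit_r2star <- function(series, model = c("S4", "S1", "S2", "S3"), gz = 0,
                       xi = 1, profile_source = NULL, r2star_max = 2000) {
  model <- match.arg(model)
  stopifnot(inherits(series, "echo_series"))
  y <- series$magnitude
  te <- series$te
  if (all(y == 0)) {
    return(structure(list(s0 = NA_real_, r2star = NA_real_,
                          residual_norm = NA_real_, model = model,
                          convergence = FALSE, bound_active = FALSE,
                          masked = TRUE, te = te, magnitude = y,
                          f_mag = rep(1, length(te))),
                     class = "r2star_fit"))
  }
  proto <- attr(series, "protocol")
  fmag <- model_f_mag(model, te, gz, xi, profile_source,
                      g_slice = proto$g_slice)
  fit <- fit_r2star_core(te, y, fmag, r2star_max)
  structure(list(s0 = unname(fit["s0"]), r2star = unname(fit["r2star"]),
                 residual_norm = sqrt(unname(fit["rss"])), model = model,
                 convergence = is.finite(fit["rss"]),
                 bound_active = fit["bound"] > 0, masked = FALSE,
                 te = te, magnitude = y, f_mag = fmag),
            class = "r2star_fit")
}

#' @export
print.r2star_fit <- function(x, ...) {
  cat(sprintf("<r2star_fit %s> R2* = %.4g s^-1, S0 = %.4g%s\n", x$model,
              x$r2star, x$s0,
              if (isTRUE(x$bound_active)) " (bound active)" else ""))
  invisible(x)
}

#' @export
tidy.r2star_fit <- function(x, ...) {
  tibble(term = c("s0", "r2star"), estimate = c(x$s0, x$r2star))
}

#' @export
glance.r2star_fit <- function(x, ...) {
  tibble(r2star = x$r2star, s0 = x$s0, residual_norm = x$residual_norm,
         model = x$model, convergence = x$convergence,
         bound_active = x$bound_active)
}

#' Fitted values of an R2* fit
#' @param object An `r2star_fit`.
#' @param ... Unused.
#' @return Tibble with `te`, `magnitude`, `fitted`.
#' @export
augment.r2star_fit <- function(object, ...) {
  tibble(te = object$te, magnitude = object$magnitude,
         fitted = object$s0 * exp(-object$r2star * object$te) * object$f_mag)
}

#' Voxel-wise R2* mapping over a volume
#'
#' Applies [fit_r2star()] to every foreground voxel of a 4D magnitude
#' volume (x, y, slice, echo), building one dephasing lookup per unique
#' signed slice gradient (so alternating-polarity protocols are handled
#' per slice). Voxels with a singular slice scaling
#' (`G_slice + G_z` near 0) are masked and counted.
#'
#' @param volume 4D array of magnitudes.
#' @param maps A [field_maps()] with `gz` and `xi` volumes matching the
#'   spatial dimensions.
#' @param model `"S1"` to `"S4"`.
#' @param protocol Named list with `pulse` (config list or `rf_pulse`),
#'   `alpha` (rad), `g_slice` (signed mT/m; scalar or per-slice vector),
#'   and `te` (s).
#' @param mask Optional logical 3D array; default: voxels with any signal.
#' @param xi_range,gz_step Lookup-table construction parameters.
#' @return An `r2star_map` list with arrays `r2star`, `s0`,
#'   `residual_norm`, logical `converged`, the `mask` used, counts of
#'   masked/singular voxels, and the model.
#' @export
fit_r2star_map <- function(volume, maps, model = "S4", protocol,
                           mask = NULL, xi_range = c(0.5, 1.5), gz_step = 5) {
  d <- dim(volume)
  if (length(d) != 4) {
    abort("`volume` must be 4D (x, y, slice, echo).",
          class = "dephasr_invalid_argument")
  }
  sp <- d[1:3]
  if (model != "S1") {
    if (!all(dim(maps$gz) == sp)) {
      abort("gz map geometry does not match the volume.",
            class = "dephasr_invalid_argument")
    }
  }
  te <- protocol$te
  if (length(te) != d[4]) {
    abort("protocol `te` must match the echo dimension.",
          class = "dephasr_invalid_argument")
  }
  if (is.null(mask)) mask <- apply(volume != 0, 1:3, any)
  g_slice <- protocol$g_slice
  g_per_slice <- rep_len(g_slice, sp[3])

  out_r2 <- array(NA_real_, sp); out_s0 <- array(NA_real_, sp)
  out_res <- array(NA_real_, sp); out_cv <- array(FALSE, sp)
  n_singular <- 0L

  pulse <- protocol$pulse
  if (!inherits(pulse, "rf_pulse") && model != "S1") {
    pulse <- rf_pulse_from_config(pulse)
  }

  for (g in unique(g_per_slice)) {
    slices <- which(g_per_slice == g)
    sel <- array(FALSE, sp); sel[, , slices] <- TRUE
    vox <- which(mask & sel)
    if (length(vox) == 0) next
    ymat <- matrix(volume, prod(sp), d[4])[vox, , drop = FALSE]

    if (model == "S1") {
      fmat <- matrix(1, length(vox), d[4])
    } else {
      gzv <- maps$gz[vox]
      # singular slice scaling: flag and drop
      if (model == "S4") {
        bad <- abs(g + gzv * 1e-3) < 1e-3 * abs(g)
        if (any(bad)) {
          n_singular <- n_singular + sum(bad)
          keep <- !bad
          vox <- vox[keep]; ymat <- ymat[keep, , drop = FALSE]
          gzv <- gzv[keep]
        }
      }
      src <- if (model == "S4") {
        dephasing_lookup(
          xi_profile_grid(pulse, g, protocol$alpha, xi_range = xi_range),
          range(gzv), te, model = "S4", gz_step = gz_step)
      } else {
        dephasing_lookup(
          simulate_profile(rf_scale_to_flip(pulse, protocol$alpha), g),
          range(gzv), te, model = model, gz_step = gz_step)
      }
      xiv <- if (model == "S4") pmin(pmax(maps$xi[vox], xi_range[1]),
                                     xi_range[2]) else 1
      fmat <- lookup_f_mag(src, gzv, xiv)
    }

    for (k in seq_along(vox)) {
      y <- ymat[k, ]
      if (all(y == 0)) next
      fit <- fit_r2star_core(te, y, fmat[k, ], tol = 1e-6)
      v <- vox[k]
      out_r2[v] <- fit["r2star"]; out_s0[v] <- fit["s0"]
      out_res[v] <- sqrt(fit["rss"]); out_cv[v] <- is.finite(fit["rss"])
    }
  }
  structure(list(r2star = out_r2, s0 = out_s0, residual_norm = out_res,
                 converged = out_cv, mask = mask, model = model,
                 n_masked = sum(!mask), n_singular = n_singular,
                 protocol = protocol),
            class = "r2star_map")
}

#' @export
print.r2star_map <- function(x, ...) {
  cat(sprintf("<r2star_map %s> %s voxels fit, %d singular, median R2* = %.3g s^-1\n",
              x$model, format(sum(x$mask)), x$n_singular,
              stats::median(x$r2star[x$mask], na.rm = TRUE)))
  invisible(x)
}

#' @export
glance.r2star_map <- function(x, ...) {
  v <- x$r2star[x$mask]
  tibble(model = x$model, n_fit = sum(x$mask), n_singular = x$n_singular,
         r2star_median = stats::median(v, na.rm = TRUE),
         r2star_mean = mean(v, na.rm = TRUE))
}
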