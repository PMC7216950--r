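# Through-slice dephasing factors.
#
# F(t) = integral of M_xy(lambda * z) * exp(i gamma G_z z t) dz, evaluated by
# trapezoidal quadrature on the slice-profile grid and normalized so that
# F(0) = 1. The field offset at slice centre contributes only a global phase
# exp(i dw0 t) that drops out of |F| and is tracked separately.

#' Slice-profile scaling factor from gradient superposition
#'
#' The background through-slice gradient adds to the slice-select gradient
#' during excitation, broadening or narrowing the excited slice by
#' `lambda = G_slice / (G_slice + G_z)` (signs respected; both gradients
#' expressed along the same axis).
#'
#' @param g_slice Signed slice-select gradient in mT/m.
#' @param gz Through-slice field gradient in microtesla per metre.
#' @return Dimensionless scaling factor.
#' @export
#' @examples
#' lambda_factor(8.29, 100)
lambda_factor <- function(g_slice, gz) {
  if (any(g_slice == 0)) {
    abort("`g_slice` must be nonzero.", class = "dephasr_invalid_argument")
  }
  denom <- g_slice + gz * 1e-3 # both mT/m
  if (any(abs(denom) < 1e-12)) {
    abort("G_slice + G_z = 0: slice scaling is singular for this voxel.",
          class = "dephasr_singularity_error")
  }
  g_slice / denom
}

#' Default echo-time grid of the phantom protocol
#'
#' 32 monopolar echoes, TE1 = 4 ms, spacing 5 ms (4 to 159 ms).
#'
#' @return Echo times in seconds.
#' @export
acquisition_te_grid <- function() seq(0.004, 0.159, by = 0.005)

#' Default time grid for sensitivity RMSE comparisons
#'
#' Dense 1 ms grid from 1 to 200 ms, covering the full decay of the
#' dephasing factor at the simulated gradient strengths.
#'
#' @return Times in seconds.
#' @export
sensitivity_time_grid <- function() seq(0.001, 0.200, by = 0.001)

# profile values entering the quadrature (F2 discards the phase)
profile_values_scaled <- function(profile, use_phase = TRUE) {
  m <- profile$mxy
  if (!use_phase) m <- complex(real = Mod(m))
  m
}

#' Complex dephasing factor of a slice profile
#'
#' Computes `F(t) = integral M_xy(lambda z) exp(i gamma G_z z t) dz /
#' integral M_xy(lambda z) dz` on the echo-time grid `t` by trapezoidal
#' quadrature over the simulated slice profile. The model id selects how the
#' profile enters:
#'
#' * `"F1"`: no modeling, `F(t) = 1` (mono-exponential reference);
#' * `"F2"`: magnitude-only profile (`phi_xy` zeroed), nominal flip,
#'   `lambda = 1`;
#' * `"F3"`: full complex profile at the nominal flip angle, `lambda = 1`;
#' * `"F4"`: complex profile at the B1-scaled flip angle (pass a profile
#'   from [profile_at_xi()]) with the supplied slice scaling `lambda`;
#' * `"FT1"`: as F3/F4 but with a steady-state profile from
#'   [steady_state_profile()].
#'
#' `lambda` scaling is applied by scaling the sampling coordinates
#' (`z' = lambda z`), which after the substitution `u = lambda z` is exactly
#' equivalent to evaluating the unscaled factor at `t / lambda`; the
#' implementation uses this closed form, so no interpolation error enters.
#'
#' @param profile A `slice_profile` matching the model requirements.
#' @param gz Through-slice field gradient in microtesla per metre.
#' @param te Echo-time grid in seconds.
#' @param model One of `"F1"`, `"F2"`, `"F3"`, `"F4"`, `"FT1"`.
#' @param lambda Slice scaling factor (used by F4/FT1; default 1).
#' @param delta_omega0 Field offset at slice centre in rad/s; recorded in the
#'   result but excluded from F (global phase, irrelevant to `|F|`).
#' @return A `dephasing_factor` tibble with columns `te` and `f` (complex),
#'   normalized so `F(0) = 1`.
#' @export
#' @examples
#' p <- simulate_profile(rf_scale_to_flip(rf_sinc_hanning(), pi / 2), 8.29)
#' f3 <- dephasing_factor(p, gz = 100, te = acquisition_te_grid(), "F3")
#' head(Mod(f3$f))
dephasing_factor <- function(profile, gz, te, model = c("F3", "F1", "F2", "F4", "FT1"),
                             lambda = 1, delta_omega0 = 0) {
  model <- match.arg(model)
  stopifnot(inherits(profile, "slice_profile"))
  z <- profile$z
  dz <- z[2] - z[1]
  if (model == "F1") {
    f <- rep(complex(real = 1), length(te))
    return(new_dephasing_factor(te, f, model, gz, lambda, delta_omega0))
  }
  if (model %in% c("F2", "F3") && abs(lambda - 1) > 1e-12) {
    abort(sprintf("model %s is defined with lambda = 1.", model),
          class = "dephasr_invalid_argument")
  }
  if (model == "FT1" && attr(profile, "e1") == 0) {
    warn("FT1 requested on a profile with E1 = 0; result equals F3/F4.")
  }
  # aliasing guard: phase advance per z-step must stay below pi
  if (max(abs(.gamma * gz * 1e-6 * dz * te / lambda)) > pi) {
    abort("gamma * G_z * dz * max(te) exceeds pi per grid step; refine the z grid.",
          class = "dephasr_resolution_error")
  }
  m <- profile_values_scaled(profile, use_phase = model != "F2")
  w <- rep(1, length(z)); w[1] <- 0.5; w[length(z)] <- 0.5
  wm <- w * m
  kern <- exp(1i * .gamma * gz * 1e-6 * outer(z, te / lambda))
  f <- as.vector(t(kern) %*% wm)
  f0 <- sum(wm)
  new_dephasing_factor(te, f / f0, model, gz, lambda, delta_omega0)
}

new_dephasing_factor <- function(te, f, model, gz, lambda, delta_omega0 = 0) {
  out <- tibble(te = te, f = f)
  class(out) <- c("dephasing_factor", class(out))
  attr(out, "model") <- model
  attr(out, "gz") <- gz
  attr(out, "lambda") <- lambda
  attr(out, "delta_omega0") <- delta_omega0
  out
}

#' @export
print.dephasing_factor <- function(x, ...) {
  cat(sprintf("<dephasing_factor> %s, G_z = %.4g uT/m, lambda = %.4g, %d echoes\n",
              attr(x, "model"), attr(x, "gz"), attr(x, "lambda"), nrow(x)))
  invisible(x)
}

#' RMS difference between two dephasing factors
#'
#' `100 * sqrt(mean((|Fa| - |Fb|)^2))` over a common echo-time grid, the
#' figure of merit used throughout the sensitivity analysis.
#'
#' @param fa,fb `dephasing_factor` objects on identical grids.
#' @return RMSE in percent.
#' @export
rmse_between_factors <- function(fa, fb) {
  if (nrow(fa) != nrow(fb) || max(abs(fa$te - fb$te)) > 1e-12) {
    abort("factors must share the same echo-time grid.",
          class = "dephasr_invalid_argument")
  }
  100 * sqrt(mean((Mod(fa$f) - Mod(fb$f))^2))
}
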