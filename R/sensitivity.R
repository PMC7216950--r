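#' Sensitivity of the dephasing factor to its model parameters
#'
#' Deterministic parameter sweeps quantifying how much each ingredient of the
#' full dephasing model matters, as RMS differences (percent) between
#' dephasing factors on a common time grid:
#'
#' * `"phase"`: neglecting the through-slice phase — RMSE between the
#'   full-phase factor and the magnitude-only factor (F2) as a function of
#'   flip angle, for both slice-gradient polarities;
#' * `"b1"`: transmit-field scale — RMSE between the factor at `xi` (profile
#'   re-simulated at flip `alpha * xi`) and at `xi = 1`, per flip angle;
#' * `"lambda"`: slice scaling — RMSE between the factor with coordinate
#'   scaling `lambda` and with `lambda = 1`, at a strong gradient;
#' * `"lambda_gz"`: the physically reachable slice scaling — for each swept
#'   `G_z`, RMSE between the factor using `lambda = G_slice/(G_slice+G_z)`
#'   and `lambda = 1`;
#' * `"t1"`: neglecting saturation — RMSE between the steady-state factor
#'   (`FT1`) and the relaxation-free factor (F3) over `TR/T1`, with the flip
#'   angle tied to the Ernst angle.
#'
#' @param sweep Which parameter to sweep.
#' @param pulse Unscaled `rf_pulse` (default sinc-Hanning 2 ms, BWT 2.7).
#' @param g_slice Slice-select gradient magnitude in mT/m (default 8.29).
#' @param gz Through-slice gradient in microtesla/m (default 100; 500 for the
#'   `"lambda"` sweep).
#' @param te Comparison time grid (default [sensitivity_time_grid()]).
#' @param alphas Flip angles in degrees (defaults per sweep).
#' @param xis B1 scales for the `"b1"` sweep (default `seq(0.6, 1.4, 0.05)`).
#' @param lambdas Scalings for the `"lambda"` sweep (default
#'   `seq(0.8, 1.2, 0.05)`).
#' @param gzs Gradients for the `"lambda_gz"` sweep (default
#'   `seq(100, 500, 100)`).
#' @param tr_t1 TR/T1 ratios for the `"t1"` sweep (default `1:5`).
#' @param ernst_fractions Flip-angle fractions of the Ernst angle for the
#'   `"t1"` sweep (default `c(1, 0.8, 0.6)`).
#' @param z Position grid for the simulations.
#' @return A tibble with the swept parameter columns and an `rmse` column
#'   (percent), one row per swept point.
#' @export
#' @examples
#' \donttest{
#' sensitivity_sweep("phase", alphas = c(30, 90))
#' }
sensitivity_sweep <- function(sweep = c("phase", "b1", "lambda", "lambda_gz", "t1"),
                              pulse = rf_sinc_hanning(),
                              g_slice = 8.29, gz = NULL,
                              te = sensitivity_time_grid(),
                              alphas = NULL,
                              xis = seq(0.6, 1.4, by = 0.05),
                              lambdas = seq(0.8, 1.2, by = 0.05),
                              gzs = seq(100, 500, by = 100),
                              tr_t1 = 1:5,
                              ernst_fractions = c(1, 0.8, 0.6),
                              z = default_z_grid()) {
  sweep <- match.arg(sweep)
  sim <- function(alpha_rad, g) {
    simulate_profile(rf_scale_to_flip(pulse, alpha_rad), g, z)
  }
  switch(sweep,
    phase = {
      alphas <- alphas %||% seq(10, 90, by = 10)
      gz <- gz %||% 100
      grid <- expand.grid(alpha = alphas, polarity = c(1, -1))
      rmse <- purrr::pmap_dbl(grid, function(alpha, polarity) {
        p <- sim(alpha * pi / 180, polarity * g_slice)
        rmse_between_factors(
          dephasing_factor(p, gz, te, "F3"),
          dephasing_factor(p, gz, te, "F2"))
      })
      tibble(sweep = "phase", alpha = grid$alpha, polarity = grid$polarity,
             gz = gz, rmse = rmse)
    },
    b1 = {
      alphas <- alphas %||% c(30, 60, 90)
      gz <- gz %||% 100
      purrr::map_dfr(alphas, function(a) {
        ref <- dephasing_factor(sim(a * pi / 180, g_slice), gz, te, "F3")
        rmse <- purrr::map_dbl(xis, function(x) {
          px <- simulate_profile(rf_scale_to_flip(pulse, a * pi / 180, x),
                                 g_slice, z)
          rmse_between_factors(dephasing_factor(px, gz, te, "F4"), ref)
        })
        tibble(sweep = "b1", alpha = a, xi = xis, gz = gz, rmse = rmse)
      })
    },
    lambda = {
      alphas <- alphas %||% c(30, 90)
      gz <- gz %||% 500
      purrr::map_dfr(alphas, function(a) {
        p <- sim(a * pi / 180, g_slice)
        ref <- dephasing_factor(p, gz, te, "F4", lambda = 1)
        rmse <- purrr::map_dbl(lambdas, function(l) {
          rmse_between_factors(dephasing_factor(p, gz, te, "F4", lambda = l), ref)
        })
        tibble(sweep = "lambda", alpha = a, lambda = lambdas, gz = gz,
               rmse = rmse)
      })
    },
    lambda_gz = {
      alphas <- alphas %||% c(30, 90)
      purrr::map_dfr(alphas, function(a) {
        p <- sim(a * pi / 180, g_slice)
        rmse <- purrr::map_dbl(gzs, function(g) {
          lam <- lambda_factor(g_slice, g)
          rmse_between_factors(
            dephasing_factor(p, g, te, "F4", lambda = lam),
            dephasing_factor(p, g, te, "F4", lambda = 1))
        })
        tibble(sweep = "lambda_gz", alpha = a, gz = gzs,
               lambda = lambda_factor(g_slice, gzs), rmse = rmse)
      })
    },
    t1 = {
      gz <- gz %||% 100
      grid <- expand.grid(tr_t1 = tr_t1, fraction = ernst_fractions)
      rmse <- purrr::pmap_dbl(grid, function(tr_t1, fraction) {
        e1 <- exp(-tr_t1)
        a <- fraction * acos(e1)
        p <- sim(a, g_slice)
        rmse_between_factors(
          dephasing_factor(steady_state_profile(p, e1), gz, te, "FT1"),
          dephasing_factor(p, gz, te, "F3"))
      })
      tibble(sweep = "t1", tr_t1 = grid$tr_t1,
             ernst_fraction = grid$fraction, gz = gz, rmse = rmse)
    })
}
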