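# Bloch simulations are the expensive step; cache profiles shared across
# test files (keyed by flip angle, polarity and pulse) for the session.

.dephasr_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .dephasr_test_cache)) {
    assign(key, force(expr), envir = .dephasr_test_cache)
  }
  get(key, envir = .dephasr_test_cache)
}

std_pulse <- function() cached("pulse_sh", rf_sinc_hanning())

# standard sinc-Hanning profile at 8.29 mT/m
std_profile <- function(alpha_deg, pol = 1) {
  cached(sprintf("prof_%g_%d", alpha_deg, pol),
         simulate_profile(rf_scale_to_flip(std_pulse(), alpha_deg * pi / 180),
                          pol * 8.29))
}

std_xi_grid <- function() {
  cached("xigrid_90",
         xi_profile_grid(std_pulse(), 8.29, pi / 2, xi_range = c(0.6, 1.4)))
}

# coarse z grid keeps refinement comparisons cheap
short_z <- function(dz = 80e-6, halfwidth = 0.02) {
  seq(-halfwidth, halfwidth, by = dz)
}
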