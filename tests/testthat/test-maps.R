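test_that("temporal unwrapping removes 2 pi jumps along echoes", {
  te <- seq(0.004, 0.059, by = 0.005)
  true_phase <- 2 * pi * 80 * te # wraps several times
  wrapped <- Arg(exp(1i * true_phase))
  u <- unwrap_echo_phase(wrapped)
  expect_equal(u, true_phase, tolerance = 1e-12)
  # array form
  arr <- array(rep(wrapped, each = 4), c(2, 2, length(te)))
  ua <- unwrap_echo_phase(arr)
  expect_equal(ua[1, 2, ], true_phase, tolerance = 1e-12)
})

test_that("field-offset fit recovers exact slopes", {
  te <- seq(0.004, 0.029, by = 0.005)
  phase <- array(rep(2 * pi * 50 * te, each = 8), c(2, 2, 2, 6))
  dw0 <- fit_delta_omega0(phase, te)
  expect_equal(as.vector(dw0), rep(2 * pi * 50, 8), tolerance = 1e-10)
  # constant phase: zero slope
  expect_equal(as.vector(fit_delta_omega0(array(1.3, c(2, 2, 1, 6)), te)),
               rep(0, 4))
  # two-echo variant
  dw2 <- fit_delta_omega0(phase, te, method = "two_echo")
  expect_equal(as.vector(dw2), rep(2 * pi * 50, 8), tolerance = 1e-10)
  expect_error(fit_delta_omega0(phase, te, n_echoes = 10),
               class = "dephasr_invalid_argument")
})

test_that("field-offset fit is unbiased to 1% at SNR 50", {
  te <- seq(0.004, 0.029, by = 0.005)
  slope <- 2 * pi * 50
  nvox <- 4000
  phases <- withr::with_seed(42, {
    matrix(rep(slope * te, each = nvox), nvox, 6) +
      matrix(rnorm(nvox * 6, sd = 1 / 50), nvox, 6)
  })
  est <- fit_delta_omega0(array(phases, c(nvox, 1, 1, 6)), te)
  expect_lt(abs(mean(est) - slope) / slope, 0.01)
})

test_that("gradient map differentiates the field map exactly for polynomials", {
  gam <- gyromagnetic_ratio()
  dz <- 4e-3
  nz <- 9
  zc <- (seq_len(nz) - 1) * dz
  # linear field from a 100 uT/m gradient: exact everywhere incl. boundaries
  lin <- array(rep(gam * 100e-6 * zc, each = 4), c(2, 2, nz))
  gl <- gz_map_from_fieldmap(lin, dz)
  expect_equal(as.vector(gl), rep(100, 4 * nz), tolerance = 1e-9)
  # quadratic field: central difference exact at interior slices
  a <- 3e5
  quad <- array(rep(a * zc^2, each = 4), c(2, 2, nz))
  gq <- gz_map_from_fieldmap(quad, dz)
  for (i in 2:(nz - 1)) {
    expect_equal(gq[1, 1, i], 2 * a * zc[i] / gam * 1e6, tolerance = 1e-9)
  }
  expect_error(gz_map_from_fieldmap(lin[, , 1, drop = FALSE], dz),
               class = "dephasr_invalid_argument")
})

test_that("gradient map tracks a smooth field within the discretization bound", {
  gam <- gyromagnetic_ratio()
  dz <- 4e-3
  nz <- 25
  zc <- (seq_len(nz) - 1) * dz
  k <- 2 * pi / 0.12
  fld <- array(rep(1000 * sin(k * zc), each = 1), c(1, 1, nz))
  g <- gz_map_from_fieldmap(fld, dz)
  truth <- 1000 * k * cos(k * zc) / gam * 1e6
  bound <- 1000 * k^3 * dz^2 / 6 / gam * 1e6 # |f'''| h^2 / 6 for central diff
  interior <- 2:(nz - 1)
  expect_lt(max(abs(g[1, 1, interior] - truth[interior])), bound * 1.01)
  # per-slice-constant field has identically zero gradient
  cst <- array(rep(rep(7, nz), each = 4), c(2, 2, nz))
  expect_true(all(gz_map_from_fieldmap(cst, dz) == 0))
})

test_that("B1 normalization scales, clips, and counts", {
  m <- array(900, c(2, 2, 2))
  xi <- normalize_b1(m, 900)
  expect_true(all(xi == 1))
  expect_equal(attr(xi, "n_clipped"), 0L)
  m[1, 1, 1] <- 0.49 * 900
  expect_message(xi2 <- normalize_b1(m, 900), "clipped 1")
  expect_equal(xi2[1, 1, 1], 0.5)
  expect_equal(attr(xi2, "n_clipped"), 1L)
  expect_error(normalize_b1(m, -1), class = "dephasr_invalid_argument")
})

test_that("navigator correction is an isometry with the expected group structure", {
  withr::local_seed(7)
  d <- c(8, 2, 3, 16) # lines x channels x echoes x readout
  k <- array(complex(real = rnorm(prod(d)), imaginary = rnorm(prod(d))), d)
  te <- c(0.01, 0.02, 0.03)
  phi <- matrix(rnorm(16, sd = 0.3), 8, 2)
  nav <- structure(list(phi = phi, te_navi = 0.0654), class = "navigator_series")
  out <- navigator_correct(k, nav, te)
  expect_equal(Mod(out), Mod(k), tolerance = 1e-12)
  # identical navigator phases leave the data unchanged
  nav0 <- structure(list(phi = matrix(0.7, 8, 2), te_navi = 0.0654),
                    class = "navigator_series")
  expect_equal(navigator_correct(k, nav0, te), k, tolerance = 1e-12)
  # applying twice equals applying the doubled phase difference
  twice <- navigator_correct(out, nav, te)
  nav2 <- structure(list(phi = 2 * phi, te_navi = 0.0654),
                    class = "navigator_series")
  expect_equal(twice, navigator_correct(k, nav2, te), tolerance = 1e-10)
  # at TE = TE_navi the full measured difference is applied
  out_navi <- navigator_correct(k[, , 1, , drop = FALSE], nav, 0.0654)
  manual <- k[, , 1, ] * array(exp(-1i * sweep(phi, 2, phi[1, ])), d[c(1, 2, 4)])
  expect_equal(out_navi[, , 1, ], manual, tolerance = 1e-12)
})

test_that("navigator mean phase uses the centre of the readout", {
  d <- c(4, 1, 64)
  nav_ro <- array(complex(modulus = 1, argument = 0.4), d)
  # corrupt the outer readout portions; the centre 25% decides the phase
  nav_ro[, , c(1:20, 45:64)] <- complex(modulus = 1, argument = -2)
  ns <- navigator_series(nav_ro, 0.0654)
  expect_equal(as.vector(ns$phi), rep(0.4, 4), tolerance = 1e-12)
})

test_that("navigator correction removes respiratory-like ghosting", {
  n <- 64
  img <- matrix(0, n, n)
  img[20:44, 24:40] <- 1 # simple block object
  te <- c(0.005, 0.02, 0.04)
  drift <- 0.3 * sin(2 * pi * seq_len(n) / 40)
  sim <- forward_kspace_with_drift(img, te, drift, te_navi = 0.0654)
  recon <- function(k2) {
    n <- nrow(k2)
    Mod(mvfft(t(mvfft(t(k2), inverse = TRUE)), inverse = TRUE)) / n^2
  }
  corrected <- navigator_correct(sim$kspace, sim$nav, te)
  for (e in seq_along(te)) {
    clean <- recon(sim$kspace_clean[, 1, e, ])
    err_raw <- max(abs(recon(sim$kspace[, 1, e, ]) - clean))
    err_cor <- max(abs(recon(corrected[, 1, e, ]) - clean))
    expect_lt(err_cor, err_raw / 10)
  }
})
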