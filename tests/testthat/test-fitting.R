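test_that("noiseless mono-exponential decay is recovered to numerical precision", {
  te <- acquisition_te_grid()
  y <- 3.2 * exp(-20 * te)
  for (model in c("S1", "S3")) {
    src <- if (model == "S3") std_profile(30) else NULL
    fit <- fit_r2star(echo_series(te, y), model, gz = 0, profile_source = src)
    expect_equal(fit$r2star, 20, tolerance = 1e-6)
    expect_equal(fit$s0, 3.2, tolerance = 1e-6)
  }
})

test_that("with F = 1 all models nest down to the mono-exponential fit", {
  te <- acquisition_te_grid()
  y <- withr::with_seed(3, 5 * exp(-30 * te) * (1 + rnorm(length(te), sd = 0.02)))
  base <- fit_r2star(echo_series(te, y), "S1")
  s2 <- fit_r2star(echo_series(te, y), "S2", gz = 0,
                   profile_source = std_profile(30))
  s3 <- fit_r2star(echo_series(te, y), "S3", gz = 0,
                   profile_source = std_profile(30))
  s4 <- fit_r2star(echo_series(te, y,
                               protocol = list(g_slice = 8.29)), "S4",
                   gz = 0, xi = 1, profile_source = std_xi_grid())
  for (fit in list(s2, s3, s4)) {
    expect_equal(fit$r2star, base$r2star, tolerance = 1e-6)
    expect_equal(fit$s0, base$s0, tolerance = 1e-6)
  }
})

test_that("fits are equivariant under magnitude rescaling", {
  te <- acquisition_te_grid()
  y <- withr::with_seed(4, 2 * exp(-40 * te) * (1 + rnorm(length(te), sd = 0.01)))
  f1 <- fit_r2star(echo_series(te, y), "S1")
  f2 <- fit_r2star(echo_series(te, 100 * y), "S1")
  expect_equal(f2$r2star, f1$r2star, tolerance = 1e-7)
  expect_equal(f2$s0, 100 * f1$s0, tolerance = 1e-6)
  # MWF likewise scale-free
  te27 <- 2.37e-3 + 2.2e-3 * (0:26)
  ym <- 0.15 * exp(-te27 / 0.010) + 0.85 * exp(-te27 / 0.060)
  m1 <- attr(fit_mwf(echo_series(te27, ym)), "mwf")
  m2 <- attr(fit_mwf(echo_series(te27, 50 * ym)), "mwf")
  expect_equal(m1, m2, tolerance = 1e-9)
})

test_that("forward-simulated dephased decay is inverted by the matching model", {
  te <- acquisition_te_grid()
  grid <- std_xi_grid()
  gz <- 100
  xi <- 1.1
  lam <- lambda_factor(8.29, gz)
  fmag <- Mod(dephasing_factor(profile_at_xi(grid, xi), gz, te, "F4",
                               lambda = lam)$f)
  y <- 10 * exp(-25 * te) * fmag
  series <- echo_series(te, y, protocol = list(g_slice = 8.29))
  s4 <- fit_r2star(series, "S4", gz = gz, xi = xi, profile_source = grid)
  expect_lt(abs(s4$r2star - 25), 0.1)
  # the uncorrected model overestimates the decay rate
  s1 <- fit_r2star(series, "S1")
  expect_gt(s1$r2star, 25 + 1)
})

test_that("tidy/glance/augment expose the fit in broom style", {
  te <- acquisition_te_grid()
  fit <- fit_r2star(echo_series(te, 3 * exp(-20 * te)), "S1")
  td <- tidy(fit)
  expect_equal(td$term, c("s0", "r2star"))
  gl <- glance(fit)
  expect_true(gl$convergence)
  au <- augment(fit)
  expect_equal(au$fitted, au$magnitude, tolerance = 1e-6)
})

test_that("all-zero voxels are masked, not fit", {
  te <- acquisition_te_grid()
  fit <- fit_r2star(echo_series(te, rep(0, length(te))), "S1")
  expect_true(fit$masked)
  expect_true(is.na(fit$r2star))
  # map level: an empty mask yields empty output without error
  vol <- array(0, c(2, 2, 2, length(te)))
  maps <- field_maps(gz = array(0, c(2, 2, 2)), xi = array(1, c(2, 2, 2)),
                     slice_spacing = 4e-3)
  res <- fit_r2star_map(vol, maps, "S1",
                        protocol = list(te = te, g_slice = 8.29,
                                        alpha = pi / 2))
  expect_true(all(is.na(res$r2star)))
  expect_equal(sum(res$mask), 0)
})

test_that("uncorrected R2* inflates monotonically with the through-slice gradient", {
  te <- acquisition_te_grid()
  grid <- xi_profile_grid(std_pulse(), 8.29, 30 * pi / 180,
                          xi_range = c(0.95, 1.05))
  lk <- dephasing_lookup(grid, c(0, 150), te, "S4")
  gzs <- seq(0, 150, by = 25)
  r1 <- vapply(gzs, function(g) {
    y <- as.vector(lookup_f_mag(lk, g, 1)) * exp(-20 * te)
    fit_r2star(echo_series(te, y), "S1")$r2star
  }, numeric(1))
  expect_true(all(diff(r1) > 0))
  expect_gt(r1[length(r1)] / r1[1], 3) # strong inflation at 150 uT/m
})

test_that("two-compartment spectra give the expected myelin water fraction", {
  te <- 2.37e-3 + 2.2e-3 * (0:26)
  # single compartment at 60 ms: no myelin water
  single <- fit_mwf(echo_series(te, exp(-te / 0.060)))
  expect_equal(attr(single, "mwf"), 0, tolerance = 1e-9)
  # 15% at 10 ms / 85% at 60 ms
  y <- 0.15 * exp(-te / 0.010) + 0.85 * exp(-te / 0.060)
  two <- fit_mwf(echo_series(te, y))
  expect_equal(attr(two, "mwf"), 0.15, tolerance = 0.01)
  expect_true(all(two$amplitude >= 0))
})

test_that("dephasing correction removes the MWF bias from through-slice gradients", {
  te <- 2.37e-3 + 2.2e-3 * (0:26)
  y <- 0.15 * exp(-te / 0.010) + 0.85 * exp(-te / 0.060)
  # white-matter-like gradients: uncorrected MWF is biased low, corrected
  # fits recover the truth
  for (gz in c(20, 40, 60)) {
    fmag <- Mod(dephasing_factor(std_profile(90), gz, te, "F3")$f)
    corrected <- fit_mwf(echo_series(te, y * fmag), f = fmag)
    uncorrected <- fit_mwf(echo_series(te, y * fmag))
    expect_lt(abs(attr(corrected, "mwf") - 0.15), 0.02)
    expect_lt(attr(uncorrected, "mwf"), attr(corrected, "mwf") - 0.02)
  }
  # at very strong gradients the uncorrected estimate breaks down entirely
  # while the corrected fit still recovers the truth
  fmag <- Mod(dephasing_factor(std_profile(90), 100, te, "F3")$f)
  corrected <- fit_mwf(echo_series(te, y * fmag), f = fmag)
  expect_lt(abs(attr(corrected, "mwf") - 0.15), 0.02)
})

test_that("echoes near dephasing nulls are excluded and degenerate fits flagged", {
  te <- 2.37e-3 + 2.2e-3 * (0:26)
  fmag <- c(rep(1, 20), rep(0.01, 7)) # last echoes below the floor
  fit <- fit_mwf(echo_series(te, exp(-te / 0.05)), f = fmag)
  expect_equal(attr(fit, "n_excluded"), 7L)
  all_dead <- fit_mwf(echo_series(te, exp(-te / 0.05)), f = rep(0.01, 27))
  expect_true(attr(all_dead, "flagged"))
  expect_true(is.na(attr(all_dead, "mwf")))
})
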