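# RF excitation pulse envelopes.
#
# A pulse is a tibble with columns `t` (s) and `b1` (microtesla) plus
# attributes describing its construction. Envelopes are built with a unit
# time-integral (gamma * integral(B1 dt) == 1 rad) and only acquire physical
# amplitude through rf_scale_to_flip().

new_rf_pulse <- function(t, b1, shape, t_pulse, dt, bwt = NA_real_,
                         sigma = NA_real_, alpha = NA_real_, xi = 1) {
  out <- tibble(t = t, b1 = b1)
  class(out) <- c("rf_pulse", class(out))
  attr(out, "shape") <- shape
  attr(out, "t_pulse") <- t_pulse
  attr(out, "dt") <- dt
  attr(out, "bwt") <- bwt
  attr(out, "sigma") <- sigma
  attr(out, "alpha") <- alpha # prescribed flip (rad), NA until scaled
  attr(out, "xi") <- xi
  out
}

# sample grid: n = round(t_pulse/dt) points spanning [0, t_pulse] so that the
# windowed envelope is exactly zero at both stored endpoints and exactly
# symmetric about t_pulse/2
pulse_time_grid <- function(t_pulse, dt) {
  if (!is.numeric(t_pulse) || t_pulse <= 0 || !is.numeric(dt) || dt <= 0) {
    abort("`t_pulse` and `dt` must be positive.", class = "dephasr_invalid_argument")
  }
  n <- round(t_pulse / dt)
  if (n < 100) {
    abort("`dt` must divide the pulse into at least 100 samples.",
          class = "dephasr_resolution_error")
  }
  seq(0, t_pulse, length.out = n)
}

# trapezoid integral on the sample grid
trapz_integral <- function(t, y) sum((head(y, -1) + tail(y, -1)) / 2 * diff(t))

unit_area <- function(t, y) y / trapz_integral(t, y)

#' Sinc envelope with Hanning window
#'
#' Constructs a sinc-shaped RF excitation envelope apodized with a Hanning
#' window spanning the full pulse duration, the standard vendor shape for 2D
#' slice-selective excitation. The unwindowed sinc term is
#' `sin(pi * BWT * tau / T) / (pi * BWT * tau / T)` with `tau = t - T/2`, so
#' the bandwidth-time product `bwt` counts total excitation
#' bandwidth x duration.
#'
#' The returned envelope has unit time-integral; scale it to a flip angle
#' with [rf_scale_to_flip()].
#'
#' @param t_pulse Pulse duration in seconds.
#' @param bwt Bandwidth-time product (dimensionless, >= 1).
#' @param dt Sampling step in seconds; must divide `t_pulse` into at least
#'   100 samples.
#' @return An `rf_pulse` tibble with columns `t` (s) and `b1`.
#' @export
#' @examples
#' p <- rf_sinc_hanning(2e-3, 2.7, 2e-6)
#' nrow(p)
rf_sinc_hanning <- function(t_pulse = 2e-3, bwt = 2.7, dt = 2e-6) {
  if (!is.numeric(bwt) || bwt < 1) {
    abort("`bwt` must be >= 1.", class = "dephasr_invalid_argument")
  }
  t <- pulse_time_grid(t_pulse, dt)
  tau <- t - t_pulse / 2
  x <- pi * bwt * tau / t_pulse
  s <- ifelse(abs(x) < 1e-12, 1, sin(x) / x)
  w <- 0.5 * (1 - cos(2 * pi * t / t_pulse))
  new_rf_pulse(t, unit_area(t, s * w), "sinc_hanning", t_pulse, dt, bwt = bwt)
}

#' Truncated Gaussian envelope
#'
#' Gaussian RF envelope `exp(-(t - T/2)^2 / (2 sigma^2))`, hard-truncated to
#' `[0, t_pulse]` and centred at `t_pulse/2`, with unit time-integral.
#'
#' @param t_pulse Pulse duration in seconds.
#' @param sigma Gaussian width in seconds, `0 < sigma < t_pulse`.
#' @param dt Sampling step in seconds.
#' @return An `rf_pulse` tibble.
#' @export
rf_gaussian <- function(t_pulse = 2e-3, sigma = 280e-6, dt = 2e-6) {
  if (!is.numeric(sigma) || sigma <= 0 || sigma >= t_pulse) {
    abort("`sigma` must satisfy 0 < sigma < t_pulse.",
          class = "dephasr_invalid_argument")
  }
  t <- pulse_time_grid(t_pulse, dt)
  env <- exp(-(t - t_pulse / 2)^2 / (2 * sigma^2))
  new_rf_pulse(t, unit_area(t, env), "gaussian", t_pulse, dt, sigma = sigma)
}

#' Scale a pulse to a target flip angle
#'
#' Multiplies the envelope amplitude so that on-resonance spins at the slice
#' centre are rotated by exactly `alpha * xi` radians:
#' `gamma * integral(B1 dt) = alpha * xi` (trapezoid rule on the sample
#' grid). `xi` is the local transmit-field (B1+) scale from a normalized B1
#' map; `xi = 1` gives the nominal flip angle.
#'
#' @param pulse An `rf_pulse`.
#' @param alpha Prescribed flip angle in radians.
#' @param xi Transmit-field scale (default 1).
#' @return The scaled `rf_pulse`, with `b1` in microtesla.
#' @export
rf_scale_to_flip <- function(pulse, alpha, xi = 1) {
  stopifnot(inherits(pulse, "rf_pulse"))
  eff <- alpha * xi
  if (!is.numeric(eff) || eff <= 0 || eff > pi) {
    abort("`alpha * xi` must lie in (0, pi]; over-rotation is unsupported.",
          class = "dephasr_invalid_argument")
  }
  area <- trapz_integral(pulse$t, pulse$b1) # in (uT s) units of current scale
  scale <- eff / (.gamma * area * 1e-6)     # b1 stored in uT
  out <- pulse
  out$b1 <- pulse$b1 * scale
  attr(out, "alpha") <- alpha
  attr(out, "xi") <- xi
  out
}

#' Flip angle delivered by a pulse
#'
#' On-resonance rotation `gamma * integral(B1 dt)` in radians, with `b1`
#' interpreted in microtesla.
#'
#' @param pulse An `rf_pulse`.
#' @return Flip angle in radians.
#' @export
rf_flip_integral <- function(pulse) {
  .gamma * trapz_integral(pulse$t, pulse$b1) * 1e-6
}

#' Read / write pulses as two-column text
#'
#' Plain-text serialization: two whitespace-separated columns `t` (s) and
#' `b1` (microtesla), one sample per line, `#`-prefixed header lines carrying
#' the construction attributes.
#'
#' @param pulse An `rf_pulse`.
#' @param path File path.
#' @return `write_rf_pulse()` returns `path` invisibly; `read_rf_pulse()`
#'   returns an `rf_pulse`.
#' @export
write_rf_pulse <- function(pulse, path) {
  stopifnot(inherits(pulse, "rf_pulse"))
  hdr <- sprintf(
    "# shape=%s t_pulse=%.12g dt=%.12g bwt=%.12g sigma=%.12g alpha=%.12g xi=%.12g",
    attr(pulse, "shape"), attr(pulse, "t_pulse"), attr(pulse, "dt"),
    attr(pulse, "bwt"), attr(pulse, "sigma"), attr(pulse, "alpha"),
    attr(pulse, "xi"))
  body <- sprintf("%.15e %.15e", pulse$t, pulse$b1)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_rf_pulse
#' @export
read_rf_pulse <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")][1]
  kv <- strsplit(sub("^#\\s*", "", hdr), "\\s+")[[1]]
  vals <- setNames(
    sub("^[^=]+=", "", kv),
    sub("=.*$", "", kv))
  num <- function(k) suppressWarnings(as.numeric(vals[[k]]))
  body <- lines[!startsWith(lines, "#")]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  new_rf_pulse(m[, 1], m[, 2], vals[["shape"]], num("t_pulse"), num("dt"),
               bwt = num("bwt"), sigma = num("sigma"), alpha = num("alpha"),
               xi = num("xi"))
}

#' Pulse description from a config block
#'
#' Builds a pulse from a list like `list(shape = "sinc_hanning",
#' t_pulse = 2e-3, bwt = 2.7, dt = 2e-6)` or
#' `list(shape = "gaussian", t_pulse = 2e-3, sigma = 280e-6, dt = 2e-6)`.
#'
#' @param desc Named list with `shape`, `t_pulse`, `dt` and `bwt` or `sigma`.
#' @return An `rf_pulse` (unscaled).
#' @export
rf_pulse_from_config <- function(desc) {
  shape <- desc$shape %||% abort("pulse config needs a `shape`.",
                                 class = "dephasr_config_error")
  dt <- desc$dt %||% 2e-6
  switch(shape,
    sinc_hanning = rf_sinc_hanning(desc$t_pulse, desc$bwt, dt),
    gaussian = rf_gaussian(desc$t_pulse, desc$sigma, dt),
    abort(sprintf("unknown pulse shape '%s'", shape),
          class = "dephasr_config_error"))
}

#' @export
print.rf_pulse <- function(x, ...) {
  cat(sprintf("<rf_pulse> %s, T = %.3g ms, %d samples%s\n",
              attr(x, "shape"), attr(x, "t_pulse") * 1e3, nrow(x),
              if (is.na(attr(x, "alpha"))) " (unscaled)"
              else sprintf(", flip = %.1f deg x xi = %.3g",
                           attr(x, "alpha") * 180 / pi, attr(x, "xi"))))
  invisible(x)
}
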