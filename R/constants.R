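#' Proton gyromagnetic ratio
#'
#' The gyromagnetic ratio of the proton used throughout the package,
#' gamma = 2.6752e8 rad s^-1 T^-1 (gamma / 2 pi ~ 42.577 MHz/T). All
#' conversions between field gradients and precession frequencies use this
#' single constant.
#'
#' @return Gyromagnetic ratio in rad s^-1 T^-1.
#' @export
#' @examples
#' gyromagnetic_ratio() / (2 * pi) / 1e6 # MHz/T
gyromagnetic_ratio <- function() 2.6752e8

# internal shorthand
.gamma <- 2.6752e8
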