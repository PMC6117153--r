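# Unit conventions used throughout the package:
#   lengths mm, times ms, diffusivities mm^2/s, gradient amplitudes G/cm.
# All conversions to SI happen here, nowhere else.

#' Gyromagnetic ratio of the proton
#'
#' Fixed at 2.675e8 rad s^-1 T^-1 (1H).
#' @format Numeric scalar, rad s^-1 T^-1.
#' @export
GAMMA_1H <- 2.675e8

#' Convert acquisition units to SI
#'
#' Helpers converting the interface units (ms, G/cm) to SI (s, T/m).
#' 1 G/cm = 1e-4 T / 1e-2 m = 1e-2 T/m.
#'
#' @param ms time in milliseconds.
#' @param gauss_per_cm gradient amplitude in G/cm.
#' @return Time in seconds, or gradient in T/m.
#' @keywords internal
ms_to_s <- function(ms) ms * 1e-3

#' @rdname ms_to_s
#' @keywords internal
gauss_cm_to_tesla_m <- function(gauss_per_cm) gauss_per_cm * 1e-2

#' Stejskal-Tanner b-value for rectangular gradient pulses
#'
#' Computes b = gamma^2 G^2 delta^2 (Delta - delta/3) for an idealised
#' pulsed-gradient spin echo with rectangular gradient lobes, returned in
#' s/mm^2. This is the weighting contributed by the motion-probing
#' gradients alone; cross terms with imaging gradients are not modelled,
#' so a scanner-calculated b-value can be larger. Supply such an external
#' value through the `b_nominal` field of [acq_params()] when available.
#'
#' @param delta_small gradient pulse duration, ms (> 0).
#' @param delta_big leading-edge pulse separation, ms (>= delta_small).
#' @param G gradient amplitude, G/cm (>= 0).
#' @return b-value in s/mm^2.
#' @examples
#' stejskal_tanner_b(5, 26, 4.2)   # ~76.8 s/mm^2
#' @export
stejskal_tanner_b <- function(delta_small, delta_big, G) {
  if (any(delta_small <= 0)) {
    stop("gradient pulse duration delta_small must be > 0", call. = FALSE)
  }
  if (any(delta_big < delta_small)) {
    stop("pulse separation delta_big must be >= delta_small", call. = FALSE)
  }
  if (any(G < 0)) stop("gradient amplitude G must be >= 0", call. = FALSE)
  d <- ms_to_s(delta_small)
  D <- ms_to_s(delta_big)
  g <- gauss_cm_to_tesla_m(G)
  b_si <- GAMMA_1H^2 * g^2 * d^2 * (D - d / 3) # s/m^2
  b_si * 1e-6                                  # s/mm^2
}
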