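#' Generate a synthetic unipolar electrogram with known AT and RT
#'
#' Builds a waveform from Gaussian-derivative wavelets so that the steepest
#' *negative* slope occurs exactly at the activation time `at` (QRS) and the
#' steepest *positive* slope exactly at the recovery time `rt` (T wave) —
#' the Wyatt convention read off a unipolar electrogram.  With the QRS
#' modelled as `A_q g'(t; at, w_q)` the slope is `A_q g''`, whose global
#' minimum sits at `at`; the T wave `-A_t g'(t; rt, w_t)` has slope maximum
#' at `rt`.  Ground truth is attached so detector error can be measured.
#'
#' @param at,rt activation and recovery time (ms), `0 < at < rt`.
#' @param fs sampling rate (samples/s).
#' @param noise_sd additive Gaussian noise SD (a.u.; QRS amplitude is 1).
#' @param duration record length (ms); default `rt + 150`.
#' @param qrs_width,t_width Gaussian widths (ms) of the two wavelets.
#' @param t_amp T-wave amplitude relative to the unit QRS amplitude.
#' @param seed RNG seed for the noise draw.
#' @return An [electrogram()] object with attribute `truth`
#'   (`list(at, rt, ari)`).
#' @examples
#' e <- gen_electrogram(at = 50, rt = 350, fs = 1000, noise_sd = 0)
#' attr(e, "truth")$ari  # 300 ms
#' @export
gen_electrogram <- function(at, rt, fs = 1000, noise_sd = 0.02,
                            duration = rt + 150, qrs_width = 8,
                            t_width = 10, t_amp = 0.5, seed = 1L) {
  if (rt <= at) stop("recovery must follow activation (rt > at)")
  if (at <= 0 || rt >= duration) stop("require 0 < at < rt < duration")
  t <- seq(0, duration, by = 1000 / fs)           # ms
  dgauss <- function(t, c, w) {
    # first derivative of a Gaussian, scaled to unit peak amplitude
    -(t - c) / w^2 * exp(-(t - c)^2 / (2 * w^2)) * w * exp(0.5)
  }
  v <- dgauss(t, at, qrs_width) - t_amp * dgauss(t, rt, t_width)
  if (noise_sd > 0)
    v <- v + with_seed(seed, rnorm(length(v), sd = noise_sd))
  e <- electrogram(v, fs = fs)
  attr(e, "truth") <- list(at = at, rt = rt, ari = rt - at)
  e
}
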