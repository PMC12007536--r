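#' Gaussian MT pulse waveform
#'
#' Piecewise-constant RF amplitude samples omega1 (rad/s) for a Gaussian MT
#' pulse of duration `tau`, truncated at +/- 2.5 sigma (sigma = tau/5) and
#' renormalized so that the discrete flip-angle integral
#' `sum(omega1 * dt)` equals `fa_mt` in radians exactly.
#'
#' @param fa_mt flip angle of the MT pulse (degrees).
#' @param tau pulse duration (s).
#' @param n_segments number of piecewise-constant segments (>= 16).
#' @return Numeric vector of `n_segments` omega1 samples (rad/s), with
#'   attribute `dt` = `tau / n_segments`.
#' @export
gaussian_pulse_waveform <- function(fa_mt, tau, n_segments = 64L) {
  stopifnot(tau > 0, n_segments >= 16, fa_mt >= 0)
  dt <- tau / n_segments
  t <- (seq_len(n_segments) - 0.5) * dt
  sigma <- tau / 5
  shape <- exp(-((t - tau / 2)^2) / (2 * sigma^2))
  fa_rad <- fa_mt * pi / 180
  w1 <- if (fa_rad == 0) rep(0, n_segments) else shape * fa_rad / (sum(shape) * dt)
  attr(w1, "dt") <- dt
  w1
}

# RF energy integral of one pulse: sum(omega1^2 * dt), units rad^2/s.
# Proportional to fa_mt^2 at fixed shape/duration.
pulse_energy <- function(fa_mt, tau, n_segments = 64L) {
  w1 <- gaussian_pulse_waveform(fa_mt, tau, n_segments)
  sum(w1^2) * attr(w1, "dt")
}
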