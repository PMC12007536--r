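#' Pulsed MT preparation
#'
#' Describes the off-resonance saturation train played before each slice
#' excitation: `n_pulses` Gaussian pulses of duration `tau` and flip angle
#' `fa_mt`, separated by gaps `delta_t`, at offset `offset_hz`. With
#' `polarity = "alternating"` (dual irradiation) the sign of the offset flips
#' on successive pulses, which quenches the build-up of dipolar order.
#'
#' @param offset_hz irradiation offset frequency (Hz, > 0).
#' @param polarity `"positive"` (single-sided) or `"alternating"` (dual).
#' @param n_pulses number of MT pulses per preparation.
#' @param tau pulse duration (s).
#' @param delta_t inter-pulse gap (s).
#' @param fa_mt MT pulse flip angle (degrees).
#' @param shape pulse shape (only `"gaussian"`).
#' @return Object of class `mt_prep`.
#' @export
mt_prep <- function(offset_hz = 3000, polarity = c("alternating", "positive"),
                    n_pulses = 7L, tau = 1e-3, delta_t = 0.3e-3, fa_mt = 596,
                    shape = "gaussian") {
  polarity <- match.arg(polarity)
  shape <- match.arg(shape, "gaussian")
  stopifnot(offset_hz > 0, n_pulses >= 0, tau > 0, delta_t >= 0, fa_mt >= 0)
  structure(list(offset_hz = offset_hz, polarity = polarity,
                 n_pulses = as.integer(n_pulses), tau = tau,
                 delta_t = delta_t, fa_mt = fa_mt, shape = shape),
            class = "mt_prep")
}

#' MT-diffusion sequence protocol
#'
#' One MT preparation precedes the diffusion-weighted 2D-EPI acquisition of
#' each slice, so the sequence repetition time is `tr_mt * n_slices` and the
#' dual (MT-on + MT-off) acquisition lasts
#' `tr_mt * n_slices * (n_directions + n_b0) * 2`. Defaults are the fixed
#' protocol parameters of the optimization study (2.6 mm isotropic, 62 slices,
#' TE 58 ms, b = 1500 s/mm^2, 30 directions + 1 b0), with a 3.2 W/kg head SAR
#' limit operated at 97% and a 10-minute total scan-time budget.
#'
#' @param prep an [mt_prep()].
#' @param tr_mt per-slice repetition time (s); must leave room for the
#'   preparation train.
#' @param n_slices,n_directions,n_b0 acquisition counts.
#' @param te echo time (s, metadata).
#' @param b_value diffusion weighting (s/mm^2).
#' @param resolution voxel size (mm, metadata).
#' @param t_exc,t_ref excitation / refocusing pulse durations (s, metadata;
#'   carried for completeness, not simulated).
#' @param sar_limit SAR limit (W/kg).
#' @param sar_target_fraction fraction of the limit to operate at.
#' @param max_scan_time scan-time constraint for the dual acquisition (s).
#' @return Object of class `mt_protocol`.
#' @export
sequence_protocol <- function(prep = mt_prep(), tr_mt = 90e-3, n_slices = 62L,
                              te = 58e-3, b_value = 1500, n_directions = 30L,
                              n_b0 = 1L, resolution = 2.6,
                              t_exc = 3.328e-3, t_ref = 9.472e-3,
                              sar_limit = 3.2, sar_target_fraction = 0.97,
                              max_scan_time = 600) {
  stopifnot(inherits(prep, "mt_prep"), tr_mt > 0, n_slices >= 1,
            n_directions >= 0, n_b0 >= 0, sar_limit > 0,
            sar_target_fraction > 0, sar_target_fraction <= 1)
  prep_len <- prep$n_pulses * (prep$tau + prep$delta_t)
  if (tr_mt < prep_len)
    stop("tr_mt (", tr_mt, " s) is shorter than the MT preparation train (",
         prep_len, " s)")
  structure(list(prep = prep, tr_mt = tr_mt, n_slices = as.integer(n_slices),
                 te = te, b_value = b_value,
                 n_directions = as.integer(n_directions),
                 n_b0 = as.integer(n_b0), resolution = resolution,
                 t_exc = t_exc, t_ref = t_ref, sar_limit = sar_limit,
                 sar_target_fraction = sar_target_fraction,
                 max_scan_time = max_scan_time),
            class = "mt_protocol")
}

#' @export
print.mt_protocol <- function(x, ...) {
  p <- x$prep
  cat(sprintf("MT-diffusion protocol: offset %.3g kHz, %s polarity, %d x %.2g ms pulses, FA_MT %.0f deg\n",
              p$offset_hz / 1000, p$polarity, p$n_pulses, p$tau * 1000, p$fa_mt))
  cat(sprintf("  TR_MT %.0f ms, %d slices, %d dir + %d b0, b = %.0f s/mm^2; dual scan time %.1f s\n",
              x$tr_mt * 1000, x$n_slices, x$n_directions, x$n_b0, x$b_value,
              scan_time(x)))
  invisible(x)
}

#' Total dual-acquisition duration
#'
#' Scan time of the MT-on plus MT-off pair:
#' `tr_mt * n_slices * (n_directions + n_b0) * 2` seconds.
#'
#' @param protocol an [sequence_protocol()].
#' @return Duration in seconds.
#' @export
scan_time <- function(protocol) {
  stopifnot(inherits(protocol, "mt_protocol"))
  protocol$tr_mt * protocol$n_slices *
    (protocol$n_directions + protocol$n_b0) * 2
}
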