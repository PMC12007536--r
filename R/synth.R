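#' Synthesize MT-off / MT-on diffusion volumes from a phantom
#'
#' Generates the two 4D datasets through the same forward model the fitter
#' uses: per voxel and volume, the signal is the sum over streamline segments
#' of `segment length x bundle weight x zeppelin attenuation` plus the ball
#' term. The MT-on weights are `x_off * (1 - true_mtr)` per bundle and the
#' MT-on ball level is `ball_off * (1 - ball_mtr)`. Noise (if any) is applied
#' to both volumes with the standard deviation referenced to the mean
#' in-bundle MT-off b0 signal.
#'
#' @param phantom an [make_crossing_phantom()] result.
#' @param scheme an [acquisition_scheme()] (default [make_scheme()]).
#' @param zp,bp response parameters.
#' @param noise a [noise_spec()].
#' @return List with 4D arrays `mt_off` and `mt_on`, the `scheme`, and
#'   `b0_level` (the noise reference).
#' @export
synthesize_dwi <- function(phantom, scheme = make_scheme(),
                           zp = zeppelin_params(), bp = ball_params(),
                           noise = noise_spec("none")) {
  stopifnot(inherits(phantom, "mt_phantom"))
  gs <- phantom$grid_shape
  n_vol <- scheme$n_volumes
  nvox <- prod(gs)
  b <- scheme$bvals; g <- scheme$bvecs
  w_off <- vapply(phantom$bundles, function(x) x$true_weight, numeric(1))
  mtr_b <- vapply(phantom$bundles, function(x) x$true_mtr, numeric(1))
  w_on <- w_off * (1 - mtr_b)

  s_off <- matrix(0, nvox, n_vol)
  s_on <- matrix(0, nvox, n_vol)
  for (i in seq_along(phantom$segments)) {
    s <- phantom$segments[[i]]
    if (nrow(s) == 0) next
    bi <- phantom$streamline_bundle[i]
    v <- 1L + s$ix + s$iy * gs[1] + s$iz * gs[1] * gs[2]
    for (k in seq_len(nrow(s))) {
      att <- s$len[k] * zeppelin_response(b, g, c(s$dx[k], s$dy[k], s$dz[k]), zp)
      s_off[v[k], ] <- s_off[v[k], ] + w_off[bi] * att
      s_on[v[k], ] <- s_on[v[k], ] + w_on[bi] * att
    }
  }
  ball_att <- ball_response(b, bp)
  ball_v <- as.vector(phantom$ball_map)
  s_off <- s_off + outer(ball_v, ball_att)
  s_on <- s_on + outer(ball_v * (1 - phantom$ball_mtr), ball_att)

  b0_off <- rowMeans(s_off[, scheme$b0, drop = FALSE])
  b0_level <- if (any(b0_off > 0)) mean(b0_off[b0_off > 0]) else 1

  mt_off <- array(s_off, c(gs, n_vol))
  mt_on <- array(s_on, c(gs, n_vol))
  if (noise$model != "none") {
    if (!is.null(noise$seed)) set.seed(noise$seed)
    spec <- noise_spec(noise$model, noise$snr, seed = NULL)
    mt_off <- add_noise(mt_off, spec, b0_level)
    mt_on <- add_noise(mt_on, spec, b0_level)
  }
  list(mt_off = mt_off, mt_on = mt_on, scheme = scheme, b0_level = b0_level)
}
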