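#' Zeppelin (axially symmetric tensor) parameters
#'
#' The combined intra- plus extra-axonal compartment of one fiber population.
#' Defaults are the fixed white-matter values used throughout:
#' axial diffusivity 1.7e-3 mm^2/s, radial 0.6e-3 mm^2/s.
#'
#' @param d_par axial diffusivity (mm^2/s).
#' @param d_perp radial diffusivity (mm^2/s); must satisfy
#'   `d_par >= d_perp > 0`.
#' @return Object of class `zeppelin_params`.
#' @export
zeppelin_params <- function(d_par = 1.7e-3, d_perp = 0.6e-3) {
  stopifnot(d_perp > 0, d_par >= d_perp)
  structure(list(d_par = d_par, d_perp = d_perp), class = "zeppelin_params")
}

#' Ball (isotropic free-water) parameters
#' @param d_iso isotropic diffusivity (mm^2/s), default 3e-3.
#' @return Object of class `ball_params`.
#' @export
ball_params <- function(d_iso = 3e-3) {
  stopifnot(d_iso > 0)
  structure(list(d_iso = d_iso), class = "ball_params")
}

#' Zeppelin signal attenuation
#'
#' `exp(-b * (d_perp + (d_par - d_perp) * (g . v)^2))` for gradient direction
#' `g` and fiber direction `v`. Vectorized over volumes: `b` may be a vector
#' and `g` a matrix with one row per volume.
#'
#' @param b b-value(s) (s/mm^2).
#' @param g unit gradient direction (length-3 vector) or matrix (n x 3).
#' @param v unit fiber direction (length 3).
#' @param zp a [zeppelin_params()].
#' @return Attenuation in (0, 1], same length as `b`.
#' @export
zeppelin_response <- function(b, g, v, zp = zeppelin_params()) {
  g <- if (is.matrix(g)) g else matrix(g, ncol = 3)
  ct2 <- drop(g %*% v)^2
  exp(-b * (zp$d_perp + (zp$d_par - zp$d_perp) * ct2))
}

#' Ball signal attenuation
#' @param b b-value(s) (s/mm^2).
#' @param bp a [ball_params()].
#' @return `exp(-b * d_iso)`.
#' @export
ball_response <- function(b, bp = ball_params()) {
  stopifnot(all(b >= 0))
  exp(-b * bp$d_iso)
}

#' Fractional anisotropy of a zeppelin
#' @param zp a [zeppelin_params()].
#' @return FA of the axially symmetric tensor (d_par, d_perp, d_perp).
#' @export
zeppelin_fa <- function(zp) {
  (zp$d_par - zp$d_perp) / sqrt(zp$d_par^2 + 2 * zp$d_perp^2)
}

#' Zeppelin with prescribed FA and mean diffusivity
#'
#' Closed-form inversion of the FA formula for an axially symmetric tensor
#' (prolate branch, `d_par >= d_perp`): with `delta = fa / sqrt(3 - 2*fa^2)`,
#' `d_par = md * (1 + 2*delta)` and `d_perp = md * (1 - delta)`.
#'
#' @param target_fa fractional anisotropy in `[0, 1)`.
#' @param mean_diffusivity mean diffusivity (mm^2/s); default is the MD of
#'   the default zeppelin.
#' @return A [zeppelin_params()] with the requested FA and MD.
#' @export
fa_to_zeppelin <- function(target_fa,
                           mean_diffusivity = (1.7e-3 + 2 * 0.6e-3) / 3) {
  stopifnot(target_fa >= 0, target_fa < 1, mean_diffusivity > 0)
  delta <- target_fa / sqrt(3 - 2 * target_fa^2)
  zeppelin_params(mean_diffusivity * (1 + 2 * delta),
                  mean_diffusivity * (1 - delta))
}
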