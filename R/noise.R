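#' Noise specification
#'
#' @param model `"none"`, `"rician"` or `"gaussian"`.
#' @param snr signal-to-noise ratio defined on the b0 level: the noise
#'   standard deviation is `b0_level / snr`.
#' @param seed integer seed for reproducible noise; `NULL` uses the current
#'   RNG state.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(model = c("none", "rician", "gaussian"), snr = 30,
                       seed = NULL) {
  model <- match.arg(model)
  if (model != "none") stopifnot(snr > 0)
  structure(list(model = model, snr = snr, seed = seed), class = "noise_spec")
}

#' Apply noise to a signal volume
#'
#' Rician noise replaces each signal S with `sqrt((S + n1)^2 + n2^2)` for
#' independent zero-mean Gaussians n1, n2 of standard deviation
#' `b0_level / snr`; Gaussian noise adds n1 only.
#'
#' @param volume numeric array of signals.
#' @param noise a [noise_spec()].
#' @param b0_level reference b0 signal level defining the SNR.
#' @return Noisy array of the same shape.
#' @export
add_noise <- function(volume, noise, b0_level) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$model == "none") return(volume)
  stopifnot(b0_level > 0)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  sigma <- b0_level / noise$snr
  n1 <- array(stats::rnorm(length(volume), sd = sigma), dim(volume))
  if (noise$model == "gaussian") return(volume + n1)
  n2 <- array(stats::rnorm(length(volume), sd = sigma), dim(volume))
  sqrt((volume + n1)^2 + n2^2)
}
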