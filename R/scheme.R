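#' Diffusion acquisition scheme
#'
#' @param bvals numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs matrix of gradient directions, `length(bvals)` rows x 3
#'   columns. Directions of b > 0 volumes must be unit vectors; off-norm
#'   directions (by more than 1e-3) are re-normalized with a warning.
#' @param b0_threshold b-values within this of zero are classified as b = 0
#'   volumes (default 50 s/mm^2).
#' @return Object of class `mt_scheme`: list with `bvals`, `bvecs`, `b0`
#'   (logical mask), `n_volumes`.
#' @export
acquisition_scheme <- function(bvals, bvecs, b0_threshold = 50) {
  bvecs <- as.matrix(bvecs)
  stopifnot(is.numeric(bvals), nrow(bvecs) == length(bvals), ncol(bvecs) == 3)
  b0 <- bvals <= b0_threshold
  if (!any(b0)) stop("scheme must contain at least one b = 0 volume")
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(nrm[!b0] == 0))
    stop("zero-norm gradient direction on a b > 0 volume")
  off <- !b0 & abs(nrm - 1) > 1e-3
  if (any(off)) {
    warning("re-normalizing ", sum(off), " gradient direction(s) off unit norm")
  }
  fix <- !b0 & abs(nrm - 1) > 1e-12
  bvecs[fix, ] <- bvecs[fix, , drop = FALSE] / nrm[fix]
  bvecs[b0, ] <- 0
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs, b0 = b0,
                 n_volumes = length(bvals)),
            class = "mt_scheme")
}

# Deterministic quasi-uniform directions on the sphere (golden-angle spiral).
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- 2 * pi * i * (1 + sqrt(5)) / 2
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Default single-shell scheme
#'
#' `n_b0` b = 0 volumes followed by `n_dir` quasi-uniform directions at
#' b-value `b` (defaults: 1 b0 + 30 directions at 1500 s/mm^2).
#'
#' @param n_dir number of diffusion-weighted directions.
#' @param n_b0 number of b = 0 volumes.
#' @param b shell b-value (s/mm^2).
#' @return An [acquisition_scheme()].
#' @export
make_scheme <- function(n_dir = 30, n_b0 = 1, b = 1500) {
  bvals <- c(rep(0, n_b0), rep(b, n_dir))
  bvecs <- rbind(matrix(0, n_b0, 3), fibonacci_directions(n_dir))
  acquisition_scheme(bvals, bvecs)
}
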