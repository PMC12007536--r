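# Small in-code fixtures shared across test files.

# Reduced crossing phantom for fast unit tests (fewer streamlines than the
# default study phantom used in the acceptance suite).
small_phantom <- function(seed = 7, n_streamlines = 12L, ...) {
  ext <- c(20, 20, 20) * 2
  mid <- ext / 2
  m <- 2.4
  bundles <- list(
    bundle_spec("xbundle", c(1L, 2L),
                rbind(c(m, mid[2], mid[3]), c(ext[1] - m, mid[2], mid[3])),
                n_streamlines = n_streamlines, true_mtr = 0.30),
    bundle_spec("ybundle", c(3L, 4L),
                rbind(c(mid[1], m, mid[3]), c(mid[1], ext[2] - m, mid[3])),
                n_streamlines = n_streamlines, true_mtr = 0.40))
  make_crossing_phantom(bundles = bundles, seed = seed, ...)
}

small_scheme <- function(n_dir = 12) make_scheme(n_dir = n_dir)

# dense polyline resampling used by the tracing-conservation oracle
resample_dense <- function(points, step) {
  out <- list(points[1, , drop = FALSE])
  for (s in seq_len(nrow(points) - 1)) {
    p0 <- points[s, ]; p1 <- points[s + 1, ]
    L <- sqrt(sum((p1 - p0)^2))
    n <- max(2, ceiling(L / step))
    t <- seq(0, 1, length.out = n)[-1]
    out[[s + 1]] <- cbind(p0[1] + t * (p1[1] - p0[1]),
                          p0[2] + t * (p1[2] - p0[2]),
                          p0[3] + t * (p1[3] - p0[3]))
  }
  do.call(rbind, out)
}

# protocol with a short preparation for fast steady-state tests
fast_protocol <- function(...) {
  sequence_protocol(prep = mt_prep(n_pulses = 3L, fa_mt = 300), tr_mt = 40e-3,
                    n_slices = 10L, ...)
}
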