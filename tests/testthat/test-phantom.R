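test_that("phantom generation is deterministic and geometrically sound", {
  ph1 <- small_phantom(seed = 5)
  ph2 <- small_phantom(seed = 5)
  expect_identical(ph1$tractogram, ph2$tractogram)
  # crossing voxels contain segments of both bundles
  vox_of <- function(bi) {
    segs <- do.call(rbind, ph1$segments[ph1$streamline_bundle == bi])
    unique(paste(segs$ix, segs$iy, segs$iz))
  }
  expect_gt(length(intersect(vox_of(1), vox_of(2))), 0)
  # every streamline connects its bundle's node pair
  expect_true(all(ph1$node_pairs[ph1$streamline_bundle == 1, ] %in% c(1, 2)))
  expect_true(all(ph1$node_pairs[ph1$streamline_bundle == 2, ] %in% c(3, 4)))
})

test_that("an empty bundle is allowed and a leaking tube is not", {
  ext <- c(20, 20, 20) * 2
  b_empty <- bundle_spec("none", c(5L, 6L),
                         rbind(c(5, 20, 20), c(35, 20, 20)),
                         n_streamlines = 0L)
  ph <- make_crossing_phantom(bundles = list(
    bundle_spec("x", c(1L, 2L), rbind(c(5, 20, 20), c(35, 20, 20)),
                n_streamlines = 3L), b_empty), seed = 2)
  expect_equal(length(ph$tractogram), 3L)
  # a tube hugging the grid edge leaks once transverse jitter is applied
  expect_error(make_crossing_phantom(bundles = list(
    bundle_spec("leak", c(1L, 2L), rbind(c(5, 1, 20), c(35, 1, 20)),
                n_streamlines = 20L, radius = 3)), seed = 2),
    "leaves the grid")
})

test_that("ground-truth bundle MTR is exact by construction", {
  ph <- small_phantom()
  w_off <- ph$truth$true_weight
  w_on <- w_off * (1 - ph$truth$true_mtr)
  L <- streamline_lengths(ph$segments)
  for (bi in seq_len(nrow(ph$truth))) {
    ids <- which(ph$streamline_bundle == bi)
    mtr <- 1 - sum(L[ids] * w_on[bi]) / sum(L[ids] * w_off[bi])
    expect_equal(mtr, ph$truth$true_mtr[bi], tolerance = 1e-12)
  }
})

test_that("noise model honors its contracts", {
  x <- array(runif(1000), c(10, 10, 10))
  expect_identical(add_noise(x, noise_spec("none"), 1), x)
  n1 <- add_noise(x, noise_spec("rician", snr = 20, seed = 4), 1)
  n2 <- add_noise(x, noise_spec("rician", snr = 20, seed = 4), 1)
  expect_identical(n1, n2)
  # Rician floor at S = 0 has the Rayleigh mean sigma * sqrt(pi/2)
  z <- array(0, c(40, 40, 40))
  sigma <- 1 / 30
  nz <- add_noise(z, noise_spec("rician", snr = 30, seed = 8), 1)
  expect_equal(mean(nz), sigma * sqrt(pi / 2), tolerance = 0.01)
})

test_that("synthesized volumes follow the forward model", {
  sc <- small_scheme()
  # zero MTR everywhere makes MT-on identical to MT-off
  ph0 <- make_crossing_phantom(bundles = list(
    bundle_spec("x", c(1L, 2L), rbind(c(5, 20, 20), c(35, 20, 20)),
                n_streamlines = 4L, true_mtr = 0)),
    ball_mtr = 0, seed = 3)
  d0 <- synthesize_dwi(ph0, sc)
  expect_equal(d0$mt_on, d0$mt_off, tolerance = 1e-14)
  # very high SNR converges to the noiseless volume
  d_noisy <- synthesize_dwi(ph0, sc, noise = noise_spec("rician", 1e7, seed = 1))
  expect_equal(d_noisy$mt_off, d0$mt_off, tolerance = 1e-4)
})

test_that("a fully traversed voxel matches the closed-form zeppelin curve", {
  # one straight streamline along x through the grid center, no jitter
  gs <- c(5, 5, 5); vs <- 2
  ph <- make_crossing_phantom(bundles = list(
    bundle_spec("x", c(1L, 2L), rbind(c(1, 5, 5), c(9, 5, 5)),
                n_streamlines = 1L, radius = 1e-9, true_mtr = 0.3)),
    grid_shape = gs, voxel_size = vs, ball_coeff = 0.5, seed = 1)
  sc <- small_scheme()
  dat <- synthesize_dwi(ph, sc)
  ball <- ph$ball_map[1]
  v <- c(1, 0, 0)
  expected <- 2 * zeppelin_response(sc$bvals, sc$bvecs, v) +
    ball * ball_response(sc$bvals)
  got <- dat$mt_off[3, 3, 3, ]
  expect_equal(got, expected, tolerance = 1e-10)
  got_on <- dat$mt_on[3, 3, 3, ]
  expect_equal(got_on, 0.7 * 2 * zeppelin_response(sc$bvals, sc$bvecs, v) +
                 ball * ball_response(sc$bvals), tolerance = 1e-10)
})
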