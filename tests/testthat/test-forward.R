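test_that("compartment responses match their closed forms", {
  zp <- zeppelin_params()
  v <- c(1, 0, 0)
  expect_equal(zeppelin_response(0, c(0, 0, 0), v, zp), 1)
  expect_equal(zeppelin_response(1500, v, v, zp), exp(-2.55))
  expect_equal(zeppelin_response(1500, v, v, zp), 0.078082, tolerance = 1e-5)
  expect_equal(zeppelin_response(1500, c(0, 1, 0), v, zp), exp(-0.9))
  expect_equal(zeppelin_response(1500, c(0, 1, 0), v, zp), 0.406570,
               tolerance = 1e-5)
  bp <- ball_params()
  expect_equal(ball_response(0, bp), 1)
  expect_equal(ball_response(1500, bp), exp(-4.5))
  expect_equal(ball_response(1500, bp), 0.011109, tolerance = 1e-4)
  b <- seq(0, 3000, by = 500)
  expect_true(all(diff(ball_response(b, bp)) < 0))
})

test_that("FA <-> zeppelin conversion round-trips", {
  zp0 <- fa_to_zeppelin(0, 1e-3)
  expect_equal(zp0$d_par, 1e-3)
  expect_equal(zp0$d_perp, 1e-3)
  # defaults: FA(1.7e-3, 0.6e-3) = 0.579
  fa <- zeppelin_fa(zeppelin_params())
  expect_equal(fa, 0.579, tolerance = 1e-3)
  md <- (1.7e-3 + 2 * 0.6e-3) / 3
  zp <- fa_to_zeppelin(fa, md)
  expect_equal(zp$d_par, 1.7e-3, tolerance = 1e-6)
  expect_equal(zp$d_perp, 0.6e-3, tolerance = 1e-6)
  # FA monotone in the axial/radial ratio at fixed MD
  fas <- vapply(seq(0.1, 0.8, by = 0.1), function(f)
    zeppelin_fa(fa_to_zeppelin(f, md)), numeric(1))
  expect_true(all(diff(fas) > 0))
})

test_that("streamline tracing is exact on axis-aligned and diagonal paths", {
  vs <- 2.6
  gs <- c(5, 5, 5)
  # axis-aligned span of exactly 3 voxels
  sl <- rbind(c(0, 1.3, 1.3), c(3 * vs, 1.3, 1.3))
  seg <- trace_streamline(sl, gs, vs)
  expect_equal(nrow(seg), 3)
  expect_equal(seg$len, rep(vs, 3), tolerance = 1e-12)
  expect_equal(seg$ix, 0:2)
  # in-plane diagonal of one cubic voxel
  sl2 <- rbind(c(2.6, 2.6, 1.3), c(2 * 2.6, 2 * 2.6, 1.3))
  seg2 <- trace_streamline(sl2, gs, vs)
  expect_equal(nrow(seg2), 1)
  expect_equal(seg2$len, vs * sqrt(2), tolerance = 1e-12)
  # entirely outside -> empty
  out <- trace_streamline(rbind(c(-10, -10, -10), c(-5, -5, -5)), gs, vs)
  expect_equal(nrow(out), 0)
})

test_that("tracing conserves arc length against a dense-resampling oracle", {
  set.seed(11)
  vs <- 2; gs <- c(10, 10, 10)
  for (rep in 1:100) {
    pts <- matrix(runif(5 * 3, 1, 19), 5, 3)
    seg <- trace_streamline(pts, gs, vs)
    # brute force: resample at 1e-3 mm and accumulate step lengths in-grid
    dense <- resample_dense(pts, 1e-3)
    mid <- (dense[-1, , drop = FALSE] + dense[-nrow(dense), , drop = FALSE]) / 2
    steps <- sqrt(rowSums((dense[-1, , drop = FALSE] -
                             dense[-nrow(dense), , drop = FALSE])^2))
    inside <- mid[, 1] >= 0 & mid[, 1] < 20 & mid[, 2] >= 0 & mid[, 2] < 20 &
      mid[, 3] >= 0 & mid[, 3] < 20
    expect_equal(sum(seg$len), sum(steps[inside]), tolerance = 1e-3)
  }
})

test_that("assembled system matches hand-built values on a single voxel", {
  vs <- 2; gs <- c(3, 3, 3)
  sl <- list(rbind(c(2, 3, 3), c(4, 3, 3)))  # crosses voxel (1,1,1), length 2
  scheme <- acquisition_scheme(c(0, 1500), rbind(c(0, 0, 0), c(1, 0, 0)))
  dwi <- array(1, c(gs, 2))
  norm <- array(1, gs)
  prob <- assemble_system(sl, scheme, gs, vs, dwi, norm)
  A <- as.matrix(prob$A)
  expect_equal(dim(A), c(2, 2))
  zp <- zeppelin_params()
  expect_equal(A[, 1], c(2 * 1, 2 * exp(-1500 * zp$d_par)),
               ignore_attr = TRUE)
  expect_equal(A[, 2], c(1, exp(-4.5)), ignore_attr = TRUE)
  expect_equal(prob$y, c(1, 1))
  expect_equal(prob$lengths, 2)
})

test_that("column order tracks streamline order and entries are non-negative", {
  ph <- small_phantom()
  sc <- small_scheme()
  dat <- synthesize_dwi(ph, sc)
  gs <- ph$grid_shape
  norm <- array(rowMeans(matrix(dat$mt_off, ncol = sc$n_volumes)[, sc$b0,
                                drop = FALSE]), gs)
  prob <- assemble_system(ph$tractogram, sc, gs, ph$voxel_size, dat$mt_off,
                          norm, segments = ph$segments)
  A <- prob$A
  expect_true(all(A@x >= 0))
  n_str <- prob$n_streamlines
  nz_per_col <- diff(A@p)
  expect_true(all(nz_per_col[seq_len(n_str)] >= 1))
  # permuting the tractogram permutes the streamline columns identically
  perm <- rev(seq_along(ph$tractogram))
  prob2 <- assemble_system(ph$tractogram[perm], sc, gs, ph$voxel_size,
                           dat$mt_off, norm)
  expect_equal(as.matrix(prob2$A[, seq_len(n_str)]),
               as.matrix(prob$A[, perm]), tolerance = 1e-12)
})

test_that("non-positive normalizer voxels are reported", {
  vs <- 2; gs <- c(3, 3, 3)
  sl <- list(rbind(c(2, 3, 3), c(4, 3, 3)))
  scheme <- acquisition_scheme(c(0, 1500), rbind(c(0, 0, 0), c(1, 0, 0)))
  dwi <- array(1, c(gs, 2))
  norm <- array(0, gs)
  expect_error(assemble_system(sl, scheme, gs, vs, dwi, norm),
               "non-positive normalizer")
})
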