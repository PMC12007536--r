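# end-to-end fits on the reduced phantom, shared across this file
ph <- small_phantom()
sc <- small_scheme()
dat <- synthesize_dwi(ph, sc)
fit <- dual_fit(dat$mt_on, dat$mt_off, ph$tractogram, sc, ph$voxel_size,
                max_iter = 20000L, segments = ph$segments)

test_that("the operator reproduces the generator's signal exactly", {
  w_off <- ph$truth$true_weight[ph$streamline_bundle]
  x_true <- c(w_off, rep(ph$ball_map[1], fit$problem$n_mask))
  expect_lt(max(abs(as.vector(fit$problem$A %*% x_true) - fit$problem$y)),
            1e-10)
})

test_that("noiseless self-generated data recovers the true weights", {
  w <- coef(fit)
  w_off_true <- ph$truth$true_weight[ph$streamline_bundle]
  w_on_true <- w_off_true * (1 - ph$truth$true_mtr[ph$streamline_bundle])
  expect_lt(max(abs(w[, "x_off"] - w_off_true)), 1e-6)
  expect_lt(max(abs(w[, "x_on"] - w_on_true)), 1e-6)
  # per-streamline MT attenuation ratio
  expect_equal(as.numeric(w[, "x_on"] / w[, "x_off"]),
               1 - ph$truth$true_mtr[ph$streamline_bundle],
               tolerance = 1e-4)
})

test_that("identical inputs give identical weight vectors", {
  f2 <- dual_fit(dat$mt_off, dat$mt_off, ph$tractogram, sc, ph$voxel_size,
                 max_iter = 20000L, segments = ph$segments)
  w <- coef(f2)
  expect_equal(w[, "x_on"], w[, "x_off"], tolerance = 1e-12)
})

test_that("residual and isotropic maps reflect the generator", {
  expect_lt(max(fit$rmse_off, na.rm = TRUE), 1e-8)
  expect_lt(max(fit$rmse_on, na.rm = TRUE), 1e-8)
  # recovered ball fraction matches the generated uniform ball level
  norm_map <- array(NA_real_, ph$grid_shape)
  norm_map[fit$problem$mask_lin] <- fit$problem$norm
  expect_equal(fit$iso_off[fit$problem$mask_lin],
               ph$ball_map[1] / fit$problem$norm, tolerance = 1e-5)
  # a ball-free phantom yields a near-zero isotropic map in bundle voxels
  ph0 <- small_phantom(ball_coeff = 0)
  d0 <- synthesize_dwi(ph0, sc)
  f0 <- dual_fit(d0$mt_on, d0$mt_off, ph0$tractogram, sc, ph0$voxel_size,
                 max_iter = 20000L, segments = ph0$segments)
  expect_lt(max(f0$iso_off, na.rm = TRUE), 1e-6)
})

test_that("bundle grouping applies the positive-weight rule", {
  x_on <- c(1, 2, 0, 3)
  x_off <- c(1, 2, 2, 3)
  pairs <- rbind(c(1, 2), c(2, 1), c(1, 2), c(0, 2))
  g <- group_streamlines(x_on, x_off, pairs)
  # streamline 3 zeroed in MT-on only -> excluded; 4 unconnected -> discarded
  expect_equal(names(g), "1-2")
  expect_equal(g[["1-2"]], c(1L, 2L))
})

test_that("bundle MTR follows the volume-weighted ratio formula", {
  r <- bundle_mtr(1:2, lengths = c(10, 20), x_on = c(0.7, 0.4),
                  x_off = c(1.0, 0.5))
  expect_equal(r$vol_off, 20)
  expect_equal(r$vol_on, 15)
  expect_equal(r$mtr, 0.25)
  # homogeneous bundle: x_on = (1-m) x_off gives exactly m
  m <- 0.37
  r2 <- bundle_mtr(1:3, lengths = c(5, 9, 2), x_on = (1 - m) * c(1, 2, 3),
                   x_off = c(1, 2, 3))
  expect_equal(r2$mtr, m)
  # global weight rescaling leaves the ratio unchanged
  r3 <- bundle_mtr(1:2, lengths = c(10, 20), x_on = 7 * c(0.7, 0.4),
                   x_off = 7 * c(1.0, 0.5))
  expect_equal(r3$mtr, r$mtr)
})

test_that("noiseless end-to-end bundle MTR matches the ground truth", {
  bt <- bundle_table(fit, ph$node_pairs)
  expect_equal(nrow(bt), 2L)
  expect_equal(bt$mtr, ph$truth$true_mtr, tolerance = 1e-3)
})

test_that("connectome matrices are symmetric and round-trip through CSV", {
  bt <- bundle_table(fit, ph$node_pairs)
  cn <- build_connectome(bt, n_nodes = 4)
  expect_equal(cn$mtr, t(cn$mtr))
  expect_equal(cn$vol_off, t(cn$vol_off))
  expect_equal(cn$mtr[1, 2], bt$mtr[1])
  expect_true(is.nan(cn$mtr[1, 3]))
  f <- tempfile(fileext = ".csv")
  write_connectome_csv(cn$mtr, f)
  back <- read_connectome_csv(f)
  expect_identical(back[is.finite(back)], cn$mtr[is.finite(cn$mtr)])
  dup <- rbind(bt, bt[1, ])
  expect_error(build_connectome(dup, 4), "duplicate")
})

test_that("Rician repeatability at SNR 30 is unbiased within tolerance", {
  bts <- lapply(1:2, function(r) {
    d <- synthesize_dwi(ph, sc, noise = noise_spec("rician", 30, seed = 100 + r))
    f <- dual_fit(d$mt_on, d$mt_off, ph$tractogram, sc, ph$voxel_size,
                  max_iter = 5000L, segments = ph$segments)
    bundle_table(f, ph$node_pairs)
  })
  m1 <- bts[[1]]$mtr; m2 <- bts[[2]]$mtr
  rescan_pct <- 100 * abs(m1 - m2) / ((m1 + m2) / 2)
  expect_true(all(rescan_pct < 10))
  bias <- (m1 + m2) / 2 - ph$truth$true_mtr
  expect_true(all(abs(bias) < 0.01))
})
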