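test_that("diffusion-weighted MTR map uses b > 0 volumes only", {
  sc <- acquisition_scheme(c(0, 1500, 1500),
                           rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  off <- array(0, c(1, 1, 1, 3)); on <- off
  off[1, 1, 1, ] <- c(9, 0.5, 0.3)   # b0 value must not enter
  on[1, 1, 1, ] <- c(1, 0.4, 0.2)
  m <- mtr_dw_map(on, off, sc)
  expect_equal(m[1, 1, 1], 1 - 0.3 / 0.4)
  m2 <- mtr_dw_map(on, off, sc, method = "mean_of_ratios")
  expect_equal(m2[1, 1, 1], 1 - mean(c(0.4 / 0.5, 0.2 / 0.3)))
  # proportional signals give the proportionality MTR; identical give 0
  expect_equal(mtr_dw_map(off * 0.6, off, sc)[1, 1, 1], 0.4)
  expect_equal(mtr_dw_map(off, off, sc)[1, 1, 1], 0)
  # non-positive MT-off mean is flagged NaN
  off[1, 1, 1, 2:3] <- 0
  expect_true(is.nan(mtr_dw_map(on, off, sc)[1, 1, 1]))
})

test_that("median along a streamline is interpolated and robust", {
  vs <- 1
  cmap <- array(0.42, c(6, 6, 6))
  sl <- rbind(c(1, 3, 3), c(2.5, 3, 3), c(4, 3, 3))
  expect_equal(sample_median_along_streamline(cmap, sl, vs), 0.42)
  # outlier-robust: nearest-neighbor samples (0.1, 0.2, 0.9) -> 0.2
  vmap <- array(NaN, c(3, 1, 1))
  vmap[, 1, 1] <- c(0.1, 0.2, 0.9)
  sl3 <- rbind(c(0.5, 0.5, 0.5), c(1.5, 0.5, 0.5), c(2.5, 0.5, 0.5))
  expect_equal(sample_median_along_streamline(vmap, sl3, vs,
                                              interp = "nearest"), 0.2)
  # linear gradient along x: the median equals the midpoint value
  gmap <- array(rep((seq_len(20) - 0.5), 20 * 20), c(20, 20, 20))
  slg <- cbind(seq(2, 18, length.out = 31), 10, 10)
  expect_equal(sample_median_along_streamline(gmap, slg, vs), 10,
               tolerance = 1e-6)
  # all-NaN samples give NaN
  nmap <- array(NaN, c(3, 3, 3))
  expect_true(is.nan(sample_median_along_streamline(nmap, sl3, vs)))
})

test_that("tractometry bundle value averages per-streamline medians", {
  vs <- 1
  map <- array(NaN, c(10, 10, 10))
  map[, 1:5, ] <- 0.3
  map[, 6:10, ] <- 0.5
  sl_a <- cbind(seq(1, 9, 1), 2.5, 5)
  sl_b <- cbind(seq(1, 9, 1), 7.5, 5)
  expect_equal(tractometry_bundle_mtr(map, list(sl_a, sl_b), vs), 0.4)
  expect_equal(tractometry_bundle_mtr(map, list(sl_a), vs), 0.3)
  expect_true(is.nan(tractometry_bundle_mtr(array(NaN, c(3, 3, 3)),
                                            list(sl_a / 3), vs)))
})

test_that("tensor FA map recovers compartment anisotropy", {
  sc <- make_scheme(n_dir = 30)
  gs <- c(3, 3, 3)
  v <- c(1, 0, 0)
  zep <- zeppelin_response(sc$bvals, sc$bvecs, v)
  ball <- ball_response(sc$bvals)
  mix <- 0.5 * zep + 0.5 * zeppelin_response(sc$bvals, sc$bvecs, c(0, 1, 0))
  dwi <- array(0, c(gs, sc$n_volumes))
  for (q in seq_len(sc$n_volumes)) {
    dwi[1, 1, 1, q] <- zep[q]
    dwi[2, 1, 1, q] <- ball[q]
    dwi[3, 1, 1, q] <- mix[q]
  }
  fa <- tensor_fa_map(dwi, sc)
  expect_equal(fa[1, 1, 1], zeppelin_fa(zeppelin_params()), tolerance = 1e-3)
  expect_lt(fa[2, 1, 1], 1e-3)
  expect_lt(fa[3, 1, 1], fa[1, 1, 1])  # crossing lowers the apparent FA
  expect_true(is.nan(fa[1, 2, 1]))     # zero signal is masked
})

test_that("single-fiber reference is the tract-density-weighted mean", {
  gs <- c(3, 1, 1)
  segs <- list(data.frame(ix = c(0, 1, 2), iy = 0, iz = 0, len = 1,
                          dx = 1, dy = 0, dz = 0),
               data.frame(ix = 1, iy = 0, iz = 0, len = 1,
                          dx = 1, dy = 0, dz = 0))
  fa_map <- array(0.9, gs)
  mtr <- array(c(0.3, 0.4, 0.5), gs)
  # densities (1, 2, 1), values (0.3, 0.4, 0.5) -> 0.4
  expect_equal(single_fiber_reference(segs, fa_map, mtr, gs), 0.4)
  # uniform map: weighting is irrelevant
  expect_equal(single_fiber_reference(segs, fa_map, array(0.33, gs), gs), 0.33)
  expect_warning(r <- single_fiber_reference(segs, array(0.1, gs), mtr, gs),
                 "FA threshold")
  expect_true(is.nan(r))
})

test_that("method comparison reports percent differences and paired tests", {
  ts <- rbind(a = c(0.30, 0.32, 0.29), b = c(0.40, 0.39, 0.42))
  tm <- ts * 0.9
  cmp <- compare_methods(ts, tm)
  expect_equal(cmp$bundles$pct_difference,
               100 * (rowMeans(ts) - rowMeans(tm)) /
                 ((rowMeans(ts) + rowMeans(tm)) / 2),
               ignore_attr = TRUE)
  # identical methods: 0% difference everywhere
  cmp0 <- compare_methods(ts, ts)
  expect_true(all(cmp0$bundles$pct_difference == 0))
  # paired t between bundles matches the textbook statistic
  row <- subset(cmp$bundle_tests, method == "tract_specific")
  oracle <- paired_t_oracle(ts[1, ], ts[2, ])
  expect_equal(row$t, oracle$t, tolerance = 1e-10)
  expect_equal(row$p, oracle$p, tolerance = 1e-10)
  # zero-variance differences are flagged degenerate, not infinite
  tz <- rbind(a = c(0.1, 0.2, 0.3), b = c(0.2, 0.3, 0.4))
  cz <- compare_methods(tz, tz)
  expect_true(all(cz$bundle_tests$degenerate))
  expect_true(all(is.na(cz$bundle_tests$t)))
})
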