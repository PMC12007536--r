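#' Diffusion-weighted MTR map
#'
#' Voxel-wise MTR computed from the diffusion-weighted volumes only,
#' omitting the b = 0 images: by default
#' `1 - mean_q(S_on) / mean_q(S_off)` over b > 0 volumes (ratio of
#' direction-averaged signals). The alternative averaging convention (mean
#' of per-direction ratios) is available via `method`.
#'
#' @param mt_on,mt_off 4D signal arrays.
#' @param scheme an [acquisition_scheme()].
#' @param method `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @return 3D MTR array; `NaN` where the MT-off mean is non-positive.
#' @export
mtr_dw_map <- function(mt_on, mt_off, scheme,
                       method = c("ratio_of_means", "mean_of_ratios")) {
  method <- match.arg(method)
  stopifnot(all(dim(mt_on) == dim(mt_off)),
            dim(mt_off)[4] == scheme$n_volumes)
  gs <- dim(mt_off)[1:3]
  dw <- !scheme$b0
  on_m <- matrix(mt_on, ncol = scheme$n_volumes)[, dw, drop = FALSE]
  off_m <- matrix(mt_off, ncol = scheme$n_volumes)[, dw, drop = FALSE]
  if (method == "ratio_of_means") {
    num <- rowMeans(on_m); den <- rowMeans(off_m)
    out <- ifelse(den > 0, 1 - num / den, NaN)
  } else {
    ratio <- on_m / off_m
    ratio[off_m <= 0] <- NaN
    out <- 1 - rowMeans(ratio)
  }
  array(out, gs)
}

# trilinear interpolation of a 3D map at mm points (cell-centered voxels)
trilinear_sample <- function(map, points, voxel_size) {
  gs <- dim(map)
  p <- as.matrix(points) / voxel_size - 0.5
  p <- pmin(pmax(p, 0), matrix(gs - 1, nrow(points), 3, byrow = TRUE))
  i0 <- pmin(floor(p), matrix(gs - 2, nrow(points), 3, byrow = TRUE))
  i0 <- pmax(i0, 0)
  f <- p - i0
  out <- numeric(nrow(p))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (dx * f[, 1] + (1 - dx) * (1 - f[, 1])) *
      (dy * f[, 2] + (1 - dy) * (1 - f[, 2])) *
      (dz * f[, 3] + (1 - dz) * (1 - f[, 3]))
    idx <- cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1, i0[, 3] + dz + 1)
    out <- out + w * map[idx]
  }
  out
}

#' Median of a scalar map along a streamline
#'
#' Samples the map at the streamline vertices with trilinear interpolation
#' (nearest-neighbor via `interp = "nearest"`) and takes the median over
#' vertices (`NaN` samples excluded; the result is `NaN` if all are).
#'
#' @param map 3D scalar array.
#' @param streamline vertex matrix (mm).
#' @param voxel_size voxel size (mm).
#' @param interp `"trilinear"` or `"nearest"`.
#' @return Scalar median.
#' @export
sample_median_along_streamline <- function(map, streamline, voxel_size,
                                           interp = c("trilinear", "nearest")) {
  interp <- match.arg(interp)
  pts <- as.matrix(streamline)
  if (interp == "trilinear") {
    s <- trilinear_sample(map, pts, voxel_size)
  } else {
    gs <- dim(map)
    v <- pmin(pmax(floor(pts / voxel_size), 0),
              matrix(gs - 1, nrow(pts), 3, byrow = TRUE))
    s <- map[v + 1]
  }
  s <- s[is.finite(s)]
  if (length(s) == 0) return(NaN)
  stats::median(s)
}

#' Conventional tractometry bundle MTR
#'
#' Mean across a bundle's streamlines of the per-streamline median of the
#' scalar map; streamlines with all-`NaN` samples are excluded.
#'
#' @param map 3D scalar array (typically [mtr_dw_map()]).
#' @param streamlines list of vertex matrices.
#' @param voxel_size voxel size (mm).
#' @param interp interpolation passed to [sample_median_along_streamline()].
#' @return Scalar bundle value (`NaN` if no valid streamline).
#' @export
tractometry_bundle_mtr <- function(map, streamlines, voxel_size,
                                   interp = "trilinear") {
  med <- vapply(streamlines, sample_median_along_streamline, numeric(1),
                map = map, voxel_size = voxel_size, interp = interp)
  med <- med[is.finite(med)]
  if (length(med) == 0) return(NaN)
  mean(med)
}

#' Diffusion tensor FA map
#'
#' Per-voxel log-linear least-squares diffusion tensor fit; FA from the
#' tensor eigenvalues, clamped to `[0, 1]`. Voxels with any non-positive
#' signal (or fewer than 6 b > 0 directions in the scheme) are `NaN`.
#'
#' @param dwi 4D signal array.
#' @param scheme an [acquisition_scheme()].
#' @return 3D FA array.
#' @export
tensor_fa_map <- function(dwi, scheme) {
  dw <- !scheme$b0
  if (sum(dw) < 6) stop("tensor fit needs at least 6 b > 0 directions")
  gs <- dim(dwi)[1:3]
  b <- scheme$bvals; g <- scheme$bvecs
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  sm <- matrix(dwi, ncol = scheme$n_volumes)
  ok <- apply(sm, 1, function(r) all(is.finite(r)) && all(r > 0))
  fa <- rep(NaN, nrow(sm))
  XtXi <- solve(crossprod(X)) %*% t(X)
  coefs <- XtXi %*% t(log(pmax(sm[ok, , drop = FALSE], .Machine$double.xmin)))
  if (any(ok)) {
    idx <- which(ok)
    for (j in seq_along(idx)) {
      cf <- coefs[, j]
      D <- matrix(c(cf[2], cf[5], cf[6],
                    cf[5], cf[3], cf[7],
                    cf[6], cf[7], cf[4]), 3, 3)
      ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
      md <- mean(ev)
      denom <- sum(ev^2)
      fa[idx[j]] <- if (denom > 0)
        min(1, max(0, sqrt(1.5 * sum((ev - md)^2) / denom))) else NaN
    }
  }
  array(fa, gs)
}

#' Tract density of a bundle
#'
#' Number of streamline segments per voxel (segments, not unique
#' streamlines).
#'
#' @param segments list of [trace_streamline()] tables for the bundle's
#'   streamlines.
#' @param grid_shape voxel counts per axis.
#' @return 3D count array.
#' @export
tract_density <- function(segments, grid_shape) {
  td <- array(0, grid_shape)
  for (s in segments) {
    if (nrow(s) == 0) next
    v <- 1L + s$ix + s$iy * grid_shape[1] + s$iz * grid_shape[1] * grid_shape[2]
    for (k in v) td[k] <- td[k] + 1
  }
  td
}

#' Single-fiber-voxel reference MTR of a bundle
#'
#' Over the voxels traversed by the bundle whose FA exceeds the threshold,
#' the tract-density-weighted mean of the diffusion-weighted MTR map. Used
#' as the partial-volume-free reference a bundle's MTR estimate is compared
#' against.
#'
#' @param segments bundle streamline tracing ([trace_streamline()] tables).
#' @param fa_map 3D FA array.
#' @param mtr_dw 3D MTR array.
#' @param grid_shape voxel counts per axis.
#' @param fa_threshold single-fiber FA threshold (default 0.6).
#' @return Weighted mean MTR (`NaN` with a warning if no voxel passes).
#' @export
single_fiber_reference <- function(segments, fa_map, mtr_dw, grid_shape,
                                   fa_threshold = 0.6) {
  td <- tract_density(segments, grid_shape)
  sel <- which(td > 0 & is.finite(fa_map) & fa_map > fa_threshold &
                 is.finite(mtr_dw))
  if (length(sel) == 0) {
    warning("no traversed voxel passes the FA threshold ", fa_threshold)
    return(NaN)
  }
  sum(mtr_dw[sel] * td[sel]) / sum(td[sel])
}
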