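#' Bundle specification for the synthetic phantom
#'
#' @param name bundle label.
#' @param node_pair two distinct integer node ids the bundle connects.
#' @param centerline ordered control points (n x 3, mm in the grid frame).
#' @param n_streamlines number of streamlines to generate.
#' @param radius tube radius (mm) confining the streamlines.
#' @param true_mtr ground-truth bundle MTR in `[0, 1)`.
#' @param true_weight MT-off signal per unit length per streamline.
#' @return Object of class `bundle_spec`.
#' @export
bundle_spec <- function(name, node_pair, centerline, n_streamlines = 40L,
                        radius = 3, true_mtr = 0.3, true_weight = 1) {
  centerline <- as.matrix(centerline)
  stopifnot(length(node_pair) == 2, node_pair[1] != node_pair[2],
            nrow(centerline) >= 2, ncol(centerline) == 3,
            true_mtr >= 0, true_mtr < 1, true_weight > 0, radius > 0,
            n_streamlines >= 0)
  structure(list(name = name, node_pair = as.integer(node_pair),
                 centerline = centerline,
                 n_streamlines = as.integer(n_streamlines), radius = radius,
                 true_mtr = true_mtr, true_weight = true_weight),
            class = "bundle_spec")
}

# resample a polyline at (approximately) fixed arc-length steps
resample_polyline <- function(points, step = 0.5) {
  seg <- diff(points)
  lens <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(lens))
  total <- cum[length(cum)]
  s <- seq(0, total, by = step)
  if (s[length(s)] < total) s <- c(s, total)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(points) - 1)
  frac <- (s - cum[idx]) / lens[idx]
  points[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
}

# two unit vectors orthogonal to v
orthonormal_frame <- function(v) {
  v <- v / sqrt(sum(v^2))
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * v) * v
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(v[2] * e1[3] - v[3] * e1[2],
          v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Synthetic crossing-fiber phantom
#'
#' Generates a voxel grid containing fiber bundles with known per-bundle MTR
#' and streamline weights, emulating intersecting tracts (a pons/CST-style
#' crossing). Streamlines are jittered copies of each bundle centerline:
#' a radial Gaussian transverse displacement (sd `radius/2`, truncated at the
#' tube radius, constant along the streamline), resampled at 0.5 mm steps.
#' Box-shaped node regions are placed around the centerline endpoints and
#' every streamline starts and ends inside its bundle's two node boxes.
#'
#' A uniform free-water "ball" background (MTR 0 by default) is added over
#' the whole grid at `ball_coeff` times the mean in-bundle b0 streamline
#' signal; it is the isotropic partial-volume contaminant that the
#' tract-specific method rejects and conventional tractometry does not.
#'
#' @param bundles list of [bundle_spec()]; `NULL` for the default two
#'   orthogonal bundles (true MTR 0.30 and 0.40) crossing at the grid center.
#' @param grid_shape voxel counts per axis (default 20 x 20 x 20).
#' @param voxel_size isotropic voxel size in mm (default 2).
#' @param ball_coeff ball b0 level as a fraction of the mean in-bundle b0
#'   streamline signal (default 0.3; 0 disables the ball).
#' @param ball_mtr MTR applied to the ball compartment (default 0).
#' @param node_box_mm half-width (mm) of the cubic node end regions.
#' @param step resampling step along streamlines (mm).
#' @param seed integer seed; the generator is fully reproducible.
#' @return Object of class `mt_phantom`: grid geometry, bundle specs, the
#'   tractogram (list of vertex matrices), `streamline_bundle` (bundle index
#'   per streamline), `node_pairs` (n x 2), `node_label_map` (3D array),
#'   `segments` (cached voxel tracing), `ball_map` (3D b0-level array),
#'   `ball_mtr`, and `truth` (per-bundle ground-truth table).
#' @export
make_crossing_phantom <- function(bundles = NULL, grid_shape = c(20, 20, 20),
                                  voxel_size = 2, ball_coeff = 0.3,
                                  ball_mtr = 0, node_box_mm = 5, step = 0.5,
                                  seed = 1L) {
  ext <- grid_shape * voxel_size
  if (is.null(bundles)) {
    mid <- ext / 2
    m <- voxel_size * 1.2  # end margin inside the grid
    bundles <- list(
      bundle_spec("xbundle", c(1L, 2L),
                  rbind(c(m, mid[2], mid[3]), c(ext[1] - m, mid[2], mid[3])),
                  true_mtr = 0.30),
      bundle_spec("ybundle", c(3L, 4L),
                  rbind(c(mid[1], m, mid[3]), c(mid[1], ext[2] - m, mid[3])),
                  true_mtr = 0.40))
  }
  stopifnot(length(bundles) >= 1,
            all(vapply(bundles, inherits, logical(1), "bundle_spec")))
  set.seed(seed)
  tractogram <- list()
  str_bundle <- integer()
  for (bi in seq_along(bundles)) {
    b <- bundles[[bi]]
    cl <- resample_polyline(b$centerline, step)
    v <- cl[nrow(cl), ] - cl[1, ]
    fr <- orthonormal_frame(v)
    for (k in seq_len(b$n_streamlines)) {
      repeat {
        u <- stats::rnorm(2, sd = b$radius / 2)
        if (sum(u^2) <= b$radius^2) break
      }
      offs <- u[1] * fr$e1 + u[2] * fr$e2
      pts <- sweep(cl, 2, offs, `+`)
      if (any(pts < 0) || any(sweep(pts, 2, ext, `>=`)))
        stop("bundle '", b$name, "' tube leaves the grid")
      tractogram[[length(tractogram) + 1L]] <- pts
      str_bundle <- c(str_bundle, bi)
    }
  }
  # node label map: cubic boxes around centerline endpoints
  node_label_map <- array(0L, grid_shape)
  centers <- (arrayInd(seq_len(prod(grid_shape)), grid_shape) - 0.5) * voxel_size
  for (b in bundles) {
    ends <- b$centerline[c(1, nrow(b$centerline)), , drop = FALSE]
    for (e in 1:2) {
      inside <- abs(centers[, 1] - ends[e, 1]) <= node_box_mm &
        abs(centers[, 2] - ends[e, 2]) <= node_box_mm &
        abs(centers[, 3] - ends[e, 3]) <= node_box_mm
      node_label_map[inside] <- b$node_pair[e]
    }
  }
  node_pairs <- streamline_node_pairs(tractogram, node_label_map, voxel_size)

  segments <- trace_tractogram(tractogram, grid_shape, voxel_size)
  # ball level from the mean in-bundle b0 streamline signal
  w_off <- vapply(bundles, function(b) b$true_weight,
                  numeric(1))[str_bundle]
  b0img <- array(0, grid_shape)
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    if (nrow(s) == 0) next
    v <- 1L + s$ix + s$iy * grid_shape[1] + s$iz * grid_shape[1] * grid_shape[2]
    for (k in seq_len(nrow(s)))
      b0img[v[k]] <- b0img[v[k]] + s$len[k] * w_off[i]
  }
  ball_level <- if (any(b0img > 0)) ball_coeff * mean(b0img[b0img > 0]) else 0
  ball_map <- array(ball_level, grid_shape)

  truth <- data.frame(
    bundle = vapply(bundles, function(b) b$name, character(1)),
    node_a = vapply(bundles, function(b) b$node_pair[1], integer(1)),
    node_b = vapply(bundles, function(b) b$node_pair[2], integer(1)),
    true_mtr = vapply(bundles, function(b) b$true_mtr, numeric(1)),
    true_weight = vapply(bundles, function(b) b$true_weight, numeric(1)),
    n_streamlines = vapply(bundles, function(b) b$n_streamlines, integer(1)))

  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 bundles = bundles, tractogram = tractogram,
                 streamline_bundle = str_bundle, node_pairs = node_pairs,
                 node_label_map = node_label_map, segments = segments,
                 ball_map = ball_map, ball_mtr = ball_mtr, truth = truth,
                 seed = seed),
            class = "mt_phantom")
}

#' Node pair of each streamline from a label volume
#'
#' Labels a streamline by the node regions containing its first and last
#' vertex (0 when an endpoint falls outside every node region).
#'
#' @param tractogram list of vertex matrices (mm).
#' @param node_label_map 3D integer array of node labels (0 = none).
#' @param voxel_size voxel size (mm).
#' @return Integer matrix, one row per streamline, columns `node_a`,
#'   `node_b`.
#' @export
streamline_node_pairs <- function(tractogram, node_label_map, voxel_size) {
  gs <- dim(node_label_map)
  lab <- function(p) {
    v <- pmin(pmax(floor(p / voxel_size), 0), gs - 1)
    node_label_map[v[1] + 1, v[2] + 1, v[3] + 1]
  }
  out <- t(vapply(tractogram, function(pts)
    c(lab(pts[1, ]), lab(pts[nrow(pts), ])), integer(2)))
  colnames(out) <- c("node_a", "node_b")
  out
}

#' @export
print.mt_phantom <- function(x, ...) {
  cat("Crossing-fiber phantom:", paste(x$grid_shape, collapse = " x "),
      "voxels of", x$voxel_size, "mm,", length(x$tractogram), "streamlines\n")
  print(x$truth, row.names = FALSE)
  invisible(x)
}
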