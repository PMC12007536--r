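#' Clip a streamline against the voxel lattice
#'
#' Exact geometric tracing: each polyline segment is clipped against the grid
#' box and split at every voxel boundary plane. Voxels are half-open boxes
#' `[i*s, (i+1)*s)` with 0-based indices; streamline coordinates are in mm in
#' the grid frame. Per sub-segment the unit direction of the parent polyline
#' segment is retained, so the sum of lengths equals the arc length inside
#' the grid.
#'
#' @param points streamline vertices, n x 3 matrix (mm).
#' @param grid_shape integer vector of voxel counts per axis.
#' @param voxel_size isotropic voxel size (mm).
#' @return data.frame with 0-based voxel indices `ix, iy, iz`, segment
#'   `len` (mm) and unit direction `dx, dy, dz`. Empty if the streamline
#'   lies entirely outside the grid.
#' @export
trace_streamline <- function(points, grid_shape, voxel_size) {
  points <- as.matrix(points)
  stopifnot(nrow(points) >= 2, ncol(points) == 3, voxel_size > 0)
  ext <- grid_shape * voxel_size
  out <- vector("list", nrow(points) - 1)
  for (s in seq_len(nrow(points) - 1)) {
    p0 <- points[s, ]; p1 <- points[s + 1, ]
    L <- sqrt(sum((p1 - p0)^2))
    if (L < 1e-12) next
    d <- (p1 - p0) / L
    # clip [0, L] to the grid box (slab method)
    t0 <- 0; t1 <- L
    for (a in 1:3) {
      if (abs(d[a]) < 1e-14) {
        if (p0[a] < 0 || p0[a] >= ext[a]) { t0 <- Inf; break }
      } else {
        ta <- (0 - p0[a]) / d[a]; tb <- (ext[a] - p0[a]) / d[a]
        if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
        t0 <- max(t0, ta); t1 <- min(t1, tb)
      }
    }
    if (!is.finite(t0) || t0 >= t1) next
    # voxel boundary crossings inside (t0, t1)
    ts <- c(t0, t1)
    for (a in 1:3) {
      if (abs(d[a]) < 1e-14) next
      lo <- p0[a] + d[a] * t0; hi <- p0[a] + d[a] * t1
      if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
      ks <- seq(ceiling(lo / voxel_size), floor(hi / voxel_size))
      ks <- ks[ks >= 1 & ks <= grid_shape[a] - 1]
      if (length(ks))
        ts <- c(ts, (ks * voxel_size - p0[a]) / d[a])
    }
    ts <- sort(unique(pmin(pmax(ts, t0), t1)))
    lens <- diff(ts)
    keep <- lens > 1e-12
    if (!any(keep)) next
    tm <- (ts[-length(ts)] + ts[-1])[keep] / 2
    mids <- cbind(p0[1] + d[1] * tm, p0[2] + d[2] * tm, p0[3] + d[3] * tm)
    vox <- pmin(pmax(floor(mids / voxel_size), 0),
                matrix(grid_shape - 1, nrow(mids), 3, byrow = TRUE))
    out[[s]] <- data.frame(ix = vox[, 1], iy = vox[, 2], iz = vox[, 3],
                           len = lens[keep], dx = d[1], dy = d[2], dz = d[3])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0)
    return(data.frame(ix = integer(), iy = integer(), iz = integer(),
                      len = numeric(), dx = numeric(), dy = numeric(),
                      dz = numeric()))
  do.call(rbind, out)
}

# Trace every streamline of a tractogram; returns a list of segment tables.
trace_tractogram <- function(tractogram, grid_shape, voxel_size) {
  lapply(tractogram, trace_streamline, grid_shape = grid_shape,
         voxel_size = voxel_size)
}

#' Arc length of each streamline inside the grid
#' @param segments list of segment tables from [trace_streamline()].
#' @return Numeric vector of lengths (mm).
#' @export
streamline_lengths <- function(segments) {
  vapply(segments, function(s) sum(s$len), numeric(1))
}
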