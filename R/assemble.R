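#' Assemble the global streamline forward model
#'
#' Builds the sparse linear system relating non-negative unknowns (one
#' zeppelin weight per streamline plus one ball weight per fitted voxel) to
#' the b0-normalized signal of every (voxel, volume) pair. A streamline's
#' entry at (voxel, volume) is the sum over its voxel segments of
#' `segment length x zeppelin attenuation` along the segment direction; the
#' ball column of a voxel carries the isotropic attenuation. The fitted mask
#' is the set of voxels traversed by at least one streamline, optionally
#' dilated; b = 0 rows are included (they anchor the total signal fraction).
#'
#' @param tractogram list of streamline vertex matrices (mm, grid frame).
#' @param scheme an [acquisition_scheme()].
#' @param grid_shape voxel counts per axis.
#' @param voxel_size isotropic voxel size (mm).
#' @param dwi 4D array of signals (grid_shape x n_volumes).
#' @param normalizer 3D array, the MT-off b = 0 image used to normalize both
#'   fits; must be positive inside the mask.
#' @param zp,bp compartment parameters ([zeppelin_params()], [ball_params()]).
#' @param dilate number of 26-neighborhood dilation passes applied to the
#'   mask (default 0).
#' @param segments optional precomputed [trace_tractogram()] output.
#' @return Object of class `mt_fit_problem`: sparse operator `A`
#'   (rows ordered voxel-major, `n_vol` consecutive rows per mask voxel;
#'   columns: streamlines then ball voxels), observations `y`, `mask`
#'   (matrix of 0-based voxel indices), `lengths` (streamline arc lengths),
#'   plus geometry and scheme metadata.
#' @export
assemble_system <- function(tractogram, scheme, grid_shape, voxel_size,
                            dwi, normalizer, zp = zeppelin_params(),
                            bp = ball_params(), dilate = 0L, segments = NULL) {
  stopifnot(inherits(scheme, "mt_scheme"))
  n_vol <- scheme$n_volumes
  stopifnot(length(dim(dwi)) == 4, all(dim(dwi)[1:3] == grid_shape),
            dim(dwi)[4] == n_vol, all(dim(normalizer) == grid_shape))
  if (is.null(segments))
    segments <- trace_tractogram(tractogram, grid_shape, voxel_size)
  n_str <- length(segments)
  lin <- function(ix, iy, iz)
    1L + ix + iy * grid_shape[1] + iz * grid_shape[1] * grid_shape[2]
  trav <- unique(unlist(lapply(segments, function(s)
    if (nrow(s)) lin(s$ix, s$iy, s$iz) else integer())))
  mask_lin <- sort(trav)
  if (dilate > 0) mask_lin <- dilate_mask(mask_lin, grid_shape, dilate)
  if (length(mask_lin) == 0) stop("no voxel is traversed by any streamline")
  vox_pos <- integer(prod(grid_shape))
  vox_pos[mask_lin] <- seq_along(mask_lin)
  n_mask <- length(mask_lin)

  norm_v <- normalizer[mask_lin]
  if (any(!is.finite(norm_v)) || any(norm_v <= 0))
    stop("non-positive normalizer inside the fitted mask at voxel(s): ",
         paste(utils::head(mask_lin[!is.finite(norm_v) | norm_v <= 0], 10),
               collapse = ", "))

  b <- scheme$bvals; g <- scheme$bvecs
  ball_col <- ball_response(b, bp)

  ri <- vector("list", n_str + 1L)
  ci <- vector("list", n_str + 1L)
  xv <- vector("list", n_str + 1L)
  for (i in seq_len(n_str)) {
    s <- segments[[i]]
    if (nrow(s) == 0) next
    v <- lin(s$ix, s$iy, s$iz)
    uv <- unique(v)
    acc <- matrix(0, n_vol, length(uv))
    colnames(acc) <- as.character(uv)
    for (k in seq_len(nrow(s))) {
      att <- s$len[k] * zeppelin_response(b, g, c(s$dx[k], s$dy[k], s$dz[k]), zp)
      j <- match(v[k], uv)
      acc[, j] <- acc[, j] + att
    }
    m <- vox_pos[uv]
    ri[[i]] <- as.vector(outer(seq_len(n_vol), (m - 1L) * n_vol, `+`))
    ci[[i]] <- rep(i, n_vol * length(uv))
    # rows carry the same per-voxel b0 normalization as the observations,
    # so generation and fitting share one forward model exactly
    xv[[i]] <- as.vector(sweep(acc, 2, norm_v[m], `/`))
  }
  # ball columns
  ri[[n_str + 1L]] <- as.vector(outer(seq_len(n_vol),
                                      (seq_len(n_mask) - 1L) * n_vol, `+`))
  ci[[n_str + 1L]] <- rep(n_str + seq_len(n_mask), each = n_vol)
  xv[[n_str + 1L]] <- rep(ball_col, n_mask) / rep(norm_v, each = n_vol)

  A <- Matrix::sparseMatrix(i = unlist(ri), j = unlist(ci), x = unlist(xv),
                            dims = c(n_mask * n_vol, n_str + n_mask))

  y <- problem_observations_internal(dwi, mask_lin, norm_v, grid_shape, n_vol)
  mask_idx <- arrayInd(mask_lin, grid_shape) - 1L
  structure(list(A = A, y = y, n_streamlines = n_str, n_mask = n_mask,
                 mask_lin = mask_lin, mask = mask_idx, norm = norm_v,
                 grid_shape = grid_shape, voxel_size = voxel_size,
                 n_vol = n_vol, scheme = scheme, zp = zp, bp = bp,
                 lengths = streamline_lengths(segments)),
            class = "mt_fit_problem")
}

problem_observations_internal <- function(dwi, mask_lin, norm_v, grid_shape,
                                          n_vol) {
  dmat <- matrix(dwi, nrow = prod(grid_shape), ncol = n_vol)
  as.vector(t(dmat[mask_lin, , drop = FALSE] / norm_v))
}

#' Observations of another volume under an assembled problem
#'
#' Normalizes `dwi` by the problem's stored MT-off b0 normalizer and orders
#' it row-compatibly with the problem operator, so the same operator can be
#' fit to the MT-on data.
#'
#' @param problem an [assemble_system()] result.
#' @param dwi 4D array on the same grid.
#' @return Observation vector.
#' @export
problem_observations <- function(problem, dwi) {
  stopifnot(inherits(problem, "mt_fit_problem"),
            all(dim(dwi)[1:3] == problem$grid_shape),
            dim(dwi)[4] == problem$n_vol)
  problem_observations_internal(dwi, problem$mask_lin, problem$norm,
                                problem$grid_shape, problem$n_vol)
}

# one or more 26-neighborhood dilation passes on a linear-index voxel set
dilate_mask <- function(mask_lin, grid_shape, passes) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  for (p in seq_len(passes)) {
    idx <- arrayInd(mask_lin, grid_shape)
    nb <- do.call(rbind, lapply(seq_len(nrow(off)), function(k)
      sweep(idx, 2, off[k, ], `+`)))
    ok <- nb[, 1] >= 1 & nb[, 1] <= grid_shape[1] &
      nb[, 2] >= 1 & nb[, 2] <= grid_shape[2] &
      nb[, 3] >= 1 & nb[, 3] <= grid_shape[3]
    nb <- nb[ok, , drop = FALSE]
    mask_lin <- sort(unique(nb[, 1] + (nb[, 2] - 1L) * grid_shape[1] +
                              (nb[, 3] - 1L) * grid_shape[1] * grid_shape[2]))
  }
  mask_lin
}
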