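#' Non-negative least squares by accelerated projected gradient
#'
#' Minimizes `0.5 * ||A x - y||^2` subject to `x >= 0` with Nesterov-
#' accelerated projected gradient descent at fixed step `1/L`, where `L` (the
#' largest squared singular value of `A`) is estimated by power iteration.
#' Acceleration is restarted whenever the candidate would increase the
#' objective, falling back to a plain projected-gradient step from the
#' current iterate, so the recorded objective is non-increasing. Iteration
#' stops when the relative objective change drops below `tol`.
#'
#' @param problem an [assemble_system()] result, or a matrix `A` (dense or
#'   sparse) if `y` is given.
#' @param y observation vector (ignored when `problem` is an
#'   `mt_fit_problem` unless supplied to override its stored observations).
#' @param tol relative objective-change stopping tolerance.
#' @param max_iter iteration cap.
#' @return Object of class `mt_nnls_fit`: `x` (weights), `streamline_weights`
#'   and `ball_weights` (when solved from a problem), `objective`,
#'   `iterations`, `trace` (objective per iteration).
#' @export
nnls_solve <- function(problem, y = NULL, tol = 1e-10, max_iter = 5000L) {
  if (inherits(problem, "mt_fit_problem")) {
    A <- problem$A
    if (is.null(y)) y <- problem$y
    n_str <- problem$n_streamlines
  } else {
    A <- problem
    if (is.null(y)) stop("y is required when a bare matrix is supplied")
    n_str <- NULL
  }
  stopifnot(nrow(A) == length(y))
  n <- ncol(A)
  obj <- function(x, r = A %*% x - y) 0.5 * sum(r^2)

  # largest squared singular value by power iteration
  v <- rep(1 / sqrt(n), n)
  L <- 1
  for (k in 1:100) {
    w <- as.vector(Matrix::crossprod(A, A %*% v))
    L <- sqrt(sum(w^2))
    if (L == 0) break
    v <- w / L
  }
  if (L == 0) L <- 1
  step <- 1 / (L * 1.0001)

  x <- rep(0, n); z <- x; tk <- 1
  f <- obj(x)
  f0 <- f
  trace <- numeric(max_iter)
  iters <- 0L
  for (it in seq_len(max_iter)) {
    g <- as.vector(Matrix::crossprod(A, A %*% z - y))
    x_new <- pmax(0, z - step * g)
    f_new <- obj(x_new)
    if (f_new > f) {
      # restart: guaranteed-descent projected-gradient step from x
      g <- as.vector(Matrix::crossprod(A, A %*% x - y))
      x_new <- pmax(0, x - step * g)
      f_new <- obj(x_new)
      z <- x_new; tk <- 1
    } else {
      t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
      z <- x_new + ((tk - 1) / t_new) * (x_new - x)
      tk <- t_new
    }
    if (!is.finite(f_new) || f_new > 10 * f0 + 1)
      stop("nnls_solve: divergent objective at iteration ", it)
    iters <- it
    trace[it] <- f_new
    rel <- abs(f - f_new) / max(f, .Machine$double.eps)
    x <- x_new; f <- f_new
    if (rel < tol) break
  }
  out <- list(x = x, objective = f, iterations = iters,
              trace = trace[seq_len(iters)])
  if (!is.null(n_str)) {
    out$streamline_weights <- x[seq_len(n_str)]
    out$ball_weights <- x[n_str + seq_len(n - n_str)]
  }
  structure(out, class = "mt_nnls_fit")
}

#' @export
print.mt_nnls_fit <- function(x, ...) {
  cat("NNLS fit:", length(x$x), "unknowns,", x$iterations,
      "iterations, objective", signif(x$objective, 6), "\n")
  invisible(x)
}

#' Per-voxel residual and isotropic-fraction maps
#'
#' @param problem an [assemble_system()] result.
#' @param result an [nnls_solve()] result for that problem.
#' @param y optional observation vector the fit used (defaults to the
#'   problem's stored observations).
#' @return List with `rmse_map` (root-mean-squared residual over each mask
#'   voxel's rows) and `iso_map` (ball weight per voxel), both 3D arrays,
#'   `NA` outside the mask.
#' @export
residual_maps <- function(problem, result, y = NULL) {
  stopifnot(inherits(problem, "mt_fit_problem"),
            inherits(result, "mt_nnls_fit"))
  if (is.null(y)) y <- problem$y
  r <- as.vector(problem$A %*% result$x) - y
  rm <- matrix(r, nrow = problem$n_vol)
  rmse_v <- sqrt(colMeans(rm^2))
  rmse_map <- array(NA_real_, problem$grid_shape)
  iso_map <- array(NA_real_, problem$grid_shape)
  rmse_map[problem$mask_lin] <- rmse_v
  # ball signal fraction in b0-normalized units
  iso_map[problem$mask_lin] <- result$ball_weights / problem$norm
  list(rmse_map = rmse_map, iso_map = iso_map)
}
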