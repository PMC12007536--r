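# Independent oracles used by the tests. These deliberately re-derive the
# quantities through different algorithms than the package implementation.

# --- active-set (Lawson-Hanson) non-negative least squares ---------------
lawson_hanson_nnls <- function(A, y, tol = 1e-12) {
  A <- as.matrix(A)
  n <- ncol(A)
  P <- logical(n)
  x <- rep(0, n)
  for (outer in 1:(10 * n + 10)) {
    w <- drop(crossprod(A, y - A %*% x))
    if (all(P) || max(w[!P]) <= tol) break
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      s <- rep(0, n)
      Ap <- A[, P, drop = FALSE]
      s[P] <- drop(solve(crossprod(Ap), crossprod(Ap, y)))
      if (all(s[P] > tol)) { x <- s; break }
      q <- P & (s <= tol)
      alpha <- min(x[q] / (x[q] - s[q]))
      x <- x + alpha * (s - x)
      P <- P & (x > tol)
      x[!P] <- 0
    }
  }
  x
}

# --- classical RK4 on the two-pool + dipolar ODE -------------------------
# State (Mxa, Mya, Mza, Mzb, beta); written from the rate equations, not
# from the package's generator matrix.
two_pool_rhs <- function(s, tis, ra, w1, offset_hz, G) {
  dw <- 2 * pi * offset_hz
  W <- pi * w1^2 * G
  kf <- tis$R * tis$M0b
  kr <- tis$R
  rb <- 1 / tis$T1b
  c(-s[1] / tis$T2a + dw * s[2],
    -dw * s[1] - s[2] / tis$T2a + w1 * s[3],
    -w1 * s[2] + ra * (1 - s[3]) - kf * s[3] + kr * s[4],
    rb * (tis$M0b - s[4]) + kf * s[3] - kr * s[4] - W * (s[4] - dw * s[5]),
    W * (dw / tis$omega_loc^2) * (s[4] - dw * s[5]) - s[5] / tis$T1d)
}

rk4_two_pool <- function(s, tis, ra, w1, offset_hz, G, dt, nsteps) {
  h <- dt / nsteps
  for (i in seq_len(nsteps)) {
    k1 <- two_pool_rhs(s, tis, ra, w1, offset_hz, G)
    k2 <- two_pool_rhs(s + h / 2 * k1, tis, ra, w1, offset_hz, G)
    k3 <- two_pool_rhs(s + h / 2 * k2, tis, ra, w1, offset_hz, G)
    k4 <- two_pool_rhs(s + h * k3, tis, ra, w1, offset_hz, G)
    s <- s + h / 6 * (k1 + 2 * k2 + k3 * 2 + k4)
  }
  s
}

# --- composite-Simpson super-Lorentzian ----------------------------------
# Fixed fine grid split at the singular angle, independent of the adaptive
# quadrature in the package.
simpson_super_lorentzian <- function(offset_hz, T2b, n = 200001L) {
  x <- 2 * pi * abs(offset_hz) * T2b
  f <- function(u) {
    d <- 3 * u^2 - 1
    sqrt(2 / pi) * T2b / abs(d) * exp(-2 * (x / d)^2)
  }
  simpson <- function(lo, hi) {
    u <- seq(lo, hi, length.out = n)
    h <- u[2] - u[1]
    v <- f(u)
    h / 3 * (v[1] + v[n] + 4 * sum(v[seq(2, n - 1, 2)]) +
               2 * sum(v[seq(3, n - 2, 2)]))
  }
  u0 <- 1 / sqrt(3)
  simpson(0, u0 - 1e-12) + simpson(u0 + 1e-12, 1)
}

# --- textbook paired t statistic -----------------------------------------
paired_t_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  tval <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = tval, df = n - 1,
       p = 2 * stats::pt(-abs(tval), df = n - 1))
}
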