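#' Saturation state of the two-pool system
#'
#' State vector advanced by the saturation integrator: free-pool
#' magnetization (Mxa, Mya, Mza; M0a = 1), bound-pool longitudinal
#' magnetization Mzb, and the dipolar-order variable beta (inverse spin
#' temperature of the dipolar reservoir, in rad/s^-1 units such that the
#' saturation term reads `W * (Mzb - 2*pi*offset*beta)`).
#'
#' @param Mxa,Mya,Mza free-pool magnetization components.
#' @param Mzb bound-pool longitudinal magnetization.
#' @param beta dipolar-order variable.
#' @return Named numeric vector of class `saturation_state`.
#' @export
saturation_state <- function(Mxa = 0, Mya = 0, Mza = 1, Mzb = 0.1, beta = 0) {
  structure(c(Mxa = Mxa, Mya = Mya, Mza = Mza, Mzb = Mzb, beta = beta),
            class = "saturation_state")
}

#' Thermal-equilibrium state of a tissue
#' @param tissue a [two_pool_tissue()].
#' @return A [saturation_state()] at equilibrium: (0, 0, 1, M0b, 0).
#' @export
equilibrium_state <- function(tissue) {
  saturation_state(0, 0, 1, tissue$M0b, 0)
}

# Affine generator of the coupled two-pool + dipolar system for constant RF
# amplitude w1 (rad/s) at offset dw = 2*pi*offset_hz (rad/s). The 6th
# component is the constant 1 that carries relaxation toward equilibrium.
# Free pool: full Bloch equations (no lineshape approximation; valid down to
# ~1 kHz offsets). Bound pool: saturation rate W = pi*w1^2*G(offset) with the
# Provotorov dipolar coupling -W*(Mzb - dw*beta); dipolar order:
# dbeta/dt = W*(dw/omega_loc^2)*(Mzb - dw*beta) - beta/T1d.
sat_generator <- function(tissue, ra, w1, offset_hz, G) {
  dw <- 2 * pi * offset_hz
  kf <- tissue$R * tissue$M0b
  kr <- tissue$R
  rb <- 1 / tissue$T1b
  W <- pi * w1^2 * G
  wl2 <- tissue$omega_loc^2
  M <- matrix(0, 6, 6)
  M[1, 1] <- -1 / tissue$T2a; M[1, 2] <- dw
  M[2, 1] <- -dw; M[2, 2] <- -1 / tissue$T2a; M[2, 3] <- w1
  M[3, 2] <- -w1; M[3, 3] <- -(ra + kf); M[3, 4] <- kr; M[3, 6] <- ra
  M[4, 3] <- kf; M[4, 4] <- -(rb + kr + W); M[4, 5] <- W * dw
  M[4, 6] <- rb * tissue$M0b
  M[5, 4] <- W * dw / wl2; M[5, 5] <- -(W * dw^2 / wl2 + 1 / tissue$T1d)
  M
}

expm6 <- function(M) as.matrix(Matrix::expm(Matrix::Matrix(M)))

#' Advance the saturation state over one constant-RF segment
#'
#' Integrates the coupled free-pool Bloch / bound-pool saturation / dipolar
#' order system over `dt` with constant RF amplitude `w1` at `offset_hz`, via
#' the matrix exponential of the affine system (exact for piecewise-constant
#' coefficients; no step-size tuning).
#'
#' @param state a [saturation_state()].
#' @param tissue a [two_pool_tissue()].
#' @param w1 RF amplitude (rad/s) over the segment.
#' @param offset_hz irradiation offset (Hz); its sign sets the polarity.
#' @param dt segment duration (s, > 0).
#' @param ra intrinsic free-pool longitudinal rate; derived from the tissue
#'   when `NULL`.
#' @return The advanced [saturation_state()].
#' @export
integrate_saturation <- function(state, tissue, w1, offset_hz, dt, ra = NULL) {
  stopifnot(dt > 0, length(state) == 5)
  if (!all(is.finite(state))) stop("non-finite saturation state")
  if (is.null(ra)) ra <- derive_intrinsic_ra(tissue)
  G <- if (w1 == 0) 0 else lineshape_g(abs(offset_hz), tissue$T2b, tissue$lineshape)
  P <- expm6(sat_generator(tissue, ra, w1, offset_hz, G) * dt)
  out <- drop(P %*% c(unclass(state), 1))[1:5]
  saturation_state(out[1], out[2], out[3], out[4], out[5])
}

# Propagator (6x6) of one Gaussian MT pulse at the signed offset, composed
# from piecewise-constant segments.
pulse_propagator <- function(tissue, ra, prep, offset_signed, G,
                             n_segments = 64L) {
  w1 <- gaussian_pulse_waveform(prep$fa_mt, prep$tau, n_segments)
  dt <- attr(w1, "dt")
  P <- diag(6)
  for (k in seq_along(w1))
    P <- expm6(sat_generator(tissue, ra, w1[k], offset_signed, G) * dt) %*% P
  P
}

# Build the per-TR_MT cycle propagators: the preparation train (pulses with
# the polarity scheme, each followed by the gap delta_t) and the remainder
# of TR_MT (free relaxation preceded by a transverse spoiler standing in for
# the diffusion gradients/crushers). The signal proxy is Mza read right after
# the train.
cycle_propagators <- function(protocol, tissue, ra, n_segments = 64L) {
  prep <- protocol$prep
  G <- lineshape_g(prep$offset_hz, tissue$T2b, tissue$lineshape)
  P_pos <- pulse_propagator(tissue, ra, prep, prep$offset_hz, G, n_segments)
  P_neg <- if (prep$polarity == "alternating")
    pulse_propagator(tissue, ra, prep, -prep$offset_hz, G, n_segments)
  else P_pos
  P_gap <- if (prep$delta_t > 0)
    expm6(sat_generator(tissue, ra, 0, prep$offset_hz, G) * prep$delta_t)
  else diag(6)
  # Free-pool transverse coherence is not carried from pulse to pulse: at
  # multi-kHz offsets the residual Mxy is dephased by B0 dispersion long
  # before the next pulse, and tracking it makes the polarity comparison
  # depend on an unphysical coherent pathway. Within-pulse transverse
  # dynamics (direct saturation) remain exact.
  spoil <- diag(6); spoil[1, 1] <- 0; spoil[2, 2] <- 0
  train <- diag(6)
  for (p in seq_len(prep$n_pulses)) {
    Pp <- if (prep$polarity == "alternating" && p %% 2 == 0) P_neg else P_pos
    train <- P_gap %*% spoil %*% Pp %*% train
  }
  t_rel <- protocol$tr_mt - prep$n_pulses * (prep$tau + prep$delta_t)
  P_rel <- expm6(sat_generator(tissue, ra, 0, prep$offset_hz, G) * t_rel)
  list(train = train, rest = P_rel %*% spoil)
}

#' Steady-state MT-prepared signal
#'
#' Repeats the per-slice cycle (MT preparation train, then free relaxation
#' filling the remainder of TR_MT with the transverse magnetization spoiled
#' by the diffusion gradients) from thermal equilibrium until the
#' cycle-to-cycle change of the free-pool longitudinal magnetization read at
#' excitation falls below `tol`. With alternating polarity the offset sign
#' flips on successive pulses, restarting positive at each preparation.
#'
#' @param protocol an [sequence_protocol()].
#' @param tissue a [two_pool_tissue()].
#' @param with_prep `FALSE` simulates the MT-off acquisition (FA_MT = 0).
#' @param n_segments RF waveform segments per pulse.
#' @param tol convergence tolerance on Mza between consecutive cycles.
#' @param max_cycles iteration cap.
#' @return Mza at excitation (signal proxy, units of M0a), with attributes
#'   `cycles` and `delta`.
#' @export
steady_state_signal <- function(protocol, tissue, with_prep = TRUE,
                                n_segments = 64L, tol = 1e-8,
                                max_cycles = 500L) {
  stopifnot(inherits(protocol, "mt_protocol"), inherits(tissue, "two_pool_tissue"))
  if (!with_prep) {
    protocol$prep$fa_mt <- 0
  }
  ra <- derive_intrinsic_ra(tissue)
  cp <- cycle_propagators(protocol, tissue, ra, n_segments)
  s <- c(0, 0, 1, tissue$M0b, 0, 1)
  sig_prev <- Inf
  for (i in seq_len(max_cycles)) {
    s_read <- cp$train %*% s
    sig <- s_read[3]
    if (!is.finite(sig)) stop("steady_state_signal: non-finite state at cycle ", i)
    delta <- abs(sig - sig_prev)
    if (delta < tol)
      return(structure(sig, cycles = i, delta = delta))
    sig_prev <- sig
    s <- cp$rest %*% s_read
  }
  stop("steady_state_signal: no convergence in ", max_cycles,
       " cycles (last delta = ", signif(abs(sig - sig_prev), 3), ")")
}
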