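# Two-layer spinal CPG: rhythm generation by four coupled phase
# oscillators (one per limb) and pattern formation by four rectangular
# pulses per limb combined through muscle-specific synergy weights.

#' Oscillator network state
#'
#' Four phase oscillators (left/right x fore/hind) with contralateral
#' antiphase coupling (gain `K1`) and ipsilateral coupling at relative
#' phase `Delta` (gain `K2`):
#' `phidot_fore = 2 pi / T - K1 sin(phi_fore - phi_contra - pi)
#'               - K2 sin(phi_fore - phi_hind + Delta)` and the hindlimb
#' equations carry `-Delta`.
#'
#' @param phi named numeric(4) of phases in `[0, 2 pi)`, order
#'   `LF, RF, LH, RH`
#' @param T gait cycle duration (s)
#' @param K1,K2 coupling gains (1/s)
#' @param Delta ipsilateral phase offset (rad): `pi/2` walk, `pi` trot
#' @return object of class `rat_oscillators`
#' @export
oscillator_state <- function(phi = gait_fixed_point(pi / 2), T = 0.26,
                             K1 = 20, K2 = 10, Delta = pi / 2) {
  if (T <= 0) stop("cycle duration T must be positive")
  phi <- setNames(as.numeric(phi) %% (2 * pi), c("LF", "RF", "LH", "RH"))
  structure(list(phi = phi, T = T, K1 = K1, K2 = K2, Delta = Delta),
            class = "rat_oscillators")
}

#' Phase-locked configuration of a gait
#'
#' The coupling fixed point: contralateral pairs in antiphase and
#' `phi_fore - phi_hind = -Delta`.  Anchored so that the right hindlimb
#' starts its extension phase (`phi_RH = 0`).
#'
#' @param Delta ipsilateral phase offset (rad)
#' @return named numeric(4) of phases
#' @export
gait_fixed_point <- function(Delta) {
  phi <- c(LF = pi - Delta, RF = 2 * pi - Delta, LH = pi, RH = 0)
  phi %% (2 * pi)
}

.osc_rhs <- function(phi, T, K1, K2, Delta) {
  w <- 2 * pi / T
  c(w - K1 * sin(phi[1] - phi[2] - pi) - K2 * sin(phi[1] - phi[3] + Delta),
    w - K1 * sin(phi[2] - phi[1] - pi) - K2 * sin(phi[2] - phi[4] + Delta),
    w - K1 * sin(phi[3] - phi[4] - pi) - K2 * sin(phi[3] - phi[1] - Delta),
    w - K1 * sin(phi[4] - phi[3] - pi) - K2 * sin(phi[4] - phi[2] - Delta))
}

#' Advance the oscillator network one step
#'
#' Fourth-order Runge-Kutta step of the four coupled phase equations,
#' phases wrapped to `[0, 2 pi)` afterwards.
#'
#' @param state a `rat_oscillators`
#' @param dt time step (s)
#' @return updated `rat_oscillators`
#' @export
oscillator_step <- function(state, dt) {
  if (dt <= 0) stop("dt must be positive")
  f <- function(p) .osc_rhs(p, state$T, state$K1, state$K2, state$Delta)
  p <- unname(state$phi)
  k1 <- f(p); k2 <- f(p + dt / 2 * k1)
  k3 <- f(p + dt / 2 * k2); k4 <- f(p + dt * k3)
  state$phi <- setNames((p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)) %% (2 * pi),
                        names(state$phi))
  state
}

#' Synergy pulse schedule
#'
#' Onset phases `Phi_i` and end phases `Psi_i` of the four rectangular
#' pulses (early/late extension, early/late flexion) plus the muscle
#' weight matrix.  With no rescaling (`beta = beta_hat`) the nominal
#' values are `Phi = (0, 0.40, 1.24, 1.42) pi` and
#' `Psi = (0.33, 0.89, 1.42, 1.71) pi`.
#'
#' @param beta extension-phase fraction; the nominal schedule is
#'   rescaled by [scaled_pulse_phases()] and [scaled_weights()]
#' @param cfg configuration list
#' @return object of class `rat_synergy_schedule` with elements `Phi`,
#'   `Psi` (rad) and `w` (muscles x 4 weight matrix)
#' @export
synergy_schedule <- function(beta = NULL, cfg = default_config()) {
  ctl <- cfg$control
  Phi <- ctl$Phi_hat_pi * pi
  Psi <- ctl$Psi_hat_pi * pi
  muscles <- muscle_set(cfg)
  w <- as.matrix(muscles[, c("w1", "w2", "w3", "w4")])
  rownames(w) <- muscles$name
  limb <- setNames(muscles$limb, muscles$name)
  out <- structure(list(Phi = Phi, Psi = Psi, w = w, limb = limb,
                        beta_hat = ctl$beta_hat),
                   class = "rat_synergy_schedule")
  if (!is.null(beta)) {
    ph <- scaled_pulse_phases(beta, out)
    out$Phi <- ph$Phi; out$Psi <- ph$Psi
    out$w <- scaled_weights(beta, out)
  }
  .schedule_check(out)
  out
}

.schedule_check <- function(s) {
  stopifnot(s$Phi[1] == 0, all(s$Phi >= 0), all(s$Phi < s$Psi),
            all(s$Psi <= 2 * pi), all(s$w >= 0))
  invisible(s)
}

#' Rectangular pulse values at a phase
#'
#' `p_i = 1` iff `Phi_i <= phi < Psi_i` (half-open interval).
#'
#' @param schedule a `rat_synergy_schedule`
#' @param phi phase in `[0, 2 pi)`
#' @return integer vector `p_1..p_4` of 0/1
#' @export
pulse_values <- function(schedule, phi) {
  as.integer(phi >= schedule$Phi & phi < schedule$Psi)
}

#' Synergy motor command
#'
#' `u_syn_m = sum_i w_{m,i} p_i(phi_limb)`, each muscle reading the
#' oscillator of its own limb.
#'
#' @param schedule a `rat_synergy_schedule`
#' @param phi either a single phase (applied to all muscles) or a named
#'   numeric(4) of limb phases (`LF`, `RF`, `LH`, `RH`)
#' @return named numeric vector of per-muscle commands
#' @export
synergy_command <- function(schedule, phi) {
  if (length(phi) == 1) {
    p <- pulse_values(schedule, phi)
    return(setNames(as.numeric(schedule$w %*% p), rownames(schedule$w)))
  }
  stopifnot(length(phi) == 4)
  if (is.null(names(phi))) names(phi) <- c("LF", "RF", "LH", "RH")
  out <- numeric(nrow(schedule$w))
  for (i in seq_along(out)) {
    p <- pulse_values(schedule, phi[[schedule$limb[i]]])
    out[i] <- sum(schedule$w[i, ] * p)
  }
  setNames(out, rownames(schedule$w))
}
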