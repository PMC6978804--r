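# Gait selection and speed modulation.  Gait is chosen by the
# ipsilateral phase offset Delta alone (pi/2 walk, pi trot).  Speed is
# modulated by the extension fraction beta: the flexion (swing) duration
# T_fl stays fixed while the extension (stance) duration T_ex = beta T
# changes, so T = T_fl / (1 - beta).  Pulse timings, extension-pulse
# weights and the regulator references are all rescaled from their
# nominal values (at beta_hat = 0.62) as functions of beta.

#' Gait configuration
#'
#' @param gait `"walk"` (`Delta = pi/2`) or `"trot"` (`Delta = pi`)
#' @param beta extension fraction in (0, 1); defaults to the nominal
#'   `beta_hat`
#' @param cfg configuration list
#' @return object of class `rat_gait_config` with `Delta`, `beta`,
#'   `beta_hat`, `T_fl`, `T` and `T_ex`
#' @export
gait_config <- function(gait = c("walk", "trot"), beta = NULL,
                        cfg = default_config()) {
  gait <- match.arg(gait)
  ctl <- cfg$control
  if (is.null(beta)) beta <- ctl$beta_hat
  if (beta <= 0 || beta >= 1) stop("beta must lie in (0, 1)")
  T <- ctl$T_fl_s / (1 - beta)
  structure(list(gait = gait, Delta = if (gait == "walk") pi / 2 else pi,
                 beta = beta, beta_hat = ctl$beta_hat,
                 T_fl = ctl$T_fl_s, T = T, T_ex = beta * T),
            class = "rat_gait_config")
}

#' Rescaled pulse phases
#'
#' Extension pulses (i = 1, 2) scale with `beta / beta_hat`; flexion
#' pulses (i = 3, 4) scale with `(1 - beta) / (1 - beta_hat)` and shift
#' by `2 pi (beta - beta_hat) / (1 - beta_hat)`, which keeps the
#' extension/flexion boundary at `Phi_3 = 2 pi beta` for every beta.
#'
#' @param beta extension fraction in (0, 1)
#' @param schedule nominal schedule ([synergy_schedule()])
#' @return list with rescaled `Phi` and `Psi` (rad)
#' @export
scaled_pulse_phases <- function(beta, schedule = synergy_schedule()) {
  if (beta <= 0 || beta >= 1) stop("beta must lie in (0, 1)")
  bh <- schedule$beta_hat
  sc_ext <- beta / bh
  sc_fl <- (1 - beta) / (1 - bh)
  sh_fl <- 2 * pi * (beta - bh) / (1 - bh)
  list(Phi = c(sc_ext * schedule$Phi[1:2], sc_fl * schedule$Phi[3:4] + sh_fl),
       Psi = c(sc_ext * schedule$Psi[1:2], sc_fl * schedule$Psi[3:4] + sh_fl))
}

#' Rescaled synergy weights
#'
#' Extension-pulse weights (i = 1, 2) scale with
#' `(1 - beta) / (1 - beta_hat)` (shorter extension pulses are made
#' stronger and vice versa); flexion-pulse weights are unchanged.
#'
#' @inheritParams scaled_pulse_phases
#' @return rescaled weight matrix
#' @export
scaled_weights <- function(beta, schedule = synergy_schedule()) {
  if (beta <= 0 || beta >= 1) stop("beta must lie in (0, 1)")
  w <- schedule$w
  w[, 1:2] <- w[, 1:2] * (1 - beta) / (1 - schedule$beta_hat)
  w
}

#' Rescaled regulator references
#'
#' Each reference moves linearly with beta:
#' `ref = ref_hat + alpha (beta - beta_hat)`, with
#' `alpha_shoulder = alpha_hip = 0.01 m` and `alpha_speed = -4.7 m/s`
#' by default (longer extension phases mean slower, lower gaits).
#'
#' @param beta extension fraction
#' @param cfg configuration list
#' @return named numeric: `h0_shoulder`, `h0_hip` (m), `v0` (m/s)
#' @export
scaled_references <- function(beta, cfg = default_config()) {
  ctl <- cfg$control
  db <- beta - ctl$beta_hat
  c(h0_shoulder = ctl$h0_shoulder_m + ctl$alpha_shoulder_m * db,
    h0_hip = ctl$h0_hip_m + ctl$alpha_hip_m * db,
    v0 = ctl$v0_ms + ctl$alpha_speed_ms * db)
}

#' Quasi-static beta ramp
#'
#' Piecewise-linear schedule moving beta toward a target by at most
#' `rate` per gait cycle, never overshooting.
#'
#' @param from current beta
#' @param to target beta
#' @param rate change per gait cycle (> 0)
#' @param bounds admissible beta interval
#' @return data frame with columns `cycle` and `beta` (one row per gait
#'   cycle until the target is reached)
#' @export
beta_ramp <- function(from, to, rate = 0.005, bounds = c(0.3, 0.9)) {
  if (rate <= 0) stop("ramp rate must be positive")
  if (to < bounds[1] || to > bounds[2])
    stop("target beta outside configured bounds")
  n <- ceiling(round(abs(to - from) / rate, 9))
  beta <- from + sign(to - from) * rate * seq_len(n)
  beta <- if (to >= from) pmin(beta, to) else pmax(beta, to)
  data.frame(cycle = seq_len(length(beta)), beta = beta)
}
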