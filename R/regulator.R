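# Brainstem/cerebellar movement regulator: posture (shoulder and hip
# height) and forward-speed feedback for stance limbs, delivered with a
# fixed sensorimotor delay (15 ms by default).

.height_muscles <- c("BR", "TRIL", "VL", "TA", "SO")
.speed_muscles <- c("SSP", "SPD", "IP", "GM", "TA", "SO")

#' Regulator parameters
#'
#' Reference shoulder/hip heights and desired speed, the proportional
#' and derivative height gains (BR, TRIL for the shoulder; VL, TA, SO
#' for the hip), speed gains (SSP, SPD, IP, GM, TA, SO) and the
#' sensorimotor delay.
#'
#' @param cfg configuration list
#' @return object of class `rat_regulator_params`
#' @export
regulator_params <- function(cfg = default_config()) {
  ctl <- cfg$control
  out <- list(h0_shoulder = ctl$h0_shoulder_m, h0_hip = ctl$h0_hip_m,
              v0 = ctl$v0_ms,
              K_height = unlist(ctl$K_height), D_height = unlist(ctl$D_height),
              K_speed = unlist(ctl$K_speed),
              tau_delay = ctl$tau_delay_ms * 1e-3)
  if (out$tau_delay < 0) stop("delay must be nonnegative")
  class(out) <- "rat_regulator_params"
  out
}

#' Height-regulation command for one muscle
#'
#' `p = -K (h - h0) - D hdot` while the limb is in stance, else 0.
#' Shoulder height drives BR and TRIL; hip height drives VL, TA and SO.
#'
#' @param params a `rat_regulator_params`
#' @param muscle base muscle name (`BR`, `TRIL`, `VL`, `TA`, `SO`)
#' @param h sensed height (m)
#' @param hdot sensed height rate (m/s)
#' @param in_stance is the limb's tip in ground contact?
#' @param beta optional extension fraction; shifts the reference via
#'   [scaled_references()] when not at the nominal value
#' @param cfg configuration list (for reference scaling)
#' @return dimensionless command
#' @export
height_command <- function(params, muscle, h, hdot, in_stance,
                           beta = NULL, cfg = default_config()) {
  if (!muscle %in% .height_muscles)
    stop("no height regulation for muscle '", muscle, "'")
  if (!in_stance) return(0)
  h0 <- if (muscle %in% c("BR", "TRIL")) params$h0_shoulder else params$h0_hip
  if (!is.null(beta)) {
    refs <- scaled_references(beta, cfg = cfg)
    h0 <- if (muscle %in% c("BR", "TRIL")) refs[["h0_shoulder"]]
          else refs[["h0_hip"]]
  }
  -params$K_height[[muscle]] * (h - h0) - params$D_height[[muscle]] * hdot
}

#' Speed-regulation command for one muscle
#'
#' `p = -K (v - v0)` while the limb is in stance, else 0.
#'
#' @param params a `rat_regulator_params`
#' @param muscle base muscle name (`SSP`, `SPD`, `IP`, `GM`, `TA`, `SO`)
#' @param v sensed forward speed (m/s)
#' @param in_stance is the limb's tip in ground contact?
#' @param beta optional extension fraction (shifts the reference speed)
#' @param cfg configuration list
#' @return dimensionless command
#' @export
speed_command <- function(params, muscle, v, in_stance,
                          beta = NULL, cfg = default_config()) {
  if (!muscle %in% .speed_muscles)
    stop("no speed regulation for muscle '", muscle, "'")
  if (!in_stance) return(0)
  v0 <- params$v0
  if (!is.null(beta)) v0 <- scaled_references(beta, cfg = cfg)[["v0"]]
  -params$K_speed[[muscle]] * (v - v0)
}

#' Delay buffer for regulator commands
#'
#' Ring buffer holding per-muscle command samples written once per
#' control step; reading at time `t` returns the sample written at
#' `t - tau_delay` (an exact multiple of the control step) and zeros
#' before the buffer has filled.
#'
#' @param n_channels number of command channels
#' @param tau_delay delay (s)
#' @param dt control step (s)
#' @return object of class `rat_delay_buffer`
#' @export
delay_buffer <- function(n_channels, tau_delay = 0.015, dt = 2e-5) {
  steps <- max(1L, as.integer(round(tau_delay / dt)))
  structure(list(buf = matrix(0, steps, n_channels), steps = steps,
                 written = 0L, slot = 0L, dt = dt, tau_delay = tau_delay),
            class = "rat_delay_buffer")
}

#' Write to and read from the delay buffer
#'
#' Writes the current command sample and returns the sample from
#' `tau_delay` earlier (zeros during the initial `tau_delay`).
#'
#' @param buffer a `rat_delay_buffer`
#' @param x numeric vector of commands (length `n_channels`)
#' @return list with the updated `buffer` and the `delayed` sample
#' @export
delay_step <- function(buffer, x) {
  slot <- buffer$slot + 1L
  delayed <- if (buffer$written >= buffer$steps) buffer$buf[slot, ]
             else rep(0, ncol(buffer$buf))
  buffer$buf[slot, ] <- x
  buffer$slot <- (buffer$slot + 1L) %% buffer$steps
  buffer$written <- buffer$written + 1L
  list(buffer = buffer, delayed = delayed)
}

#' Delayed regulator output
#'
#' Convenience wrapper: `u_reg(t) = p_height(t - tau) + p_speed(t - tau)`
#' realized by pushing the summed stance-gated commands through the
#' delay buffer.
#'
#' @param buffer a `rat_delay_buffer`
#' @param p_height,p_speed numeric vectors of instantaneous commands
#' @return list with updated `buffer` and `u_reg`
#' @export
regulator_output <- function(buffer, p_height, p_speed) {
  st <- delay_step(buffer, p_height + p_speed)
  list(buffer = st$buffer, u_reg = st$delayed)
}
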