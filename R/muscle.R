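# Hill-type muscles: 6 per forelimb (SSP, SPD, BR, TRIL, BIC, TRI) and
# 7 per hindlimb (IP, GM, VL, TA, SO, BF, GA).
#
# Muscle kinematics use a linear joint-angle map: at the neutral posture
# (shoulder 60, elbow 85, hip 70, knee 90, ankle 100 deg) every
# uniarticular muscle sits at 85% of its maximum length and every
# biarticular muscle at 75%; 2 deg of joint motion corresponds to 1% of
# maximum length (BIC shoulder 4.5 deg, GA ankle 1.5 deg, GA knee
# 4.5 deg).  A muscle with extensor action at a joint shortens as that
# joint angle increases.  Contraction velocities are normalized by
# 1.8 maximum lengths per second.

.neutral_deg <- c(shoulder = 60, elbow = 85, hip = 70, knee = 90, ankle = 100)
.joint_coord <- c(shoulder = "sh", elbow = "el", hip = "hip",
                  knee = "kn", ankle = "ank")

#' The muscle set
#'
#' Builds the table of all 26 muscle instances (13 per side) with
#' maximum tensions, moment arms, geometry coefficients, activation time
#' constants, synergy weights and regulator gains, all in SI units.
#' The per-muscle maximum length `lmax` (needed only to express
#' contraction velocity in m/s for the energetics) is calibrated so that
#' the linear length map is consistent with the joint moment arm
#' (`lmax = MA * coef * pi / 1.8`, averaged over spanned joints).
#'
#' @param cfg configuration list
#' @return data frame of class `rat_muscles`, one row per muscle
#' @export
muscle_set <- function(cfg = default_config()) {
  mc <- cfg$muscles
  geo <- cfg$muscle_geometry
  ctl <- cfg$control
  rows <- list()
  for (side in c("L", "R")) {
    for (base in names(mc$table)) {
      mt <- mc$table[[base]]
      jn <- names(mt$joints)
      nj <- length(jn)
      j1 <- mt$joints[[1]]
      j2 <- if (nj > 1) mt$joints[[2]] else NULL
      cpd <- geo$deg_per_pct_default
      coef1 <- if (is.null(j1$deg_per_pct)) cpd else j1$deg_per_pct
      coef2 <- if (nj > 1) {
        if (is.null(j2$deg_per_pct)) cpd else j2$deg_per_pct
      } else NA_real_
      ma1 <- j1$MA_mm * 1e-3
      ma2 <- if (nj > 1) j2$MA_mm * 1e-3 else NA_real_
      lmax <- mean(c(ma1 * coef1, if (nj > 1) ma2 * coef2)) * pi / 1.8
      w <- rep(0, 4)
      wspec <- ctl$weights[[base]]
      if (!is.null(wspec))
        for (p in 1:4) {
          v <- wspec[[paste0("p", p)]]
          if (!is.null(v)) w[p] <- v
        }
      gk <- function(block) {
        v <- ctl[[block]][[base]]
        if (is.null(v)) 0 else v
      }
      limb <- c(FL = "LF", FR = "RF", HL = "LH", HR = "RH")[[paste0(
        substr(toupper(mt$limb), 1, 1), side)]]
      rows[[length(rows) + 1]] <- data.frame(
        name = paste0(base, "_", side), base = base, side = side,
        limb = limb,
        fmax = mt$Fmax_N, tact = mc$tau_act_s, tdeact = mc$tau_deact_s,
        base_len = if (nj > 1) geo$neutral_length$biarticular
                   else geo$neutral_length$uniarticular,
        lmax = lmax, njoints = nj,
        joint1 = jn[1], action1 = j1$action, ma1 = ma1, coef1 = coef1,
        neut1 = geo$neutral_posture_deg[[jn[1]]],
        joint2 = if (nj > 1) jn[2] else NA_character_,
        action2 = if (nj > 1) j2$action else NA_character_,
        ma2 = ma2, coef2 = coef2,
        neut2 = if (nj > 1) geo$neutral_posture_deg[[jn[2]]] else NA_real_,
        w1 = w[1], w2 = w[2], w3 = w[3], w4 = w[4],
        Kh = gk("K_height"), Dh = gk("D_height"), Ksp = gk("K_speed"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  # order: LF, RF, LH, RH blocks
  out <- out[order(match(out$limb, c("LF", "RF", "LH", "RH"))), ]
  rownames(out) <- out$name
  stopifnot(all(out$fmax > 0), all(out$tact > 0), all(out$tdeact > 0))
  class(out) <- c("rat_muscles", "data.frame")
  out
}

# +1 if the muscle lengthens as the joint angle increases (flexor at
# that joint), -1 if it shortens (extensor)
.len_sign <- function(action) ifelse(action == "flexor", 1, -1)

# resolve the angle (deg) of a spanned joint from a named map that may
# use generic joint names ("ankle") or side-specific coordinate names
# ("ank_L")
.angle_of <- function(angles, joint, side) {
  coord <- paste0(.joint_coord[[joint]], "_", side)
  if (!is.null(angles[[coord]])) return(angles[[coord]])
  if (!is.null(angles[[joint]])) return(angles[[joint]])
  stop("missing angle for joint '", joint, "'")
}

#' Normalized muscle length
#'
#' Evaluates the linear joint-angle-to-length map for each muscle:
#' `lbar = base + sum_j sign_j (angle_j - neutral_j) / coef_j * 0.01`,
#' where a muscle with extensor action at a joint shortens as that
#' angle increases.
#'
#' @param muscles a `rat_muscles` table (or subset of rows)
#' @param joint_angles named list/vector of joint angles in degrees;
#'   names may be generic (`shoulder`, `elbow`, `hip`, `knee`, `ankle`)
#'   or side-specific coordinate names (`sh_L`, ...)
#' @return named numeric vector of normalized lengths
#' @export
muscle_length <- function(muscles, joint_angles) {
  joint_angles <- as.list(joint_angles)
  out <- numeric(nrow(muscles))
  for (i in seq_len(nrow(muscles))) {
    m <- muscles[i, ]
    l <- m$base_len +
      .len_sign(m$action1) *
        (.angle_of(joint_angles, m$joint1, m$side) - m$neut1) / m$coef1 * 0.01
    if (m$njoints > 1)
      l <- l + .len_sign(m$action2) *
        (.angle_of(joint_angles, m$joint2, m$side) - m$neut2) / m$coef2 * 0.01
    out[i] <- l
  }
  setNames(out, muscles$name)
}

#' Normalized muscle contraction velocity
#'
#' Contraction-positive: `vbar = -(d lbar / dt) / 1.8`, with joint rates
#' in degrees per second.
#'
#' @inheritParams muscle_length
#' @param joint_rates named list/vector of joint angular rates (deg/s)
#' @param vnorm velocity normalization (maximum lengths per second)
#' @return named numeric vector of normalized contraction velocities
#' @export
muscle_velocity <- function(muscles, joint_angles, joint_rates,
                            vnorm = 1.8) {
  joint_rates <- as.list(joint_rates)
  out <- numeric(nrow(muscles))
  for (i in seq_len(nrow(muscles))) {
    m <- muscles[i, ]
    dl <- .len_sign(m$action1) *
      .angle_of(joint_rates, m$joint1, m$side) / m$coef1 * 0.01
    if (m$njoints > 1)
      dl <- dl + .len_sign(m$action2) *
        .angle_of(joint_rates, m$joint2, m$side) / m$coef2 * 0.01
    out[i] <- -dl / vnorm
  }
  setNames(out, muscles$name)
}

#' Muscle force curves
#'
#' Force-length, force-velocity and passive curves, normalized so that
#' `fl(1) = 1`, `fv(0) = 1` and `fp(lbar) = 0` for `lbar <= 1`.
#'
#' @param cfg configuration list
#' @return list of functions `fl`, `fv`, `fp` plus the parameter block
#' @export
muscle_curves <- function(cfg = default_config()) {
  p <- cfg$muscle_curves
  fl <- function(l) exp(-((l - 1) / p$fl_width)^2)
  fv <- function(v) {
    vapply(v, function(vi) {
      if (vi >= p$fv_vmax) return(0)
      if (vi >= 0)
        return((1 - vi / p$fv_vmax) / (1 + vi / (p$fv_vmax * p$fv_shape)))
      f <- p$fv_ecc_cap - (p$fv_ecc_cap - 1) * (1 + vi) /
        (1 - p$fv_ecc_a * vi / p$fv_ecc_b)
      min(max(f, 1), p$fv_ecc_cap)
    }, numeric(1))
  }
  fp <- function(l) ifelse(l > 1, p$fp_scale * (exp(p$fp_rate * (l - 1)) - 1), 0)
  fdamp <- function(v) ifelse(v < 0, -p$fp_damp * v, 0)
  list(fl = fl, fv = fv, fp = fp, fdamp = fdamp, params = p)
}

#' Muscle tension
#'
#' `F = Fmax (a fl(lbar) fv(vbar) + fp(lbar))`, clamped to be
#' nonnegative.
#'
#' @param fmax maximum isometric tension (N)
#' @param a activation in `[0, 1]`
#' @param lbar normalized length
#' @param vbar normalized contraction velocity (contraction-positive)
#' @param curves as returned by [muscle_curves()]
#' @return tension in newtons
#' @export
muscle_tension <- function(fmax, a, lbar, vbar, curves = muscle_curves()) {
  if (any(a < 0 | a > 1)) stop("activation must lie in [0, 1]")
  pmax(0, fmax * (a * curves$fl(lbar) * curves$fv(vbar) + curves$fp(lbar)))
}

#' One integration step of the activation dynamics
#'
#' First-order activation/deactivation dynamics
#' `tau_act * adot + (tau_act/tau_deact + (1 - tau_act/tau_deact) u) a = u`
#' advanced by `dt` with a fourth-order Runge-Kutta step (the same
#' integrator used in the full simulation), result clamped to `[0, 1]`.
#'
#' @param a current activation
#' @param u motor command in `[0, 1]` (held constant over the step)
#' @param dt step (s), must be positive
#' @param tau_act activation time constant (s)
#' @param tau_deact deactivation time constant (s)
#' @return updated activation
#' @export
activation_step <- function(a, u, dt, tau_act = 0.011, tau_deact = 0.018) {
  if (dt <= 0) stop("dt must be positive")
  r <- tau_act / tau_deact
  f <- function(a) (u - (r + (1 - r) * u) * a) / tau_act
  k1 <- f(a); k2 <- f(a + dt / 2 * k1)
  k3 <- f(a + dt / 2 * k2); k4 <- f(a + dt * k3)
  pmin(1, pmax(0, a + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)))
}

#' Joint torques from muscle tensions
#'
#' Constant moment arms; torques are extensor-positive, so a muscle with
#' extensor action at a joint contributes `+MA * F` there and a flexor
#' `-MA * F`.  Biarticular muscles contribute at both spanned joints.
#'
#' @param tensions named numeric vector, one tension (N) per muscle row
#' @param muscles the `rat_muscles` table
#' @return named numeric(10) of joint torques (N m) in coordinate order
#' @export
joint_torques_from_muscles <- function(tensions, muscles) {
  tau <- setNames(rep(0, 10), .joint_names)
  for (i in seq_len(nrow(muscles))) {
    m <- muscles[i, ]
    f <- tensions[[m$name]]
    j1 <- paste0(.joint_coord[[m$joint1]], "_", m$side)
    tau[j1] <- tau[j1] - .len_sign(m$action1) * m$ma1 * f
    if (m$njoints > 1) {
      j2 <- paste0(.joint_coord[[m$joint2]], "_", m$side)
      tau[j2] <- tau[j2] - .len_sign(m$action2) * m$ma2 * f
    }
  }
  tau
}

# muscle table -> flat arrays for the C++ simulation core
.muscles_to_arrays <- function(muscles, model, cfg = default_config()) {
  coord_idx <- function(joint, side) {
    match(paste0(.joint_coord[[joint]], "_", side), model$coord_names) - 1L
  }
  n <- nrow(muscles)
  j1 <- integer(n); j2 <- integer(n)
  for (i in seq_len(n)) {
    j1[i] <- coord_idx(muscles$joint1[i], muscles$side[i])
    j2[i] <- if (muscles$njoints[i] > 1)
      coord_idx(muscles$joint2[i], muscles$side[i]) else -1L
  }
  limb_idx <- match(muscles$limb, .tip_names) - 1L
  list(fmax = muscles$fmax, tact = muscles$tact, tdeact = muscles$tdeact,
       lmax = muscles$lmax, base_len = muscles$base_len,
       njoints = as.integer(muscles$njoints), j1 = j1, j2 = j2,
       lsign1 = .len_sign(muscles$action1),
       lsign2 = ifelse(is.na(muscles$action2), 0, .len_sign(muscles$action2)),
       coef1 = muscles$coef1,
       coef2 = ifelse(is.na(muscles$coef2), 1, muscles$coef2),
       neut1 = muscles$neut1,
       neut2 = ifelse(is.na(muscles$neut2), 0, muscles$neut2),
       ma1 = muscles$ma1, ma2 = ifelse(is.na(muscles$ma2), 0, muscles$ma2),
       osc = limb_idx, limb = limb_idx,
       Kh = muscles$Kh, Dh = muscles$Dh, Ksp = muscles$Ksp,
       w_hat = as.matrix(muscles[, c("w1", "w2", "w3", "w4")]),
       curves = cfg$muscle_curves)
}
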