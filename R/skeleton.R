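# Planar skeleton: trunk + 2-link forelimbs + 3-link hindlimbs.
#
# Generalized coordinates (13), in order:
#   x, z        trunk reference point (m), at the trunk link midpoint
#   pitch       trunk pitch (rad), positive nose-up
#   sh_L, el_L, sh_R, el_R          forelimb joint angles (rad)
#   hip_L, kn_L, ank_L, hip_R, kn_R, ank_R   hindlimb joint angles (rad)
#
# Joint angles follow the anatomical convention: angles increase with
# extension; with limb segments collinear and perpendicular to the trunk
# the shoulder is 120 deg, elbow 180, hip 120, knee 180, ankle 180.

.coord_names <- c("x", "z", "pitch",
                  "sh_L", "el_L", "sh_R", "el_R",
                  "hip_L", "kn_L", "ank_L", "hip_R", "kn_R", "ank_R")
.joint_names <- .coord_names[4:13]
.tip_names <- c("LF", "RF", "LH", "RH")

# joint kinematic conventions: relative CCW angle = offset + sense * q.
# The sense fixes which way a limb folds; the offset follows from the
# reference configuration (shoulder/hip 120 deg, elbow/knee/ankle 180
# deg with segments collinear and perpendicular to the trunk).
.joint_sense_default <- c(sh = 1, el = -1, hip = -1, kn = 1, ank = -1)
.joint_ref_deg <- c(sh = 120, el = 180, hip = 120, kn = 180, ank = 180)
.joint_ref_rel <- c(sh = -90, el = 0, hip = -90, kn = 0, ank = 0)
.joint_offsets <- function(sense) {
  .joint_ref_rel - sense * .joint_ref_deg
}

#' Skeleton parameters
#'
#' Builds the per-link parameter set (mass, length, moment of inertia,
#' CoM position) from a configuration block with unit-suffixed fields
#' (`mass_g`, `length_mm`, `moi_gmm2`, `com_frac`); values are converted
#' to SI.  Left and right limbs share the same link parameters.
#'
#' @param cfg configuration list as returned by [default_config()]
#' @return object of class `rat_skeleton_params`
#' @export
skeleton_params <- function(cfg = default_config()) {
  sk <- cfg$skeleton
  links <- lapply(sk$links, function(l) {
    list(mass = l$mass_g * 1e-3,
         length = l$length_mm * 1e-3,
         inertia = l$moi_gmm2 * 1e-9,     # g mm^2 -> kg m^2
         com_frac = if (is.null(l$com_frac)) 0.5 else l$com_frac)
  })
  js <- .joint_sense_default
  if (!is.null(sk$joint_sense))
    for (nm in names(sk$joint_sense)) js[[nm]] <- sk$joint_sense[[nm]]
  out <- list(links = links, gravity = sk$gravity_ms2, joint_sense = js)
  class(out) <- "rat_skeleton_params"
  out
}

# generic planar-tree model constructor (also used by test fixtures)
planar_model <- function(parent, jtype, sense, offset, anchor_x, anchor_z,
                         mass, comx, inertia, length, tips, gravity = 9.81) {
  m <- list(parent = as.integer(parent), jtype = as.integer(jtype),
            sense = as.numeric(sense), offset = as.numeric(offset),
            anchor_x = as.numeric(anchor_x), anchor_z = as.numeric(anchor_z),
            mass = as.numeric(mass), comx = as.numeric(comx),
            inertia = as.numeric(inertia), length = as.numeric(length),
            tips = as.integer(tips), gravity = as.numeric(gravity))
  class(m) <- "planar_model"
  m
}

#' Build the rat skeleton model
#'
#' Assembles the 11-link planar linkage (plus two massless prismatic
#' pseudo-bodies carrying the floating trunk) as an immutable model
#' object used by all dynamics and kinematics routines.
#'
#' @param params a `rat_skeleton_params` object
#' @return object of class `rat_skeleton`
#' @export
build_skeleton <- function(params = skeleton_params()) {
  stopifnot(inherits(params, "rat_skeleton_params"))
  .joint_sense <- params$joint_sense
  .joint_offset_deg <- .joint_offsets(.joint_sense)
  for (nm in names(params$links)) {
    l <- params$links[[nm]]
    if (!(l$mass > 0) || !(l$length > 0) || !(l$inertia > 0))
      stop("nonpositive mass/length/inertia for link '", nm, "'")
  }
  L <- params$links
  lt <- L$trunk$length
  deg <- pi / 180

  lk <- function(name) L[[name]]
  # body table, 0-based parents; order fixed (see .coord_names)
  spec <- list(
    list(name = "base_x", parent = -1L, jtype = 0L, s = 1, off = 0,
         ax = 0, az = 0, link = NULL),
    list(name = "base_z", parent = 0L, jtype = 1L, s = 1, off = 0,
         ax = 0, az = 0, link = NULL),
    list(name = "trunk", parent = 1L, jtype = 2L, s = 1, off = 0,
         ax = 0, az = 0, link = "trunk"),
    list(name = "brachium_L", parent = 2L, jtype = 2L,
         s = .joint_sense["sh"], off = .joint_offset_deg["sh"] * deg,
         ax = lt / 2, az = 0, link = "brachium"),
    list(name = "antebrachium_L", parent = 3L, jtype = 2L,
         s = .joint_sense["el"], off = .joint_offset_deg["el"] * deg,
         ax = lk("brachium")$length, az = 0, link = "antebrachium"),
    list(name = "brachium_R", parent = 2L, jtype = 2L,
         s = .joint_sense["sh"], off = .joint_offset_deg["sh"] * deg,
         ax = lt / 2, az = 0, link = "brachium"),
    list(name = "antebrachium_R", parent = 5L, jtype = 2L,
         s = .joint_sense["el"], off = .joint_offset_deg["el"] * deg,
         ax = lk("brachium")$length, az = 0, link = "antebrachium"),
    list(name = "thigh_L", parent = 2L, jtype = 2L,
         s = .joint_sense["hip"], off = .joint_offset_deg["hip"] * deg,
         ax = -lt / 2, az = 0, link = "thigh"),
    list(name = "shank_L", parent = 7L, jtype = 2L,
         s = .joint_sense["kn"], off = .joint_offset_deg["kn"] * deg,
         ax = lk("thigh")$length, az = 0, link = "shank"),
    list(name = "foot_L", parent = 8L, jtype = 2L,
         s = .joint_sense["ank"], off = .joint_offset_deg["ank"] * deg,
         ax = lk("shank")$length, az = 0, link = "foot"),
    list(name = "thigh_R", parent = 2L, jtype = 2L,
         s = .joint_sense["hip"], off = .joint_offset_deg["hip"] * deg,
         ax = -lt / 2, az = 0, link = "thigh"),
    list(name = "shank_R", parent = 10L, jtype = 2L,
         s = .joint_sense["kn"], off = .joint_offset_deg["kn"] * deg,
         ax = lk("thigh")$length, az = 0, link = "shank"),
    list(name = "foot_R", parent = 11L, jtype = 2L,
         s = .joint_sense["ank"], off = .joint_offset_deg["ank"] * deg,
         ax = lk("shank")$length, az = 0, link = "foot"))

  n <- length(spec)
  g <- function(f) vapply(spec, function(b) {
    if (is.null(b$link)) return(0)
    li <- L[[b$link]]
    switch(f, mass = li$mass, length = li$length, inertia = li$inertia,
           comx = (li$com_frac - if (b$link == "trunk") 0.5 else 0) *
                  li$length)
  }, numeric(1))

  m <- planar_model(
    parent = vapply(spec, `[[`, integer(1), "parent"),
    jtype = vapply(spec, `[[`, integer(1), "jtype"),
    sense = vapply(spec, function(b) as.numeric(b$s), numeric(1)),
    offset = vapply(spec, function(b) as.numeric(b$off), numeric(1)),
    anchor_x = vapply(spec, function(b) as.numeric(b$ax), numeric(1)),
    anchor_z = vapply(spec, function(b) as.numeric(b$az), numeric(1)),
    mass = g("mass"), comx = g("comx"), inertia = g("inertia"),
    length = g("length"),
    tips = c(4L, 6L, 9L, 12L),        # 0-based: antebrachia + feet
    gravity = params$gravity)

  m$body_names <- vapply(spec, `[[`, character(1), "name")
  m$coord_names <- .coord_names
  m$params <- params
  # total body mass: trunk once, limb links twice each
  m$total_mass <- sum(m$mass)
  class(m) <- c("rat_skeleton", "planar_model")
  m
}

#' @export
print.rat_skeleton <- function(x, ...) {
  cat("rat planar skeleton: 11 links, 13 generalized coordinates\n")
  cat(sprintf("total mass %.4f kg, gravity %.2f m/s^2\n",
              x$total_mass, x$gravity))
  invisible(x)
}

#' Skeleton state
#'
#' @param q generalized coordinates (13): trunk x, z (m), pitch (rad)
#'   and the ten joint angles (rad), in the order documented in
#'   [build_skeleton()]
#' @param qd generalized rates, same order
#' @return object of class `rat_state`
#' @export
skeleton_state <- function(q, qd = rep(0, length(q))) {
  q <- as.numeric(q); qd <- as.numeric(qd)
  if (length(q) != 13 || length(qd) != 13)
    stop("state must have 13 coordinates and 13 rates")
  if (any(!is.finite(q)) || any(!is.finite(qd)))
    stop("non-finite values in state")
  names(q) <- .coord_names
  names(qd) <- .coord_names
  structure(list(q = q, qd = qd), class = "rat_state")
}

#' Reference configuration
#'
#' All limb segments collinear and perpendicular to the trunk: shoulder
#' 120 deg, elbow 180, hip 120, knee 180, ankle 180.
#'
#' @param z trunk height (m)
#' @param x trunk horizontal position (m)
#' @param pitch trunk pitch (rad)
#' @return a `rat_state`
#' @export
reference_state <- function(z = 0.06, x = 0, pitch = 0) {
  deg <- pi / 180
  q <- c(x, z, pitch,
         120, 180, 120, 180,
         120, 180, 180, 120, 180, 180)
  q[4:13] <- q[4:13] * deg
  skeleton_state(q)
}

.state_check <- function(state) {
  if (!inherits(state, "rat_state")) stop("expected a rat_state")
  if (any(!is.finite(state$q)) || any(!is.finite(state$qd)))
    stop("non-finite values in state")
  invisible(state)
}

#' Generalized accelerations of the skeleton
#'
#' Solves M(q) qdd = Q - C(q, qd) - G(q) + J^T F_ext for the forced
#' linkage.  Joint torques are extensor-positive: a positive torque
#' increases the corresponding joint angle.
#'
#' @param model a `rat_skeleton`
#' @param state a `rat_state`
#' @param joint_torques numeric(10), one entry per joint in coordinate
#'   order (`sh_L`, `el_L`, `sh_R`, `el_R`, `hip_L`, `kn_L`, `ank_L`,
#'   `hip_R`, `kn_R`, `ank_R`), N m
#' @param tip_forces 4 x 2 matrix of planar forces (N) at the limb tips
#'   (rows LF, RF, LH, RH; columns x, z)
#' @return numeric(13) generalized accelerations
#' @export
generalized_accelerations <- function(model, state,
                                      joint_torques = rep(0, 10),
                                      tip_forces = matrix(0, 4, 2)) {
  .state_check(state)
  stopifnot(length(joint_torques) == 10)
  tip_forces <- as.matrix(tip_forces)
  stopifnot(all(dim(tip_forces) == c(4, 2)))
  Q <- c(0, 0, 0, as.numeric(joint_torques))
  qdd <- .pd_fwd_dyn(unclass(model), state$q, state$qd, Q, tip_forces)
  setNames(as.numeric(qdd), .coord_names)
}

#' Contact parameters
#'
#' Viscoelastic ground contact at the limb tips.  Vertical force is
#' stiffness x penetration + damping x penetration rate, clamped to be
#' nonnegative; horizontal force is a spring-damper to an anchor point
#' set at touchdown.
#'
#' @param cfg configuration list
#' @return object of class `rat_contact_params`
#' @export
contact_params <- function(cfg = default_config()) {
  ct <- cfg$contact
  out <- list(k_vert = ct$k_vert_Nm, c_vert = ct$c_vert_Nsm,
              k_horiz = ct$k_horiz_Nm, c_horiz = ct$c_horiz_Nsm,
              ground = ct$ground_z_m)
  if (any(unlist(out[1:4]) < 0)) stop("contact stiffness/damping must be >= 0")
  class(out) <- "rat_contact_params"
  out
}

#' Ground contact forces at the limb tips
#'
#' @param model a `rat_skeleton`
#' @param state a `rat_state`
#' @param cparams a `rat_contact_params`
#' @param anchor_x horizontal anchor positions (4), used for tips in
#'   contact; defaults to each tip's current x (no horizontal spring
#'   deflection)
#' @return list with `force` (4 x 2 matrix, rows LF/RF/LH/RH) and
#'   `stance` (logical(4): vertical force > 0)
#' @export
contact_forces <- function(model, state, cparams = contact_params(),
                           anchor_x = NULL) {
  .state_check(state)
  k <- .pd_fk(unclass(model), state$q, state$qd)
  tp <- k$tip_pos; tv <- k$tip_vel
  if (is.null(anchor_x)) anchor_x <- tp[, 1]
  F <- matrix(0, 4, 2, dimnames = list(.tip_names, c("x", "z")))
  pen <- cparams$ground - tp[, 2]
  for (t in 1:4) {
    if (pen[t] > 0) {
      fz <- cparams$k_vert * pen[t] - cparams$c_vert * tv[t, 2]
      F[t, 2] <- max(0, fz)
      F[t, 1] <- -cparams$k_horiz * (tp[t, 1] - anchor_x[t]) -
                  cparams$c_horiz * tv[t, 1]
    }
  }
  list(force = F, stance = F[, 2] > 0)
}

#' Kinematic queries
#'
#' Heights of the shoulder and hip joint centers above ground, limb-tip
#' positions and velocities, and trunk-CoM position/velocity.
#'
#' @param model a `rat_skeleton`
#' @param state a `rat_state`
#' @return list with `shoulder_height` (L, R), `hip_height` (L, R),
#'   `shoulder_height_rate`, `hip_height_rate`, `tip_pos`, `tip_vel`
#'   (4 x 2, rows LF/RF/LH/RH), `trunk_com`, `trunk_com_vel`
#' @export
kinematic_queries <- function(model, state) {
  .state_check(state)
  k <- .pd_fk(unclass(model), state$q, state$qd)
  orig <- k$origin; ov <- k$origin_vel
  dimnames(k$tip_pos) <- list(.tip_names, c("x", "z"))
  dimnames(k$tip_vel) <- list(.tip_names, c("x", "z"))
  list(shoulder_height = setNames(orig[c(4, 6), 2], c("L", "R")),
       shoulder_height_rate = setNames(ov[c(4, 6), 2], c("L", "R")),
       hip_height = setNames(orig[c(8, 11), 2], c("L", "R")),
       hip_height_rate = setNames(ov[c(8, 11), 2], c("L", "R")),
       tip_pos = k$tip_pos, tip_vel = k$tip_vel,
       trunk_com = setNames(k$com[3, ], c("x", "z")),
       trunk_com_vel = setNames(k$com_vel[3, ], c("x", "z")))
}

#' Total mechanical energy
#'
#' Kinetic plus gravitational potential energy of all links (datum at
#' ground height z = 0).
#'
#' @param model a `rat_skeleton` (or any planar model)
#' @param state a `rat_state`
#' @return energy in joules
#' @export
total_mechanical_energy <- function(model, state) {
  .state_check(state)
  .pd_energy(unclass(model), state$q, state$qd)
}

# --- posing helpers -------------------------------------------------------

# inverse kinematics for one limb: joint angles (deg) that place the
# tip at `target` (m, world-frame offset from the proximal joint).
# Forelimbs bend with the elbow behind the shoulder, hindlimbs with the
# knee ahead of the hip; the hindlimb ankle starts from `q_ank` and is
# extended just enough to reach.
.limb_ik <- function(model, limb = c("fore", "hind"), target, pitch_deg,
                     q_ank = 100) {
  limb <- match.arg(limb)
  L <- model$params$links
  d <- sqrt(sum(target^2))
  lam <- atan2(target[2], target[1]) * 180 / pi
  if (limb == "fore") {
    l1 <- L$brachium$length; l2 <- L$antebrachium$length
    d <- min(d, (l1 + l2) * 0.999)
    interior <- acos(max(-1, min(1, (l1^2 + l2^2 - d^2) /
                                   (2 * l1 * l2)))) * 180 / pi
    alpha <- acos(max(-1, min(1, (d^2 + l1^2 - l2^2) /
                                (2 * d * l1)))) * 180 / pi
    chi1 <- lam - alpha                    # elbow behind the shoulder
    c(sh = (chi1 - pitch_deg) + 210, el = interior)
  } else {
    lth <- L$thigh$length; lsh <- L$shank$length; lf <- L$foot$length
    repeat {
      delta <- (180 - q_ank) * pi / 180
      cx <- lsh + lf * cos(delta); cz <- lf * sin(delta)
      L2 <- sqrt(cx^2 + cz^2)
      if (lth + L2 >= d * 1.001 || q_ank >= 179) break
      q_ank <- q_ank + 1
    }
    d <- min(d, (lth + L2) * 0.999)
    gamma <- atan2(cz, cx) * 180 / pi
    interior <- acos(max(-1, min(1, (lth^2 + L2^2 - d^2) /
                                   (2 * lth * L2)))) * 180 / pi
    alpha <- acos(max(-1, min(1, (d^2 + lth^2 - L2^2) /
                                (2 * d * lth)))) * 180 / pi
    chi1 <- lam + alpha                    # knee ahead of the hip
    c(hip = 30 - (chi1 - pitch_deg), kn = interior - gamma, ank = q_ank)
  }
}

#' Pose the model in a standing configuration
#'
#' Places the trunk so that the shoulder and hip joints sit at the given
#' heights, and solves each limb so that its tip touches the ground
#' directly below its proximal joint.  The hindlimb ankle starts from
#' the neutral 100 deg and is extended just enough for the tip to reach
#' the ground.
#'
#' @param model a `rat_skeleton`
#' @param h_shoulder shoulder height (m)
#' @param h_hip hip height (m)
#' @param x trunk x position (m)
#' @param vx initial forward velocity (m/s)
#' @return a `rat_state`
#' @export
pose_standing <- function(model, h_shoulder = 0.033, h_hip = 0.054,
                          x = 0, vx = 0) {
  L <- model$params$links
  lt <- L$trunk$length
  pitch <- asin(max(-1, min(1, (h_shoulder - h_hip) / lt)))
  pitch_deg <- pitch * 180 / pi
  # trunk midpoint height from the two girdle heights
  zmid <- (h_shoulder + h_hip) / 2

  f <- .limb_ik(model, "fore", c(0, -h_shoulder), pitch_deg)
  h <- .limb_ik(model, "hind", c(0, -h_hip), pitch_deg)
  q_sh <- f[["sh"]]; q_el <- f[["el"]]
  q_hip <- h[["hip"]]; q_kn <- h[["kn"]]; q_ank <- h[["ank"]]

  q <- c(x, zmid, pitch,
         q_sh, q_el, q_sh, q_el,
         q_hip, q_kn, q_ank, q_hip, q_kn, q_ank)
  q[4:13] <- q[4:13] * pi / 180
  qd <- rep(0, 13); qd[1] <- vx
  skeleton_state(q, qd)
}
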