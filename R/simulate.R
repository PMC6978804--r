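# Global integration loop: RK4 at dt = 0.02 ms coupling the skeleton,
# the 26 muscle activations, the four oscillator phases and the delayed
# regulators, plus gait-cycle detection and the beta-sweep experiment
# driver.

#' Simulation configuration
#'
#' @param gait `"walk"` or `"trot"`
#' @param beta extension fraction at the start (default: nominal)
#' @param beta_target final extension fraction; when it differs from
#'   `beta`, beta is ramped quasi-statically at `ramp_rate` per cycle
#' @param duration simulated time (s)
#' @param dt integration step (s); 2e-5 by default
#' @param log_every store every n-th step (50 keeps a 1 kHz record)
#' @param initial_speed initial forward velocity (m/s); defaults to the
#'   regulator reference speed at the starting beta
#' @param init_phases `"fixed_point"` (start phase-locked) or
#'   `"random"` (uniform phases from `seed`)
#' @param assist numeric(2): end of the full-strength trunk-support
#'   window and end of its fade (s); defaults to the configured
#'   `hold_s`/`fade_s` schedule
#' @param seed integer seed for random phase initialization
#' @param cfg configuration list (see [default_config()])
#' @return object of class `rat_sim_config`
#' @export
sim_config <- function(gait = c("walk", "trot"), beta = NULL,
                       beta_target = NULL, duration = 5,
                       dt = NULL, log_every = NULL,
                       initial_speed = NULL,
                       init_phases = c("fixed_point", "random"),
                       assist = NULL,
                       seed = 1L, cfg = default_config()) {
  gait <- match.arg(gait)
  init_phases <- match.arg(init_phases)
  gc0 <- gait_config(gait, beta, cfg)
  if (is.null(beta_target)) beta_target <- gc0$beta
  if (is.null(dt)) dt <- cfg$sim$dt_s
  if (is.null(log_every)) log_every <- cfg$sim$log_every
  if (dt <= 0) stop("dt must be positive")
  if (duration <= 0) stop("duration must be positive")
  if (is.null(assist))
    assist <- c(cfg$sim$assist$hold_s,
                cfg$sim$assist$hold_s + cfg$sim$assist$fade_s)
  structure(list(gait = gait, beta = gc0$beta, beta_target = beta_target,
                 assist = assist,
                 Delta = gc0$Delta, duration = duration, dt = dt,
                 log_every = as.integer(log_every),
                 initial_speed = initial_speed,
                 init_phases = init_phases, seed = as.integer(seed),
                 cfg = cfg),
            class = "rat_sim_config")
}

.ctrl_list <- function(config) {
  ctl <- config$cfg$control
  list(K1 = ctl$K1, K2 = ctl$K2, Delta = config$Delta,
       Tfl = ctl$T_fl_s, beta_hat = ctl$beta_hat,
       Phi_hat = ctl$Phi_hat_pi * pi, Psi_hat = ctl$Psi_hat_pi * pi,
       h0_shoulder = ctl$h0_shoulder_m, h0_hip = ctl$h0_hip_m,
       v0 = ctl$v0_ms,
       alpha_shoulder = ctl$alpha_shoulder_m, alpha_hip = ctl$alpha_hip_m,
       alpha_speed = ctl$alpha_speed_ms,
       tau_delay = ctl$tau_delay_ms * 1e-3,
       vnorm = config$cfg$muscle_geometry$velocity_norm_lmax_per_s,
       ramp_rate = ctl$ramp_rate_per_cycle)
}

.sim_list <- function(config) {
  sm <- config$cfg$sim
  ct <- config$cfg$contact
  asst <- config$cfg$sim$assist
  refs <- scaled_references(config$beta_target, cfg = config$cfg)
  list(dt = config$dt, duration = config$duration,
       log_every = config$log_every,
       k_vert = ct$k_vert_Nm, c_vert = ct$c_vert_Nsm,
       k_horiz = ct$k_horiz_Nm, c_horiz = ct$c_horiz_Nsm,
       mu = ct$mu_friction,
       pitch_max = sm$pitch_max_deg * pi / 180,
       height_fail_frac = sm$height_fail_frac,
       qd_max = sm$qd_max,
       jl_min = config$cfg$skeleton$joint_limits$min_deg * pi / 180,
       jl_max = config$cfg$skeleton$joint_limits$max_deg * pi / 180,
       jl_k = config$cfg$skeleton$joint_limits$k_Nm_per_rad,
       jl_c = config$cfg$skeleton$joint_limits$c_Nm_s_per_rad,
       assist_until = config$assist[1], assist_end = config$assist[2],
       assist_floor = asst$floor,
       assist_kz = asst$kz, assist_cz = asst$cz,
       assist_kp = asst$kp, assist_cp = asst$cp,
       assist_zref = (refs[["h0_shoulder"]] + refs[["h0_hip"]]) / 2 +
         asst$z_offset,
       assist_pref = asin(max(-1, min(1,
         (refs[["h0_shoulder"]] - refs[["h0_hip"]]) /
           (config$cfg$skeleton$links$trunk$length_mm * 1e-3)))),
       beta_start = config$beta, beta_target = config$beta_target)
}

.initial_condition <- function(config, model, muscles) {
  refs <- scaled_references(config$beta, cfg = config$cfg)
  vx <- if (is.null(config$initial_speed)) refs[["v0"]]
        else config$initial_speed
  if (config$init_phases == "random") {
    set.seed(config$seed)
    phi <- stats::runif(4, 0, 2 * pi)
  } else {
    phi <- gait_fixed_point(config$Delta)
  }
  st <- .pose_for_phases(config, model, refs, phi, vx)
  sched <- synergy_schedule(config$beta, config$cfg)
  u0 <- synergy_command(sched, setNames(phi, c("LF", "RF", "LH", "RH")))
  a0 <- pmin(1, pmax(0, u0[muscles$name]))
  list(q = unname(st$q), qd = unname(st$qd), a = unname(a0),
       phi = unname(phi))
}

# Phase-consistent starting posture: the trunk sits at the reference
# heights; limbs whose oscillator phase lies in the extension (stance)
# phase start on the ground with a fore-aft tip offset matching their
# stance progress; limbs in the flexion (swing) phase start lifted with
# the tip placed according to their swing progress.
.pose_for_phases <- function(config, model, refs, phi, vx,
                             lift = 0.006, fore_bias = 0.006) {
  beta <- config$beta
  h_sh <- refs[["h0_shoulder"]]; h_hip <- refs[["h0_hip"]]
  Tfl <- config$cfg$control$T_fl_s
  T_ex <- beta * Tfl / (1 - beta)
  sweep <- min(vx * T_ex, 0.5 * h_sh)
  lt <- model$params$links$trunk$length
  pitch <- asin(max(-1, min(1, (h_sh - h_hip) / lt)))
  pitch_deg <- pitch * 180 / pi
  tip_target <- function(ph, h) {
    ph <- ph %% (2 * pi)
    if (ph < 2 * pi * beta) {              # stance: front -> back
      s <- ph / (2 * pi * beta)
      c((0.5 - s) * sweep, -h)
    } else {                               # swing: back -> front
      s <- (ph - 2 * pi * beta) / (2 * pi * (1 - beta))
      c((s - 0.5) * sweep, -(h - lift))
    }
  }
  # stance forelimbs start as near-straight struts (elbow at its stop,
  # where the limb bears weight skeletally); the strut height follows
  # from the fore-aft foot offset
  Lfore <- model$params$links$brachium$length +
    model$params$links$antebrachium$length
  # the forefoot operates ahead of the shoulder on average (the load
  # torque of a forward-planted strut balances the net retraction
  # torque of the stance muscles), hence a forward placement bias
  fore_target <- function(ph) {
    tg <- tip_target(ph, h_sh)
    tg[1] <- tg[1] + fore_bias
    if ((ph %% (2 * pi)) < 2 * pi * beta)
      tg[2] <- -min(sqrt(max((0.9995 * Lfore)^2 - tg[1]^2, 1e-8)), h_sh)
    tg
  }
  lf <- .limb_ik(model, "fore", fore_target(phi[1]), pitch_deg)
  rf <- .limb_ik(model, "fore", fore_target(phi[2]), pitch_deg)
  lh <- .limb_ik(model, "hind", tip_target(phi[3], h_hip), pitch_deg)
  rh <- .limb_ik(model, "hind", tip_target(phi[4], h_hip), pitch_deg)
  q <- c(0, (h_sh + h_hip) / 2, pitch,
         c(lf[["sh"]], lf[["el"]], rf[["sh"]], rf[["el"]],
           lh[["hip"]], lh[["kn"]], lh[["ank"]],
           rh[["hip"]], rh[["kn"]], rh[["ank"]]) * pi / 180)
  qd <- rep(0, 13); qd[1] <- vx
  # stance tips must start at rest on the ground: solve two joint rates
  # per stance limb so the tip velocity cancels the trunk's advance
  stance <- ((phi %% (2 * pi)) < 2 * pi * beta)
  limb_joints <- list(c(4, 5), c(6, 7), c(8, 9), c(11, 12))
  tipv <- function(q, qd, t) .pd_fk(unclass(model), q, qd)$tip_vel[t, ]
  for (t in which(stance)) {
    jj <- limb_joints[[t]]
    v0 <- tipv(q, qd, t)
    h <- 1e-6
    J <- sapply(jj, function(j) {
      qp <- q; qp[j] <- qp[j] + h
      qm <- q; qm[j] <- qm[j] - h
      (.pd_fk(unclass(model), qp, rep(0, 13))$tip_pos[t, ] -
         .pd_fk(unclass(model), qm, rep(0, 13))$tip_pos[t, ]) / (2 * h)
    })
    qd[jj] <- tryCatch(solve(J, -v0), error = function(e) c(0, 0))
  }
  skeleton_state(q, qd)
}

.work_cols <- c("pos", "neg", "syn_pos", "syn_neg", "height_pos",
                "height_neg", "speed_pos", "speed_neg",
                "passive_pos", "passive_neg")

.wrap_trajectory <- function(raw, config, model, muscles) {
  colnames(raw$q) <- colnames(raw$qd) <- model$coord_names
  colnames(raw$phi) <- colnames(raw$stance) <- .tip_names
  colnames(raw$tip_force) <- paste0(rep(.tip_names, each = 2), c("_x", "_z"))
  for (nm in c("a", "u", "u_syn", "u_height", "u_speed", "tension",
               "lbar", "vbar"))
    colnames(raw[[nm]]) <- muscles$name
  colnames(raw$work) <- .work_cols
  names(raw$events$touchdown) <- names(raw$events$liftoff) <- .tip_names
  raw$config <- config
  raw$model <- model
  raw$muscles <- muscles
  class(raw) <- "rat_trajectory"
  raw
}

#' @export
print.rat_trajectory <- function(x, ...) {
  cat(sprintf("rat_trajectory: %s, %.2f s logged at %.0f Hz, status '%s'\n",
              x$config$gait, max(x$time) - min(x$time),
              1 / (x$time[2] - x$time[1]), x$status))
  invisible(x)
}

#' Run a forward-dynamics locomotion simulation
#'
#' Integrates the coupled system (13-DOF skeleton, 26 muscle
#' activations and three per-muscle component activations, 4 oscillator
#' phases) with RK4.  Per control step: oscillator phases give the
#' synergy command, the delay buffer supplies the regulator command
#' sensed 15 ms earlier, the summed command is clamped to `[0, 1]`,
#' muscle tensions and joint torques are formed, ground contact forces
#' applied, and the equations of motion advanced.
#'
#' @param config a `rat_sim_config`
#' @param resume optional resume block from a previous trajectory
#'   (`traj$resume`) to continue a simulation seamlessly
#' @return object of class `rat_trajectory`: a 1 kHz record of states,
#'   phases, commands, tensions, contact forces, cumulative work
#'   integrals, touchdown/liftoff events, and a `resume` block
#' @export
simulate_gait <- function(config, resume = NULL) {
  stopifnot(inherits(config, "rat_sim_config"))
  model <- build_skeleton(skeleton_params(config$cfg))
  muscles <- muscle_set(config$cfg)
  marr <- .muscles_to_arrays(muscles, model, config$cfg)
  init <- if (!is.null(resume)) resume
          else .initial_condition(config, model, muscles)
  raw <- .sim_run(unclass(model), marr, .ctrl_list(config),
                  .sim_list(config), init)
  .wrap_trajectory(raw, config, model, muscles)
}

#' Detect gait cycles
#'
#' Cycle windows run between successive right-hindlimb touchdowns.
#' Also reports per-limb duty factors (stance fraction of the cycle)
#' and the ipsilateral footfall lag (fore touchdown relative to hind
#' touchdown, as a fraction of the cycle).
#'
#' @param traj a `rat_trajectory`
#' @param min_cycle minimum credible cycle duration (s), used to reject
#'   contact chatter at touchdown
#' @return list with `windows` (data frame: start, end, duration),
#'   `duty_factor` (per limb), `ipsilateral_lag` (left and right side)
#' @export
detect_cycles <- function(traj, min_cycle = 0.05) {
  td <- lapply(traj$events$touchdown, .debounce, min_gap = min_cycle)
  rh <- td$RH
  if (length(rh) < 2) stop("no steady gait: fewer than 2 right-hindlimb touchdowns")
  windows <- data.frame(start = rh[-length(rh)], end = rh[-1])
  windows$duration <- windows$end - windows$start
  duty <- vapply(.tip_names, function(l) {
    mean(.stance_fraction(traj, l, windows))
  }, numeric(1))
  lag <- c(L = .footfall_lag(td$LF, td$LH, windows),
           R = .footfall_lag(td$RF, td$RH, windows))
  list(windows = windows, duty_factor = duty, ipsilateral_lag = lag)
}

# drop touchdown events closer than min_gap to the previous kept one
.debounce <- function(times, min_gap) {
  times <- as.numeric(times)
  if (length(times) < 2) return(times)
  keep <- times[1]
  for (t in times[-1]) if (t - keep[length(keep)] >= min_gap) keep <- c(keep, t)
  keep
}

.stance_fraction <- function(traj, limb, windows) {
  st <- traj$stance[, limb]
  vapply(seq_len(nrow(windows)), function(i) {
    sel <- traj$time >= windows$start[i] & traj$time < windows$end[i]
    if (!any(sel)) return(NA_real_)
    mean(st[sel] > 0)
  }, numeric(1))
}

# mean fractional lag of `fore` touchdowns after the nearest preceding
# `hind` touchdown
.footfall_lag <- function(fore, hind, windows) {
  Tm <- mean(windows$duration)
  lags <- vapply(fore, function(tf) {
    prev <- hind[hind <= tf]
    if (!length(prev)) return(NA_real_)
    (tf - max(prev)) / Tm
  }, numeric(1))
  lags <- lags[is.finite(lags)]
  if (!length(lags)) return(NA_real_)
  median(lags %% 1)
}

#' Mean forward speed over detected cycles
#'
#' Trunk-CoM horizontal displacement over an integer number of detected
#' cycles divided by the elapsed time.
#'
#' @param traj a `rat_trajectory`
#' @param cycles which cycle indices to use (default: all complete
#'   cycles after discarding the configured transient)
#' @param discard number of initial cycles to discard
#' @return mean speed (m/s)
#' @export
mean_speed <- function(traj, cycles = NULL, discard = 0) {
  cyc <- detect_cycles(traj)$windows
  if (is.null(cycles)) cycles <- seq_len(nrow(cyc))
  cycles <- cycles[cycles > discard]
  if (!length(cycles)) stop("no cycles left after discarding transient")
  t0 <- cyc$start[min(cycles)]; t1 <- cyc$end[max(cycles)]
  x <- .trunk_com_x(traj)
  (.interp(traj$time, x, t1) - .interp(traj$time, x, t0)) / (t1 - t0)
}

#' Beta sweep experiment
#'
#' For each requested extension fraction, ramps beta quasi-statically
#' from the previous operating point, lets the gait settle, then
#' averages speed and per-cycle energetics over steady cycles.  The
#' sweep is chained outward from the nominal beta in both directions so
#' that each point starts from the nearest steady gait.
#'
#' @param gait `"walk"` or `"trot"`
#' @param betas extension fractions to visit (default: configured sweep
#'   grid)
#' @param settle_cycles steady cycles discarded after the ramp
#' @param measure_cycles steady cycles averaged for the report
#' @param cfg configuration list
#' @param verbose print one line per point?
#' @return data frame of class `rat_sweep`: one row per beta with mean
#'   speed, stride length, work, CoT and its components, and run status
#' @export
sweep_beta <- function(gait = c("walk", "trot"), betas = NULL,
                       settle_cycles = NULL, measure_cycles = NULL,
                       cfg = default_config(), verbose = FALSE) {
  gait <- match.arg(gait)
  sm <- cfg$sim
  if (is.null(betas)) {
    bs <- sm$beta_sweep
    betas <- seq(bs$min, bs$max, by = bs$step)
  }
  if (is.null(settle_cycles)) settle_cycles <- sm$discard_cycles
  if (is.null(measure_cycles)) measure_cycles <- sm$measure_cycles
  bhat <- cfg$control$beta_hat
  rate <- cfg$control$ramp_rate_per_cycle

  # settle the nominal gait once, reuse for both sweep directions; the
  # warm-up covers the start-up assist window plus a few steady cycles
  Tn <- cfg$control$T_fl_s / (1 - bhat)
  warm_dur <- cfg$sim$assist$hold_s + cfg$sim$assist$fade_s +
    (settle_cycles + 3) * Tn
  warm <- simulate_gait(sim_config(gait, beta = bhat, duration = warm_dur,
                                   cfg = cfg))
  if (warm$status != "ok")
    stop("nominal ", gait, " failed to reach steady gait")
  rows <- list()
  run_chain <- function(targets, start_resume) {
    res <- start_resume
    for (b in targets) {
      Tb <- cfg$control$T_fl_s / (1 - b)
      ramp_cycles <- ceiling(abs(b - res$beta) / rate)
      dur <- ramp_cycles * (Tn + Tb) / 2 +
        (settle_cycles + measure_cycles + 1) * Tb
      cfgb <- sim_config(gait, beta = b, beta_target = b, duration = dur,
                         cfg = cfg)
      tr <- simulate_gait(cfgb, resume = res)
      row <- .sweep_row(tr, b, measure_cycles)
      if (verbose)
        message(sprintf("%s beta=%.3f speed=%.3f status=%s",
                        gait, b, row$speed, row$status))
      rows[[length(rows) + 1]] <<- row
      if (row$status != "ok") break
      res <- tr$resume
    }
  }
  down <- sort(betas[betas <= bhat], decreasing = TRUE)
  up <- sort(betas[betas > bhat])
  run_chain(down, warm$resume)
  run_chain(up, warm$resume)
  out <- do.call(rbind, rows)
  out <- out[order(out$beta), ]
  rownames(out) <- NULL
  class(out) <- c("rat_sweep", "data.frame")
  out
}

.sweep_row <- function(tr, beta, measure_cycles) {
  fail <- data.frame(beta = beta, speed = NA_real_, D = NA_real_,
                     W = NA_real_, eps = NA_real_, eps_syn = NA_real_,
                     eps_height = NA_real_, eps_speed = NA_real_,
                     duty_factor = NA_real_, T_cycle = NA_real_,
                     status = tr$status, stringsAsFactors = FALSE)
  if (tr$status != "ok") return(fail)
  cyc <- try(detect_cycles(tr), silent = TRUE)
  if (inherits(cyc, "try-error")) { fail$status <- "no_gait"; return(fail) }
  nw <- nrow(cyc$windows)
  use <- cyc$windows[cyc$windows$end > max(cyc$windows$end) -
                       measure_cycles * mean(cyc$windows$duration) - 1e-9, ]
  if (nrow(use) < 2) { fail$status <- "too_few_cycles"; return(fail) }
  en <- energetics_report(tr, use)
  data.frame(beta = beta, speed = mean(en$speed), D = mean(en$D),
             W = mean(en$W), eps = mean(en$eps),
             eps_syn = mean(en$eps_syn), eps_height = mean(en$eps_height),
             eps_speed = mean(en$eps_speed),
             duty_factor = mean(cyc$duty_factor),
             T_cycle = mean(use$duration), status = "ok",
             stringsAsFactors = FALSE)
}
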