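# Per-cycle energetics: positive and negative muscle work, stride
# length, cost of transport eps = W / D with the negative (eccentric)
# work down-weighted by 1/4, and the decomposition of the cost into
# synergy, posture and speed contributions.

#' Positive and negative mechanical muscle work
#'
#' Trapezoidal quadrature of `eta_+ = int sum_m F_m [v_m]^+ dt` and
#' `eta_- = 1/4 int sum_m F_m [-v_m]^+ dt` over a cycle window, with
#' `v_m` the contraction velocity in m/s (positive for contraction).
#'
#' @param tension matrix (time x muscles) of tensions (N), or a vector
#'   for a single muscle
#' @param velocity matching matrix/vector of contraction velocities (m/s)
#' @param time sample times (s)
#' @return list with `eta_pos`, `eta_neg` (already divided by 4) and
#'   `W = eta_pos + eta_neg`, all in joules
#' @export
mechanical_work <- function(tension, velocity, time) {
  tension <- as.matrix(tension); velocity <- as.matrix(velocity)
  if (length(time) < 2) stop("empty cycle window")
  stopifnot(nrow(tension) == length(time), all(dim(tension) == dim(velocity)))
  Ppos <- rowSums(tension * pmax(velocity, 0))
  Pneg <- rowSums(tension * pmax(-velocity, 0))
  trap <- function(y) sum(diff(time) * (head(y, -1) + tail(y, -1)) / 2)
  eta_pos <- trap(Ppos)
  eta_neg <- trap(Pneg) / 4
  list(eta_pos = eta_pos, eta_neg = eta_neg, W = eta_pos + eta_neg)
}

# interpolate a cumulative-quantity column at arbitrary times
.interp <- function(t, y, at) approx(t, y, xout = at, rule = 2)$y

#' Stride length over a cycle window
#'
#' Horizontal trunk-CoM displacement between the window edges.  A
#' negative displacement (backward drift) is returned as-is with a
#' warning since the cost of transport is undefined there.
#'
#' @param traj a `rat_trajectory`
#' @param window numeric(2): start and end time (s)
#' @return stride length (m)
#' @export
stride_length <- function(traj, window) {
  x <- .trunk_com_x(traj)
  D <- .interp(traj$time, x, window[2]) - .interp(traj$time, x, window[1])
  if (D < 0) warning("backward drift over cycle window; CoT undefined")
  D
}

.trunk_com_x <- function(traj) {
  cx <- traj$model$comx[3]
  traj$q[, 1] + cx * cos(traj$q[, 3])
}

#' Cost of transport
#'
#' `eps = W / D` (J/m).
#'
#' @param W mechanical work over one gait cycle (J)
#' @param D stride length (m)
#' @return cost of transport; `NaN` with a warning if `D <= 0`
#' @export
cot <- function(W, D) {
  if (D <= 0) {
    warning("nonpositive stride length; CoT undefined")
    return(NaN)
  }
  W / D
}

# difference of a cumulative work accumulator over a window
.acc_diff <- function(traj, col, window) {
  .interp(traj$time, traj$work[, col], window[2]) -
    .interp(traj$time, traj$work[, col], window[1])
}

#' Per-cycle energetics report
#'
#' For each detected cycle window: positive/negative work, total work,
#' stride length, mean speed, cost of transport and its synergy,
#' posture and speed components (active-term work driven by each
#' command component's own activation), plus the passive-term work kept
#' separate.
#'
#' @param traj a `rat_trajectory`
#' @param windows data frame with `start`/`end` columns, as returned by
#'   [detect_cycles()]; defaults to all detected cycles
#' @return data frame of class `rat_energetics`, one row per cycle
#' @export
energetics_report <- function(traj, windows = NULL) {
  if (is.null(windows)) windows <- detect_cycles(traj)$windows
  n <- nrow(windows)
  if (n < 1) stop("no cycle windows")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    w <- c(windows$start[i], windows$end[i])
    eta_pos <- .acc_diff(traj, "pos", w)
    eta_neg <- .acc_diff(traj, "neg", w) / 4
    W <- eta_pos + eta_neg
    D <- stride_length(traj, w)
    Tcyc <- w[2] - w[1]
    comp <- vapply(c("syn", "height", "speed", "passive"), function(cc) {
      .acc_diff(traj, paste0(cc, "_pos"), w) +
        .acc_diff(traj, paste0(cc, "_neg"), w) / 4
    }, numeric(1))
    eps <- if (D > 0) W / D else NaN
    out[[i]] <- data.frame(
      cycle = i, start = w[1], end = w[2], duration = Tcyc,
      eta_pos = eta_pos, eta_neg = eta_neg, W = W, D = D,
      speed = D / Tcyc, eps = eps,
      eps_syn = comp[["syn"]] / D, eps_height = comp[["height"]] / D,
      eps_speed = comp[["speed"]] / D, W_passive = comp[["passive"]])
  }
  rep <- do.call(rbind, out)
  class(rep) <- c("rat_energetics", "data.frame")
  rep
}

#' Cost-of-transport decomposition
#'
#' Component costs from the three command sources (synergy pulses,
#' posture regulation, speed regulation).  Each component command was
#' passed through its own copy of the activation dynamics during the
#' simulation; component tensions use the active term only
#' (`Fmax a_comp fl fv` on the realized length/velocity).  Passive-term
#' work is excluded from the components and reported separately.
#'
#' @param traj a `rat_trajectory`
#' @param window numeric(2) cycle window; defaults to the last detected
#'   cycle
#' @return named numeric: `eps_syn`, `eps_height`, `eps_speed`,
#'   `eps_active` (active-term cost under the full command) and
#'   `residual = eps_active - (eps_syn + eps_height + eps_speed)`
#' @export
cot_decomposition <- function(traj, window = NULL) {
  if (is.null(window)) {
    wd <- detect_cycles(traj)$windows
    window <- c(wd$start[nrow(wd)], wd$end[nrow(wd)])
  }
  D <- stride_length(traj, window)
  comp <- vapply(c("syn", "height", "speed"), function(cc) {
    (.acc_diff(traj, paste0(cc, "_pos"), window) +
       .acc_diff(traj, paste0(cc, "_neg"), window) / 4) / D
  }, numeric(1))
  W_act <- (.acc_diff(traj, "pos", window) -
              .acc_diff(traj, "passive_pos", window)) +
    (.acc_diff(traj, "neg", window) - .acc_diff(traj, "passive_neg", window)) / 4
  eps_active <- W_act / D
  c(eps_syn = comp[["syn"]], eps_height = comp[["height"]],
    eps_speed = comp[["speed"]], eps_active = eps_active,
    residual = eps_active - sum(comp))
}
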