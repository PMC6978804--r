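# Independent numerical-Lagrangian oracle for the skeleton dynamics.
# Forward kinematics are re-derived here in plain R directly from the
# joint-angle conventions; the Lagrangian and its derivatives are then
# evaluated by finite differences, so the oracle shares no code with
# the compiled dynamics.

oracle_fk <- function(q) {
  deg <- pi / 180
  lt <- 0.093; lb <- 0.0161; la <- 0.019
  lth <- 0.0185; lsh <- 0.0272; lf <- 0.0177
  mid <- c(q[1], q[2]); pitch <- q[3]
  u <- function(th) c(cos(th), sin(th))
  sh <- mid + 0.0465 * u(pitch); hp <- mid - 0.0465 * u(pitch)
  limb_f <- function(qsh, qel) {
    thb <- pitch + (qsh - 210 * deg)
    tha <- thb + (pi - qel)
    el <- sh + lb * u(thb)
    list(br = list(c = sh + lb / 2 * u(thb), th = thb),
         an = list(c = el + la / 2 * u(tha), th = tha),
         tip = el + la * u(tha))
  }
  limb_h <- function(qh, qk, qa) {
    thth <- pitch + (30 * deg - qh)
    thsh <- thth + (qk - pi)
    thft <- thsh + (pi - qa)
    kn <- hp + lth * u(thth); an <- kn + lsh * u(thsh)
    list(th = list(c = hp + lth / 2 * u(thth), th = thth),
         sh = list(c = kn + lsh / 2 * u(thsh), th = thsh),
         ft = list(c = an + lf / 2 * u(thft), th = thft),
         tip = an + lf * u(thft))
  }
  list(trunk = list(c = mid, th = pitch),
       LF = limb_f(q[4], q[5]), RF = limb_f(q[6], q[7]),
       LH = limb_h(q[8], q[9], q[10]), RH = limb_h(q[11], q[12], q[13]))
}

.or_mass <- c(tr = 0.0998, br = 0.0016, an = 0.0016,
              th = 0.0052, sh = 0.0028, ft = 0.0015)
.or_inert <- c(tr = 1.41e-4, br = 5.7e-8, an = 5.3e-8,
               th = 5.73e-7, sh = 2.62e-7, ft = 7.5e-8)

oracle_bodies <- function(q) {
  f <- oracle_fk(q)
  list(list(f$trunk$c, f$trunk$th, .or_mass["tr"], .or_inert["tr"]),
       list(f$LF$br$c, f$LF$br$th, .or_mass["br"], .or_inert["br"]),
       list(f$LF$an$c, f$LF$an$th, .or_mass["an"], .or_inert["an"]),
       list(f$RF$br$c, f$RF$br$th, .or_mass["br"], .or_inert["br"]),
       list(f$RF$an$c, f$RF$an$th, .or_mass["an"], .or_inert["an"]),
       list(f$LH$th$c, f$LH$th$th, .or_mass["th"], .or_inert["th"]),
       list(f$LH$sh$c, f$LH$sh$th, .or_mass["sh"], .or_inert["sh"]),
       list(f$LH$ft$c, f$LH$ft$th, .or_mass["ft"], .or_inert["ft"]),
       list(f$RH$th$c, f$RH$th$th, .or_mass["th"], .or_inert["th"]),
       list(f$RH$sh$c, f$RH$sh$th, .or_mass["sh"], .or_inert["sh"]),
       list(f$RH$ft$c, f$RH$ft$th, .or_mass["ft"], .or_inert["ft"]))
}

oracle_lagrangian <- function(q, qd, g = 9.81) {
  eps <- 1e-5
  b1 <- oracle_bodies(q + eps * qd)
  b0 <- oracle_bodies(q - eps * qd)
  bb <- oracle_bodies(q)
  Tk <- 0; V <- 0
  for (i in seq_along(bb)) {
    vc <- (b1[[i]][[1]] - b0[[i]][[1]]) / (2 * eps)
    om <- (b1[[i]][[2]] - b0[[i]][[2]]) / (2 * eps)
    Tk <- Tk + 0.5 * bb[[i]][[3]] * sum(vc^2) + 0.5 * bb[[i]][[4]] * om^2
    V <- V + bb[[i]][[3]] * g * bb[[i]][[1]][2]
  }
  Tk - V
}

# residual of the Lagrange equations at (q, qd, qdd) under generalized
# forces Q, relative to the force scale
oracle_eom_residual <- function(q, qd, qdd, Q, h2 = 5e-4) {
  dLdqd <- function(q, qd) {
    sapply(1:13, function(k) {
      dp <- qd; dm <- qd; dp[k] <- dp[k] + h2; dm[k] <- dm[k] - h2
      (oracle_lagrangian(q, dp) - oracle_lagrangian(q, dm)) / (2 * h2)
    })
  }
  dLdq <- sapply(1:13, function(k) {
    qp <- q; qm <- q; qp[k] <- qp[k] + h2; qm[k] <- qm[k] - h2
    (oracle_lagrangian(qp, qd) - oracle_lagrangian(qm, qd)) / (2 * h2)
  })
  ddt <- (dLdqd(q + h2 * qd, qd + h2 * qdd) -
            dLdqd(q - h2 * qd, qd - h2 * qdd)) / (2 * h2)
  res <- ddt - dLdq - Q
  max(abs(res)) / max(abs(Q) + abs(dLdq) + 1e-6)
}

# random dynamically admissible state for oracle checks
oracle_random_state <- function() {
  q <- c(runif(1, -0.1, 0.1), runif(1, 0.04, 0.08), runif(1, -0.3, 0.3),
         runif(10, c(60, 85, 60, 85, 60, 90, 100, 60, 90, 100) * pi / 180 - 0.4,
               c(120, 180, 120, 180, 120, 180, 180, 120, 180, 180) *
                 pi / 180 + 0.2))
  qd <- runif(13, -3, 3); qd[1:2] <- runif(2, -0.5, 0.5)
  list(q = q, qd = qd)
}
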