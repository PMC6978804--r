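test_that("skeleton assembles with the measured link parameters", {
  m <- build_skeleton()
  # trunk once, limb links twice each
  expect_equal(m$total_mass, 0.1252, tolerance = 1e-12)

  bad <- skeleton_params()
  bad$links$thigh$mass <- 0
  expect_error(build_skeleton(bad), "thigh")
  bad2 <- skeleton_params()
  bad2$links$foot$length <- -0.01
  expect_error(build_skeleton(bad2), "foot")
})

test_that("reference configuration is left-right symmetric", {
  m <- build_skeleton()
  k <- kinematic_queries(m, reference_state(z = 0.06))
  # left and right tips coincide in height and x for each girdle
  expect_equal(k$tip_pos["LF", ], k$tip_pos["RF", ])
  expect_equal(k$tip_pos["LH", ], k$tip_pos["RH", ])
  # limbs hang straight below the girdle joints
  expect_equal(unname(k$tip_pos["LF", "x"]), 0.0465, tolerance = 1e-12)
  expect_equal(unname(k$tip_pos["LH", "x"]), -0.0465, tolerance = 1e-12)
  expect_equal(unname(k$tip_pos["LF", "z"]), 0.06 - 0.0351, tolerance = 1e-12)
  expect_equal(unname(k$tip_pos["LH", "z"]), 0.06 - 0.0634, tolerance = 1e-12)
})

test_that("unforced equilibria behave correctly", {
  m <- build_skeleton()
  st <- reference_state(z = 0.06)
  m0 <- m; m0$gravity <- 0
  expect_equal(max(abs(generalized_accelerations(m0, st))), 0)
  # with gravity the free skeleton falls as a rigid body
  qdd <- generalized_accelerations(m, st)
  expect_equal(unname(qdd["z"]), -9.81, tolerance = 1e-9)
  expect_equal(unname(qdd["x"]), 0, tolerance = 1e-9)
  expect_error(generalized_accelerations(m, st, rep(0, 3)), "10")
})

test_that("kinematic queries are translation invariant", {
  m <- build_skeleton()
  s1 <- reference_state(z = 0.06, x = 0)
  s2 <- reference_state(z = 0.06, x = 1)
  k1 <- kinematic_queries(m, s1)
  k2 <- kinematic_queries(m, s2)
  expect_equal(k1$shoulder_height, k2$shoulder_height)
  expect_equal(k1$hip_height, k2$hip_height)
  expect_equal(k2$tip_pos[, "x"] - k1$tip_pos[, "x"], rep(1, 4),
               ignore_attr = TRUE)
})

test_that("standing pose reaches the reference heights", {
  m <- build_skeleton()
  st <- pose_standing(m, 0.033, 0.054)
  k <- kinematic_queries(m, st)
  expect_equal(unname(k$shoulder_height), c(0.033, 0.033), tolerance = 1e-6)
  expect_equal(unname(k$hip_height), c(0.054, 0.054), tolerance = 1e-6)
  # limb tips on the ground
  expect_equal(max(abs(k$tip_pos[, "z"])), 0, tolerance = 1e-6)
})

test_that("contact forces are one-sided and vertically nonnegative", {
  m <- build_skeleton()
  cp <- contact_params()
  # tips above ground: no force
  st <- reference_state(z = 0.08)
  cf <- contact_forces(m, st, cp)
  expect_equal(max(abs(cf$force)), 0)
  expect_false(any(cf$stance))
  # hind tips penetrate 1 mm at rest: 1 N vertical with 1000 N/m
  st2 <- reference_state(z = 0.0634 - 0.001)
  cf2 <- contact_forces(m, st2, cp)
  expect_equal(unname(cf2$force["LH", "z"]), 1.0, tolerance = 1e-9)
  expect_true(all(cf2$force[, "z"] >= 0))
  # fast upward tip motion: clamped at zero, never adhesive
  st3 <- st2
  st3$qd[2] <- 10
  cf3 <- contact_forces(m, st3, cp)
  expect_true(all(cf3$force[, "z"] >= 0))
  expect_equal(unname(cf3$force["LH", "z"]), 0)
})

test_that("generalized accelerations match the numerical Lagrangian", {
  m <- build_skeleton()
  set.seed(421)
  worst <- 0
  for (rep in 1:25) {
    s <- oracle_random_state()
    tau <- runif(10, -0.02, 0.02)
    tf <- matrix(runif(8, -0.5, 0.5), 4, 2)
    qdd <- generalized_accelerations(m, skeleton_state(s$q, s$qd), tau, tf)
    # tip-force generalized forces via virtual work on the oracle FK
    tipQ <- function(q) {
      f <- oracle_fk(q)
      sum(rbind(f$LF$tip, f$RF$tip, f$LH$tip, f$RH$tip) * tf)
    }
    h <- 1e-6
    Q <- c(0, 0, 0, tau)
    for (k in 1:13) {
      qp <- s$q; qm <- s$q
      qp[k] <- qp[k] + h; qm[k] <- qm[k] - h
      Q[k] <- Q[k] + (tipQ(qp) - tipQ(qm)) / (2 * h)
    }
    worst <- max(worst, oracle_eom_residual(s$q, s$qd, qdd, Q))
  }
  expect_lt(worst, 1e-4)
})

test_that("passive contact-free motion conserves mechanical energy", {
  m <- build_skeleton()
  set.seed(7)
  st <- reference_state(z = 1.0)
  q <- st$q; q[4:13] <- q[4:13] + runif(10, -0.3, 0.3)
  x <- c(q, rep(0, 13))
  E0 <- total_mechanical_energy(m, skeleton_state(x[1:13], x[14:26]))
  dt <- 2e-5
  derivf <- function(x) {
    c(x[14:26],
      generalized_accelerations(m, skeleton_state(x[1:13], x[14:26])))
  }
  for (n in 1:10000) {   # 0.2 s of free swing
    k1 <- derivf(x); k2 <- derivf(x + dt / 2 * k1)
    k3 <- derivf(x + dt / 2 * k2); k4 <- derivf(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  E1 <- total_mechanical_energy(m, skeleton_state(x[1:13], x[14:26]))
  expect_lt(abs(E1 - E0) / abs(E0), 1e-6)
})

test_that("doubling all velocities quadruples the kinetic term", {
  m <- build_skeleton()
  set.seed(11)
  s <- oracle_random_state()
  V <- total_mechanical_energy(m, skeleton_state(s$q, 0 * s$qd))
  E1 <- total_mechanical_energy(m, skeleton_state(s$q, s$qd))
  E2 <- total_mechanical_energy(m, skeleton_state(s$q, 2 * s$qd))
  expect_equal(E2 - V, 4 * (E1 - V), tolerance = 1e-12)
})

test_that("pinned-link acceleration matches the pendulum closed form", {
  # near-immovable base body + one revolute link = gravity pendulum
  mb <- 1e6; Ib <- 1e6
  mp <- 0.004; lp <- 0.05; cp_ <- 0.025; Ip <- mp * lp^2 / 12
  for (th in c(0.3, 1.2, -0.7)) {
    pend <- ratgait:::planar_model(
      parent = c(-1L, 0L), jtype = c(2L, 2L), sense = c(1, 1),
      offset = c(0, 0), anchor_x = c(0, 0), anchor_z = c(0, 0),
      mass = c(mb, mp), comx = c(0, cp_), inertia = c(Ib, Ip),
      length = c(0.1, lp), tips = integer(0), gravity = 9.81)
    qdd <- ratgait:::.pd_fwd_dyn(pend, c(0, th), c(0, 0), c(0, 0),
                                 matrix(0, 0, 2))
    # theta measured from +x; gravity torque = -m g c cos(theta)
    I_pivot <- Ip + mp * cp_^2
    expect_equal(qdd[2], -mp * 9.81 * cp_ * cos(th) / I_pivot,
                 tolerance = 1e-6)
  }
})
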