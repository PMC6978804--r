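neutral <- c(shoulder = 60, elbow = 85, hip = 70, knee = 90, ankle = 100)

test_that("normalized lengths at the neutral posture are 85%/75%", {
  mus <- muscle_set()
  l0 <- muscle_length(mus, neutral)
  expect_equal(unname(l0[mus$njoints == 1]),
               rep(0.85, sum(mus$njoints == 1)))
  expect_equal(unname(l0[mus$njoints == 2]),
               rep(0.75, sum(mus$njoints == 2)))
})

test_that("length map follows the degrees-per-percent coefficients", {
  mus <- muscle_set()
  ta <- mus[mus$name == "TA_L", ]
  # ankle flexor lengthens with extension: 10 deg / (2 deg per 1%) = 5%
  expect_equal(unname(muscle_length(ta, c(neutral[1:4], ankle = 110))), 0.90)
  so <- mus[mus$name == "SO_L", ]
  expect_equal(unname(muscle_length(so, c(neutral[1:4], ankle = 110))), 0.80)
  # GA: 1.5 deg/1% at the ankle, 4.5 deg/1% at the knee
  ga <- mus[mus$name == "GA_R", ]
  expect_equal(unname(muscle_length(ga, c(neutral[1:3], knee = 99, ankle = 100))),
               0.75 + 0.02)
  expect_equal(unname(muscle_length(ga, c(neutral[1:3], knee = 90, ankle = 103))),
               0.75 - 0.02)
  expect_error(muscle_length(ta, c(shoulder = 60)), "ankle")
})

test_that("contraction velocity is the normalized length rate", {
  mus <- muscle_set()
  ta <- mus[mus$name == "TA_L", ]
  rates0 <- c(shoulder = 0, elbow = 0, hip = 0, knee = 0, ankle = 0)
  expect_equal(unname(muscle_velocity(ta, neutral, rates0)), 0)
  # ankle extending at 2 deg/s lengthens TA at 0.01/s
  v <- muscle_velocity(ta, neutral, c(rates0[1:4], ankle = 2))
  expect_equal(unname(v), -0.01 / 1.8, tolerance = 1e-12)
  v2 <- muscle_velocity(ta, neutral, c(rates0[1:4], ankle = -2))
  expect_equal(unname(v2), -unname(v))
})

test_that("tension follows the Hill form with normalized curves", {
  cv <- muscle_curves()
  expect_equal(cv$fl(1), 1)
  expect_equal(cv$fv(0), 1)
  expect_equal(cv$fp(0.95), 0)
  expect_true(all(cv$fv(seq(-2, 5, by = 0.1)) >= 0))
  # passive term vanishes below maximum length: zero activation => zero force
  expect_equal(muscle_tension(3.5, 0, 0.85, 0, cv), 0)
  # SO at maximum tension point
  expect_equal(muscle_tension(3.5, 1, 1, 0, cv), 3.5)
  # linear in activation
  f1 <- muscle_tension(10, 1, 0.9, 0.1, cv)
  f05 <- muscle_tension(10, 0.5, 0.9, 0.1, cv)
  expect_equal(f05, f1 / 2)
  expect_error(muscle_tension(10, 1.5, 1, 0, cv), "0, 1")
})

test_that("activation dynamics reproduce the printed time constants", {
  dt <- 2e-5
  a <- 0
  for (n in seq_len(round(0.011 / dt))) a <- activation_step(a, 1, dt)
  expect_equal(a, 1 - exp(-1), tolerance = 1e-6)
  a <- 1
  for (n in seq_len(round(0.018 / dt))) a <- activation_step(a, 0, dt)
  expect_equal(a, exp(-1), tolerance = 1e-6)
  expect_equal(activation_step(0, 0, dt), 0)
  expect_error(activation_step(0.5, 1, -1), "positive")
})

test_that("activation step converges to the analytic solution as dt shrinks", {
  sol <- function(t) 1 - exp(-t / 0.011)
  errs <- sapply(c(2e-3, 1e-3, 5e-4), function(dt) {
    a <- 0
    for (n in seq_len(round(0.02 / dt))) a <- activation_step(a, 1, dt)
    abs(a - sol(0.02))
  })
  expect_true(all(diff(errs) <= 0))   # error decreases with dt
  expect_lt(errs[3], 1e-7)
})

test_that("activation stays in [0,1] under arbitrary command trains", {
  set.seed(99)
  a <- runif(26)
  for (step in 1:200) {
    u <- ifelse(runif(26) < 0.5, 0, runif(26))
    a <- activation_step(a, u, 5e-4)
    expect_true(all(a >= 0 & a <= 1))
  }
})

test_that("joint torques follow the tabulated moment arms, extensor-positive", {
  mus <- muscle_set()
  zero <- setNames(rep(0, 26), mus$name)
  t1 <- zero; t1["TRIL_L"] <- 1
  tq <- joint_torques_from_muscles(t1, mus)
  expect_equal(unname(tq["el_L"]), 0.0059)
  expect_equal(sum(abs(tq)), 0.0059)
  # biarticular BF: hip extensor 2.5 mm, knee flexor 12.5 mm
  t2 <- zero; t2["BF_L"] <- 1
  tq2 <- joint_torques_from_muscles(t2, mus)
  expect_equal(unname(tq2["hip_L"]), 0.0025)
  expect_equal(unname(tq2["kn_L"]), -0.0125)
  expect_equal(joint_torques_from_muscles(zero, mus),
               setNames(rep(0, 10), names(tq)))
})

test_that("every joint has both extensor and flexor muscles", {
  mus <- muscle_set()
  acts <- list()
  for (i in seq_len(nrow(mus))) {
    m <- mus[i, ]
    j1 <- paste0(m$joint1, "_", m$side)
    acts[[j1]] <- union(acts[[j1]], m$action1)
    if (m$njoints > 1) {
      j2 <- paste0(m$joint2, "_", m$side)
      acts[[j2]] <- union(acts[[j2]], m$action2)
    }
  }
  expect_length(acts, 10)
  for (j in names(acts))
    expect_setequal(acts[[j]], c("extensor", "flexor"))
})
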