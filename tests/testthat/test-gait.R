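test_that("nominal duty parameter follows from the phase durations", {
  # T_fl = 0.10 s, T_ex = 0.16 s
  expect_equal(round(0.16 / (0.10 + 0.16), 2), 0.62)
  gc <- gait_config("walk")
  expect_equal(gc$beta, 0.62)
  expect_equal(gc$T, 0.10 / (1 - 0.62))
  expect_equal(gc$T_ex, gc$beta * gc$T)
})

test_that("gait selection changes only the phase offset", {
  w <- gait_config("walk"); t <- gait_config("trot")
  expect_equal(w$Delta, pi / 2)
  expect_equal(t$Delta, pi)
  w$Delta <- NULL; t$Delta <- NULL
  w$gait <- NULL; t$gait <- NULL
  attributes(w) <- NULL; attributes(t) <- NULL
  expect_identical(w, t)
  # schedules and weights are gait-independent by construction
  expect_identical(synergy_schedule(0.6)$w, synergy_schedule(0.6)$w)
})

test_that("pulse phases rescale by the extension fraction", {
  s <- synergy_schedule()
  # identity at the nominal beta
  ph <- scaled_pulse_phases(0.62, s)
  expect_equal(ph$Phi, s$Phi, tolerance = 1e-12)
  expect_equal(ph$Psi, s$Psi, tolerance = 1e-12)
  # the extension/flexion boundary sits at 2 pi beta for every beta
  for (b in c(0.4, 0.5, 0.62, 0.7))
    expect_equal(scaled_pulse_phases(b, s)$Phi[3], 2 * pi * b,
                 tolerance = 1e-12)
  ph5 <- scaled_pulse_phases(0.5, s)
  expect_equal(ph5$Phi[1], 0)
  expect_equal(ph5$Psi[1], (0.5 / 0.62) * 0.33 * pi)
  expect_error(scaled_pulse_phases(1.2, s), "beta")
})

test_that("extension-pulse weights rescale, flexion weights do not", {
  s <- synergy_schedule()
  w5 <- scaled_weights(0.5, s)
  expect_equal(w5["SO_L", 1], 0.58 * 0.5 / 0.38)
  expect_equal(w5["TRIL_R", 2], 0.57 * 0.5 / 0.38)
  expect_equal(w5[, 3:4], s$w[, 3:4])
  expect_equal(scaled_weights(0.62, s), s$w, tolerance = 1e-12)
})

test_that("regulator references shift linearly with beta", {
  r0 <- scaled_references(0.62)
  expect_equal(unname(r0), c(0.033, 0.054, 0.4))
  r <- scaled_references(0.64)
  expect_equal(unname(r["v0"]), 0.4 - 4.7 * 0.02)
  expect_equal(unname(r["h0_shoulder"]), 0.033 + 0.01 * 0.02)
  expect_equal(unname(r["h0_hip"]), 0.054 + 0.01 * 0.02)
})

test_that("beta ramps are monotone and reach the target", {
  r <- beta_ramp(0.62, 0.58, rate = 0.005)
  expect_equal(nrow(r), 8)
  expect_equal(r$beta[8], 0.58)
  expect_true(all(diff(r$beta) <= 0))
  expect_true(all(r$beta >= 0.58))
  r2 <- beta_ramp(0.6, 0.6)
  expect_equal(nrow(r2), 0)
  expect_error(beta_ramp(0.6, 2, rate = 0.01), "bounds")
})

test_that("cycle duration keeps the flexion time invariant", {
  for (b in seq(0.4, 0.8, by = 0.05)) {
    gc <- gait_config("walk", beta = b)
    expect_equal(gc$T * (1 - b), 0.10, tolerance = 1e-12)
  }
})

test_that("scaled schedules remain valid pulse schedules", {
  for (b in c(0.45, 0.56, 0.62, 0.68, 0.8)) {
    s <- synergy_schedule(b)
    expect_true(all(s$Phi < s$Psi))
    expect_true(all(s$Psi <= 2 * pi))
    expect_equal(s$Phi[1], 0)
  }
})
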