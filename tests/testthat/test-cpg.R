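test_that("uncoupled oscillators drift at 2 pi / T", {
  os <- oscillator_state(T = 0.26, K1 = 0, K2 = 0, Delta = pi / 2)
  os2 <- oscillator_step(os, 0.001)
  expect_equal(unname((os2$phi - os$phi) %% (2 * pi)),
               rep(2 * pi * 0.001 / 0.26, 4), tolerance = 1e-12)
  expect_error(oscillator_state(T = -1), "positive")
  expect_error(oscillator_step(os, 0), "positive")
})

test_that("the gait fixed point cancels all coupling terms", {
  for (Delta in c(pi / 2, pi)) {
    os <- oscillator_state(gait_fixed_point(Delta), T = 0.26, Delta = Delta)
    os2 <- oscillator_step(os, 0.002)
    drift <- (os2$phi - os$phi) %% (2 * pi)
    expect_equal(unname(drift), rep(2 * pi * 0.002 / 0.26, 4),
                 tolerance = 1e-9)
  }
})

test_that("phases lock to the gait pattern from perturbed starts", {
  set.seed(5)
  for (Delta in c(pi / 2, pi)) {
    phi0 <- gait_fixed_point(Delta) + runif(4, -0.3, 0.3)
    os <- oscillator_state(phi0, T = 0.26, K1 = 20, K2 = 10, Delta = Delta)
    for (n in 1:10000) os <- oscillator_step(os, 1e-4)   # 1 s
    rel <- function(a, b) {
      d <- (os$phi[[a]] - os$phi[[b]]) %% (2 * pi)
      min(d, 2 * pi - d)
    }
    # contralateral antiphase
    expect_equal(rel("LF", "RF"), pi, tolerance = 0.01)
    expect_equal(rel("LH", "RH"), pi, tolerance = 0.01)
    # ipsilateral offset Delta (fore lags hind by Delta)
    dlf <- (os$phi[["LF"]] - os$phi[["LH"]]) %% (2 * pi)
    expect_equal(dlf, 2 * pi - Delta, tolerance = 0.01)
  }
})

test_that("rectangular pulses follow the printed schedule", {
  s <- synergy_schedule()
  expect_equal(pulse_values(s, 0.2 * pi), c(1, 0, 0, 0))
  expect_equal(pulse_values(s, 0.5 * pi), c(0, 1, 0, 0))
  expect_equal(pulse_values(s, 1.3 * pi), c(0, 0, 1, 0))
  expect_equal(pulse_values(s, 1.5 * pi), c(0, 0, 0, 1))
  expect_equal(pulse_values(s, 1.9 * pi), c(0, 0, 0, 0))
  # half-open intervals: onset included, end excluded
  expect_equal(pulse_values(s, 0.40 * pi), c(0, 1, 0, 0))
  expect_equal(pulse_values(s, 0.33 * pi), c(0, 0, 0, 0))
  # pulses within each pair are disjoint
  expect_lte(s$Psi[1], s$Phi[2])
  expect_lte(s$Psi[3], s$Phi[4])
})

test_that("synergy commands combine weights and pulses", {
  s <- synergy_schedule()
  u1 <- synergy_command(s, 0.2 * pi)
  expect_equal(unname(u1["SO_L"]), 0.58)
  expect_equal(unname(u1["GM_R"]), 0.61)
  u2 <- synergy_command(s, 0.5 * pi)
  expect_equal(unname(u2["TRIL_L"]), 0.57)
  expect_equal(unname(synergy_command(s, 1.9 * pi)), rep(0, 26))
  # per-limb phases: forelimb muscles read the fore oscillator
  u3 <- synergy_command(s, c(LF = 0.2 * pi, RF = 1.9 * pi,
                             LH = 0.5 * pi, RH = 1.9 * pi))
  expect_equal(unname(u3["TRIL_L"]), 0.47)   # LF in pulse 1
  expect_equal(unname(u3["TRIL_R"]), 0)      # RF outside all pulses
  expect_equal(unname(u3["SO_L"]), 0.14)     # LH in pulse 2
})

test_that("synergy command is piecewise constant with few breakpoints", {
  s <- synergy_schedule()
  phis <- seq(0, 2 * pi, length.out = 4001)
  u <- sapply(phis[-length(phis)], function(p) {
    sum(synergy_command(s, p)[c("SO_L", "TRIL_L", "IP_L", "SSP_L")])
  })
  expect_lte(sum(diff(u) != 0), 8)
})
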