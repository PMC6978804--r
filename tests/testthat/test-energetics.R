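# a minimal synthetic trajectory for the pure-arithmetic energetics ops
fake_traj <- function(speed = 0.2, T_end = 1) {
  tm <- seq(0, T_end, by = 1e-3)
  work <- matrix(0, length(tm), 10)
  colnames(work) <- c("pos", "neg", "syn_pos", "syn_neg", "height_pos",
                      "height_neg", "speed_pos", "speed_neg",
                      "passive_pos", "passive_neg")
  q <- matrix(0, length(tm), 13)
  q[, 1] <- speed * tm
  structure(list(time = tm, q = q, work = work,
                 model = list(comx = c(0, 0, 0, rep(0, 10))),
                 events = list(touchdown = list(LF = numeric(0),
                                                RF = numeric(0),
                                                LH = numeric(0),
                                                RH = c(0, 0.26, 0.52)),
                               liftoff = list())),
            class = "rat_trajectory")
}

test_that("mechanical work integrates tension times contraction velocity", {
  tm <- seq(0, 1, by = 1e-3)
  Fm <- matrix(1, length(tm), 1)
  # constant contraction at 0.1 m/s for 1 s
  w <- mechanical_work(Fm, matrix(0.1, length(tm), 1), tm)
  expect_equal(w$eta_pos, 0.1, tolerance = 1e-12)
  expect_equal(w$eta_neg, 0)
  expect_equal(w$W, 0.1)
  # lengthening work is down-weighted by 1/4
  w2 <- mechanical_work(Fm, matrix(-0.1, length(tm), 1), tm)
  expect_equal(w2$eta_pos, 0)
  expect_equal(w2$eta_neg, 0.025, tolerance = 1e-12)
  # zero velocity: no work
  w3 <- mechanical_work(Fm, matrix(0, length(tm), 1), tm)
  expect_equal(w3$W, 0)
  expect_error(mechanical_work(Fm[1, , drop = FALSE],
                               matrix(0.1, 1, 1), tm[1]), "window")
})

test_that("stride length is the trunk displacement over the window", {
  tr <- fake_traj(speed = 0.2)
  expect_equal(stride_length(tr, c(0, 0.26)), 0.052, tolerance = 1e-9)
  tr0 <- fake_traj(speed = 0)
  expect_equal(stride_length(tr0, c(0, 0.26)), 0)
  trb <- fake_traj(speed = -0.1)
  expect_warning(D <- stride_length(trb, c(0, 0.26)), "backward")
  expect_lt(D, 0)
})

test_that("cost of transport is work per distance", {
  expect_equal(cot(0.1, 0.1), 1)
  expect_equal(cot(0.2, 0.2), 1)          # homogeneity
  expect_equal(cot(0, 0.1), 0)
  expect_warning(expect_true(is.nan(cot(0.1, 0))), "undefined")
})

test_that("component decomposition vanishes without its command source", {
  # regulators silenced: height and speed components must be zero and
  # the synergy component must equal the active-term cost
  cfg <- default_config()
  cfg$control$K_height <- list()
  cfg$control$D_height <- list()
  cfg$control$K_speed <- list()
  cfg$sim$assist$floor <- 1     # short supported run is enough here
  tr <- simulate_gait(sim_config("walk", duration = 1.2, cfg = cfg))
  wd <- detect_cycles(tr)$windows
  w <- c(wd$start[nrow(wd)], wd$end[nrow(wd)])
  dec <- cot_decomposition(tr, w)
  expect_equal(unname(dec["eps_height"]), 0, tolerance = 1e-12)
  expect_equal(unname(dec["eps_speed"]), 0, tolerance = 1e-12)
  # single-source: syn component reproduces the active-term cost up to
  # the clamping of the summed command
  expect_equal(unname(dec["eps_syn"]), unname(dec["eps_active"]),
               tolerance = 0.05)
})

test_that("in-simulation work accumulators match offline quadrature", {
  cfg <- default_config()
  cfg$sim$assist$floor <- 1
  tr <- simulate_gait(sim_config("walk", duration = 1.0, cfg = cfg))
  sel <- tr$time >= 0.3 & tr$time <= 0.9
  vnorm <- cfg$muscle_geometry$velocity_norm_lmax_per_s
  vm <- sweep(tr$vbar[sel, ], 2, tr$muscles$lmax * vnorm, "*")
  off <- mechanical_work(tr$tension[sel, ], vm, tr$time[sel])
  acc_pos <- .subset2(as.data.frame(tr$work), "pos")
  onl_pos <- acc_pos[max(which(sel))] - acc_pos[min(which(sel))]
  # 1 kHz offline quadrature vs full-rate accumulation
  expect_equal(off$eta_pos, onl_pos, tolerance = 0.02)
})

test_that("work accumulators converge under step refinement", {
  run <- function(dt) {
    cfg <- default_config()
    cfg$sim$assist$floor <- 1
    tr <- simulate_gait(sim_config("walk", duration = 0.3, dt = dt,
                                   log_every = round(1e-3 / dt), cfg = cfg))
    n <- nrow(tr$work)
    c(tr$work[n, "pos"], tr$work[n, "neg"])
  }
  w1 <- run(2e-5)
  w2 <- run(1e-5)
  expect_equal(w1[1], w2[1], tolerance = 1e-3)
  expect_equal(w1[2], w2[2], tolerance = 1e-3)
})
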