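test_that("cycle detection splits on right-hindlimb touchdowns", {
  tr <- structure(list(
    time = seq(0, 2, by = 1e-3),
    stance = matrix(1, 2001, 4, dimnames = list(NULL, c("LF","RF","LH","RH"))),
    events = list(touchdown = list(LF = 1.06, RF = 1.19, LH = 0.93,
                                   RH = c(1.00, 1.26, 1.52)),
                  liftoff = list(LF = numeric(0), RF = numeric(0),
                                 LH = numeric(0), RH = numeric(0)))),
    class = "rat_trajectory")
  cyc <- detect_cycles(tr)
  expect_equal(nrow(cyc$windows), 2)
  expect_equal(cyc$windows$duration, c(0.26, 0.26))
  tr$events$touchdown$RH <- 1.0
  expect_error(detect_cycles(tr), "no steady gait")
})

test_that("suspended model without gravity stays put", {
  cfg <- default_config()
  cfg$skeleton$gravity_ms2 <- 0
  for (mn in names(cfg$control$weights)) cfg$control$weights[[mn]] <- NULL
  cfg$control$K_height <- list(); cfg$control$D_height <- list()
  cfg$control$K_speed <- list()
  cfg$muscle_curves$fp_scale <- 0    # no passive tension either
  cfg$sim$assist$floor <- 0
  cfg$sim$assist$hold_s <- 0; cfg$sim$assist$fade_s <- 1e-6
  tr <- simulate_gait(sim_config("walk", duration = 0.05,
                                 initial_speed = 0, cfg = cfg))
  n <- nrow(tr$q)
  expect_equal(tr$q[n, ], tr$q[1, ], tolerance = 1e-8)
})

test_that("simulation is deterministic", {
  cfg <- default_config()
  t1 <- simulate_gait(sim_config("walk", duration = 0.3, cfg = cfg))
  t2 <- simulate_gait(sim_config("walk", duration = 0.3, cfg = cfg))
  expect_identical(t1$q, t2$q)
  expect_identical(t1$work, t2$work)
  expect_identical(t1$events, t2$events)
})

test_that("resumed simulations continue seamlessly", {
  cfg <- default_config()
  whole <- simulate_gait(sim_config("walk", duration = 0.4, cfg = cfg))
  part1 <- simulate_gait(sim_config("walk", duration = 0.2, cfg = cfg))
  part2 <- simulate_gait(sim_config("walk", duration = 0.2, cfg = cfg),
                         resume = part1$resume)
  n <- nrow(whole$q)
  # time stamps are re-accumulated on resume, so agreement is to
  # floating-point drift of the chaotic gait, not bitwise
  expect_equal(part2$q[nrow(part2$q), ], whole$q[n, ], tolerance = 1e-4)
})

test_that("trajectories carry a consistent record", {
  cfg <- default_config()
  tr <- simulate_gait(sim_config("walk", duration = 0.25, cfg = cfg))
  expect_s3_class(tr, "rat_trajectory")
  expect_true(all(diff(tr$time) > 0))
  expect_false(any(!is.finite(tr$q)))
  expect_true(all(tr$a >= 0 & tr$a <= 1))
  expect_true(all(tr$u >= 0 & tr$u <= 1))
  expect_true(all(tr$tension >= 0))
  expect_true(all(tr$tip_force[, c(2, 4, 6, 8)] >= 0))
  expect_equal(colnames(tr$q), ratgait:::.coord_names)
})

test_that("trajectory output files round-trip", {
  cfg <- default_config()
  tr <- simulate_gait(sim_config("walk", duration = 0.3, cfg = cfg))
  dir <- tempfile("ratgait_out")
  f <- write_trajectory(tr, dir)
  expect_true(all(file.exists(f[c("trajectory", "events", "config")])))
  df <- read.csv(f[["trajectory"]])
  expect_true(all(diff(df$time) > 0))
  cfg2 <- load_config(f[["config"]])
  expect_equal(cfg2$control$K1, cfg$control$K1)
  expect_equal(cfg2$run$gait, "walk")
  # comparison-data reader
  cmp <- file.path(dir, "cmp.csv")
  write.csv(data.frame(time = c(0, 0.1), hip_deg = c(100, 110)), cmp,
            row.names = FALSE)
  expect_equal(nrow(read_comparison_csv(cmp)), 2)
  bad <- file.path(dir, "bad.csv")
  write.csv(data.frame(a = 1:2), bad, row.names = FALSE)
  expect_error(read_comparison_csv(bad), "time")
  unlink(dir, recursive = TRUE)
})

test_that("sweep summaries are written as CSV and JSON", {
  sw <- structure(data.frame(beta = c(0.59, 0.62), speed = c(0.2, 0.21),
                             D = c(0.05, 0.05), W = c(0.02, 0.02),
                             eps = c(0.4, 0.4), eps_syn = c(0.3, 0.3),
                             eps_height = c(0.01, 0.01),
                             eps_speed = c(0.01, 0.01),
                             duty_factor = c(0.4, 0.4),
                             T_cycle = c(0.24, 0.26),
                             status = "ok"),
                  class = c("rat_sweep", "data.frame"))
  dir <- tempfile("ratgait_sw")
  f <- write_sweep(sw, dir)
  expect_true(all(file.exists(f)))
  js <- jsonlite::read_json(f[["json"]], simplifyVector = TRUE)
  expect_equal(js$beta, c(0.59, 0.62))
  unlink(dir, recursive = TRUE)
})
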