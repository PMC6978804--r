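# Output writers (CSV/JSON/YAML) and the optional comparison-data
# reader.  All outputs are plain text.

#' Write simulation outputs
#'
#' Writes the (already downsampled) trajectory, the touchdown/liftoff
#' event log, the per-cycle energetics table and the fully resolved
#' configuration into a directory.
#'
#' @param traj a `rat_trajectory`
#' @param dir output directory (created if missing)
#' @return named character vector of the files written, invisibly
#' @export
write_trajectory <- function(traj, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  f <- c(trajectory = file.path(dir, "trajectory.csv"),
         events = file.path(dir, "events.csv"),
         energetics = file.path(dir, "energetics.csv"),
         config = file.path(dir, "config_resolved.yaml"))
  df <- data.frame(time = traj$time, beta = traj$beta,
                   traj$q, traj$qd, phi = traj$phi, stance = traj$stance,
                   traj$tip_force,
                   a = traj$a, u = traj$u, tension = traj$tension,
                   check.names = TRUE)
  write.csv(df, f[["trajectory"]], row.names = FALSE)
  ev <- do.call(rbind, lapply(.tip_names, function(l) {
    rbind(
      if (length(traj$events$touchdown[[l]]))
        data.frame(limb = l, event = "touchdown",
                   time = traj$events$touchdown[[l]]),
      if (length(traj$events$liftoff[[l]]))
        data.frame(limb = l, event = "liftoff",
                   time = traj$events$liftoff[[l]]))
  }))
  ev <- ev[order(ev$time), ]
  write.csv(ev, f[["events"]], row.names = FALSE)
  en <- try(energetics_report(traj), silent = TRUE)
  if (!inherits(en, "try-error"))
    write.csv(as.data.frame(en), f[["energetics"]], row.names = FALSE)
  cfg <- traj$config$cfg
  cfg$run <- list(gait = traj$config$gait, beta = traj$config$beta,
                  beta_target = traj$config$beta_target,
                  duration = traj$config$duration, dt = traj$config$dt,
                  seed = traj$config$seed, status = traj$status)
  write_config(cfg, f[["config"]])
  invisible(f)
}

#' Write a beta-sweep summary
#'
#' @param sweep a `rat_sweep` table
#' @param dir output directory
#' @return file paths, invisibly
#' @export
write_sweep <- function(sweep, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f <- c(csv = file.path(dir, "sweep.csv"),
         json = file.path(dir, "sweep.json"))
  write.csv(as.data.frame(sweep), f[["csv"]], row.names = FALSE)
  jsonlite::write_json(as.data.frame(sweep), f[["json"]],
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(f)
}

#' Read a comparison time series
#'
#' Reads a user-supplied kinematic or EMG CSV (columns: `time` plus one
#' column per signal) for side-by-side comparison with simulated
#' trajectories.
#'
#' @param path CSV path
#' @return data frame with a numeric `time` column
#' @export
read_comparison_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"time" %in% names(df)) stop("comparison CSV needs a 'time' column")
  if (is.unsorted(df$time)) stop("comparison CSV 'time' must be sorted")
  df
}
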