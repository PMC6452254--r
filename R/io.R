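# Config files (YAML), trajectory CSV export, and config hashing.

#' Read a simulation config file
#'
#' YAML config with optional top-level sections `body`, `environment`,
#' `controller`, `cortex`, `experiment`; unknown keys are preserved.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Write a simulation config file
#'
#' @param config Named list.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Hash of an arbitrary configuration object
#'
#' Stable content hash used to tag trajectories and experiment reports.
#'
#' @param x Any R object.
#' @return Character hash.
#' @export
config_hash <- function(x) rlang::hash(x)

#' Export a trajectory to columnar CSV files
#'
#' Writes `states.csv` (tick, time, base pose, joint angles/velocities),
#' `motors.csv` and, for fetus trajectories, `receptors.csv` (tactile and
#' spindle channels) into a directory.
#'
#' @param traj A `trajectory`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
export_trajectory_csv <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nj <- traj$n_joints
  states <- as.data.frame(traj$states)
  names(states) <- c("x", "y", "phi", "vx", "vy", "omega",
                     paste0("theta_", seq_len(nj)),
                     paste0("thetadot_", seq_len(nj)))
  states <- cbind(tick = seq_len(nrow(states)) - 1, time = traj$time,
                  states)
  write.csv(states, file.path(dir, "states.csv"), row.names = FALSE)
  if (!is.null(traj$u)) {
    u <- as.data.frame(traj$u)
    names(u) <- paste0("u_", seq_len(ncol(u)))
    write.csv(cbind(time = traj$time, u), file.path(dir, "motors.csv"),
              row.names = FALSE)
  }
  if (!is.null(traj$activation)) {
    a <- as.data.frame(traj$activation)
    names(a) <- paste0("act_", seq_len(ncol(a)))
    write.csv(cbind(time = traj$time, a), file.path(dir, "motors.csv"),
              row.names = FALSE)
  }
  if (!is.null(traj$tactile)) {
    r <- as.data.frame(cbind(traj$tactile, traj$spindle_length,
                             traj$spindle_velocity))
    names(r) <- c(paste0("tactile_", seq_len(ncol(traj$tactile))),
                  paste0("spindle_len_", seq_len(ncol(traj$spindle_length))),
                  paste0("spindle_vel_", seq_len(ncol(traj$spindle_velocity))))
    write.csv(cbind(time = traj$time, r),
              file.path(dir, "receptors.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Flat CSV rows for metric values
#'
#' Appends rows `(metric, value, config_hash, seed)` to a CSV file,
#' creating it with a header if absent.
#'
#' @param metrics Named numeric vector or list.
#' @param path CSV path.
#' @param config_hash,seed Provenance columns.
#' @return `path`, invisibly.
#' @export
append_metrics_csv <- function(metrics, path, config_hash = "", seed = NA) {
  df <- data.frame(metric = names(metrics),
                   value = as.numeric(unlist(metrics)),
                   config_hash = config_hash, seed = seed)
  write.table(df, path, sep = ",", row.names = FALSE,
              col.names = !file.exists(path), append = file.exists(path))
  invisible(path)
}
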