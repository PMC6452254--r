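# Synthetic input generators: receptor streams with controlled block
# correlation structure, oscillatory test signals, and kinematic scripted
# trajectories.  These let the cortex, plasticity and metrics layers be
# exercised without running physics.

#' Specification of a block-correlated synthetic receptor stream
#'
#' Channels are partitioned into blocks (body "parts"); a Gaussian
#' latent-factor construction delivers a target within-block correlation
#' `rho_in` and between-block correlation `rho_out`
#' (`0 <= rho_out <= rho_in <= 1`), guaranteeing a positive semi-definite
#' correlation target by construction.
#'
#' @param n_channels Total channels.
#' @param blocks Integer or factor of length `n_channels` assigning each
#'   channel to a block.
#' @param rho_in,rho_out Target correlations.
#' @param noise_sd Additional independent noise SD (on top of the
#'   unit-variance construction).
#' @param duration Number of samples.
#' @param seed RNG seed.
#' @return A `stream_spec` object.
#' @export
stream_spec <- function(n_channels, blocks, rho_in = 0.8, rho_out = 0.1,
                        noise_sd = 0, duration = 1e4, seed = 1) {
  blocks <- as.integer(as.factor(blocks))
  if (length(blocks) != n_channels)
    stop("block partition must cover all channels")
  if (!(rho_out >= 0 && rho_out <= rho_in && rho_in <= 1))
    stop("need 0 <= rho_out <= rho_in <= 1 (got ", rho_out, ", ", rho_in,
         ")")
  structure(list(n_channels = n_channels, blocks = blocks,
                 rho_in = rho_in, rho_out = rho_out, noise_sd = noise_sd,
                 duration = duration, seed = seed), class = "stream_spec")
}

#' Generate a block-correlated receptor stream
#'
#' `x_c(t) = sqrt(rho_out) g(t) + sqrt(rho_in - rho_out) z_b(c)(t) +
#'  sqrt(1 - rho_in) e_c(t)` with a global factor `g`, one shared factor
#' `z_b` per block and channel noise `e_c`, all standard normal -- giving
#' exactly the target correlations in expectation.  The Gaussian values
#' are mapped to nonnegative receptor values by a soft floor
#' (`pmax(0, x + 3)`, later rescaled to `[0, 1]` by `/6`), which clips a
#' negligible tail (<0.2%) and so preserves the correlation structure.
#'
#' @param spec A [stream_spec()].
#' @return Matrix `duration x n_channels` of nonnegative receptor values
#'   in `[0, 1]`; attribute `"gauss"` holds the latent Gaussian stream.
#' @export
synth_receptor_stream <- function(spec) {
  stopifnot(inherits(spec, "stream_spec"))
  set.seed(spec$seed)
  n <- spec$duration; nc <- spec$n_channels
  nb <- max(spec$blocks)
  g <- rnorm(n)
  z <- matrix(rnorm(n * nb), n, nb)
  e <- matrix(rnorm(n * nc), n, nc)
  x <- sqrt(spec$rho_out) * g +
    sqrt(spec$rho_in - spec$rho_out) * z[, spec$blocks] +
    sqrt(1 - spec$rho_in) * e
  if (spec$noise_sd > 0) x <- x + rnorm(n * nc, 0, spec$noise_sd)
  out <- clip((x + 3) / 6, 0, 1)
  attr(out, "gauss") <- x
  attr(out, "blocks") <- spec$blocks
  out
}

#' Oscillatory multichannel test signals
#'
#' Sinusoids at a common frequency with specified fixed phase offsets plus
#' per-channel random-walk phase jitter -- fixtures for phase-locking
#' analyses.
#'
#' @param n Channels.
#' @param frequency Hz (> 0).
#' @param duration Seconds.
#' @param fs Sampling rate (Hz).
#' @param offsets Fixed phase offsets (rad), recycled to `n`.
#' @param jitter_sd Per-sample SD of each channel's phase random walk.
#' @param seed RNG seed.
#' @return Matrix `time x n`.
#' @export
synth_oscillatory_signals <- function(n = 2, frequency = 2, duration = 10,
                                      fs = 100, offsets = 0,
                                      jitter_sd = 0, seed = 1) {
  stopifnot(frequency > 0)
  set.seed(seed)
  nt <- round(duration * fs)
  t <- seq_len(nt) / fs
  offsets <- rep_len(offsets, n)
  sapply(seq_len(n), function(i) {
    jit <- if (jitter_sd > 0) cumsum(rnorm(nt, 0, jitter_sd)) else 0
    sin(2 * pi * frequency * t + offsets[i] + jit)
  })
}

#' Scripted (kinematic) fetus trajectory
#'
#' Interpolates joint-angle targets over time without dynamics and runs
#' the sensing pipeline on every frame -- used for probe movements (e.g.
#' an arm sweep in front of the eyes) and for constructing event-count
#' fixtures.
#'
#' @param body A fetus `body_spec`.
#' @param script Data frame with column `time` (strictly increasing, s)
#'   and one column per scripted joint (angle targets in rad); unscripted
#'   joints stay at rest (0).
#' @param env An `environment_spec` used by the sensing model.
#' @param control_dt Frame interval (s).
#' @param visual_on Render camera frames.
#' @return A `trajectory` object (kinematic: no energies/forces from
#'   dynamics; tactile from the static contact/self-touch model).
#' @export
scripted_trajectory <- function(body, script, env, control_dt = 0.01,
                                visual_on = FALSE) {
  stopifnot(body$type == "fetus", is.data.frame(script),
            "time" %in% names(script))
  if (nrow(script) > 1 && is.unsorted(script$time, strictly = TRUE))
    stop("script times must be strictly increasing")
  jn <- body$joints$name
  cols <- if (nrow(script) > 1) intersect(names(script), jn) else character(0)
  duration <- if (nrow(script)) max(script$time) else 0
  times <- seq(0, duration, by = control_dt)
  nj <- body$n_joints
  theta <- matrix(0, length(times), nj, dimnames = list(NULL, jn))
  for (cn in cols)
    theta[, cn] <- approx(script$time, script[[cn]], times, rule = 2)$y
  thdot <- rbind(0, diff(theta) / control_dt)
  st0 <- initial_state(body, env)
  ntx <- nrow(body$taxels)
  tactile <- matrix(0, length(times), ntx)
  tax_xr <- matrix(0, length(times), ntx)
  tax_yr <- matrix(0, length(times), ntx)
  sp_len <- matrix(0, length(times), body$n_actuators)
  sp_vel <- matrix(0, length(times), body$n_actuators)
  visual <- if (visual_on) vector("list", length(times)) else NULL
  states <- matrix(NA_real_, length(times), length(st0))
  for (k in seq_along(times)) {
    st <- st0
    st[7:(6 + nj)] <- theta[k, ]
    st[(7 + nj):(6 + 2 * nj)] <- thdot[k, ]
    states[k, ] <- st
    fr <- sense(body, st, env, visual_on = visual_on)
    tactile[k, ] <- fr$tactile
    sp_len[k, ] <- fr$spindle_length
    sp_vel[k, ] <- fr$spindle_velocity
    kin <- fetus_kinematics(st, body$cbody)
    tax_xr[k, ] <- kin$tax_x
    tax_yr[k, ] <- kin$tax_y
    if (visual_on) visual[[k]] <- fr$visual
  }
  traj <- list(type = "fetus", kinematic = TRUE, time = times,
               states = states, tactile = tactile,
               spindle_length = sp_len, spindle_velocity = sp_vel,
               visual = visual, tax_x = tax_xr, tax_y = tax_yr,
               taxel_every = 1, control_dt = control_dt, dt = control_dt,
               seed = NA, n_joints = nj, taxels = body$taxels,
               seg_radius = body$segments$radius[
                 match(body$taxels$segment, body$segments$name)],
               config_hash = rlang::hash(list(script, unclass(env))))
  class(traj) <- "trajectory"
  traj
}
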