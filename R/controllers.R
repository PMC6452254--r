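# Controller elements: chaotic quadratic maps and Bonhoeffer-van der Pol
# (FitzHugh-Nagumo) oscillators, plus the per-muscle spinal circuit wrapper.

#' One step of the quadratic (logistic-family) map
#'
#' Computes `f(x) = 1 - alpha * x^2`, the chaotic map used as the controller
#' element of each actuator's sensory--motor loop.  For `alpha` in `[0, 2]`
#' the map sends `[-1, 1]` into `[1 - alpha, 1]`, a subset of `[-1, 1]`, so
#' iterated dynamics stay bounded.  The map is chaotic (positive Lyapunov
#' exponent) above the band-merging onset near `alpha = 1.4011`.
#'
#' @param x Map state(s), each in `[-1, 1]`.
#' @param alpha Map parameter(s) in `[0, 2]`; recycled against `x`.
#' @return `1 - alpha * x^2`, elementwise.
#' @examples
#' logistic_step(0, 1.8)        # 1
#' logistic_step(0.1, 2)        # 0.98
#' @export
logistic_step <- function(x, alpha) {
  if (any(!is.finite(x)) || any(abs(x) > 1 + 1e-12))
    stop("map state out of range [-1, 1]: x = ", x[which.max(abs(x))])
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 2))
    stop("map parameter out of range [0, 2]: alpha = ",
         alpha[which(alpha < 0 | alpha > 2 | !is.finite(alpha))[1]])
  1 - alpha * pmin(x * x, 1)
}

#' Bank of chaotic map controller units
#'
#' Creates `n` chaotic units, one per actuator.  Each unit's effective input
#' is a convex combination of its sensor signal, its own previous output
#' (weak self feedback) and the mean previous output of all units (weak
#' input mixing); the unit output is one [logistic_step()] of that input.
#'
#' @param n Number of units (actuators).
#' @param alpha Map parameter, scalar or length-`n`.
#' @param eps_self Self-feedback weight in `[0, 1)`.
#' @param eps_mix Mean-field input-mixing weight in `[0, 1)`;
#'   `eps_self + eps_mix` must be `< 1`.
#' @param x0 Initial map states in `[-1, 1]`, scalar or length-`n`.
#' @return An object of class `"chaotic_controller"`.
#' @export
chaotic_controller <- function(n, alpha = 1.7, eps_self = 0.05,
                               eps_mix = 0.05, x0 = 0) {
  stopifnot(n >= 1)
  if (eps_self < 0 || eps_mix < 0 || eps_self >= 1 || eps_mix >= 1 ||
      eps_self + eps_mix >= 1)
    stop("coupling weights must satisfy 0 <= eps_self + eps_mix < 1 (got ",
         eps_self, " + ", eps_mix, ")")
  alpha <- rep_len(alpha, n)
  if (any(alpha < 0 | alpha > 2))
    stop("map parameter out of range [0, 2]: alpha = ",
         alpha[which(alpha < 0 | alpha > 2)[1]])
  x0 <- rep_len(x0, n)
  if (any(abs(x0) > 1)) stop("initial state out of range [-1, 1]")
  structure(list(n = n, alpha = alpha, eps_self = eps_self,
                 eps_mix = eps_mix, x = x0, u = x0),
            class = "chaotic_controller")
}

#' Advance a bank of chaotic controller units by one control tick
#'
#' @param ctrl A [chaotic_controller()].
#' @param s Sensor vector scaled to `[-1, 1]`, length `ctrl$n`.
#' @return The updated controller; motor outputs are in `$u` (all in
#'   `[-1, 1]`) and the effective inputs in `$x`.
#' @export
chaotic_controller_step <- function(ctrl, s) {
  stopifnot(inherits(ctrl, "chaotic_controller"))
  if (length(s) != ctrl$n)
    stop("sensor vector length ", length(s),
         " does not match unit count ", ctrl$n)
  s <- clip(s, -1, 1)
  eff <- (1 - ctrl$eps_self - ctrl$eps_mix) * s +
    ctrl$eps_self * ctrl$u + ctrl$eps_mix * mean(ctrl$u)
  ctrl$x <- eff
  ctrl$u <- logistic_step(eff, ctrl$alpha)
  ctrl
}

#' Bonhoeffer-van der Pol (FitzHugh-Nagumo) oscillator bank
#'
#' The classic two-variable excitable system
#' \deqn{dv/dt = c (v - v^3/3 - w + I), \quad dw/dt = (v + a - b w) / c}
#' with defaults `a = 0.7`, `b = 0.8`, `c = 3`.  At zero drive the system
#' has a unique stable resting point (`v \approx -1.199`); a constant
#' supra-threshold drive `I` puts it on a bounded limit cycle, the regime
#' used as a per-muscle central pattern generator.  `rate` rescales time so
#' one limit cycle spans a physiologically plausible movement period.
#'
#' @param n Number of oscillators.
#' @param a,b,c Standard BVP coefficients.
#' @param v0,w0 Initial state, scalar or length-`n` (defaults: resting point).
#' @param rate Time scale factor (model time units per second).
#' @return An object of class `"bvp_units"`.
#' @export
bvp_units <- function(n = 1, a = 0.7, b = 0.8, c = 3.0,
                      v0 = -1.19941, w0 = -0.62426, rate = 1) {
  stopifnot(n >= 1, rate > 0)
  structure(list(n = n, a = a, b = b, c = c,
                 v = rep_len(v0, n), w = rep_len(w0, n), rate = rate),
            class = "bvp_units")
}

#' Advance BVP oscillators one step (semi-implicit Euler)
#'
#' The fast variable is updated explicitly and the slow variable with the
#' already-updated fast value.  The fixed step must satisfy
#' `dt * rate * c < ~0.2` for stable integration at the default parameters;
#' the package-wide default `dt = 1e-3` s with `rate <= 20` is well inside
#' that bound.
#'
#' @param units A [bvp_units()] bank.
#' @param drive External drive, scalar or length-`n` (dimensionless).
#' @param dt Time step in seconds.
#' @param step_index Optional index reported in divergence errors.
#' @return Updated `bvp_units` object.
#' @export
bvp_step <- function(units, drive = 0, dt = 1e-3, step_index = NA) {
  stopifnot(inherits(units, "bvp_units"), dt > 0)
  h <- dt * units$rate
  v <- units$v + h * units$c * (units$v - units$v^3 / 3 - units$w + drive)
  w <- units$w + h * (v + units$a - units$b * units$w) / units$c
  if (any(!is.finite(v)) || any(!is.finite(w)))
    stop("BVP oscillator diverged",
         if (!is.na(step_index)) paste0(" at step ", step_index) else "")
  units$v <- v
  units$w <- w
  units
}

#' Run BVP oscillators for many steps
#'
#' @inheritParams bvp_step
#' @param n_steps Number of steps.
#' @param drive Scalar, length-`n`, or `n_steps x n` matrix of drives.
#' @return List with `units` (final state) and `v`, `w` trace matrices
#'   (`n_steps x n`).
#' @export
bvp_run <- function(units, drive = 0, dt = 1e-3, n_steps = 1000) {
  vs <- matrix(NA_real_, n_steps, units$n)
  ws <- matrix(NA_real_, n_steps, units$n)
  dmat <- if (is.matrix(drive)) drive else
    matrix(rep_len(drive, units$n), n_steps, units$n, byrow = TRUE)
  for (k in seq_len(n_steps)) {
    units <- bvp_step(units, dmat[k, ], dt, step_index = k)
    vs[k, ] <- units$v
    ws[k, ] <- units$w
  }
  list(units = units, v = vs, w = ws)
}

#' Spinal circuit units: one oscillator + motor neuron pool per muscle
#'
#' Each muscle has its own BVP oscillator (no cross-muscle connections);
#' muscle receptors feed back into the oscillator drive.  The gamma motor
#' neuron acts as a spindle-gain: spindle length and velocity afferents are
#' scaled by `gamma_mn` before entering the drive, while Golgi tendon
#' tension enters unscaled.  The alpha motor neuron activation is a clipped
#' linear squash of the oscillator's fast variable into `[0, 1]`.
#'
#' @param n_muscles Number of muscles (= number of spinal units).
#' @param base_drive Constant oscillator drive; the default 0.8 is
#'   supra-threshold, producing a limit cycle.
#' @param afferent_gain Receptor-to-oscillator feedback weight.
#' @param gamma_mn Spindle gain (>= 0).
#' @param c_len,c_vel,c_ten Mixing weights of normalized spindle length,
#'   spindle velocity and tendon tension in the afferent signal.
#' @param v_on,v_span Activation squash: `clip((v - v_on)/v_span, 0, 1)`.
#' @param rate Oscillator time scale (see [bvp_units()]); the default 4
#'   gives a limit-cycle period of roughly 2 s, in the range of slow fetal
#'   limb cycles.
#' @param v0,w0 Initial oscillator states (vectors allow desynchronized
#'   starts across muscles).
#' @return Object of class `"spinal_units"`.
#' @export
spinal_units <- function(n_muscles, base_drive = 0.8, afferent_gain = 0.3,
                         gamma_mn = 1, c_len = 0.5, c_vel = 0.3,
                         c_ten = 0.2, v_on = 0, v_span = 1.5, rate = 4,
                         v0 = -1.19941, w0 = -0.62426) {
  if (any(gamma_mn < 0)) stop("gamma_mn must be >= 0")
  structure(list(
    n = n_muscles,
    osc = bvp_units(n_muscles, v0 = v0, w0 = w0, rate = rate),
    base_drive = base_drive,
    afferent_gain = rep_len(afferent_gain, n_muscles),
    gamma_mn = rep_len(gamma_mn, n_muscles),
    c_len = c_len, c_vel = c_vel, c_ten = c_ten,
    v_on = v_on, v_span = v_span,
    activation = numeric(n_muscles)),
    class = "spinal_units")
}

#' Advance spinal units one step and read out muscle activations
#'
#' @param units A [spinal_units()] bank.
#' @param afferents List with numeric vectors `spindle_length`,
#'   `spindle_velocity`, `tendon_tension` (length `n`, normalized scales).
#' @param dt Time step (s).
#' @param extra_drive Additional oscillator drive (e.g. learned tactile
#'   drive), scalar or length-`n`.
#' @param step_index Optional index for divergence errors.
#' @return Updated `spinal_units`; activations in `$activation`, in `[0,1]`.
#' @export
spinal_step <- function(units, afferents, dt = 1e-3, extra_drive = 0,
                        step_index = NA) {
  stopifnot(inherits(units, "spinal_units"))
  af <- units$gamma_mn * (units$c_len * afferents$spindle_length +
                          units$c_vel * afferents$spindle_velocity) +
    units$c_ten * afferents$tendon_tension
  if (any(!is.finite(af))) stop("non-finite afferent input")
  drive <- units$base_drive + units$afferent_gain * af + extra_drive
  units$osc <- bvp_step(units$osc, drive, dt, step_index)
  units$activation <- clip((units$osc$v - units$v_on) / units$v_span, 0, 1)
  units
}

zero_afferents <- function(n) {
  list(spindle_length = numeric(n), spindle_velocity = numeric(n),
       tendon_tension = numeric(n))
}

#' Sample BVP states at random limit-cycle phases
#'
#' Integrates one oscillator to its attractor under the given drive and
#' samples `(v, w)` at `n` uniformly random phases of the cycle -- used to
#' desynchronize per-muscle oscillators at simulation start.
#'
#' @param n Number of states to sample.
#' @param drive Constant drive (supra-threshold for a cycle).
#' @param rate Oscillator time scale.
#' @param dt Integration step (s).
#' @return List with vectors `v`, `w`.
#' @export
bvp_phase_states <- function(n, drive = 0.8, rate = 4, dt = 1e-3) {
  u <- bvp_units(1, rate = rate)
  r <- bvp_run(u, drive, dt, n_steps = round(12 / rate / dt))
  v <- r$v[, 1]
  burn <- length(v) %/% 2
  idx <- burn + sample.int(length(v) - burn, n, replace = TRUE)
  list(v = v[idx], w = r$w[idx, 1])
}
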