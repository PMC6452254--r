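# Hebbian learning of full tactile -> motor connections: the closed-loop
# developmental mechanism. Many-to-many weights from skin taxels to the
# alpha motor neurons (W_alpha) and to the oscillator drives (W_osc), both
# trained by the same Oja-style normalized Hebb rule.

#' Spinal tactile-to-motor weight matrices
#'
#' @param n_taxels Number of tactile channels.
#' @param n_muscles Number of muscles.
#' @param w_max Upper weight bound.
#' @param gain Global tactile-to-alpha gain multiplier (>= 0); the quantity
#'   swept in the developmental gain experiment.
#' @param w0 Initial weight value (scalar or matrix).
#' @return Object of class `"spinal_weights"` with matrices `W_alpha` and
#'   `W_osc` (`n_taxels x n_muscles`), the `gain`, and a running tactile
#'   normalizer.
#' @export
spinal_weights <- function(n_taxels, n_muscles, w_max = 1, gain = 1,
                           w0 = 0.01) {
  stopifnot(n_taxels >= 1, n_muscles >= 1, w_max > 0, gain >= 0)
  W <- matrix(w0, n_taxels, n_muscles)
  structure(list(W_alpha = W, W_osc = W, w_max = w_max, gain = gain,
                 n_taxels = n_taxels, n_muscles = n_muscles,
                 tact_q = 1.0,               # running 95th-percentile scale
                 tact_mu = numeric(n_taxels), # per-taxel running mean
                 act_mu = numeric(n_muscles)),# per-muscle running mean
            class = "spinal_weights")
}

# update the running normalizers: a 95th-percentile force scale that
# rises quickly but decays very slowly (so a lull in movement cannot
# collapse the scale and blow up the normalized feedback), plus per-taxel
# and per-muscle running means used for phasic (mean-subtracted) coding
normalize_update <- function(weights, tactile, activation = NULL,
                             eta_up = 0.02, eta_down = 0.002,
                             eta_mu = 0.01) {
  q <- as.numeric(quantile(tactile, 0.95))
  if (q > 0) {
    eta <- if (q > weights$tact_q) eta_up else eta_down
    weights$tact_q <- (1 - eta) * weights$tact_q + eta * q
  }
  weights$tact_mu <- (1 - eta_mu) * weights$tact_mu + eta_mu * tactile
  if (!is.null(activation))
    weights$act_mu <- (1 - eta_mu) * weights$act_mu + eta_mu * activation
  weights
}

# phasic tactile: rectified deviation from the running mean, scaled into
# [0, 1] by the running force normalizer
normalize_tactile <- function(weights, tactile) {
  clip((tactile - weights$tact_mu) / max(weights$tact_q, 1e-9), 0, 1)
}

# phasic activation: rectified deviation from the running mean
phasic_activation <- function(weights, activation) {
  clip(activation - weights$act_mu, 0, 1)
}

#' Oja-style Hebbian update of the spinal weights
#'
#' `dW[i,j] = lr * post_j * (pre_i - post_j * W[i,j])`: the Hebbian
#' coincidence term with multiplicative decay that keeps each column's norm
#' bounded (the scalar fixed point for constant unit pre/post is `W = 1`).
#' Entries are clipped to `[0, w_max]`.  Both `W_alpha` and `W_osc` use the
#' same rule.
#'
#' @param weights A [spinal_weights()] object.
#' @param tactile Normalized tactile vector in `[0, 1]` (length `n_taxels`).
#' @param activations Per-muscle activations in `[0, 1]`.
#' @param lr Learning rate (> 0).
#' @return Updated `spinal_weights`.
#' @export
hebbian_update <- function(weights, tactile, activations, lr = 0.05) {
  stopifnot(inherits(weights, "spinal_weights"), lr > 0)
  if (length(tactile) != weights$n_taxels ||
      length(activations) != weights$n_muscles)
    stop("shape mismatch: tactile ", length(tactile), " x activations ",
         length(activations), ", weights ", weights$n_taxels, " x ",
         weights$n_muscles)
  oja <- function(W) {
    dW <- lr * (outer(tactile, activations) -
                  sweep(W, 2, activations^2, "*"))
    clip(W + dW, 0, weights$w_max)
  }
  weights$W_alpha <- oja(weights$W_alpha)
  weights$W_osc <- oja(weights$W_osc)
  weights
}

#' Learned tactile drive to the motor periphery
#'
#' Pre-squash drive is `gain * (tactile %*% W)`, exactly linear in
#' `gain`; with phasic (mean-subtracted, rectified) tactile input the
#' active set is sparse, which keeps the drive in the sensitive range of
#' the squash; the
#' output is squashed to `[0, 1]` with `tanh` before being summed with
#' the oscillator drive (`which = "osc"`) or added to the alpha motor
#' neuron activation (`which = "alpha"`).
#'
#' @param weights A [spinal_weights()] object.
#' @param tactile Normalized tactile vector.
#' @param which `"alpha"` or `"osc"`.
#' @param squash Apply the `tanh` squash? (`FALSE` returns the linear
#'   pre-squash drive.)
#' @return Per-muscle drive vector.
#' @export
spinal_drive <- function(weights, tactile, which = c("alpha", "osc"),
                         squash = TRUE) {
  which <- match.arg(which)
  if (length(tactile) != weights$n_taxels)
    stop("tactile length ", length(tactile), " does not match taxel count ",
         weights$n_taxels)
  W <- if (which == "alpha") weights$W_alpha else weights$W_osc
  pre <- weights$gain * as.numeric(tactile %*% W)
  if (squash) tanh(pre) else pre
}
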