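# Scaled-down spiking cortical sheet: LIF neurons on a unit square,
# distance-dependent random connectivity, 5:1 excitatory:inhibitory ratio,
# pair-based STDP on excitatory->excitatory synapses (recurrent and
# afferent).  Receptor channels are rate-coded into Poisson spike input.

default_lif <- function() {
  list(tau_m = 0.020, v_rest = -65, v_thresh = -50, v_reset = -65,
       refractory = 0.002, tau_syn_e = 0.005, tau_syn_i = 0.010)
}

default_stdp <- function() {
  list(A_plus = 4, A_minus = 4.4, tau_plus = 0.020,
       tau_minus = 0.020, w_max = 450,
       A_plus_in = 3, A_minus_in = 1.5, w_max_in = 500)
}

#' Build a cortical sheet
#'
#' Neurons are placed uniformly on the unit square; the left 70% of the
#' sheet is the somatosensory zone, the right 30% the visual zone.
#' Excitatory neurons outnumber inhibitory exactly 5:1; `n_neurons` is
#' rounded down to the nearest multiple of 6 to make the ratio exact.
#' Connection probability decays with sheet distance under a Gaussian
#' kernel (`connection_prob * exp(-d^2 / (2 radius^2))`) plus a small
#' uniform long-range probability `p_far` that provides cross-zone links.
#' Inhibitory outgoing weights are negative (Dale's principle); only
#' excitatory->excitatory synapses are plastic.
#'
#' @param n_neurons Requested neuron count (>= 120).
#' @param connection_radius Gaussian kernel radius on the unit sheet.
#' @param connection_prob Peak connection probability at distance 0.
#' @param seed RNG seed (placement and wiring are deterministic given it).
#' @param p_far Distance-independent connection probability.
#' @param w_exc Mean excitatory weight (synaptic current amplitude,
#'   voltage/s); weights are lognormal around it.
#' @param g_inh Inhibitory/excitatory weight ratio.
#' @param lif,stdp Parameter lists (see `default_lif`/`default_stdp`
#'   internals); any missing entries take the defaults.
#' @return A `cortex_net` object.
#' @export
build_cortex <- function(n_neurons = 1998, connection_radius = 0.08,
                         connection_prob = 0.5, seed = 1, p_far = 0.004,
                         w_exc = 150, g_inh = 4, lif = list(),
                         stdp = list()) {
  n <- 6L * (n_neurons %/% 6L)
  if (n < 120L)
    stop("cannot build a valid 5:1 E:I sheet with n_neurons = ", n_neurons,
         " (need >= 120)")
  set.seed(seed)
  n_inh <- n %/% 6L
  n_exc <- 5L * n_inh
  is_exc <- c(rep(TRUE, n_exc), rep(FALSE, n_inh))
  # interleave so E/I are spatially mixed
  ord <- sample.int(n)
  is_exc <- is_exc[ord]
  pos <- cbind(x = runif(n), y = runif(n))
  lifp <- utils::modifyList(default_lif(), lif)
  stdpp <- utils::modifyList(default_stdp(), stdp)

  # wiring in blocks to bound memory
  src <- dst <- integer(0)
  blk <- 4e6 %/% n + 1
  for (i0 in seq(1, n, by = blk)) {
    ii <- i0:min(i0 + blk - 1, n)
    d2 <- outer(pos[ii, 1], pos[, 1], "-")^2 +
      outer(pos[ii, 2], pos[, 2], "-")^2
    p <- connection_prob * exp(-d2 / (2 * connection_radius^2)) + p_far
    hit <- which(matrix(runif(length(p)), nrow(p)) < p, arr.ind = TRUE)
    keep <- (ii[hit[, 1]] != hit[, 2])   # no self-synapses
    src <- c(src, ii[hit[, 1]][keep])
    dst <- c(dst, hit[, 2][keep])
  }
  w <- ifelse(is_exc[src],
              pmin(stats::rlnorm(length(src), log(w_exc) - 0.125, 0.5),
                   stdpp$w_max),
              g_inh * w_exc)
  plastic <- is_exc[src] & is_exc[dst]
  # per-neuron excitability heterogeneity (lognormal background drive)
  drive_scale <- stats::rlnorm(n, -0.03125, 0.25)
  net <- structure(list(
    n = n, n_exc = n_exc, n_inh = n_inh, is_exc = is_exc, pos = pos,
    drive_scale = drive_scale,
    syn = data.frame(src = src, dst = dst, w = w, plastic = plastic),
    lif = lifp, stdp = stdpp, seed = seed,
    somato_frac = 0.7, input = NULL), class = "cortex_net")
  compile_cortex(net)
}

# CSR/CSC index arrays for the C++ engine
compile_cortex <- function(net) {
  n <- net$n
  s <- net$syn
  m <- nrow(s)
  oo <- order(s$src)
  out_ptr <- cumsum(c(0L, tabulate(s$src, n)))
  io <- order(s$dst)
  in_ptr <- cumsum(c(0L, tabulate(s$dst, n)))
  net$compiled <- list(
    out_ptr = as.integer(out_ptr), out_syn = as.integer(oo - 1L),
    syn_dst = as.integer(s$dst - 1L),
    in_ptr = as.integer(in_ptr), in_syn = as.integer(io - 1L),
    syn_src = as.integer(s$src - 1L),
    plastic = s$plastic)
  net
}

#' Attach receptor channels to the cortical sheet
#'
#' Builds the input map: every channel (tactile taxel, proprioceptive
#' muscle afferent, or visual pixel) projects to `k` target neurons.
#' Somatosensory channels of the same body part share a cluster centre in
#' the somatosensory zone and target excitatory neurons near it; visual
#' channels map retinotopically into the visual zone.
#'
#' Each channel also receives `k_far` weak "exuberant" targets sampled
#' uniformly over all excitatory neurons.  These diffuse afferents are
#' plastic like the local ones: activity whose correlation structure is
#' part-specific prunes them (depression dominates for uncorrelated
#' pre/post), while globally correlated activity strengthens them --
#' the substrate on which somatotopic refinement (or its failure)
#' happens, and the only anatomical route by which channels of one part
#' or modality can invade another's territory.
#'
#' @param net A `cortex_net`.
#' @param channels Data frame with columns `name`, `modality`
#'   (`"tactile"`, `"proprio"`, `"visual"`) and `part` (body-part label;
#'   for visual channels, the pixel index).
#' @param k Local (part-cluster) targets per channel.
#' @param sigma Spatial spread of each part's projection.
#' @param w_in Initial local afferent weight.
#' @param k_far Diffuse targets per channel.
#' @param w_far Initial diffuse afferent weight.
#' @param seed RNG seed.
#' @return The net with `$input` filled; errors if a channel set is empty.
#' @export
attach_inputs <- function(net, channels, k = 10, sigma = 0.05,
                          w_in = 70, k_far = 12, w_far = 70, seed = 1) {
  stopifnot(inherits(net, "cortex_net"), nrow(channels) > 0)
  set.seed(seed + 7L)
  sf <- net$somato_frac
  som <- channels$modality %in% c("tactile", "proprio")
  parts <- unique(channels$part[som])
  # part cluster centres on a grid in the somatosensory zone
  gp <- ceiling(sqrt(length(parts)))
  cx <- sf * (0.12 + 0.76 * ((seq_along(parts) - 1) %% gp) / max(gp - 1, 1))
  cy <- 0.12 + 0.76 * ((seq_along(parts) - 1) %/% gp) / max(gp - 1, 1)
  centres <- data.frame(part = parts, x = cx, y = cy)
  nvis <- sum(!som)
  exc <- which(net$is_exc)
  tgt <- vector("list", nrow(channels))
  wgt <- vector("list", nrow(channels))
  for (i in seq_len(nrow(channels))) {
    if (som[i]) {
      ci <- match(channels$part[i], centres$part)
      px <- centres$x[ci] + rnorm(1, 0, 0.01)
      py <- centres$y[ci] + rnorm(1, 0, 0.01)
    } else {
      j <- sum(!som[seq_len(i)])        # visual channel rank
      g <- ceiling(sqrt(nvis))
      px <- sf + (1 - sf) * (0.1 + 0.8 * ((j - 1) %% g) / max(g - 1, 1))
      py <- 0.1 + 0.8 * ((j - 1) %/% g) / max(g - 1, 1)
    }
    d2 <- (net$pos[, 1] - px)^2 + (net$pos[, 2] - py)^2
    pr <- exp(-d2[exc] / (2 * sigma^2))
    near <- exc[order(pr, decreasing = TRUE)[seq_len(k)]]
    far <- sample(setdiff(exc, near), k_far)
    tgt[[i]] <- c(near, far)
    wgt[[i]] <- c(rep(w_in, k), rep(w_far, k_far))
  }
  chan_ptr <- cumsum(c(0L, lengths(tgt)))
  chan_tgt <- unlist(tgt) - 1L
  nt <- length(chan_tgt)
  win <- unlist(wgt)
  win_plastic <- net$is_exc[chan_tgt + 1L]
  # per-neuron index of afferent synapses (for potentiation on post spike)
  chan_of <- rep(seq_len(nrow(channels)) - 1L, lengths(tgt))
  no <- order(chan_tgt)
  ntgt_ptr <- cumsum(c(0L, tabulate(chan_tgt + 1L, net$n)))
  net$input <- list(channels = channels, centres = centres,
                    chan_ptr = as.integer(chan_ptr),
                    chan_tgt = as.integer(chan_tgt),
                    w_in = win, win_plastic = win_plastic,
                    ntgt_ptr = as.integer(ntgt_ptr),
                    ntgt_idx = as.integer(no - 1L),
                    ntgt_chan = as.integer(chan_of[no]),
                    k = k)
  net
}

# low-level driver shared by resting / training / probing
cortex_engine <- function(net, rates, frame_steps, duration, dt = 1e-3,
                          stdp_on = FALSE, noise_rate = 150,
                          noise_amp = 600, seed = 1,
                          record_spikes = TRUE, vmean_every = 10,
                          i_const = NULL, norm_every = 0) {
  if (is.null(net$input)) {
    inp <- list(chan_ptr = 0L, chan_tgt = integer(0), w_in = numeric(0),
                win_plastic = logical(0), ntgt_ptr = integer(net$n + 1),
                ntgt_idx = integer(0), ntgt_chan = integer(0))
  } else inp <- net$input
  if (is.null(rates)) rates <- matrix(0, max(length(inp$chan_ptr) - 1, 1), 1)
  n_steps <- round(duration / dt)
  cortex_run_cpp(net$n, net$is_exc,
                 net$compiled$out_ptr, net$compiled$out_syn,
                 net$compiled$syn_dst,
                 net$compiled$in_ptr, net$compiled$in_syn,
                 net$compiled$syn_src,
                 net$syn$w, net$compiled$plastic,
                 inp$chan_ptr, inp$chan_tgt, inp$w_in, inp$win_plastic,
                 inp$ntgt_ptr, inp$ntgt_idx, inp$ntgt_chan,
                 rates, as.integer(frame_steps),
                 net$lif, net$stdp, stdp_on,
                 noise_rate,
                 noise_amp * (net$drive_scale %||% rep(1, net$n)),
                 i_const %||% numeric(net$n),
                 as.integer(n_steps), dt, as.integer(seed),
                 record_spikes, as.integer(vmean_every),
                 as.integer(norm_every))
}

#' One LIF network step (reference implementation)
#'
#' Explicit membrane update `dV = dt * ((v_rest - V)/tau_m + I_syn + I)`;
#' threshold crossings emit spikes, reset the membrane and start the
#' refractory period; synaptic currents decay exponentially.  This is the
#' single-step reference used in unit tests; long simulations run in the
#' compiled engine with identical update equations.
#'
#' @param net A `cortex_net`.
#' @param state List with `V`, `ge`, `gi`, `refr` (or `NULL` to start at
#'   rest).
#' @param input Per-neuron external current (voltage/s).
#' @param dt Time step (s), at most 1 ms.
#' @return List with `state` and integer vector `fired`.
#' @export
lif_step <- function(net, state = NULL, input = 0, dt = 1e-3) {
  stopifnot(dt <= 1e-3 + 1e-12)
  p <- net$lif
  if (is.null(state))
    state <- list(V = rep(p$v_rest, net$n), ge = numeric(net$n),
                  gi = numeric(net$n), refr = integer(net$n))
  input <- rep_len(input, net$n)
  state$ge <- state$ge * exp(-dt / p$tau_syn_e)
  state$gi <- state$gi * exp(-dt / p$tau_syn_i)
  active <- state$refr <= 0
  state$refr <- pmax(state$refr - 1L, 0L)
  V <- state$V
  V[active] <- V[active] + dt * ((p$v_rest - V[active]) / p$tau_m +
                                   state$ge[active] - state$gi[active] +
                                   input[active])
  if (any(!is.finite(V))) stop("membrane potential diverged")
  fired <- which(V >= p$v_thresh & active)
  V[fired] <- p$v_reset
  state$refr[fired] <- as.integer(round(p$refractory / dt))
  state$V <- V
  for (f in fired) {
    ks <- which(net$syn$src == f)
    for (k in ks) {
      if (net$is_exc[f]) state$ge[net$syn$dst[k]] <-
          state$ge[net$syn$dst[k]] + net$syn$w[k]
      else state$gi[net$syn$dst[k]] <- state$gi[net$syn$dst[k]] +
          net$syn$w[k]
    }
  }
  list(state = state, fired = fired)
}

#' Pair-based STDP weight change for one synapse
#'
#' Evaluates the standard additive pair rule with exponential traces over
#' explicit pre/post spike time lists: each post spike potentiates by
#' `A_plus * sum(exp(-(t_post - t_pre)/tau_plus))` over earlier pre spikes,
#' each pre spike depresses by `A_minus * sum(exp(-(t_pre - t_post)/
#' tau_minus))` over earlier post spikes.
#'
#' @param pre_times,post_times Spike times (s), sorted.
#' @param stdp STDP parameter list (defaults as in [build_cortex()]).
#' @return Net weight change (unclipped).
#' @export
stdp_pair_delta <- function(pre_times, post_times, stdp = default_stdp()) {
  dw <- 0
  for (tp in post_times) {
    dt_ <- tp - pre_times[pre_times < tp]
    dw <- dw + stdp$A_plus * sum(exp(-dt_ / stdp$tau_plus))
  }
  for (tq in pre_times) {
    dt_ <- tq - post_times[post_times < tq]
    dw <- dw - stdp$A_minus * sum(exp(-dt_ / stdp$tau_minus))
  }
  dw
}

#' Resting-state run
#'
#' Drives the sheet with background Poisson noise only and collects
#' resting-state statistics: per-neuron rates, excitatory/inhibitory
#' population rates, and mean membrane depolarization relative to rest.
#' A silent network is flagged as degenerate rather than an error.
#'
#' @param net A `cortex_net`.
#' @param duration Seconds (>= 10 recommended for stable statistics).
#' @param noise_rate Background input rate per neuron (Hz).
#' @param noise_amp Background synaptic amplitude.
#' @param seed RNG seed.
#' @return List with `rates`, `rate_exc`, `rate_inh`, `mean_depol`,
#'   `degenerate`, `spikes` (data frame), `v_mean` trace.
#' @export
run_resting <- function(net, duration = 10, noise_rate = 150,
                        noise_amp = 600, seed = 1) {
  res <- cortex_engine(net, NULL, 1L, duration, stdp_on = FALSE,
                       noise_rate = noise_rate, noise_amp = noise_amp,
                       seed = seed)
  degen <- res$n_spikes == 0
  list(rates = res$rates,
       rate_exc = mean(res$rates[net$is_exc]),
       rate_inh = mean(res$rates[!net$is_exc]),
       mean_depol = mean(res$v_mean) - net$lif$v_rest,
       degenerate = degen,
       spikes = data.frame(t = res$spike_t, id = res$spike_id + 1L),
       v_mean = res$v_mean)
}

#' Train the cortex on a receptor stream
#'
#' Receptor values (normalized to `[0, 1]`) become inhomogeneous Poisson
#' input spike rates (`rate = r_max * value`); STDP is active on all
#' excitatory->excitatory synapses (recurrent and afferent).
#'
#' @param net A `cortex_net` with inputs attached.
#' @param stream Matrix `frames x channels`, values in `[0, 1]` (clipped),
#'   columns matching `net$input$channels` order.
#' @param frame_dt Seconds per stream frame.
#' @param r_max Peak input rate (Hz).
#' @param seed RNG seed.
#' @param dt Engine step (s).
#' @param noise_rate,noise_amp Background drive.
#' @return The trained net; `$learning_log` holds total spike count and
#'   mean absolute weight change of recurrent and afferent weights.
#' @export
train_on_stream <- function(net, stream, frame_dt = 0.01, r_max = 100,
                            seed = 1, dt = 1e-3, noise_rate = 150,
                            noise_amp = 600) {
  if (is.null(net$input))
    stop("no input map attached; call attach_inputs() first")
  if (ncol(stream) != nrow(net$input$channels))
    stop("stream has ", ncol(stream), " channels but the input map has ",
         nrow(net$input$channels))
  rates <- t(clip(stream, 0, 1)) * r_max
  frame_steps <- max(1L, round(frame_dt / dt))
  duration <- nrow(stream) * frame_dt
  w0 <- net$syn$w
  win0 <- net$input$w_in
  res <- cortex_engine(net, rates, frame_steps, duration, dt = dt,
                       stdp_on = TRUE, noise_rate = noise_rate,
                       noise_amp = noise_amp, seed = seed,
                       record_spikes = FALSE, vmean_every = 0L)
  net$syn$w <- res$w
  net$input$w_in <- res$w_in
  net$learning_log <- list(n_spikes = res$n_spikes,
                           mean_dw = mean(abs(res$w - w0)),
                           mean_dwin = mean(abs(res$w_in - win0)))
  net
}

#' Probe the cortex with a channel subset
#'
#' Each trial is a baseline window with background noise only followed by
#' a stimulation window in which the selected channels fire Poisson spikes
#' at `amplitude * r_max`.  The response is the per-neuron evoked minus
#' baseline spike count, converted to spikes/s and averaged over trials.
#'
#' @param net A `cortex_net` with inputs attached.
#' @param channels Integer indices (into `net$input$channels`) to
#'   stimulate; must be non-empty.
#' @param amplitude Stimulus amplitude in `[0, 1]` units of `r_max`.
#' @param n_trials Number of trials (>= 5).
#' @param seed RNG seed.
#' @param window Seconds per (baseline or evoked) window.
#' @param r_max Peak rate (Hz).
#' @param noise_rate,noise_amp Background drive.
#' @param label Stimulus label stored in the map.
#' @return A `response_map`: `response` (spikes/s per neuron), `label`,
#'   probe metadata.
#' @export
stimulate_probe <- function(net, channels, amplitude = 1, n_trials = 5,
                            seed = 1, window = 0.15, r_max = 100,
                            noise_rate = 150, noise_amp = 600,
                            label = "probe") {
  if (length(channels) == 0) stop("empty channel set")
  if (n_trials < 5) stop("n_trials must be >= 5")
  nchan <- nrow(net$input$channels)
  nframes <- 2L * n_trials
  rates <- matrix(0, nchan, nframes)
  rates[channels, seq(2, nframes, by = 2)] <- amplitude * r_max
  dt <- 1e-3
  frame_steps <- round(window / dt)
  res <- cortex_engine(net, rates, frame_steps, nframes * window, dt = dt,
                       stdp_on = FALSE, noise_rate = noise_rate,
                       noise_amp = noise_amp, seed = seed,
                       record_spikes = TRUE, vmean_every = 0L)
  frame_of <- pmin(floor(res$spike_t / window), nframes - 1)
  evoked <- frame_of %% 2 == 1
  cnt_e <- tabulate(res$spike_id[evoked] + 1L, net$n)
  cnt_b <- tabulate(res$spike_id[!evoked] + 1L, net$n)
  structure(list(label = label,
                 response = (cnt_e - cnt_b) / (n_trials * window),
                 amplitude = amplitude, n_trials = n_trials,
                 window = window, seed = seed),
            class = "response_map")
}

#' @export
print.cortex_net <- function(x, ...) {
  cat("<cortex_net>", x$n, "neurons (", x$n_exc, "E /", x$n_inh, "I ),",
      nrow(x$syn), "synapses,",
      if (is.null(x$input)) "no inputs" else
        paste(nrow(x$input$channels), "input channels"), "\n")
  invisible(x)
}
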