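# End-to-end experiment drivers: insect locomotion emergence, wall
# adaptation, intrauterine-vs-extrauterine body-map learning, multimodal
# integration, and closed-loop spinal development.  All condition
# contrasts use paired seeds.

#' Body-part label of every taxel
#'
#' Groups taxels into the six body parts used for correlation analyses and
#' cortical probing: left/right arm, left/right leg, head, trunk.
#'
#' @param body A fetus `body_spec`.
#' @return Character vector, one label per taxel.
#' @export
taxel_parts <- function(body) {
  seg <- body$taxels$segment
  ifelse(grepl("arm|hand", seg) & grepl("_L", seg), "armL",
  ifelse(grepl("arm|hand", seg) & grepl("_R", seg), "armR",
  ifelse(grepl("thigh|shank", seg) & grepl("_L", seg), "legL",
  ifelse(grepl("thigh|shank", seg) & grepl("_R", seg), "legR",
  ifelse(seg == "head", "head", "trunk")))))
}

muscle_parts <- function(body) {
  jn <- body$joints$name[body$muscles$joint]
  ifelse(grepl("shoulder|elbow", jn) & grepl("_L", jn), "armL",
  ifelse(grepl("shoulder|elbow", jn) & grepl("_R", jn), "armR",
  ifelse(grepl("hip|knee", jn) & grepl("_L", jn), "legL",
  ifelse(grepl("hip|knee", jn) & grepl("_R", jn), "legR",
  ifelse(jn == "neck", "head", "trunk")))))
}

#' Receptor channel table for a fetus body
#'
#' One tactile channel per taxel, one proprioceptive channel per muscle,
#' and optionally one visual channel per camera pixel (two 16x16 eyes).
#'
#' @param body A fetus `body_spec`.
#' @param visual Include visual channels?
#' @return Data frame `name`, `modality`, `part` for [attach_inputs()].
#' @export
receptor_channels <- function(body, visual = FALSE) {
  ch <- rbind(
    data.frame(name = paste0("tax_", body$taxels$id), modality = "tactile",
               part = taxel_parts(body), stringsAsFactors = FALSE),
    data.frame(name = paste0("mus_", seq_len(body$n_actuators)),
               modality = "proprio", part = muscle_parts(body),
               stringsAsFactors = FALSE))
  if (visual) {
    px <- expand.grid(eye = c("L", "R"), i = 1:16, j = 1:16)
    ch <- rbind(ch, data.frame(
      name = paste0("vis_", px$eye, "_", px$i, "_", px$j),
      modality = "visual", part = paste0("eye", px$eye),
      stringsAsFactors = FALSE))
  }
  ch
}

#' Convert a trajectory into a normalized receptor stream
#'
#' Columns follow [receptor_channels()] order: tactile, proprioceptive
#' spindle length and, if recorded, visual pixels.  Every channel is
#' passed through a phasic-adaptation high-pass (rectified deviation from
#' an exponential running mean with time constant `adapt_tau`), modelling
#' receptor adaptation: the cortex is driven by changes in receptor
#' activity, not by tonic levels.  Channels are then scaled by their
#' joint 95th percentile into `[0, 1]`.
#'
#' @param traj A fetus `trajectory`.
#' @param visual Include visual columns (requires frames recorded).
#' @param adapt_tau Adaptation time constant (s).
#' @return Matrix `frames x channels` in `[0, 1]`.
#' @export
trajectory_stream <- function(traj, visual = FALSE, adapt_tau = 1.5) {
  highpass <- function(X) {
    a <- exp(-traj$control_dt / adapt_tau)
    mu <- matrix(0, nrow(X), ncol(X))
    m <- X[1, ]
    for (k in seq_len(nrow(X))) {
      m <- a * m + (1 - a) * X[k, ]
      mu[k, ] <- m
    }
    pmax(X - mu, 0)
  }
  scale95 <- function(X) {
    q <- quantile(X[X > 0], 0.95, na.rm = TRUE)
    if (!is.finite(q) || q <= 0) q <- 1
    clip(X / q, 0, 1)
  }
  tact <- scale95(highpass(traj$tactile))
  prop <- scale95(highpass(clip((traj$spindle_length + 1.5) / 3, 0, 1)))
  out <- cbind(tact, prop)
  if (visual) {
    if (is.null(traj$visual) || is.null(traj$visual[[1]]))
      stop("trajectory has no visual frames")
    vis <- t(vapply(traj$visual,
                    function(v) c(as.numeric(v$left), as.numeric(v$right)),
                    numeric(512)))
    out <- cbind(out, scale95(highpass(vis)))
  }
  out
}

new_report <- function(experiment, config, seeds, per_seed, summary,
                       verdicts) {
  structure(list(
    experiment = experiment, config = config,
    config_hash = config_hash(config), seeds = seeds,
    per_seed = per_seed, summary = summary, verdicts = verdicts,
    provenance = list(
      package_version = as.character(utils::packageVersion("embodysim")),
      timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
    class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>", x$experiment, "| seeds:",
      paste(x$seeds, collapse = ","), "\n")
  for (nm in names(x$summary))
    cat("  ", nm, "=",
        paste(signif(unlist(x$summary[[nm]]), 4), collapse = " "), "\n")
  for (nm in names(x$verdicts))
    cat("  [", if (isTRUE(x$verdicts[[nm]])) "PASS" else "FAIL", "]",
        nm, "\n")
  invisible(x)
}

#' Write an experiment report to JSON (and metrics to CSV)
#'
#' @param report An `experiment_report`.
#' @param dir Output directory.
#' @return Directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    report[c("experiment", "config_hash", "seeds", "summary", "verdicts",
             "provenance")],
    file.path(dir, paste0(report$experiment, ".json")),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

# default insect controller for a given seed: heterogeneous map parameters
# inside the chaotic band, weak self-feedback and mixing
default_insect_controller <- function(n_legs = 12, seed = 1) {
  set.seed(seed * 100 + 17)
  chaotic_controller(n_legs, alpha = runif(n_legs, 1.55, 1.85),
                     eps_self = 0.05, eps_mix = 0.02)
}

# first time the sliding-window PLV is high and flat for k windows
plv_stable_time <- function(pl, control_dt, k = 3, sd_thresh = 0.06,
                            min_plv = 0.6, after = 0) {
  t <- pl$index * control_dt
  ok <- which(t > after)
  for (i in ok) {
    if (i + k - 1 > nrow(pl)) break
    seg <- pl$plv[i:(i + k - 1)]
    if (all(is.finite(seg)) && mean(seg) > min_plv && sd(seg) < sd_thresh)
      return(t[i])
  }
  NA_real_
}

#' Insect locomotion emergence experiment
#'
#' Runs the 12-legged robot with the chaotic-map controller on an open
#' plane for each seed, and measures net displacement of the body centre
#' (the passive baseline is exactly zero: with a zero controller no force
#' is ever generated) and the time for the inter-leg phase-locking value
#' to reach a stable epoch.
#'
#' @param seeds Integer seeds.
#' @param duration Simulated seconds per seed.
#' @param control_dt Control tick (s); 0.1 s is the insect default.
#' @param config Optional overrides: `n_legs`, `K`, `tau_max`,
#'   `alpha` (vector), `arena_half`.
#' @param min_displacement Displacement (m) counted as locomotion.
#' @param transient_budget Stable-PLV deadline (s).
#' @return An `experiment_report`.
#' @export
run_insect_locomotion <- function(seeds = 1:5, duration = 30,
                                  control_dt = 0.1, config = list(),
                                  min_displacement = 0.1,
                                  transient_budget = 10) {
  n_legs <- config$n_legs %||% 12
  body <- build_insect_body(n_legs = n_legs, K = config$K %||% 0.08,
                            tau_max = config$tau_max %||% 0.12)
  env <- environment_spec("walled_arena",
                          arena_half = config$arena_half %||% Inf)
  per_seed <- lapply(seeds, function(s) {
    ctrl <- if (!is.null(config$alpha))
      chaotic_controller(n_legs, alpha = config$alpha,
                         eps_self = 0.05, eps_mix = 0.02)
    else default_insect_controller(n_legs, s)
    tr <- simulate_embodied(body, env, ctrl, duration = duration,
                            control_dt = control_dt, seed = s)
    xy <- tr$states[, 1:2]
    disp <- sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
    w <- round(2 / control_dt)
    pl <- plv_timecourse(tr$u, window = w, step = w %/% 2)
    list(seed = s, displacement = disp,
         plv = pl$plv,
         stable_time = plv_stable_time(pl, control_dt),
         trajectory_range = range(xy))
  })
  disp <- vapply(per_seed, `[[`, numeric(1), "displacement")
  stab <- vapply(per_seed, `[[`, numeric(1), "stable_time")
  ok <- disp > min_displacement & !is.na(stab) & stab <= transient_budget
  report <- new_report(
    "insect_locomotion",
    list(duration = duration, control_dt = control_dt, config = config),
    seeds,
    per_seed,
    summary = list(displacement = disp, stable_time = stab,
                   n_locomoting = sum(ok)),
    verdicts = list(
      majority_locomote_with_fast_transient = sum(ok) >= length(seeds) / 2,
      displacement_above_passive_baseline = all(disp > 0)))
  report
}

# mean direction of motion over a tick index window
heading_of <- function(xy, idx) {
  d <- colSums(diff(xy[idx, , drop = FALSE]))
  atan2(d[2], d[1])
}

angle_diff <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d) * 180 / pi
}

#' Wall adaptation experiment
#'
#' The locomoting robot is placed in a walled square arena.  At the first
#' wall contact the inter-leg phase pattern is perturbed; the experiment
#' measures the drop and re-stabilization of the sliding-window PLV
#' (re-entrainment time from contact until the PLV regains its
#' pre-contact criterion) and the change of locomotion heading.
#'
#' @param seeds Integer seeds.
#' @param duration Simulated seconds.
#' @param arena_half Arena half-width (m).
#' @param control_dt Control tick (s).
#' @param heading_threshold Degrees counted as adaptation.
#' @return An `experiment_report`; per-seed `re_entrainment` (s) and
#'   `heading_change` (deg); seeds that never reach a wall are flagged
#'   inconclusive.
#' @export
run_wall_adaptation <- function(seeds = 1:8, duration = 90,
                                arena_half = 0.6, control_dt = 0.1,
                                heading_threshold = 45) {
  body <- build_insect_body()
  env <- environment_spec("walled_arena", arena_half = arena_half)
  w <- round(2 / control_dt)
  per_seed <- lapply(seeds, function(s) {
    ctrl <- default_insect_controller(12, s)
    tr <- simulate_embodied(body, env, ctrl, duration = duration,
                            control_dt = control_dt, seed = s)
    hit <- which(tr$wall_contact & tr$time > 2)
    if (!length(hit))
      return(list(seed = s, inconclusive = TRUE))
    tc <- tr$time[hit[1]]
    ic <- hit[1]
    pl <- plv_timecourse(tr$u, window = w, step = w %/% 2)
    tw <- pl$index * control_dt
    pre <- pl$plv[tw < tc & tw > tc - 5]
    post <- which(tw > tc)
    crit <- quantile(pre, 0.25, na.rm = TRUE)
    dip <- min(pl$plv[tw >= tc - 1 & tw <= tc + 2], na.rm = TRUE)
    re <- NA_real_
    for (i in post) {
      if (i + 1 > nrow(pl)) break
      if (all(pl$plv[i:(i + 1)] >= crit)) { re <- tw[i] - tc; break }
    }
    xy <- tr$states[, 1:2]
    nb <- max(1, ic - round(3 / control_dt)):max(1, ic - 2)
    h_pre <- heading_of(xy, nb)
    na <- min(nrow(xy), ic + round(2 / control_dt)):
      min(nrow(xy), ic + round(8 / control_dt))
    h_post <- heading_of(xy, na)
    list(seed = s, inconclusive = FALSE, contact_time = tc,
         plv_pre = mean(pre, na.rm = TRUE), plv_dip = dip,
         re_entrainment = re,
         heading_change = angle_diff(h_pre, h_post))
  })
  concl <- Filter(function(p) !isTRUE(p$inconclusive), per_seed)
  hc <- vapply(concl, `[[`, numeric(1), "heading_change")
  re <- vapply(concl, `[[`, numeric(1), "re_entrainment")
  dip <- vapply(concl, function(p) p$plv_pre - p$plv_dip, numeric(1))
  adapting <- hc > heading_threshold & !is.na(re)
  report <- new_report(
    "wall_adaptation",
    list(duration = duration, arena_half = arena_half,
         control_dt = control_dt), seeds, per_seed,
    summary = list(
      n_conclusive = length(concl), n_adapting = sum(adapting),
      heading_change = hc, re_entrainment = re, plv_drop = dip,
      median_re_entrainment = median(re[adapting], na.rm = TRUE)),
    verdicts = list(
      majority_adapt = sum(adapting) > length(concl) / 2,
      plv_drops_at_contact = mean(dip > 0, na.rm = TRUE) > 0.5))
  report
}

# shared helper: one developmental learning run -> trained cortex
grow_and_train <- function(condition, seed, body, duration, train_frac = 1,
                           n_neurons = 1998, visual = TRUE,
                           lif = list(), stdp = list()) {
  env <- if (condition == "intrauterine")
    environment_spec("uterus_fluid", radius = fit_uterus(body))
  else environment_spec("flat_plane")
  tr <- simulate_embodied(body, env, spinal_units(body$n_actuators),
                          duration = duration, seed = seed,
                          visual_on = visual, record_taxels = FALSE)
  ch <- receptor_channels(body, visual = visual)
  net <- build_cortex(n_neurons, seed = seed, lif = lif, stdp = stdp)
  net <- attach_inputs(net, ch, seed = seed)
  stream <- trajectory_stream(tr, visual = visual)
  nf <- round(nrow(stream) * train_frac)
  net <- train_on_stream(net, stream[seq_len(nf), , drop = FALSE],
                         frame_dt = tr$control_dt, seed = seed)
  list(net = net, trajectory = tr, env = env, channels = ch)
}

probe_parts <- function(net, body, parts = c("armL", "armR", "legL",
                                             "legR", "head", "trunk"),
                        seed = 1, amplitude = 0.8) {
  tp <- taxel_parts(body)
  maps <- lapply(parts, function(p) {
    chans <- which(net$input$channels$modality == "tactile" &
                     net$input$channels$part == p)
    stimulate_probe(net, chans, amplitude = amplitude, n_trials = 5,
                    seed = seed, label = p)
  })
  names(maps) <- parts
  maps
}

#' Body-map acquisition experiment (intrauterine vs. extrauterine)
#'
#' For each seed, a fetus body moves spontaneously under its spinal
#' oscillators in the uterus and, with identical initialization, on the
#' flat plane; the cortex (same seed, identical initial network) learns
#' each receptor stream; every body part is then probed and the
#' segregation index of the response maps compared between conditions.
#' A receptor-correlation precheck verifies the environmental mechanism:
#' within-part tactile correlation is higher in fluid, cross-part
#' correlation higher on the plane.
#'
#' @param seeds Integer seeds (>= 10 for the paired test).
#' @param duration Movement/learning session length (s).
#' @param n_neurons Cortex size.
#' @param taxel_count Taxels on the body.
#' @param visual Record/learn visual channels too (needed if the trained
#'   nets feed the multimodal experiment).
#' @param return_nets Keep the trained networks in the report (large).
#' @return An `experiment_report`; `summary$p_value` is the one-sided
#'   paired test for segregation(intra) > segregation(extra).
#' @export
run_bodymap_experiment <- function(seeds = 1:10, duration = 100,
                                   n_neurons = 1998, taxel_count = 300,
                                   visual = FALSE, return_nets = FALSE) {
  body <- build_fetus_body(32, "humanlike", taxel_count)
  parts6 <- taxel_parts(body)
  per_seed <- lapply(seeds, function(s) {
    res <- lapply(c("intrauterine", "extrauterine"), function(cond) {
      gt <- grow_and_train(cond, s, body, duration, visual = visual)
      maps <- probe_parts(gt$net, body, seed = s)
      # precheck correlations on the phasic stream the cortex receives;
      # "within-limb" is computed over the four limbs (the trunk's lying
      # contact on the plane is a different mechanism)
      X <- trajectory_stream(gt$trajectory)[, seq_len(nrow(body$taxels))]
      keep <- apply(X, 2, sd) > 1e-9
      C <- cor(X[, keep]); p <- parts6[keep]
      same <- outer(p, p, "=="); diag(C) <- NA
      limb <- p %in% c("armL", "armR", "legL", "legR")
      limb2 <- outer(limb, limb, "&")
      list(seg = segregation_index(maps)$value,
           within = mean(C[same & limb2], na.rm = TRUE),
           between = mean(C[!same], na.rm = TRUE),
           net = if (return_nets) gt$net)
    })
    names(res) <- c("intra", "extra")
    res
  })
  seg_i <- vapply(per_seed, function(p) p$intra$seg, numeric(1))
  seg_e <- vapply(per_seed, function(p) p$extra$seg, numeric(1))
  wi <- vapply(per_seed, function(p) p$intra$within, numeric(1))
  we <- vapply(per_seed, function(p) p$extra$within, numeric(1))
  bi <- vapply(per_seed, function(p) p$intra$between, numeric(1))
  be <- vapply(per_seed, function(p) p$extra$between, numeric(1))
  pv <- tryCatch(t.test(seg_i, seg_e, paired = TRUE,
                        alternative = "greater")$p.value,
                 error = function(e) NA_real_)
  new_report(
    "bodymap",
    list(duration = duration, n_neurons = n_neurons,
         taxel_count = taxel_count, visual = visual),
    seeds, per_seed,
    summary = list(segregation_intra = seg_i, segregation_extra = seg_e,
                   p_value = pv,
                   within_corr_intra = wi, within_corr_extra = we,
                   between_corr_intra = bi, between_corr_extra = be),
    verdicts = list(
      intra_more_segregated = isTRUE(pv < 0.05),
      within_corr_higher_in_fluid =
        isTRUE(t.test(wi, we, paired = TRUE,
                      alternative = "greater")$p.value < 0.05),
      between_corr_higher_on_plane =
        isTRUE(t.test(be, bi, paired = TRUE,
                      alternative = "greater")$p.value < 0.05)))
}

# scripted arm sweep passing the right hand in front of the eyes
arm_sweep_script <- function(duration = 20, cycles = 5) {
  t <- seq(0, duration, length.out = 80)
  data.frame(time = t,
             shoulder_R = 0.45 * sin(2 * pi * cycles * t / duration),
             elbow_R = 0.35 * sin(2 * pi * cycles * t / duration + pi / 3))
}

#' Multimodal integration experiment
#'
#' Cortices trained under the two conditions are "transplanted" onto
#' identical 40-week bodies lying on the flat plane (taxel layout is
#' preserved, so channels remap one-to-one).  A scripted arm movement in
#' front of the eyes generates synchronized visual, tactile and
#' proprioceptive input; each cortex is probed with the combined stimulus
#' and with each modality alone, and the multimodal indices are compared
#' by sign test across seeds.
#'
#' @param seeds Integer seeds.
#' @param duration Learning session length (s) for the pre-training runs.
#' @param n_neurons Cortex size.
#' @param trained Optional list of per-seed `list(intra = net, extra =
#'   net)` (e.g. from [run_bodymap_experiment()] with `visual = TRUE` and
#'   `return_nets = TRUE`); if `NULL`, training runs are performed here.
#' @return An `experiment_report`.
#' @export
run_multimodal_experiment <- function(seeds = 1:10, duration = 100,
                                      n_neurons = 1998, trained = NULL) {
  body32 <- build_fetus_body(32, "humanlike", 300)
  body40 <- build_fetus_body(40, "humanlike", 300)
  envp <- environment_spec("flat_plane")
  script <- arm_sweep_script()
  probe_traj <- scripted_trajectory(body40, script, envp,
                                    control_dt = 0.05, visual_on = TRUE)
  stream <- trajectory_stream(probe_traj, visual = TRUE)
  ch <- receptor_channels(body40, visual = TRUE)
  act <- colMeans(stream)
  mod <- ch$modality
  sets <- list(
    visual = which(mod == "visual" & act > 0.02),
    tactile = which(mod == "tactile" & act > 0.05 &
                      ch$part %in% c("armR", "head")),
    proprio = which(mod == "proprio" & act > 0.05 &
                      ch$part %in% c("armR")))
  sets <- Filter(length, sets)
  per_seed <- lapply(seq_along(seeds), function(i) {
    s <- seeds[i]
    nets <- if (!is.null(trained)) trained[[i]] else {
      list(intra = grow_and_train("intrauterine", s, body32, duration,
                                  n_neurons = n_neurons)$net,
           extra = grow_and_train("extrauterine", s, body32, duration,
                                  n_neurons = n_neurons)$net)
    }
    idx <- lapply(nets, function(net) {
      uni <- lapply(sets, function(cs)
        stimulate_probe(net, cs, amplitude = 0.8, n_trials = 5, seed = s))
      comb <- stimulate_probe(net, unlist(sets), amplitude = 0.8,
                              n_trials = 5, seed = s)
      multimodal_index(comb, uni)
    })
    list(seed = s, intra = idx$intra, extra = idx$extra)
  })
  mi <- vapply(per_seed, `[[`, numeric(1), "intra")
  me <- vapply(per_seed, `[[`, numeric(1), "extra")
  wins <- sum(mi > me)
  pv <- tryCatch(binom.test(wins, length(seeds),
                            alternative = "greater")$p.value,
                 error = function(e) NA_real_)
  new_report(
    "multimodal",
    list(duration = duration, n_neurons = n_neurons), seeds, per_seed,
    summary = list(index_intra = mi, index_extra = me, wins = wins,
                   p_value = pv),
    verdicts = list(intra_stronger_multimodal = wins > length(seeds) / 2))
}

#' Closed-loop spinal development experiment
#'
#' The fetus moves in the uterus while Hebbian tactile-to-motor learning
#' is active.  The driver measures time courses of jerky-movement events
#' and hand--face contact events, their onset times relative to the early
#' baseline, and compares the human-like against the uniform taxel
#' distribution across a gain sweep.
#'
#' @param taxel_distribution `"humanlike"` or `"uniform"`.
#' @param gains Tactile-to-alpha gain multipliers to sweep.
#' @param seeds Integer seeds.
#' @param duration Total simulated seconds (baseline is the first
#'   `baseline` seconds, while learned weights are still near zero).
#' @param baseline Baseline period (s).
#' @param lr Hebbian learning rate per 10 ms tick.
#' @param window Rate window (s).
#' @param jerk_threshold Angular acceleration threshold (rad/s^2).
#' @return An `experiment_report`.
#' @export
run_closedloop_development <- function(taxel_distribution = "humanlike",
                                       gains = c(1, 2, 3), seeds = 1:5,
                                       duration = 250, baseline = 40,
                                       lr = 1e-3, window = 25,
                                       jerk_threshold = 60) {
  body <- build_fetus_body(32, taxel_distribution, 300)
  env <- environment_spec("uterus_fluid", radius = fit_uterus(body))
  # "firm" hand-face touch: skin surfaces compressed to 60% of the
  # combined segment radii, separating genuine touches from grazes
  rad <- body$segments$radius
  d_firm <- 0.6 * (rad[match("forearm_hand_L", body$segments$name)] +
                     rad[match("head", body$segments$name)])
  nj <- body$n_joints
  per_run <- list()
  for (g in gains) for (s in seeds) {
    W <- spinal_weights(nrow(body$taxels), body$n_actuators, gain = g)
    tr <- simulate_embodied(body, env,
                            spinal_units(body$n_actuators,
                                         base_drive = 0.55),
                            duration = duration, seed = s,
                            plasticity = W, lr = lr,
                            fb_warmup = baseline)
    th <- tr$states[, 7:(6 + nj)]
    jk <- jerk_event_rate(th, tr$control_dt, jerk_threshold)
    ct <- contact_event_rate(tr, "hand", "face", d_touch = d_firm,
                             debounce = 1)
    rj <- rate_timecourse(jk$onsets, duration, window)
    rc <- rate_timecourse(ct$onsets, duration, window)
    # baseline: pre-feedback windows, skipping the start-up transient
    bidx <- which(rj$time > window / 2 & rj$time < baseline + window)
    if (length(bidx) < 2) bidx <- seq_len(max(2, length(bidx)))
    oj <- onset_time(rj$rate, rj$time, bidx, k = 1.5, m = 2)
    oc <- onset_time(rc$rate, rc$time, bidx, k = 1.5, m = 2)
    base_j <- mean(rj$rate[bidx]); late_j <- mean(tail(rj$rate, 3))
    base_c <- mean(rc$rate[bidx]); late_c <- mean(tail(rc$rate, 3))
    per_run[[length(per_run) + 1]] <- list(
      gain = g, seed = s, jerk_onset = oj, contact_onset = oc,
      jerk_rise = late_j - base_j, contact_rise = late_c - base_c,
      jerk_rate = rj, contact_rate = rc,
      final_mean_w = mean(tr$plasticity$W_alpha))
  }
  gvec <- vapply(per_run, `[[`, numeric(1), "gain")
  oj <- vapply(per_run, `[[`, numeric(1), "jerk_onset")
  oc <- vapply(per_run, `[[`, numeric(1), "contact_onset")
  order_ok <- vapply(seq_along(per_run), function(i) {
    if (is.na(oj[i])) return(FALSE)
    is.na(oc[i]) || oj[i] < oc[i]   # contact may rise after the window
  }, logical(1))
  ordering_by_gain <- vapply(gains, function(g)
    mean(order_ok[gvec == g]) > 0.5, logical(1))
  new_report(
    "closedloop_development",
    list(taxel_distribution = taxel_distribution, gains = gains,
         duration = duration, baseline = baseline, lr = lr,
         jerk_threshold = jerk_threshold), seeds, per_run,
    summary = list(
      jerk_onset = oj, contact_onset = oc,
      jerk_rise = vapply(per_run, `[[`, numeric(1), "jerk_rise"),
      contact_rise = vapply(per_run, `[[`, numeric(1), "contact_rise"),
      ordering_by_gain = setNames(as.list(ordering_by_gain),
                                  paste0("gain_", gains))),
    verdicts = list(
      jerk_before_contact_all_gains = all(ordering_by_gain),
      rates_increase = mean(vapply(per_run, `[[`, numeric(1),
                                   "jerk_rise") > 0) > 0.5))
}
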