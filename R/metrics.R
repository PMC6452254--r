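# Analysis statistics: Lyapunov exponents of the controller map, phase
# synchronization, detrended fluctuation analysis, movement event rates,
# and cortical response indices.

#' Largest Lyapunov exponent of the quadratic map
#'
#' Orbit average of `ln|f'(x)| = ln|-2 alpha x|` along the iterated map
#' `f(x) = 1 - alpha x^2` after a burn-in.  Visits within `eps` of the
#' critical point `x = 0` are clamped to `eps` so a superstable orbit
#' cannot produce `-Inf` (documented guard).  At `alpha = 2` the map is
#' conjugate to the tent map and the exponent is `ln 2`.
#'
#' @param alpha Map parameter in `(0, 2]`.
#' @param n_iter Orbit length used for the average (>= 1e4).
#' @param burn_in Discarded initial iterates (>= 1e3).
#' @param x0 Initial state.
#' @param eps Guard radius around `x = 0`.
#' @return Exponent in nats per iteration.
#' @export
largest_lyapunov_map <- function(alpha, n_iter = 1e6, burn_in = 1e3,
                                 x0 = 0.1, eps = 1e-12) {
  stopifnot(alpha > 0, alpha <= 2, n_iter >= 1e4, burn_in >= 1e3)
  cpp_logistic_lyap(alpha, x0, as.integer(n_iter), as.integer(burn_in), eps)
}

#' Chaos onset of the quadratic map by bisection
#'
#' Bisects on the sign of [largest_lyapunov_map()] over an interval
#' assumed to bracket the transition to chaos, returning the boundary
#' parameter.
#'
#' @param lo,hi Bracket (exponent must be `<= 0` at `lo`, `> 0` at `hi`).
#' @param tol Bisection tolerance on alpha.
#' @param n_iter,burn_in,x0 Passed to [largest_lyapunov_map()].
#' @return The boundary alpha.
#' @export
chaos_onset_alpha <- function(lo = 1.3, hi = 1.5, tol = 1e-3,
                              n_iter = 1e6, burn_in = 1e3, x0 = 0.1) {
  f <- function(a) largest_lyapunov_map(a, n_iter, burn_in, x0)
  if (f(lo) > 0 || f(hi) <= 0)
    stop("bracket [", lo, ", ", hi, "] does not straddle the chaos onset")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# discrete analytic signal (FFT construction); returns complex series
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x - mean(x))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# instantaneous phase by linear interpolation between upward zero crossings
zerocross_phase <- function(x) {
  xc <- x - mean(x)
  up <- which(xc[-length(xc)] < 0 & xc[-1] >= 0)
  if (length(up) < 3) return(rep(NA_real_, length(x)))
  ph <- rep(NA_real_, length(x))
  for (k in seq_len(length(up) - 1)) {
    i0 <- up[k]; i1 <- up[k + 1]
    ph[i0:i1] <- 2 * pi * (k - 1 + (seq(i0, i1) - i0) / (i1 - i0))
  }
  ph
}

#' Pairwise phase-locking values
#'
#' For each channel pair, `PLV = |mean(exp(1i * (phi_a - phi_b)))|` with
#' instantaneous phases from the analytic signal (default) or an
#' upward-zero-crossing interpolation.  Invariant to constant phase
#' offsets; the matrix is symmetric with unit diagonal.  A (near-)constant
#' channel has undefined phase: its pairs are flagged `NA`.
#'
#' @param signals Matrix, time x channels (>= 2 channels).
#' @param method `"analytic"` or `"zerocross"`.
#' @return Symmetric matrix of PLVs in `[0, 1]` (NA where undefined).
#' @export
phase_sync_matrix <- function(signals, method = c("analytic", "zerocross")) {
  method <- match.arg(method)
  signals <- as.matrix(signals)
  stopifnot(ncol(signals) >= 2)
  constant <- apply(signals, 2, function(v) sd(v) < 1e-12)
  ph <- apply(signals, 2, function(v) {
    if (sd(v) < 1e-12) return(rep(NA_real_, length(v)))
    if (method == "analytic") Arg(analytic_signal(v)) else zerocross_phase(v)
  })
  nc <- ncol(signals)
  out <- matrix(NA_real_, nc, nc)
  diag(out) <- 1
  for (a in seq_len(nc - 1)) for (b in (a + 1):nc) {
    if (constant[a] || constant[b]) next
    dp <- ph[, a] - ph[, b]
    dp <- dp[is.finite(dp)]
    if (!length(dp)) next
    out[a, b] <- out[b, a] <- Mod(mean(exp(1i * dp)))
  }
  out
}

#' Sliding-window mean phase-locking value
#'
#' Mean off-diagonal PLV of a multichannel signal in sliding windows; the
#' package's summary of inter-leg (or inter-muscle) coordination over time.
#'
#' @param signals Time x channels matrix.
#' @param window Window length in samples.
#' @param step Hop in samples.
#' @param method Phase method, see [phase_sync_matrix()].
#' @return Data frame with window-centre `index` and `plv`.
#' @export
plv_timecourse <- function(signals, window, step = window %/% 2,
                           method = "analytic") {
  n <- nrow(signals)
  starts <- seq(1, n - window + 1, by = step)
  plv <- vapply(starts, function(s) {
    m <- phase_sync_matrix(signals[s:(s + window - 1), , drop = FALSE],
                           method = method)
    mean(m[upper.tri(m)], na.rm = TRUE)
  }, numeric(1))
  data.frame(index = starts + window / 2, plv = plv)
}

#' Detrended fluctuation analysis exponent
#'
#' First-order DFA: the series is integrated, divided into windows of
#' varying size, linearly detrended per window, and the RMS fluctuation
#' regressed on window size in log-log space.  White noise gives 0.5,
#' a random walk 1.5.
#'
#' @param series Numeric series (length >= 1024).
#' @param windows Integer window sizes (>= 4 distinct values).
#' @return List with `alpha` (slope), `log_n`, `log_f`, and `degenerate`
#'   flag (constant input).
#' @export
dfa_exponent <- function(series,
                         windows = unique(round(2^seq(2, log2(length(series) / 4),
                                                      length.out = 12)))) {
  stopifnot(length(series) >= 1024)
  if (length(windows) < 4) stop("need at least 4 window sizes")
  if (sd(series) < 1e-14)
    return(list(alpha = NA_real_, degenerate = TRUE))
  y <- cumsum(series - mean(series))
  fl <- vapply(windows, function(w) {
    nw <- length(y) %/% w
    idx <- seq_len(nw * w)
    seg <- matrix(y[idx], w, nw)
    t <- seq_len(w)
    X <- cbind(1, t)
    resid <- seg - X %*% qr.solve(X, seg)
    sqrt(mean(resid^2))
  }, numeric(1))
  fit <- lm(log(fl) ~ log(windows))
  list(alpha = unname(coef(fit)[2]), log_n = log(windows), log_f = log(fl),
       degenerate = FALSE)
}

#' Jerk (high acceleration--deceleration) event rate
#'
#' Counts intervals in which the angular acceleration magnitude of any
#' joint crosses the threshold upward and returns below it within
#' `max_dur` seconds, i.e. brief acceleration--deceleration bursts.
#'
#' @param theta Matrix of joint angles, time x joints (rad).
#' @param dt Sampling interval (s).
#' @param threshold Acceleration threshold (rad/s^2, > 0).
#' @param max_dur Maximal burst duration (s).
#' @return List with `rate` (events per minute over the whole series),
#'   `n_events`, and `onsets` (event start times in s, all joints pooled);
#'   use [rate_timecourse()] for a windowed series.
#' @export
jerk_event_rate <- function(theta, dt, threshold, max_dur = 0.5) {
  stopifnot(threshold > 0, dt > 0)
  theta <- as.matrix(theta)
  if (nrow(theta) < 3)
    return(list(rate = 0, n_events = 0, onsets = numeric(0)))
  acc <- abs(diff(theta, differences = 2)) / dt^2
  maxlen <- max_dur / dt
  onsets <- numeric(0)
  for (j in seq_len(ncol(acc))) {
    above <- acc[, j] > threshold
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    ok <- which(r$values & r$lengths <= maxlen)
    # a complete burst crosses up and back down within the series
    ok <- ok[ends[ok] < length(above)]
    onsets <- c(onsets, starts[ok] * dt)
  }
  onsets <- sort(onsets)
  list(rate = length(onsets) / (nrow(theta) * dt / 60),
       n_events = length(onsets), onsets = onsets)
}

#' Contact event rate between two taxel regions
#'
#' A contact event is the onset of taxel--taxel proximity (below
#' `d_touch`) between any region-A taxel and any region-B taxel, debounced
#' by a refractory time.
#'
#' Taxels sit on segment centrelines, so the touch threshold should be
#' about the sum of the two segment radii (skin surfaces meeting); pass
#' `d_touch = NULL` (default) to derive it that way from the trajectory's
#' taxel table, plus a 1 cm skin tolerance window.
#'
#' @param traj A fetus `trajectory` (taxel positions recorded).
#' @param regionA,regionB Region tags from the fixed vocabulary.
#' @param d_touch Contact distance threshold (m), or `NULL` to derive
#'   from segment radii.
#' @param debounce Refractory time between counted events (s).
#' @return List with `rate` (events per minute), `n_events`, `onsets`
#'   (times in s).
#' @export
contact_event_rate <- function(traj, regionA = "hand", regionB = "face",
                               d_touch = NULL, debounce = 0.5) {
  if (!regionA %in% TAXEL_REGIONS || !regionB %in% TAXEL_REGIONS)
    stop("unknown region tag: ", regionA, "/", regionB)
  ia <- which(traj$taxels$region == regionA)
  ib <- which(traj$taxels$region == regionB)
  if (is.null(d_touch)) {
    rad <- traj$seg_radius
    d_touch <- if (is.null(rad)) 0.05 else
      max(rad[ia], 0) + max(rad[ib], 0)
  }
  dt_rec <- traj$control_dt * traj$taxel_every
  nrec <- nrow(traj$tax_x)
  if (!length(ia) || !length(ib) || nrec < 2)
    return(list(rate = 0, n_events = 0, onsets = numeric(0)))
  touching <- vapply(seq_len(nrec), function(k) {
    dx <- outer(traj$tax_x[k, ia], traj$tax_x[k, ib], "-")
    dy <- outer(traj$tax_y[k, ia], traj$tax_y[k, ib], "-")
    any(dx^2 + dy^2 < d_touch^2)
  }, logical(1))
  onset_idx <- which(diff(c(FALSE, touching)) == 1)
  onsets <- (onset_idx - 1) * dt_rec
  if (length(onsets) > 1) {
    keep <- c(TRUE, diff(onsets) > debounce)
    onsets <- onsets[keep]
  }
  dur_min <- (nrec - 1) * dt_rec / 60
  list(rate = length(onsets) / dur_min, n_events = length(onsets),
       onsets = onsets)
}

#' Segregation index of body-part response maps
#'
#' `1 - mean` pairwise cosine similarity of the nonnegative-rectified
#' response vectors: 1 for orthogonal (perfectly segregated) maps, 0 for
#' identical maps.  All-zero maps are excluded pair-wise and reported.
#'
#' @param maps List of `response_map`s (or plain numeric vectors), one per
#'   body part; >= 2, equal lengths.
#' @return List (class `segregation_score`) with `value`, the pairwise
#'   cosine `overlap` matrix, `parts`, and `excluded` pairs.
#' @export
segregation_index <- function(maps) {
  stopifnot(length(maps) >= 2)
  vecs <- lapply(maps, function(m)
    pmax(if (inherits(m, "response_map")) m$response else m, 0))
  stopifnot(length(unique(lengths(vecs))) == 1)
  parts <- names(maps) %||% paste0("part", seq_along(maps))
  k <- length(vecs)
  ov <- matrix(NA_real_, k, k, dimnames = list(parts, parts))
  diag(ov) <- 1
  excluded <- character(0)
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    na <- sqrt(sum(vecs[[a]]^2)); nb <- sqrt(sum(vecs[[b]]^2))
    if (na == 0 || nb == 0) {
      excluded <- c(excluded, paste(parts[a], parts[b], sep = "~"))
      next
    }
    ov[a, b] <- ov[b, a] <- sum(vecs[[a]] * vecs[[b]]) / (na * nb)
  }
  off <- ov[upper.tri(ov)]
  structure(list(value = 1 - mean(off, na.rm = TRUE), overlap = ov,
                 parts = parts, excluded = excluded),
            class = "segregation_score")
}

#' Multimodal integration index
#'
#' Ratio of the norm of the response to a combined (multi-modality)
#' stimulus to the sum of the norms of the unimodal responses; values
#' above the additive baseline indicate superadditive integration.
#'
#' @param combined Response to the combined stimulus (`response_map` or
#'   vector).
#' @param unimodal List of unimodal responses.
#' @return Scalar index; `NA` with a warning if all unimodal norms are 0.
#' @export
multimodal_index <- function(combined, unimodal) {
  getv <- function(m) pmax(if (inherits(m, "response_map")) m$response
                           else m, 0)
  cn <- sqrt(sum(getv(combined)^2))
  un <- sum(vapply(unimodal, function(m) sqrt(sum(getv(m)^2)), numeric(1)))
  if (un == 0) {
    warning("all unimodal responses are zero; index undefined")
    return(NA_real_)
  }
  cn / un
}

#' Onset time of a sustained rate increase
#'
#' First time a windowed rate exceeds `baseline mean + k * SD` for `m`
#' consecutive windows.
#'
#' @param rate Numeric series of windowed rates.
#' @param times Times of the windows (s).
#' @param baseline_idx Indices of the baseline windows.
#' @param k SD multiplier (default 2).
#' @param m Consecutive windows required (default 3).
#' @return Onset time in seconds, or `NA` ("no onset").
#' @export
onset_time <- function(rate, times, baseline_idx, k = 2, m = 3) {
  stopifnot(length(rate) == length(times), length(baseline_idx) >= 2)
  mu <- mean(rate[baseline_idx]); s <- sd(rate[baseline_idx])
  thr <- mu + k * max(s, 1e-12)
  above <- rate > thr
  above[baseline_idx] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= m)
  if (!length(hit)) return(NA_real_)
  times[ends[hit[1]] - r$lengths[hit[1]] + 1]
}

#' Windowed event-rate time course
#'
#' Helper converting event times into a rate series on regular windows.
#'
#' @param event_times Event times (s).
#' @param duration Total duration (s).
#' @param window Window length (s).
#' @return Data frame `time` (window centre), `rate` (events/min).
#' @export
rate_timecourse <- function(event_times, duration, window) {
  breaks <- seq(0, duration, by = window)
  if (length(breaks) < 2) return(data.frame(time = numeric(0),
                                            rate = numeric(0)))
  cnt <- graphics::hist(event_times[event_times >= 0 &
                                      event_times <= duration],
                        breaks = breaks, plot = FALSE)$counts
  data.frame(time = breaks[-length(breaks)] + window / 2,
             rate = cnt / (window / 60))
}

#' @export
print.segregation_score <- function(x, ...) {
  cat("<segregation_score>", round(x$value, 4), "over",
      length(x$parts), "parts\n")
  invisible(x)
}
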