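#' Action-potential detection criteria
#'
#' The threshold criterion is a fixed rate of depolarization: an AP is
#' scored where dV/dt first crosses `dVdt_threshold` upward ahead of a peak
#' exceeding `min_peak`, with successive events separated by at least
#' `refractory`. Defaults: 10 mV/ms, 0 mV, 2 ms, no smoothing at 50 kHz.
#' An alternative threshold definition (maximum of the second derivative)
#' is available via `method = "d2v"`.
#'
#' @param dVdt_threshold threshold rate of rise, mV/ms
#' @param min_peak minimum peak voltage for a spike, mV
#' @param refractory minimum event separation, ms
#' @param smooth_ms moving-average window applied before differentiation
#'   (0 = none)
#' @param method `"dvdt"` (interpolated dV/dt criterion crossing, default)
#'   or `"d2v"` (maximum curvature before the peak)
#' @return a `detection_criteria` list
#' @export
detection_criteria <- function(dVdt_threshold = 10, min_peak = 0,
                               refractory = 2, smooth_ms = 0,
                               method = c("dvdt", "d2v")) {
  method <- match.arg(method)
  if (dVdt_threshold <= 0 || refractory <= 0 || smooth_ms < 0)
    stop("detection criteria must be positive (smoothing may be 0)")
  structure(list(dVdt_threshold = dVdt_threshold, min_peak = min_peak,
                 refractory = refractory, smooth_ms = smooth_ms,
                 method = method),
            class = "detection_criteria")
}

#' Detect action potentials in a current-clamp sweep
#'
#' Finds every AP as an upward dV/dt criterion crossing followed by a
#' voltage peak above `min_peak`. The threshold time is sub-sample
#' interpolated on the dV/dt trace and the threshold voltage is the
#' membrane potential interpolated at that instant. Events closer than the
#' refractory period to the previous accepted event are merged into it.
#'
#' @param sweep a current-clamp [new_sweep] sampled at >= 10 kHz
#' @param criteria a [detection_criteria]
#' @return data.frame with one row per AP: `threshold_time`,
#'   `threshold_voltage`, `peak_time`, `peak_voltage`, `max_dVdt`
#'   (times ms, voltages mV), ordered by `threshold_time`
#' @export
detect_aps <- function(sweep, criteria = detection_criteria()) {
  stopifnot(inherits(sweep, "sweep"))
  if (sweep$clamp_mode != "current")
    stop("AP detection requires a current-clamp sweep")
  if (sweep$sampling_rate < 10000)
    stop("sampling rate must be >= 10 kHz")
  v <- sweep$recorded
  dt <- 1000 / sweep$sampling_rate
  if (criteria$smooth_ms > 0) {
    w <- max(1L, round(criteria$smooth_ms / dt))
    if (w > 1L) v <- stats::filter(v, rep(1 / w, w), sides = 2)
    v[is.na(v)] <- sweep$recorded[is.na(v)]
    v <- as.numeric(v)
  }
  n <- length(v)
  t <- (seq_len(n) - 1) * dt
  # forward difference; dv[i] is the slope on [t[i], t[i+1])
  dv <- diff(v) / dt

  empty <- data.frame(threshold_time = numeric(0),
                      threshold_voltage = numeric(0),
                      peak_time = numeric(0), peak_voltage = numeric(0),
                      max_dVdt = numeric(0))

  # candidate peaks: local maxima above min_peak
  pk <- which(v[-c(1, n)] > v[-c(n - 1, n)] & v[-c(1, n)] >= v[-c(1, 2)]) + 1L
  pk <- pk[v[pk] >= criteria$min_peak]
  if (!length(pk)) return(empty)

  thr <- criteria$dVdt_threshold
  events <- empty
  last_time <- -Inf
  prev_peak_idx <- 1L
  for (p in pk) {
    # refractory: peaks within the refractory period extend the last event
    if (t[p] - last_time < criteria$refractory) {
      if (nrow(events) && v[p] > events$peak_voltage[nrow(events)]) {
        events$peak_voltage[nrow(events)] <- v[p]
        events$peak_time[nrow(events)] <- t[p]
        last_time <- t[p]
      }
      next
    }
    # walk back from the peak: skip the low-slope shoulder at the top, then
    # the high-slope rising phase; the criterion crossing sits at its foot
    j <- p - 1L
    while (j >= prev_peak_idx && dv[j] < thr) j <- j - 1L
    if (j < prev_peak_idx || dv[j] < thr) next  # never reached criterion
    i <- j
    while (i >= 1L && i >= prev_peak_idx && dv[i] >= thr) i <- i - 1L
    if (i >= 1L && dv[i] < thr) {
      # crossing between slope samples i and i+1 (slopes at interval starts)
      frac <- if (dv[i + 1L] == dv[i]) 0 else (thr - dv[i]) / (dv[i + 1L] - dv[i])
      frac <- min(max(frac, 0), 1)
      t_thr <- t[i] + frac * dt
      v_thr <- v[i] + frac * (v[i + 1L] - v[i])
      mx <- max(dv[(i + 1L):(p - 1L)])
    } else {
      t_thr <- t[i + 1L]; v_thr <- v[i + 1L]
      mx <- max(dv[max(i + 1L, 1L):(p - 1L)])
    }
    events <- rbind(events, data.frame(
      threshold_time = t_thr, threshold_voltage = v_thr,
      peak_time = t[p], peak_voltage = v[p],
      max_dVdt = mx))
    last_time <- t[p]
    prev_peak_idx <- p
  }
  if (criteria$method == "d2v" && nrow(events)) {
    # curvature-maximum alternative: within each rising phase take the
    # sample of maximum second derivative below the dV/dt crossing
    d2 <- diff(dv) / dt
    for (r in seq_len(nrow(events))) {
      i0 <- max(1L, floor(events$threshold_time[r] / dt) - 50L)
      i1 <- max(i0 + 1L, floor(events$threshold_time[r] / dt))
      j <- i0 + which.max(d2[i0:i1]) - 1L
      events$threshold_time[r] <- t[j + 1L]
      events$threshold_voltage[r] <- v[j + 1L]
    }
  }
  events[order(events$threshold_time), , drop = FALSE]
}

# linear-interpolated time at which v crosses `level`, searching from index
# i0 to i1; direction +1 upward, -1 downward; returns NA if never crossed
cross_time <- function(t, v, level, i0, i1, direction) {
  idx <- i0:(i1 - 1L)
  if (direction > 0) hit <- which(v[idx] < level & v[idx + 1L] >= level)
  else hit <- which(v[idx] > level & v[idx + 1L] <= level)
  if (!length(hit)) return(NA_real_)
  i <- idx[hit[1L]]
  t[i] + (level - v[i]) / (v[i + 1L] - v[i]) * (t[i + 1L] - t[i])
}

#' Measure the waveform of one action potential
#'
#' All level-crossing times are obtained by linear interpolation between
#' samples. Amplitude is threshold-to-peak; overshoot is 0 mV-to-peak; rise
#' is the 10-90% time of the rising phase, fall the 90-10% time of the
#' falling phase, and half-width the time between the 50% crossings of the
#' two phases. The 10/50/90% levels are referenced to amplitude
#' (threshold-to-peak) on both phases.
#'
#' @param sweep the current-clamp [new_sweep] containing the event
#' @param event one row of [detect_aps] output
#' @param next_event_time threshold time of the following event (bounds the
#'   falling phase); `Inf` if none
#' @param shoulder_cut score cut-off for the shoulder flag. The score is the
#'   fraction of the 90-10% falling segment spent below a quarter of its
#'   peak repolarization rate (0 for a linear fall); it is exploratory,
#'   while fall time and half-width are the quantitative surface.
#' @return one-row data.frame: `amplitude`, `overshoot`, `rise`, `fall`,
#'   `half_width`, `shoulder_score`, `shoulder_flag`, `partial` (fall
#'   truncated by sweep end or next event; durations NA in that case)
#' @export
measure_ap <- function(sweep, event, next_event_time = Inf,
                       shoulder_cut = 0.56) {
  stopifnot(inherits(sweep, "sweep"))
  v <- sweep$recorded
  dt <- 1000 / sweep$sampling_rate
  n <- length(v)
  t <- (seq_len(n) - 1) * dt

  thr_v <- event$threshold_voltage
  amp <- event$peak_voltage - thr_v
  if (amp <= 0) stop("event has non-positive amplitude")
  lev <- thr_v + c(0.10, 0.50, 0.90) * amp

  i_thr <- max(1L, floor(event$threshold_time / dt))
  i_pk <- round(event$peak_time / dt) + 1L
  i_end <- if (is.finite(next_event_time)) min(n, floor(next_event_time / dt) + 1L) else n

  r10 <- cross_time(t, v, lev[1], i_thr, i_pk, +1)
  r50 <- cross_time(t, v, lev[2], i_thr, i_pk, +1)
  r90 <- cross_time(t, v, lev[3], i_thr, i_pk, +1)
  f90 <- cross_time(t, v, lev[3], i_pk, i_end, -1)
  f50 <- if (!is.na(f90)) cross_time(t, v, lev[2], i_pk, i_end, -1) else NA_real_
  f10 <- if (!is.na(f50)) cross_time(t, v, lev[1], i_pk, i_end, -1) else NA_real_

  partial <- anyNA(c(r10, r50, r90, f90, f50, f10))
  rise <- if (is.na(r10) || is.na(r90)) NA_real_ else r90 - r10
  fall <- if (is.na(f90) || is.na(f10)) NA_real_ else f10 - f90
  half <- if (is.na(r50) || is.na(f50)) NA_real_ else f50 - r50

  # shoulder: a sustained slowing of the falling limb between the 90% and
  # 10% levels. Scored as the fraction of that segment spent below a
  # quarter of the segment's peak repolarization rate: 0 for a linear fall
  # (constant rate), near 0 for a smooth spike, large when an inflection
  # plateau stretches the descent
  score <- 0
  if (!partial) {
    j0 <- max(1L, ceiling(f90 / dt) + 1L)
    j1 <- min(n - 1L, floor(f10 / dt) + 1L)
    if (j1 - j0 >= 4L) {
      seg <- abs(diff(v)[j0:(j1 - 1L)] / dt)
      env <- max(seg)
      if (env > 0) score <- mean(seg < 0.25 * env)
    }
  }

  data.frame(amplitude = amp, overshoot = event$peak_voltage,
             rise = rise, fall = fall, half_width = half,
             shoulder_score = score, shoulder_flag = score >= shoulder_cut,
             partial = partial)
}

#' Waveform of the first AP at rheobase
#'
#' The paper-standard AP for waveform comparisons: the first event on the
#' first step sweep that evoked any AP. Non-responders yield an explicit
#' absent result (`NULL`), never a silent drop.
#'
#' @param family list of current-clamp sweeps ordered by amplitude
#' @param rheo a `rheobase_result` from [rheobase_from_family]
#' @param criteria a [detection_criteria]
#' @return [measure_ap] row for the first rheobase event, or `NULL` for a
#'   non-responder
#' @export
first_ap_at_rheobase <- function(family, rheo,
                                 criteria = detection_criteria()) {
  if (!isTRUE(rheo$responder)) return(NULL)
  sw <- family[[rheo$sweep_number]]
  ev <- detect_aps(sw, criteria)
  if (!nrow(ev)) stop("rheobase sweep has no detectable AP on re-analysis")
  nxt <- if (nrow(ev) > 1) ev$threshold_time[2] else Inf
  measure_ap(sw, ev[1, ], next_event_time = nxt)
}
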