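#' @useDynLib drgephys, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

CC_FAMILIES <- c("cc_ramp", "cc_step", "cc_hyper", "cc_zero", "opto_train")
VC_FAMILIES <- c("vc_na_ramp", "vc_na_step", "vc_k_prepulse")
GROUP_LABELS <- c("control", "kcl", "control_recovery", "kcl_recovery", "dark", "hz1")

#' Stimulus segment
#'
#' One piece of a command waveform. Time intervals are half-open
#' `[t_start, t_end)`; a `ramp` interpolates linearly from `amp_start` to
#' `amp_end`; `hold` and `step` are constant; `pulse_train` emits square
#' pulses of `pulse_width` ms every `period` ms at `pulse_amp`, zero between
#' pulses. Amplitudes are pA in current clamp and mV in voltage clamp.
#'
#' @param kind one of `"hold"`, `"step"`, `"ramp"`, `"pulse_train"`
#' @param t_start,t_end segment interval in ms, `t_end > t_start`
#' @param amp_start,amp_end command amplitude at the segment edges
#' @param period,pulse_width,pulse_amp pulse-train geometry (ms, ms, amplitude)
#' @return a `stim_segment` list
#' @export
stim_segment <- function(kind, t_start, t_end, amp_start, amp_end = amp_start,
                         period = NA_real_, pulse_width = NA_real_,
                         pulse_amp = NA_real_) {
  kind <- match.arg(kind, c("hold", "step", "ramp", "pulse_train"))
  if (!is.finite(t_start) || !is.finite(t_end) || t_end <= t_start)
    stop("segment requires t_end > t_start")
  if (kind %in% c("hold", "step") && amp_start != amp_end)
    stop("hold/step segments must have amp_start == amp_end")
  if (kind == "pulse_train" &&
      (!is.finite(period) || !is.finite(pulse_width) || !is.finite(pulse_amp)))
    stop("pulse_train requires period, pulse_width and pulse_amp")
  structure(list(kind = kind, t_start = t_start, t_end = t_end,
                 amp_start = amp_start, amp_end = amp_end,
                 period = period, pulse_width = pulse_width,
                 pulse_amp = pulse_amp),
            class = "stim_segment")
}

# evaluate one segment at times t (ms); vectorized, exact piecewise-linear
eval_segment <- function(seg, t) {
  switch(seg$kind,
    hold = ,
    step = rep(seg$amp_start, length(t)),
    ramp = seg$amp_start + (seg$amp_end - seg$amp_start) *
      (t - seg$t_start) / (seg$t_end - seg$t_start),
    pulse_train = ifelse(((t - seg$t_start) %% seg$period) < seg$pulse_width,
                         seg$pulse_amp, 0))
}

# evaluate a full segment list at times t; segments must tile [0, dur)
eval_segments <- function(segments, t) {
  out <- numeric(length(t))
  hit <- rep(FALSE, length(t))
  dur <- max(vapply(segments, function(s) s$t_end, 0))
  for (seg in segments) {
    # half-open [t_start, t_end), except the final instant of the sweep
    idx <- t >= seg$t_start & (t < seg$t_end | (t == seg$t_end & t == dur))
    out[idx] <- eval_segment(seg, t[idx])
    hit[idx] <- hit[idx] | idx[idx]
  }
  if (!all(hit)) stop("time points outside the declared segments")
  out
}

#' Build a stimulation protocol
#'
#' Resolves a named protocol family into a fully specified [protocol] object:
#' current-clamp ramp/step families are 1 s stimuli delivered from a -60 mV
#' holding potential in 10 pA increments capped at 1,000 pA for mouse
#' presets (100 pA / 10,000 pA for human); the sodium-current ramp holds at
#' -80 mV then ramps the command from -100 to +20 mV over 600 ms; the
#' sodium step family applies 1 s steps from -60 to +20 mV in 10 mV
#' increments (9 sweeps); the potassium prepulse pair tests at +40 mV after
#' a 150 ms prepulse to -80 mV or +10 mV from a -70 mV hold; `opto_train`
#' is a train of 10 ms light pulses at a stated frequency.
#'
#' @param family one of `cc_ramp`, `cc_step`, `cc_hyper`, `cc_zero`,
#'   `opto_train`, `vc_na_ramp`, `vc_na_step`, `vc_k_prepulse`
#' @param species `"mouse"` or `"human"`; required for current-clamp
#'   families (sets increment and cap)
#' @param sampling_rate samples per second, default 50 kHz
#' @param freq_hz,n_pulses pulse-train frequency and count (`opto_train`)
#' @param prepulse_ms prepulse duration for `vc_k_prepulse` (ms)
#' @return a `protocol` object: ordered sweep definitions, each a list of
#'   [stim_segment]s plus the sweep's nominal amplitude
#' @export
make_protocol <- function(family, species = NULL, sampling_rate = 50000,
                          freq_hz = 1, n_pulses = 60, prepulse_ms = 150) {
  if (!family %in% c(CC_FAMILIES, VC_FAMILIES))
    stop("unknown protocol family: ", family)
  is_cc <- family %in% CC_FAMILIES
  if (is_cc) {
    if (is.null(species)) stop("species_preset required for current-clamp families")
    species <- match.arg(species, c("mouse", "human"))
    inc <- if (species == "mouse") 10 else 100
    cap <- if (species == "mouse") 1000 else 10000
  } else {
    inc <- NA_real_; cap <- NA_real_
    if (is.null(species)) species <- "mouse"
  }

  pre <- 100; stim <- 1000; post <- 200  # cc sweep geometry, ms

  sweeps <- switch(family,
    cc_step = lapply(seq_len(cap / inc), function(k) {
      amp <- k * inc
      list(amp = amp, stim_on = pre, stim_off = pre + stim, segments = list(
        stim_segment("hold", 0, pre, 0),
        stim_segment("step", pre, pre + stim, amp),
        stim_segment("hold", pre + stim, pre + stim + post, 0)))
    }),
    cc_ramp = lapply(seq_len(cap / inc), function(k) {
      amp <- k * inc
      list(amp = amp, stim_on = pre, stim_off = pre + stim, segments = list(
        stim_segment("hold", 0, pre, 0),
        stim_segment("ramp", pre, pre + stim, 0, amp),
        stim_segment("hold", pre + stim, pre + stim + post, 0)))
    }),
    cc_hyper = {
      amp <- -inc
      list(list(amp = amp, stim_on = pre, stim_off = pre + stim, segments = list(
        stim_segment("hold", 0, pre, 0),
        stim_segment("step", pre, pre + stim, amp),
        stim_segment("hold", pre + stim, pre + stim + post, 0))))
    },
    cc_zero = list(list(amp = 0, stim_on = pre, stim_off = pre + stim,
                        segments = list(
      stim_segment("hold", 0, pre + stim + post, 0)))),
    opto_train = {
      period <- 1000 / freq_hz
      dur <- n_pulses * period
      list(list(amp = 1, stim_on = pre, stim_off = pre + dur,
                freq_hz = freq_hz, n_pulses = n_pulses, segments = list(
        stim_segment("hold", 0, pre, 0),
        stim_segment("pulse_train", pre, pre + dur, 0,
                     period = period, pulse_width = 10, pulse_amp = 1),
        stim_segment("hold", pre + dur, pre + dur + 100, 0))))
    },
    vc_na_ramp = list(list(amp = 20, stim_on = 100, stim_off = 700,
                           segments = list(
      stim_segment("hold", 0, 100, -80),
      stim_segment("ramp", 100, 700, -100, 20),
      stim_segment("hold", 700, 800, -80)))),
    vc_na_step = lapply(seq(-60, 20, by = 10), function(vstep) {
      list(amp = vstep, stim_on = 100, stim_off = 1100, segments = list(
        stim_segment("hold", 0, 100, -80),
        stim_segment("step", 100, 1100, vstep),
        stim_segment("hold", 1100, 1200, -80)))
    }),
    vc_k_prepulse = lapply(c(-80, 10), function(vpre) {
      list(amp = vpre, stim_on = 100 + prepulse_ms,
           stim_off = 100 + prepulse_ms + 500, prepulse = vpre, segments = list(
        stim_segment("hold", 0, 100, -70),
        stim_segment("step", 100, 100 + prepulse_ms, vpre),
        stim_segment("step", 100 + prepulse_ms, 100 + prepulse_ms + 500, 40),
        stim_segment("hold", 100 + prepulse_ms + 500,
                     100 + prepulse_ms + 600, -70)))
    })
  )

  structure(list(
    family = family,
    clamp_mode = if (is_cc) "current" else "voltage",
    holding_level = if (is_cc) -60 else if (family == "vc_k_prepulse") -70 else -80,
    species = species,
    sampling_rate = sampling_rate,
    increment = inc,
    cap = cap,
    sweeps = sweeps
  ), class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("<protocol %s: %s clamp, %d sweep(s), %g kHz, %s preset>\n",
              x$family, x$clamp_mode, length(x$sweeps),
              x$sampling_rate / 1000, x$species))
  invisible(x)
}

# duration in ms of one sweep definition
sweep_duration <- function(sweep_def) {
  max(vapply(sweep_def$segments, function(s) s$t_end, 0))
}

# sample times (ms) for one sweep definition at the protocol rate;
# sample 0 is protocol time 0
sweep_times <- function(sweep_def, sampling_rate) {
  dt <- 1000 / sampling_rate
  seq(0, sweep_duration(sweep_def) - dt, by = dt)
}

# resolve the command waveform of sweep k as a sampled vector
protocol_command <- function(protocol, k) {
  def <- protocol$sweeps[[k]]
  eval_segments(def$segments, sweep_times(def, protocol$sampling_rate))
}

#' Construct a single sweep
#'
#' The atom of all analysis: a recorded trace paired with its command
#' waveform. Units are fixed by the clamp mode (`recorded` in mV and
#' `command` in pA for current clamp; recorded pA, command mV for voltage
#' clamp). Time is carried implicitly by `sampling_rate` and the sample
#' index; sample 0 is protocol time 0.
#'
#' @param sweep_index position of the sweep in its family (1-based)
#' @param recorded,command numeric vectors of identical length
#' @param sampling_rate Hz
#' @param clamp_mode `"current"` or `"voltage"`
#' @param segments the [stim_segment] list that generated `command`
#' @param amp nominal sweep amplitude (peak command of the stimulus)
#' @param stim_on,stim_off stimulus epoch in ms
#' @param light optional 0/1 light schedule (same length as `recorded`)
#' @return a `sweep` object
#' @export
new_sweep <- function(sweep_index, recorded, command, sampling_rate,
                      clamp_mode, segments, amp = NA_real_,
                      stim_on = NA_real_, stim_off = NA_real_, light = NULL) {
  if (length(recorded) != length(command))
    stop("recorded and command must have identical length")
  if (anyNA(recorded) || anyNA(command)) stop("missing samples are not allowed")
  clamp_mode <- match.arg(clamp_mode, c("current", "voltage"))
  structure(list(sweep_index = sweep_index, recorded = recorded,
                 command = command, sampling_rate = sampling_rate,
                 clamp_mode = clamp_mode, segments = segments, amp = amp,
                 stim_on = stim_on, stim_off = stim_off, light = light),
            class = "sweep")
}

#' @export
print.sweep <- function(x, ...) {
  cat(sprintf("<sweep %d: %s clamp, %d samples @ %g kHz, amp %g>\n",
              x$sweep_index, x$clamp_mode, length(x$recorded),
              x$sampling_rate / 1000, x$amp))
  invisible(x)
}

#' Evaluate the command waveform at an arbitrary time
#'
#' Exact piecewise-linear evaluation of the declared stimulus segments, used
#' e.g. to attribute a ramp rheobase to the instantaneous injected current at
#' the moment of spike threshold.
#'
#' @param sweep a [new_sweep] object carrying its segment list
#' @param t time in ms, within `[0, sweep duration]`
#' @return command amplitude at `t` (pA or mV per clamp mode)
#' @export
command_at <- function(sweep, t) {
  dur <- length(sweep$recorded) * 1000 / sweep$sampling_rate
  if (any(t < 0 | t > dur)) stop("t out of range [0, ", dur, "] ms")
  eval_segments(sweep$segments, t)
}

#' Assemble a recording
#'
#' A cell's worth of sweeps, grouped by protocol family, with identity and
#' provenance metadata. Small-diameter presets are enforced: mouse cells
#' must be under 30 um, human under 60 um.
#'
#' @param cell_id unique identifier
#' @param group treatment group, one of `control`, `kcl`, `control_recovery`,
#'   `kcl_recovery`, `dark`, `hz1`
#' @param species `"mouse"` or `"human"`
#' @param diameter soma diameter, um
#' @param sweeps named list: family name -> list of [new_sweep] objects
#' @param provenance free-form list (synthetic seed, source file, ...)
#' @return a `recording` object
#' @export
new_recording <- function(cell_id, group, species, diameter, sweeps,
                          provenance = list()) {
  group <- match.arg(group, GROUP_LABELS)
  species <- match.arg(species, c("mouse", "human"))
  lim <- if (species == "mouse") 30 else 60
  if (!is.finite(diameter) || diameter >= lim)
    stop(sprintf("diameter must be < %d um for %s presets", lim, species))
  stopifnot(is.list(sweeps))
  structure(list(cell_id = cell_id, group = group, species = species,
                 diameter = diameter, sweeps = sweeps,
                 provenance = provenance),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  fam <- vapply(names(x$sweeps),
                function(f) sprintf("%s(%d)", f, length(x$sweeps[[f]])), "")
  cat(sprintf("<recording %s: %s %s, %.1f um; %s>\n", x$cell_id, x$species,
              x$group, x$diameter, paste(fam, collapse = " ")))
  invisible(x)
}
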