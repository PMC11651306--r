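# Per-cell excitability pipeline: rheobase, responder rule, suprathreshold
# counts, passive properties, firing-subtype classification, opto fidelity.

stim_kind <- function(sweep) {
  kinds <- vapply(sweep$segments, function(s) s$kind, "")
  k <- setdiff(unique(kinds), "hold")
  if (length(k) != 1) k <- "hold"
  k
}

# events restricted to the stimulus epoch; attribution is by peak time so an
# onset spike whose interpolated threshold lands a fraction of a sample
# before stimulus onset is still counted
stim_events <- function(sweep, criteria) {
  ev <- detect_aps(sweep, criteria)
  ev[ev$peak_time >= sweep$stim_on & ev$peak_time < sweep$stim_off, ,
     drop = FALSE]
}

#' Rheobase from an ordered current-injection family
#'
#' Rheobase is the minimum injected current that evokes at least one AP:
#' the peak command amplitude of the first sweep (ascending amplitudes)
#' with a detected event in the stimulus epoch. Cells that never fire up to
#' the cap are non-responders and carry the cap as their rheobase for
#' analysis (1,000 pA mouse, 10,000 pA human).
#'
#' @param family list of current-clamp sweeps sorted by increasing amplitude
#' @param criteria a [detection_criteria]
#' @param cap current-injection cutoff in pA
#' @return a `rheobase_result`: `protocol_kind`, `rheobase` (pA),
#'   `responder`, `sweep_number` (position in `family`), `cutoff`, and for
#'   ramp responders `current_at_threshold` (instantaneous injected current
#'   when dV/dt crossed the criterion, via [command_at])
#' @export
rheobase_from_family <- function(family, criteria = detection_criteria(),
                                 cap = 1000) {
  if (!length(family)) stop("empty sweep family")
  kinds <- vapply(family, stim_kind, "")
  if (length(unique(kinds)) != 1)
    stop("mixed protocol kinds in family: ", paste(unique(kinds), collapse = ", "))
  amps <- vapply(family, function(s) s$amp, 0)
  if (is.unsorted(amps)) stop("family must be sorted by increasing amplitude")

  for (j in seq_along(family)) {
    if (amps[j] > cap) break
    ev <- stim_events(family[[j]], criteria)
    if (nrow(ev)) {
      i_at_thr <- if (kinds[1] == "ramp")
        command_at(family[[j]], ev$threshold_time[1]) else amps[j]
      return(structure(list(protocol_kind = kinds[1], rheobase = amps[j],
                            responder = TRUE, sweep_number = j,
                            cutoff = cap, current_at_threshold = i_at_thr),
                       class = "rheobase_result"))
    }
  }
  structure(list(protocol_kind = kinds[1], rheobase = cap, responder = FALSE,
                 sweep_number = NA_integer_, cutoff = cap,
                 current_at_threshold = NA_real_),
            class = "rheobase_result")
}

#' @export
print.rheobase_result <- function(x, ...) {
  cat(sprintf("<rheobase %s: %g pA (%s, cutoff %g pA)>\n", x$protocol_kind,
              x$rheobase, if (x$responder) "responder" else "non-responder",
              x$cutoff))
  invisible(x)
}

# snap a target amplitude to the largest available family amplitude <= target
snap_down <- function(amps, target) {
  ok <- amps[amps <= target]
  if (!length(ok)) NA_real_ else max(ok)
}

#' AP counts at one to four times rheobase
#'
#' Accommodation measure: the number of APs evoked by step stimuli at 1-4x
#' rheobase. Multiples are snapped down to the family's discrete amplitude
#' grid; a multiple beyond the injection cap (or with no sweep on the grid)
#' is flagged absent rather than counted as zero.
#'
#' @param family ordered step-family sweeps
#' @param rheo a responder [rheobase_from_family] result
#' @param criteria a [detection_criteria]
#' @return data.frame: `multiple`, `amp` (snapped pA), `count` (NA when
#'   absent), `absent`
#' @export
suprathreshold_counts <- function(family, rheo,
                                  criteria = detection_criteria()) {
  if (!isTRUE(rheo$responder)) stop("suprathreshold counts require a responder")
  amps <- vapply(family, function(s) s$amp, 0)
  out <- data.frame(multiple = 1:4, amp = NA_real_, count = NA_integer_,
                    absent = TRUE)
  for (m in 1:4) {
    target <- m * rheo$rheobase
    if (target > rheo$cutoff && m > 1) next        # beyond cap: absent
    a <- snap_down(amps, min(target, rheo$cutoff))
    if (is.na(a) || a < rheo$rheobase) next
    j <- which(amps == a)[1]
    out$amp[m] <- a
    out$count[m] <- nrow(stim_events(family[[j]], criteria))
    out$absent[m] <- FALSE
  }
  out
}

#' Classify the firing pattern of a step responder
#'
#' Rule-based subtype labels: `delayed` if the first AP at rheobase comes
#' at least 100 ms after stimulus onset; otherwise `single` if every
#' available suprathreshold sweep carries exactly one AP and it falls
#' within the onset window; otherwise `repeated` if the suprathreshold
#' sweeps fire within the onset window and any sweep fires two or more
#' APs; `unclassified` otherwise (with a reason). The onset window
#' defaults to the first 100 ms, symmetric with the delayed rule.
#'
#' @param family ordered step-family sweeps
#' @param rheo a [rheobase_from_family] result
#' @param criteria a [detection_criteria]
#' @param onset_window ms after stimulus onset counting as "at the start"
#' @param delayed_latency minimum rheobase first-AP latency for `delayed`
#' @return a `firing_subtype`: `label`, `first_ap_latency` (ms), `reason`
#' @export
classify_firing <- function(family, rheo, criteria = detection_criteria(),
                            onset_window = 100, delayed_latency = 100) {
  subtype <- function(label, latency, reason = NA_character_)
    structure(list(label = label, first_ap_latency = latency, reason = reason),
              class = "firing_subtype")
  if (!isTRUE(rheo$responder))
    return(subtype("unclassified", NA_real_, "non-responder"))

  rsw <- family[[rheo$sweep_number]]
  rev_ <- stim_events(rsw, criteria)
  if (!nrow(rev_))
    return(subtype("unclassified", NA_real_, "no event on rheobase sweep"))
  latency <- rev_$threshold_time[1] - rsw$stim_on
  if (latency >= delayed_latency) return(subtype("delayed", latency))

  cnt <- suprathreshold_counts(family, rheo, criteria)
  avail <- which(!cnt$absent)
  if (!length(avail))
    return(subtype("unclassified", latency, "no suprathreshold sweeps"))

  amps <- vapply(family, function(s) s$amp, 0)
  onset_ok <- logical(0); n_aps <- integer(0)
  for (m in avail) {
    j <- which(amps == cnt$amp[m])[1]
    ev <- stim_events(family[[j]], criteria)
    n_aps <- c(n_aps, nrow(ev))
    onset_ok <- c(onset_ok,
                  nrow(ev) > 0 &&
                    (ev$threshold_time[1] - family[[j]]$stim_on) < onset_window)
  }
  if (all(n_aps == 1L) && all(onset_ok)) return(subtype("single", latency))
  if (all(onset_ok) && any(n_aps >= 2L)) return(subtype("repeated", latency))
  subtype("unclassified", latency, "no rule matched")
}

#' @export
print.firing_subtype <- function(x, ...) {
  cat(sprintf("<firing subtype: %s (first-AP latency %.1f ms)%s>\n", x$label,
              x$first_ap_latency,
              if (!is.na(x$reason)) paste0(" - ", x$reason) else ""))
  invisible(x)
}

#' Resting membrane potential
#'
#' Mean potential over a 1 s epoch with no current injection. Cells outside
#' the -75 to -40 mV inclusion window are excluded from all downstream
#' group statistics.
#'
#' @param sweep a zero-injection current-clamp sweep
#' @return list: `V_rest` (mV), `included`
#' @export
resting_potential <- function(sweep) {
  stopifnot(inherits(sweep, "sweep"))
  if (is.na(sweep$stim_on) || is.na(sweep$stim_off))
    stop("zero-injection epoch missing from sweep")
  if (any(sweep$command != 0)) stop("sweep has non-zero current injection")
  dt <- 1000 / sweep$sampling_rate
  idx <- seq(floor(sweep$stim_on / dt) + 1, floor(sweep$stim_off / dt))
  v <- mean(sweep$recorded[idx])
  list(V_rest = v, included = v >= -75 && v <= -40)
}

#' Input resistance from a hyperpolarizing step
#'
#' `R_in = dV_steady / I_injected`, reported positive in megaohms. The
#' steady deflection is the mean over the last 20% of the step relative to
#' the pre-stimulus baseline; a residual-slope check guards against an
#' unsettled plateau.
#'
#' @param sweep current-clamp sweep with a hyperpolarizing step
#' @param injected injected current in pA (negative)
#' @return R_in in MOhm
#' @export
input_resistance <- function(sweep, injected = NULL) {
  stopifnot(inherits(sweep, "sweep"))
  if (is.null(injected)) injected <- sweep$amp
  if (injected == 0) stop("injected current must be non-zero")
  if (injected > 0) stop("input resistance uses a hyperpolarizing (negative) injection")
  dt <- 1000 / sweep$sampling_rate
  base_idx <- seq_len(max(1, floor(sweep$stim_on / dt)))
  i0 <- floor((sweep$stim_off - 0.2 * (sweep$stim_off - sweep$stim_on)) / dt) + 1
  i1 <- floor(sweep$stim_off / dt)
  plateau <- sweep$recorded[i0:i1]
  tt <- (i0:i1) * dt
  slope <- stats::coef(stats::lm(plateau ~ tt))[2]
  if (abs(slope) > 0.02)
    warning("plateau slope ", signif(slope, 2), " mV/ms: steady state may not be reached")
  dv <- mean(plateau) - mean(sweep$recorded[base_idx])
  abs(1000 * dv / injected)   # mV/pA -> GOhm; x1000 -> MOhm
}

#' Membrane capacitance from the charging transient
#'
#' Software surrogate for amplifier-based capacitance compensation: fits a
#' mono-exponential to the voltage relaxation at the onset of a
#' hyperpolarizing step and converts via `C_m = tau / R_in`.
#'
#' @param sweep hyperpolarizing current-clamp sweep
#' @param R_in input resistance in MOhm ([input_resistance])
#' @param fit_ms fit window after stimulus onset
#' @return list: `C_m` (pF), `tau` (ms), `failed`
#' @export
estimate_capacitance <- function(sweep, R_in, fit_ms = 80) {
  stopifnot(inherits(sweep, "sweep"))
  dt <- 1000 / sweep$sampling_rate
  i_on <- floor(sweep$stim_on / dt) + 1L
  i_fit <- i_on:min(length(sweep$recorded), i_on + round(fit_ms / dt))
  tt <- (i_fit - i_on) * dt
  vv <- sweep$recorded[i_fit]
  v0 <- mean(sweep$recorded[seq_len(max(1, i_on - 1L))])
  vinf <- mean(vv[tt > 0.75 * max(tt)])
  dv <- vinf - v0
  noise_sd <- stats::sd(sweep$recorded[seq_len(max(2, i_on - 1L))])
  if (abs(dv) < 5 * max(noise_sd, 1e-9) || abs(dv) < 0.5)
    return(list(C_m = NA_real_, tau = NA_real_, failed = TRUE))
  tau0 <- tt[which(abs(vv - v0) >= 0.632 * abs(dv))[1]]
  if (is.na(tau0) || tau0 <= 0) tau0 <- 5
  fit <- tryCatch(
    stats::nls(vv ~ vinf_ + (v0_ - vinf_) * exp(-tt / tau_),
               start = list(vinf_ = vinf, v0_ = v0, tau_ = tau0),
               control = stats::nls.control(warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    tau <- stats::coef(fit)[["tau_"]]
  } else {
    # fall back to a log-linear fit of the early relaxation (the gated
    # conductances make simulated transients only approximately exponential
    # and nls occasionally refuses them)
    resid <- (vv - vinf) / (v0 - vinf)
    use <- which(resid > 0.05 & tt <= 4 * tau0)
    if (length(use) < 10)
      return(list(C_m = NA_real_, tau = NA_real_, failed = TRUE))
    tau <- -1 / stats::coef(stats::lm(log(resid[use]) ~ tt[use]))[[2]]
    if (!is.finite(tau) || tau <= 0)
      return(list(C_m = NA_real_, tau = NA_real_, failed = TRUE))
  }
  list(C_m = 1000 * tau / R_in, tau = tau, failed = FALSE)
}

#' Firing fidelity to a light-pulse train
#'
#' Fraction of light pulses followed by at least one AP whose threshold
#' time falls within `response_window` ms of pulse onset. "Reliable" firing
#' means fidelity of exactly 1.0.
#'
#' @param sweep an optogenetic current-clamp sweep carrying its light
#'   schedule
#' @param criteria a [detection_criteria]
#' @param response_window ms after each pulse onset
#' @return list: `fidelity`, `reliable`, `n_pulses`, `n_responses`
#' @export
firing_fidelity <- function(sweep, criteria = detection_criteria(),
                            response_window = 25) {
  stopifnot(inherits(sweep, "sweep"))
  tr <- Filter(function(s) s$kind == "pulse_train", sweep$segments)
  if (!length(tr)) stop("sweep has no pulse-train segment (empty schedule)")
  tr <- tr[[1]]
  onsets <- seq(tr$t_start, tr$t_end - tr$pulse_width / 2, by = tr$period)
  if (!length(onsets)) stop("empty pulse schedule")
  ev <- detect_aps(sweep, criteria)
  hit <- vapply(onsets, function(t0)
    any(ev$threshold_time >= t0 & ev$threshold_time < t0 + response_window),
    TRUE)
  f <- mean(hit)
  list(fidelity = f, reliable = f == 1.0, n_pulses = length(onsets),
       n_responses = sum(hit))
}

#' Full excitability profile of one recording
#'
#' Runs the complete per-cell pipeline on a [new_recording]: resting
#' potential and inclusion flag (`cc_zero`), input resistance and
#' capacitance (`cc_hyper`), ramp and step rheobase with responder flags,
#' AP counts at 1-4x rheobase, firing subtype, first-AP waveform at
#' rheobase, and optogenetic fidelity when an `opto_train` family is
#' present.
#'
#' @param recording a `recording`
#' @param criteria a [detection_criteria]
#' @param onset_window see [classify_firing]
#' @return an `excitability_profile` list
#' @export
excitability_profile <- function(recording, criteria = detection_criteria(),
                                 onset_window = 100) {
  stopifnot(inherits(recording, "recording"))
  cap <- if (recording$species == "mouse") 1000 else 10000
  sw <- recording$sweeps
  prof <- list(cell_id = recording$cell_id, group = recording$group,
               species = recording$species,
               V_rest = NA_real_, included = NA,
               R_in = NA_real_, C_m = NA_real_,
               ramp = NULL, step = NULL, counts = NULL,
               subtype = NULL, first_ap = NULL, fidelity = NULL)

  if (!is.null(sw$cc_zero)) {
    rp <- resting_potential(sw$cc_zero[[1]])
    prof$V_rest <- rp$V_rest; prof$included <- rp$included
  }
  if (!is.null(sw$cc_hyper)) {
    hs <- sw$cc_hyper[[1]]
    prof$R_in <- input_resistance(hs)
    cm <- estimate_capacitance(hs, prof$R_in)
    prof$C_m <- cm$C_m
  }
  if (!is.null(sw$cc_ramp))
    prof$ramp <- rheobase_from_family(sw$cc_ramp, criteria, cap)
  if (!is.null(sw$cc_step)) {
    prof$step <- rheobase_from_family(sw$cc_step, criteria, cap)
    if (prof$step$responder) {
      prof$counts <- suprathreshold_counts(sw$cc_step, prof$step, criteria)
      prof$subtype <- classify_firing(sw$cc_step, prof$step, criteria,
                                      onset_window)
      prof$first_ap <- first_ap_at_rheobase(sw$cc_step, prof$step, criteria)
    } else {
      prof$subtype <- classify_firing(sw$cc_step, prof$step, criteria,
                                      onset_window)
    }
  }
  if (!is.null(sw$opto_train))
    prof$fidelity <- firing_fidelity(sw$opto_train[[1]], criteria)

  structure(prof, class = "excitability_profile")
}

#' @export
print.excitability_profile <- function(x, ...) {
  cat(sprintf("<excitability %s [%s %s]>\n", x$cell_id, x$species, x$group))
  cat(sprintf("  V_rest %.1f mV (%s) | R_in %.0f MOhm | C_m %.1f pF\n",
              x$V_rest, if (isTRUE(x$included)) "included" else "excluded",
              x$R_in, x$C_m))
  if (!is.null(x$ramp))
    cat(sprintf("  ramp rheobase %g pA (%s)\n", x$ramp$rheobase,
                if (x$ramp$responder) "responder" else "NR"))
  if (!is.null(x$step))
    cat(sprintf("  step rheobase %g pA (%s)\n", x$step$rheobase,
                if (x$step$responder) "responder" else "NR"))
  if (!is.null(x$counts))
    cat("  APs at 1-4x:", paste(x$counts$count, collapse = " "), "\n")
  if (!is.null(x$subtype))
    cat(sprintf("  subtype: %s\n", x$subtype$label))
  if (!is.null(x$fidelity))
    cat(sprintf("  opto fidelity: %.3f (%d/%d)\n", x$fidelity$fidelity,
                x$fidelity$n_responses, x$fidelity$n_pulses))
  invisible(x)
}

#' Flatten excitability profiles into a per-cell table
#'
#' One row per cell with all profile fields, non-responder rheobase written
#' as the cap value alongside an explicit `responder` column (so analyses
#' can reproduce both the all-cells and responders-only variants).
#'
#' @param profiles list of [excitability_profile] objects
#' @return data.frame
#' @export
profile_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    cnt <- if (!is.null(p$counts)) p$counts$count else rep(NA_integer_, 4)
    fa <- p$first_ap
    data.frame(
      cell_id = p$cell_id, group = p$group, species = p$species,
      V_rest = p$V_rest, included = p$included,
      R_in = p$R_in, C_m = p$C_m,
      rheobase_ramp = if (!is.null(p$ramp)) p$ramp$rheobase else NA_real_,
      responder_ramp = if (!is.null(p$ramp)) p$ramp$responder else NA,
      rheobase_step = if (!is.null(p$step)) p$step$rheobase else NA_real_,
      responder_step = if (!is.null(p$step)) p$step$responder else NA,
      aps_1x = cnt[1], aps_2x = cnt[2], aps_3x = cnt[3], aps_4x = cnt[4],
      subtype = if (!is.null(p$subtype)) p$subtype$label else NA_character_,
      latency = if (!is.null(p$subtype)) p$subtype$first_ap_latency else NA_real_,
      amplitude = if (!is.null(fa)) fa$amplitude else NA_real_,
      overshoot = if (!is.null(fa)) fa$overshoot else NA_real_,
      rise = if (!is.null(fa)) fa$rise else NA_real_,
      fall = if (!is.null(fa)) fa$fall else NA_real_,
      half_width = if (!is.null(fa)) fa$half_width else NA_real_,
      shoulder = if (!is.null(fa)) fa$shoulder_flag else NA,
      fidelity = if (!is.null(p$fidelity)) p$fidelity$fidelity else NA_real_)
  })
  do.call(rbind, rows)
}
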