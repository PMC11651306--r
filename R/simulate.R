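# Simulation wrappers around the compiled integrator.

# Holding bias: the injected current that makes the holding level a fixed
# point of the model (gates at steady state), mirroring the experimenter's
# bias current in current clamp.
holding_bias <- function(params, v_hold = -60) {
  steady_current_cpp(unclass(params), v_hold, 0)
}

#' Simulate one current-clamp sweep
#'
#' Integrates the membrane equation along sweep `k` of a current-clamp
#' protocol. A pre-recording settle period lets the model reach its own
#' steady state first: stimulus families are held at -60 mV by an
#' auto-computed bias current; zero-injection (resting-potential) sweeps are
#' left unbiased so the cell sits at its own resting potential.
#'
#' @param params a [model_params]
#' @param protocol a current-clamp [make_protocol]
#' @param k sweep number within the family
#' @param seed integer seed for the membrane noise (set per sweep)
#' @param oversample integration substeps per output sample
#' @param settle_ms pre-recording settle duration
#' @return a [new_sweep] (recorded mV, command pA)
#' @export
simulate_cc_sweep <- function(params, protocol, k, seed = NULL,
                              oversample = 4, settle_ms = NULL) {
  stopifnot(inherits(protocol, "protocol"))
  if (protocol$clamp_mode != "current")
    stop("protocol is not current clamp")
  def <- protocol$sweeps[[k]]
  dt <- 1000 / protocol$sampling_rate
  times <- sweep_times(def, protocol$sampling_rate)
  opto <- protocol$family == "opto_train"
  free_rest <- protocol$family == "cc_zero"

  if (opto) {
    light <- eval_segments(def$segments, times)
    cmd <- numeric(length(times))
  } else {
    light <- numeric(0)
    cmd <- eval_segments(def$segments, times)
  }

  if (free_rest) {
    bias <- 0
    if (is.null(settle_ms)) settle_ms <- 800
  } else {
    bias <- holding_bias(params, protocol$holding_level)
    if (is.null(settle_ms)) settle_ms <- 200
  }

  if (!is.null(seed)) set.seed(seed)
  v <- sim_cc_cpp(unclass(params), cmd, light, dt, oversample,
                  protocol$holding_level, bias, settle_ms,
                  params$noise_sigma)
  new_sweep(sweep_index = k, recorded = v, command = cmd,
            sampling_rate = protocol$sampling_rate, clamp_mode = "current",
            segments = def$segments, amp = def$amp,
            stim_on = def$stim_on, stim_off = def$stim_off,
            light = if (opto) light else NULL)
}

#' Simulate a current-clamp recording
#'
#' Runs every sweep of the protocol (or a subset) and assembles a
#' [new_recording]. Deterministic given `seed`: each sweep's noise stream is
#' seeded by a value derived from `seed` and the sweep amplitude, so the
#' same sweep is bit-identical wherever it is regenerated.
#'
#' @param params a [model_params]
#' @param protocol a current-clamp [make_protocol]
#' @param seed master integer seed
#' @param cell_id,group,diameter recording metadata
#' @param sweep_numbers subset of sweeps to run (default: all)
#' @inheritParams simulate_cc_sweep
#' @return a `recording` with one family
#' @export
simulate_current_clamp <- function(params, protocol, seed = 1,
                                   cell_id = "sim_cell", group = "control",
                                   diameter = 22, sweep_numbers = NULL,
                                   oversample = 4, settle_ms = NULL) {
  if (is.null(sweep_numbers)) sweep_numbers <- seq_along(protocol$sweeps)
  sweeps <- lapply(sweep_numbers, function(k) {
    simulate_cc_sweep(params, protocol, k,
                      seed = sweep_seed(seed, protocol$family,
                                        protocol$sweeps[[k]]$amp),
                      oversample = oversample, settle_ms = settle_ms)
  })
  out <- list()
  out[[protocol$family]] <- sweeps
  new_recording(cell_id, group, protocol$species, diameter, out,
                provenance = list(source = "synthetic", seed = seed))
}

#' Simulate a voltage-clamp recording
#'
#' Ideal-clamp simulation: the membrane follows the command exactly and the
#' recorded current is the sum of the channels selected by `channel_mask`
#' (emulating the pharmacological isolation baths: the sodium-isolating
#' solution blocks the potassium channels and vice versa). No
#' series-resistance error or capacitive transient is modeled.
#'
#' @param params a [model_params]
#' @param protocol a voltage-clamp [make_protocol]
#' @param channel_mask character subset of
#'   `c("naf", "nas", "kdr", "ka", "leak")`
#' @param cell_id,group,diameter recording metadata
#' @param oversample integration substeps per output sample
#' @return a `recording` (recorded pA, command mV)
#' @export
simulate_voltage_clamp <- function(params, protocol,
                                   channel_mask = c("naf", "nas", "leak"),
                                   cell_id = "sim_cell", group = "control",
                                   diameter = 22, oversample = 4) {
  stopifnot(inherits(protocol, "protocol"))
  if (protocol$clamp_mode != "voltage")
    stop("protocol is not voltage clamp")
  if (length(channel_mask) == 0) stop("empty channel mask")
  known <- c("naf", "nas", "kdr", "ka", "leak")
  if (!all(channel_mask %in% known))
    stop("unknown channels in mask: ",
         paste(setdiff(channel_mask, known), collapse = ", "))
  mask <- as.list(stats::setNames(known %in% channel_mask, known))
  dt <- 1000 / protocol$sampling_rate
  sweeps <- lapply(seq_along(protocol$sweeps), function(k) {
    def <- protocol$sweeps[[k]]
    cmd <- eval_segments(def$segments, sweep_times(def, protocol$sampling_rate))
    i <- sim_vc_cpp(unclass(params), cmd, dt, oversample, mask,
                    settle_ms = 200)
    new_sweep(sweep_index = k, recorded = i, command = cmd,
              sampling_rate = protocol$sampling_rate, clamp_mode = "voltage",
              segments = def$segments, amp = def$amp,
              stim_on = def$stim_on, stim_off = def$stim_off)
  })
  out <- list()
  out[[protocol$family]] <- sweeps
  new_recording(cell_id, group, protocol$species, diameter, out,
                provenance = list(source = "synthetic",
                                  mask = paste(channel_mask, collapse = "+")))
}

# Deterministic per-sweep seed: mixes the master seed, a protocol-family
# code and the sweep amplitude so a sweep at a given amplitude is identical
# between the 10 pA acquisition grid and the 1 pA ground-truth search.
# Plain 31-bit integer hash (documented counter scheme).
sweep_seed <- function(master, family, amp) {
  fam_code <- match(family, c(CC_FAMILIES, VC_FAMILIES))
  if (is.na(fam_code)) fam_code <- 0L
  m <- 2147483629
  x <- (as.numeric(master) %% m)
  x <- (x * 48271 + fam_code * 69621) %% m
  x <- (x * 48271 + (round(abs(amp) * 10) %% m)) %% m
  as.integer(x %% 2147483647)
}
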