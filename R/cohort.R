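# Cohort synthesis: matched per-cell parameter draws, treatment scalings,
# adaptive protocol acquisition, and fine-grid ground-truth rheobase.

# map recording group labels to treatment presets
group_treatment <- function(group) {
  switch(group,
    control = "control", kcl = "kcl24h",
    control_recovery = "control", kcl_recovery = "recovery",
    dark = "dark", hz1 = "hz1",
    stop("unknown group label: ", group))
}

# 31-bit deterministic mix for derived seeds
mix_seed <- function(...) {
  m <- 2147483629
  x <- 17
  for (v in c(...)) x <- (x * 48271 + as.numeric(v) * 69621 + 11) %% m
  as.integer(x %% 2147483647)
}

#' Cohort configuration
#'
#' Design of a synthetic cohort: cells per group, group-to-treatment
#' mapping with a firing-phenotype mixture, inter-cell parameter jitter,
#' and the master seed. Base cell parameters are drawn per cell index,
#' shared across groups (the same culture split across conditions), so
#' treatment contrasts are matched; membrane-noise streams differ per
#' group. Identical config + seed reproduces bit-identical bundles.
#'
#' @param n_per_group cells per group (> 0)
#' @param groups character vector of group labels from
#'   `control, kcl, control_recovery, kcl_recovery, dark, hz1`
#' @param mixture named phenotype probabilities
#'   (`single`/`delayed`/`repeated`), applied to every group
#' @param jitter_cv log-normal coefficient of variation of the conductance
#'   jitter
#' @param cm_cv log-normal CV of the capacitance jitter
#' @param seed master seed
#' @param species `"mouse"` or `"human"`
#' @param families protocol families to synthesize per cell
#' @param base_params baseline [model_params]
#' @param compute_truth run the 1 pA fine-grid ground-truth rheobase search
#' @return a `cohort_config`
#' @export
cohort_config <- function(n_per_group = 30,
                          groups = c("control", "kcl", "kcl_recovery"),
                          mixture = c(single = 0.3, delayed = 0.15,
                                      repeated = 0.55),
                          jitter_cv = 0.15, cm_cv = 0.1, seed = 1,
                          species = "mouse",
                          families = c("cc_zero", "cc_hyper", "cc_ramp",
                                       "cc_step"),
                          base_params = NULL,
                          compute_truth = TRUE) {
  if (is.null(base_params))
    base_params <- if (species == "human") human_model_params() else model_params()
  if (n_per_group <= 0) stop("n_per_group must be positive")
  stopifnot(all(groups %in% GROUP_LABELS))
  if (anyDuplicated(groups)) stop("duplicate group labels")
  if (abs(sum(mixture) - 1) > 1e-8) stop("mixture must sum to 1")
  stopifnot(all(names(mixture) %in% c("single", "delayed", "repeated")))
  structure(list(n_per_group = n_per_group, groups = groups,
                 mixture = mixture, jitter_cv = jitter_cv, cm_cv = cm_cv,
                 seed = seed, species = species, families = families,
                 base_params = base_params, compute_truth = compute_truth),
            class = "cohort_config")
}

# log-normal multiplier with unit mean and the given CV
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# base (pre-treatment) cell draw for cell index i: depends only on
# (master seed, i) so all groups share it
draw_base_cell <- function(config, i) {
  set.seed(mix_seed(config$seed, 1000 + i))
  p <- unclass(config$base_params)
  for (g in c("g_naf", "g_nas", "g_kdr", "g_ka", "g_leakk", "g_leakns"))
    p[[g]] <- p[[g]] * rlnorm_cv(1, config$jitter_cv)
  p$C_m <- p$C_m * rlnorm_cv(1, config$cm_cv)
  u <- stats::runif(1)
  cum <- cumsum(config$mixture)
  phen <- names(config$mixture)[which(u <= cum)[1]]
  dia_lim <- if (config$species == "mouse") c(15, 28) else c(30, 55)
  diameter <- stats::runif(1, dia_lim[1], dia_lim[2])
  list(params = do.call(model_params, p), phenotype = phen,
       diameter = diameter)
}

# build one current-clamp sweep definition at an arbitrary amplitude
# (continuous version of the make_protocol families)
cc_sweep_def <- function(family, amp) {
  pre <- 100; stim <- 1000; post <- 200
  segs <- switch(family,
    cc_step = list(stim_segment("hold", 0, pre, 0),
                   stim_segment("step", pre, pre + stim, amp),
                   stim_segment("hold", pre + stim, pre + stim + post, 0)),
    cc_ramp = list(stim_segment("hold", 0, pre, 0),
                   stim_segment("ramp", pre, pre + stim, 0, amp),
                   stim_segment("hold", pre + stim, pre + stim + post, 0)),
    stop("fine-grid sweeps support cc_step and cc_ramp only"))
  list(amp = amp, stim_on = pre, stim_off = pre + stim, segments = segs)
}

# simulate one cc sweep at an arbitrary amplitude with the shared
# per-amplitude seed scheme
sim_cc_amp <- function(params, family, amp, cell_seed, sampling_rate = 50000,
                       oversample = 4) {
  def <- cc_sweep_def(family, amp)
  cmd <- eval_segments(def$segments, sweep_times(def, sampling_rate))
  bias <- holding_bias(params, -60)
  set.seed(sweep_seed(cell_seed, family, amp))
  v <- sim_cc_cpp(unclass(params), cmd, numeric(0), 1000 / sampling_rate,
                  oversample, -60, bias, 200, params$noise_sigma)
  new_sweep(sweep_index = NA_integer_, recorded = v, command = cmd,
            sampling_rate = sampling_rate, clamp_mode = "current",
            segments = def$segments, amp = amp,
            stim_on = def$stim_on, stim_off = def$stim_off)
}

#' Fine-grid ground-truth rheobase
#'
#' Minimum amplitude, on a `resolution` pA grid (default 1 pA), at which
#' the simulated cell fires at least one AP: an ascending coarse scan
#' localizes the lowest firing decade (firing can fail again at strong
#' drive through depolarization block, so a global bisection would be
#' invalid), then a bisection refines inside it. The per-sweep noise
#' stream is seeded by the sweep amplitude, so any amplitude shared with
#' the acquisition grid reproduces the identical trace.
#'
#' @param params resolved [model_params] of the cell
#' @param family `"cc_ramp"` or `"cc_step"`
#' @param cell_seed per-cell seed (same one used for the recording)
#' @param cap injection cap, pA
#' @param resolution search grid, pA
#' @param criteria a [detection_criteria]
#' @return list: `rheobase` (pA; `cap` when the cell never fires),
#'   `responder`
#' @export
true_rheobase <- function(params, family, cell_seed, cap = 1000,
                          resolution = 1, criteria = detection_criteria()) {
  fires <- function(amp) {
    sw <- sim_cc_amp(params, family, amp, cell_seed)
    nrow(stim_events(sw, criteria)) > 0
  }
  # firing is monotone near onset but can fail again at very strong drive
  # (depolarization block), so first localize the lowest firing decade by an
  # ascending coarse scan, then bisect on the fine grid inside it
  coarse <- 10 * resolution
  hi <- NA_real_
  for (amp in seq(coarse, cap, by = coarse))
    if (fires(amp)) { hi <- amp; break }
  if (is.na(hi)) return(list(rheobase = cap, responder = FALSE))
  lo <- hi - coarse           # invariant: hi fires, lo does not
  while (hi - lo > resolution) {
    mid <- lo + resolution * round((hi - lo) / (2 * resolution))
    mid <- max(lo + resolution, min(hi - resolution, mid))
    if (fires(mid)) hi <- mid else lo <- mid
  }
  list(rheobase = hi, responder = TRUE)
}

# adaptively acquire one cell's recording: run families in the order an
# experimenter would, stopping ramp/step families at the first responding
# sweep and adding the suprathreshold multiples for the step family
simulate_cell <- function(params, config, group, cell_id, cell_seed,
                          diameter, criteria = detection_criteria()) {
  species <- config$species
  cap <- if (species == "mouse") 1000 else 10000
  inc <- if (species == "mouse") 10 else 100
  sweeps <- list()

  for (fam in config$families) {
    if (fam %in% c("cc_zero", "cc_hyper")) {
      proto <- make_protocol(fam, species)
      sweeps[[fam]] <- list(simulate_cc_sweep(
        params, proto, 1, seed = sweep_seed(cell_seed, fam,
                                            proto$sweeps[[1]]$amp)))
    } else if (fam %in% c("cc_ramp", "cc_step")) {
      fam_sweeps <- list()
      rheo <- NA_real_
      for (k in seq_len(cap / inc)) {
        amp <- k * inc
        sw <- sim_cc_amp(params, fam, amp, cell_seed)
        sw$sweep_index <- k
        fam_sweeps[[k]] <- sw
        if (nrow(stim_events(sw, criteria))) { rheo <- amp; break }
      }
      if (fam == "cc_step" && !is.na(rheo)) {
        extra <- unique(pmin(inc * floor((2:4) * rheo / inc), cap))
        extra <- setdiff(extra[extra > rheo], vapply(fam_sweeps,
                                                     function(s) s$amp, 0))
        for (amp in extra) {
          sw <- sim_cc_amp(params, fam, amp, cell_seed)
          sw$sweep_index <- as.integer(amp / inc)
          fam_sweeps[[length(fam_sweeps) + 1]] <- sw
        }
        ord <- order(vapply(fam_sweeps, function(s) s$amp, 0))
        fam_sweeps <- fam_sweeps[ord]
      }
      sweeps[[fam]] <- fam_sweeps
    } else if (fam == "vc_na_ramp" || fam == "vc_na_step") {
      proto <- make_protocol(fam, species)
      rec <- simulate_voltage_clamp(params, proto,
                                    channel_mask = c("naf", "nas", "leak"),
                                    cell_id = cell_id, group = group,
                                    diameter = diameter)
      sweeps[[fam]] <- rec$sweeps[[fam]]
    } else if (fam == "vc_k_prepulse") {
      proto <- make_protocol(fam, species)
      rec <- simulate_voltage_clamp(params, proto,
                                    channel_mask = c("kdr", "ka", "leak"),
                                    cell_id = cell_id, group = group,
                                    diameter = diameter)
      sweeps[[fam]] <- rec$sweeps[[fam]]
    } else if (fam == "opto_train") {
      proto <- make_protocol(fam, species, freq_hz = 1, n_pulses = 20)
      sweeps[[fam]] <- list(simulate_cc_sweep(
        params, proto, 1, seed = sweep_seed(cell_seed, fam, 1)))
    } else stop("unknown protocol family in config: ", fam)
  }

  new_recording(cell_id, group, species, diameter, sweeps,
                provenance = list(source = "synthetic", seed = cell_seed))
}

# ground-truth row for one resolved cell
cell_truth_row <- function(config, params, phenotype, group, treat, cell_id,
                           cell_seed, cap, criteria) {
  tr_ramp <- tr_step <- list(rheobase = NA_real_, responder = NA)
  if (config$compute_truth) {
    if ("cc_ramp" %in% config$families)
      tr_ramp <- true_rheobase(params, "cc_ramp", cell_seed, cap,
                               criteria = criteria)
    if ("cc_step" %in% config$families)
      tr_step <- true_rheobase(params, "cc_step", cell_seed, cap,
                               criteria = criteria)
  }
  data.frame(
    cell_id = cell_id, group = group, treatment = treat,
    phenotype = phenotype, cell_seed = cell_seed,
    C_m = params$C_m, g_naf = params$g_naf, g_nas = params$g_nas,
    g_kdr = params$g_kdr, g_ka = params$g_ka,
    g_leakk = params$g_leakk, g_leakns = params$g_leakns,
    s_min = params$s_min,
    true_rheobase_ramp = tr_ramp$rheobase,
    true_responder_ramp = tr_ramp$responder,
    true_rheobase_step = tr_step$rheobase,
    true_responder_step = tr_step$responder)
}

#' Generate a synthetic cohort with ground truth
#'
#' Simulates `n_per_group` cells for every group of the design, applying
#' the group's treatment preset on top of matched per-cell base draws, and
#' returns the recordings together with a ground-truth table (true
#' parameters, intended phenotype, and the 1 pA fine-grid rheobase when
#' `compute_truth` is on). Fully deterministic per master seed; optionally
#' writes one bundle per cell plus `ground_truth.csv`.
#'
#' @param config a [cohort_config]
#' @param out_dir optional directory for bundles + ground truth table
#' @param criteria a [detection_criteria]
#' @return list: `recordings` (named by cell id), `truth` (data.frame),
#'   `config`
#' @export
generate_cohort <- function(config, out_dir = NULL,
                            criteria = detection_criteria()) {
  stopifnot(inherits(config, "cohort_config"))
  cap <- if (config$species == "mouse") 1000 else 10000
  recordings <- list()
  truth <- list()

  for (g in config$groups) {
    treat <- group_treatment(g)
    for (i in seq_len(config$n_per_group)) {
      base <- draw_base_cell(config, i)
      params <- apply_presets(base$params, base$phenotype, treat)
      cell_id <- sprintf("%s_%03d", g, i)
      if (cell_id %in% names(recordings)) stop("duplicate cell id: ", cell_id)
      cell_seed <- mix_seed(config$seed, match(g, GROUP_LABELS), i)
      rec <- simulate_cell(params, config, g, cell_id, cell_seed,
                           base$diameter, criteria)
      recordings[[cell_id]] <- rec

      truth[[cell_id]] <- cell_truth_row(config, params, base$phenotype, g,
                                         treat, cell_id, cell_seed, cap,
                                         criteria)
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (rec in recordings) write_bundle(rec, out_dir)
    utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  list(recordings = recordings, truth = truth, config = config)
}


#' Profile a cohort cell-by-cell with flat memory use
#'
#' Equivalent to [generate_cohort] followed by [excitability_profile] and
#' [profile_table], but each cell's raw 50 kHz sweeps are discarded as soon
#' as the cell is profiled. Study-scale cohorts (dozens of cells with full
#' ramp families) would otherwise hold gigabytes of traces at once.
#'
#' @param config a [cohort_config]
#' @param criteria a [detection_criteria]
#' @return list: `cells` (per-cell [profile_table]), `truth`, `config`
#' @export
cohort_profiles <- function(config, criteria = detection_criteria()) {
  stopifnot(inherits(config, "cohort_config"))
  cap <- if (config$species == "mouse") 1000 else 10000
  cells <- list()
  truth <- list()
  for (g in config$groups) {
    treat <- group_treatment(g)
    for (i in seq_len(config$n_per_group)) {
      base <- draw_base_cell(config, i)
      params <- apply_presets(base$params, base$phenotype, treat)
      cell_id <- sprintf("%s_%03d", g, i)
      cell_seed <- mix_seed(config$seed, match(g, GROUP_LABELS), i)
      rec <- simulate_cell(params, config, g, cell_id, cell_seed,
                           base$diameter, criteria)
      cells[[cell_id]] <- profile_table(list(
        excitability_profile(rec, criteria)))
      rm(rec)
      truth[[cell_id]] <- cell_truth_row(config, params, base$phenotype, g,
                                         treat, cell_id, cell_seed, cap,
                                         criteria)
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  list(cells = cells, truth = truth, config = config)
}
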