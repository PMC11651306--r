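#' Nernst potassium reversal potential
#'
#' `E_K = RT/F * ln(K_out / K_in)`. Raising extracellular potassium (e.g.
#' 30 mM KCl in the bath) depolarizes `E_K` and with it the resting
#' potential.
#'
#' @param K_out,K_in extra-/intracellular potassium, mM (both > 0)
#' @param RT_over_F thermal voltage in mV; 25.7 mV at room temperature
#' @return reversal potential in mV
#' @examples
#' nernst_EK(30, 140)   # about -39.6 mV
#' nernst_EK(5, 140)    # about -85.6 mV
#' @export
nernst_EK <- function(K_out, K_in = 140, RT_over_F = 25.7) {
  if (any(K_out <= 0) || any(K_in <= 0))
    stop("potassium concentrations must be positive")
  RT_over_F * log(K_out / K_in)
}

#' Conductance-based model parameters
#'
#' Baseline parameter set for the single-compartment DRG-neuron model. All
#' conductances in nS, capacitance in pF, potentials in mV, concentrations
#' in mM. `E_K` is always derived from `K_out`/`K_in` via [nernst_EK], never
#' stored. `s_min`/`tau_s_scale` shape slow sodium inactivation
#' (accommodation); `tau_b_scale` stretches A-type inactivation.
#' `noise_sigma` is additive membrane-voltage noise in mV per sqrt(ms),
#' applied only in current clamp.
#'
#' @param ... named overrides of the defaults
#' @return a `model_params` list
#' @export
model_params <- function(...) {
  p <- list(
    C_m = 25,
    g_naf = 160, g_nas = 55, g_kdr = 200, g_ka = 15,
    g_leakk = 2.0, g_leakns = 1.1, g_chr2 = 0,
    E_na = 66, E_leakns = 0,
    K_in = 140, K_out = 5, RT_over_F = 25.7,
    s_min = 0.55, s_vh = -35, tau_s_scale = 1, tau_b_scale = 0.3,
    noise_sigma = 0.12)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown model parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  if (p$C_m <= 0) stop("C_m must be positive")
  if (p$K_in <= 0 || p$K_out <= 0) stop("potassium concentrations must be positive")
  gs <- c("g_naf", "g_nas", "g_kdr", "g_ka", "g_leakk", "g_leakns", "g_chr2")
  if (any(unlist(p[gs]) < 0)) stop("conductances must be non-negative")
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  C_m %.3g pF | gNaF %.3g gNaS %.3g gKdr %.3g gKA %.3g nS\n",
              x$C_m, x$g_naf, x$g_nas, x$g_kdr, x$g_ka))
  cat(sprintf("  leak K %.3g / NS %.3g nS | E_K %.1f mV (K_out %g mM) | s_min %.2f\n",
              x$g_leakk, x$g_leakns, nernst_EK(x$K_out, x$K_in, x$RT_over_F),
              x$K_out, x$s_min))
  invisible(x)
}

#' Firing-phenotype presets
#'
#' Parameter deltas, relative to the baseline [model_params], that produce
#' the three firing patterns seen in small DRG neurons: `repeated` is the
#' baseline (fires at stimulus onset and keeps firing), `single` adds strong
#' and fast slow-inactivation of the fast sodium conductance so the cell
#' accommodates after one onset spike, and `delayed` raises the A-type
#' conductance so spike onset is pushed beyond 100 ms at rheobase.
#'
#' @param label `"single"`, `"delayed"` or `"repeated"`
#' @return a `phenotype_preset` list of multipliers/overrides
#' @export
phenotype_preset <- function(label) {
  label <- match.arg(label, c("single", "delayed", "repeated"))
  deltas <- switch(label,
    repeated = list(),
    single   = list(s_min = 0.02, s_vh = -52, tau_s_scale = 0.015, g_ka_mult = 0.35),
    delayed  = list(g_ka_mult = 9, tau_b_scale = 2.0))
  structure(c(list(label = label), deltas), class = "phenotype_preset")
}

#' Treatment presets
#'
#' The experimental conditions the simulator emulates. `kcl24h` models the
#' adaptive response to 24 h sustained depolarization as a down-scaling of
#' both voltage-gated sodium conductances (`s_na`, default 0.45) with a mild
#' non-significant A-type increase (`s_a`, default 1.15); `recovery`
#' restores both scales to 1. `acute_kcl` changes only the bath potassium to
#' 30 mM (depolarization via Nernst, no conductance change). `dark` and
#' `hz1` are the optogenetic cohorts: ChR2 present, with `hz1` additionally
#' carrying a 1 Hz light-schedule history (no excitability change).
#'
#' @param label one of `control`, `kcl24h`, `recovery`, `acute_kcl`,
#'   `dark`, `hz1`
#' @param s_na,s_a sodium / A-type conductance scale overrides
#' @return a `treatment_preset`
#' @export
treatment_preset <- function(label, s_na = NULL, s_a = NULL) {
  label <- match.arg(label, c("control", "kcl24h", "recovery", "acute_kcl",
                              "dark", "hz1"))
  p <- switch(label,
    control   = list(s_na = 1,    s_a = 1,    K_out = NA, chr2 = FALSE),
    kcl24h    = list(s_na = 0.45, s_a = 1.15, K_out = NA, chr2 = FALSE),
    recovery  = list(s_na = 1,    s_a = 1,    K_out = NA, chr2 = FALSE),
    acute_kcl = list(s_na = 1,    s_a = 1,    K_out = 30, chr2 = FALSE),
    dark      = list(s_na = 1,    s_a = 1,    K_out = NA, chr2 = TRUE),
    hz1       = list(s_na = 1,    s_a = 1,    K_out = NA, chr2 = TRUE))
  if (!is.null(s_na)) p$s_na <- s_na
  if (!is.null(s_a))  p$s_a  <- s_a
  if (label %in% c("control", "recovery") && p$s_na != 1)
    stop("control/recovery must have s_na = 1")
  if (label == "kcl24h" && !(p$s_na > 0 && p$s_na < 1))
    stop("kcl24h requires 0 < s_na < 1")
  structure(c(list(label = label), p), class = "treatment_preset")
}

#' Apply phenotype and treatment presets to a baseline parameter set
#'
#' @param base a [model_params] object
#' @param phenotype a [phenotype_preset] (or label)
#' @param treatment a [treatment_preset] (or label)
#' @param g_chr2 light-gated conductance used when the treatment carries
#'   ChR2 (nS)
#' @return a resolved `model_params`
#' @export
apply_presets <- function(base, phenotype = "repeated", treatment = "control",
                          g_chr2 = 0.8) {
  if (is.character(phenotype)) phenotype <- phenotype_preset(phenotype)
  if (is.character(treatment)) treatment <- treatment_preset(treatment)
  p <- unclass(base)
  if (!is.null(phenotype$s_min)) p$s_min <- phenotype$s_min
  if (!is.null(phenotype$s_vh)) p$s_vh <- phenotype$s_vh
  if (!is.null(phenotype$tau_s_scale)) p$tau_s_scale <- phenotype$tau_s_scale
  if (!is.null(phenotype$tau_b_scale)) p$tau_b_scale <- phenotype$tau_b_scale
  if (!is.null(phenotype$g_ka_mult)) p$g_ka <- p$g_ka * phenotype$g_ka_mult
  p$g_naf <- p$g_naf * treatment$s_na
  p$g_nas <- p$g_nas * treatment$s_na
  p$g_ka  <- p$g_ka  * treatment$s_a
  if (!is.na(treatment$K_out)) p$K_out <- treatment$K_out
  p$g_chr2 <- if (isTRUE(treatment$chr2)) g_chr2 else 0
  do.call(model_params, p)
}

#' Frozen gating kinetics tables
#'
#' Steady-state activation/inactivation and time constants of every gate on
#' a voltage grid. These constants are fixed in compiled code; this table is
#' the regression surface that pins them and the source for closed-form
#' gating oracles.
#'
#' @param v voltage grid, mV
#' @param params a [model_params] (for `s_min` and the tau scales)
#' @return data.frame with `*_inf` and `*_tau` columns per gate
#' @export
gating_tables <- function(v = seq(-120, 60, by = 5), params = model_params()) {
  gating_tables_cpp(as.numeric(v), params$s_min, params$s_vh,
                    params$tau_s_scale, params$tau_b_scale)
}

#' Human-preset baseline parameters
#'
#' Human sensory neurons are larger (capacitance near 120 pF) but the model
#' reuses the mouse gating kinetics: capacitance and every conductance are
#' scaled by a common factor, which preserves the voltage dynamics and
#' firing phenotypes while moving rheobase into the hundreds-of-pA range
#' matched to the human 100 pA / 10 nA stimulation grid.
#'
#' @param C_m target capacitance, pF
#' @param base mouse baseline to scale
#' @return a [model_params]
#' @export
human_model_params <- function(C_m = 120, base = model_params()) {
  f <- C_m / base$C_m
  model_params(C_m = C_m,
               g_naf = base$g_naf * f, g_nas = base$g_nas * f,
               g_kdr = base$g_kdr * f, g_ka = base$g_ka * f,
               g_leakk = base$g_leakk * f, g_leakns = base$g_leakns * f)
}
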