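# Voltage-clamp stage: leak subtraction, sodium ramp/step peaks and IV
# curves, current density, A-type isolation by prepulse subtraction.

#' Fit a linear leak model
#'
#' Ordinary linear fit `I ~ (V_cmd - V_hold)` over all samples whose
#' command voltage lies in a subthreshold window (default -100 to -80 mV,
#' the foot of the sodium ramp) where no gated current activates. A
#' nonlinearity check rejects windows contaminated by gated current.
#'
#' @param sweeps list of voltage-clamp sweeps (or one sweep)
#' @param window command-voltage window, mV
#' @param v_hold reference holding command, mV
#' @param tol_pA maximum residual magnitude accepted in the window
#' @return a `leak_model`: `g_leak` (nS), `offset` (pA), `window`,
#'   `v_hold`, `max_resid`
#' @export
fit_leak <- function(sweeps, window = c(-100, -80), v_hold = -80,
                     tol_pA = 5) {
  if (inherits(sweeps, "sweep")) sweeps <- list(sweeps)
  # drop samples after the stimulus epoch: tail currents deactivating after
  # the return to holding would contaminate the fit
  clip <- function(s) {
    n <- length(s$recorded)
    keep <- if (is.na(s$stim_off)) rep(TRUE, n)
            else (seq_len(n) - 1) * 1000 / s$sampling_rate < s$stim_off
    list(v = s$command[keep], i = s$recorded[keep])
  }
  parts <- lapply(sweeps, clip)
  v <- unlist(lapply(parts, `[[`, "v"))
  i <- unlist(lapply(parts, `[[`, "i"))
  sel <- v >= window[1] & v <= window[2]
  if (sum(sel) < 2) stop("leak window contains no samples")
  vv <- v[sel] - v_hold
  if (length(unique(round(v[sel], 6))) < 2)
    stop("leak window spans a single command voltage: fit is underdetermined")
  fit <- stats::lm(i[sel] ~ vv)
  r <- stats::residuals(fit)
  if (max(abs(r)) > tol_pA)
    stop("nonlinearity in leak window (max residual ",
         signif(max(abs(r)), 3), " pA): gated current present?")
  structure(list(g_leak = unname(stats::coef(fit)[2]),
                 offset = unname(stats::coef(fit)[1]),
                 window = window, v_hold = v_hold,
                 max_resid = max(abs(r))),
            class = "leak_model")
}

#' @export
print.leak_model <- function(x, ...) {
  cat(sprintf("<leak: %.3f nS, offset %.2f pA @ hold %g mV (window %g..%g, max resid %.2g pA)>\n",
              x$g_leak, x$offset, x$v_hold, x$window[1], x$window[2],
              x$max_resid))
  invisible(x)
}

#' Subtract the linear leak from a voltage-clamp sweep
#'
#' `corrected(t) = I(t) - (g_leak * (V_cmd(t) - V_hold) + offset)`.
#'
#' @param sweep a voltage-clamp sweep
#' @param leak a [fit_leak] model
#' @return the sweep with the leak removed from `recorded`
#' @export
leak_subtract <- function(sweep, leak) {
  stopifnot(inherits(sweep, "sweep"), inherits(leak, "leak_model"))
  sweep$recorded <- sweep$recorded -
    (leak$g_leak * (sweep$command - leak$v_hold) + leak$offset)
  sweep
}

#' Peak inward current on the sodium ramp
#'
#' Most-negative sample of the leak-subtracted ramp sweep (inward currents
#' are negative) and the command voltage at that sample. If no deflection
#' exceeds the noise floor (3 SD of the pre-stimulus baseline), the peak is
#' reported as zero with a flag.
#'
#' @param sweep leak-subtracted `vc_na_ramp` sweep
#' @return list: `peak` (pA, negative), `v_at_peak` (mV), `no_inward` flag
#' @export
ramp_peak_inward <- function(sweep) {
  stopifnot(inherits(sweep, "sweep"))
  dt <- 1000 / sweep$sampling_rate
  idx <- seq(floor(sweep$stim_on / dt) + 1, floor(sweep$stim_off / dt))
  base <- sweep$recorded[seq_len(max(2, floor(sweep$stim_on / dt)))]
  floor_pA <- 3 * stats::sd(base)
  k <- idx[which.min(sweep$recorded[idx])]
  peak <- sweep$recorded[k]
  if (peak > -max(floor_pA, 1))
    return(list(peak = 0, v_at_peak = NA_real_, no_inward = TRUE))
  list(peak = peak, v_at_peak = sweep$command[k], no_inward = FALSE)
}

#' IV curve from a step family
#'
#' Per-step peak inward current within the step epoch (minimum-sample
#' convention) and its density `peak / C_m`.
#'
#' @param family leak-subtracted `vc_na_step` sweeps
#' @param C_m membrane capacitance, pF (> 0)
#' @return an `iv_curve` data.frame: `v` (mV), `peak` (pA), `density`
#'   (pA/pF)
#' @export
step_iv <- function(family, C_m) {
  if (C_m <= 0) stop("C_m must be positive")
  v <- vapply(family, function(s) s$amp, 0)
  if (is.unsorted(v, strictly = TRUE))
    stop("step voltages must be strictly increasing")
  peak <- vapply(family, function(s) {
    dt <- 1000 / s$sampling_rate
    idx <- seq(floor(s$stim_on / dt) + 1, floor(s$stim_off / dt))
    min(s$recorded[idx])
  }, 0)
  structure(data.frame(v = v, peak = peak, density = peak / C_m),
            class = c("iv_curve", "data.frame"))
}

#' Current density at a command voltage
#'
#' Reads the IV curve at `v`; the voltage must lie exactly on the step
#' grid.
#'
#' @param iv an [step_iv] curve
#' @param v command voltage, mV
#' @return density in pA/pF
#' @export
density_at <- function(iv, v) {
  j <- which(iv$v == v)
  if (!length(j))
    stop("voltage ", v, " mV is not on the IV grid (",
         paste(iv$v, collapse = ", "), ")")
  iv$density[j]
}

#' Isolate the A-type potassium current by prepulse subtraction
#'
#' The +40 mV test current after a -80 mV prepulse (A-type available)
#' minus the test current after a +10 mV prepulse (A-type inactivated)
#' leaves the inactivating component; the non-inactivating component
#' cancels. The A-type trace is reported as positive outward; its peak
#' density is `max / C_m` and the non-inactivating steady density is the
#' mean of the +10-prepulse trace over the last 20% of the test epoch
#' divided by `C_m`.
#'
#' @param sweep_m80,sweep_p10 test sweeps after the -80 mV and +10 mV
#'   prepulses, sharing one time base
#' @param C_m membrane capacitance, pF
#' @return an `atype_result`: `a_peak_density`, `sustained_density`
#'   (pA/pF), `a_trace` (pA, test epoch), `t_ms`
#' @export
isolate_a_type <- function(sweep_m80, sweep_p10, C_m) {
  stopifnot(inherits(sweep_m80, "sweep"), inherits(sweep_p10, "sweep"))
  if (C_m <= 0) stop("C_m must be positive")
  if (length(sweep_m80$recorded) != length(sweep_p10$recorded) ||
      sweep_m80$sampling_rate != sweep_p10$sampling_rate ||
      sweep_m80$stim_on != sweep_p10$stim_on ||
      sweep_m80$stim_off != sweep_p10$stim_off)
    stop("prepulse sweeps have mismatched time bases")
  dt <- 1000 / sweep_m80$sampling_rate
  idx <- seq(floor(sweep_m80$stim_on / dt) + 1, floor(sweep_m80$stim_off / dt))
  a_trace <- sweep_m80$recorded[idx] - sweep_p10$recorded[idx]
  late <- idx[idx > sweep_m80$stim_off / dt -
                0.2 * (sweep_m80$stim_off - sweep_m80$stim_on) / dt]
  structure(list(
    a_peak_density = max(a_trace) / C_m,
    sustained_density = mean(sweep_p10$recorded[late]) / C_m,
    a_trace = a_trace,
    t_ms = (idx - 1) * dt),
    class = "atype_result")
}

#' @export
print.atype_result <- function(x, ...) {
  cat(sprintf("<A-type peak %.2f pA/pF | sustained %.2f pA/pF>\n",
              x$a_peak_density, x$sustained_density))
  invisible(x)
}

#' Voltage-clamp summary for one cell
#'
#' Convenience wrapper: fits the leak on the ramp foot, subtracts it, and
#' returns ramp peak, step IV with density at 0 mV, and the A-type /
#' sustained densities when the prepulse pair is present.
#'
#' @param recording a `recording` holding `vc_na_ramp` and/or `vc_na_step`
#'   and/or `vc_k_prepulse` families
#' @param C_m capacitance used for densities, pF
#' @return list with `ramp`, `iv`, `density_0`, `atype` components (NULL
#'   when the family is absent)
#' @export
vclamp_summary <- function(recording, C_m) {
  sw <- recording$sweeps
  out <- list(ramp = NULL, iv = NULL, density_0 = NA_real_, atype = NULL)
  if (!is.null(sw$vc_na_ramp)) {
    ramp <- sw$vc_na_ramp[[1]]
    leak <- fit_leak(ramp, window = c(-100, -80), v_hold = -80)
    out$ramp <- ramp_peak_inward(leak_subtract(ramp, leak))
  }
  if (!is.null(sw$vc_na_step)) {
    fam <- sw$vc_na_step
    leak <- fit_leak(fam[1:2], window = c(-85, -55), v_hold = -80)
    fam <- lapply(fam, leak_subtract, leak = leak)
    out$iv <- step_iv(fam, C_m)
    out$density_0 <- density_at(out$iv, 0)
  }
  if (!is.null(sw$vc_k_prepulse)) {
    pre <- vapply(sw$vc_k_prepulse, function(s) s$segments[[2]]$amp_start, 0)
    out$atype <- isolate_a_type(sw$vc_k_prepulse[[which(pre == -80)]],
                                sw$vc_k_prepulse[[which(pre == 10)]], C_m)
  }
  out
}
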