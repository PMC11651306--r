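# Synthetic waveform builders and independent oracles shared across tests.

# current-clamp sweep from an arbitrary voltage trace (flat zero command)
trace_sweep <- function(v, rate = 50000, stim_on = 0,
                        stim_off = length(v) * 1000 / rate) {
  dur <- length(v) * 1000 / rate
  new_sweep(1L, recorded = v, command = numeric(length(v)),
            sampling_rate = rate, clamp_mode = "current",
            segments = list(stim_segment("hold", 0, dur, 0)),
            amp = 0, stim_on = stim_on, stim_off = stim_off)
}

# Gaussian spike riding on a flat baseline
gaussian_spike_sweep <- function(baseline = -60, peak = 40, center = 20,
                                 sigma = 0.5, dur = 40, rate = 50000) {
  t <- seq(0, dur - 1000 / rate, by = 1000 / rate)
  v <- baseline + (peak - baseline) * exp(-((t - center)^2) / (2 * sigma^2))
  trace_sweep(v, rate)
}

# triangular spike with linear rise and fall; knot times fall on the grid
linear_spike_sweep <- function(base = -40, peak = 40, t_on = 10,
                               rise_ms = 1, fall_ms = 2, dur = 30,
                               rate = 50000) {
  t <- seq(0, dur - 1000 / rate, by = 1000 / rate)
  v <- rep(base, length(t))
  up <- t >= t_on & t < t_on + rise_ms
  v[up] <- base + (peak - base) * (t[up] - t_on) / rise_ms
  dn <- t >= t_on + rise_ms & t < t_on + rise_ms + fall_ms
  v[dn] <- peak - (peak - base) * (t[dn] - t_on - rise_ms) / fall_ms
  trace_sweep(v, rate)
}

# mono-exponential RC relaxation to a hyperpolarizing step
rc_sweep <- function(R_MOhm = 500, C_pF = 20, I_pA = -10, v0 = -60,
                     pre = 100, stim = 1000, post = 200, rate = 50000,
                     noise_sd = 0) {
  tau <- R_MOhm * C_pF / 1000      # ms
  dv <- R_MOhm * I_pA / 1000       # mV
  t <- seq(0, pre + stim + post - 1000 / rate, by = 1000 / rate)
  v <- rep(v0, length(t))
  on <- t >= pre & t < pre + stim
  v[on] <- v0 + dv * (1 - exp(-(t[on] - pre) / tau))
  off <- t >= pre + stim
  v_end <- v0 + dv * (1 - exp(-stim / tau))
  v[off] <- v0 + (v_end - v0) * exp(-(t[off] - pre - stim) / tau)
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
  cmd <- ifelse(on, I_pA, 0)
  new_sweep(1L, recorded = v, command = cmd, sampling_rate = rate,
            clamp_mode = "current",
            segments = list(stim_segment("hold", 0, pre, 0),
                            stim_segment("step", pre, pre + stim, I_pA),
                            stim_segment("hold", pre + stim, pre + stim + post, 0)),
            amp = I_pA, stim_on = pre, stim_off = pre + stim)
}

# a step-family sweep whose recording contains `n_spikes` Gaussian spikes
fake_step_sweep <- function(amp, n_spikes, first_at = 5, isi = 50,
                            rate = 50000, pre = 100, stim = 1000,
                            post = 200) {
  t <- seq(0, pre + stim + post - 1000 / rate, by = 1000 / rate)
  v <- rep(-60, length(t))
  if (n_spikes > 0) {
    centers <- pre + first_at + (seq_len(n_spikes) - 1) * isi
    for (cc in centers) v <- pmax(v, -60 + 100 * exp(-((t - cc)^2) / 0.5))
  }
  cmd <- ifelse(t >= pre & t < pre + stim, amp, 0)
  new_sweep(as.integer(amp / 10), recorded = v, command = cmd,
            sampling_rate = rate, clamp_mode = "current",
            segments = list(stim_segment("hold", 0, pre, 0),
                            stim_segment("step", pre, pre + stim, amp),
                            stim_segment("hold", pre + stim, pre + stim + post, 0)),
            amp = amp, stim_on = pre, stim_off = pre + stim)
}

# brute-force AP-count oracle: local maxima above 0 mV separated by >= 2 ms,
# restricted to the stimulus epoch
oracle_count <- function(sweep, min_sep_ms = 2) {
  v <- sweep$recorded
  dt <- 1000 / sweep$sampling_rate
  n <- length(v)
  pk <- which(v[-c(1, n)] > v[-c(n - 1, n)] & v[-c(1, n)] >= v[-c(1, 2)]) + 1L
  pk <- pk[v[pk] > 0]
  tms <- (pk - 1) * dt
  pk <- pk[tms >= sweep$stim_on & tms < sweep$stim_off]
  if (!length(pk)) return(0L)
  cnt <- 1L
  last <- (pk[1] - 1) * dt
  for (p in pk[-1]) {
    tp <- (p - 1) * dt
    if (tp - last >= min_sep_ms) { cnt <- cnt + 1L; last <- tp }
  }
  cnt
}

# hypergeometric enumeration oracle for the two-sided Fisher test
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  pr <- vapply(support, function(x)
    exp(lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1)), 0)
  p_obs <- pr[support == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
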