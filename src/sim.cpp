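// Single-compartment conductance-based model of a small-diameter DRG neuron.
//
// Units: mV, ms, pA, nS, pF, mM.  nS * mV = pA; pF * mV / ms = pA.
//
// Currents:
//   I_NaF  = g_naf * s * mf^3 * hf * (V - E_Na)   fast TTX-sensitive Na+
//   I_NaS  = g_nas * ms^3 * hs * (V - E_Na)       slow Na+ (AP shoulder; small
//                                                 non-inactivating window via hs floor)
//   I_Kdr  = g_kdr * n^4 * (V - E_K)              delayed rectifier
//   I_KA   = g_ka  * a * b * (V - E_K)            A-type (inactivating) K+
//   I_lK   = g_leakk  * (V - E_K)                 K-selective leak
//   I_lNS  = g_leakns * (V - E_leakns)            non-selective leak
//   I_ChR2 = g_chr2 * light(t) * V                light-gated, E_rev = 0 mV
//
// E_K = RT_over_F * ln(K_out / K_in) (Nernst), recomputed from concentrations
// on every call, never stored.
//
// The gate 's' is slow Na+ inactivation shared by the fast conductance; its
// floor s_min and time-constant scale tau_s_scale set the accommodation
// phenotype.  tau_b_scale stretches A-type inactivation (delayed phenotype).
//
// Integration: exponential Euler on V (unconditionally stable for the
// conductance form) and on every gate; additive membrane-voltage noise
// sigma * sqrt(dt) per substep, current clamp only.

#include <Rcpp.h>
using namespace Rcpp;

struct Params {
  double C_m;
  double g_naf, g_nas, g_kdr, g_ka, g_leakk, g_leakns, g_chr2;
  double E_na, E_leakns;
  double K_in, K_out, RT_over_F;
  double s_min, s_vh, tau_s_scale, tau_b_scale;
  double E_k; // derived
};

static Params unpack(const List& p) {
  Params q;
  q.C_m      = as<double>(p["C_m"]);
  q.g_naf    = as<double>(p["g_naf"]);
  q.g_nas    = as<double>(p["g_nas"]);
  q.g_kdr    = as<double>(p["g_kdr"]);
  q.g_ka     = as<double>(p["g_ka"]);
  q.g_leakk  = as<double>(p["g_leakk"]);
  q.g_leakns = as<double>(p["g_leakns"]);
  q.g_chr2   = as<double>(p["g_chr2"]);
  q.E_na     = as<double>(p["E_na"]);
  q.E_leakns = as<double>(p["E_leakns"]);
  q.K_in     = as<double>(p["K_in"]);
  q.K_out    = as<double>(p["K_out"]);
  q.RT_over_F= as<double>(p["RT_over_F"]);
  q.s_min    = as<double>(p["s_min"]);
  q.s_vh     = as<double>(p["s_vh"]);
  q.tau_s_scale = as<double>(p["tau_s_scale"]);
  q.tau_b_scale = as<double>(p["tau_b_scale"]);
  if (q.C_m <= 0) stop("C_m must be positive");
  if (q.K_in <= 0 || q.K_out <= 0) stop("K_in and K_out must be positive");
  if (q.g_naf < 0 || q.g_nas < 0 || q.g_kdr < 0 || q.g_ka < 0 ||
      q.g_leakk < 0 || q.g_leakns < 0 || q.g_chr2 < 0)
    stop("conductances must be non-negative");
  q.E_k = q.RT_over_F * std::log(q.K_out / q.K_in);
  return q;
}

static inline double boltz(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp((vh - v) / k));
}

// --- frozen gating kinetics -------------------------------------------------
// (documented in the methods vignette; regression-tested via gating_tables)

static inline double mf_inf(double v){ return boltz(v, -42.0, 5.0); }
static inline double mf_tau(double v){ return 0.05 + 0.25 / std::cosh((v + 42.0) / 15.0); }
static inline double hf_inf(double v){ return 0.007 + 0.993 / (1.0 + std::exp((v + 52.0) / 4.5)); }
static inline double hf_tau(double v){ return 0.4 + 3.0 / (1.0 + std::exp(-(v + 45.0) / 6.0)); }

static inline double s_inf(double v, double s_min, double s_vh){
  return s_min + (1.0 - s_min) / (1.0 + std::exp((v - s_vh) / 6.0));
}
static inline double s_tau(double v, double s_vh, double scl){
  // fast entry when depolarized, slow recovery near rest
  return scl * (8.0 + 420.0 / (1.0 + std::exp((v - s_vh - 10.0) / 6.0)));
}

static inline double ms_inf(double v){ return boltz(v, -15.0, 6.0); }
static inline double ms_tau(double v){ return 1.0 + 5.0 / std::cosh((v + 15.0) / 15.0); }
static inline double hs_inf(double v){
  return 0.16 + 0.84 / (1.0 + std::exp((v + 55.0) / 8.0));
}
static inline double hs_tau(double v){ return 6.0 + 40.0 / std::cosh((v + 55.0) / 15.0); }

static inline double n_inf(double v){ return boltz(v, -12.0, 9.0); }
static inline double n_tau(double v){ return 0.6 + 12.0 / std::cosh((v + 45.0) / 25.0); }

static inline double a_inf(double v){ return boltz(v, -34.0, 8.0); }
static inline double a_tau(double v){ return 4.0 + 3.0 / std::cosh((v + 34.0) / 15.0); }
static inline double b_inf(double v){ return 0.12 + 0.88 / (1.0 + std::exp((v + 65.0) / 6.0)); }
static inline double b_tau(double v, double scl){
  return scl * (25.0 + 150.0 / std::cosh((v + 65.0) / 20.0));
}

struct Gates { double mf, hf, s, ms, hs, n, a, b; };

static Gates gates_at_inf(double v, const Params& q) {
  Gates g;
  g.mf = mf_inf(v); g.hf = hf_inf(v); g.s = s_inf(v, q.s_min, q.s_vh);
  g.ms = ms_inf(v); g.hs = hs_inf(v);
  g.n = n_inf(v); g.a = a_inf(v); g.b = b_inf(v);
  return g;
}

static inline void step_gates(Gates& g, double v, double dt, const Params& q) {
  g.mf = mf_inf(v) + (g.mf - mf_inf(v)) * std::exp(-dt / mf_tau(v));
  g.hf = hf_inf(v) + (g.hf - hf_inf(v)) * std::exp(-dt / hf_tau(v));
  double si = s_inf(v, q.s_min, q.s_vh);
  g.s  = si + (g.s - si) * std::exp(-dt / s_tau(v, q.s_vh, q.tau_s_scale));
  g.ms = ms_inf(v) + (g.ms - ms_inf(v)) * std::exp(-dt / ms_tau(v));
  g.hs = hs_inf(v) + (g.hs - hs_inf(v)) * std::exp(-dt / hs_tau(v));
  g.n  = n_inf(v) + (g.n - n_inf(v)) * std::exp(-dt / n_tau(v));
  g.a  = a_inf(v) + (g.a - a_inf(v)) * std::exp(-dt / a_tau(v));
  double bi = b_inf(v);
  g.b  = bi + (g.b - bi) * std::exp(-dt / b_tau(v, q.tau_b_scale));
}

// per-channel conductances (nS) given gate state
static inline double cond_naf(const Gates& g, const Params& q) {
  return q.g_naf * g.s * g.mf * g.mf * g.mf * g.hf;
}
static inline double cond_nas(const Gates& g, const Params& q) {
  return q.g_nas * g.ms * g.ms * g.ms * g.hs;
}
static inline double cond_kdr(const Gates& g, const Params& q) {
  double n2 = g.n * g.n; return q.g_kdr * n2 * n2;
}
static inline double cond_ka(const Gates& g, const Params& q) {
  return q.g_ka * g.a * g.b;
}

// total ionic current (pA, outward positive) at voltage v
static inline double i_total(double v, const Gates& g, const Params& q, double light) {
  return cond_naf(g, q) * (v - q.E_na) +
         cond_nas(g, q) * (v - q.E_na) +
         cond_kdr(g, q) * (v - q.E_k) +
         cond_ka(g, q)  * (v - q.E_k) +
         q.g_leakk  * (v - q.E_k) +
         q.g_leakns * (v - q.E_leakns) +
         q.g_chr2 * light * v;
}

// [[Rcpp::export]]
NumericVector sim_cc_cpp(List params, NumericVector i_cmd, NumericVector light,
                         double dt_ms, int oversample, double v0,
                         double bias_pA, double settle_ms, double noise_sigma) {
  Params q = unpack(params);
  const int n = i_cmd.size();
  if (n == 0) stop("empty command");
  const bool has_light = light.size() > 0;
  if (has_light && light.size() != n) stop("light schedule length mismatch");
  if (oversample < 1) stop("oversample must be >= 1");
  const double dt = dt_ms / oversample;
  const double sq = noise_sigma * std::sqrt(dt);

  double v = v0;
  Gates g = gates_at_inf(v, q);
  NumericVector out(n);

  // settle under the pre-stimulus conditions so recorded samples start from
  // the model's own steady state (mirrors the experimenter's pause before
  // each sweep)
  int settle_n = (int)std::ceil(settle_ms / dt);
  double l0 = has_light ? light[0] : 0.0;
  for (int j = 0; j < settle_n; ++j) {
    double gtot = cond_naf(g, q) + cond_nas(g, q) + cond_kdr(g, q) +
                  cond_ka(g, q) + q.g_leakk + q.g_leakns + q.g_chr2 * l0;
    double drive = cond_naf(g, q) * q.E_na + cond_nas(g, q) * q.E_na +
                   cond_kdr(g, q) * q.E_k + cond_ka(g, q) * q.E_k +
                   q.g_leakk * q.E_k + q.g_leakns * q.E_leakns +
                   bias_pA + i_cmd[0];
    double vss = drive / gtot;
    v = vss + (v - vss) * std::exp(-gtot * dt / q.C_m);
    if (sq > 0) v += sq * norm_rand();
    step_gates(g, v, dt, q);
    if (!std::isfinite(v) || std::fabs(v) > 500.0)
      stop("integration blow-up during settle");
  }

  for (int k = 0; k < n; ++k) {
    out[k] = v;
    double lk = has_light ? light[k] : 0.0;
    for (int j = 0; j < oversample; ++j) {
      double gtot = cond_naf(g, q) + cond_nas(g, q) + cond_kdr(g, q) +
                    cond_ka(g, q) + q.g_leakk + q.g_leakns + q.g_chr2 * lk;
      double drive = cond_naf(g, q) * q.E_na + cond_nas(g, q) * q.E_na +
                     cond_kdr(g, q) * q.E_k + cond_ka(g, q) * q.E_k +
                     q.g_leakk * q.E_k + q.g_leakns * q.E_leakns +
                     bias_pA + i_cmd[k];
      double vss = drive / gtot;
      v = vss + (v - vss) * std::exp(-gtot * dt / q.C_m);
      if (sq > 0) v += sq * norm_rand();
      step_gates(g, v, dt, q);
      if (!std::isfinite(v) || std::fabs(v) > 500.0)
        stop("integration blow-up: non-finite membrane potential");
    }
  }
  return out;
}

// Ideal voltage clamp: V follows the command exactly, gates relax along it,
// recorded current is the sum of the channels selected by the mask.
// No series-resistance error and no capacitive transient (stated limitation).
// [[Rcpp::export]]
NumericVector sim_vc_cpp(List params, NumericVector v_cmd, double dt_ms,
                         int oversample, List mask, double settle_ms) {
  Params q = unpack(params);
  const int n = v_cmd.size();
  if (n == 0) stop("empty command");
  if (oversample < 1) stop("oversample must be >= 1");
  bool use_naf = as<bool>(mask["naf"]);
  bool use_nas = as<bool>(mask["nas"]);
  bool use_kdr = as<bool>(mask["kdr"]);
  bool use_ka  = as<bool>(mask["ka"]);
  bool use_leak= as<bool>(mask["leak"]);
  if (!(use_naf || use_nas || use_kdr || use_ka || use_leak))
    stop("empty channel mask");
  const double dt = dt_ms / oversample;

  double v = v_cmd[0];
  Gates g = gates_at_inf(v, q);
  int settle_n = (int)std::ceil(settle_ms / dt);
  for (int j = 0; j < settle_n; ++j) step_gates(g, v, dt, q);

  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    v = v_cmd[k];
    double i = 0.0;
    if (use_naf) i += cond_naf(g, q) * (v - q.E_na);
    if (use_nas) i += cond_nas(g, q) * (v - q.E_na);
    if (use_kdr) i += cond_kdr(g, q) * (v - q.E_k);
    if (use_ka)  i += cond_ka(g, q)  * (v - q.E_k);
    if (use_leak) i += q.g_leakk * (v - q.E_k) + q.g_leakns * (v - q.E_leakns);
    out[k] = i;
    for (int j = 0; j < oversample; ++j) step_gates(g, v, dt, q);
  }
  return out;
}

// Total steady-state ionic current at a clamped voltage (gates at x_inf),
// used to compute the holding bias and as an analytic fixed-point oracle.
// [[Rcpp::export]]
double steady_current_cpp(List params, double v, double light) {
  Params q = unpack(params);
  Gates g = gates_at_inf(v, q);
  return i_total(v, g, q, light);
}

// Steady-state gate values and time constants on a voltage grid.  This is the
// frozen-kinetics regression surface and the source for analytic gating
// oracles in tests.
// [[Rcpp::export]]
DataFrame gating_tables_cpp(NumericVector v, double s_min, double s_vh,
                            double tau_s_scale, double tau_b_scale) {
  int n = v.size();
  NumericVector mfi(n), mft(n), hfi(n), hft(n), si(n), st(n),
                msi(n), mst(n), hsi(n), hst(n), ni(n), nt(n),
                ai(n), at(n), bi(n), bt(n);
  for (int k = 0; k < n; ++k) {
    double x = v[k];
    mfi[k] = mf_inf(x); mft[k] = mf_tau(x);
    hfi[k] = hf_inf(x); hft[k] = hf_tau(x);
    si[k] = s_inf(x, s_min, s_vh); st[k] = s_tau(x, s_vh, tau_s_scale);
    msi[k] = ms_inf(x); mst[k] = ms_tau(x);
    hsi[k] = hs_inf(x); hst[k] = hs_tau(x);
    ni[k] = n_inf(x); nt[k] = n_tau(x);
    ai[k] = a_inf(x); at[k] = a_tau(x);
    bi[k] = b_inf(x); bt[k] = b_tau(x, tau_b_scale);
  }
  return DataFrame::create(
    _["v"] = v,
    _["mf_inf"] = mfi, _["mf_tau"] = mft,
    _["hf_inf"] = hfi, _["hf_tau"] = hft,
    _["s_inf"] = si,  _["s_tau"] = st,
    _["ms_inf"] = msi, _["ms_tau"] = mst,
    _["hs_inf"] = hsi, _["hs_tau"] = hst,
    _["n_inf"] = ni,  _["n_tau"] = nt,
    _["a_inf"] = ai,  _["a_tau"] = at,
    _["b_inf"] = bi,  _["b_tau"] = bt);
}
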