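// Core integrator for the l-ALT circuit: AdEx olfactory receptor neurons,
// conductance-based LIF antennal-lobe network (PN/LN/GIN) and lateral horn
// decision neuron, with event-driven iSTDP (LN->PN) and octopamine-modulated
// STDP (PN->LHN, LN->LN). Forward Euler at a fixed dt; all randomness comes
// from a counter-seeded xoshiro256++ stream so runs are bit-reproducible.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG -----

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline uint32_t next32() { return (uint32_t)(next() >> 32); }
  // uniform on (0, 1)
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// Marsaglia-Tsang ziggurat tables for the standard normal
struct Ziggurat {
  uint32_t kn[128];
  double wn[128], fn[128];
  Ziggurat() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};

static const Ziggurat ZIG;

inline double rnorm_zig(Xoshiro &rng) {
  for (;;) {
    const int32_t hz = (int32_t)rng.next32();
    const uint32_t iz = (uint32_t)hz & 127u;
    const uint32_t ahz = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
    if (ahz < ZIG.kn[iz]) return hz * ZIG.wn[iz];
    if (iz == 0) {
      // base strip: tail sampling
      double x, y;
      do {
        x = -std::log(rng.unif()) * 0.2904764463;  // 1/3.442619855899
        y = -std::log(rng.unif());
      } while (y + y < x * x);
      return hz > 0 ? 3.442619855899 + x : -3.442619855899 - x;
    }
    const double x = hz * ZIG.wn[iz];
    if (ZIG.fn[iz] + rng.unif() * (ZIG.fn[iz - 1] - ZIG.fn[iz]) <
        std::exp(-0.5 * x * x))
      return x;
  }
}

inline double clipw(double w, double lo, double hi) {
  return w < lo ? lo : (w > hi ? hi : w);
}

}  // namespace

// [[Rcpp::export]]
NumericVector zig_norm_cpp(int n, double seed) {
  Xoshiro rng((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rnorm_zig(rng);
  return out;
}

// ------------------------------------------------------------- runner -----

// [[Rcpp::export]]
List run_trials_cpp(List cfg, List conn, NumericMatrix drives, List sched,
                    IntegerVector snapshot_after, bool record_spikes,
                    bool record_u, bool orn_only, double seed) {
  // --- unpack configuration -----------------------------------------------
  const double dt = as<double>(cfg["dt"]);
  // AdEx (ORN)
  const double C_orn = as<double>(cfg["C_orn"]);
  const double gL = as<double>(cfg["gL"]);
  const double EL = as<double>(cfg["EL"]);
  const double DT = as<double>(cfg["DeltaT"]);
  const double VT = as<double>(cfg["VT"]);
  const double a_ad = as<double>(cfg["a_adapt"]);
  const double tau_w = as<double>(cfg["tau_w"]);
  const double b_ad = as<double>(cfg["b_adapt"]);
  const double v_reset = as<double>(cfg["v_reset"]);
  const double V_peak = as<double>(cfg["V_peak"]);
  const double sigma_orn = as<double>(cfg["sigma_orn"]);
  const double I_base = as<double>(cfg["I_base"]);
  const double w_init = as<double>(cfg["w_init"]);
  const int refrac_orn_steps =
      (int)std::lround(as<double>(cfg["refrac_orn"]) / dt);
  // LIF
  const double tau_pn = as<double>(cfg["tau_pn"]);
  const double tau_ln = as<double>(cfg["tau_ln"]);
  const double tau_gin = as<double>(cfg["tau_gin"]);
  const double tau_lhn = as<double>(cfg["tau_lhn"]);
  const double R_m = as<double>(cfg["R_m"]);
  const double Vth = as<double>(cfg["V_thresh"]);
  const double Vre = as<double>(cfg["V_reset_lif"]);
  const int refrac_steps = (int)std::lround(as<double>(cfg["refrac_lif"]) / dt);
  const double sigma_pn = as<double>(cfg["sigma_pn"]);
  const double sigma_ln = as<double>(cfg["sigma_ln"]);
  const double sigma_gin = as<double>(cfg["sigma_gin"]);
  const double sigma_lhn = as<double>(cfg["sigma_lhn"]);
  const double VE = as<double>(cfg["V_E"]);
  const double VI = as<double>(cfg["V_I"]);
  const double VgI = as<double>(cfg["V_gI"]);
  // synapse kinetics
  const double dE = std::exp(-dt / as<double>(cfg["tau_E"]));
  const double dI = std::exp(-dt / as<double>(cfg["tau_I"]));
  const double dG = std::exp(-dt / as<double>(cfg["tau_gin_syn"]));
  // plasticity
  const double eta = as<double>(cfg["eta"]);
  const double tau_istdp = as<double>(cfg["tau_istdp"]);
  const double rho0 = as<double>(cfg["rho0"]);  // Hz
  const double alpha = 2.0 * (rho0 / 1000.0) * tau_istdp;
  const double A_plus = as<double>(cfg["A_plus"]);
  const double A_minus = as<double>(cfg["A_minus"]);
  const double d_istdp = std::exp(-dt / tau_istdp);
  const double d_plus = std::exp(-dt / as<double>(cfg["tau_plus"]));
  const double d_minus = std::exp(-dt / as<double>(cfg["tau_minus"]));
  const double ln_ln_rate = as<double>(cfg["ln_ln_rate"]);
  const double A_plus_ll = A_plus * ln_ln_rate;
  const double A_minus_ll = A_minus * ln_ln_rate;
  const double d_oct = as<double>(cfg["d_oct"]);
  const double tau_d = as<double>(cfg["tau_d"]);
  const double us_drive = as<double>(cfg["us_drive_lhn"]);
  const bool strict_elig = as<double>(cfg["strict_eligibility"]) != 0.0;

  // --- connectome ----------------------------------------------------------
  const int n_g = as<int>(conn["n_glomeruli"]);
  const int per_type = as<int>(conn["orn_per_type"]);
  const int n_orn = n_g * per_type;
  NumericVector c_op = clone(as<NumericVector>(conn["c_orn_pn"]));
  NumericVector c_ol = clone(as<NumericVector>(conn["c_orn_ln"]));
  NumericMatrix c_lnpn = clone(as<NumericMatrix>(conn["c_ln_pn"]));
  NumericMatrix c_lnln = clone(as<NumericMatrix>(conn["c_ln_ln"]));
  NumericMatrix c_pnln = as<NumericMatrix>(conn["c_pn_ln"]);
  NumericVector c_pnlhn = clone(as<NumericVector>(conn["c_pn_lhn"]));
  const double c_ginpn = as<double>(conn["c_gin_pn"]);
  const double c_pngin = as<double>(conn["c_pn_gin"]);
  const double s_op = as<double>(conn["scale_orn_pn"]);
  const double s_ol = as<double>(conn["scale_orn_ln"]);
  const double s_lnpn = as<double>(conn["scale_ln_pn"]);
  const double s_lnln = as<double>(conn["scale_ln_ln"]);
  const double s_pnln = as<double>(conn["scale_pn_ln"]);
  const double s_pnlhn = as<double>(conn["scale_pn_lhn"]);
  const double wmax_lnpn = as<double>(conn["wmax_ln_pn"]);
  const double wmax_lnln = as<double>(conn["wmax_ln_ln"]);
  const double wmax_pnlhn = as<double>(conn["wmax_pn_lhn"]);

  // --- schedule ------------------------------------------------------------
  NumericVector onset_ms = sched["onset_ms"];
  NumericVector offset_ms = sched["offset_ms"];
  NumericVector length_ms = sched["length_ms"];
  IntegerVector rewarded = sched["rewarded"];
  NumericVector reward_ms = sched["reward_ms"];
  IntegerVector istdp_on = sched["istdp"];
  IntegerVector assoc_on = sched["assoc"];
  const int n_trials = onset_ms.size();

  Xoshiro rng((uint64_t)seed);

  // --- state ---------------------------------------------------------------
  std::vector<double> v_orn(n_orn), w_orn(n_orn);
  std::vector<int> ref_orn(n_orn);
  std::vector<double> u_pn(n_g), u_ln(n_g);
  std::vector<int> ref_pn(n_g), ref_ln(n_g);
  double u_gin = 0, u_lhn = 0;
  int ref_gin = 0, ref_lhn = 0;
  std::vector<double> gE_orn(n_g), gE_pn(n_g), gI_ln(n_g);
  double g_gin = 0;
  std::vector<double> xPN_i(n_g), xLN_i(n_g);        // iSTDP traces
  std::vector<double> xPN_p(n_g), xLN_p(n_g), xLN_m(n_g);  // STDP traces
  double xLHN_m = 0;
  std::vector<double> inc_gE_orn(n_g);
  std::vector<int> spk_pn(n_g), spk_ln(n_g);
  std::vector<double> sum_in(n_g), sum_exc(n_g), sum_ll(n_g);
  std::vector<double> drv(n_g), base_drv(n_g, I_base);

  // --- outputs -------------------------------------------------------------
  NumericMatrix r_orn(n_trials, n_g), r_pn(n_trials, n_g), r_ln(n_trials, n_g);
  NumericMatrix s_orn(n_trials, n_g), s_pn(n_trials, n_g), s_ln(n_trials, n_g);
  NumericVector r_lhn(n_trials), s_lhn(n_trials), r_gin(n_trials),
      s_gin(n_trials);
  std::vector<int> cnt_stim_orn(n_orn), cnt_pre_orn(n_orn);
  std::vector<int> cnt_stim(2 * n_g + 2), cnt_pre(2 * n_g + 2);
  List snaps_lnpn, snaps_lnln;
  std::vector<int> spk_trial, spk_pop, spk_id;
  std::vector<double> spk_t;
  std::vector<double> u_trace;
  int u_trace_steps = 0;

  std::vector<bool> snap_here(n_trials + 1, false);
  for (int i = 0; i < snapshot_after.size(); ++i) {
    int k = snapshot_after[i];
    if (k >= 0 && k <= n_trials) snap_here[k] = true;
  }
  if (snap_here[0]) {
    snaps_lnpn.push_back(clone(c_lnpn));
    snaps_lnln.push_back(clone(c_lnln));
  }

  const double inv_C = dt / C_orn;

  for (int tr = 0; tr < n_trials; ++tr) {
    const int steps = (int)std::lround(length_ms[tr] / dt);
    const int on_s = (int)std::lround(onset_ms[tr] / dt);
    const int off_s = (int)std::lround(offset_ms[tr] / dt);
    const bool istdp = istdp_on[tr] != 0;
    const bool assoc = assoc_on[tr] != 0;
    const bool rew = rewarded[tr] != 0;
    const double t_rew = reward_ms[tr];
    for (int k = 0; k < n_g; ++k) drv[k] = drives(tr, k);

    // fresh trial state (weights persist across trials)
    std::fill(v_orn.begin(), v_orn.end(), EL);
    std::fill(w_orn.begin(), w_orn.end(), w_init);
    std::fill(ref_orn.begin(), ref_orn.end(), 0);
    std::fill(u_pn.begin(), u_pn.end(), 0.0);
    std::fill(u_ln.begin(), u_ln.end(), 0.0);
    std::fill(ref_pn.begin(), ref_pn.end(), 0);
    std::fill(ref_ln.begin(), ref_ln.end(), 0);
    u_gin = u_lhn = 0;
    ref_gin = ref_lhn = 0;
    std::fill(gE_orn.begin(), gE_orn.end(), 0.0);
    std::fill(gE_pn.begin(), gE_pn.end(), 0.0);
    std::fill(gI_ln.begin(), gI_ln.end(), 0.0);
    g_gin = 0;
    std::fill(xPN_i.begin(), xPN_i.end(), 0.0);
    std::fill(xLN_i.begin(), xLN_i.end(), 0.0);
    std::fill(xPN_p.begin(), xPN_p.end(), 0.0);
    std::fill(xLN_p.begin(), xLN_p.end(), 0.0);
    std::fill(xLN_m.begin(), xLN_m.end(), 0.0);
    xLHN_m = 0;
    std::fill(cnt_stim_orn.begin(), cnt_stim_orn.end(), 0);
    std::fill(cnt_pre_orn.begin(), cnt_pre_orn.end(), 0);
    std::fill(cnt_stim.begin(), cnt_stim.end(), 0);
    std::fill(cnt_pre.begin(), cnt_pre.end(), 0);
    if (record_u && tr == 0) {
      u_trace.assign((size_t)steps * n_g, 0.0);
      u_trace_steps = steps;
    }

    for (int t = 0; t < steps; ++t) {
      const double tms = t * dt;
      const bool in_stim = (t >= on_s && t < off_s);
      const bool in_pre = (t < on_s);
      // decay conductances and traces
      for (int k = 0; k < n_g; ++k) {
        gE_orn[k] *= dE;
        gE_pn[k] *= dE;
        gI_ln[k] *= dI;
        xPN_i[k] *= d_istdp;
        xLN_i[k] *= d_istdp;
        xPN_p[k] *= d_plus;
        xLN_p[k] *= d_plus;
        xLN_m[k] *= d_minus;
      }
      g_gin *= dG;
      xLHN_m *= d_minus;
      std::fill(inc_gE_orn.begin(), inc_gE_orn.end(), 0.0);
      int n_spk_pn = 0, n_spk_ln = 0;
      bool lhn_spiked = false, gin_spiked = false;

      double fd = 1.0;
      if (assoc && rew && tms >= t_rew) {
        const double arg = (tms - t_rew) / tau_d;
        fd = strict_elig ? 1.0 + d_oct * std::exp(arg < 30.0 ? arg : 30.0)
                         : 1.0 + d_oct * std::exp(-arg);
      }

      // --- ORNs (AdEx) ---
      const double *Icur = in_stim ? drv.data() : base_drv.data();
      for (int i = 0; i < n_orn; ++i) {
        if (ref_orn[i] > 0) {
          --ref_orn[i];
          continue;
        }
        const int k = i / per_type;
        double v = v_orn[i];
        const double I = Icur[k] + sigma_orn * rnorm_zig(rng);
        const double arg = (v - VT) / DT;
        const double ex =
            arg > -8.0 ? gL * DT * std::exp(arg < 20.0 ? arg : 20.0) : 0.0;
        const double vn = v + inv_C * (-gL * (v - EL) + ex - w_orn[i] + I);
        w_orn[i] += dt / tau_w * (a_ad * (v - EL) - w_orn[i]);
        v = vn;
        if (v >= V_peak) {
          v = v_reset;
          w_orn[i] += b_ad;
          ref_orn[i] = refrac_orn_steps;
          inc_gE_orn[k] += 1.0;
          if (in_stim) ++cnt_stim_orn[i];
          else if (in_pre) ++cnt_pre_orn[i];
          if (record_spikes) {
            spk_trial.push_back(tr + 1);
            spk_pop.push_back(0);
            spk_id.push_back(i + 1);
            spk_t.push_back(tms);
          }
        }
        v_orn[i] = v;
      }

      if (!orn_only) {
        // --- PNs ---
        for (int i = 0; i < n_g; ++i) sum_in[i] = 0.0;
        for (int j = 0; j < n_g; ++j) {
          const double gj = gI_ln[j];
          if (gj > 1e-12) {
            const double *col = &c_lnpn(0, j);
            for (int i = 0; i < n_g; ++i) sum_in[i] += col[i] * gj;
          }
        }
        for (int i = 0; i < n_g; ++i) {
          if (record_u && tr == 0) u_trace[(size_t)t * n_g + i] = u_pn[i];
          if (ref_pn[i] > 0) {
            --ref_pn[i];
            continue;
          }
          double u = u_pn[i];
          const double I = s_op * c_op[i] * gE_orn[i] * (VE - u) +
                           s_lnpn * sum_in[i] * (VI - u) +
                           c_ginpn * g_gin * (VgI - u);
          u += dt / tau_pn * (-u + R_m * I) + sigma_pn * rnorm_zig(rng);
          if (u >= Vth) {
            u = Vre;
            ref_pn[i] = refrac_steps;
            spk_pn[n_spk_pn++] = i;
            if (in_stim) ++cnt_stim[i];
            else if (in_pre) ++cnt_pre[i];
            if (record_spikes) {
              spk_trial.push_back(tr + 1);
              spk_pop.push_back(1);
              spk_id.push_back(i + 1);
              spk_t.push_back(tms);
            }
          }
          u_pn[i] = u;
        }

        // --- LNs ---
        std::fill(sum_exc.begin(), sum_exc.end(), 0.0);
        std::fill(sum_ll.begin(), sum_ll.end(), 0.0);
        for (int j = 0; j < n_g; ++j) {
          const double ge = gE_pn[j];
          if (ge > 1e-12) {
            const double *col = &c_pnln(0, j);
            for (int i = 0; i < n_g; ++i) sum_exc[i] += col[i] * ge;
          }
          const double gi = gI_ln[j];
          if (gi > 1e-12) {
            const double *col = &c_lnln(0, j);
            for (int i = 0; i < n_g; ++i) sum_ll[i] += col[i] * gi;
          }
        }
        for (int i = 0; i < n_g; ++i) {
          if (ref_ln[i] > 0) {
            --ref_ln[i];
            continue;
          }
          double u = u_ln[i];
          const double I = s_ol * c_ol[i] * gE_orn[i] * (VE - u) +
                           s_pnln * sum_exc[i] * (VE - u) +
                           s_lnln * sum_ll[i] * (VI - u);
          u += dt / tau_ln * (-u + R_m * I) + sigma_ln * rnorm_zig(rng);
          if (u >= Vth) {
            u = Vre;
            ref_ln[i] = refrac_steps;
            spk_ln[n_spk_ln++] = i;
            if (in_stim) ++cnt_stim[n_g + i];
            else if (in_pre) ++cnt_pre[n_g + i];
            if (record_spikes) {
              spk_trial.push_back(tr + 1);
              spk_pop.push_back(2);
              spk_id.push_back(i + 1);
              spk_t.push_back(tms);
            }
          }
          u_ln[i] = u;
        }

        // --- GIN ---
        if (ref_gin > 0) {
          --ref_gin;
        } else {
          double sE = 0.0;
          for (int j = 0; j < n_g; ++j) sE += gE_pn[j];
          const double I = c_pngin * sE * (VE - u_gin);
          u_gin += dt / tau_gin * (-u_gin + R_m * I) +
                   sigma_gin * rnorm_zig(rng);
          if (u_gin >= Vth) {
            u_gin = Vre;
            ref_gin = refrac_steps;
            gin_spiked = true;
            if (in_stim) ++cnt_stim[2 * n_g];
            else if (in_pre) ++cnt_pre[2 * n_g];
            if (record_spikes) {
              spk_trial.push_back(tr + 1);
              spk_pop.push_back(3);
              spk_id.push_back(1);
              spk_t.push_back(tms);
            }
          }
        }

        // --- LHN ---
        if (ref_lhn > 0) {
          --ref_lhn;
        } else {
          double sE = 0.0;
          for (int j = 0; j < n_g; ++j) sE += c_pnlhn[j] * gE_pn[j];
          // sucrose reward (VUM-mx1) depolarizes the LHN during the US window
          const double I_us =
              (rew && tms >= t_rew && t < off_s) ? us_drive : 0.0;
          const double I = s_pnlhn * sE * (VE - u_lhn) + I_us;
          u_lhn += dt / tau_lhn * (-u_lhn + R_m * I) +
                   sigma_lhn * rnorm_zig(rng);
          if (u_lhn >= Vth) {
            u_lhn = Vre;
            ref_lhn = refrac_steps;
            lhn_spiked = true;
            if (in_stim) ++cnt_stim[2 * n_g + 1];
            else if (in_pre) ++cnt_pre[2 * n_g + 1];
            if (record_spikes) {
              spk_trial.push_back(tr + 1);
              spk_pop.push_back(4);
              spk_id.push_back(1);
              spk_t.push_back(tms);
            }
          }
        }

        // --- plasticity (traces hold spikes strictly before this step) ---
        if (istdp) {
          for (int s = 0; s < n_spk_pn; ++s) {  // post event: potentiation
            const int i = spk_pn[s];
            for (int j = 0; j < n_g; ++j) {
              if (j == i) continue;
              c_lnpn(i, j) = clipw(c_lnpn(i, j) + eta * xLN_i[j], 0.0,
                                   wmax_lnpn);
            }
          }
          for (int s = 0; s < n_spk_ln; ++s) {  // pre event: +/- around alpha
            const int j = spk_ln[s];
            for (int i = 0; i < n_g; ++i) {
              if (i == j) continue;
              c_lnpn(i, j) = clipw(c_lnpn(i, j) + eta * (xPN_i[i] - alpha),
                                   0.0, wmax_lnpn);
            }
          }
        }
        if (assoc) {
          if (lhn_spiked) {  // post at LHN: causal potentiation
            for (int j = 0; j < n_g; ++j)
              c_pnlhn[j] = clipw(c_pnlhn[j] + fd * A_plus * xPN_p[j], 0.0,
                                 wmax_pnlhn);
          }
          for (int s = 0; s < n_spk_pn; ++s) {  // pre at PN: anti-causal
            const int j = spk_pn[s];
            c_pnlhn[j] = clipw(c_pnlhn[j] + fd * A_minus * xLHN_m, 0.0,
                               wmax_pnlhn);
          }
          if (ln_ln_rate != 0.0) {
            for (int s = 0; s < n_spk_ln; ++s) {  // LN->LN modulated STDP
              const int i = spk_ln[s];
              for (int j = 0; j < n_g; ++j) {  // as post neuron
                if (j == i) continue;
                c_lnln(i, j) = clipw(c_lnln(i, j) + fd * A_plus_ll * xLN_p[j],
                                     0.0, wmax_lnln);
              }
              for (int k = 0; k < n_g; ++k) {  // as pre neuron
                if (k == i) continue;
                c_lnln(k, i) = clipw(c_lnln(k, i) + fd * A_minus_ll * xLN_m[k],
                                     0.0, wmax_lnln);
              }
            }
          }
        }

        // --- apply this step's spikes to conductances and traces ---
        for (int s = 0; s < n_spk_pn; ++s) {
          const int i = spk_pn[s];
          gE_pn[i] += 1.0;
          xPN_i[i] += 1.0;
          xPN_p[i] += 1.0;
        }
        for (int s = 0; s < n_spk_ln; ++s) {
          const int i = spk_ln[s];
          gI_ln[i] += 1.0;
          xLN_i[i] += 1.0;
          xLN_p[i] += 1.0;
          xLN_m[i] += 1.0;
        }
        if (gin_spiked) g_gin += 1.0;
        if (lhn_spiked) xLHN_m += 1.0;
      }
      for (int k = 0; k < n_g; ++k) gE_orn[k] += inc_gE_orn[k];
    }

    // --- per-trial rates ----------------------------------------------------
    const double stim_s = (off_s - on_s) * dt / 1000.0;
    const double pre_s = on_s * dt / 1000.0;
    for (int k = 0; k < n_g; ++k) {
      int cs = 0, cp = 0;
      for (int m = 0; m < per_type; ++m) {
        cs += cnt_stim_orn[k * per_type + m];
        cp += cnt_pre_orn[k * per_type + m];
      }
      r_orn(tr, k) = stim_s > 0 ? cs / (per_type * stim_s) : NA_REAL;
      s_orn(tr, k) = pre_s > 0 ? cp / (per_type * pre_s) : NA_REAL;
      r_pn(tr, k) = stim_s > 0 ? cnt_stim[k] / stim_s : NA_REAL;
      s_pn(tr, k) = pre_s > 0 ? cnt_pre[k] / pre_s : NA_REAL;
      r_ln(tr, k) = stim_s > 0 ? cnt_stim[n_g + k] / stim_s : NA_REAL;
      s_ln(tr, k) = pre_s > 0 ? cnt_pre[n_g + k] / pre_s : NA_REAL;
    }
    r_gin[tr] = stim_s > 0 ? cnt_stim[2 * n_g] / stim_s : NA_REAL;
    s_gin[tr] = pre_s > 0 ? cnt_pre[2 * n_g] / pre_s : NA_REAL;
    r_lhn[tr] = stim_s > 0 ? cnt_stim[2 * n_g + 1] / stim_s : NA_REAL;
    s_lhn[tr] = pre_s > 0 ? cnt_pre[2 * n_g + 1] / pre_s : NA_REAL;

    if (!std::isfinite(u_pn[0]) || !std::isfinite(u_lhn))
      stop("non-finite membrane potential at trial %d", tr + 1);

    if (snap_here[tr + 1]) {
      snaps_lnpn.push_back(clone(c_lnpn));
      snaps_lnln.push_back(clone(c_lnln));
    }
  }

  List out = List::create(
      _["rates_orn"] = r_orn, _["rates_pn"] = r_pn, _["rates_ln"] = r_ln,
      _["spont_orn"] = s_orn, _["spont_pn"] = s_pn, _["spont_ln"] = s_ln,
      _["rate_lhn"] = r_lhn, _["spont_lhn"] = s_lhn, _["rate_gin"] = r_gin,
      _["spont_gin"] = s_gin, _["snapshots_ln_pn"] = snaps_lnpn,
      _["snapshots_ln_ln"] = snaps_lnln,
      _["c_ln_pn"] = c_lnpn, _["c_ln_ln"] = c_lnln, _["c_pn_lhn"] = c_pnlhn);
  if (record_spikes) {
    out["spikes"] = DataFrame::create(
        _["trial"] = wrap(spk_trial), _["pop"] = wrap(spk_pop),
        _["neuron"] = wrap(spk_id), _["time_ms"] = wrap(spk_t));
  }
  if (record_u && u_trace_steps > 0) {
    NumericMatrix um(u_trace_steps, n_g);
    for (int t = 0; t < u_trace_steps; ++t)
      for (int i = 0; i < n_g; ++i) um(t, i) = u_trace[(size_t)t * n_g + i];
    out["u_pn_trace"] = um;
  }
  return out;
}
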