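// Implicit branched-cable integrator for the multicompartment
// conductance-based SNc dopaminergic neuron model.
//
// Voltage advances by a backward-Euler step: ionic conductances are frozen
// at the step's gate values, making the membrane current linear in V, and
// the resulting symmetric tree-structured system is solved exactly by Hines
// elimination (parents ordered before children). Gates then relax by the
// exact exponential update at the new voltage (first-order staggered
// scheme); shell calcium follows its linear decay ODE, also integrated
// exactly over the step. Unconditionally stable at dt = 0.02 ms.
//
// Units: mV, ms, uS, nA, nF, mM, um^3. Currents outward-positive.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double FARADAY = 96485.33212; // C/mol

static inline double boltz(double v, double v50, double k) {
  return 1.0 / (1.0 + std::exp(-(v - v50) / k));
}

static inline double tau_na_m(double v) {
  double x = (v + 20.0) / 30.0;
  return 0.01 + 0.33 / (1.0 + x * x);
}
static inline double tau_na_h(double v) {
  double x = (v + 50.0) / 8.0;
  return 0.7 + 16.0 / (1.0 + x * x);
}
static inline double tau_kdr_m(double v) {
  double x = v + 32.0;
  return 4.0 * std::exp(-0.000729 * x * x) + 4.0;
}
static inline double tau_h_m(double v) {
  double x = v / 11.06;
  return 556.0 + 1100.0 * std::exp(-0.5 * x * x);
}
static inline double tau_cal_m(double v) {
  double x = v + 39.26;
  double a;
  if (std::fabs(x) < 1e-7) a = 0.209 * 4.111;
  else a = -0.209 * x / std::expm1(-x / 4.111);
  return 1.0 / (a + 0.944 * std::exp(-(v + 15.38) / 224.1));
}

// [[Rcpp::export]]
List simulate_cable(IntegerVector parent, NumericVector cap_nF,
                    NumericVector g_axial_uS, NumericMatrix gmax_uS,
                    List kin, NumericVector ca_vol_um3,
                    double dt, int nsteps,
                    NumericMatrix stim, int stim_comp,
                    IntegerVector record, int ca_record,
                    Nullable<List> init_state, double v_init) {
  const int n = parent.size();
  const int GNA = 0, GKDR = 1, GA = 2, GH = 3, GCAL = 4, GSK = 5, GLEAK = 6;

  const double na_vm = kin["na_vm"], na_km = kin["na_km"];
  const double na_vh = kin["na_vh"], na_kh = kin["na_kh"];
  const double kdr_vm = kin["kdr_vm"], kdr_km = kin["kdr_km"];
  const double a_vm = kin["a_vm"], a_km = kin["a_km"];
  const double a_vh = kin["a_vh"], a_kh = kin["a_kh"];
  const double a_tau_m = kin["a_tau_m"], a_tau_h = kin["a_tau_h"];
  const double h_vm = kin["h_vm"], h_km = kin["h_km"];
  const double cal_vm = kin["cal_vm"], cal_km = kin["cal_km"];
  const double sk_kd = kin["sk_kd"];
  const double e_na = kin["erev_na"], e_kdr = kin["erev_kdr"];
  const double e_a = kin["erev_a"], e_h = kin["erev_h"];
  const double e_cal = kin["erev_cal"], e_sk = kin["erev_sk"];
  const double e_leak = kin["erev_leak"];
  const double ca_tau = kin["ca_tau"], ca0 = kin["ca_baseline"];
  const double ca_buffer = kin["ca_buffering"]; // free fraction of influx

  const double sk_kd4 = sk_kd * sk_kd * sk_kd * sk_kd;
  const double em_a = std::exp(-dt / a_tau_m);
  const double eh_a = std::exp(-dt / a_tau_h);
  const double e_ca = std::exp(-dt / ca_tau);

  // voltage lookup tables for steady states and per-step relaxation
  // factors exp(-dt/tau); 0.05 mV grid over the guarded voltage range,
  // linear interpolation (error << the 0.2 mV discretization of any
  // physiological feature)
  const double VMIN = -200.0, VMAX = 200.0, VSTEP = 0.05;
  const int NTAB = (int)((VMAX - VMIN) / VSTEP) + 1;
  std::vector<double> t_minf_na(NTAB), t_em_na(NTAB), t_hinf_na(NTAB),
      t_eh_na(NTAB), t_minf_kdr(NTAB), t_em_kdr(NTAB), t_minf_a(NTAB),
      t_hinf_a(NTAB), t_minf_h(NTAB), t_em_h(NTAB), t_minf_cal(NTAB),
      t_em_cal(NTAB);
  for (int j = 0; j < NTAB; j++) {
    const double vv = VMIN + j * VSTEP;
    t_minf_na[j] = boltz(vv, na_vm, na_km);
    t_em_na[j] = std::exp(-dt / tau_na_m(vv));
    t_hinf_na[j] = boltz(vv, na_vh, na_kh);
    t_eh_na[j] = std::exp(-dt / tau_na_h(vv));
    t_minf_kdr[j] = boltz(vv, kdr_vm, kdr_km);
    t_em_kdr[j] = std::exp(-dt / tau_kdr_m(vv));
    t_minf_a[j] = boltz(vv, a_vm, a_km);
    t_hinf_a[j] = boltz(vv, a_vh, a_kh);
    t_minf_h[j] = boltz(vv, h_vm, h_km);
    t_em_h[j] = std::exp(-dt / tau_h_m(vv));
    t_minf_cal[j] = boltz(vv, cal_vm, cal_km);
    t_em_cal[j] = std::exp(-dt / tau_cal_m(vv));
  }
  double tpos, tfrac; int tj; // table lookup scratch
  #define TABV(tab) (tab[tj] + tfrac * (tab[tj + 1] - tab[tj]))

  std::vector<double> v(n), ca(n, ca0);
  std::vector<double> m_na(n), h_na(n), m_kdr(n), m_a(n), h_a(n),
      m_h(n), m_cal(n);

  if (init_state.isNotNull()) {
    List st(init_state);
    NumericVector sv = st["v"], sca = st["ca"];
    NumericMatrix sg = st["gates"];
    if (sv.size() != n) stop("initial state size mismatch");
    for (int i = 0; i < n; i++) {
      v[i] = sv[i]; ca[i] = sca[i];
      m_na[i] = sg(i, 0); h_na[i] = sg(i, 1); m_kdr[i] = sg(i, 2);
      m_a[i] = sg(i, 3); h_a[i] = sg(i, 4); m_h[i] = sg(i, 5);
      m_cal[i] = sg(i, 6);
    }
  } else {
    for (int i = 0; i < n; i++) {
      v[i] = v_init;
      m_na[i] = boltz(v_init, na_vm, na_km);
      h_na[i] = boltz(v_init, na_vh, na_kh);
      m_kdr[i] = boltz(v_init, kdr_vm, kdr_km);
      m_a[i] = boltz(v_init, a_vm, a_km);
      h_a[i] = boltz(v_init, a_vh, a_kh);
      m_h[i] = boltz(v_init, h_vm, h_km);
      m_cal[i] = boltz(v_init, cal_vm, cal_km);
    }
  }

  const int nrec = record.size();
  NumericMatrix vout(nsteps + 1, nrec);
  NumericVector caout(ca_record > 0 ? nsteps + 1 : 0);
  for (int r = 0; r < nrec; r++) vout(0, r) = v[record[r] - 1];
  if (ca_record > 0) caout[0] = ca[ca_record - 1];

  std::vector<double> diag(n), rhs(n), cdt(n);
  for (int i = 0; i < n; i++) cdt[i] = cap_nF[i] / dt;
  const int nseg = stim.nrow();

  for (int step = 1; step <= nsteps; step++) {
    const double t = (step - 1) * dt; // stimulus evaluated over [t, t+dt)
    double inj = 0.0;
    for (int s = 0; s < nseg; s++) {
      if (t >= stim(s, 0) && t < stim(s, 0) + stim(s, 1)) inj += stim(s, 2);
    }

    for (int i = 0; i < n; i++) {
      double G = 0.0, GE = 0.0, g;
      g = gmax_uS(i, GNA) * m_na[i] * m_na[i] * m_na[i] * h_na[i];
      G += g; GE += g * e_na;
      double m2 = m_kdr[i] * m_kdr[i];
      g = gmax_uS(i, GKDR) * m2 * m2;
      G += g; GE += g * e_kdr;
      g = gmax_uS(i, GA) * m_a[i] * h_a[i];
      G += g; GE += g * e_a;
      g = gmax_uS(i, GH) * m_h[i];
      G += g; GE += g * e_h;
      g = gmax_uS(i, GCAL) * m_cal[i];
      G += g; GE += g * e_cal;
      double c4 = ca[i] * ca[i] * ca[i] * ca[i];
      g = gmax_uS(i, GSK) * (c4 / (c4 + sk_kd4));
      G += g; GE += g * e_sk;
      g = gmax_uS(i, GLEAK);
      G += g; GE += g * e_leak;
      diag[i] = cdt[i] + G;
      rhs[i] = cdt[i] * v[i] + GE;
    }
    if (stim_comp > 0) rhs[stim_comp - 1] += inj;

    // axial couplings (symmetric): A[i,p] = A[p,i] = -g_axial[i]
    for (int i = 1; i < n; i++) {
      diag[i] += g_axial_uS[i];
      diag[parent[i] - 1] += g_axial_uS[i];
    }
    // Hines elimination, leaves to root
    for (int i = n - 1; i >= 1; i--) {
      const int p = parent[i] - 1;
      const double f = g_axial_uS[i] / diag[i];
      diag[p] -= f * g_axial_uS[i];
      rhs[p] += f * rhs[i];
    }
    v[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; i++) {
      v[i] = (rhs[i] + g_axial_uS[i] * v[parent[i] - 1]) / diag[i];
    }

    // gates: exact exponential relaxation at the new voltage
    for (int i = 0; i < n; i++) {
      const double vi = v[i];
      if (!std::isfinite(vi) || std::fabs(vi) > 200.0) {
        stop("voltage diverged (|V| > 200 mV) at step %d, compartment %d",
             step, i + 1);
      }
      tpos = (vi - VMIN) / VSTEP;
      tj = (int)tpos;
      if (tj < 0) { tj = 0; tfrac = 0.0; }
      else if (tj >= NTAB - 1) { tj = NTAB - 2; tfrac = 1.0; }
      else tfrac = tpos - tj;
      double inf;
      inf = TABV(t_minf_na);
      m_na[i] = inf + (m_na[i] - inf) * TABV(t_em_na);
      inf = TABV(t_hinf_na);
      h_na[i] = inf + (h_na[i] - inf) * TABV(t_eh_na);
      inf = TABV(t_minf_kdr);
      m_kdr[i] = inf + (m_kdr[i] - inf) * TABV(t_em_kdr);
      inf = TABV(t_minf_a);
      m_a[i] = inf + (m_a[i] - inf) * em_a;
      inf = TABV(t_hinf_a);
      h_a[i] = inf + (h_a[i] - inf) * eh_a;
      inf = TABV(t_minf_h);
      m_h[i] = inf + (m_h[i] - inf) * TABV(t_em_h);
      inf = TABV(t_minf_cal);
      m_cal[i] = inf + (m_cal[i] - inf) * TABV(t_em_cal);

      // calcium: influx from the L-type current into a thin shell, plus
      // first-order decay to baseline, integrated exactly over the step
      if (ca_vol_um3[i] > 0.0 && gmax_uS(i, GCAL) > 0.0) {
        const double i_cal = gmax_uS(i, GCAL) * m_cal[i] * (vi - e_cal); // nA
        double flux = -i_cal * ca_buffer * 1e6 /
            (2.0 * FARADAY * ca_vol_um3[i]); // mM/ms
        if (flux < 0.0) flux = 0.0;
        const double ca_inf = ca0 + flux * ca_tau;
        ca[i] = ca_inf + (ca[i] - ca_inf) * e_ca;
      }
    }

    for (int r = 0; r < nrec; r++) vout(step, r) = v[record[r] - 1];
    if (ca_record > 0) caout[step] = ca[ca_record - 1];
  }

  NumericVector vfin(n), cafin(n);
  NumericMatrix gfin(n, 7);
  for (int i = 0; i < n; i++) {
    vfin[i] = v[i]; cafin[i] = ca[i];
    gfin(i, 0) = m_na[i]; gfin(i, 1) = h_na[i]; gfin(i, 2) = m_kdr[i];
    gfin(i, 3) = m_a[i]; gfin(i, 4) = h_a[i]; gfin(i, 5) = m_h[i];
    gfin(i, 6) = m_cal[i];
  }
  return List::create(_["v"] = vout, _["ca"] = caout,
                      _["state"] = List::create(_["v"] = vfin,
                                                _["gates"] = gfin,
                                                _["ca"] = cafin));
}
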