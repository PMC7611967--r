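// Semi-implicit integrator for the double-cable (axonal + periaxonal)
// compartmental model. Voltages advance by backward Euler on a pentadiagonal
// linear system (states interleaved along the chain: V_i, then U_i for
// myelinated segments); gating variables advance by exponential Euler at the
// pre-step voltage. The system is stiff (near-sealed paranodal periaxonal
// space), so the implicit voltage step is essential.
//
// Units: V, U in mV; conductances in mS; capacitances in uF; currents in uA;
// time in ms. With these units C dV/dt [uA] balances G*V [uA] directly.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double rate_linoid(double A, double V0, double k, double v) {
  double x = (v - V0) / k;
  if (std::fabs(x) < 1e-7) return A * k;
  return A * (v - V0) / (1.0 - std::exp(-x));
}
static inline double rate_linoid_neg(double A, double V0, double k, double v) {
  double x = (v - V0) / k;
  if (std::fabs(x) < 1e-7) return A * k;
  return A * (V0 - v) / (1.0 - std::exp(x));
}
static inline double rate_sigmoid(double A, double V0, double k, double v) {
  return A / (1.0 + std::exp((v - V0) / k));
}

// Pentadiagonal solve, in place, no pivoting (the system is diagonally
// dominant: C/dt plus positive conductances on the diagonal).
static void band_solve(int n, std::vector<double>& b0, std::vector<double>& b1,
                       std::vector<double>& b2, std::vector<double>& b3,
                       std::vector<double>& b4, std::vector<double>& rhs) {
  for (int i = 0; i < n; ++i) {
    double piv = b2[i];
    if (i + 1 < n && b1[i + 1] != 0.0) {
      double f = b1[i + 1] / piv;
      b2[i + 1] -= f * b3[i];
      b3[i + 1] -= f * b4[i];
      rhs[i + 1] -= f * rhs[i];
      b1[i + 1] = 0.0;
    }
    if (i + 2 < n && b0[i + 2] != 0.0) {
      double f = b0[i + 2] / piv;
      b1[i + 2] -= f * b3[i];
      b2[i + 2] -= f * b4[i];
      rhs[i + 2] -= f * rhs[i];
      b0[i + 2] = 0.0;
    }
  }
  for (int i = n - 1; i >= 0; --i) {
    double x = rhs[i];
    if (i + 1 < n) x -= b3[i] * rhs[i + 1];
    if (i + 2 < n) x -= b4[i] * rhs[i + 2];
    rhs[i] = x / b2[i];
  }
}

// [[Rcpp::export(name = ".cable_integrate")]]
List cable_integrate(List sys, NumericVector state0, NumericVector kin,
                     double dt, int nsteps, double t0,
                     IntegerVector stim_seg, NumericVector stim_on,
                     NumericVector stim_off, NumericVector stim_amp,
                     int record_stride, IntegerVector record_segs,
                     bool record_peri) {
  const IntegerVector is_myel = sys["is_myel"];
  const IntegerVector excitable = sys["excitable"];
  const NumericVector C = sys["C_uF"];
  const NumericVector gL = sys["gL_mS"];
  const NumericVector eL = sys["eL_mV"];
  const NumericVector Gnaf = sys["Gnaf_mS"];
  const NumericVector Gnap = sys["Gnap_mS"];
  const NumericVector Gks = sys["Gks_mS"];
  const NumericVector Gklt = sys["Gklt_mS"];
  const NumericVector Gihs = sys["Gihs_mS"];
  const NumericVector Gihi = sys["Gihi_mS"];
  const NumericVector Cmy = sys["Cmy_uF"];
  const NumericVector Gmy = sys["Gmy_mS"];
  const NumericVector gax = sys["gax_mS"];        // length n-1
  const NumericVector gpp = sys["gperi_pair_mS"]; // length n-1
  const NumericVector gpg = sys["gperi_ground_mS"];

  const int n = is_myel.size();
  // row layout: V_i, then U_i for myelinated i
  std::vector<int> rowV(n), rowU(n, -1);
  int ntot = 0;
  for (int i = 0; i < n; ++i) {
    rowV[i] = ntot++;
    if (is_myel[i]) rowU[i] = ntot++;
  }

  // state: V[n], U[n], gates m,h,p,s,w,qs,qi each [n]
  if (state0.size() != 9 * n) stop("state vector has wrong length");
  std::vector<double> V(n), U(n), m(n), h(n), p(n), s(n), w(n), qs(n), qi(n);
  for (int i = 0; i < n; ++i) {
    V[i] = state0[i];          U[i] = state0[n + i];
    m[i] = state0[2 * n + i];  h[i] = state0[3 * n + i];
    p[i] = state0[4 * n + i];  s[i] = state0[5 * n + i];
    w[i] = state0[6 * n + i];  qs[i] = state0[7 * n + i];
    qi[i] = state0[8 * n + i];
  }

  // kinetics constants (see defaultKinetics())
  const double maA = kin[0],  maV = kin[1],  mak = kin[2];
  const double mbA = kin[3],  mbV = kin[4],  mbk = kin[5];
  const double haA = kin[6],  haV = kin[7],  hak = kin[8];
  const double hbA = kin[9],  hbV = kin[10], hbk = kin[11];
  const double paA = kin[12], paV = kin[13], pak = kin[14];
  const double pbA = kin[15], pbV = kin[16], pbk = kin[17];
  const double saA = kin[18], saV = kin[19], sak = kin[20];
  const double sbA = kin[21], sbV = kin[22], sbk = kin[23];
  const double waA = kin[24], waV = kin[25], wak = kin[26];
  const double wbA = kin[27], wbV = kin[28], wbk = kin[29];
  const double eNa = kin[30], eK = kin[31], eH = kin[32];
  const double vhS = kin[33], vhI = kin[34], ihSlope = kin[35],
               ihTau = kin[36];

  const int nrecseg = record_segs.size();
  const int nrec = (record_stride > 0) ? (nsteps / record_stride + 1) : 0;
  NumericVector time_out(nrec);
  NumericMatrix V_out(nrec, nrecseg);
  NumericMatrix U_out(record_peri ? nrec : 0, record_peri ? nrecseg : 0);

  std::vector<double> b0(ntot), b1(ntot), b2(ntot), b3(ntot), b4(ntot),
      rhs(ntot);
  std::vector<double> Vprev(n), Uprev(n);

  int irec = 0;
  if (record_stride > 0) {
    time_out[0] = t0;
    for (int j = 0; j < nrecseg; ++j) {
      V_out(0, j) = V[record_segs[j]];
      if (record_peri) U_out(0, j) = U[record_segs[j]];
    }
    irec = 1;
  }

  const int nstim = stim_seg.size();
  double max_dvdt_last = 0.0;

  for (int step = 0; step < nsteps; ++step) {
    const double t = t0 + step * dt;

    // 1. gates by exponential Euler at V_n
    for (int i = 0; i < n; ++i) {
      if (!excitable[i]) continue;
      const double v = V[i];
      double a, b, tau, xinf, ef;
      if (Gnaf[i] > 0.0 || Gnap[i] > 0.0) {
        a = rate_linoid(maA, maV, mak, v);
        b = rate_linoid_neg(mbA, mbV, mbk, v);
        tau = 1.0 / (a + b); xinf = a * tau; ef = std::exp(-dt / tau);
        m[i] = xinf + (m[i] - xinf) * ef;
        a = rate_linoid_neg(haA, haV, hak, v);
        b = rate_sigmoid(hbA, hbV, hbk, v);
        tau = 1.0 / (a + b); xinf = a * tau; ef = std::exp(-dt / tau);
        h[i] = xinf + (h[i] - xinf) * ef;
        a = rate_linoid(paA, paV, pak, v);
        b = rate_linoid_neg(pbA, pbV, pbk, v);
        tau = 1.0 / (a + b); xinf = a * tau; ef = std::exp(-dt / tau);
        p[i] = xinf + (p[i] - xinf) * ef;
      }
      if (Gks[i] > 0.0) {
        a = rate_sigmoid(saA, saV, sak, v);
        b = rate_sigmoid(sbA, sbV, sbk, v);
        tau = 1.0 / (a + b); xinf = a * tau; ef = std::exp(-dt / tau);
        s[i] = xinf + (s[i] - xinf) * ef;
      }
      if (Gklt[i] > 0.0) {
        a = rate_sigmoid(waA, waV, wak, v);
        b = rate_sigmoid(wbA, wbV, wbk, v);
        tau = 1.0 / (a + b); xinf = a * tau; ef = std::exp(-dt / tau);
        w[i] = xinf + (w[i] - xinf) * ef;
      }
      if (Gihs[i] > 0.0) {
        xinf = 1.0 / (1.0 + std::exp((v - vhS) / ihSlope));
        ef = std::exp(-dt / ihTau);
        qs[i] = xinf + (qs[i] - xinf) * ef;
      }
      if (Gihi[i] > 0.0) {
        xinf = 1.0 / (1.0 + std::exp((v - vhI) / ihSlope));
        ef = std::exp(-dt / ihTau);
        qi[i] = xinf + (qi[i] - xinf) * ef;
      }
    }

    // 2. assemble banded system
    std::fill(b0.begin(), b0.end(), 0.0);
    std::fill(b1.begin(), b1.end(), 0.0);
    std::fill(b2.begin(), b2.end(), 0.0);
    std::fill(b3.begin(), b3.end(), 0.0);
    std::fill(b4.begin(), b4.end(), 0.0);
    std::fill(rhs.begin(), rhs.end(), 0.0);

    for (int i = 0; i < n; ++i) {
      const int rV = rowV[i];
      const double cdt = C[i] / dt;
      if (is_myel[i]) {
        const int rU = rowU[i];
        // intracellular KCL: C d(V-U)/dt + gL (V-U-eL) = axial + stim
        b2[rV] += cdt + gL[i];
        // coupling V_i -> U_i (offset -1 from rV's perspective of rU row;
        // rU = rV + 1 so in row rV the U_i column is rV+1 => b3)
        b3[rV] -= cdt + gL[i];
        rhs[rV] += cdt * (V[i] - U[i]) + gL[i] * eL[i];
        // periaxonal KCL
        b2[rU] += Cmy[i] / dt + Gmy[i] + cdt + gL[i] + gpg[i];
        b1[rU] -= cdt + gL[i]; // V_i column = rU - 1
        rhs[rU] += Cmy[i] / dt * U[i] - cdt * (V[i] - U[i]) - gL[i] * eL[i];
      } else {
        b2[rV] += cdt + gL[i];
        rhs[rV] += cdt * V[i] + gL[i] * eL[i];
        if (excitable[i]) {
          const double gnaf = Gnaf[i] * m[i] * m[i] * m[i] * h[i];
          const double gnap = Gnap[i] * p[i] * p[i] * p[i];
          const double gks = Gks[i] * s[i];
          const double gklt = Gklt[i] * w[i];
          const double gihs = Gihs[i] * qs[i];
          const double gihi = Gihi[i] * qi[i];
          b2[rV] += gnaf + gnap + gks + gklt + gihs + gihi;
          rhs[rV] += (gnaf + gnap) * eNa + (gks + gklt) * eK +
                     (gihs + gihi) * eH;
        }
      }
      // axial coupling to the right neighbour
      if (i + 1 < n) {
        const double g = gax[i];
        const int rW = rowV[i + 1];
        b2[rV] += g;
        b2[rW] += g;
        // column offsets
        if (rW - rV == 1) { b3[rV] -= g; b1[rW] -= g; }
        else              { b4[rV] -= g; b0[rW] -= g; }
        // periaxonal longitudinal coupling
        if (is_myel[i] && is_myel[i + 1] && gpp[i] > 0.0) {
          const int rU = rowU[i], rU2 = rowU[i + 1];
          b2[rU] += gpp[i];
          b2[rU2] += gpp[i];
          // rU2 - rU == 2 always (V_{i+1} sits between)
          b4[rU] -= gpp[i];
          b0[rU2] -= gpp[i];
        }
      }
    }

    // 3. stimulus
    for (int k = 0; k < nstim; ++k) {
      if (t >= stim_on[k] && t < stim_off[k]) {
        rhs[rowV[stim_seg[k]]] += stim_amp[k];
      }
    }

    // 4. solve and update
    Vprev = V; Uprev = U;
    band_solve(ntot, b0, b1, b2, b3, b4, rhs);
    for (int i = 0; i < n; ++i) {
      V[i] = rhs[rowV[i]];
      if (is_myel[i]) U[i] = rhs[rowU[i]];
      if (!std::isfinite(V[i]))
        stop("numerical divergence at step %d, segment %d", step + 1, i + 1);
    }

    if (step == nsteps - 1) {
      for (int i = 0; i < n; ++i) {
        double dv = std::fabs(V[i] - Vprev[i]) / dt;
        if (dv > max_dvdt_last) max_dvdt_last = dv;
        if (is_myel[i]) {
          double du = std::fabs(U[i] - Uprev[i]) / dt;
          if (du > max_dvdt_last) max_dvdt_last = du;
        }
      }
    }

    if (record_stride > 0 && ((step + 1) % record_stride == 0) &&
        irec < nrec) {
      time_out[irec] = t0 + (step + 1) * dt;
      for (int j = 0; j < nrecseg; ++j) {
        V_out(irec, j) = V[record_segs[j]];
        if (record_peri) U_out(irec, j) = U[record_segs[j]];
      }
      ++irec;
    }
  }

  NumericVector state(9 * n);
  for (int i = 0; i < n; ++i) {
    state[i] = V[i];          state[n + i] = U[i];
    state[2 * n + i] = m[i];  state[3 * n + i] = h[i];
    state[4 * n + i] = p[i];  state[5 * n + i] = s[i];
    state[6 * n + i] = w[i];  state[7 * n + i] = qs[i];
    state[8 * n + i] = qi[i];
  }
  return List::create(_["time"] = time_out, _["V"] = V_out, _["U"] = U_out,
                      _["state"] = state, _["max_dvdt"] = max_dvdt_last);
}
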