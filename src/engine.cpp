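// Time-stepping core of the spinal circuit simulator.
//
// Forward Euler at a fixed step for every state variable: Izhikevich neurons,
// muscle-cell RC circuits, and the damped-pendulum body segments. Gap-junction
// currents use the delayed presynaptic potential (delay = distance / cv);
// chemical synapses are event-triggered dual-exponential kernels whose clock
// is reset at each delayed upward crossing of the release threshold (renewal,
// single t0). Chemical currents are forced to zero during the initial
// settling window. Drive noise (sigma_d) multiplies the tonic command by a
// fresh Gaussian(1, sigma_d) draw per neuron per step, using R's RNG so that
// set.seed() governs the whole simulation.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Window { double start, end; };

static inline bool in_windows(const std::vector<Window>& ws, double t) {
  for (size_t i = 0; i < ws.size(); ++i)
    if (t >= ws[i].start && t < ws[i].end) return true;
  return false;
}

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(NumericMatrix neuron_params,   // n x 9: a b c d Vmax Vr Vt k C
                NumericVector drive_amp,
                NumericVector drive_onset,
                IntegerVector conn_pre,        // 1-based
                IntegerVector conn_post,
                IntegerVector conn_type,       // 0 gap, 1 glut, 2 gly
                NumericVector conn_weight,
                IntegerVector conn_delay_steps,
                IntegerVector musc_mn,         // 1-based source MN per muscle
                NumericVector musc_weight,
                double musc_R, double musc_C,
                double body_zeta, double body_omega0, double body_gain,
                double E_glut, double E_gly,
                double tau_r, double tau_f, double V_thr,
                double dt, double duration, double chem_off_ms,
                double sigma_d,
                int record_stride,
                bool record_V,
                NumericMatrix silence_windows, // neuron(1-based), start, end
                NumericMatrix block_windows,   // type(1 glut/2 gly), start, end
                bool silence_includes_gap,
                int gap_form,
                double nm_Vref) {
  // gap_form: 0 printed absolute, 1 difference, 2 rest-referenced deviation
  const int n = neuron_params.nrow();
  const int nc = conn_pre.size();
  const int nm = musc_mn.size();
  const int nsom = nm / 2;                 // left block then right block
  const int nsteps = (int) std::lround(duration / dt);
  if (nsteps <= 0) stop("duration must be positive");
  if (record_stride < 1) stop("record_stride must be >= 1");

  // unpack neuron parameters
  std::vector<double> a(n), b(n), cr(n), d(n), Vmax(n), Vr(n), Vt(n), k(n),
      Cm(n);
  for (int i = 0; i < n; ++i) {
    a[i] = neuron_params(i, 0); b[i] = neuron_params(i, 1);
    cr[i] = neuron_params(i, 2); d[i] = neuron_params(i, 3);
    Vmax[i] = neuron_params(i, 4); Vr[i] = neuron_params(i, 5);
    Vt[i] = neuron_params(i, 6); k[i] = neuron_params(i, 7);
    Cm[i] = neuron_params(i, 8);
  }

  // per-neuron silencing windows
  std::vector< std::vector<Window> > silw(n);
  for (int r = 0; r < silence_windows.nrow(); ++r) {
    int idx = (int) silence_windows(r, 0) - 1;
    if (idx < 0 || idx >= n) stop("silence window refers to unknown neuron");
    Window w; w.start = silence_windows(r, 1); w.end = silence_windows(r, 2);
    silw[idx].push_back(w);
  }
  std::vector<Window> blk_glut, blk_gly;
  for (int r = 0; r < block_windows.nrow(); ++r) {
    Window w; w.start = block_windows(r, 1); w.end = block_windows(r, 2);
    if ((int) block_windows(r, 0) == 1) blk_glut.push_back(w);
    else blk_gly.push_back(w);
  }
  bool any_sil = silence_windows.nrow() > 0;

  // history ring buffer for delayed potentials
  int maxdel = 0;
  for (int c = 0; c < nc; ++c)
    if (conn_delay_steps[c] > maxdel) maxdel = conn_delay_steps[c];
  const int HB = maxdel + 2;
  std::vector<double> hist((size_t) n * HB);
  std::vector<double> V(n), u(n, 0.0), V0(n);
  for (int i = 0; i < n; ++i) {
    V[i] = Vr[i]; V0[i] = Vr[i];
    for (int s = 0; s < HB; ++s) hist[(size_t) i * HB + s] = Vr[i];
  }

  // chemical kernel state per connection. The dual-exponential kernel is
  // normalized to unit peak so that the synaptic weight is the peak
  // conductance.
  const double ka = std::exp(-dt / tau_r), kb = std::exp(-dt / tau_f);
  double kscale = 1.0;
  if (tau_r != tau_f) {
    const double tpk = std::log(tau_f / tau_r) * tau_r * tau_f /
                       (tau_f - tau_r);
    kscale = 1.0 / (std::exp(-tpk / tau_f) - std::exp(-tpk / tau_r));
  }
  std::vector<double> A(nc, 0.0), B(nc, 0.0);
  std::vector<char> act(nc, 0);
  std::vector<int> pre0(nc), post0(nc);
  for (int c = 0; c < nc; ++c) { pre0[c] = conn_pre[c] - 1;
                                 post0[c] = conn_post[c] - 1; }

  // muscle + body state
  std::vector<double> Vm(nm, 0.0), Im(nm, 0.0);
  std::vector<double> Amus(nm, 0.0), Bmus(nm, 0.0);
  std::vector<char> actm(nm, 0);
  std::vector<double> th(nsom, 0.0), om(nsom, 0.0);

  // recording
  const int nrec = nsteps / record_stride + 1;
  NumericVector rec_t(nrec);
  NumericMatrix rec_V(record_V ? nrec : 1, record_V ? n : 1);
  NumericMatrix rec_Vm(nrec, nm), rec_Im(nrec, nm), rec_th(nrec, nsom);
  std::vector< std::vector<double> > spikes(n);

  rec_t[0] = 0.0;
  if (record_V) for (int i = 0; i < n; ++i) rec_V(0, i) = V[i];
  for (int m = 0; m < nm; ++m) { rec_Vm(0, m) = 0.0; rec_Im(0, m) = 0.0; }
  for (int q = 0; q < nsom; ++q) rec_th(0, q) = 0.0;
  int ri = 1;

  std::vector<double> Igap(n), Ichem(n);
  RNGScope rngscope;

  for (int s = 0; s < nsteps; ++s) {
    const double t = s * dt;
    const bool chem_on = (t >= chem_off_ms);
    const bool glut_blocked = in_windows(blk_glut, t);
    const bool gly_blocked = in_windows(blk_gly, t);
    const int slot_now = s % HB;

    std::fill(Igap.begin(), Igap.end(), 0.0);
    std::fill(Ichem.begin(), Ichem.end(), 0.0);

    for (int c = 0; c < nc; ++c) {
      const int ds = conn_delay_steps[c];
      const int idx = s - ds;
      const int p = pre0[c];
      const double vdel = idx < 0 ? V0[p]
                                  : hist[(size_t) p * HB + (idx % HB)];
      if (conn_type[c] == 0) {
        double drivev;
        if (gap_form == 1) drivev = vdel - V[post0[c]];
        else if (gap_form == 2) drivev = vdel - V0[p];
        else drivev = vdel;
        Igap[post0[c]] += conn_weight[c] * drivev;
      } else {
        if (act[c]) {
          A[c] *= ka; B[c] *= kb;
          if (B[c] < 1e-12) { act[c] = 0; A[c] = 0.0; B[c] = 0.0; }
        }
        const int idxp = idx - 1;
        const double vprev = idxp < 0 ? V0[p]
          : hist[(size_t) p * HB + (((idxp % HB) + HB) % HB)];
        if (vprev < V_thr && vdel >= V_thr) {
          A[c] = 1.0; B[c] = 1.0; act[c] = 1;
        }
        if (act[c] && chem_on) {
          const bool glut = conn_type[c] == 1;
          if ((glut && !glut_blocked) || (!glut && !gly_blocked)) {
            const double E = glut ? E_glut : E_gly;
            Ichem[post0[c]] += conn_weight[c] * (V[post0[c]] - E) *
                               (A[c] - B[c]) * kscale;
          }
        }
      }
    }

    // neuromuscular synapses (event kernel, fixed driving-force reference)
    for (int m = 0; m < nm; ++m) {
      if (actm[m]) {
        Amus[m] *= ka; Bmus[m] *= kb;
        if (Bmus[m] < 1e-12) { actm[m] = 0; Amus[m] = 0.0; Bmus[m] = 0.0; }
      }
      const int p = musc_mn[m] - 1;
      const double vnow = V[p];
      const int idxp = s - 1;
      const double vprev = idxp < 0 ? V0[p]
        : hist[(size_t) p * HB + (idxp % HB)];
      if (vprev < V_thr && vnow >= V_thr) {
        Amus[m] = 1.0; Bmus[m] = 1.0; actm[m] = 1;
      }
      Im[m] = (actm[m] && chem_on)
        ? musc_weight[m] * (nm_Vref - E_glut) * (Amus[m] - Bmus[m]) * kscale
        : 0.0;
    }

    // body segments forced by right-left muscle difference
    for (int q = 0; q < nsom; ++q) {
      const double F = body_gain * (Vm[nsom + q] - Vm[q]);
      const double th1 = th[q] + dt * om[q];
      const double om1 = om[q] + dt * (F - 2.0 * body_zeta * body_omega0 *
                                       om[q] - body_omega0 * body_omega0 *
                                       th[q]);
      th[q] = th1; om[q] = om1;
    }
    // muscle RC update (leak negative; input current from the MN kernel)
    for (int m = 0; m < nm; ++m)
      Vm[m] += dt * (-Vm[m] / (musc_R * musc_C) + Im[m] / musc_C);

    // neuron update
    const int slot_next = (s + 1) % HB;
    for (int i = 0; i < n; ++i) {
      double Idr = 0.0;
      if (drive_amp[i] > 0.0 && t >= drive_onset[i]) {
        double f = 1.0;
        if (sigma_d > 0.0) f += sigma_d * norm_rand();
        Idr = drive_amp[i] * f;
      }
      double Itot;
      if (any_sil && !silw[i].empty() && in_windows(silw[i], t)) {
        Itot = silence_includes_gap ? 0.0 : Igap[i];
      } else {
        Itot = Igap[i] + Ichem[i] + Idr;
      }
      const double dV = (k[i] * (V[i] - Vr[i]) * (V[i] - Vt[i]) - u[i] +
                         Itot) / Cm[i];
      const double du = a[i] * (b[i] * (V[i] - Vr[i]) - u[i]);
      double V1 = V[i] + dt * dV;
      double u1 = u[i] + dt * du;
      double vtrace;
      if (V1 >= Vmax[i]) {
        spikes[i].push_back((s + 1) * dt);
        vtrace = Vmax[i];
        V1 = cr[i];
        u1 += d[i];
      } else {
        vtrace = V1;
      }
      if (!std::isfinite(V1) || std::fabs(V1) > 1e5)
        stop("membrane potential diverged at t = %f ms (neuron %d)",
             t, i + 1);
      V[i] = V1; u[i] = u1;
      hist[(size_t) i * HB + slot_next] = vtrace;
    }
    (void) slot_now;

    if ((s + 1) % record_stride == 0 && ri < nrec) {
      rec_t[ri] = (s + 1) * dt;
      if (record_V)
        for (int i = 0; i < n; ++i)
          rec_V(ri, i) = hist[(size_t) i * HB + slot_next];
      for (int m = 0; m < nm; ++m) {
        rec_Vm(ri, m) = Vm[m]; rec_Im(ri, m) = Im[m];
      }
      for (int q = 0; q < nsom; ++q) rec_th(ri, q) = th[q];
      ++ri;
    }
  }

  List spk(n);
  for (int i = 0; i < n; ++i) spk[i] = NumericVector(spikes[i].begin(),
                                                     spikes[i].end());
  return List::create(
    _["time"] = rec_t,
    _["V"] = record_V ? rec_V : NumericMatrix(0, 0),
    _["spikes"] = spk,
    _["muscle_V"] = rec_Vm,
    _["muscle_I"] = rec_Im,
    _["theta"] = rec_th);
}
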