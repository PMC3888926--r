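// Compiled core of the six-area leaky-integrator network.
//
// State is updated synchronously: outputs are computed from the state at
// step t, net inputs are assembled from those outputs, the Hebbian rule is
// applied to the excitatory->excitatory weights using O(t) and V(t), and
// only then do the membrane potentials, adaptation averages and area-global
// averages take their Euler step.  Noise is drawn from R's RNG (all
// excitatory cells in index order, then all inhibitory cells), so whole
// trajectories are reproducible with set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct DynPar {
  double dt, tau, k1, k2, Vb, alpha, tauA, kS, tauS, g_inh;
  bool inh_baseline;
};

struct PlastPar {
  bool enabled;
  double dw, th_pre, th_plus, th_minus, w_max;
};

static DynPar read_dyn(const List& par) {
  DynPar p;
  p.dt = as<double>(par["dt"]);
  p.tau = as<double>(par["tau"]);
  p.k1 = as<double>(par["k1"]);
  p.k2 = as<double>(par["k2"]);
  p.Vb = as<double>(par["Vb"]);
  p.alpha = as<double>(par["alpha"]);
  p.tauA = as<double>(par["tauA"]);
  p.kS = as<double>(par["kS"]);
  p.tauS = as<double>(par["tauS"]);
  p.g_inh = as<double>(par["g_inh"]);
  p.inh_baseline = as<bool>(par["inh_baseline"]);
  return p;
}

static PlastPar read_plast(const List& par) {
  PlastPar p;
  p.enabled = as<bool>(par["enabled"]);
  p.dw = as<double>(par["delta_w"]);
  p.th_pre = as<double>(par["theta_pre"]);
  p.th_plus = as<double>(par["theta_plus"]);
  p.th_minus = as<double>(par["theta_minus"]);
  p.w_max = as<double>(par["w_max"]);
  return p;
}

static inline double exc_out(double v, double phi) {
  double o = v - phi;
  if (o <= 0.0) return 0.0;
  if (o >= 1.0) return 1.0;
  return o;
}

[[noreturn]] static void stop_nonfinite(int j, int n_cells, int rows,
                                        const char* layer) {
  int area = j / n_cells;
  int within = j % n_cells;
  int row = within % rows + 1;
  int col = within / rows + 1;
  stop("non-finite membrane input for %s cell: area %d, row %d, col %d",
       layer, area + 1, row, col);
}

// Runs n_steps of the network, mutating state (and, with plasticity, the
// weight slot Wx) in place.  Returns the summed excitatory output over the
// block.  If rec is non-null, row (rec_offset + t) receives the excitatory
// outputs used at step t (t = 0 .. n_steps-1).
static double run_block(const IntegerVector& Wp, const IntegerVector& Wi,
                        NumericVector& Wx,
                        const IntegerVector& Ep, const IntegerVector& Ei,
                        const NumericVector& Ex,
                        NumericVector& Ve, NumericVector& Vi,
                        NumericVector& om, NumericVector& omS,
                        const DynPar& P, const PlastPar& L,
                        int n_steps,
                        const IntegerVector& stim, double amp,
                        int stim_from, int stim_to,
                        NumericMatrix* rec, int rec_offset,
                        int n_cells, int n_areas, int rows) {
  const int n_e = Ve.size();
  const double ae = P.dt / P.tau;
  const double aA = P.dt / P.tauA;
  const double aS = P.dt / P.tauS;
  std::vector<double> Oe(n_e), Oi(n_e), vin_e(n_e), vin_i(n_e);
  std::vector<double> areaO(n_areas);
  std::vector<char> pre_act(n_e);
  double sum_out = 0.0;

  for (int t = 0; t < n_steps; ++t) {
    if ((t & 1023) == 0) checkUserInterrupt();
    // outputs at step t
    for (int j = 0; j < n_e; ++j) {
      Oe[j] = exc_out(Ve[j], P.alpha * om[j]);
      Oi[j] = Vi[j] > 0.0 ? Vi[j] : 0.0;
    }
    if (rec) {
      for (int j = 0; j < n_e; ++j) (*rec)(rec_offset + t, j) = Oe[j];
    }
    std::fill(areaO.begin(), areaO.end(), 0.0);
    for (int j = 0; j < n_e; ++j) {
      areaO[j / n_cells] += Oe[j];
      sum_out += Oe[j];
    }
    // net inputs
    const bool stim_on = amp != 0.0 && (t + 1) >= stim_from && (t + 1) <= stim_to;
    for (int j = 0; j < n_e; ++j) {
      double acc = P.Vb - P.kS * omS[j / n_cells] - P.g_inh * Oi[j];
      for (int k = Wp[j]; k < Wp[j + 1]; ++k) acc += Wx[k] * Oe[Wi[k]];
      vin_e[j] = acc;
    }
    if (stim_on) {
      for (int s = 0; s < stim.size(); ++s) vin_e[stim[s]] += amp;
    }
    const double inh_b = P.inh_baseline ? P.Vb : 0.0;
    for (int j = 0; j < n_e; ++j) {
      double acc = inh_b;
      for (int k = Ep[j]; k < Ep[j + 1]; ++k) acc += Ex[k] * Oe[Ei[k]];
      vin_i[j] = acc;
    }
    // Hebbian LTP/LTD on excitatory->excitatory links, using O(t) and V(t)
    if (L.enabled) {
      for (int j = 0; j < n_e; ++j) pre_act[j] = Oe[j] >= L.th_pre;
      for (int j = 0; j < n_e; ++j) {
        const double vpost = Ve[j];
        if (vpost < L.th_minus) continue;  // every branch is a no-op
        const bool hi = vpost >= L.th_plus;
        for (int k = Wp[j]; k < Wp[j + 1]; ++k) {
          double w = Wx[k];
          if (pre_act[Wi[k]]) {
            w += hi ? L.dw : -L.dw;
          } else if (hi) {
            w -= L.dw;
          } else {
            continue;
          }
          if (w < 0.0) w = 0.0; else if (w > L.w_max) w = L.w_max;
          Wx[k] = w;
        }
      }
    }
    // Euler integration (synchronous); noise: exc cells first, then inh
    for (int j = 0; j < n_e; ++j) {
      if (!R_finite(vin_e[j])) stop_nonfinite(j, n_cells, rows, "excitatory");
      const double eta = unif_rand() - 0.5;
      Ve[j] += ae * (-Ve[j] + P.k1 * (vin_e[j] + P.k2 * eta));
    }
    for (int j = 0; j < n_e; ++j) {
      if (!R_finite(vin_i[j])) stop_nonfinite(j, n_cells, rows, "inhibitory");
      const double eta = unif_rand() - 0.5;
      Vi[j] += ae * (-Vi[j] + P.k1 * (vin_i[j] + P.k2 * eta));
    }
    for (int j = 0; j < n_e; ++j) om[j] += aA * (-om[j] + Oe[j]);
    for (int a = 0; a < n_areas; ++a) omS[a] += aS * (-omS[a] + areaO[a]);
  }
  return sum_out;
}

static void refresh_outputs(NumericVector& Ve, NumericVector& Vi,
                            NumericVector& om, NumericVector& Oe,
                            NumericVector& Oi, const DynPar& P) {
  for (int j = 0; j < Ve.size(); ++j) {
    Oe[j] = exc_out(Ve[j], P.alpha * om[j]);
    Oi[j] = Vi[j] > 0.0 ? Vi[j] : 0.0;
  }
}

// [[Rcpp::export]]
List cpp_simulate(S4 W_ee, S4 W_ei,
                  NumericVector Ve, NumericVector Vi,
                  NumericVector om, NumericVector omS,
                  NumericVector Oe, NumericVector Oi,
                  List par, List plast,
                  int n_steps,
                  IntegerVector stim0, double stim_amp,
                  int stim_from, int stim_to,
                  bool record,
                  int n_cells, int n_areas, int rows) {
  DynPar P = read_dyn(par);
  PlastPar L = read_plast(plast);
  IntegerVector Wp = W_ee.slot("p"), Wi = W_ee.slot("i");
  NumericVector Wx = W_ee.slot("x");
  IntegerVector Ep = W_ei.slot("p"), Ei = W_ei.slot("i");
  NumericVector Ex = W_ei.slot("x");

  NumericMatrix rec;
  NumericMatrix* recp = nullptr;
  if (record) {
    rec = NumericMatrix(n_steps, Ve.size());
    recp = &rec;
  }
  double sum_out = run_block(Wp, Wi, Wx, Ep, Ei, Ex, Ve, Vi, om, omS,
                             P, L, n_steps, stim0, stim_amp,
                             stim_from, stim_to, recp, 0,
                             n_cells, n_areas, rows);
  refresh_outputs(Ve, Vi, om, Oe, Oi, P);
  List out = List::create(_["sum_out"] = sum_out);
  if (record) out["recording"] = rec;
  return out;
}

// Full training loop: alternating stimulus blocks (one pattern's P1 + M1
// cells driven for stim_steps) and inter-stimulus intervals, with
// plasticity on throughout.  Mutates Wx and the state vectors in place.
// [[Rcpp::export]]
List cpp_train(S4 W_ee, S4 W_ei,
               NumericVector Ve, NumericVector Vi,
               NumericVector om, NumericVector omS,
               NumericVector Oe, NumericVector Oi,
               List par, List plast,
               List pattern_cells,   // per pattern: 0-based global indices
               IntegerVector order,  // 1-based pattern id per presentation
               IntegerVector isi,    // ISI steps per presentation
               int stim_steps, double stim_amp,
               int n_cells, int n_areas, int rows) {
  DynPar P = read_dyn(par);
  PlastPar L = read_plast(plast);
  IntegerVector Wp = W_ee.slot("p"), Wi = W_ee.slot("i");
  NumericVector Wx = W_ee.slot("x");
  IntegerVector Ep = W_ei.slot("p"), Ei = W_ei.slot("i");
  NumericVector Ex = W_ei.slot("x");

  const int n_pres = order.size();
  if (isi.size() != n_pres) stop("order and isi lengths differ");
  std::vector<IntegerVector> pats(pattern_cells.size());
  for (int k = 0; k < pattern_cells.size(); ++k) {
    pats[k] = as<IntegerVector>(pattern_cells[k]);
  }
  const int nnz = Wx.size();
  NumericVector act_stim(n_pres), act_isi(n_pres), mean_w(n_pres);
  IntegerVector empty(0);

  for (int pr = 0; pr < n_pres; ++pr) {
    const int pid = order[pr] - 1;
    if (pid < 0 || pid >= (int)pats.size()) stop("pattern id out of range");
    act_stim[pr] = run_block(Wp, Wi, Wx, Ep, Ei, Ex, Ve, Vi, om, omS,
                             P, L, stim_steps, pats[pid], stim_amp,
                             1, stim_steps, nullptr, 0,
                             n_cells, n_areas, rows);
    act_isi[pr] = run_block(Wp, Wi, Wx, Ep, Ei, Ex, Ve, Vi, om, omS,
                            P, L, isi[pr], empty, 0.0, 0, 0, nullptr, 0,
                            n_cells, n_areas, rows);
    double s = 0.0;
    for (int k = 0; k < nnz; ++k) s += Wx[k];
    mean_w[pr] = s / nnz;
  }
  refresh_outputs(Ve, Vi, om, Oe, Oi, P);
  return List::create(_["act_stim"] = act_stim,
                      _["act_isi"] = act_isi,
                      _["mean_w"] = mean_w);
}
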