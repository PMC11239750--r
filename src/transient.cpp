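#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Pulsatile hyperemic simulation of a stenosed coronary tree coupled to
// five-element coronary-bed Windkessel models at every outlet.
//
// Per time step, the algebraic tree network and the Windkessel ODEs are
// coupled by fixed-point iteration until self-consistent:
//   1. damped Newton on the N outlet flows q for the tree network with the
//      current iterate of the Windkessel proximal pressures p1:
//        F_k(q) = p_out,k(q) - p1_k - Ra_k q_k = 0,
//      where p_out,k follows by marching pressures from the inlet and each
//      segment drop is R_lin q_s + K2 q_s |q_s| (viscous + turbulent lump);
//   2. trapezoidal (Crank-Nicolson) update of the two bed states per
//      outlet, with the LV-pressure increment applied exactly (closed-form
//      2x2 solve); the updated p1 feeds back into the network solve.
// The scheme is A-stable and second-order in dt. Cycles repeat until the
// cycle-mean distal pressure changes by less than `tol` (relative) or
// `max_cycles` is reached.

static void solve_dense(std::vector<double>& A, std::vector<double>& b, int n) {
  // Gaussian elimination with partial pivoting; A is n x n row-major.
  for (int col = 0; col < n; ++col) {
    int piv = col;
    double best = std::fabs(A[col * n + col]);
    for (int r = col + 1; r < n; ++r) {
      double v = std::fabs(A[r * n + col]);
      if (v > best) { best = v; piv = r; }
    }
    if (best == 0.0) stop("singular Jacobian in transient network solve");
    if (piv != col) {
      for (int c = 0; c < n; ++c) std::swap(A[col * n + c], A[piv * n + c]);
      std::swap(b[col], b[piv]);
    }
    for (int r = col + 1; r < n; ++r) {
      double f = A[r * n + col] / A[col * n + col];
      if (f == 0.0) continue;
      for (int c = col; c < n; ++c) A[r * n + c] -= f * A[col * n + c];
      b[r] -= f * b[col];
    }
  }
  for (int r = n - 1; r >= 0; --r) {
    double s = b[r];
    for (int c = r + 1; c < n; ++c) s -= A[r * n + c] * b[c];
    b[r] = s / A[r * n + r];
  }
}

struct NetEval {
  std::vector<double> q_seg, p_dist;
  double p_d, p_les;
};

// [[Rcpp::export]]
List transient_kernel(IntegerVector parent,       // 1-based, 0 for root
                      NumericVector R_lin,        // per-segment linear resistance
                      NumericVector K2,           // per-segment quadratic lump
                      IntegerVector outlet_seg,   // 1-based segment per outlet
                      IntegerMatrix inc,          // S x N path incidence
                      NumericVector Ra, NumericVector Ram, NumericVector Rd,
                      NumericVector Ca, NumericVector Cmyo,
                      double p_v, double dt,
                      NumericVector pa_cycle,     // inlet pressure at step ends
                      NumericVector plv_cycle,    // LV pressure at step ends
                      int max_cycles, double tol,
                      int meas_seg, double meas_R, double meas_K2,
                      int lesion_seg,
                      NumericVector p1_init, NumericVector p2_init,
                      NumericVector q_init,
                      double newton_tol = 1e-8, int newton_max = 60) {
  const int S = parent.size();
  const int N = outlet_seg.size();
  const int spc = pa_cycle.size();
  if (plv_cycle.size() != spc) stop("waveform sample lengths differ");

  std::vector<double> q(N), p1(N), p2(N);
  for (int k = 0; k < N; ++k) {
    q[k] = q_init[k]; p1[k] = p1_init[k]; p2[k] = p2_init[k];
  }

  NetEval ev;
  ev.q_seg.resize(S);
  ev.p_dist.resize(S);

  auto eval_net = [&](const std::vector<double>& qq, double pa) {
    for (int s = 0; s < S; ++s) ev.q_seg[s] = 0.0;
    for (int s = 0; s < S; ++s)
      for (int k = 0; k < N; ++k)
        if (inc(s, k)) ev.q_seg[s] += qq[k];
    for (int s = 0; s < S; ++s) {
      double pp = (parent[s] == 0) ? pa : ev.p_dist[parent[s] - 1];
      double qs = ev.q_seg[s];
      ev.p_dist[s] = pp - (R_lin[s] * qs + K2[s] * qs * std::fabs(qs));
    }
    int m = meas_seg - 1;
    double ppm = (parent[m] == 0) ? pa : ev.p_dist[parent[m] - 1];
    double qm = ev.q_seg[m];
    ev.p_d = ppm - meas_R * qm - meas_K2 * qm * std::fabs(qm);
    int l = lesion_seg - 1;
    ev.p_les = (parent[l] == 0) ? pa : ev.p_dist[parent[l] - 1];
  };

  const int max_steps = max_cycles * spc;
  NumericVector out_pa(max_steps), out_pd(max_steps), out_ples(max_steps),
      out_qin(max_steps);
  NumericMatrix out_qk(max_steps, N);

  std::vector<double> F(N), Fn(N), qn(N), A(N * N), rhs(N);
  std::vector<double> p_out_prev(N), p1_old(N), p2_old(N), p1_it(N);
  double prev_cycle_mean = NA_REAL;
  bool converged = false;
  int cycles_done = 0, steps_done = 0;

  // previous-step outlet pressures start from the (steady) initial state
  for (int k = 0; k < N; ++k) p_out_prev[k] = p1[k] + Ra[k] * q[k];

  auto newton_flows = [&](double pa, const std::vector<double>& p1_bc) {
    // damped Newton for F_k(q) = p_out,k(q) - p1_bc_k - Ra_k q_k = 0
    auto res = [&](const std::vector<double>& qq, std::vector<double>& FF) {
      eval_net(qq, pa);
      double worst = 0.0;
      for (int k = 0; k < N; ++k) {
        FF[k] = ev.p_dist[outlet_seg[k] - 1] - p1_bc[k] - Ra[k] * qq[k];
        worst = std::max(worst, std::fabs(FF[k]));
      }
      return worst;
    };
    double worst = res(q, F);
    for (int it = 0; it < newton_max && worst > newton_tol; ++it) {
      for (int k = 0; k < N; ++k)
        for (int j = 0; j < N; ++j) {
          double sum = 0.0;
          for (int s = 0; s < S; ++s)
            if (inc(s, k) && inc(s, j))
              sum += R_lin[s] + 2.0 * K2[s] * std::fabs(ev.q_seg[s]);
          A[k * N + j] = -sum - (k == j ? Ra[k] : 0.0);
        }
      for (int k = 0; k < N; ++k) rhs[k] = -F[k];
      solve_dense(A, rhs, N);
      double lambda = 1.0;
      while (true) {
        for (int k = 0; k < N; ++k) qn[k] = q[k] + lambda * rhs[k];
        double wn = res(qn, Fn);
        if (wn < worst || lambda < 1e-6) {
          q = qn; F = Fn; worst = wn;
          break;
        }
        lambda *= 0.5;
      }
    }
    eval_net(q, pa);  // leave ev consistent with accepted q
  };

  for (int cyc = 0; cyc < max_cycles && !converged; ++cyc) {
    double pd_sum = 0.0;
    for (int k_step = 0; k_step < spc; ++k_step) {
      double pa = pa_cycle[k_step];
      double plv_prev = plv_cycle[(k_step - 1 + spc) % spc];
      double plv = plv_cycle[k_step];

      for (int k = 0; k < N; ++k) {
        p1_old[k] = p1[k]; p2_old[k] = p2[k]; p1_it[k] = p1[k];
      }

      // fixed-point coupling of network solve and trapezoidal bed update
      for (int pass = 0; pass < 12; ++pass) {
        newton_flows(pa, p1_it);
        double change = 0.0;
        for (int k = 0; k < N; ++k) {
          double p_out = ev.p_dist[outlet_seg[k] - 1];
          double ca_dt = Ca[k] / dt, cm_dt = Cmyo[k] / dt;
          double flux1_old = (p_out_prev[k] - p1_old[k]) / Ra[k] -
                             (p1_old[k] - p2_old[k]) / Ram[k];
          double flux2_old = (p1_old[k] - p2_old[k]) / Ram[k] -
                             (p2_old[k] - p_v) / Rd[k];
          double a11 = ca_dt + 0.5 / Ra[k] + 0.5 / Ram[k];
          double a12 = -0.5 / Ram[k];
          double a21 = -0.5 / Ram[k];
          double a22 = cm_dt + 0.5 / Ram[k] + 0.5 / Rd[k];
          double b1 = ca_dt * p1_old[k] + 0.5 * p_out / Ra[k] +
                      0.5 * flux1_old;
          double b2 = cm_dt * p2_old[k] + 0.5 * p_v / Rd[k] +
                      0.5 * flux2_old + cm_dt * (plv - plv_prev);
          double det = a11 * a22 - a12 * a21;
          double p1n = (b1 * a22 - a12 * b2) / det;
          double p2n = (a11 * b2 - a21 * b1) / det;
          change = std::max(change, std::fabs(p1n - p1_it[k]));
          p1_it[k] = p1n; p2[k] = p2n;
        }
        if (change < 1e-10) break;
      }
      newton_flows(pa, p1_it);  // final network state at the converged p1
      for (int k = 0; k < N; ++k) {
        p1[k] = p1_it[k];
        p_out_prev[k] = ev.p_dist[outlet_seg[k] - 1];
      }

      double qin = 0.0;
      for (int k = 0; k < N; ++k) qin += q[k];
      out_pa[steps_done] = pa;
      out_pd[steps_done] = ev.p_d;
      out_ples[steps_done] = ev.p_les;
      out_qin[steps_done] = qin;
      for (int k = 0; k < N; ++k) out_qk(steps_done, k) = q[k];
      pd_sum += ev.p_d;
      ++steps_done;
    }
    ++cycles_done;
    double cycle_mean = pd_sum / spc;
    if (cyc > 0 &&
        std::fabs(cycle_mean - prev_cycle_mean) <=
            tol * std::max(std::fabs(cycle_mean), 1e-12))
      converged = true;
    prev_cycle_mean = cycle_mean;
  }

  return List::create(
      _["p_a"] = out_pa[Range(0, steps_done - 1)],
      _["p_d"] = out_pd[Range(0, steps_done - 1)],
      _["p_lesion_prox"] = out_ples[Range(0, steps_done - 1)],
      _["q_in"] = out_qin[Range(0, steps_done - 1)],
      _["q_out"] = out_qk(Range(0, steps_done - 1), _),
      _["n_cycles"] = cycles_done,
      _["converged"] = converged,
      _["p1"] = NumericVector(p1.begin(), p1.end()),
      _["p2"] = NumericVector(p2.begin(), p2.end()));
}
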