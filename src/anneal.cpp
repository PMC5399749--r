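// Simulated-annealing search over hard partitions, minimising the
// penalised classification-likelihood objective
//   O = -2 L + k * lambda,  k = (M-1) + M*n_r + 2*M*n_e,
// where L is the classification log-likelihood under per-cluster ML
// estimates. Candidate moves are evaluated against per-cluster sufficient
// statistics (counts, binary column sums, continuous sums and sums of
// squares) without mutating the state; only accepted moves are applied.
// A rejected REASSIGN/MERGE/NEW costs O(n_r + n_e); a rejected SPLIT costs
// O(cluster size * (n_r + n_e)) to accumulate one half's statistics.
// All randomness comes from R's RNG stream, so runs are reproducible
// under set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

inline int rand_int(int n) { // uniform on 0..n-1 from R's stream
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct State {
  int N, nr, ne;
  const double *Rb; // N x nr, column-major
  const double *E;  // N x ne, column-major
  double p_floor, s_floor;
  int M;
  std::vector<int> z;          // 0-based cluster per entity
  std::vector<int> size;
  std::vector<double> sum_r;   // cluster-major blocks of length nr
  std::vector<double> sum_e;   // length ne
  std::vector<double> sum_e2;  // length ne
  std::vector<double> term;    // cached per-cluster log-lik contribution
  double L;

  inline double rb(int i, int j) const { return Rb[i + (size_t)N * j]; }
  inline double ee(int i, int l) const { return E[i + (size_t)N * l]; }

  // log-likelihood contribution of a cluster given raw sufficient stats,
  // including its n * log(n / N) mixing term
  double term_from(int n, const double *sr, const double *se,
                   const double *se2) const {
    if (n == 0) return 0.0;
    double t = n * (std::log((double)n) - std::log((double)N));
    for (int j = 0; j < nr; ++j) {
      double cnt = sr[j];
      double p = cnt / n;
      if (p < p_floor) p = p_floor;
      if (p > 1 - p_floor) p = 1 - p_floor;
      t += cnt * std::log(p) + (n - cnt) * std::log(1 - p);
    }
    for (int l = 0; l < ne; ++l) {
      double mu = se[l] / n;
      double var = se2[l] / n - mu * mu;
      if (var < 0) var = 0;
      double sd = std::sqrt(var);
      if (sd < s_floor) sd = s_floor;
      t += -0.5 * n * std::log(2.0 * M_PI) - n * std::log(sd)
           - 0.5 * n * var / (sd * sd);
    }
    return t;
  }

  double *sr(int c) { return &sum_r[(size_t)c * nr]; }
  double *se(int c) { return &sum_e[(size_t)c * ne]; }
  double *se2(int c) { return &sum_e2[(size_t)c * ne]; }

  void add_point(int i, int c, int sign) {
    size[c] += sign;
    double *a = sr(c);
    for (int j = 0; j < nr; ++j) a[j] += sign * rb(i, j);
    double *b = se(c), *b2 = se2(c);
    for (int l = 0; l < ne; ++l) {
      double v = ee(i, l);
      b[l] += sign * v;
      b2[l] += sign * v * v;
    }
  }

  void ensure_capacity(int m) {
    if ((int)size.size() < m) {
      size.resize(m, 0);
      term.resize(m, 0.0);
      sum_r.resize((size_t)m * nr, 0.0);
      sum_e.resize((size_t)m * ne, 0.0);
      sum_e2.resize((size_t)m * ne, 0.0);
    }
  }

  // remove empty cluster c, swapping in the last cluster; L is unchanged
  // (the emptied slot contributes 0, the swapped cluster keeps its term)
  void drop_cluster(int c) {
    int last = M - 1;
    if (c != last) {
      for (int i = 0; i < N; ++i) if (z[i] == last) z[i] = c;
      size[c] = size[last];
      term[c] = term[last];
      std::copy(sr(last), sr(last) + nr, sr(c));
      std::copy(se(last), se(last) + ne, se(c));
      std::copy(se2(last), se2(last) + ne, se2(c));
    }
    size[last] = 0;
    term[last] = 0.0;
    std::fill(sr(last), sr(last) + nr, 0.0);
    std::fill(se(last), se(last) + ne, 0.0);
    std::fill(se2(last), se2(last) + ne, 0.0);
    --M;
  }

  double objective(double lam) const {
    double k = (M - 1) + (double)M * nr + 2.0 * (double)M * ne;
    return -2.0 * L + k * lam;
  }

  void rebuild() { // full recomputation, cancels incremental drift
    std::fill(size.begin(), size.end(), 0);
    std::fill(sum_r.begin(), sum_r.end(), 0.0);
    std::fill(sum_e.begin(), sum_e.end(), 0.0);
    std::fill(sum_e2.begin(), sum_e2.end(), 0.0);
    for (int i = 0; i < N; ++i) add_point(i, z[i], +1);
    L = 0.0;
    for (int c = 0; c < M; ++c) {
      term[c] = term_from(size[c], sr(c), se(c), se2(c));
      L += term[c];
    }
  }

  void init(const IntegerVector &z0) {
    M = 0;
    for (int i = 0; i < N; ++i) M = std::max(M, z0[i]);
    z.assign(z0.begin(), z0.end());
    for (int i = 0; i < N; ++i) --z[i];
    ensure_capacity(M);
    rebuild();
  }
};

struct Scratch { // candidate-cluster stat buffers
  std::vector<double> r1, e1, e21, r2, e2_, e22;
  void init(int nr, int ne) {
    r1.resize(nr); e1.resize(ne); e21.resize(ne);
    r2.resize(nr); e2_.resize(ne); e22.resize(ne);
  }
};

// buf <- cluster stats of c, with point i added (sign=+1) or removed (-1)
void point_adjusted(const State &s, int c, int i, int sign,
                    std::vector<double> &r, std::vector<double> &e,
                    std::vector<double> &e2) {
  const double *a = &s.sum_r[(size_t)c * s.nr];
  for (int j = 0; j < s.nr; ++j) r[j] = a[j] + sign * s.rb(i, j);
  const double *b = &s.sum_e[(size_t)c * s.ne];
  const double *b2 = &s.sum_e2[(size_t)c * s.ne];
  for (int l = 0; l < s.ne; ++l) {
    double v = s.ee(i, l);
    e[l] = b[l] + sign * v;
    e2[l] = b2[l] + sign * v * v;
  }
}

} // namespace

// [[Rcpp::export(name = ".anneal_core")]]
List anneal_core(NumericMatrix Rb, NumericMatrix E, IntegerVector z0,
                 double lam, double p_floor, double sigma_floor,
                 double t_init, double t_final, double cooling,
                 int moves_per_temp, int max_no_improve) {
  State s;
  s.N = Rb.nrow();
  s.nr = Rb.ncol();
  s.ne = E.ncol();
  s.Rb = Rb.begin();
  s.E = E.begin();
  s.p_floor = p_floor;
  s.s_floor = sigma_floor;
  s.init(z0);

  const double k_per = 1.0 + s.nr + 2.0 * s.ne; // params per extra cluster
  double cur = s.objective(lam);
  double best = cur;
  std::vector<int> best_z = s.z;
  int best_M = s.M;

  Scratch sc;
  sc.init(s.nr, s.ne);
  std::vector<int> members; members.reserve(s.N);
  std::vector<char> is_mover(s.N, 0);

  std::vector<double> tr_t, tr_cur, tr_best;
  std::vector<int> tr_m;
  long long n_moves = 0, n_accept = 0;

  int levels_no_improve = 0;
  for (double T = t_init; T >= t_final; T *= cooling) {
    bool improved = false;
    for (int step = 0; step < moves_per_temp; ++step) {
      if (s.N < 2) break;
      int mv;
      for (;;) { // resample until an applicable move type is drawn
        mv = rand_int(4);
        if (mv == 0 && s.M >= 2) break;            // REASSIGN
        if (mv == 1 && s.M < s.N) break;           // SPLIT
        if (mv == 2 && s.M >= 2) break;            // MERGE
        if (mv == 3 && s.M < s.N) break;           // NEW
      }
      ++n_moves;
      double dL = 0.0, dO = 0.0;
      bool applied = false;

      if (mv == 0) { // REASSIGN entity i: cluster c -> existing cluster t
        int i = rand_int(s.N);
        int c = s.z[i];
        int t = rand_int(s.M - 1);
        if (t >= c) ++t;
        point_adjusted(s, c, i, -1, sc.r1, sc.e1, sc.e21);
        point_adjusted(s, t, i, +1, sc.r2, sc.e2_, sc.e22);
        double term_c = s.term_from(s.size[c] - 1, sc.r1.data(),
                                    sc.e1.data(), sc.e21.data());
        double term_t = s.term_from(s.size[t] + 1, sc.r2.data(),
                                    sc.e2_.data(), sc.e22.data());
        dL = term_c + term_t - s.term[c] - s.term[t];
        int dM = (s.size[c] == 1) ? -1 : 0;
        dO = -2.0 * dL + dM * k_per * lam;
        if (dO <= 0 || unif_rand() < std::exp(-dO / T)) {
          s.add_point(i, c, -1);
          s.add_point(i, t, +1);
          s.term[c] = term_c;
          s.term[t] = term_t;
          s.z[i] = t;
          s.L += dL;
          if (s.size[c] == 0) s.drop_cluster(c);
          applied = true;
        }
      } else if (mv == 1) { // SPLIT a cluster of size >= 2 at random
        int c = rand_int(s.M);
        while (s.size[c] < 2) c = rand_int(s.M);
        members.clear();
        for (int i = 0; i < s.N; ++i) if (s.z[i] == c) members.push_back(i);
        int nc = (int)members.size();
        int stay = rand_int(nc);
        int go = rand_int(nc - 1);
        if (go >= stay) ++go;
        // movers -> new cluster; both halves guaranteed non-empty
        int n_mov = 0;
        for (int t = 0; t < nc; ++t) {
          bool mov = (t == go) ? true
                   : (t == stay) ? false
                   : (unif_rand() < 0.5);
          is_mover[members[t]] = mov;
          if (mov) ++n_mov;
        }
        std::fill(sc.r2.begin(), sc.r2.end(), 0.0);
        std::fill(sc.e2_.begin(), sc.e2_.end(), 0.0);
        std::fill(sc.e22.begin(), sc.e22.end(), 0.0);
        for (int t = 0; t < nc; ++t) {
          int i = members[t];
          if (!is_mover[i]) continue;
          for (int j = 0; j < s.nr; ++j) sc.r2[j] += s.rb(i, j);
          for (int l = 0; l < s.ne; ++l) {
            double v = s.ee(i, l);
            sc.e2_[l] += v;
            sc.e22[l] += v * v;
          }
        }
        const double *cr = &s.sum_r[(size_t)c * s.nr];
        const double *ce = &s.sum_e[(size_t)c * s.ne];
        const double *ce2 = &s.sum_e2[(size_t)c * s.ne];
        for (int j = 0; j < s.nr; ++j) sc.r1[j] = cr[j] - sc.r2[j];
        for (int l = 0; l < s.ne; ++l) {
          sc.e1[l] = ce[l] - sc.e2_[l];
          sc.e21[l] = ce2[l] - sc.e22[l];
        }
        double term_a = s.term_from(nc - n_mov, sc.r1.data(), sc.e1.data(),
                                    sc.e21.data());
        double term_b = s.term_from(n_mov, sc.r2.data(), sc.e2_.data(),
                                    sc.e22.data());
        dL = term_a + term_b - s.term[c];
        dO = -2.0 * dL + k_per * lam;
        if (dO <= 0 || unif_rand() < std::exp(-dO / T)) {
          int newc = s.M;
          s.ensure_capacity(newc + 1);
          ++s.M;
          std::copy(sc.r1.begin(), sc.r1.end(), s.sr(c));
          std::copy(sc.e1.begin(), sc.e1.end(), s.se(c));
          std::copy(sc.e21.begin(), sc.e21.end(), s.se2(c));
          std::copy(sc.r2.begin(), sc.r2.end(), s.sr(newc));
          std::copy(sc.e2_.begin(), sc.e2_.end(), s.se(newc));
          std::copy(sc.e22.begin(), sc.e22.end(), s.se2(newc));
          s.size[c] = nc - n_mov;
          s.size[newc] = n_mov;
          s.term[c] = term_a;
          s.term[newc] = term_b;
          for (int t = 0; t < nc; ++t) {
            int i = members[t];
            if (is_mover[i]) s.z[i] = newc;
          }
          s.L += dL;
          applied = true;
        }
        for (int t = 0; t < nc; ++t) is_mover[members[t]] = 0;
      } else if (mv == 2) { // MERGE clusters a <- b
        int a = rand_int(s.M);
        int b = rand_int(s.M - 1);
        if (b >= a) ++b;
        const double *ar = &s.sum_r[(size_t)a * s.nr];
        const double *br = &s.sum_r[(size_t)b * s.nr];
        for (int j = 0; j < s.nr; ++j) sc.r1[j] = ar[j] + br[j];
        const double *ae = &s.sum_e[(size_t)a * s.ne];
        const double *be = &s.sum_e[(size_t)b * s.ne];
        const double *ae2 = &s.sum_e2[(size_t)a * s.ne];
        const double *be2 = &s.sum_e2[(size_t)b * s.ne];
        for (int l = 0; l < s.ne; ++l) {
          sc.e1[l] = ae[l] + be[l];
          sc.e21[l] = ae2[l] + be2[l];
        }
        double term_m = s.term_from(s.size[a] + s.size[b], sc.r1.data(),
                                    sc.e1.data(), sc.e21.data());
        dL = term_m - s.term[a] - s.term[b];
        dO = -2.0 * dL - k_per * lam;
        if (dO <= 0 || unif_rand() < std::exp(-dO / T)) {
          for (int i = 0; i < s.N; ++i) if (s.z[i] == b) s.z[i] = a;
          std::copy(sc.r1.begin(), sc.r1.end(), s.sr(a));
          std::copy(sc.e1.begin(), sc.e1.end(), s.se(a));
          std::copy(sc.e21.begin(), sc.e21.end(), s.se2(a));
          s.size[a] += s.size[b];
          s.size[b] = 0;
          s.term[a] = term_m;
          s.term[b] = 0.0;
          std::fill(s.sr(b), s.sr(b) + s.nr, 0.0);
          std::fill(s.se(b), s.se(b) + s.ne, 0.0);
          std::fill(s.se2(b), s.se2(b) + s.ne, 0.0);
          s.L += dL;
          s.drop_cluster(b);
          applied = true;
        }
      } else { // NEW: entity i leaves a cluster of size >= 2 for a fresh
               // singleton cluster
        int i = rand_int(s.N);
        while (s.size[s.z[i]] < 2) i = rand_int(s.N);
        int c = s.z[i];
        point_adjusted(s, c, i, -1, sc.r1, sc.e1, sc.e21);
        double term_c = s.term_from(s.size[c] - 1, sc.r1.data(),
                                    sc.e1.data(), sc.e21.data());
        for (int j = 0; j < s.nr; ++j) sc.r2[j] = s.rb(i, j);
        for (int l = 0; l < s.ne; ++l) {
          double v = s.ee(i, l);
          sc.e2_[l] = v;
          sc.e22[l] = v * v;
        }
        double term_s = s.term_from(1, sc.r2.data(), sc.e2_.data(),
                                    sc.e22.data());
        dL = term_c + term_s - s.term[c];
        dO = -2.0 * dL + k_per * lam;
        if (dO <= 0 || unif_rand() < std::exp(-dO / T)) {
          int newc = s.M;
          s.ensure_capacity(newc + 1);
          ++s.M;
          s.add_point(i, c, -1);
          s.add_point(i, newc, +1);
          s.term[c] = term_c;
          s.term[newc] = term_s;
          s.z[i] = newc;
          s.L += dL;
          applied = true;
        }
      }

      if (applied) {
        ++n_accept;
        cur = s.objective(lam);
        if (cur < best - 1e-12) { // strict improvement; first-found wins ties
          best = cur;
          best_z = s.z;
          best_M = s.M;
          improved = true;
        }
      }
    }
    s.rebuild();
    cur = s.objective(lam);
    tr_t.push_back(T);
    tr_cur.push_back(cur);
    tr_best.push_back(best);
    tr_m.push_back(s.M);
    if (improved) levels_no_improve = 0; else ++levels_no_improve;
    if (levels_no_improve >= max_no_improve) break;
  }

  IntegerVector out_z(s.N);
  for (int i = 0; i < s.N; ++i) out_z[i] = best_z[i] + 1;
  return List::create(
    _["assignment"] = out_z,
    _["n_clusters"] = best_M,
    _["best_objective"] = best,
    _["trace"] = DataFrame::create(
      _["temperature"] = tr_t,
      _["current_objective"] = tr_cur,
      _["best_objective"] = tr_best,
      _["n_clusters"] = tr_m),
    _["n_moves"] = (double)n_moves,
    _["n_accepted"] = (double)n_accept);
}
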