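#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Event-driven structured coalescent for the 2+2(+outgroup pair) sample.
// Populations (backwards in time): 0 = population 1, absorbing the ancestral
// population at t_split and the root population at t_out; 1 = population 2
// (exists for s < t_split); 2 = outgroup (exists for s < t_out).
// Sizes are diploid; a pair of chromosomes coalesces at rate 1/(2N) per
// generation. All waiting times are continuous-time exponentials.

namespace {

struct Lin {
  int d1, d2, dout, pop;
  double birth;
};

struct Demog {
  double N1, N2, Na, t_split, lambda, tau_b, phi;
  bool has_out;
  double t_out, N_out, N_root;

  // ancestral size schedule, backwards from the split:
  // Na for phi generations, lambda*Na for tau_b, then Na (N_root past t_out)
  double anc_size(double s) const {
    if (has_out && s >= t_out) return N_root;
    if (s < t_split + phi) return Na;
    if (s < t_split + phi + tau_b) return lambda * Na;
    return Na;
  }
  double pop_size(int pop, double s) const {
    if (pop == 0) return (s < t_split) ? N1 : anc_size(s);
    if (pop == 1) return N2;
    return N_out;
  }
};

}  // namespace

// [[Rcpp::export]]
List sim_batch_cpp(int R, double N1, double N2, double Na, double t_split,
                   double lambda, double tau_b, double phi, double gamma,
                   double delta, int recipient, int donor, bool has_out,
                   double t_out, double N_out, double N_root) {
  Demog dem{N1, N2, Na, t_split, lambda, tau_b, phi,
            has_out, t_out, N_out, N_root};

  std::vector<double> bnd;
  if (gamma > 0.0 && delta > 0.0) bnd.push_back(delta);
  bnd.push_back(t_split);
  if (lambda != 1.0 && tau_b > 0.0) {
    bnd.push_back(t_split + phi);
    bnd.push_back(t_split + phi + tau_b);
  }
  if (has_out) bnd.push_back(t_out);
  std::sort(bnd.begin(), bnd.end());

  // per-configuration branch-length accumulators (index d1 + 3*d2 + 9*dout)
  std::vector<double> acc(27, 0.0), acc2(27, 0.0), lrep(27, 0.0);
  double tot_len_acc = 0.0;
  int n_h1 = 0, n_h2 = 0;
  const int rec_pop = recipient - 1;
  const int don_pop = donor - 1;

  for (int rep = 0; rep < R; ++rep) {
    std::fill(lrep.begin(), lrep.end(), 0.0);
    std::vector<Lin> lv;
    lv.reserve(6);
    lv.push_back({1, 0, 0, 0, 0.0});
    lv.push_back({1, 0, 0, 0, 0.0});
    lv.push_back({0, 1, 0, 1, 0.0});
    lv.push_back({0, 1, 0, 1, 0.0});
    if (has_out) {
      lv.push_back({0, 0, 1, 2, 0.0});
      lv.push_back({0, 0, 1, 2, 0.0});
    }

    double s = 0.0;
    double t_pair1 = -1.0, t_pair2 = -1.0;
    bool mig_done = !(gamma > 0.0);
    if (!mig_done && delta <= 0.0) {
      for (auto &l : lv)
        if (l.pop == rec_pop && R::unif_rand() < gamma) l.pop = don_pop;
      mig_done = true;
    }

    size_t bi = 0;
    while (lv.size() > 1) {
      double nb = (bi < bnd.size()) ? bnd[bi] : R_PosInf;
      int cnt[3] = {0, 0, 0};
      for (auto &l : lv) ++cnt[l.pop];
      double rate[3], total = 0.0;
      for (int p = 0; p < 3; ++p) {
        double k = cnt[p];
        rate[p] = (k >= 2) ? k * (k - 1.0) / (4.0 * dem.pop_size(p, s)) : 0.0;
        total += rate[p];
      }
      double w = (total > 0.0) ? R::exp_rand() / total : R_PosInf;
      if (s + w >= nb) {
        s = nb;
        ++bi;
        if (!mig_done && nb == delta) {
          for (auto &l : lv)
            if (l.pop == rec_pop && R::unif_rand() < gamma) l.pop = don_pop;
          mig_done = true;
        }
        if (nb == t_split)
          for (auto &l : lv)
            if (l.pop == 1) l.pop = 0;
        if (has_out && nb == t_out)
          for (auto &l : lv)
            if (l.pop == 2) l.pop = 0;
        continue;
      }
      s += w;
      double u = R::unif_rand() * total;
      int p = (u < rate[0]) ? 0 : ((u < rate[0] + rate[1]) ? 1 : 2);
      int k = cnt[p];
      int ia = (int)(R::unif_rand() * k);
      if (ia >= k) ia = k - 1;
      int ib = (int)(R::unif_rand() * (k - 1));
      if (ib >= k - 1) ib = k - 2;
      if (ib >= ia) ++ib;
      int idx_a = -1, idx_b = -1, seen = 0;
      for (int i = 0; i < (int)lv.size(); ++i) {
        if (lv[i].pop == p) {
          if (seen == ia) idx_a = i;
          if (seen == ib) idx_b = i;
          ++seen;
        }
      }
      Lin &A = lv[idx_a];
      Lin &B = lv[idx_b];
      if (t_pair1 < 0 && A.d1 > 0 && B.d1 > 0) t_pair1 = s;
      if (t_pair2 < 0 && A.d2 > 0 && B.d2 > 0) t_pair2 = s;
      lrep[A.d1 + 3 * A.d2 + 9 * A.dout] += s - A.birth;
      lrep[B.d1 + 3 * B.d2 + 9 * B.dout] += s - B.birth;
      Lin merged{A.d1 + B.d1, A.d2 + B.d2, A.dout + B.dout, p, s};
      int hi = std::max(idx_a, idx_b), lo = std::min(idx_a, idx_b);
      lv.erase(lv.begin() + hi);
      lv.erase(lv.begin() + lo);
      lv.push_back(merged);
    }
    for (int i = 0; i < 27; ++i) {
      acc[i] += lrep[i];
      acc2[i] += lrep[i] * lrep[i];
      tot_len_acc += lrep[i];
    }
    if (t_pair1 >= 0 && t_pair1 < t_split) ++n_h1;
    if (t_pair2 >= 0 && t_pair2 < t_split) ++n_h2;
  }

  NumericVector L(27), Lse(27);
  for (int i = 0; i < 27; ++i) {
    double mean = acc[i] / R;
    L[i] = mean;
    double var = (acc2[i] / R - mean * mean) / (R - 1.0);
    Lse[i] = var > 0 ? std::sqrt(var) : 0.0;
  }
  L.attr("dim") = IntegerVector::create(3, 3, 3);
  Lse.attr("dim") = IntegerVector::create(3, 3, 3);
  return List::create(
      _["L"] = L, _["L_se"] = Lse,
      _["alpha1_mc"] = 1.0 - (double)n_h1 / R,
      _["alpha2_mc"] = 1.0 - (double)n_h2 / R,
      _["mean_total_length"] = tot_len_acc / R);
}

// Four-lineage coalescent in a single population with piecewise-constant
// diploid size: sizes[e] applies on [breaks[e-1], breaks[e]). Returns the
// mean duration spent with 4, 3 and 2 lineages.

// [[Rcpp::export]]
List sim_t4_cpp(int R, NumericVector breaks, NumericVector sizes) {
  int nb = breaks.size();
  if (sizes.size() != nb + 1) stop("need length(sizes) == length(breaks) + 1");
  double m4 = 0.0, m3 = 0.0, m2 = 0.0;
  for (int rep = 0; rep < R; ++rep) {
    double s = 0.0, t4 = 0.0, t3 = 0.0, t2 = 0.0;
    int k = 4, ei = 0;
    while (k > 1) {
      while (ei < nb && s >= breaks[ei]) ++ei;
      double end = (ei < nb) ? breaks[ei] : R_PosInf;
      double rate = k * (k - 1.0) / (4.0 * sizes[ei]);
      double w = R::exp_rand() / rate;
      double dur = (s + w >= end) ? end - s : w;
      if (k == 4) t4 += dur; else if (k == 3) t3 += dur; else t2 += dur;
      s += dur;
      if (dur == w) --k;  // otherwise an epoch boundary was hit first
    }
    m4 += t4; m3 += t3; m2 += t2;
  }
  return List::create(_["ET44"] = m4 / R, _["ET43"] = m3 / R,
                      _["ET42"] = m2 / R);
}
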