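// Coalescent simulation core: neutral genealogies under a piecewise-constant
// population-size trajectory, with infinite-sites mutation and (optionally)
// recombination through the ancestral recombination graph.  Times are in
// generations backwards from the present; sizes are diploid individuals.
// Uses R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Waiting time to the next event from time t under coalescent hazard
// pairs/(2 N(t)) plus a constant competing rate extra.  bounds/sizes define
// the step trajectory (bounds[0] == 0, last epoch unbounded).  Returns the
// event time; *is_coal reports the event type.
static double next_event(double t, double pairs,
                         const std::vector<double> &bounds,
                         const std::vector<double> &sizes,
                         double extra, bool *is_coal) {
  double target = R::exp_rand();
  int nb = bounds.size();
  int ep = nb - 1;
  for (int i = 0; i < nb; ++i)
    if (t < bounds[i]) { ep = i - 1; break; }
  for (;;) {
    double coal = pairs / (2.0 * sizes[ep]);
    double rate = coal + extra;
    double upper = (ep < nb - 1) ? bounds[ep + 1] : R_PosInf;
    double span = upper - t;
    if (rate * span >= target) {
      t += target / rate;
      *is_coal = (unif_rand() < coal / rate);
      return t;
    }
    target -= rate * span;
    t = upper;
    ++ep;
  }
}

// Fast path (rho = 0): one genealogy of n tips; returns S and the per-site
// mean pairwise difference.
// [[Rcpp::export(name = ".cpp_sim_tree")]]
List cpp_sim_tree(int n, double mu, double L, NumericVector bounds,
                  NumericVector sizes) {
  std::vector<double> b(bounds.begin(), bounds.end());
  std::vector<double> Nsz(sizes.begin(), sizes.end());
  std::vector<double> birth(2 * n - 1, 0.0);
  std::vector<int> count(2 * n - 1, 0);
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) { active[i] = i; count[i] = 1; }
  double t = 0.0, S = 0.0, pi_num = 0.0;
  int nxt = n;
  bool is_coal;
  while ((int)active.size() > 1) {
    int k = active.size();
    t = next_event(t, k * (k - 1) / 2.0, b, Nsz, 0.0, &is_coal);
    int i = (int)(unif_rand() * k); if (i == k) i = k - 1;
    int j = (int)(unif_rand() * (k - 1)); if (j == k - 1) j = k - 2;
    if (j >= i) ++j;
    int a = active[i], bb = active[j];
    double cnt_a = R::rpois(mu * L * (t - birth[a]));
    double cnt_b = R::rpois(mu * L * (t - birth[bb]));
    S += cnt_a + cnt_b;
    pi_num += cnt_a * (double)count[a] * (n - count[a]) +
              cnt_b * (double)count[bb] * (n - count[bb]);
    birth[nxt] = t;
    count[nxt] = count[a] + count[bb];
    if (i > j) std::swap(i, j);
    active.erase(active.begin() + j);
    active.erase(active.begin() + i);
    active.push_back(nxt);
    ++nxt;
  }
  double npair = n * (n - 1) / 2.0;
  return List::create(_["S"] = S, _["pi"] = pi_num / npair / L);
}

struct Seg { double s, e; int cnt; };

// ARG path: lineages carry ancestral segments with carrier counts;
// mutations are drawn per lineage at its death.
// [[Rcpp::export(name = ".cpp_sim_arg")]]
List cpp_sim_arg(int n, double mu, double rho, double L,
                 NumericVector bounds, NumericVector sizes) {
  std::vector<double> b(bounds.begin(), bounds.end());
  std::vector<double> Nsz(sizes.begin(), sizes.end());
  std::vector<std::vector<Seg> > lin(n);
  std::vector<double> birth(n, 0.0), span(n, L);
  for (int i = 0; i < n; ++i) {
    Seg s0; s0.s = 0.0; s0.e = L; s0.cnt = 1;
    lin[i].push_back(s0);
  }
  double t = 0.0, S = 0.0, pi_num = 0.0;
  bool is_coal;
  while (lin.size() >= 2) {
    int k = lin.size();
    double span_tot = 0.0;
    for (int i = 0; i < k; ++i) span_tot += span[i];
    t = next_event(t, k * (k - 1) / 2.0, b, Nsz, rho * span_tot, &is_coal);
    if (is_coal) {
      int i = (int)(unif_rand() * k); if (i == k) i = k - 1;
      int j = (int)(unif_rand() * (k - 1)); if (j == k - 1) j = k - 2;
      if (j >= i) ++j;
      // mutations on the two dying lineages
      for (int w = 0; w < 2; ++w) {
        int idx = (w == 0) ? i : j;
        double dur = t - birth[idx];
        for (size_t q = 0; q < lin[idx].size(); ++q) {
          double cnt = R::rpois(mu * dur * (lin[idx][q].e - lin[idx][q].s));
          S += cnt;
          pi_num += cnt * (double)lin[idx][q].cnt * (n - lin[idx][q].cnt);
        }
      }
      // merge segment lists by boundary sweep
      std::vector<double> pts;
      for (size_t q = 0; q < lin[i].size(); ++q) {
        pts.push_back(lin[i][q].s); pts.push_back(lin[i][q].e);
      }
      for (size_t q = 0; q < lin[j].size(); ++q) {
        pts.push_back(lin[j][q].s); pts.push_back(lin[j][q].e);
      }
      std::sort(pts.begin(), pts.end());
      pts.erase(std::unique(pts.begin(), pts.end()), pts.end());
      std::vector<Seg> merged;
      size_t pa = 0, pb = 0;
      for (size_t q = 0; q + 1 < pts.size(); ++q) {
        double mid = (pts[q] + pts[q + 1]) / 2.0;
        int cnt = 0;
        while (pa < lin[i].size() && lin[i][pa].e <= mid) ++pa;
        if (pa < lin[i].size() && lin[i][pa].s <= mid) cnt += lin[i][pa].cnt;
        while (pb < lin[j].size() && lin[j][pb].e <= mid) ++pb;
        if (pb < lin[j].size() && lin[j][pb].s <= mid) cnt += lin[j][pb].cnt;
        if (cnt > 0 && cnt < n) {
          if (!merged.empty() && merged.back().e == pts[q] &&
              merged.back().cnt == cnt)
            merged.back().e = pts[q + 1];
          else {
            Seg sg; sg.s = pts[q]; sg.e = pts[q + 1]; sg.cnt = cnt;
            merged.push_back(sg);
          }
        }
      }
      // replace i and j (erase higher index first)
      int hi = std::max(i, j), lo = std::min(i, j);
      lin.erase(lin.begin() + hi); birth.erase(birth.begin() + hi);
      span.erase(span.begin() + hi);
      lin.erase(lin.begin() + lo); birth.erase(birth.begin() + lo);
      span.erase(span.begin() + lo);
      if (!merged.empty()) {
        lin.push_back(merged);
        birth.push_back(t);
        span.push_back(merged.back().e - merged.front().s);
      }
    } else {
      // recombination: pick lineage proportional to span
      double u = unif_rand() * span_tot, acc = 0.0;
      int li = k - 1;
      for (int i = 0; i < k; ++i) {
        acc += span[i];
        if (u <= acc) { li = i; break; }
      }
      double dur = t - birth[li];
      for (size_t q = 0; q < lin[li].size(); ++q) {
        double cnt = R::rpois(mu * dur * (lin[li][q].e - lin[li][q].s));
        S += cnt;
        pi_num += cnt * (double)lin[li][q].cnt * (n - lin[li][q].cnt);
      }
      double lo = lin[li].front().s, hi = lin[li].back().e;
      double x = lo + unif_rand() * (hi - lo);
      std::vector<Seg> left, right;
      for (size_t q = 0; q < lin[li].size(); ++q) {
        Seg sg = lin[li][q];
        if (sg.e <= x) left.push_back(sg);
        else if (sg.s >= x) right.push_back(sg);
        else {
          Seg l2 = sg, r2 = sg;
          l2.e = x; r2.s = x;
          left.push_back(l2); right.push_back(r2);
        }
      }
      lin.erase(lin.begin() + li); birth.erase(birth.begin() + li);
      span.erase(span.begin() + li);
      if (!left.empty()) {
        lin.push_back(left); birth.push_back(t);
        span.push_back(left.back().e - left.front().s);
      }
      if (!right.empty()) {
        lin.push_back(right); birth.push_back(t);
        span.push_back(right.back().e - right.front().s);
      }
    }
  }
  double npair = n * (n - 1) / 2.0;
  return List::create(_["S"] = S, _["pi"] = pi_num / npair / L);
}
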