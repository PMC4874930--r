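// Exact min-sum variable elimination kernel for the reference surface
// solver. Factors are dense tables over level assignments (all variables
// share the same number of levels); eliminating a column joins every
// factor touching it into one table (the eliminated variable laid out as
// the fastest axis) and minimizes it out. Complexity is exponential in
// the elimination width, so this is a validation tool for small graphs,
// not a production solver.

#include <Rcpp.h>
#include <limits>
#include <set>
#include <vector>

using namespace Rcpp;

namespace {

struct Factor {
  std::vector<int> vars;       // 0-based column ids, fastest axis first
  std::vector<double> vals;
};

}  // namespace

// [[Rcpp::export(name = ".ref_dp_min_cpp")]]
double ref_dp_min_cpp(NumericMatrix cost, IntegerMatrix edges, double sc,
                      double sp, IntegerVector elim_order) {
  const int n = cost.nrow();
  const int nc = cost.ncol();
  const double inf = std::numeric_limits<double>::infinity();

  std::vector<Factor> factors;
  factors.reserve(nc + edges.nrow());
  for (int i = 0; i < nc; ++i) {
    Factor f;
    f.vars.assign(1, i);
    f.vals.resize(n);
    for (int j = 0; j < n; ++j) f.vals[j] = cost(j, i);
    factors.push_back(std::move(f));
  }
  for (int e = 0; e < edges.nrow(); ++e) {
    Factor f;
    f.vars.resize(2);
    f.vars[0] = edges(e, 0) - 1;
    f.vars[1] = edges(e, 1) - 1;
    f.vals.resize(static_cast<size_t>(n) * n);
    for (int j2 = 0; j2 < n; ++j2)
      for (int j1 = 0; j1 < n; ++j1) {
        const double d = std::abs(j1 - j2);
        f.vals[j1 + static_cast<size_t>(n) * j2] = d > sc ? inf : sp * d;
      }
    factors.push_back(std::move(f));
  }

  double constant = 0.0;
  for (int oi = 0; oi < elim_order.size(); ++oi) {
    const int v = elim_order[oi] - 1;
    std::vector<Factor> touch, rest;
    for (auto &f : factors) {
      bool t = false;
      for (int vv : f.vars) t = t || (vv == v);
      (t ? touch : rest).push_back(std::move(f));
    }
    if (touch.empty()) {
      factors.swap(rest);
      continue;
    }
    // joint scope, eliminated variable first (fastest axis)
    std::set<int> vs;
    for (const auto &f : touch)
      for (int vv : f.vars) vs.insert(vv);
    std::vector<int> jv;
    jv.push_back(v);
    for (int vv : vs)
      if (vv != v) jv.push_back(vv);
    const int k = static_cast<int>(jv.size());
    size_t size = 1;
    for (int t = 0; t < k; ++t) size *= n;

    std::vector<double> acc(size, 0.0);
    for (const auto &f : touch) {
      // stride of each joint axis within the factor's layout
      std::vector<size_t> stride(k, 0);
      size_t st = 1;
      for (size_t m = 0; m < f.vars.size(); ++m, st *= n) {
        for (int t = 0; t < k; ++t)
          if (jv[t] == f.vars[m]) stride[t] = st;
      }
      std::vector<int> digit(k, 0);
      size_t fidx = 0;
      for (size_t li = 0; li < size; ++li) {
        acc[li] += f.vals[fidx];
        for (int t = 0; t < k; ++t) {
          ++digit[t];
          fidx += stride[t];
          if (digit[t] < n) break;
          digit[t] = 0;
          fidx -= stride[t] * static_cast<size_t>(n);
        }
      }
    }
    // minimize out the first axis (contiguous blocks of n)
    if (k == 1) {
      double mn = acc[0];
      for (int j = 1; j < n; ++j) mn = std::min(mn, acc[j]);
      constant += mn;
    } else {
      Factor nf;
      nf.vars.assign(jv.begin() + 1, jv.end());
      const size_t outsize = size / n;
      nf.vals.resize(outsize);
      for (size_t o = 0; o < outsize; ++o) {
        const double *p = &acc[o * n];
        double mn = p[0];
        for (int j = 1; j < n; ++j) mn = std::min(mn, p[j]);
        nf.vals[o] = mn;
      }
      rest.push_back(std::move(nf));
    }
    factors.swap(rest);
  }
  for (const auto &f : factors) {
    double mn = inf;
    for (double x : f.vals) mn = std::min(mn, x);
    constant += mn;
  }
  return constant;
}
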