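#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// One pass of 2-D block matching by normalized cross-correlation on a
// depth x beam matrix. Node indices are 0-based; per-node kernel half
// sizes allow depth-dependent kernels. The search is seeded per node
// (coarse-to-fine). Ties at equal correlation resolve to the smallest
// lag magnitude (lags are visited in order of increasing magnitude and
// only a strictly larger correlation replaces the incumbent). The integer
// argmax is refined per axis by parabolic interpolation of the
// correlation samples. Nodes whose kernel or search window exits the
// grid are invalid (NA displacement, quality 0); flat (zero-variance)
// kernels return zero displacement with quality 0.
// [[Rcpp::export]]
NumericMatrix ncc_match_cpp(NumericMatrix ref, NumericMatrix mov,
                            IntegerVector node_i, IntegerVector node_j,
                            IntegerVector kh_d, IntegerVector kh_b,
                            int lag_d, int lag_b,
                            IntegerVector seed_d, IntegerVector seed_b,
                            bool zero_mean) {
  const int nd = ref.nrow(), nb = ref.ncol();
  const int nn = node_i.size();
  NumericMatrix out(nn, 5);
  const int npd = 2 * lag_d + 1, npb = 2 * lag_b + 1;

  // lag visit order: increasing magnitude
  std::vector<std::pair<int, std::pair<int, int> > > order;
  order.reserve(npd * npb);
  for (int p = -lag_d; p <= lag_d; ++p)
    for (int q = -lag_b; q <= lag_b; ++q)
      order.push_back(std::make_pair(p * p + q * q, std::make_pair(p, q)));
  std::stable_sort(order.begin(), order.end());

  std::vector<double> corr(npd * npb);

  for (int k = 0; k < nn; ++k) {
    const int ci = node_i[k], cj = node_j[k];
    const int kd = kh_d[k], kb = kh_b[k];
    const int sd = seed_d[k], sb = seed_b[k];
    out(k, 0) = NA_REAL; out(k, 1) = NA_REAL; out(k, 2) = 0.0;
    // bounds: reference kernel and the full seeded search region in mov
    if (ci - kd < 0 || ci + kd >= nd || cj - kb < 0 || cj + kb >= nb)
      continue;
    if (ci + sd - lag_d - kd < 0 || ci + sd + lag_d + kd >= nd ||
        cj + sb - lag_b - kb < 0 || cj + sb + lag_b + kb >= nb)
      continue;

    const int kn = (2 * kd + 1) * (2 * kb + 1);
    // reference kernel statistics
    double sum_r = 0.0, ss_r = 0.0;
    for (int a = -kd; a <= kd; ++a)
      for (int b = -kb; b <= kb; ++b) {
        const double v = ref(ci + a, cj + b);
        sum_r += v; ss_r += v * v;
      }
    // flatness is judged on the mean-removed kernel regardless of the
    // correlation centering: a constant patch carries no speckle signature
    const double cvar = ss_r - sum_r * sum_r / kn;
    if (cvar <= 1e-300) { out(k, 0) = 0.0; out(k, 1) = 0.0;
      out(k, 3) = 0.0; out(k, 4) = 0.0; continue; }
    const double mean_r = zero_mean ? sum_r / kn : 0.0;
    const double var_r = ss_r - kn * mean_r * mean_r;
    if (var_r <= 0.0) { out(k, 0) = 0.0; out(k, 1) = 0.0;
      out(k, 3) = 0.0; out(k, 4) = 0.0; continue; }

    double best = R_NegInf; int bp = 0, bq = 0;
    for (size_t o = 0; o < order.size(); ++o) {
      const int p = order[o].second.first, q = order[o].second.second;
      double sum_m = 0.0, ss_m = 0.0, cross = 0.0;
      const int oi = ci + sd + p, oj = cj + sb + q;
      for (int a = -kd; a <= kd; ++a)
        for (int b = -kb; b <= kb; ++b) {
          const double vm = mov(oi + a, oj + b);
          sum_m += vm; ss_m += vm * vm;
          cross += vm * ref(ci + a, cj + b);
        }
      const double mean_m = zero_mean ? sum_m / kn : 0.0;
      const double var_m = ss_m - kn * mean_m * mean_m;
      double cc;
      if (var_m <= 0.0) cc = 0.0;
      else cc = (cross - kn * mean_r * mean_m) / std::sqrt(var_r * var_m);
      corr[(p + lag_d) * npb + (q + lag_b)] = cc;
      if (cc > best) { best = cc; bp = p; bq = q; }
    }

    // parabolic sub-sample refinement per axis (only away from the edge)
    double dd = 0.0, db = 0.0;
    if (bp > -lag_d && bp < lag_d) {
      const double cm = corr[(bp - 1 + lag_d) * npb + (bq + lag_b)];
      const double c0 = corr[(bp + lag_d) * npb + (bq + lag_b)];
      const double cp = corr[(bp + 1 + lag_d) * npb + (bq + lag_b)];
      const double den = cm - 2.0 * c0 + cp;
      if (den < 0.0) {
        dd = (cm - cp) / (2.0 * den);
        if (dd > 0.5) dd = 0.5; if (dd < -0.5) dd = -0.5;
      }
    }
    if (bq > -lag_b && bq < lag_b) {
      const double cm = corr[(bp + lag_d) * npb + (bq - 1 + lag_b)];
      const double c0 = corr[(bp + lag_d) * npb + (bq + lag_b)];
      const double cp = corr[(bp + lag_d) * npb + (bq + 1 + lag_b)];
      const double den = cm - 2.0 * c0 + cp;
      if (den < 0.0) {
        db = (cm - cp) / (2.0 * den);
        if (db > 0.5) db = 0.5; if (db < -0.5) db = -0.5;
      }
    }
    out(k, 0) = sd + bp + dd;
    out(k, 1) = sb + bq + db;
    out(k, 2) = best;
    out(k, 3) = sd + bp;
    out(k, 4) = sb + bq;
  }
  return out;
}

// 2-D median filter with reflected edges. NA entries are skipped inside
// the window; an all-NA window (or NA center with no neighbours) gives NA.
// [[Rcpp::export]]
NumericMatrix medfilt2_cpp(NumericMatrix x, int hh, int hw) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> buf((2 * hh + 1) * (2 * hw + 1));
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      int n = 0;
      for (int a = -hh; a <= hh; ++a) {
        int ia = i + a;
        if (ia < 0) ia = -ia - 1;
        if (ia >= nr) ia = 2 * nr - ia - 1;
        for (int b = -hw; b <= hw; ++b) {
          int jb = j + b;
          if (jb < 0) jb = -jb - 1;
          if (jb >= nc) jb = 2 * nc - jb - 1;
          const double v = x(ia, jb);
          if (!ISNAN(v)) buf[n++] = v;
        }
      }
      if (n == 0) { out(i, j) = NA_REAL; continue; }
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.begin() + n);
      double med = buf[n / 2];
      if (n % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + n / 2);
        med = 0.5 * (med + lo);
      }
      out(i, j) = med;
    }
  }
  return out;
}
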