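#include <Rcpp.h>
using namespace Rcpp;

// Nearest-neighbour query between two point clouds (brute force; clouds in
// this pipeline are a few hundred points, where a KD-tree buys nothing).
// Returns for each query point the distance to, and tangent dot product
// with, its nearest target point.
// [[Rcpp::export(name = ".nn_dotprod_cpp")]]
List nn_dotprod_cpp(NumericMatrix qpts, NumericMatrix qtan,
                    NumericMatrix tpts, NumericMatrix ttan) {
  const int nq = qpts.nrow(), nt = tpts.nrow();
  NumericVector dist(nq), dotp(nq);
  IntegerVector idx(nq);
  const double *tx = &tpts(0, 0), *ty = &tpts(0, 1), *tz = &tpts(0, 2);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    int bj = 0;
    const double qx = qpts(i, 0), qy = qpts(i, 1), qz = qpts(i, 2);
    for (int j = 0; j < nt; ++j) {
      const double dx = qx - tx[j], dy = qy - ty[j], dz = qz - tz[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    dist[i] = std::sqrt(best);
    double dp = qtan(i, 0) * ttan(bj, 0) + qtan(i, 1) * ttan(bj, 1) +
                qtan(i, 2) * ttan(bj, 2);
    dotp[i] = std::fabs(dp);
    idx[i] = bj + 1;
  }
  return List::create(_["dist"] = dist, _["dotprod"] = dotp, _["index"] = idx);
}

// raw NBLAST kernel on column-major coordinate arrays under the parametric
// score s(d, dp) = dp * exp(-d^2 / (2 sigma^2)) - c
static double raw_score(const double *qp, const double *qt, int nq,
                        const double *tp, const double *tt, int nt,
                        double s2, double cost) {
  const double *qx = qp, *qy = qp + nq, *qz = qp + 2 * nq;
  const double *tx = tp, *ty = tp + nt, *tz = tp + 2 * nt;
  double total = 0.0;
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    int bj = 0;
    const double x = qx[i], y = qy[i], z = qz[i];
    for (int j = 0; j < nt; ++j) {
      const double dx = x - tx[j], dy = y - ty[j], dz = z - tz[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    const double dp = qt[i] * tt[bj] + qt[i + nq] * tt[bj + nt] +
                      qt[i + 2 * nq] * tt[bj + 2 * nt];
    total += std::fabs(dp) * std::exp(-best / s2) - cost;
  }
  return total;
}

// [[Rcpp::export(name = ".nblast_raw_param_cpp")]]
double nblast_raw_param_cpp(NumericMatrix qpts, NumericMatrix qtan,
                            NumericMatrix tpts, NumericMatrix ttan,
                            double sigma, double cost) {
  return raw_score(qpts.begin(), qtan.begin(), qpts.nrow(),
                   tpts.begin(), ttan.begin(), tpts.nrow(),
                   2.0 * sigma * sigma, cost);
}

// Batched mean-normalized NBLAST: queries x targets in one call.
// qpts/qtan/tpts/ttan are lists of n x 3 matrices. mask (optional, size
// queries x targets) limits which entries are computed; masked-out entries
// come back NA. When symmetric = true the query and target lists must be
// identical and only the upper triangle is computed.
// [[Rcpp::export(name = ".nblast_mean_matrix_cpp")]]
NumericMatrix nblast_mean_matrix_cpp(List qpts, List qtan,
                                     List tpts, List ttan,
                                     double sigma, double cost,
                                     Nullable<LogicalMatrix> mask,
                                     bool symmetric) {
  const int nq = qpts.size(), nt = tpts.size();
  const double s2 = 2.0 * sigma * sigma;
  std::vector<const double *> qp(nq), qt(nq), tp(nt), tt(nt);
  std::vector<int> qn(nq), tn(nt);
  for (int i = 0; i < nq; ++i) {
    NumericMatrix m = qpts[i], t = qtan[i];
    qp[i] = m.begin(); qt[i] = t.begin(); qn[i] = m.nrow();
  }
  for (int j = 0; j < nt; ++j) {
    NumericMatrix m = tpts[j], t = ttan[j];
    tp[j] = m.begin(); tt[j] = t.begin(); tn[j] = m.nrow();
  }
  std::vector<double> self_q(nq), self_t(nt);
  for (int i = 0; i < nq; ++i)
    self_q[i] = raw_score(qp[i], qt[i], qn[i], qp[i], qt[i], qn[i], s2, cost);
  if (symmetric) {
    self_t = self_q;
  } else {
    for (int j = 0; j < nt; ++j)
      self_t[j] = raw_score(tp[j], tt[j], tn[j], tp[j], tt[j], tn[j], s2, cost);
  }
  LogicalMatrix msk;
  const bool has_mask = mask.isNotNull();
  if (has_mask) msk = mask.get();
  NumericMatrix out(nq, nt);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int i = 0; i < nq; ++i) {
    for (int j = symmetric ? i : 0; j < nt; ++j) {
      if (symmetric && i == j) { out(i, j) = 1.0; continue; }
      if (has_mask && !msk(i, j)) continue;
      const double ab = raw_score(qp[i], qt[i], qn[i], tp[j], tt[j], tn[j],
                                  s2, cost);
      const double ba = raw_score(tp[j], tt[j], tn[j], qp[i], qt[i], qn[i],
                                  s2, cost);
      const double v = (ab / self_q[i] + ba / self_t[j]) / 2.0;
      out(i, j) = v;
      if (symmetric) out(j, i) = v;
    }
  }
  return out;
}
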