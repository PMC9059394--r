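#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Truncated mean with base-R mean(x, trim=) semantics: drop floor(n*trim)
// observations from each tail of the sorted sample.
static double trimmed_mean(std::vector<double> &v, double trim) {
  const int n = (int)v.size();
  if (n == 0) return 0.0;
  std::sort(v.begin(), v.end());
  int lo = (int)std::floor(n * trim);
  int hi = n - lo;
  if (hi <= lo) { lo = 0; hi = n; }
  double s = 0.0;
  for (int i = lo; i < hi; ++i) s += v[i];
  return s / (double)(hi - lo);
}

// Per cell-type gene summaries: summary expression (truncated or plain mean)
// and fraction of cells with value > 0. Summaries below the expression
// fraction threshold are forced to zero (the 20% filter). Xt is the
// cells x genes transpose (contiguous per-gene access).
static void group_summary(const std::vector<double> &Xt, int N, int G,
                          const std::vector<std::vector<int> > &members,
                          double trim, bool use_trim, double thresh,
                          NumericMatrix &summ, NumericMatrix &frac) {
  const int T = (int)members.size();
  std::vector<double> buf;
  for (int t = 0; t < T; ++t) {
    const std::vector<int> &m = members[t];
    const int n = (int)m.size();
    for (int g = 0; g < G; ++g) {
      const double *col = Xt.data() + (size_t)N * g;
      int pos = 0;
      double sum = 0.0;
      buf.clear();
      buf.reserve(n);
      for (int j = 0; j < n; ++j) {
        const double v = col[m[j]];
        if (v > 0) ++pos;
        sum += v;
        if (use_trim) buf.push_back(v);
      }
      const double fr = n > 0 ? (double)pos / (double)n : 0.0;
      double mu = 0.0;
      if (n > 0) mu = use_trim ? trimmed_mean(buf, trim) : sum / (double)n;
      if (fr < thresh) mu = 0.0;
      frac(g, t) = fr;
      summ(g, t) = mu;
    }
  }
}

static std::vector<double> transpose_mat(const NumericMatrix &X) {
  const int G = X.nrow(), N = X.ncol();
  std::vector<double> Xt((size_t)N * G);
  for (int j = 0; j < N; ++j)
    for (int g = 0; g < G; ++g)
      Xt[(size_t)N * g + j] = X(g, j);
  return Xt;
}

// Geometric mean of subunit summaries; any zero subunit nulls the complex.
static double geo_mean(const NumericMatrix &summ, const std::vector<int> &idx,
                       int t) {
  double s = 0.0;
  for (size_t i = 0; i < idx.size(); ++i) {
    const double v = summ(idx[i], t);
    if (v <= 0) return 0.0;
    s += std::log(v);
  }
  return std::exp(s / (double)idx.size());
}

static double arith_mean(const NumericMatrix &summ,
                         const std::vector<int> &idx, int t) {
  if (idx.empty()) return 0.0;
  double s = 0.0;
  for (size_t i = 0; i < idx.size(); ++i) s += summ(idx[i], t);
  return s / (double)idx.size();
}

// Mass-action strengths for every (sender, receiver, interaction) triple.
// out has dim T x T x I, sender fastest.
static void compute_strengths(const NumericMatrix &summ, int T,
                              const std::vector<std::vector<int> > &lig,
                              const std::vector<std::vector<int> > &rec,
                              const std::vector<std::vector<int> > &ago,
                              const std::vector<std::vector<int> > &ant,
                              const std::vector<std::vector<int> > &cst,
                              const std::vector<std::vector<int> > &cin,
                              double kh, bool use_cof, double *out) {
  const int I = (int)lig.size();
  std::vector<double> L(T), sendf(T), Rm(T);
  for (int i = 0; i < I; ++i) {
    for (int t = 0; t < T; ++t) {
      L[t] = geo_mean(summ, lig[i], t);
      double sf = 1.0;
      if (use_cof) {
        const double ag = arith_mean(summ, ago[i], t);
        const double an = arith_mean(summ, ant[i], t);
        sf = (1.0 + ag / (kh + ag)) * (kh / (kh + an));
      }
      sendf[t] = sf;
      double R = geo_mean(summ, rec[i], t);
      if (use_cof) {
        const double cs = arith_mean(summ, cst[i], t);
        const double ci = arith_mean(summ, cin[i], t);
        R *= (1.0 + cs / (kh + cs)) * (kh / (kh + ci));
      }
      Rm[t] = R;
    }
    double *oi = out + (size_t)i * T * T;
    for (int r = 0; r < T; ++r)
      for (int s = 0; s < T; ++s) {
        const double lr = L[s] * Rm[r];
        oi[s + (size_t)T * r] = lr > 0 ? lr / (kh + lr) * sendf[s] : 0.0;
      }
  }
}

static std::vector<std::vector<int> > as_index(const List &L) {
  std::vector<std::vector<int> > out(L.size());
  for (int i = 0; i < L.size(); ++i) {
    IntegerVector iv = L[i];
    out[i].resize(iv.size());
    for (int j = 0; j < iv.size(); ++j) out[i][j] = iv[j] - 1;
  }
  return out;
}

static std::vector<std::vector<int> > membership(const IntegerVector &type,
                                                 int n_types) {
  std::vector<std::vector<int> > m(n_types);
  for (int j = 0; j < type.size(); ++j) m[type[j] - 1].push_back(j);
  return m;
}

// [[Rcpp::export]]
List group_summary_cpp(NumericMatrix expr, IntegerVector type, int n_types,
                       double trim, bool use_trim, double thresh) {
  NumericMatrix summ(expr.nrow(), n_types), frac(expr.nrow(), n_types);
  std::vector<double> Xt = transpose_mat(expr);
  std::vector<std::vector<int> > members = membership(type, n_types);
  group_summary(Xt, expr.ncol(), expr.nrow(), members, trim, use_trim,
                thresh, summ, frac);
  return List::create(_["mean"] = summ, _["frac"] = frac);
}

// Full inference: observed strengths plus permutation p-values obtained by
// shuffling cell-type labels across cells (counts per type preserved).
// p = (1 + #{permuted >= observed}) / (1 + n_perm); a zero observed strength
// therefore reports p = 1. Uses the R RNG: seed with set.seed() upstream.
// [[Rcpp::export]]
List ccc_infer_cpp(NumericMatrix expr, IntegerVector type, int n_types,
                   List lig, List rec, List ago, List ant, List cst, List cin,
                   double kh, double trim, bool use_trim, double thresh,
                   bool use_cofactors, int n_perm) {
  const int G = expr.nrow();
  const int N = expr.ncol();
  const int T = n_types;
  const int I = (int)lig.size();
  const size_t len = (size_t)T * T * I;

  std::vector<std::vector<int> > vlig = as_index(lig), vrec = as_index(rec),
                                 vago = as_index(ago), vant = as_index(ant),
                                 vcst = as_index(cst), vcin = as_index(cin);

  NumericMatrix summ(G, T), frac(G, T);
  std::vector<double> Xt = transpose_mat(expr);
  std::vector<std::vector<int> > members = membership(type, n_types);
  group_summary(Xt, N, G, members, trim, use_trim, thresh, summ, frac);

  NumericVector obs(len);
  compute_strengths(summ, T, vlig, vrec, vago, vant, vcst, vcin, kh,
                    use_cofactors, REAL(obs));

  std::vector<int> ge(len, 0);
  NumericMatrix psumm(G, T), pfrac(G, T);
  std::vector<double> perm_s(len);
  for (int b = 0; b < n_perm; ++b) {
    IntegerVector perm = sample(N, N, false);
    IntegerVector ptype(N);
    for (int j = 0; j < N; ++j) ptype[j] = type[perm[j] - 1];
    std::vector<std::vector<int> > pm = membership(ptype, n_types);
    group_summary(Xt, N, G, pm, trim, use_trim, thresh, psumm, pfrac);
    compute_strengths(psumm, T, vlig, vrec, vago, vant, vcst, vcin, kh,
                      use_cofactors, perm_s.data());
    const double *o = REAL(obs);
    for (size_t q = 0; q < len; ++q)
      if (perm_s[q] >= o[q]) ++ge[q];
    if (b % 16 == 15) Rcpp::checkUserInterrupt();
  }

  NumericVector pval(len);
  for (size_t q = 0; q < len; ++q)
    pval[q] = (1.0 + ge[q]) / (1.0 + n_perm);

  obs.attr("dim") = Dimension(T, T, I);
  pval.attr("dim") = Dimension(T, T, I);
  return List::create(_["strength"] = obs, _["pval"] = pval,
                      _["mean"] = summ, _["frac"] = frac);
}
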