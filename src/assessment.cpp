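// Age-structured krill population dynamics and the penalized negative
// log-likelihood. One translation unit evaluates the model for the
// optimizer (objective / finite-difference gradient / Hessian on the
// transformed estimation scale) and produces the full trajectory report
// used by project() and the pseudo-data generator.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double BIG = 1e10;        // returned for non-finite states
static const double COMP_FLOOR = 1e-10;

struct Series {
  std::vector<int> idx_pos;            // 0-based model-year offsets
  std::vector<double> idx_obs, idx_sig2;
  std::vector<int> cmp_pos;
  std::vector<double> cmp_obs;         // row-major [year, bin]
  std::vector<double> cmp_neff;
  int nb = 0;
};

struct Problem {
  int A = 7, Y = 41, NPRE = 5, NB = 30, NS = 6;
  int f_start = 0;                     // first year offset with F > 0
  std::vector<double> mat;             // maturity at age
  double wa = 1e-9, wb = 3.0;
  std::vector<double> edges;           // NB + 1 bin edges
  std::vector<Series> surveys;
  std::vector<int> catch_pos;
  std::vector<double> catch_obs;
  Series fcomp;
  double l1 = 1, l2 = 1, l3 = 1, l4 = 0.1, l5 = 0.1, l6 = 10, fcap = 1.5;
  bool bias_correct = true;
  int npar() const { return 13 + NPRE + 2 * Y + 3 * NS; }
  // layout offsets into the canonical parameter vector
  int o_eps_r()  const { return 2; }
  int o_sig_r()  const { return 2 + NPRE + Y; }
  int o_m()      const { return o_sig_r() + 1; }
  int o_ssel()   const { return o_m() + 1; }
  int o_fsel()   const { return o_ssel() + 2 * NS; }
  int o_mu_f()   const { return o_fsel() + 2; }
  int o_eps_f()  const { return o_mu_f() + 1; }
  int o_sig_c()  const { return o_eps_f() + Y; }
  int o_q_f()    const { return o_sig_c() + 1; }
  int o_h()      const { return o_q_f() + 1; }
  int o_q_s()    const { return o_h() + 1; }
  int o_growth() const { return o_q_s() + NS; }
};

static Series as_series(const List& s) {
  Series out;
  out.idx_pos = as<std::vector<int>>(s["idx_pos"]);
  out.idx_obs = as<std::vector<double>>(s["idx_obs"]);
  out.idx_sig2 = as<std::vector<double>>(s["idx_sig2"]);
  out.cmp_pos = as<std::vector<int>>(s["cmp_pos"]);
  NumericMatrix cm = s["cmp_obs"];
  out.nb = cm.ncol();
  out.cmp_obs.assign(cm.begin(), cm.end());  // column-major, handled below
  out.cmp_neff = as<std::vector<double>>(s["cmp_neff"]);
  return out;
}

static Problem build_problem(const List& pb) {
  Problem P;
  P.A = as<int>(pb["n_ages"]);
  P.Y = as<int>(pb["n_years"]);
  P.NPRE = as<int>(pb["n_pre"]);
  P.NS = as<int>(pb["n_surveys"]);
  P.f_start = as<int>(pb["f_start"]);
  P.mat = as<std::vector<double>>(pb["maturity"]);
  P.wa = as<double>(pb["weight_a"]);
  P.wb = as<double>(pb["weight_b"]);
  P.edges = as<std::vector<double>>(pb["edges"]);
  P.NB = (int)P.edges.size() - 1;
  List sv = pb["surveys"];
  for (int s = 0; s < P.NS; ++s) P.surveys.push_back(as_series(sv[s]));
  P.catch_pos = as<std::vector<int>>(pb["catch_pos"]);
  P.catch_obs = as<std::vector<double>>(pb["catch_obs"]);
  P.fcomp = as_series(pb["fishery_comp"]);
  List w = pb["weights"];
  P.l1 = as<double>(w["lambda1"]); P.l2 = as<double>(w["lambda2"]);
  P.l3 = as<double>(w["lambda3"]); P.l4 = as<double>(w["lambda4"]);
  P.l5 = as<double>(w["lambda5"]); P.l6 = as<double>(w["lambda6"]);
  P.fcap = as<double>(w["f_cap"]);
  P.bias_correct = as<bool>(pb["bias_correct"]);
  return P;
}

struct Report {
  std::vector<double> N, Z, Cage;      // Y x A, row-major
  std::vector<double> F, SSB, R, catch_pred;
  std::vector<double> pred_index;      // NS x Y, row-major
  std::vector<double> pred_scomp;      // NS x Y x NB
  std::vector<double> pred_fcomp;      // Y x NB
  std::vector<double> AL;              // A x NB
  std::vector<double> w, sel_f;
  std::vector<double> sel_s;           // NS x A
  double B0 = 0, R0 = 0, phi0 = 0;
  double nll_catch = 0, nll_fcomp = 0;
  std::vector<double> nll_index, nll_scomp;
  double lam[6] = {0, 0, 0, 0, 0, 0};
  double total = 0;
};

static inline double logistic(double a, double alpha, double beta) {
  return 1.0 / (1.0 + std::exp(-(a - alpha) / beta));
}

// core model evaluation; returns penalized NLL, fills rep when non-null
static double eval_model(const Problem& P, const double* x, Report* rep) {
  const int A = P.A, Y = P.Y, NPRE = P.NPRE, NB = P.NB, NS = P.NS;
  const double lnR0 = x[0], lnRbar = x[1];
  const double* eps_r = x + P.o_eps_r();
  const double sigR = std::exp(x[P.o_sig_r()]);
  const double M = std::exp(x[P.o_m()]);
  const double* ssel_par = x + P.o_ssel();
  const double alpha_f = x[P.o_fsel()], beta_f = x[P.o_fsel() + 1];
  const double mu_f = x[P.o_mu_f()];
  const double* eps_f = x + P.o_eps_f();
  const double sigC = x[P.o_sig_c()];
  const double qf = std::exp(x[P.o_q_f()]);
  const double h = x[P.o_h()];
  const double* ln_qs = x + P.o_q_s();
  const double linf = std::exp(x[P.o_growth()]);
  const double kgr = std::exp(x[P.o_growth() + 1]);
  const double sv = std::exp(x[P.o_growth() + 2]);

  if (!(sigR > 0) || !(sigC > 0) || !(beta_f > 0) || !(sv > 0)) return BIG;
  for (int s = 0; s < NS; ++s) if (!(ssel_par[2 * s + 1] > 0)) return BIG;

  // selectivities, weight-at-age, age-length transition
  std::vector<double> sel_f(A), w(A), sel_s(NS * A), AL(A * NB);
  for (int j = 0; j < A; ++j) {
    double age = j + 1.0;
    sel_f[j] = logistic(age, alpha_f, beta_f);
    double L = linf * (1.0 - std::exp(-kgr * age));
    w[j] = P.wa * std::pow(L, P.wb);
    for (int s = 0; s < NS; ++s) {
      sel_s[s * A + j] = logistic(age, ssel_par[2 * s], ssel_par[2 * s + 1]);
    }
    double cdf_prev = 0.0;
    for (int b = 0; b < NB; ++b) {
      double cdf = (b == NB - 1) ? 1.0
        : R::pnorm(P.edges[b + 1], L, sv, 1, 0);
      AL[j * NB + b] = cdf - cdf_prev;
      cdf_prev = cdf;
    }
  }

  const double bc = P.bias_correct ? 0.5 * sigR * sigR : 0.0;
  const double R0 = std::exp(lnR0);
  const double Rbar_c = std::exp(lnRbar - bc);

  // unfished spawning biomass per recruit (plus-group equilibrium)
  double phi0 = 0.0;
  for (int j = 0; j < A; ++j) {
    double l = std::exp(-M * j);
    if (j == A - 1 && A > 1) l /= (1.0 - std::exp(-M));
    if (A == 1) l = 1.0 / (1.0 - std::exp(-M));
    phi0 += P.mat[j] * w[j] * l;
  }
  const double B0 = R0 * phi0;
  if (!(B0 > 0) || !std::isfinite(B0)) return BIG;

  std::vector<double> N(Y * A), Z(Y * A), Cage(Y * A);
  std::vector<double> Fv(Y), SSB(Y), R(Y), catch_pred(Y);

  // recruitment for model years
  for (int t = 0; t < Y; ++t) {
    R[t] = std::exp(lnRbar + eps_r[NPRE + t] - bc);
  }
  // initial age structure: pre-data recruitments decayed by M (no fishing)
  N[0] = R[0];
  for (int j = 1; j < A; ++j) {
    if (j < A - 1) {
      N[j] = std::exp(lnRbar + eps_r[NPRE - j] - bc) * std::exp(-M * j);
    } else {
      N[j] = Rbar_c * std::exp(-M * j) / (1.0 - std::exp(-M));
    }
  }
  if (A == 1) N[0] = R[0];

  for (int t = 0; t < Y; ++t) {
    double Ft = (t >= P.f_start) ? std::exp(mu_f + eps_f[t]) : 0.0;
    Fv[t] = Ft;
    double ssb = 0.0, cw = 0.0;
    for (int j = 0; j < A; ++j) {
      double n = N[t * A + j];
      if (!std::isfinite(n) || n < 0) return BIG;
      ssb += P.mat[j] * w[j] * n;
      double z = M + sel_f[j] * Ft;
      Z[t * A + j] = z;
      double c = (z > 0) ? sel_f[j] * Ft / z * (1.0 - std::exp(-z)) * n : 0.0;
      Cage[t * A + j] = c;
      cw += w[j] * c;
    }
    SSB[t] = ssb;
    catch_pred[t] = qf * cw;
    if (t + 1 < Y) {
      N[(t + 1) * A] = R[t + 1];
      for (int j = 1; j < A; ++j) {
        N[(t + 1) * A + j] = N[t * A + j - 1] * std::exp(-Z[t * A + j - 1]);
      }
      if (A > 1) {
        N[(t + 1) * A + A - 1] += N[t * A + A - 1] * std::exp(-Z[t * A + A - 1]);
      } else {
        N[(t + 1) * A] += N[t * A] * std::exp(-Z[t * A]);
      }
    }
  }

  // predicted observations
  std::vector<double> pred_index(NS * Y), pred_scomp(NS * Y * NB),
    pred_fcomp(Y * NB);
  for (int s = 0; s < NS; ++s) {
    double qs = std::exp(ln_qs[s]);
    for (int t = 0; t < Y; ++t) {
      double bio = 0.0;
      for (int j = 0; j < A; ++j) bio += sel_s[s * A + j] * w[j] * N[t * A + j];
      pred_index[s * Y + t] = qs * bio;
      double tot = 0.0;
      double* row = &pred_scomp[(s * Y + t) * NB];
      for (int b = 0; b < NB; ++b) row[b] = 0.0;
      for (int j = 0; j < A; ++j) {
        double pj = sel_s[s * A + j] * N[t * A + j];
        for (int b = 0; b < NB; ++b) row[b] += pj * AL[j * NB + b];
      }
      for (int b = 0; b < NB; ++b) tot += row[b];
      if (tot > 0) for (int b = 0; b < NB; ++b) row[b] /= tot;
    }
  }
  for (int t = 0; t < Y; ++t) {
    double tot = 0.0;
    double* row = &pred_fcomp[t * NB];
    for (int b = 0; b < NB; ++b) row[b] = 0.0;
    for (int j = 0; j < A; ++j) {
      double pj = Cage[t * A + j];
      for (int b = 0; b < NB; ++b) row[b] += pj * AL[j * NB + b];
    }
    for (int b = 0; b < NB; ++b) tot += row[b];
    if (tot > 0) for (int b = 0; b < NB; ++b) row[b] /= tot;
  }

  // --- negative log-likelihood -------------------------------------------
  double total = 0.0;
  std::vector<double> nll_index(NS, 0.0), nll_scomp(NS, 0.0);
  for (int s = 0; s < NS; ++s) {
    const Series& sv = P.surveys[s];
    for (size_t i = 0; i < sv.idx_pos.size(); ++i) {
      double pred = pred_index[s * Y + sv.idx_pos[i]];
      if (!(pred > 0)) return BIG;
      double r = std::log(sv.idx_obs[i]) - std::log(pred);
      nll_index[s] += 0.5 * std::log(sv.idx_sig2[i]) +
        r * r / (2.0 * sv.idx_sig2[i]);
    }
    int ny = (int)sv.cmp_pos.size();
    for (int i = 0; i < ny; ++i) {
      const double* row = &pred_scomp[(s * Y + sv.cmp_pos[i]) * NB];
      double acc = 0.0;
      for (int b = 0; b < NB; ++b) {
        double o = sv.cmp_obs[i + b * ny];   // column-major observed
        if (o > 0) acc += o * std::log(std::max(row[b], COMP_FLOOR));
      }
      nll_scomp[s] -= sv.cmp_neff[i] * acc;
    }
    total += nll_index[s] + nll_scomp[s];
  }
  double nll_catch = 0.0;
  double sig2C = std::log(1.0 + sigC * sigC);
  for (size_t i = 0; i < P.catch_pos.size(); ++i) {
    double pred = catch_pred[P.catch_pos[i]];
    if (!(pred > 0)) return BIG;
    double r = std::log(P.catch_obs[i]) - std::log(pred);
    nll_catch += 0.5 * std::log(sig2C) + r * r / (2.0 * sig2C);
  }
  total += nll_catch;
  double nll_fcomp = 0.0;
  {
    int ny = (int)P.fcomp.cmp_pos.size();
    for (int i = 0; i < ny; ++i) {
      const double* row = &pred_fcomp[P.fcomp.cmp_pos[i] * NB];
      double acc = 0.0;
      for (int b = 0; b < NB; ++b) {
        double o = P.fcomp.cmp_obs[i + b * ny];
        if (o > 0) acc += o * std::log(std::max(row[b], COMP_FLOOR));
      }
      nll_fcomp -= P.fcomp.cmp_neff[i] * acc;
    }
  }
  total += nll_fcomp;

  // --- penalties ----------------------------------------------------------
  int n_eps = NPRE + Y;
  double sum2 = 0.0, sum1 = 0.0;
  for (int i = 0; i < n_eps; ++i) {
    sum2 += eps_r[i] * eps_r[i];
    sum1 += eps_r[i];
  }
  double lam1 = P.l1 * (sum2 / (2.0 * sigR * sigR) + n_eps * std::log(sigR));
  double lam2 = 0.0;
  for (int t = 0; t < Y; ++t) {
    double s_prev = (t == 0) ? B0 : SSB[t - 1];
    double bh = 4.0 * h * R0 * s_prev / (B0 * (1.0 - h) + (5.0 * h - 1.0) * s_prev);
    if (!(bh > 0)) return BIG;
    double d = std::log(R[t]) - std::log(bh);
    lam2 += d * d;
  }
  lam2 *= P.l2;
  double lam3 = 0.0;
  for (int i = 0; i < NPRE; ++i) lam3 += eps_r[i] * eps_r[i];
  lam3 *= P.l3;
  double mean_eps = sum1 / n_eps;
  double lam4 = P.l4 * n_eps * mean_eps * mean_eps;
  double lam5 = 0.0, lam6 = 0.0;
  for (int t = 0; t < Y; ++t) {
    lam5 += eps_f[t] * eps_f[t];
    double ex = Fv[t] - P.fcap;
    if (ex > 0) lam6 += ex * ex;
  }
  lam5 *= P.l5;
  lam6 *= P.l6;
  total += lam1 + lam2 + lam3 + lam4 + lam5 + lam6;
  if (!std::isfinite(total)) return BIG;

  if (rep) {
    rep->N = N; rep->Z = Z; rep->Cage = Cage;
    rep->F = Fv; rep->SSB = SSB; rep->R = R; rep->catch_pred = catch_pred;
    rep->pred_index = pred_index; rep->pred_scomp = pred_scomp;
    rep->pred_fcomp = pred_fcomp; rep->AL = AL; rep->w = w;
    rep->sel_f = sel_f; rep->sel_s = sel_s;
    rep->B0 = B0; rep->R0 = R0; rep->phi0 = phi0;
    rep->nll_catch = nll_catch; rep->nll_fcomp = nll_fcomp;
    rep->nll_index = nll_index; rep->nll_scomp = nll_scomp;
    rep->lam[0] = lam1; rep->lam[1] = lam2; rep->lam[2] = lam3;
    rep->lam[3] = lam4; rep->lam[4] = lam5; rep->lam[5] = lam6;
    rep->total = total;
  }
  return total;
}

static NumericMatrix wrap_mat(const std::vector<double>& v, int nr, int nc) {
  NumericMatrix m(nr, nc);               // v is row-major
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) m(i, j) = v[i * nc + j];
  return m;
}

// [[Rcpp::export]]
double krill_nll_cpp(NumericVector par, List problem) {
  Problem P = build_problem(problem);
  if ((int)par.size() != P.npar()) stop("parameter vector length mismatch");
  return eval_model(P, REAL(par), nullptr);
}

// [[Rcpp::export]]
List krill_eval_cpp(NumericVector par, List problem) {
  Problem P = build_problem(problem);
  if ((int)par.size() != P.npar()) stop("parameter vector length mismatch");
  Report rep;
  double total = eval_model(P, REAL(par), &rep);
  if (rep.N.empty()) {
    return List::create(_["total"] = total, _["ok"] = false);
  }
  List scomp(P.NS);
  NumericMatrix pidx(P.NS, P.Y);
  for (int s = 0; s < P.NS; ++s) {
    std::vector<double> sub(rep.pred_scomp.begin() + (size_t)s * P.Y * P.NB,
                            rep.pred_scomp.begin() + (size_t)(s + 1) * P.Y * P.NB);
    scomp[s] = wrap_mat(sub, P.Y, P.NB);
    for (int t = 0; t < P.Y; ++t) pidx(s, t) = rep.pred_index[s * P.Y + t];
  }
  NumericMatrix sels(P.NS, P.A);
  for (int s = 0; s < P.NS; ++s)
    for (int j = 0; j < P.A; ++j) sels(s, j) = rep.sel_s[s * P.A + j];
  return List::create(
    _["ok"] = true,
    _["total"] = total,
    _["N"] = wrap_mat(rep.N, P.Y, P.A),
    _["Z"] = wrap_mat(rep.Z, P.Y, P.A),
    _["catch_at_age"] = wrap_mat(rep.Cage, P.Y, P.A),
    _["F"] = wrap(rep.F), _["SSB"] = wrap(rep.SSB), _["R"] = wrap(rep.R),
    _["catch_pred"] = wrap(rep.catch_pred),
    _["pred_index"] = pidx,
    _["pred_scomp"] = scomp,
    _["pred_fcomp"] = wrap_mat(rep.pred_fcomp, P.Y, P.NB),
    _["age_length"] = wrap_mat(rep.AL, P.A, P.NB),
    _["weight_at_age"] = wrap(rep.w),
    _["sel_f"] = wrap(rep.sel_f), _["sel_s"] = sels,
    _["B0"] = rep.B0, _["R0"] = rep.R0, _["phi0"] = rep.phi0,
    _["nll_index"] = wrap(rep.nll_index),
    _["nll_scomp"] = wrap(rep.nll_scomp),
    _["nll_catch"] = rep.nll_catch, _["nll_fcomp"] = rep.nll_fcomp,
    _["penalties"] = NumericVector::create(rep.lam[0], rep.lam[1], rep.lam[2],
                                           rep.lam[3], rep.lam[4], rep.lam[5]));
}

// transformed estimation scale: 0 identity, 1 logit(lo, hi), 2 log
static inline double x_from_t(double t, int type, double lo, double hi) {
  if (type == 1) return lo + (hi - lo) / (1.0 + std::exp(-t));
  if (type == 2) return std::exp(t);
  return t;
}

struct TMap {
  std::vector<int> idx;                // 0-based coords into full vector
  std::vector<int> type;
  std::vector<double> lo, hi;
};

static TMap build_tmap(const IntegerVector& idx0, const IntegerVector& type,
                       const NumericVector& lo, const NumericVector& hi) {
  TMap m;
  m.idx = as<std::vector<int>>(idx0);
  m.type = as<std::vector<int>>(type);
  m.lo = as<std::vector<double>>(lo);
  m.hi = as<std::vector<double>>(hi);
  return m;
}

static double eval_t(const Problem& P, std::vector<double>& x,
                     const TMap& m, const double* t) {
  for (size_t i = 0; i < m.idx.size(); ++i) {
    x[m.idx[i]] = x_from_t(t[i], m.type[i], m.lo[i], m.hi[i]);
  }
  return eval_model(P, x.data(), nullptr);
}

// [[Rcpp::export]]
double krill_nll_t_cpp(NumericVector t, NumericVector par_full,
                       IntegerVector idx0, IntegerVector type,
                       NumericVector lo, NumericVector hi, List problem) {
  Problem P = build_problem(problem);
  TMap m = build_tmap(idx0, type, lo, hi);
  std::vector<double> x(par_full.begin(), par_full.end());
  return eval_t(P, x, m, REAL(t));
}

// central finite-difference gradient on the transformed scale, restricted
// to the coordinates in `which0` (0-based positions within t)
// [[Rcpp::export]]
NumericVector krill_grad_t_cpp(NumericVector t, NumericVector par_full,
                               IntegerVector idx0, IntegerVector type,
                               NumericVector lo, NumericVector hi,
                               List problem, IntegerVector which0,
                               double h_rel = 1e-6) {
  Problem P = build_problem(problem);
  TMap m = build_tmap(idx0, type, lo, hi);
  std::vector<double> x(par_full.begin(), par_full.end());
  std::vector<double> tv(t.begin(), t.end());
  NumericVector g(which0.size());
  for (int k = 0; k < which0.size(); ++k) {
    int i = which0[k];
    double t0 = tv[i];
    double h = h_rel * std::max(1.0, std::fabs(t0));
    tv[i] = t0 + h;
    double fp = eval_t(P, x, m, tv.data());
    tv[i] = t0 - h;
    double fm = eval_t(P, x, m, tv.data());
    tv[i] = t0;
    g[k] = (fp - fm) / (2.0 * h);
  }
  // restore full x to the unperturbed point (not strictly needed)
  return g;
}

// dense finite-difference Hessian on the transformed scale over all of t
// [[Rcpp::export]]
NumericMatrix krill_hess_t_cpp(NumericVector t, NumericVector par_full,
                               IntegerVector idx0, IntegerVector type,
                               NumericVector lo, NumericVector hi,
                               List problem, double h_rel = 1e-4) {
  Problem P = build_problem(problem);
  TMap m = build_tmap(idx0, type, lo, hi);
  std::vector<double> x(par_full.begin(), par_full.end());
  std::vector<double> tv(t.begin(), t.end());
  int n = (int)tv.size();
  std::vector<double> h(n);
  for (int i = 0; i < n; ++i) h[i] = h_rel * std::max(1.0, std::fabs(tv[i]));
  double f0 = eval_t(P, x, m, tv.data());
  NumericMatrix H(n, n);
  std::vector<double> fp(n), fm(n);
  for (int i = 0; i < n; ++i) {
    double t0 = tv[i];
    tv[i] = t0 + h[i]; fp[i] = eval_t(P, x, m, tv.data());
    tv[i] = t0 - h[i]; fm[i] = eval_t(P, x, m, tv.data());
    tv[i] = t0;
    H(i, i) = (fp[i] - 2.0 * f0 + fm[i]) / (h[i] * h[i]);
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double ti = tv[i], tj = tv[j];
      tv[i] = ti + h[i]; tv[j] = tj + h[j];
      double fpp = eval_t(P, x, m, tv.data());
      tv[j] = tj - h[j];
      double fpm = eval_t(P, x, m, tv.data());
      tv[i] = ti - h[i]; tv[j] = tj + h[j];
      double fmp = eval_t(P, x, m, tv.data());
      tv[j] = tj - h[j];
      double fmm = eval_t(P, x, m, tv.data());
      tv[i] = ti; tv[j] = tj;
      double v = (fpp - fpm - fmp + fmm) / (4.0 * h[i] * h[j]);
      H(i, j) = v;
      H(j, i) = v;
    }
  }
  return H;
}
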