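// Panel log-likelihood of the four-state stage-transition model and its
// analytic gradient.  The hot path of estimation: called once per
// quasi-Newton iteration, per bootstrap replicate and per posterior draw.
//
// theta layout (must match pack_params() on the R side):
//   [ alpha_{sd} for s=1..3, d ascending skipping d=s  (9 values) |
//     beta^F source-major (3*p)                                   |
//     beta^B for sources 2,3 source-major (2*p, free constraint)  ]
// Under the antisymmetric constraint beta^B = -beta^F and the trailing
// block is absent.  Row 1 of beta^B is structurally zero.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int AIDX[9][2] = {
  {0, 1}, {0, 2}, {0, 3}, {1, 0}, {1, 2}, {1, 3}, {2, 0}, {2, 1}, {2, 3}};

struct Theta {
  mat alpha;  // 3x4, diagonal unused
  mat bf;     // 3xp
  mat bb;     // 3xp, row 0 zero
  bool antisym;
  int p;
};

static Theta unpack(const vec& theta, int p, bool antisym) {
  Theta t;
  t.p = p;
  t.antisym = antisym;
  t.alpha.zeros(3, 4);
  for (int a = 0; a < 9; ++a) t.alpha(AIDX[a][0], AIDX[a][1]) = theta(a);
  if (p > 0) {
    t.bf.zeros(3, p);
    for (int s = 0; s < 3; ++s)
      for (int j = 0; j < p; ++j) t.bf(s, j) = theta(9 + s * p + j);
    if (antisym) {
      t.bb = -t.bf;
      t.bb.row(0).zeros();
    } else {
      t.bb.zeros(3, p);
      for (int s = 1; s < 3; ++s)
        for (int j = 0; j < p; ++j)
          t.bb(s, j) = theta(9 + 3 * p + (s - 1) * p + j);
    }
  }
  return t;
}

// one-cycle matrix (and stable log-probabilities) for linear predictors
// f[s] = x.beta^F_s, b[s] = x.beta^B_s
typedef mat::fixed<4, 4> mat44;

static void build_P(const Theta& t, const rowvec& f, const rowvec& b,
                    mat44& P, mat44& logP) {
  P.zeros();
  logP.fill(-datum::inf);
  for (int s = 0; s < 3; ++s) {
    vec eta(4, fill::zeros);  // stay (d == s) has eta = 0
    for (int d = 0; d < 4; ++d) {
      if (d == s) continue;
      eta(d) = t.alpha(s, d) + (t.p > 0 ? (d > s ? f(s) : b(s)) : 0.0);
    }
    double m = eta.max();
    if (m < 0.0) m = 0.0;
    double denom = 0.0;
    vec w(4);
    for (int d = 0; d < 4; ++d) {
      w(d) = std::exp((d == s ? 0.0 : eta(d)) - m);
      denom += w(d);
    }
    double logdenom = m + std::log(denom);
    for (int d = 0; d < 4; ++d) {
      P(s, d) = w(d) / denom;
      logP(s, d) = (d == s ? 0.0 : eta(d)) - logdenom;
    }
  }
  P(3, 3) = 1.0;
  logP(3, 3) = 0.0;
}

// [[Rcpp::export]]
double cpp_panel_loglik(const arma::vec& theta, const arma::mat& X,
                        const arma::imat& terms, int p, bool antisym,
                        double ridge) {
  Theta t = unpack(theta, p, antisym);
  mat F, B;
  if (p > 0) {
    F = X * t.bf.t();  // n x 3
    B = X * t.bb.t();
  }
  const int m = terms.n_rows;
  double ll = 0.0;
  int last_subj = -1;
  mat44 P, logP;
  mat44 pows[10];  // pows[j] = P^j
  int npow = 0;
  rowvec zf(3, fill::zeros);
  for (int r = 0; r < m; ++r) {
    int i = terms(r, 0) - 1, a = terms(r, 1) - 1, bdest = terms(r, 2) - 1,
        k = terms(r, 3);
    if (i != last_subj) {
      if (p > 0)
        build_P(t, F.row(i), B.row(i), P, logP);
      else
        build_P(t, zf, zf, P, logP);
      pows[0].eye();
      pows[1] = P;
      npow = 2;
      last_subj = i;
    }
    if (k == 1) {
      ll += logP(a, bdest);
    } else {
      if (k > 9) Rcpp::stop("cycle gap too large (max 9)");
      while (npow <= k) { pows[npow] = pows[npow - 1] * P; ++npow; }
      double val = pows[k](a, bdest);
      if (val <= 0.0) return -datum::inf;
      ll += std::log(val);
    }
    if (!std::isfinite(ll)) return -datum::inf;
  }
  if (ridge > 0.0 && p > 0) {
    ll -= ridge * accu(square(t.bf));
    if (!antisym) ll -= ridge * accu(square(t.bb));
  }
  return ll;
}

// [[Rcpp::export]]
Rcpp::List cpp_panel_loglik_grad(const arma::vec& theta, const arma::mat& X,
                                 const arma::imat& terms, int p, bool antisym,
                                 double ridge) {
  Theta t = unpack(theta, p, antisym);
  mat F, B;
  if (p > 0) {
    F = X * t.bf.t();
    B = X * t.bb.t();
  }
  const int m = terms.n_rows;
  const int q = theta.n_elem;
  double ll = 0.0;
  mat agrad(3, 4, fill::zeros);
  mat bfgrad, bbgrad;
  if (p > 0) {
    bfgrad.zeros(3, p);
    bbgrad.zeros(3, p);
  }
  int last_subj = -1;
  mat44 P, logP;
  mat44 pows[10];
  int npow = 0;
  rowvec zf(3, fill::zeros);
  bool dead = false;
  for (int r = 0; r < m && !dead; ++r) {
    int i = terms(r, 0) - 1, a = terms(r, 1) - 1, bdest = terms(r, 2) - 1,
        k = terms(r, 3);
    if (i != last_subj) {
      if (p > 0)
        build_P(t, F.row(i), B.row(i), P, logP);
      else
        build_P(t, zf, zf, P, logP);
      pows[0].eye();
      pows[1] = P;
      npow = 2;
      last_subj = i;
    }
    if (k > 9) Rcpp::stop("cycle gap too large (max 9)");
    while (npow <= k) { pows[npow] = pows[npow - 1] * P; ++npow; }
    double val = pows[k](a, bdest);
    if (val <= 0.0 || !std::isfinite(std::log(val))) {
      dead = true;
      break;
    }
    ll += (k == 1 ? logP(a, bdest) : std::log(val));
    // W(u,v) = sum_{j=0}^{k-1} [P^j](a,u) [P^{k-1-j}](v,b) / val
    mat44 W;
    W.zeros();
    for (int j = 0; j < k; ++j) {
      const mat44& L = pows[j];
      const mat44& R = pows[k - 1 - j];
      for (int u = 0; u < 4; ++u)
        for (int v = 0; v < 4; ++v) W(u, v) += L(a, u) * R(v, bdest);
    }
    W /= val;
    for (int s = 0; s < 3; ++s) {
      double rowdot = 0.0;
      for (int v = 0; v < 4; ++v) rowdot += W(s, v) * P(s, v);
      double fsum = 0.0, bsum = 0.0;
      for (int d = 0; d < 4; ++d) {
        if (d == s) continue;
        double G = P(s, d) * (W(s, d) - rowdot);
        agrad(s, d) += G;
        if (d > s)
          fsum += G;
        else
          bsum += G;
      }
      if (p > 0 && (fsum != 0.0 || bsum != 0.0)) {
        for (int j = 0; j < p; ++j) {
          bfgrad(s, j) += fsum * X(i, j);
          bbgrad(s, j) += bsum * X(i, j);
        }
      }
    }
  }
  vec grad(q, fill::zeros);
  if (dead || !std::isfinite(ll)) {
    return Rcpp::List::create(Rcpp::Named("loglik") = -datum::inf,
                              Rcpp::Named("gradient") = grad);
  }
  if (ridge > 0.0 && p > 0) {
    ll -= ridge * accu(square(t.bf));
    bfgrad -= 2.0 * ridge * t.bf;
    if (!antisym) {
      ll -= ridge * accu(square(t.bb));
      bbgrad -= 2.0 * ridge * t.bb;
    }
  }
  for (int a2 = 0; a2 < 9; ++a2) grad(a2) = agrad(AIDX[a2][0], AIDX[a2][1]);
  if (p > 0) {
    if (antisym) {
      // eta uses bb = -bf (rows 2,3), so chain the backward piece in
      mat eff = bfgrad;
      eff.row(1) -= bbgrad.row(1);
      eff.row(2) -= bbgrad.row(2);
      for (int s = 0; s < 3; ++s)
        for (int j = 0; j < p; ++j) grad(9 + s * p + j) = eff(s, j);
    } else {
      for (int s = 0; s < 3; ++s)
        for (int j = 0; j < p; ++j) grad(9 + s * p + j) = bfgrad(s, j);
      for (int s = 1; s < 3; ++s)
        for (int j = 0; j < p; ++j)
          grad(9 + 3 * p + (s - 1) * p + j) = bbgrad(s, j);
    }
  }
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("gradient") = grad);
}
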