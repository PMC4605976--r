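// Core numerical routines: NIPALS PLS1 for a +/-1 coded response, leave-one-out
// complexity selection with per-fold rescaling, VIP and selectivity-ratio
// profiles, and the stratified bootstrap engine. Kept in C++ because the
// bootstrap re-selects model complexity by full LOO inside every replicate.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double EPS = 1e-12;

// column means / sds (denominator n-1) of X restricted to the rows in use.
static void col_scale_params(const arma::mat& X, arma::rowvec& mu,
                             arma::rowvec& sig) {
  mu = arma::mean(X, 0);
  sig = arma::stddev(X, 0, 0);  // norm_type 0 -> n-1
}

static arma::mat apply_scale(const arma::mat& X, const arma::rowvec& mu,
                             const arma::rowvec& sig) {
  arma::mat Z = X.each_row() - mu;
  arma::rowvec s = sig;
  // a column constant within this fold carries no information; mapping it to
  // zero (divisor 1) keeps the fit defined without inflating any weight
  s.elem(arma::find(s < EPS)).ones();
  Z.each_row() /= s;
  return Z;
}

// NIPALS PLS1 on an already-scaled X and +/-1 y. Returns weights W (columns
// unit norm), loadings P, scores T, y-loadings q, per-component explained
// y-sum-of-squares ssy, and the cumulative regression vectors B (column a =
// regression vector of the a-component model). May stop early when the
// residual covariance vanishes (rank exhausted); ncomp reports what was fit.
static void nipals_pls1(arma::mat X, arma::vec y, int A, arma::mat& W,
                        arma::mat& P, arma::mat& T, arma::vec& q,
                        arma::vec& ssy, arma::mat& B, int& ncomp) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  W.set_size(p, A); P.set_size(p, A); T.set_size(n, A);
  q.set_size(A); ssy.set_size(A);
  ncomp = 0;
  for (int a = 0; a < A; ++a) {
    arma::vec w = X.t() * y;
    double nw = arma::norm(w);
    if (nw < EPS) break;
    w /= nw;
    arma::vec t = X * w;
    double tt = arma::dot(t, t);
    if (tt < EPS) break;
    arma::vec pv = X.t() * t / tt;
    double qa = arma::dot(y, t) / tt;
    X -= t * pv.t();
    y -= qa * t;
    W.col(a) = w; P.col(a) = pv; T.col(a) = t;
    q(a) = qa; ssy(a) = qa * qa * tt;
    ++ncomp;
  }
  W.resize(p, ncomp); P.resize(p, ncomp); T.resize(n, ncomp);
  q.resize(ncomp); ssy.resize(ncomp);
  B.set_size(p, ncomp);
  for (int a = 1; a <= ncomp; ++a) {
    arma::mat Wa = W.cols(0, a - 1), Pa = P.cols(0, a - 1);
    arma::vec ba = Wa * arma::solve(Pa.t() * Wa, q.subvec(0, a - 1));
    B.col(a - 1) = ba;
  }
}

// [[Rcpp::export]]
List cpp_nipals(const arma::mat& X, const arma::vec& y, int A) {
  arma::mat W, P, T, B; arma::vec q, ssy; int ncomp;
  nipals_pls1(X, y, A, W, P, T, q, ssy, B, ncomp);
  return List::create(_["W"] = W, _["P"] = P, _["T"] = T, _["q"] = q,
                      _["ssy"] = ssy, _["B"] = B, _["ncomp"] = ncomp);
}

// Mann-Whitney AUC: fraction of (positive, negative) score pairs with the
// positive ranked higher; ties count one half.
static double mw_auc(const arma::vec& s, const arma::ivec& pos) {
  double num = 0.0; long np = 0, nn = 0;
  for (arma::uword i = 0; i < s.n_elem; ++i) {
    if (pos(i)) { ++np; } else { ++nn; }
  }
  if (np == 0 || nn == 0) return NA_REAL;
  for (arma::uword i = 0; i < s.n_elem; ++i) {
    if (!pos(i)) continue;
    for (arma::uword j = 0; j < s.n_elem; ++j) {
      if (pos(j)) continue;
      if (s(i) > s(j)) num += 1.0;
      else if (s(i) == s(j)) num += 0.5;
    }
  }
  return num / (double)(np * nn);
}

// [[Rcpp::export]]
double cpp_auc(const arma::vec& scores, const arma::ivec& positive) {
  return mw_auc(scores, positive);
}

// LOO misclassification rate for complexities 1..Amax on raw (unscaled) X;
// autoscaling is refit on every training fold. A score of exactly zero is
// assigned to the negative class. Folds whose training rows collapse to one
// class are skipped (cannot happen for stratified inputs with >=2 per class).
// [[Rcpp::export]]
arma::vec cpp_loo_misclass(const arma::mat& X, const arma::vec& y, int Amax) {
  const arma::uword n = X.n_rows;
  arma::vec errs(Amax, arma::fill::zeros);
  arma::vec used(Amax, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) {
    arma::mat Xtr = X; Xtr.shed_row(i);
    arma::vec ytr = y; ytr.shed_row(i);
    if (arma::all(ytr > 0) || arma::all(ytr < 0)) continue;
    arma::rowvec mu, sig;
    col_scale_params(Xtr, mu, sig);
    arma::mat Xs = apply_scale(Xtr, mu, sig);
    arma::mat W, P, T, B; arma::vec q, ssy; int ncomp;
    nipals_pls1(Xs, ytr, Amax, W, P, T, q, ssy, B, ncomp);
    if (ncomp == 0) continue;
    arma::rowvec xi = X.row(i);
    arma::rowvec s = sig;
    s.elem(arma::find(s < EPS)).ones();
    arma::rowvec xs = (xi - mu) / s;
    for (int a = 0; a < Amax; ++a) {
      int use = std::min(a, ncomp - 1);  // model cannot grow past its rank
      double pred = arma::dot(xs, B.col(use));
      bool predpos = pred > 0.0;
      bool truepos = y(i) > 0.0;
      if (predpos != truepos) errs(a) += 1.0;
      used(a) += 1.0;
    }
  }
  for (int a = 0; a < Amax; ++a)
    errs(a) = used(a) > 0 ? errs(a) / used(a) : NA_REAL;
  return errs;
}

// VIP profile from unit-norm weights and per-component explained y-SS.
static arma::vec vip_from(const arma::mat& W, const arma::vec& ssy) {
  const double p = (double)W.n_rows;
  arma::vec num = (W % W) * ssy;
  return arma::sqrt(p * num / arma::accu(ssy));
}

// [[Rcpp::export]]
arma::vec cpp_vip(const arma::mat& W, const arma::vec& ssy) {
  return vip_from(W, ssy);
}

// Target projection of an A-component model: the single predictive direction
// is the normalised regression vector; per-variable explained / residual
// sums of squares are taken on the A-component reconstruction of X by
// default (set reconstructed = false to project raw scaled X instead).
static void target_proj(const arma::mat& Xs, const arma::mat& T,
                        const arma::mat& P, const arma::vec& b,
                        bool reconstructed, arma::vec& wtp, arma::vec& ttp,
                        arma::vec& ptp, arma::vec& expl, arma::vec& resid) {
  double nb = arma::norm(b);
  wtp = b / nb;
  arma::mat XA = reconstructed ? arma::mat(T * P.t()) : Xs;
  ttp = XA * wtp;
  double tt = arma::dot(ttp, ttp);
  ptp = XA.t() * ttp / tt;
  expl = tt * (ptp % ptp);
  arma::vec tot = arma::sum(XA % XA, 0).t();
  resid = tot - expl;
  resid.elem(arma::find(resid < 0)).zeros();  // numerical guard
}

// [[Rcpp::export]]
List cpp_target_projection(const arma::mat& Xs, const arma::mat& T,
                           const arma::mat& P, const arma::vec& b,
                           bool reconstructed) {
  arma::vec wtp, ttp, ptp, expl, resid;
  target_proj(Xs, T, P, b, reconstructed, wtp, ttp, ptp, expl, resid);
  return List::create(_["w_tp"] = wtp, _["t_tp"] = ttp, _["p_tp"] = ptp,
                      _["explained"] = expl, _["residual"] = resid);
}

// Correct classification rate of the optimal univariate threshold
// classifier, per variable, averaged over resampled train/test halves.
// trainidx is (n_train x reps), 0-based rows of X used for threshold
// training in each repetition; the remaining rows are the evaluation half.
// Both cut directions are tried; training ties resolve to the first
// minimal-error threshold in scan order.
// [[Rcpp::export]]
arma::vec cpp_mccr(const arma::mat& X, const arma::ivec& pos,
                   const arma::imat& trainidx) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  const arma::uword ntr = trainidx.n_rows, reps = trainidx.n_cols;
  arma::vec ccr(p, arma::fill::zeros);
  for (arma::uword r = 0; r < reps; ++r) {
    arma::uvec intrain(n, arma::fill::zeros);
    arma::uvec tr(ntr);
    for (arma::uword i = 0; i < ntr; ++i) {
      tr(i) = (arma::uword)trainidx(i, r);
      intrain(tr(i)) = 1;
    }
    arma::uvec te = arma::find(intrain == 0);
    for (arma::uword j = 0; j < p; ++j) {
      arma::vec xt = X.col(j);
      arma::vec xtr = xt.elem(tr);
      arma::uvec ord = arma::sort_index(xtr);
      // cumulative positives left of each cut position
      long npos = 0;
      for (arma::uword i = 0; i < ntr; ++i) if (pos(tr(i))) ++npos;
      long nneg = (long)ntr - npos;
      // cut after position c (0..ntr): x <= sorted[c-1] is "left"
      long posleft = 0, negleft = 0;
      long besterr = ntr + 1; double bestthr = -arma::datum::inf;
      bool bestdir = true;  // true: right side predicted positive
      for (arma::uword c = 0; c <= ntr; ++c) {
        long err_up = posleft + (nneg - negleft);    // right = positive
        long err_dn = negleft + (npos - posleft);    // left  = positive
        long err = std::min(err_up, err_dn);
        if (err < besterr) {
          besterr = err;
          bestdir = err_up <= err_dn;
          if (c == 0) bestthr = -arma::datum::inf;
          else if (c == ntr) bestthr = arma::datum::inf;
          else bestthr = 0.5 * (xtr(ord(c - 1)) + xtr(ord(c)));
        }
        if (c < ntr) {
          if (pos(tr(ord(c)))) ++posleft; else ++negleft;
        }
      }
      long ok = 0;
      for (arma::uword i = 0; i < te.n_elem; ++i) {
        double v = xt(te(i));
        bool predpos = bestdir ? (v > bestthr) : (v <= bestthr);
        if (predpos == (pos(te(i)) == 1)) ++ok;
      }
      ccr(j) += (double)ok / (double)te.n_elem;
    }
  }
  return ccr / (double)reps;
}

// Bootstrap engine. idx is an n_model x B matrix of 0-based row indices into
// X (a stratified resample drawn in R so that seeding stays on the R side).
// Per replicate: refit scaling on the resample (or keep the model-set scaling
// if refit_scaling is false), select complexity by LOO, fit, score the
// out-of-bag rows for the AUC, and record VIP / SR profiles.
// [[Rcpp::export]]
List cpp_bootstrap(const arma::mat& X, const arma::vec& y,
                   const arma::imat& idx, int Amax, bool collect_vip,
                   bool collect_sr, bool oob_auc, bool refit_scaling,
                   bool sr_reconstructed) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  const arma::uword B = idx.n_cols, nb = idx.n_rows;
  arma::vec aucs(B); arma::ivec acomp(B);
  arma::mat vipmat, srmat;
  if (collect_vip) vipmat.set_size(B, p);
  if (collect_sr) srmat.set_size(B, p);
  arma::rowvec mu0, sig0;
  col_scale_params(X, mu0, sig0);
  for (arma::uword rb = 0; rb < B; ++rb) {
    if (rb % 64 == 0) Rcpp::checkUserInterrupt();
    arma::uvec rows(nb);
    for (arma::uword i = 0; i < nb; ++i) rows(i) = (arma::uword)idx(i, rb);
    arma::mat Xb = X.rows(rows);
    arma::vec yb = y.elem(rows);
    arma::rowvec mu, sig;
    if (refit_scaling) col_scale_params(Xb, mu, sig);
    else { mu = mu0; sig = sig0; }
    arma::vec rates = cpp_loo_misclass(Xb, yb, Amax);
    int A = 1; double best = arma::datum::inf;
    for (int a = 0; a < Amax; ++a) {
      if (std::isfinite(rates(a)) && rates(a) < best - EPS) {
        best = rates(a); A = a + 1;
      }
    }
    arma::mat Xs = apply_scale(Xb, mu, sig);
    arma::mat W, P, T, Bmat; arma::vec q, ssy; int ncomp;
    nipals_pls1(Xs, yb, A, W, P, T, q, ssy, Bmat, ncomp);
    acomp(rb) = ncomp;
    arma::vec b = Bmat.col(ncomp - 1);
    // out-of-bag rows: model-set samples never drawn in this replicate
    arma::uvec inbag(n, arma::fill::zeros);
    for (arma::uword i = 0; i < nb; ++i) inbag(rows(i)) = 1;
    arma::uvec oob = arma::find(inbag == 0);
    if (oob_auc && oob.n_elem > 0) {
      arma::mat Xo = apply_scale(X.rows(oob), mu, sig);
      arma::vec so = Xo * b;
      arma::ivec pos(oob.n_elem);
      for (arma::uword i = 0; i < oob.n_elem; ++i)
        pos(i) = y(oob(i)) > 0 ? 1 : 0;
      aucs(rb) = mw_auc(so, pos);
    } else {
      arma::vec si = Xs * b;
      arma::ivec pos(nb);
      for (arma::uword i = 0; i < nb; ++i) pos(i) = yb(i) > 0 ? 1 : 0;
      aucs(rb) = mw_auc(si, pos);
    }
    if (collect_vip) vipmat.row(rb) = vip_from(W, ssy).t();
    if (collect_sr) {
      arma::vec wtp, ttp, ptp, expl, resid;
      target_proj(Xs, T, P, b, sr_reconstructed, wtp, ttp, ptp, expl, resid);
      arma::vec tot = expl + resid;
      arma::rowvec sr(p);
      for (arma::uword j = 0; j < p; ++j) {
        if (resid(j) < EPS * std::max(tot(j), 1.0))
          sr(j) = arma::datum::inf;
        else sr(j) = expl(j) / resid(j);
      }
      srmat.row(rb) = sr;
    }
  }
  List out = List::create(_["auc"] = aucs, _["ncomp"] = acomp);
  if (collect_vip) out["vip"] = vipmat;
  if (collect_sr) out["sr"] = srmat;
  return out;
}
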