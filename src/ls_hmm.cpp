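// Haploid Li-Stephens copying-model HMM core.
//
// States are donor haplotypes j with stationary copying weights
// w_j = f_{pop(j)} / n_{pop(j)} (sum 1).  Over d cM the chain stays on the
// current haplotype with probability exp(-rho * d), otherwise redraws a
// haplotype from w (a redraw may land on the same haplotype).  Emission is
// 1 - theta on an allele match, theta on a mismatch, and 1 (uninformative)
// where the recipient call is missing.  All recursions are normalised per
// site, so likelihoods stay finite for any panel size.

#include <Rcpp.h>
using namespace Rcpp;

static inline double emit(int donor, int recip, double theta) {
  if (recip == NA_INTEGER) return 1.0;
  if (donor == NA_INTEGER) return 0.5;
  return donor == recip ? 1.0 - theta : theta;
}

// forward pass; alpha rows are normalised to sum 1
static double forward_pass(const IntegerMatrix& donors,
                           const IntegerVector& recipient,
                           const NumericVector& w,
                           const NumericVector& stay,
                           double theta, NumericMatrix& alpha) {
  const int H = donors.nrow(), S = donors.ncol();
  double loglik = 0.0;
  double c = 0.0;
  for (int j = 0; j < H; ++j) {
    double v = w[j] * emit(donors(j, 0), recipient[0], theta);
    alpha(0, j) = v;
    c += v;
  }
  if (c <= 0.0) stop("forward recursion underflow at site 1");
  for (int j = 0; j < H; ++j) alpha(0, j) /= c;
  loglik += std::log(c);
  for (int s = 1; s < S; ++s) {
    const double st = stay[s - 1], sw = 1.0 - st;
    c = 0.0;
    for (int j = 0; j < H; ++j) {
      double v = emit(donors(j, s), recipient[s], theta) *
                 (st * alpha(s - 1, j) + sw * w[j]);
      alpha(s, j) = v;
      c += v;
    }
    if (c <= 0.0) stop("forward recursion underflow at site %d", s + 1);
    for (int j = 0; j < H; ++j) alpha(s, j) /= c;
    loglik += std::log(c);
  }
  return loglik;
}

// backward pass; beta rows normalised (arbitrary scale, fixed per row)
static void backward_pass(const IntegerMatrix& donors,
                          const IntegerVector& recipient,
                          const NumericVector& w,
                          const NumericVector& stay,
                          double theta, NumericMatrix& beta) {
  const int H = donors.nrow(), S = donors.ncol();
  for (int j = 0; j < H; ++j) beta(S - 1, j) = 1.0;
  for (int s = S - 2; s >= 0; --s) {
    const double st = stay[s], sw = 1.0 - st;
    double pooled = 0.0;
    for (int k = 0; k < H; ++k)
      pooled += w[k] * emit(donors(k, s + 1), recipient[s + 1], theta) *
                beta(s + 1, k);
    double c = 0.0;
    for (int j = 0; j < H; ++j) {
      double v = st * emit(donors(j, s + 1), recipient[s + 1], theta) *
                     beta(s + 1, j) +
                 sw * pooled;
      beta(s, j) = v;
      c += v;
    }
    if (c <= 0.0) stop("backward recursion underflow at site %d", s + 1);
    for (int j = 0; j < H; ++j) beta(s, j) /= c;
  }
}

// [[Rcpp::export(name = ".ls_forward")]]
List ls_forward(IntegerMatrix donors, IntegerVector recipient,
                NumericVector w, NumericVector stay, double theta) {
  const int H = donors.nrow(), S = donors.ncol();
  if (recipient.size() != S) stop("recipient length mismatch");
  if (w.size() != H) stop("weight length mismatch");
  if (stay.size() != S - 1) stop("stay length mismatch");
  NumericMatrix alpha(S, H);
  double loglik = forward_pass(donors, recipient, w, stay, theta, alpha);
  return List::create(_["alpha"] = alpha, _["loglik"] = loglik);
}

// full forward-backward: per-site posterior over donor haplotypes plus the
// expected redraw ("choice") counts per haplotype used by the EM M-step
// [[Rcpp::export(name = ".ls_posterior")]]
List ls_posterior(IntegerMatrix donors, IntegerVector recipient,
                  NumericVector w, NumericVector stay, double theta) {
  const int H = donors.nrow(), S = donors.ncol();
  NumericMatrix alpha(S, H), beta(S, H), gamma(S, H);
  double loglik = forward_pass(donors, recipient, w, stay, theta, alpha);
  backward_pass(donors, recipient, w, stay, theta, beta);
  NumericVector draws(H);
  for (int s = 0; s < S; ++s) {
    double c = 0.0;
    for (int j = 0; j < H; ++j) {
      double v = alpha(s, j) * beta(s, j);
      gamma(s, j) = v;
      c += v;
    }
    for (int j = 0; j < H; ++j) gamma(s, j) /= c;
  }
  // initial state is always a draw from w
  for (int j = 0; j < H; ++j) draws[j] += gamma(0, j);
  for (int s = 0; s + 1 < S; ++s) {
    const double st = stay[s], sw = 1.0 - st;
    double D = 0.0;
    for (int j = 0; j < H; ++j) {
      double e = emit(donors(j, s + 1), recipient[s + 1], theta) *
                 beta(s + 1, j);
      D += e * (st * alpha(s, j) + sw * w[j]);
    }
    for (int j = 0; j < H; ++j) {
      double e = emit(donors(j, s + 1), recipient[s + 1], theta) *
                 beta(s + 1, j);
      draws[j] += sw * w[j] * e / D;
    }
  }
  return List::create(_["gamma"] = gamma, _["loglik"] = loglik,
                      _["draws"] = draws);
}

// stochastic backward sampling of R state paths from the forward matrix,
// accumulated directly into per-site donor-subpopulation counts.
// pop_of is the 1-based subpopulation index of each haplotype.
// Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export(name = ".ls_sample_paths")]]
IntegerMatrix ls_sample_paths(NumericMatrix alpha, NumericVector w,
                              NumericVector stay, IntegerVector pop_of,
                              int K, int n_rep) {
  const int S = alpha.nrow(), H = alpha.ncol();
  IntegerMatrix counts(S, K);
  // per-site cumulative forward distributions for O(log H) draws
  NumericMatrix cum(S, H);
  for (int s = 0; s < S; ++s) {
    double acc = 0.0;
    for (int j = 0; j < H; ++j) { acc += alpha(s, j); cum(s, j) = acc; }
    for (int j = 0; j < H; ++j) cum(s, j) /= acc;
  }
  auto draw_from = [&](int s) {
    double u = unif_rand();
    int lo = 0, hi = H - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum(s, mid) < u) lo = mid + 1; else hi = mid;
    }
    return lo;
  };
  for (int r = 0; r < n_rep; ++r) {
    int z = draw_from(S - 1);
    counts(S - 1, pop_of[z] - 1) += 1;
    for (int s = S - 2; s >= 0; --s) {
      const double st = stay[s], sw = 1.0 - st;
      const double stay_mass = st * alpha(s, z);
      const double draw_mass = sw * w[z];
      if (unif_rand() * (stay_mass + draw_mass) >= stay_mass)
        z = draw_from(s);
      counts(s, pop_of[z] - 1) += 1;
    }
  }
  return counts;
}
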