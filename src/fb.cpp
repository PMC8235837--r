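#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for the per-parent two-state inheritance chain.
// ev: 2 x L per-locus evidence (unnormalised likelihoods, columns > 0),
// r:  length L-1 recombination fractions per interval.
// Returns smoothed marginals gamma (2 x L), expected crossover count per
// interval (sum over a != b of the normalised pairwise posterior xi), and
// the scaled forward/backward caches.
// [[Rcpp::export(name = ".fb_twostate_cpp")]]
List fb_twostate_cpp(NumericMatrix ev, NumericVector r) {
  const int L = ev.ncol();
  if (ev.nrow() != 2) stop("evidence must be a 2 x L matrix");
  if (r.size() != L - 1) stop("need one recombination fraction per interval");

  NumericMatrix alpha(2, L), beta(2, L), gamma(2, L);
  NumericVector exc(std::max(L - 1, 0));

  // forward, scaled to sum 1 per locus
  double a0 = 0.5 * ev(0, 0), a1 = 0.5 * ev(1, 0);
  double s = a0 + a1;
  if (s <= 0.0) { a0 = a1 = 0.5; s = 1.0; }
  alpha(0, 0) = a0 / s; alpha(1, 0) = a1 / s;
  for (int j = 1; j < L; ++j) {
    const double rj = r[j - 1];
    const double p0 = alpha(0, j - 1) * (1.0 - rj) + alpha(1, j - 1) * rj;
    const double p1 = alpha(0, j - 1) * rj + alpha(1, j - 1) * (1.0 - rj);
    a0 = ev(0, j) * p0; a1 = ev(1, j) * p1;
    s = a0 + a1;
    if (s <= 0.0) { a0 = p0; a1 = p1; s = a0 + a1; }
    alpha(0, j) = a0 / s; alpha(1, j) = a1 / s;
  }

  // backward, scaled to sum 1 per locus
  beta(0, L - 1) = 0.5; beta(1, L - 1) = 0.5;
  for (int j = L - 2; j >= 0; --j) {
    const double rj = r[j];
    const double e0 = ev(0, j + 1) * beta(0, j + 1);
    const double e1 = ev(1, j + 1) * beta(1, j + 1);
    double b0 = (1.0 - rj) * e0 + rj * e1;
    double b1 = rj * e0 + (1.0 - rj) * e1;
    s = b0 + b1;
    if (s <= 0.0) { b0 = b1 = 0.5; s = 1.0; }
    beta(0, j) = b0 / s; beta(1, j) = b1 / s;
  }

  for (int j = 0; j < L; ++j) {
    double g0 = alpha(0, j) * beta(0, j);
    double g1 = alpha(1, j) * beta(1, j);
    s = g0 + g1;
    if (s <= 0.0) { g0 = g1 = 0.5; s = 1.0; }
    gamma(0, j) = g0 / s; gamma(1, j) = g1 / s;
  }

  // pairwise posterior over neighbouring loci; expected crossovers = off-diag
  for (int j = 0; j < L - 1; ++j) {
    const double rj = r[j];
    const double e0 = ev(0, j + 1) * beta(0, j + 1);
    const double e1 = ev(1, j + 1) * beta(1, j + 1);
    const double x00 = alpha(0, j) * (1.0 - rj) * e0;
    const double x01 = alpha(0, j) * rj * e1;
    const double x10 = alpha(1, j) * rj * e0;
    const double x11 = alpha(1, j) * (1.0 - rj) * e1;
    const double tot = x00 + x01 + x10 + x11;
    exc[j] = tot > 0.0 ? (x01 + x10) / tot : rj;
  }

  return List::create(_["gamma"] = gamma, _["exc"] = exc,
                      _["alpha"] = alpha, _["beta"] = beta);
}
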