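#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Offspring genotype distribution for one reproduction step.
// Counts n0/n1/n2 are wt-hom, het, te-hom; s is the selection coefficient
// acting on te-hom only (h = 0). Parent 1 is drawn proportional to fitness;
// with probability `selfing` it selfs, otherwise parent 2 is an independent
// fitness-proportional draw (with replacement). Because parent picks are iid
// across offspring, offspring genotypes are iid and the next generation is
// exactly Multinomial(N', p).
static inline void offspring_probs(double n0, double n1, double n2,
                                   double s, double selfing, double *p) {
  const double w2 = 1.0 + s;            // te-hom fitness, guaranteed >= 0
  const double tot = n0 + n1 + n2 * w2; // N * wbar
  const double q0 = n0 / tot, q1 = n1 / tot, q2 = n2 * w2 / tot;
  const double a = 0.5 * q1 + q2;       // marginal TE gamete probability
  // selfing mixture: hom parents breed true, selfed het segregates 1:2:1
  const double s0 = q0 + 0.25 * q1;
  const double s1 = 0.5 * q1;
  const double s2 = q2 + 0.25 * q1;
  p[0] = selfing * s0 + (1.0 - selfing) * (1.0 - a) * (1.0 - a);
  p[1] = selfing * s1 + (1.0 - selfing) * 2.0 * a * (1.0 - a);
  p[2] = selfing * s2 + (1.0 - selfing) * a * a;
}

// One full replicate: founder state (K-1, 1, 0), G reproduction steps.
// drought[t] (length G) selects s_plus vs s_minus for the step *into*
// generation t+1. Hard selection: N' = min(K, round(K * wbar)); rounding is
// half-to-even (nearbyint) to match base R's round() in the exact oracle.
// Returns c(n0, n1, n2, freq, extinct).
// [[Rcpp::export]]
NumericVector sim_replicate_cpp(int K, double selfing, int G,
                                double s_plus, double s_minus,
                                LogicalVector drought) {
  int n[3] = {K - 1, 1, 0};
  bool extinct = false;
  double p[3];
  for (int t = 0; t < G; ++t) {
    const double s = drought[t] ? s_plus : s_minus;
    const double n0 = n[0], n1 = n[1], n2 = n[2];
    const double N = n0 + n1 + n2;
    const double w2 = 1.0 + s;
    const double wbar = (n0 + n1 + n2 * w2) / N;
    int Np = (int) std::nearbyint(K * wbar);
    if (Np > K) Np = K;
    if (Np <= 0) { n[0] = n[1] = n[2] = 0; extinct = true; break; }
    offspring_probs(n0, n1, n2, s, selfing, p);
    rmultinom(Np, p, 3, n);
    // allele lost: the population deterministically refills to K wild-types
    if (n[1] == 0 && n[2] == 0 && t < G - 1) { n[0] = K; break; }
  }
  const double size = n[0] + n[1] + n[2];
  const double freq = size > 0 ? (n[1] + 2.0 * n[2]) / (2.0 * size) : 0.0;
  return NumericVector::create(n[0], n[1], n[2], freq, extinct ? 1.0 : 0.0);
}

// Batched replicates with per-replicate child seeds handled on the R side
// would cost one .Call each; instead accept a seed vector and reseed R's RNG
// is not possible from C. So this batch runner draws all replicates from the
// single current RNG stream; run_replicates() in R decides which entry point
// to use. Returns a nrep x 5 matrix with the sim_replicate_cpp layout.
// [[Rcpp::export]]
NumericMatrix sim_replicates_cpp(int K, double selfing, int G,
                                 double s_plus, double s_minus,
                                 LogicalVector drought, int nrep) {
  NumericMatrix out(nrep, 5);
  for (int r = 0; r < nrep; ++r) {
    NumericVector res = sim_replicate_cpp(K, selfing, G, s_plus, s_minus, drought);
    for (int j = 0; j < 5; ++j) out(r, j) = res[j];
  }
  return out;
}

// Per-generation trajectory of one replicate: (G+1) x 5 matrix of
// generation, n0, n1, n2, freq (row 0 = founder state). Extinct generations
// keep zero counts.
// [[Rcpp::export]]
NumericMatrix sim_trajectory_cpp(int K, double selfing, int G,
                                 double s_plus, double s_minus,
                                 LogicalVector drought) {
  NumericMatrix out(G + 1, 5);
  int n[3] = {K - 1, 1, 0};
  double p[3];
  bool dead = false;
  out(0, 0) = 0; out(0, 1) = n[0]; out(0, 2) = n[1]; out(0, 3) = n[2];
  out(0, 4) = 1.0 / (2.0 * K);
  for (int t = 0; t < G; ++t) {
    if (!dead) {
      const double s = drought[t] ? s_plus : s_minus;
      const double n0 = n[0], n1 = n[1], n2 = n[2];
      const double N = n0 + n1 + n2;
      const double w2 = 1.0 + s;
      const double wbar = (n0 + n1 + n2 * w2) / N;
      int Np = (int) std::nearbyint(K * wbar);
      if (Np > K) Np = K;
      if (Np <= 0) { n[0] = n[1] = n[2] = 0; dead = true; }
      else { offspring_probs(n0, n1, n2, s, selfing, p); rmultinom(Np, p, 3, n); }
    }
    const double size = n[0] + n[1] + n[2];
    out(t + 1, 0) = t + 1;
    out(t + 1, 1) = n[0]; out(t + 1, 2) = n[1]; out(t + 1, 3) = n[2];
    out(t + 1, 4) = size > 0 ? (n[1] + 2.0 * n[2]) / (2.0 * size) : NA_REAL;
  }
  return out;
}
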