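#include <Rcpp.h>
using namespace Rcpp;

// Chromatin states are encoded as integers: M = -1, U = 0, A = +1.
// Promoter sites: F = 0, B = 1. All randomness flows through R's RNG
// (unif_rand), so set.seed() at the R level fully determines output.

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// Coupling adjustment of one parameter q favoured by signal x in [-1, 1].
// Model 1 (asymmetric multiplicative): q*(1 + C*x) for x >= 0, q/(1 + C*|x|)
// otherwise. Model 2 (signed-linear): q*(1 + C*x). Both clamped to [0, 1].
static inline double adjust_one(double q, double C, double x, int model) {
  double r;
  if (model == 2) {
    r = q * (1.0 + C * x);
  } else {
    r = (x >= 0.0) ? q * (1.0 + C * x) : q / (1.0 + C * (-x));
  }
  return clamp01(r);
}

// [[Rcpp::export]]
NumericVector cpp_adjust_params(double p1, double p2, double p3, double p4,
                                double E, double P, double C, int model) {
  NumericVector out(4);
  out[0] = adjust_one(p1, C, E, model);   // binding favoured by active PRE/TRE
  out[1] = adjust_one(p2, C, -E, model);  // unbinding favoured by silent PRE/TRE
  out[2] = adjust_one(p3, C, -P, model);  // M-feedback favoured by silent promoter
  out[3] = adjust_one(p4, C, P, model);   // A-feedback favoured by active promoter
  return out;
}

// One update attempt: pick a target uniformly; with probability 0.5 a
// feedback attempt (mediator uniform among the other S-1 nucleosomes,
// one-step conversion toward the mediator's modified state with p3/p4),
// otherwise a feedback-independent attempt (with p5, modified -> U;
// U -> A or M with equal probability). Conversions are stepwise only.
static void chromatin_attempt(std::vector<int> &st, double p3, double p4,
                              double p5) {
  const int S = (int)st.size();
  int t = (int)(unif_rand() * S);
  if (t >= S) t = S - 1;
  if (unif_rand() < 0.5) {
    int m = (int)(unif_rand() * (S - 1));
    if (m >= S - 1) m = S - 2;
    if (m >= t) ++m;  // mediator != target, uniform over the rest
    const int med = st[m];
    if (med == 1) {
      if (st[t] < 1 && unif_rand() < p4) st[t] += 1;
    } else if (med == -1) {
      if (st[t] > -1 && unif_rand() < p3) st[t] -= 1;
    }
  } else {
    if (unif_rand() < p5) {
      if (st[t] != 0) st[t] = 0;
      else st[t] = (unif_rand() < 0.5) ? 1 : -1;
    }
  }
}

// [[Rcpp::export]]
IntegerVector cpp_chromatin_sweep(IntegerVector states, double p3, double p4,
                                  double p5, int attempts) {
  std::vector<int> st(states.begin(), states.end());
  for (int i = 0; i < attempts; ++i) chromatin_attempt(st, p3, p4, p5);
  return wrap(st);
}

// [[Rcpp::export]]
IntegerVector cpp_promoter_sweep(IntegerVector sites, double p1, double p2) {
  IntegerVector out = clone(sites);
  const int s = out.size();
  for (int j = 0; j < s; ++j) {
    if (out[j] == 0) {
      if (unif_rand() < p1) out[j] = 1;
    } else {
      if (unif_rand() < p2) out[j] = 0;
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_replicate_chromatin(IntegerVector states, double wipe_prob) {
  IntegerVector out = clone(states);
  for (int j = 0; j < out.size(); ++j)
    if (unif_rand() < wipe_prob) out[j] = 0;
  return out;
}

// Full coupled engine. One step = one simulated minute: read the pre-step
// promoter activity a and PRE/TRE state E, adjust (p1,p2,p3,p4) via the
// coupling model, one promoter sweep, `attempts` chromatin attempts, then
// (if the step ends a dividing cycle) mitotic reset of the promoter and
// replication wipe of the chromatin. Row i+1 of the output records the
// state at the end of minute i+1, sampled before any division event so
// that the recorded series reflects the interphase state of the cycle
// just completed; the division's effects appear from the next minute.
// Columns: activity, a_frac, u_frac, m_frac.
// [[Rcpp::export]]
NumericMatrix cpp_run_engine(IntegerVector chrom0, IntegerVector prom0,
                             NumericVector p1v, NumericVector p2v,
                             NumericVector p3v, NumericVector p4v,
                             NumericVector p5v, NumericVector Cv,
                             IntegerVector modelv, LogicalVector divide,
                             int attempts, double wipe_prob) {
  const int T = p1v.size();
  const int S = chrom0.size();
  const int s = prom0.size();
  std::vector<int> chrom(chrom0.begin(), chrom0.end());
  std::vector<int> prom(prom0.begin(), prom0.end());
  NumericMatrix out(T + 1, 4);

  auto record = [&](int row) {
    int nB = 0;
    for (int j = 0; j < s; ++j) nB += prom[j];
    int nA = 0, nM = 0;
    for (int j = 0; j < S; ++j) {
      if (chrom[j] == 1) ++nA;
      else if (chrom[j] == -1) ++nM;
    }
    out(row, 0) = (double)nB / s;
    out(row, 1) = (double)nA / S;
    out(row, 2) = (double)(S - nA - nM) / S;
    out(row, 3) = (double)nM / S;
  };
  record(0);

  for (int i = 0; i < T; ++i) {
    double a = 0.0;
    for (int j = 0; j < s; ++j) a += prom[j];
    a /= s;
    double E = 0.0;
    for (int j = 0; j < S; ++j) E += chrom[j];
    E /= S;
    const double P = 2.0 * a - 1.0;
    const double C = Cv[i];
    const int model = modelv[i];
    const double p1 = adjust_one(p1v[i], C, E, model);
    const double p2 = adjust_one(p2v[i], C, -E, model);
    const double p3 = adjust_one(p3v[i], C, -P, model);
    const double p4 = adjust_one(p4v[i], C, P, model);

    for (int j = 0; j < s; ++j) {
      if (prom[j] == 0) {
        if (unif_rand() < p1) prom[j] = 1;
      } else {
        if (unif_rand() < p2) prom[j] = 0;
      }
    }
    for (int k = 0; k < attempts; ++k)
      chromatin_attempt(chrom, p3, p4, p5v[i]);

    record(i + 1);
    if (divide[i]) {
      std::fill(prom.begin(), prom.end(), 0);
      for (int j = 0; j < S; ++j)
        if (unif_rand() < wipe_prob) chrom[j] = 0;
    }
  }
  return out;
}

// Batched replicate sweeps for comparison against the exact chain: runs n
// independent replicates of k sweeps (attempts_per_sweep attempts each)
// from `init`, returning each final configuration encoded in base 3
// (digit j = state of nucleosome j + 1), 0-based.
// [[Rcpp::export]]
IntegerVector cpp_sweep_batch(IntegerVector init, double p3, double p4,
                              double p5, int attempts_per_sweep, int k,
                              int n) {
  const int S = init.size();
  IntegerVector out(n);
  std::vector<int> st(S);
  for (int r = 0; r < n; ++r) {
    std::copy(init.begin(), init.end(), st.begin());
    for (int sw = 0; sw < k; ++sw)
      for (int a = 0; a < attempts_per_sweep; ++a)
        chromatin_attempt(st, p3, p4, p5);
    int code = 0, pw = 1;
    for (int j = 0; j < S; ++j) {
      code += (st[j] + 1) * pw;
      pw *= 3;
    }
    out[r] = code;
  }
  return out;
}
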