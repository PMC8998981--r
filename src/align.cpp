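// Global sequence-vs-PWM alignment with affine gap penalties.
//
// Three-state formulation: M ends in a residue/column match, X ends in a
// gap in the sequence (a PWM column unmatched), Y ends in a gap in the PWM
// (a residue inserted relative to the PWM). A gap run of length g costs
// d + (g - 1) * e; switching between X and Y opens a new run. Terminal gaps
// are charged (global end-to-end alignment). Ties are broken M > X > Y,
// identically during fill and traceback, so results are deterministic.

#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Step codes shared with the R side.
static const int STEP_MATCH = 0;       // consume residue + column
static const int STEP_GAP_IN_SEQ = 1;  // consume column only
static const int STEP_GAP_IN_PWM = 2;  // consume residue only

// Pick the best of (m, x, y) with preference M > X > Y at ties.
static inline int best3(double m, double x, double y, double &val) {
  val = m;
  int s = 0;
  if (x > val) { val = x; s = 1; }
  if (y > val) { val = y; s = 2; }
  return s;
}

// Score-only DP with two rolling rows. seq holds 1-based rows of pwm.
static double align_score_only(const std::vector<int> &seq,
                               const NumericMatrix &pwm,
                               double d, double e) {
  const int L1 = (int)seq.size();
  const int L = pwm.ncol();
  std::vector<double> Mprev(L + 1), Xprev(L + 1), Yprev(L + 1);
  std::vector<double> Mcur(L + 1), Xcur(L + 1), Ycur(L + 1);

  Mprev[0] = 0.0; Xprev[0] = NEG_INF; Yprev[0] = NEG_INF;
  for (int j = 1; j <= L; ++j) {
    Mprev[j] = NEG_INF;
    Xprev[j] = -d - (j - 1) * e;
    Yprev[j] = NEG_INF;
  }
  for (int i = 1; i <= L1; ++i) {
    Mcur[0] = NEG_INF;
    Xcur[0] = NEG_INF;
    Ycur[0] = -d - (i - 1) * e;
    const int ri = seq[i - 1] - 1;
    for (int j = 1; j <= L; ++j) {
      double diag = Mprev[j - 1];
      if (Xprev[j - 1] > diag) diag = Xprev[j - 1];
      if (Yprev[j - 1] > diag) diag = Yprev[j - 1];
      Mcur[j] = (diag == NEG_INF) ? NEG_INF : diag + pwm(ri, j - 1);

      double x = Mcur[j - 1] - d;
      if (Xcur[j - 1] - e > x) x = Xcur[j - 1] - e;
      if (Ycur[j - 1] - d > x) x = Ycur[j - 1] - d;
      Xcur[j] = x;

      double y = Mprev[j] - d;
      if (Xprev[j] - d > y) y = Xprev[j] - d;
      if (Yprev[j] - e > y) y = Yprev[j] - e;
      Ycur[j] = y;
    }
    std::swap(Mprev, Mcur);
    std::swap(Xprev, Xcur);
    std::swap(Yprev, Ycur);
  }
  double best = Mprev[L];
  if (Xprev[L] > best) best = Xprev[L];
  if (Yprev[L] > best) best = Yprev[L];
  return best;
}

// [[Rcpp::export(name = ".align_score_cpp")]]
double align_score_cpp(IntegerVector seq, NumericMatrix pwm,
                       double d, double e) {
  std::vector<int> s(seq.begin(), seq.end());
  return align_score_only(s, pwm, d, e);
}

// Sum of optimal scores over a list of sequences (the objective mF).
// [[Rcpp::export(name = ".align_score_sum_cpp")]]
double align_score_sum_cpp(List seqs, NumericMatrix pwm, double d, double e) {
  double total = 0.0;
  for (int k = 0; k < seqs.size(); ++k) {
    IntegerVector sv = seqs[k];
    std::vector<int> s(sv.begin(), sv.end());
    total += align_score_only(s, pwm, d, e);
  }
  return total;
}

// Full DP with stored per-state predecessor pointers and traceback.
// Returns list(score, steps) with steps in left-to-right order.
// [[Rcpp::export(name = ".align_traceback_cpp")]]
List align_traceback_cpp(IntegerVector seq, NumericMatrix pwm,
                         double d, double e) {
  const int L1 = seq.size();
  const int L = pwm.ncol();
  const size_t W = (size_t)(L + 1);
  auto at = [W](int i, int j) { return (size_t)i * W + (size_t)j; };

  std::vector<double> M(at(L1, L) + 1, NEG_INF), X(at(L1, L) + 1, NEG_INF),
      Y(at(L1, L) + 1, NEG_INF);
  // predecessor state entering each cell/state (0=M,1=X,2=Y, -1 none)
  std::vector<signed char> pM(M.size(), -1), pX(M.size(), -1),
      pY(M.size(), -1);

  M[at(0, 0)] = 0.0;
  for (int j = 1; j <= L; ++j) {
    X[at(0, j)] = -d - (j - 1) * e;
    pX[at(0, j)] = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= L1; ++i) {
    Y[at(i, 0)] = -d - (i - 1) * e;
    pY[at(i, 0)] = (i == 1) ? 0 : 2;
  }
  for (int i = 1; i <= L1; ++i) {
    const int ri = seq[i - 1] - 1;
    for (int j = 1; j <= L; ++j) {
      double val;
      int s;
      s = best3(M[at(i - 1, j - 1)], X[at(i - 1, j - 1)], Y[at(i - 1, j - 1)],
                val);
      if (val != NEG_INF) {
        M[at(i, j)] = val + pwm(ri, j - 1);
        pM[at(i, j)] = (signed char)s;
      }
      s = best3(M[at(i, j - 1)] - d, X[at(i, j - 1)] - e,
                Y[at(i, j - 1)] - d, val);
      if (val != NEG_INF) {
        X[at(i, j)] = val;
        pX[at(i, j)] = (signed char)s;
      }
      s = best3(M[at(i - 1, j)] - d, X[at(i - 1, j)] - d,
                Y[at(i - 1, j)] - e, val);
      if (val != NEG_INF) {
        Y[at(i, j)] = val;
        pY[at(i, j)] = (signed char)s;
      }
    }
  }

  double fmax;
  int state = best3(M[at(L1, L)], X[at(L1, L)], Y[at(L1, L)], fmax);

  std::vector<int> steps;
  steps.reserve(L1 + L);
  int i = L1, j = L;
  while (i > 0 || j > 0) {
    if (state == 0) {
      steps.push_back(STEP_MATCH);
      state = pM[at(i, j)];
      --i; --j;
    } else if (state == 1) {
      steps.push_back(STEP_GAP_IN_SEQ);
      state = pX[at(i, j)];
      --j;
    } else {
      steps.push_back(STEP_GAP_IN_PWM);
      state = pY[at(i, j)];
      --i;
    }
  }
  std::reverse(steps.begin(), steps.end());
  return List::create(Named("score") = fmax,
                      Named("steps") = IntegerVector(steps.begin(),
                                                     steps.end()));
}
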