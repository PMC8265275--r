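// Intermolecular RNA-RNA duplex minimum free energy.
//
// Energy model (a deliberate simplification with published-style
// magnitudes): consecutive base pairs contribute a nearest-neighbor stack
// term equal to minus the mean of the two pair strengths
// (CG/GC 3.4, AU/UA 1.3, GU/UG 0.9 kcal/mol), bulges of 1-3 nt cost
// +3.0 + 0.5*size, internal loops of total size 2-4 nt cost
// +2.5 + 0.5*size. No intramolecular pairs, no pseudoknots; larger loops
// and bulges break the helix. A lone pair carries no stack and scores 0;
// the reported MFE is never positive.
//
// Bases are encoded A=0, C=1, G=2, U=3. Both strands are given 5'->3';
// pairing is antiparallel: if (i, j) and (i', j') are pairs with i < i'
// then j > j'.

#include <Rcpp.h>
using namespace Rcpp;

static const double PAIR_STRENGTH_CG = 3.4;
static const double PAIR_STRENGTH_AU = 1.3;
static const double PAIR_STRENGTH_GU = 0.9;
static const int MAX_BULGE = 3;
static const int MAX_INTERNAL = 4;

// pair strength; < 0 when (a, b) is not a WC or wobble pair
static double pair_strength(int a, int b) {
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return PAIR_STRENGTH_AU;
  if ((a == 1 && b == 2) || (a == 2 && b == 1)) return PAIR_STRENGTH_CG;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return PAIR_STRENGTH_GU;
  return -1.0;
}

static double stack_energy(double s_prev, double s_next) {
  return -(s_prev + s_next) / 2.0;
}

// loop penalty between consecutive pairs separated by a unpaired nt on one
// strand and b on the other; +infinity (encoded as NA) when disallowed
static double loop_penalty(int a, int b) {
  if (a == 0 && b == 0) return 0.0; // stacked, handled separately
  if (a == 0 || b == 0) {
    int size = a + b;
    if (size > MAX_BULGE) return NA_REAL;
    return 3.0 + 0.5 * size;
  }
  int size = a + b;
  if (size > MAX_INTERNAL) return NA_REAL;
  return 2.5 + 0.5 * size;
}

// core DP over s1[lo1..hi1], s2[lo2..hi2] (0-based, inclusive)
static double duplex_core(const IntegerVector& s1, const IntegerVector& s2,
                          int lo1, int hi1, int lo2, int hi2) {
  int n1 = hi1 - lo1 + 1;
  int n2 = hi2 - lo2 + 1;
  if (n1 <= 0 || n2 <= 0) return 0.0;
  std::vector<double> E((size_t)n1 * n2, NA_REAL);
  double best = 0.0;
  for (int i = 0; i < n1; ++i) {
    for (int j = n2 - 1; j >= 0; --j) {
      double sp = pair_strength(s1[lo1 + i], s2[lo2 + j]);
      if (sp < 0) continue;
      double e = 0.0; // (i, j) opens a new helix
      // extend from a previous pair (p, q), p < i, q > j
      for (int a = 0; a <= MAX_BULGE && a < i; ++a) {
        for (int b = 0; b <= MAX_BULGE && j + 1 + b < n2; ++b) {
          if (a > 0 && b > 0 && a + b > MAX_INTERNAL) continue;
          int p = i - 1 - a;
          int q = j + 1 + b;
          double prev = E[(size_t)p * n2 + q];
          if (ISNA(prev)) continue;
          double spp = pair_strength(s1[lo1 + p], s2[lo2 + q]);
          double cand;
          if (a == 0 && b == 0) {
            cand = prev + stack_energy(spp, sp);
          } else {
            double pen = loop_penalty(a, b);
            if (ISNA(pen)) continue;
            cand = prev + pen;
          }
          if (cand < e) e = cand;
        }
      }
      E[(size_t)i * n2 + j] = e;
      if (e < best) best = e;
    }
  }
  return best;
}

// [[Rcpp::export]]
double duplex_mfe_cpp(IntegerVector s1, IntegerVector s2) {
  return duplex_core(s1, s2, 0, s1.size() - 1, 0, s2.size() - 1);
}

// minimum duplex MFE over all window-vs-window pairs at the given stride;
// a tail window flush with each sequence end is always included
// [[Rcpp::export]]
double duplex_windowed_min_cpp(IntegerVector s1, IntegerVector s2,
                               int window, int step) {
  int n1 = s1.size(), n2 = s2.size();
  if (window > n1 || window > n2) stop("window longer than sequence");
  std::vector<int> starts1, starts2;
  for (int s = 0; s + window <= n1; s += step) starts1.push_back(s);
  if (starts1.back() != n1 - window) starts1.push_back(n1 - window);
  for (int s = 0; s + window <= n2; s += step) starts2.push_back(s);
  if (starts2.back() != n2 - window) starts2.push_back(n2 - window);
  double best = 0.0;
  for (int a : starts1) {
    for (int b : starts2) {
      double e = duplex_core(s1, s2, a, a + window - 1, b, b + window - 1);
      if (e < best) best = e;
    }
  }
  return best;
}

// [[Rcpp::export]]
double stack_energy_cpp(int a1, int b1, int a2, int b2) {
  double s1 = pair_strength(a1, b1);
  double s2 = pair_strength(a2, b2);
  if (s1 < 0 || s2 < 0) stop("not a base pair");
  return stack_energy(s1, s2);
}

// [[Rcpp::export]]
double loop_penalty_cpp(int a, int b) {
  double p = loop_penalty(a, b);
  return p; // NA when the loop is disallowed
}
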