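#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

// Minimum-free-energy folding over nested secondary structures with
// Watson-Crick + GU pairs, a minimum hairpin loop of 3 unpaired bases and
// additive stacked-pair energies. Lone (unstacked) pairs contribute 0, so
// the MFE is always <= 0 (the open chain scores 0).
//
// Recurrences (1-based intervals [i, j], h = 3 minimum loop):
//   V(i,j)   = best energy given (i,j) paired
//            = min( stack(i,j;i+1,j-1) + V(i+1,j-1),   if (i+1,j-1) pairable
//                   Wns(i+1,j-1) )                      otherwise inside
//   Wns(i,j) = best energy with (i,j) NOT paired together
//            = min( W(i,j-1), min_k W(i,k-1) + V(k,j) ) for i < k <= j-h-1
//   W(i,j)   = min( Wns(i,j), V(i,j) )

static const double INF = std::numeric_limits<double>::infinity();

// base encoding: A=0, C=1, G=2, U/T=3, other=-1
static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  default: return -1;
  }
}

// pair index within the 6 allowed pairs, or -1
// order must match pair_levels() in R: AU UA GC CG GU UG
static inline int pair_idx(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 1 && b == 2) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
double fold_mfe_cpp(std::string seq, Rcpp::NumericMatrix stack_energy,
                    int min_hairpin) {
  const int n = (int) seq.size();
  if (n <= 0) return 0.0;
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    s[i] = enc(seq[i]);
    if (s[i] < 0) Rcpp::stop("invalid character in sequence");
  }
  if (n < min_hairpin + 2) return 0.0;

  const int h = min_hairpin;
  std::vector<double> V(n * n, INF), W(n * n, 0.0), Wns(n * n, 0.0);
  auto at = [n](int i, int j) { return i * n + j; };

  for (int span = h + 1; span <= n - 1; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int pij = pair_idx(s[i], s[j]);
      // V
      double v = INF;
      if (pij >= 0) {
        double inner_ns = (span - 2 >= 1) ? Wns[at(i + 1, j - 1)] : 0.0;
        v = inner_ns;
        if (span >= h + 3) {
          int pin = pair_idx(s[i + 1], s[j - 1]);
          if (pin >= 0 && V[at(i + 1, j - 1)] < INF) {
            double stacked = stack_energy(pij, pin) + V[at(i + 1, j - 1)];
            if (stacked < v) v = stacked;
          }
        }
        V[at(i, j)] = v;
      }
      // Wns
      double wns = W[at(i, j - 1)];
      for (int k = i + 1; k <= j - h - 1; ++k) {
        if (V[at(k, j)] < INF) {
          double cand = (k - 1 >= i ? W[at(i, k - 1)] : 0.0) + V[at(k, j)];
          if (cand < wns) wns = cand;
        }
      }
      Wns[at(i, j)] = wns;
      // W
      double w = wns;
      if (pij >= 0 && v < w) w = v;
      W[at(i, j)] = w;
    }
  }
  double mfe = W[at(0, n - 1)];
  return mfe < 0.0 ? mfe : 0.0;
}
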