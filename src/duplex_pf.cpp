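// Partition function of intermolecular DNA duplex hybridization under a
// nearest-neighbor energy model.
//
// Grammar: antiparallel duplexes between a top strand (5'->3') and a bottom
// strand; base pairs are non-crossing and organized into helices (runs of
// stacked pairs).  A stack is admissible when its four bases have a finite
// nearest-neighbor entry: Watson-Crick/Watson-Crick stacks or tabulated
// single internal mismatch contexts (mismatches are isolated and flanked by
// WC pairs; helix termini are WC).  Every helix has >= 2 pairs.  Helices are
// separated by internal loops/bulges of total unpaired size s (1 <= s <=
// maxloop) scored by a Jacobson-Stockmayer penalty a + b*log(s).  One duplex
// initiation term per configuration plus a terminal A.T penalty per
// A.T-closing end.  The empty (unhybridized) state is excluded.
//
// States per cell (i,k), pair between top base i and bottom base k:
//   H1: rightmost helix has exactly one pair (must be WC; config start or
//       loop arrival) -- non-accepting, extended only by stacking.
//   Hk: rightmost helix has >= 2 pairs and its rightmost pair is WC
//       (accepting; the only state loops may leave from).
//   Hm: rightmost pair is an internal mismatch (non-accepting; must be
//       followed by a WC stack).
// Adjacent-mismatch and helix-terminal-mismatch exclusions are enforced by
// zero entries in the 4x4x4x4 stack table.
//
// Bottom-strand convention: the bottom array is given left-to-right in
// 3'->5' orientation, i.e. column k of the duplex pairs top[i] with bot[k].
// The R wrappers do the reverse/complement bookkeeping.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
using namespace Rcpp;

static const int NBASE = 4; // A=0, C=1, G=2, T=3; N=4 (unpairable)

static inline bool is_wc(int x, int w) {
  return (x == 0 && w == 3) || (x == 3 && w == 0) ||
         (x == 1 && w == 2) || (x == 2 && w == 1);
}
static inline bool is_at(int x, int w) {
  return (x == 0 && w == 3) || (x == 3 && w == 0);
}
static inline int sidx(int x, int y, int w, int z) {
  // -1 when any base is N (or otherwise unstackable)
  if ((x | y | w | z) & ~3) return -1;
  return ((x * 4 + y) * 4 + w) * 4 + z;
}

struct PFPar {
  std::vector<double> stackw;  // 256 Boltzmann weights, 0 = inadmissible
  std::vector<double> stackdG; // 256 dG37 (Inf = inadmissible), for MFE
  std::vector<double> lw;      // loop weights, index s = 1..maxloop
  std::vector<double> ldG;     // loop dG
  double winit, wtermAT;       // Boltzmann weights
  double init_dG, termAT_dG;
  double RT;
  int maxloop;
};

static PFPar make_par(List par) {
  PFPar p;
  NumericVector sdg = par["stack_dG"]; // length 256, NA = inadmissible
  if (sdg.size() != 256) stop("stack_dG must have length 256");
  p.init_dG = as<double>(par["init_dG"]);
  p.termAT_dG = as<double>(par["terminal_AT_dG"]);
  double la = as<double>(par["loop_a"]), lb = as<double>(par["loop_b"]);
  p.maxloop = as<int>(par["maxloop"]);
  double Tk = as<double>(par["temperature"]);
  double Rg = as<double>(par["R"]);
  p.RT = Rg * Tk;
  p.stackw.assign(256, 0.0);
  p.stackdG.assign(256, R_PosInf);
  for (int i = 0; i < 256; ++i) {
    if (!NumericVector::is_na(sdg[i])) {
      p.stackdG[i] = sdg[i];
      p.stackw[i] = std::exp(-sdg[i] / p.RT);
    }
  }
  p.winit = std::exp(-p.init_dG / p.RT);
  p.wtermAT = std::exp(-p.termAT_dG / p.RT);
  p.lw.assign(p.maxloop + 1, 0.0);
  p.ldG.assign(p.maxloop + 1, R_PosInf);
  for (int s = 1; s <= p.maxloop; ++s) {
    p.ldG[s] = la + lb * std::log((double)s);
    p.lw[s] = std::exp(-p.ldG[s] / p.RT);
  }
  return p;
}

// Z for one n x m rectangle.  Work buffers are caller-provided so grid scans
// do not reallocate: H1,Hk,Hm of size n*m; Pd of size (n+m)*(n+1) (diagonal
// prefix sums of Hk; column 0 is a zero sentinel).  Pd entries for valid
// cells are overwritten on every call; invalid ones are never read.
static double pf_rect(const int* A, const int* B, int n, int m, const PFPar& p,
                      double* H1, double* Hk, double* Hm, double* Pd) {
  if (n < 2 || m < 2) return 0.0;
  const int pw = n + 1;
  double Z = 0.0;
  for (int i = 0; i < n; ++i) {
    const int ai = A[i];
    for (int k = 0; k < m; ++k) {
      const int bk = B[k];
      const int c = i * m + k;
      double h1 = 0.0, hk = 0.0, hm = 0.0;
      if (ai < NBASE && bk < NBASE) {
        if (is_wc(ai, bk)) {
          // helix start: fresh configuration ...
          double wt = is_at(ai, bk) ? p.wtermAT : 1.0;
          h1 = p.winit * wt;
          // ... or arrival from a loop closed by a previous helix end
          if (i >= 1 && k >= 1) {
            const int smax = std::min(p.maxloop, i + k - 1);
            for (int s = 1; s <= smax; ++s) {
              const int t = i + k - 2 - s;
              if (t < 0) break;
              int lo = i - 1 - s; if (lo < 0) lo = 0;
              int hi = (s <= k - 2) ? (i - 1) : (t); // min(i-1, t)
              if (hi > i - 1) hi = i - 1;
              if (lo > hi) continue;
              const double* row = Pd + (size_t)t * pw;
              h1 += p.lw[s] * (row[hi + 1] - row[lo]);
            }
            // stack extension of an existing helix
            const int si = sidx(A[i - 1], ai, B[k - 1], bk);
            const double sw = si < 0 ? 0.0 : p.stackw[si];
            if (sw > 0.0) {
              const int cp = c - m - 1;
              hk = (H1[cp] + Hk[cp] + Hm[cp]) * sw;
            }
          }
          Z += hk * wt;
        } else if (i >= 1 && k >= 1) {
          // internal mismatch: only reachable by stacking on a WC pair
          const int si = sidx(A[i - 1], ai, B[k - 1], bk);
          const double sw = si < 0 ? 0.0 : p.stackw[si];
          if (sw > 0.0) {
            const int cp = c - m - 1;
            hm = (H1[cp] + Hk[cp]) * sw;
          }
        }
      }
      H1[c] = h1; Hk[c] = hk; Hm[c] = hm;
      double* row = Pd + (size_t)(i + k) * pw;
      row[i + 1] = row[i] + hk; // row[first-1] is the zero sentinel
    }
  }
  return Z;
}

// Minimum free energy over admissible configurations (direct O(maxloop^2)
// loop scan; used for single-duplex queries only).
static double mfe_rect(const int* A, const int* B, int n, int m, const PFPar& p) {
  if (n < 2 || m < 2) return R_PosInf;
  std::vector<double> G1((size_t)n * m, R_PosInf), Gk((size_t)n * m, R_PosInf),
      Gm((size_t)n * m, R_PosInf);
  double best = R_PosInf;
  for (int i = 0; i < n; ++i) {
    const int ai = A[i];
    for (int k = 0; k < m; ++k) {
      const int bk = B[k];
      const int c = i * m + k;
      if (ai >= NBASE || bk >= NBASE) continue;
      if (is_wc(ai, bk)) {
        double term = is_at(ai, bk) ? p.termAT_dG : 0.0;
        double g1 = p.init_dG + term;
        for (int d1 = 0; d1 <= p.maxloop && d1 <= i - 1; ++d1) {
          for (int d2 = (d1 == 0 ? 1 : 0); d1 + d2 <= p.maxloop && d2 <= k - 1; ++d2) {
            const int cp = (i - 1 - d1) * m + (k - 1 - d2);
            if (R_FINITE(Gk[cp]))
              g1 = std::min(g1, Gk[cp] + p.ldG[d1 + d2]);
          }
        }
        G1[c] = g1;
        if (i >= 1 && k >= 1) {
          const int si = sidx(A[i - 1], ai, B[k - 1], bk);
          const double sg = si < 0 ? R_PosInf : p.stackdG[si];
          if (R_FINITE(sg)) {
            const int cp = c - m - 1;
            double prev = std::min(G1[cp], std::min(Gk[cp], Gm[cp]));
            if (R_FINITE(prev)) {
              Gk[c] = prev + sg;
              best = std::min(best, Gk[c] + term);
            }
          }
        }
      } else if (i >= 1 && k >= 1) {
        const double sg = p.stackdG[sidx(A[i - 1], ai, B[k - 1], bk)];
        if (R_FINITE(sg)) {
          const int cp = c - m - 1;
          double prev = std::min(G1[cp], Gk[cp]);
          if (R_FINITE(prev)) Gm[c] = prev + sg;
        }
      }
    }
  }
  return best;
}

// [[Rcpp::export(name = ".pf_single_cpp")]]
List pf_single_cpp(IntegerVector top, IntegerVector bottom, List par) {
  PFPar p = make_par(par);
  const int n = top.size(), m = bottom.size();
  std::vector<int> A(top.begin(), top.end()), B(bottom.begin(), bottom.end());
  std::vector<double> H1((size_t)n * m), Hk((size_t)n * m), Hm((size_t)n * m),
      Pd((size_t)(n + m) * (n + 1), 0.0);
  double Z = pf_rect(A.data(), B.data(), n, m, p, H1.data(), Hk.data(),
                     Hm.data(), Pd.data());
  double mfe = mfe_rect(A.data(), B.data(), n, m, p);
  return List::create(_["Z"] = Z, _["mfe_dG"] = mfe);
}

// Z for every l x l sub-duplex of two extended regions.  Entry [a, u] is the
// partition function of top[a..a+l-1] vs bottom[u..u+l-1] (0-based a, u;
// returned as a 1-based indexed matrix).
// [[Rcpp::export(name = ".pf_grid_cpp")]]
NumericMatrix pf_grid_cpp(IntegerVector top, IntegerVector bottom, int l, List par) {
  PFPar p = make_par(par);
  const int nA = top.size(), nB = bottom.size();
  if (l < 1) stop("l must be >= 1");
  if (nA < l || nB < l) stop("extended regions shorter than l");
  const int na = nA - l + 1, nb = nB - l + 1;
  std::vector<int> A(top.begin(), top.end()), B(bottom.begin(), bottom.end());
  NumericMatrix Z(na, nb);
  std::vector<double> H1((size_t)l * l), Hk((size_t)l * l), Hm((size_t)l * l),
      Pd((size_t)(2 * l) * (l + 1), 0.0);
  for (int a = 0; a < na; ++a) {
    for (int u = 0; u < nb; ++u) {
      Z(a, u) = pf_rect(A.data() + a, B.data() + u, l, l, p, H1.data(),
                        Hk.data(), Hm.data(), Pd.data());
    }
    if (a % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return Z;
}
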