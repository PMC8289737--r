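#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sample entropy and approximate entropy (m, m+1) with Chebyshev distance,
// fused into one triangular pairwise pass. SampEn excludes self-matches;
// ApEn includes them (canonical definitions).
// [[Rcpp::export]]
NumericVector cpp_sampen_apen(NumericVector x, int m, double r) {
  int n = x.size();
  NumericVector out = NumericVector::create(NA_REAL, NA_REAL);
  if (n < m + 2 || r <= 0) return out;

  int nm1 = n - m + 1;                // templates of length m
  int nm = n - m;                     // templates of length m+1
  std::vector<int> cm(nm1, 0), cm1(nm, 0);
  long long B = 0, A = 0;
  for (int i = 0; i < nm1; ++i) {
    for (int j = i + 1; j < nm1; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
      }
      if (d <= r) {
        ++cm[i]; ++cm[j];
        if (j < nm) {                 // both templates extend to length m+1
          ++B;
          if (std::fabs(x[i + m] - x[j + m]) <= r) {
            ++A; ++cm1[i]; ++cm1[j];
          }
        }
      }
    }
  }
  // constant series gives A == B -> 0; A == 0 leaves SampEn undefined (NA)
  if (B > 0 && A > 0) out[0] = -std::log((double)A / (double)B);

  double phim = 0.0, phim1 = 0.0;
  for (int i = 0; i < nm1; ++i)
    phim += std::log((cm[i] + 1.0) / nm1);
  for (int i = 0; i < nm; ++i)
    phim1 += std::log((cm1[i] + 1.0) / nm);
  out[1] = phim / nm1 - phim1 / nm;
  return out;
}

// Recurrence quantification on a delay-embedded trajectory.
// Returns {RecurrenceRate, DET, ENTR, L} with minimum diagonal length 2,
// main diagonal (and |i-j| < theiler) excluded.
// [[Rcpp::export]]
NumericVector cpp_rqa(NumericVector x, int m, int delay, double radius,
                      int theiler) {
  int n = x.size() - (m - 1) * delay;   // number of embedded points
  NumericVector out = NumericVector::create(NA_REAL, NA_REAL, NA_REAL, NA_REAL);
  if (n < 4 || radius <= 0) return out;

  auto rec = [&](int i, int j) {
    double d = 0.0;
    for (int k = 0; k < m; ++k) {
      double dk = std::fabs(x[i + k * delay] - x[j + k * delay]);
      if (dk > d) d = dk;
    }
    return d <= radius;
  };

  long long npts = 0;                  // recurrent points (upper triangle)
  long long ndiag_pts = 0;             // recurrent points on diagonals >= 2
  std::vector<long long> hist;         // diagonal length histogram
  long long total = 0;                 // compared pairs

  for (int off = theiler; off < n; ++off) {
    int len = 0;
    for (int i = 0; i + off < n; ++i) {
      ++total;
      if (rec(i, i + off)) {
        ++npts; ++len;
      } else {
        if (len >= 2) {
          ndiag_pts += len;
          if ((int)hist.size() < len) hist.resize(len, 0);
          ++hist[len - 1];
        }
        len = 0;
      }
    }
    if (len >= 2) {
      ndiag_pts += len;
      if ((int)hist.size() < len) hist.resize(len, 0);
      ++hist[len - 1];
    }
  }

  out[0] = (double)npts / (double)total;                     // RR
  if (npts > 0) {
    out[1] = (double)ndiag_pts / (double)npts;               // DET
    long long nlines = 0; double Lsum = 0.0;
    for (size_t k = 1; k < hist.size(); ++k) { nlines += hist[k]; Lsum += (double)(k + 1) * hist[k]; }
    if (nlines > 0) {
      out[3] = Lsum / nlines;                                // mean diag length
      double H = 0.0;
      for (size_t k = 1; k < hist.size(); ++k) {
        if (hist[k] > 0) {
          double p = (double)hist[k] / (double)nlines;
          H -= p * std::log(p);
        }
      }
      out[2] = H;                                            // ENTR
    } else { out[3] = 0.0; out[2] = 0.0; }
  } else { out[1] = 0.0; out[2] = 0.0; out[3] = 0.0; }
  return out;
}

// Lempel-Ziv (LZ76) complexity: number of distinct phrases in the
// exhaustive-history parsing of a binary sequence.
// [[Rcpp::export]]
int cpp_lz76(IntegerVector s) {
  int n = s.size();
  if (n == 0) return 0;
  // Kaspar & Schuster formulation of the LZ76 exhaustive parsing
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  while (l + k <= n) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {           // no prefix reproduces the phrase: new phrase
        ++c;
        l += kmax;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  if (k > 1) ++c;             // trailing unfinished phrase
  return c;
}

// Rolling minimum with half-window hw (shrinking at the edges).
// [[Rcpp::export]]
NumericVector cpp_rollmin(NumericVector x, int hw) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - hw), hi = std::min(n - 1, i + hw);
    double m = x[lo];
    for (int j = lo + 1; j <= hi; ++j) if (x[j] < m) m = x[j];
    out[i] = m;
  }
  return out;
}
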