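#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Affine-gap DP between a subject s (rows i = 1..m) and a pattern p
// (cols j = 1..n). M[i][j] is the best score of an alignment ending
// with s[i] aligned to p[j]; X consumes subject within a gap, Y
// consumes pattern. A gap of length L costs gapOpen + L * gapExt.
//
// anchored = true : alignments start at (1,1); leading gaps are paid.
// anchored = false: free start anywhere in either sequence.
//
// Reductions returned (1-based R indexing):
//   colmax[j]  = max_i M[i][j], argi[j] = smallest such i
//   rowmax[i]  = max_j M[i][j]
//   lastcol[i] = M[i][n]   (pattern end anchored at subject i)
// [[Rcpp::export(name = ".flankDp")]]
List flankDp(std::string subject, std::string pattern, bool anchored,
             double matchScore = 2.0, double mismatchScore = -1.0,
             double gapOpen = -4.0, double gapExt = -1.0) {
  const int m = subject.size(), n = pattern.size();
  if (m == 0 || n == 0) stop("empty sequence");
  const double NEG = -std::numeric_limits<double>::infinity();

  std::vector<double> Mprev(n + 1, NEG), Mcur(n + 1, NEG);
  std::vector<double> Xprev(n + 1, NEG), Xcur(n + 1, NEG);
  std::vector<double> Yprev(n + 1, NEG), Ycur(n + 1, NEG);

  NumericVector colmax(n, NEG), rowmax(m, NEG), lastcol(m, NEG);
  IntegerVector argi(n, NA_INTEGER);

  // row 0
  if (anchored) {
    for (int j = 1; j <= n; ++j) Yprev[j] = gapOpen + j * gapExt;
  }

  for (int i = 1; i <= m; ++i) {
    Mcur.assign(n + 1, NEG);
    Xcur.assign(n + 1, NEG);
    Ycur.assign(n + 1, NEG);
    if (anchored) Xcur[0] = gapOpen + i * gapExt;

    const char si = subject[i - 1];
    for (int j = 1; j <= n; ++j) {
      const double sub = (si == pattern[j - 1]) ? matchScore : mismatchScore;
      // start of a new alignment
      double best = NEG;
      if (anchored) {
        if (i == 1 && j == 1) best = 0.0;
      } else {
        best = 0.0;  // free start anywhere
      }
      double d = Mprev[j - 1];
      if (d > best) best = d;
      d = Xprev[j - 1];
      if (d > best) best = d;
      d = Yprev[j - 1];
      if (d > best) best = d;
      Mcur[j] = (best == NEG) ? NEG : best + sub;

      // gap in pattern (consume subject i)
      double xo = (Mprev[j] == NEG) ? NEG : Mprev[j] + gapOpen + gapExt;
      double xe = (Xprev[j] == NEG) ? NEG : Xprev[j] + gapExt;
      Xcur[j] = (xo > xe) ? xo : xe;

      // gap in subject (consume pattern j)
      double yo = (Mcur[j - 1] == NEG) ? NEG : Mcur[j - 1] + gapOpen + gapExt;
      double ye = (Ycur[j - 1] == NEG) ? NEG : Ycur[j - 1] + gapExt;
      Ycur[j] = (yo > ye) ? yo : ye;

      const double mij = Mcur[j];
      if (mij > colmax[j - 1]) {
        colmax[j - 1] = mij;
        argi[j - 1] = i;
      }
      if (mij > rowmax[i - 1]) rowmax[i - 1] = mij;
    }
    lastcol[i - 1] = Mcur[n];
    std::swap(Mprev, Mcur);
    std::swap(Xprev, Xcur);
    std::swap(Yprev, Ycur);
  }

  return List::create(
    _["colmax"] = colmax, _["argi"] = argi,
    _["rowmax"] = rowmax, _["lastcol"] = lastcol);
}
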