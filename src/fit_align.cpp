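// Affine-gap "fit" alignment: the read (pattern) is aligned end-to-end,
// the subject (amplicon) locally, i.e. unaligned subject ends are free.
// Scoring convention: a gap of length L costs gap_open + gap_ext * L.
// Deterministic traceback preference: diagonal, then gap-in-read (deletion
// from the subject), then gap-in-subject (insertion). Downstream
// cut-anchored canonicalization makes labels independent of residual
// placement ties.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2;
    case 'T': return 3; default: return 4;
  }
}

// [[Rcpp::export(name = ".fit_align_cpp")]]
List fit_align_cpp(CharacterVector patterns, std::string subject,
                   double match, double mismatch, double gap_open,
                   double gap_ext) {
  const int n = subject.size();
  const int np = patterns.size();
  NumericVector out_score(np);
  IntegerVector out_start(np), out_end(np);
  CharacterVector out_pat(np), out_subj(np);

  double sub[5][5];
  for (int a = 0; a < 5; ++a)
    for (int b = 0; b < 5; ++b)
      sub[a][b] = (a == b && a < 4) ? match : mismatch;

  std::vector<int> subj_idx(n);
  for (int j = 0; j < n; ++j) subj_idx[j] = base_idx(subject[j]);

  const double NEG = -1e18;

  for (int r = 0; r < np; ++r) {
    std::string pat = as<std::string>(patterns[r]);
    const int m = pat.size();
    std::vector<int> pat_idx(m);
    for (int i = 0; i < m; ++i) pat_idx[i] = base_idx(pat[i]);

    // M: P[i] aligned to S[j]; X: gap in pattern (consumes subject);
    // Y: gap in subject (consumes pattern). (m+1) x (n+1), row-major.
    const int W = n + 1;
    std::vector<double> M((m + 1) * W, NEG), X((m + 1) * W, NEG),
        Y((m + 1) * W, NEG);
    // traceback: which matrix each cell came from (0=M,1=X,2=Y,3=start)
    std::vector<unsigned char> tbM((m + 1) * W), tbX((m + 1) * W),
        tbY((m + 1) * W);

    for (int j = 0; j <= n; ++j) M[j] = 0.0, tbM[j] = 3;  // free subject prefix
    Y[0] = NEG;
    for (int i = 1; i <= m; ++i) {
      // column 0: only gaps in subject possible
      double open_from = M[(i - 1) * W] - gap_open - gap_ext;
      double ext_from = Y[(i - 1) * W] - gap_ext;
      if (open_from >= ext_from) { Y[i * W] = open_from; tbY[i * W] = 0; }
      else { Y[i * W] = ext_from; tbY[i * W] = 2; }
      for (int j = 1; j <= n; ++j) {
        const int c = i * W + j, up = (i - 1) * W + j, lf = i * W + j - 1,
                  dg = (i - 1) * W + j - 1;
        double s = sub[pat_idx[i - 1]][subj_idx[j - 1]];
        // M: from best of M/X/Y diagonally (prefer M, X, Y)
        double bm = M[dg], bx = X[dg], by = Y[dg];
        if (bm >= bx && bm >= by) { M[c] = bm + s; tbM[c] = 0; }
        else if (bx >= by) { M[c] = bx + s; tbM[c] = 1; }
        else { M[c] = by + s; tbM[c] = 2; }
        // X: gap in pattern, consumes subject (left)
        double xo = M[lf] - gap_open - gap_ext, xe = X[lf] - gap_ext;
        if (xo >= xe) { X[c] = xo; tbX[c] = 0; } else { X[c] = xe; tbX[c] = 1; }
        // Y: gap in subject, consumes pattern (up)
        double yo = M[up] - gap_open - gap_ext, ye = Y[up] - gap_ext;
        if (yo >= ye) { Y[c] = yo; tbY[c] = 0; } else { Y[c] = ye; tbY[c] = 2; }
      }
    }
    // best over last row (free subject suffix); prefer M then X then Y,
    // and the smallest j among ties
    double best = NEG; int bj = 0; int bmat = 0;
    for (int j = 0; j <= n; ++j) {
      const int c = m * W + j;
      double cand[3] = { M[c], X[c], Y[c] };
      for (int k = 0; k < 3; ++k) {
        if (cand[k] > best) { best = cand[k]; bj = j; bmat = k; }
      }
    }
    // traceback
    std::string ap, as_;
    int i = m, j = bj, mat = bmat;
    while (i > 0) {
      const int c = i * W + j;
      if (mat == 0) {
        unsigned char f = tbM[c];
        ap.push_back(pat[i - 1]); as_.push_back(subject[j - 1]);
        --i; --j;
        if (f == 3) { mat = 0; break; }
        mat = f;
        if (i == 0) break;
      } else if (mat == 1) {
        unsigned char f = tbX[c];
        ap.push_back('-'); as_.push_back(subject[j - 1]);
        --j; mat = f;
      } else {
        unsigned char f = tbY[c];
        ap.push_back(pat[i - 1]); as_.push_back('-');
        --i; mat = f;
      }
    }
    std::reverse(ap.begin(), ap.end());
    std::reverse(as_.begin(), as_.end());
    out_score[r] = best;
    out_start[r] = j;       // 0-based aligned subject start
    out_end[r] = bj;        // 0-based exclusive aligned subject end
    out_pat[r] = ap;
    out_subj[r] = as_;
  }
  return List::create(_["score"] = out_score, _["subj_start"] = out_start,
                      _["subj_end"] = out_end, _["pattern_aln"] = out_pat,
                      _["subject_aln"] = out_subj);
}
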