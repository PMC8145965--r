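#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment over integer-encoded residues.
//
// Gap convention: a gap run of length g costs open + extend*(g-1), i.e. the
// first gapped position is charged `open`, each further position `extend`.
//
// States: H (match/mismatch layer, holds the cell optimum), E (gap in the
// query: subject residue aligned to '-'), F (gap in the subject).
// Deterministic tie-breaking everywhere: diagonal > E > F (> stop for local),
// and gap-open preferred over gap-extend; the local start cell is the
// first maximum in row-major order (smallest query index, then subject index).

static const int NEG = std::numeric_limits<int>::min() / 4;

// [[Rcpp::export(name = ".cpp_pair_align")]]
List cpp_pair_align(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                    int gap_open, int gap_extend, bool local) {
  const int n = q.size(), m = s.size();
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  // tbH: 0 stop, 1 diag, 2 from E, 3 from F; tbE/tbF: 1 open (from H), 0 extend
  std::vector<unsigned char> tbH((n + 1) * (m + 1), 0),
      tbE((n + 1) * (m + 1), 0), tbF((n + 1) * (m + 1), 0);
  const int W = m + 1;

  if (!local) {
    for (int j = 1; j <= m; ++j) {
      E[j] = -(gap_open + (j - 1) * gap_extend);
      H[j] = E[j];
      tbH[j] = 2;
      tbE[j] = (j == 1) ? 1 : 0;
    }
    for (int i = 1; i <= n; ++i) {
      F[i * W] = -(gap_open + (i - 1) * gap_extend);
      H[i * W] = F[i * W];
      tbH[i * W] = 3;
      tbF[i * W] = (i == 1) ? 1 : 0;
    }
  }

  const int A = mat.nrow();
  std::vector<int> prof(n * A);
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < A; ++a) prof[i * A + a] = mat(q[i], a);
  const int *sp = INTEGER(s);
  int *Hp = H.data(), *Ep = E.data(), *Fp = F.data();
  unsigned char *tH = tbH.data(), *tE = tbE.data(), *tF = tbF.data();

  int best = 0, bi = 0, bj = 0;
  bool have_best = false;
  for (int i = 1; i <= n; ++i) {
    const int *pr = &prof[(i - 1) * A];
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j;
      // E: gap in query (move along subject)
      int e_open = Hp[c - 1] - gap_open;
      int e_ext = Ep[c - 1] > NEG ? Ep[c - 1] - gap_extend : NEG;
      if (e_open >= e_ext) { Ep[c] = e_open; tE[c] = 1; }
      else { Ep[c] = e_ext; tE[c] = 0; }
      // F: gap in subject (move along query)
      int f_open = Hp[c - W] - gap_open;
      int f_ext = Fp[c - W] > NEG ? Fp[c - W] - gap_extend : NEG;
      if (f_open >= f_ext) { Fp[c] = f_open; tF[c] = 1; }
      else { Fp[c] = f_ext; tF[c] = 0; }
      // H
      int h = Hp[c - W - 1] + pr[sp[j - 1]]; unsigned char t = 1;
      if (Ep[c] > h) { h = Ep[c]; t = 2; }
      if (Fp[c] > h) { h = Fp[c]; t = 3; }
      if (local && h <= 0) { h = 0; t = 0; }
      Hp[c] = h; tH[c] = t;
      if (local && h > best) { best = h; bi = i; bj = j; have_best = true; }
    }
  }

  int score, ei, ej;
  if (local) {
    score = best; ei = bi; ej = bj;
    if (!have_best) {
      return List::create(_["score"] = 0, _["q_start"] = 0, _["q_end"] = 0,
                          _["s_start"] = 0, _["s_end"] = 0, _["matches"] = 0,
                          _["aligned_cols"] = 0,
                          _["q_aln"] = IntegerVector(0),
                          _["s_aln"] = IntegerVector(0));
    }
  } else {
    score = H[n * W + m]; ei = n; ej = m;
  }

  // traceback (state-aware)
  std::vector<int> qa, sa;
  int i = ei, j = ej;
  char state = 'H';
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (state == 'H') {
      unsigned char t = tbH[c];
      if (local && t == 0) break;
      if (t == 1) { qa.push_back(i - 1); sa.push_back(j - 1); --i; --j; }
      else if (t == 2) state = 'E';
      else if (t == 3) state = 'F';
      else break; // global corner
    } else if (state == 'E') {
      qa.push_back(-1); sa.push_back(j - 1);
      if (tbE[c]) state = 'H';
      --j;
    } else { // F
      qa.push_back(i - 1); sa.push_back(-1);
      if (tbF[c]) state = 'H';
      --i;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());

  int matches = 0, cols = 0, qs = ei, ss = ej;
  for (size_t k = 0; k < qa.size(); ++k) {
    if (qa[k] >= 0 && sa[k] >= 0) {
      ++cols;
      if (q[qa[k]] == s[sa[k]]) ++matches;
    }
    if (qa[k] >= 0 && qa[k] < qs) qs = qa[k];
    if (sa[k] >= 0 && sa[k] < ss) ss = sa[k];
  }
  if (qa.empty()) { qs = 0; ss = 0; ei = 0; ej = 0; }

  return List::create(_["score"] = score, _["q_start"] = qs, _["q_end"] = ei,
                      _["s_start"] = ss, _["s_end"] = ej,
                      _["matches"] = matches, _["aligned_cols"] = cols,
                      _["q_aln"] = IntegerVector(qa.begin(), qa.end()),
                      _["s_aln"] = IntegerVector(sa.begin(), sa.end()));
}

// Score-only local alignment of one query against many subjects.
// [[Rcpp::export(name = ".cpp_sw_scores")]]
IntegerVector cpp_sw_scores(IntegerVector q, List subjects, IntegerMatrix mat,
                            int gap_open, int gap_extend) {
  const int n = q.size();
  const int ns = subjects.size();
  const int A = mat.nrow();
  IntegerVector out(ns);
  // per-query score profile, row-contiguous: prof[i*A + a] = mat(q[i], a)
  std::vector<int> prof(n * A);
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < A; ++a) prof[i * A + a] = mat(q[i], a);
  std::vector<int> Hrow, Erow, Frow;
  for (int t = 0; t < ns; ++t) {
    IntegerVector sv = subjects[t];
    const int *s = INTEGER(sv);
    const int m = sv.size();
    Hrow.assign(m + 1, 0);
    Erow.assign(m + 1, NEG / 2);
    Frow.assign(m + 1, NEG / 2);
    int *H = Hrow.data(), *E = Erow.data(), *F = Frow.data();
    int best = 0;
    for (int i = 1; i <= n; ++i) {
      const int *pr = &prof[(i - 1) * A];
      int diag_prev = 0; // H[i-1][j-1]
      for (int j = 1; j <= m; ++j) {
        int e = std::max(H[j - 1] - gap_open, E[j - 1] - gap_extend);
        int f = std::max(H[j] - gap_open, F[j] - gap_extend);
        int h = diag_prev + pr[s[j - 1]];
        if (e > h) h = e;
        if (f > h) h = f;
        if (h < 0) h = 0;
        diag_prev = H[j];
        H[j] = h;
        E[j] = e;
        F[j] = f;
        if (h > best) best = h;
      }
    }
    out[t] = best;
  }
  return out;
}
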