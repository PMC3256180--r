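// Affine-gap pairwise alignment (Gotoh) with deterministic traceback.
// Convention: a gap of length L costs gap_open + L * gap_extend (the BLAST
// convention). Traceback ties prefer the diagonal, then a gap in the second
// sequence, then a gap in the first, so alignments are reproducible across
// platforms. Values are kept in rolling rows; full byte matrices hold only
// traceback codes.
#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static const double NEG_INF = -1e30;

struct AlnResult {
  double score;
  int nmatch;
  int ungapped;
  std::string aligned_a;
  std::string aligned_b;
};

// traceback codes: predecessor state, plus local-alignment start markers
enum { ST_M = 0, ST_IX = 1, ST_IY = 2, ST_START = 3, ST_ZERO = 4 };

struct Workspace {
  std::vector<double> Mp, Xp, Yp, Mc, Xc, Yc;
  std::vector<unsigned char> tbM, tbX, tbY;
  std::vector<int> ai, bi;
};

static AlnResult align_one(const std::string& a, const std::string& b,
                           const std::vector<double>& sub,
                           const int* lut, int nalpha,
                           double go, double ge,
                           bool local, bool keep, Workspace& ws) {
  const int n = (int)a.size(), m = (int)b.size();
  const int w = m + 1;
  const double gog = go + ge;
  ws.Mp.assign(w, NEG_INF); ws.Xp.assign(w, NEG_INF);
  ws.Yp.assign(w, NEG_INF);
  ws.Mc.resize(w); ws.Xc.resize(w); ws.Yc.resize(w);
  if ((int)ws.tbM.size() < (n + 1) * w) {
    ws.tbM.resize((n + 1) * w);
    ws.tbX.resize((n + 1) * w);
    ws.tbY.resize((n + 1) * w);
  }
  unsigned char* tbM = ws.tbM.data();
  unsigned char* tbX = ws.tbX.data();
  unsigned char* tbY = ws.tbY.data();
  ws.ai.resize(n); ws.bi.resize(m);
  for (int i = 0; i < n; ++i) {
    ws.ai[i] = lut[(unsigned char)a[i]];
    if (ws.ai[i] < 0) stop("residue '%c' not in substitution matrix", a[i]);
  }
  for (int j = 0; j < m; ++j) {
    ws.bi[j] = lut[(unsigned char)b[j]];
    if (ws.bi[j] < 0) stop("residue '%c' not in substitution matrix", b[j]);
  }

  // row 0
  ws.Mp[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    if (!local) { ws.Yp[j] = -(go + ge * j); }
    tbY[j] = ST_IY;
  }
  double best = 0.0;
  int best_i = 0, best_j = 0;

  for (int i = 1; i <= n; ++i) {
    double* Mp = ws.Mp.data(); double* Xp = ws.Xp.data();
    double* Yp = ws.Yp.data();
    double* Mc = ws.Mc.data(); double* Xc = ws.Xc.data();
    double* Yc = ws.Yc.data();
    Mc[0] = NEG_INF; Yc[0] = NEG_INF;
    Xc[0] = local ? NEG_INF : -(go + ge * i);
    tbX[i * w] = ST_IX;
    const double* subrow = &sub[ws.ai[i - 1] * nalpha];
    const int base = i * w;
    for (int j = 1; j <= m; ++j) {
      // M: diagonal move from best of three at (i-1, j-1)
      double vm = Mp[j - 1], vx = Xp[j - 1], vy = Yp[j - 1];
      double pm; unsigned char tm;
      if (vm >= vx && vm >= vy) { pm = vm; tm = ST_M; }
      else if (vx >= vy) { pm = vx; tm = ST_IX; }
      else { pm = vy; tm = ST_IY; }
      if (local && pm < 0) { pm = 0; tm = ST_START; }
      double mv = pm + subrow[ws.bi[j - 1]];
      if (local && mv < 0) { mv = 0; tm = ST_ZERO; }
      Mc[j] = mv; tbM[base + j] = tm;
      // IX: gap in b (vertical), from row i-1 at column j
      double x_open = (Mp[j] >= Yp[j] ? Mp[j] : Yp[j]) - gog;
      double x_ext = Xp[j] - ge;
      if (x_open >= x_ext) {
        Xc[j] = x_open;
        tbX[base + j] = (Mp[j] >= Yp[j]) ? ST_M : ST_IY;
      } else { Xc[j] = x_ext; tbX[base + j] = ST_IX; }
      // IY: gap in a (horizontal), from column j-1 of current row
      double y_open = (Mc[j - 1] >= Xc[j - 1] ? Mc[j - 1] : Xc[j - 1]) - gog;
      double y_ext = Yc[j - 1] - ge;
      if (y_open >= y_ext) {
        Yc[j] = y_open;
        tbY[base + j] = (Mc[j - 1] >= Xc[j - 1]) ? ST_M : ST_IX;
      } else { Yc[j] = y_ext; tbY[base + j] = ST_IY; }
      if (local && mv > best) { best = mv; best_i = i; best_j = j; }
    }
    ws.Mp.swap(ws.Mc); ws.Xp.swap(ws.Xc); ws.Yp.swap(ws.Yc);
  }

  AlnResult res;
  int i, j, state;
  if (local) {
    res.score = best;
    if (best <= 0) {
      res.score = 0; res.nmatch = 0; res.ungapped = 0;
      return res;
    }
    i = best_i; j = best_j; state = ST_M;
  } else {
    // after the swap, ws.Mp holds row n
    double vm = ws.Mp[m], vx = ws.Xp[m], vy = ws.Yp[m];
    if (vm >= vx && vm >= vy) { res.score = vm; state = ST_M; }
    else if (vx >= vy) { res.score = vx; state = ST_IX; }
    else { res.score = vy; state = ST_IY; }
    i = n; j = m;
  }

  std::string ra, rb;
  int nmatch = 0, ungapped = 0;
  while (true) {
    const int c = i * w + j;
    if (state == ST_M) {
      if (i == 0 || j == 0) break;
      unsigned char prev = tbM[c];
      if (local && prev == ST_ZERO) break;  // zero-valued cell: not on path
      if (keep) { ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); }
      ++ungapped;
      if (a[i - 1] == b[j - 1]) ++nmatch;
      --i; --j;
      if (local && prev == ST_START) break;  // first aligned column
      state = prev;
    } else if (state == ST_IX) {
      if (i == 0) break;
      unsigned char prev = tbX[c];
      if (keep) { ra.push_back(a[i - 1]); rb.push_back('-'); }
      --i;
      state = prev;
    } else {  // ST_IY
      if (j == 0) break;
      unsigned char prev = tbY[c];
      if (keep) { ra.push_back('-'); rb.push_back(b[j - 1]); }
      --j;
      state = prev;
    }
  }
  if (!local) {
    while (i > 0) { if (keep) { ra.push_back(a[i - 1]); rb.push_back('-'); }
      --i; }
    while (j > 0) { if (keep) { ra.push_back('-'); rb.push_back(b[j - 1]); }
      --j; }
  }
  res.nmatch = nmatch;
  res.ungapped = ungapped;
  if (keep) {
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
    res.aligned_a = ra;
    res.aligned_b = rb;
  }
  return res;
}

// [[Rcpp::export(name = ".align_pairs_cpp")]]
List align_pairs_cpp(CharacterVector seqs, IntegerVector ia,
                     IntegerVector ib, NumericMatrix submat,
                     double gap_open, double gap_extend,
                     bool local, bool keep_alignment) {
  const int np = ia.size();
  if (ib.size() != np) stop("index vectors differ in length");
  CharacterVector rn = rownames(submat);
  const int nalpha = rn.size();
  std::vector<double> sub(nalpha * nalpha);
  for (int i = 0; i < nalpha; ++i)
    for (int j = 0; j < nalpha; ++j)
      sub[i * nalpha + j] = submat(i, j);
  int lut[256];
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  for (int i = 0; i < nalpha; ++i) {
    std::string s = as<std::string>(rn[i]);
    if (s.size() == 1) lut[(unsigned char)s[0]] = i;
  }
  std::vector<std::string> sv(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) sv[i] = as<std::string>(seqs[i]);

  NumericVector score(np);
  IntegerVector nmatch(np), ungapped(np);
  CharacterVector aa(keep_alignment ? np : 0), ab(keep_alignment ? np : 0);
  Workspace ws;
  for (int p = 0; p < np; ++p) {
    const std::string& a = sv[ia[p] - 1];
    const std::string& b = sv[ib[p] - 1];
    AlnResult r = align_one(a, b, sub, lut, nalpha, gap_open, gap_extend,
                            local, keep_alignment, ws);
    score[p] = r.score;
    nmatch[p] = r.nmatch;
    ungapped[p] = r.ungapped;
    if (keep_alignment) { aa[p] = r.aligned_a; ab[p] = r.aligned_b; }
  }
  List out = List::create(_["score"] = score, _["nmatch"] = nmatch,
                          _["ungapped"] = ungapped);
  if (keep_alignment) {
    out["aligned_a"] = aa;
    out["aligned_b"] = ab;
  }
  return out;
}
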