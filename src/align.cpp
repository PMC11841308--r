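#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh) with deterministic traceback and
// masked re-runs for secondary alignments.
//
// Scoring: a gap of length L costs gap_open + (L-1) * gap_extend, i.e. the
// opening charge covers the first gapped base.
//
// CIGAR ops: M = aligned column, I = insertion in query (consumes query),
// D = deletion from query (consumes target). Traceback ties prefer
// M over D over I; the best cell is the first maximum in row-major order
// (smallest query end, then target end).

static const int NEG_BIG = -100000000;

struct Aln {
  int score, q_start, q_end, t_start, t_end, n_matches, aln_len;
  std::string cigar;
};

static inline int subst(char a, char b, int match, int mismatch) {
  if (a == b && a != 'N') return match;
  return mismatch;
}

static bool run_one(const std::string &q, const std::string &t,
                    const std::vector<char> &qmask,
                    int match, int mismatch, int go, int ge,
                    Aln &out) {
  const int n = (int)q.size(), m = (int)t.size();
  if (n == 0 || m == 0) return false;
  // dir bits: 0-1 H-dir (0 stop, 1 diag, 2 from E/D, 3 from F/I)
  //           bit2: E opened from H; bit3: F opened from H
  std::vector<unsigned char> dir((size_t)(n + 1) * (m + 1), 0);
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0), Frow(m + 1, NEG_BIG);
  int best = 0, bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    int Eij = NEG_BIG;
    Hcur[0] = 0;
    unsigned char *drow = &dir[(size_t)i * (m + 1)];
    const bool masked = qmask[i - 1] != 0;
    const char qc = q[i - 1];
    const int *hprev = Hprev.data();
    int *hcur = Hcur.data();
    int *frow = Frow.data();
    int hdiag = hprev[0]; // H[i-1][j-1]
    int hleft = 0;        // H[i][j-1]
    for (int j = 1; j <= m; ++j) {
      unsigned char d = 0;
      // E: gap in query (D op), moves along target
      int e_open = hleft - go;
      int e_ext = Eij - ge;
      if (e_open >= e_ext) { Eij = e_open; d |= 4; }
      else Eij = e_ext;
      // F: gap in target (I op), moves along query
      int f_open = hprev[j] - go;
      int f_ext = frow[j] - ge;
      int f;
      if (f_open >= f_ext) { f = f_open; d |= 8; }
      else f = f_ext;
      frow[j] = f;
      // H
      int s = masked ? NEG_BIG
                     : ((qc == t[j - 1] && qc != 'N') ? match : mismatch);
      int diag = hdiag + s;
      int h = 0; unsigned char hd = 0;
      if (diag > h) { h = diag; hd = 1; }
      if (Eij > h) { h = Eij; hd = 2; }
      if (f > h) { h = f; hd = 3; }
      // ties: 0 (fresh start) wins over everything at score 0; then M > D > I
      hdiag = hprev[j];
      hcur[j] = h;
      hleft = h;
      drow[j] = d | hd;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }
  if (best <= 0) return false;

  // traceback
  std::string ops;
  int i = bi, j = bj, nm = 0;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (true) {
    unsigned char d = dir[(size_t)i * (m + 1) + j];
    if (state == 0) {
      unsigned char hd = d & 3;
      if (hd == 0) break;
      if (hd == 1) {
        ops.push_back('M');
        if (q[i - 1] == t[j - 1] && q[i - 1] != 'N') ++nm;
        --i; --j;
      } else if (hd == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // E: emit D, consume target
      ops.push_back('D');
      bool opened = (d & 4) != 0;
      --j;
      if (opened) state = 0;
    } else { // F: emit I, consume query
      ops.push_back('I');
      bool opened = (d & 8) != 0;
      --i;
      if (opened) state = 0;
    }
  }
  // ops are reversed; build run-length CIGAR in forward order
  std::string cigar;
  int len = (int)ops.size();
  int k = len - 1;
  while (k >= 0) {
    char op = ops[k];
    int run = 0;
    while (k >= 0 && ops[k] == op) { ++run; --k; }
    cigar += std::to_string(run);
    cigar.push_back(op);
  }
  out.score = best;
  out.q_start = i; out.q_end = bi;
  out.t_start = j; out.t_end = bj;
  out.n_matches = nm;
  out.aln_len = len;
  out.cigar = cigar;
  return true;
}

// [[Rcpp::export]]
DataFrame sw_align_cpp(std::string q, std::string t,
                       int match, int mismatch, int gap_open, int gap_extend,
                       int min_score, int max_secondary) {
  int go = -gap_open, ge = -gap_extend; // penalties passed as negative scores
  std::vector<char> qmask(q.size(), 0);
  std::vector<Aln> alns;
  int max_aln = 1 + max_secondary;
  for (int r = 0; r < max_aln; ++r) {
    Aln a;
    if (!run_one(q, t, qmask, match, mismatch, go, ge, a)) break;
    if (a.score < min_score) break;
    alns.push_back(a);
    for (int i = a.q_start; i < a.q_end; ++i) qmask[i] = 1;
  }
  int na = (int)alns.size();
  IntegerVector score(na), qs(na), qe(na), ts(na), te(na), nmv(na), al(na);
  CharacterVector cg(na), rank(na);
  for (int i = 0; i < na; ++i) {
    score[i] = alns[i].score; qs[i] = alns[i].q_start; qe[i] = alns[i].q_end;
    ts[i] = alns[i].t_start; te[i] = alns[i].t_end;
    nmv[i] = alns[i].n_matches; al[i] = alns[i].aln_len;
    cg[i] = alns[i].cigar;
    rank[i] = (i == 0) ? "primary" : "secondary";
  }
  return DataFrame::create(
    _["score"] = score, _["q_start"] = qs, _["q_end"] = qe,
    _["t_start"] = ts, _["t_end"] = te, _["cigar"] = cg,
    _["n_matches"] = nmv, _["aln_len"] = al, _["rank"] = rank,
    _["stringsAsFactors"] = false);
}
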