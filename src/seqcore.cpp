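#include <Rcpp.h>
#include <cstring>
#include <string>
#include <vector>
#include <limits>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// IUPAC tables
// ---------------------------------------------------------------------------

// bitmask over {A=1, C=2, G=4, T=8}; 0 = invalid letter
static int iupac_mask_of(char c) {
  switch (c) {
  case 'A': return 1;  case 'C': return 2;  case 'G': return 4;  case 'T': return 8;
  case 'U': return 8;
  case 'R': return 1 | 4;      case 'Y': return 2 | 8;
  case 'S': return 2 | 4;      case 'W': return 1 | 8;
  case 'K': return 4 | 8;      case 'M': return 1 | 2;
  case 'B': return 2 | 4 | 8;  case 'D': return 1 | 4 | 8;
  case 'H': return 1 | 2 | 8;  case 'V': return 1 | 2 | 4;
  case 'N': return 15;
  default:  return 0;
  }
}

static char iupac_complement_of(char c) {
  switch (c) {
  case 'A': return 'T';  case 'C': return 'G';  case 'G': return 'C';  case 'T': return 'A';
  case 'U': return 'A';
  case 'R': return 'Y';  case 'Y': return 'R';  case 'S': return 'S';  case 'W': return 'W';
  case 'K': return 'M';  case 'M': return 'K';  case 'B': return 'V';  case 'V': return 'B';
  case 'D': return 'H';  case 'H': return 'D';  case 'N': return 'N';
  default:  return 0;
  }
}

// [[Rcpp::export(name = ".rc_cpp")]]
CharacterVector rc_cpp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.size(), ' ');
    for (size_t j = 0; j < s.size(); ++j) {
      char c = iupac_complement_of(s[j]);
      if (c == 0)
        stop("non-IUPAC character '%s' in sequence", std::string(1, s[j]).c_str());
      r[s.size() - 1 - j] = c;
    }
    out[i] = r;
  }
  return out;
}

// [[Rcpp::export(name = ".iupac_match_cpp")]]
bool iupac_match_cpp(std::string a, std::string b) {
  if (a.size() != 1 || b.size() != 1) stop("iupac_match expects single letters");
  char ca = a[0], cb = b[0];
  if (ca != 'A' && ca != 'C' && ca != 'G' && ca != 'T' && ca != 'N')
    stop("base '%s' is not in {A,C,G,T,N}", a.c_str());
  int mb = iupac_mask_of(cb);
  if (mb == 0) stop("'%s' is not an IUPAC nucleotide code", b.c_str());
  if (ca == 'N') return true;           // masked consensus base matches any code
  return (iupac_mask_of(ca) & mb) != 0;
}

// ---------------------------------------------------------------------------
// Minimizers: smallest k-mer (lexicographic, leftmost on ties) per window of
// w consecutive k-mer start positions; maximal runs of an identical winning
// k-mer collapse to their first occurrence.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".minimizers_cpp")]]
DataFrame minimizers_cpp(std::string seq, int k, int w) {
  std::vector<std::string> kmers_out;
  std::vector<int> pos_out;
  int n = (int) seq.size();
  int nk = n - k + 1;
  if (k < 1 || w < 1) stop("k and w must be >= 1");
  if (nk >= 1) {
    const char* s = seq.c_str();
    int nwin = std::max(1, nk - w + 1);
    for (int win = 0; win < nwin; ++win) {
      int lim = std::min(win + w, nk);
      int best = win;
      for (int p = win + 1; p < lim; ++p)
        if (strncmp(s + p, s + best, k) < 0) best = p;
      std::string km(s + best, k);
      if (kmers_out.empty() || km != kmers_out.back()) {
        kmers_out.push_back(km);
        pos_out.push_back(best);
      }
    }
  }
  return DataFrame::create(_["kmer"] = kmers_out, _["pos"] = pos_out,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Affine-gap pairwise alignment (Gotoh) with full traceback.
// States: M (a_i ~ b_j), D (gap in b, consumes a / the reference),
//         I (gap in a, consumes b / the query).
// Tie preference when scores are equal: M > D > I.
// Modes: 0 = global, 1 = semi-global (free terminal gaps, excluded from the
// alignment span), 2 = local.
// ---------------------------------------------------------------------------

static const int NEG = std::numeric_limits<int>::min() / 4;

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(std::string a, std::string b,
                    int match, int mismatch, int gap_open, int gap_extend,
                    int mode) {
  int n = (int) a.size(), m = (int) b.size();
  if (n == 0 || m == 0) stop("cannot align an empty sequence");
  size_t sz = (size_t)(n + 1) * (m + 1);
  std::vector<int> M(sz, NEG), D(sz, NEG), I(sz, NEG);
  // traceback: per state, which state fed it (0=M,1=D,2=I,3=start)
  std::vector<unsigned char> tbM(sz, 3), tbD(sz, 3), tbI(sz, 3);
  auto at = [m](int i, int j) { return (size_t) i * (m + 1) + j; };

  bool free_ends = (mode == 1);
  bool local = (mode == 2);

  M[at(0, 0)] = 0;
  for (int i = 1; i <= n; ++i) {
    if (free_ends || local) { M[at(i, 0)] = 0; tbM[at(i, 0)] = 3; }
    else {
      D[at(i, 0)] = gap_open + (i - 1) * gap_extend;
      tbD[at(i, 0)] = (i == 1) ? 0 : 1;
    }
  }
  for (int j = 1; j <= m; ++j) {
    if (free_ends || local) { M[at(0, j)] = 0; tbM[at(0, j)] = 3; }
    else {
      I[at(0, j)] = gap_open + (j - 1) * gap_extend;
      tbI[at(0, j)] = (j == 1) ? 0 : 2;
    }
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      size_t c = at(i, j), di = at(i - 1, j - 1), up = at(i - 1, j), lf = at(i, j - 1);
      int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M from best of diag states, preference M > D > I
      int best = M[di]; unsigned char tb = 0;
      if (D[di] > best) { best = D[di]; tb = 1; }
      if (I[di] > best) { best = I[di]; tb = 2; }
      int mv = (best <= NEG / 2) ? NEG : best + s;
      if (local && mv < 0) { mv = 0; tb = 3; }
      M[c] = mv; tbM[c] = tb;
      // D: consume a (gap in b)
      int dv = NEG; unsigned char tdb = 0;
      if (M[up] > NEG / 2 && M[up] + gap_open > dv) { dv = M[up] + gap_open; tdb = 0; }
      if (D[up] > NEG / 2 && D[up] + gap_extend > dv) { dv = D[up] + gap_extend; tdb = 1; }
      if (I[up] > NEG / 2 && I[up] + gap_open > dv) { dv = I[up] + gap_open; tdb = 2; }
      D[c] = dv; tbD[c] = tdb;
      // I: consume b (gap in a)
      int iv = NEG; unsigned char tib = 0;
      if (M[lf] > NEG / 2 && M[lf] + gap_open > iv) { iv = M[lf] + gap_open; tib = 0; }
      if (D[lf] > NEG / 2 && D[lf] + gap_open > iv) { iv = D[lf] + gap_open; tib = 1; }
      if (I[lf] > NEG / 2 && I[lf] + gap_extend > iv) { iv = I[lf] + gap_extend; tib = 2; }
      I[c] = iv; tbI[c] = tib;
    }
  }

  // pick endpoint
  int ei = n, ej = m; unsigned char es = 0; int score;
  if (local) {
    score = 0; ei = 0; ej = 0; es = 0;
    for (int i = 1; i <= n; ++i)
      for (int j = 1; j <= m; ++j)
        if (M[at(i, j)] > score) { score = M[at(i, j)]; ei = i; ej = j; }
  } else if (free_ends) {
    // the empty overlap (both sequences fully in terminal gaps) scores 0
    score = 0; ei = 0; ej = 0; es = 0;
    // best over last row and last column, preference M > D > I, then larger i+j
    for (int i = n, j = 1; j <= m; ++j) {
      int vals[3] = { M[at(i, j)], D[at(i, j)], I[at(i, j)] };
      for (int st = 0; st < 3; ++st)
        if (vals[st] > score) { score = vals[st]; ei = i; ej = j; es = (unsigned char) st; }
    }
    for (int j = m, i = 1; i <= n; ++i) {
      int vals[3] = { M[at(i, j)], D[at(i, j)], I[at(i, j)] };
      for (int st = 0; st < 3; ++st)
        if (vals[st] > score) { score = vals[st]; ei = i; ej = j; es = (unsigned char) st; }
    }
  } else {
    int vals[3] = { M[at(n, m)], D[at(n, m)], I[at(n, m)] };
    score = vals[0]; es = 0;
    for (int st = 1; st < 3; ++st) if (vals[st] > score) { score = vals[st]; es = (unsigned char) st; }
  }

  // traceback
  std::string ops;  // 'M' both, 'D' consume a only, 'I' consume b only
  int i = ei, j = ej; unsigned char st = es;
  int matches = 0;
  while (true) {
    // a cell whose M state is a free start anchors the alignment: emit nothing
    if (st == 0 && tbM[at(i, j)] == 3 && (free_ends || local || (i == 0 && j == 0))) break;
    if (i == 0 && j == 0) break;
    unsigned char prev;
    if (st == 0) {
      prev = tbM[at(i, j)];
      ops.push_back('M');
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (st == 1) {
      prev = tbD[at(i, j)];
      ops.push_back('D'); --i;
    } else {
      prev = tbI[at(i, j)];
      ops.push_back('I'); --j;
    }
    st = prev;
  }
  std::reverse(ops.begin(), ops.end());

  int ref_start = i, query_start = j;
  int aln_len = (int) ops.size();

  // run-length encode CIGAR
  std::string cigar;
  for (size_t p = 0; p < ops.size();) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    cigar += std::to_string(q - p);
    cigar.push_back(ops[p]);
    p = q;
  }

  return List::create(
    _["score"] = score, _["matches"] = matches, _["alignment_length"] = aln_len,
    _["cigar"] = cigar,
    _["ref_start"] = ref_start, _["ref_end"] = ei,
    _["query_start"] = query_start, _["query_end"] = ej);
}

// ---------------------------------------------------------------------------
// Primer fit: primer global, text local (best approximate occurrence), unit
// edit costs, IUPAC-aware matching. Returns the best (fewest-edit, leftmost
// end, then leftmost start) occurrence.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".primer_fit_cpp")]]
List primer_fit_cpp(std::string text, std::string primer) {
  int n = (int) text.size(), m = (int) primer.size();
  if (m == 0) stop("empty primer");
  if (n == 0) stop("empty text");
  std::vector<int> masks_t(n), masks_p(m);
  for (int j = 0; j < n; ++j) {
    int mk = iupac_mask_of(text[j]);
    if (mk == 0) stop("non-IUPAC character in text");
    masks_t[j] = (text[j] == 'N') ? 15 : mk;
  }
  for (int i = 0; i < m; ++i) {
    int mk = iupac_mask_of(primer[i]);
    if (mk == 0) stop("non-IUPAC character in primer");
    masks_p[i] = mk;
  }
  // D[i][j]: min edits aligning primer[0..i) to a suffix of text[0..j)
  std::vector<int> Dm((m + 1) * (n + 1));
  auto at = [n](int i, int j) { return (size_t) i * (n + 1) + j; };
  for (int j = 0; j <= n; ++j) Dm[at(0, j)] = 0;
  for (int i = 1; i <= m; ++i) Dm[at(i, 0)] = i;
  for (int i = 1; i <= m; ++i)
    for (int j = 1; j <= n; ++j) {
      int sub = Dm[at(i - 1, j - 1)] + (((masks_t[j - 1] & masks_p[i - 1]) != 0) ? 0 : 1);
      int del = Dm[at(i - 1, j)] + 1;   // primer base unmatched in text
      int ins = Dm[at(i, j - 1)] + 1;   // extra text base inside primer span
      int v = sub;
      if (del < v) v = del;
      if (ins < v) v = ins;
      Dm[at(i, j)] = v;
    }
  int best_j = 1, best = Dm[at(m, 1)];
  for (int j = 2; j <= n; ++j)
    if (Dm[at(m, j)] < best) { best = Dm[at(m, j)]; best_j = j; }
  if (n >= 1 && Dm[at(m, 0)] < best) { best = Dm[at(m, 0)]; best_j = 0; }
  // traceback for start, preferring diagonal then up then left
  int i = m, j = best_j;
  while (i > 0) {
    int cur = Dm[at(i, j)];
    if (j > 0 && cur == Dm[at(i - 1, j - 1)] + (((masks_t[j - 1] & masks_p[i - 1]) != 0) ? 0 : 1)) {
      --i; --j;
    } else if (cur == Dm[at(i - 1, j)] + 1) {
      --i;
    } else {
      --j;
    }
  }
  return List::create(_["edits"] = best, _["start"] = j, _["end"] = best_j);
}
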