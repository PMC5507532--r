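// Banded affine-gap Smith-Waterman local alignment, plus a bulk primer-prefix
// assigner for read pairs. Scoring convention: a gap of length L costs
// gap_open + L * gap_extend (both provided as negative numbers is NOT the
// convention here: they are penalties, passed positive).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static const int NEG = -1000000000;

// [[Rcpp::export(name = ".sw_banded_cpp")]]
List sw_banded_cpp(std::string read, std::string ref,
                   int match = 2, int mismatch = -4,
                   int gap_open = 6, int gap_extend = 1,
                   int band = 0, int diag_offset = 0) {
  const int m = (int)read.size(), n = (int)ref.size();
  if (m == 0) stop("empty read");
  if (n == 0) stop("empty reference");
  const int go = -(gap_open + gap_extend); // opening a gap of length 1
  const int ge = -gap_extend;
  const bool banded = band > 0;

  auto idx = [&](int i, int j) { return (size_t)i * (n + 1) + j; };
  static thread_local std::vector<int> M, X, Y;
  static thread_local std::vector<unsigned char> TM, TX, TY;
  size_t sz = (size_t)(m + 1) * (n + 1);
  M.assign(sz, NEG); X.assign(sz, NEG); Y.assign(sz, NEG);
  TM.assign(sz, 0); TX.assign(sz, 0); TY.assign(sz, 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int jlo = 1, jhi = n;
    if (banded) {
      jlo = std::max(1, i + diag_offset - band);
      jhi = std::min(n, i + diag_offset + band);
      if (jlo > jhi) continue;
    }
    for (int j = jlo; j <= jhi; ++j) {
      // M: diagonal
      int prev = 0; unsigned char tm = 0; // 0 = start (local)
      int pm = M[idx(i - 1, j - 1)], px = X[idx(i - 1, j - 1)], py = Y[idx(i - 1, j - 1)];
      if (pm > prev) { prev = pm; tm = 1; }
      if (px > prev) { prev = px; tm = 2; }
      if (py > prev) { prev = py; tm = 3; }
      int s = (std::toupper(read[i - 1]) == std::toupper(ref[j - 1])) ? match : mismatch;
      int mv = prev + s;
      M[idx(i, j)] = mv;
      TM[idx(i, j)] = tm;
      // X: gap consuming ref (deletion in read relative to ref)
      int xo = M[idx(i, j - 1)] + go, xe = X[idx(i, j - 1)] + ge,
          xy = Y[idx(i, j - 1)] + go;
      int xv = xo; unsigned char tx = 1;
      if (xe > xv) { xv = xe; tx = 2; }
      if (xy > xv) { xv = xy; tx = 3; }
      X[idx(i, j)] = xv; TX[idx(i, j)] = tx;
      // Y: gap consuming read (insertion in read relative to ref)
      int yo = M[idx(i - 1, j)] + go, ye = Y[idx(i - 1, j)] + ge,
          yx = X[idx(i - 1, j)] + go;
      int yv = yo; unsigned char ty = 1;
      if (ye > yv) { yv = ye; ty = 2; }
      if (yx > yv) { yv = yx; ty = 3; }
      Y[idx(i, j)] = yv; TY[idx(i, j)] = ty;
      int h = std::max(mv, std::max(xv, yv));
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0) {
    return List::create(_["score"] = 0, _["ref_start"] = NA_INTEGER,
                        _["ref_end"] = NA_INTEGER, _["read_start"] = NA_INTEGER,
                        _["read_end"] = NA_INTEGER, _["cigar"] = "");
  }
  // traceback from the best cell; determine which matrix holds it
  int i = bi, j = bj;
  char state;
  int mv = M[idx(i, j)], xv = X[idx(i, j)], yv = Y[idx(i, j)];
  if (mv >= xv && mv >= yv) state = 'M';
  else if (xv >= yv) state = 'X';
  else state = 'Y';
  std::string ops;
  while (i > 0 && j > 0) {
    if (state == 'M') {
      unsigned char t = TM[idx(i, j)];
      ops.push_back('M');
      --i; --j;
      if (t == 0) break;
      state = (t == 1) ? 'M' : (t == 2) ? 'X' : 'Y';
    } else if (state == 'X') {
      unsigned char t = TX[idx(i, j)];
      ops.push_back('D');
      --j;
      state = (t == 2) ? 'X' : (t == 1) ? 'M' : 'Y';
    } else {
      unsigned char t = TY[idx(i, j)];
      ops.push_back('I');
      --i;
      state = (t == 2) ? 'Y' : (t == 1) ? 'M' : 'X';
    }
  }
  std::reverse(ops.begin(), ops.end());
  int read_start = i + 1, ref_start = j + 1;
  // compress to CIGAR
  std::string cig;
  size_t k = 0;
  while (k < ops.size()) {
    size_t k2 = k;
    while (k2 < ops.size() && ops[k2] == ops[k]) ++k2;
    cig += std::to_string(k2 - k);
    cig.push_back(ops[k]);
    k = k2;
  }
  return List::create(_["score"] = best,
                      _["ref_start"] = ref_start, _["ref_end"] = bj,
                      _["read_start"] = read_start, _["read_end"] = bi,
                      _["cigar"] = cig);
}

static inline int prefix_mismatches(const char* a, int la,
                                    const char* b, int lb, int cap) {
  int L = std::min(la, lb), mm = 0;
  for (int k = 0; k < L; ++k) {
    if (std::toupper(a[k]) != std::toupper(b[k])) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

// For each read pair, the 1-based index of the unique amplicon whose forward
// oligo matches read1's prefix and reverse oligo matches read2's prefix
// within max_mm substitutions each; 0 when none or ambiguous.
// [[Rcpp::export(name = ".assign_pairs_cpp")]]
IntegerVector assign_pairs_cpp(CharacterVector read1, CharacterVector read2,
                               CharacterVector fwd_oligo, CharacterVector rev_oligo,
                               int max_mm = 2) {
  const int n = read1.size(), na = fwd_oligo.size();
  std::vector<std::string> fo(na), ro(na);
  for (int a = 0; a < na; ++a) {
    fo[a] = as<std::string>(fwd_oligo[a]);
    ro[a] = as<std::string>(rev_oligo[a]);
  }
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    const char* s1 = CHAR(STRING_ELT(read1, r));
    const char* s2 = CHAR(STRING_ELT(read2, r));
    int l1 = LENGTH(STRING_ELT(read1, r));
    int l2 = LENGTH(STRING_ELT(read2, r));
    int hit = 0, nhit = 0;
    for (int a = 0; a < na; ++a) {
      if (prefix_mismatches(s1, l1, fo[a].c_str(), (int)fo[a].size(), max_mm) > max_mm)
        continue;
      if (prefix_mismatches(s2, l2, ro[a].c_str(), (int)ro[a].size(), max_mm) > max_mm)
        continue;
      ++nhit;
      hit = a + 1;
      if (nhit > 1) break;
    }
    out[r] = (nhit == 1) ? hit : 0;
  }
  return out;
}
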