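#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap Smith-Waterman (Gotoh) returning the single optimal local
// alignment, with deterministic tie-breaking: among maximal-score
// alignments prefer the smallest start on A, then the smallest start on B,
// then the smallest end. A gap of length k costs gap_open + k * gap_ext
// (both negative). N (or any non-ACGT letter) never scores as a match.

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline int base_score(char a, char b, int match, int mismatch) {
  return (a == b && is_acgt(a)) ? match : mismatch;
}

// strictly better under (score desc, origin-a asc, origin-b asc)
static inline bool better(long sc1, int oa1, int ob1,
                          long sc2, int oa2, int ob2) {
  if (sc1 != sc2) return sc1 > sc2;
  if (oa1 != oa2) return oa1 < oa2;
  return ob1 < ob2;
}

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string a, std::string b,
              int match, int mismatch, int gap_open, int gap_ext) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0);
  const long NEG = -1000000000L;

  // rolling rows, index 0..m; state M ends in an aligned pair,
  // X ends in a gap in B (consumes A), Y ends in a gap in A (consumes B)
  std::vector<long> Mp(m + 1, NEG), Xp(m + 1, NEG), Yp(m + 1, NEG);
  std::vector<long> Mc(m + 1, NEG), Xc(m + 1, NEG), Yc(m + 1, NEG);
  std::vector<int> MoaP(m + 1, 0), MobP(m + 1, 0), XoaP(m + 1, 0),
      XobP(m + 1, 0), YoaP(m + 1, 0), YobP(m + 1, 0);
  std::vector<int> MoaC(m + 1, 0), MobC(m + 1, 0), XoaC(m + 1, 0),
      XobC(m + 1, 0), YoaC(m + 1, 0), YobC(m + 1, 0);
  // traceback: bits 0-1 = M pred (0 fresh, 1 M, 2 X, 3 Y);
  // bit 2 = X pred (0 from M, 1 extend); bit 3 = Y pred likewise
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);

  long bestScore = 0;
  int bestOa = 0, bestOb = 0, bestI = 0, bestJ = 0;

  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG; Xc[0] = NEG; Yc[0] = NEG;
    const char ai = a[i - 1];
    unsigned char *tbrow = &tb[(size_t)i * (m + 1)];
    for (int j = 1; j <= m; ++j) {
      // --- M state ---
      long best = 0; int boa = i, bob = j; int mcode = 0;
      if (better(Mp[j - 1], MoaP[j - 1], MobP[j - 1], best, boa, bob)) {
        best = Mp[j - 1]; boa = MoaP[j - 1]; bob = MobP[j - 1]; mcode = 1;
      }
      if (better(Xp[j - 1], XoaP[j - 1], XobP[j - 1], best, boa, bob)) {
        best = Xp[j - 1]; boa = XoaP[j - 1]; bob = XobP[j - 1]; mcode = 2;
      }
      if (better(Yp[j - 1], YoaP[j - 1], YobP[j - 1], best, boa, bob)) {
        best = Yp[j - 1]; boa = YoaP[j - 1]; bob = YobP[j - 1]; mcode = 3;
      }
      long msc = best + base_score(ai, b[j - 1], match, mismatch);
      Mc[j] = msc; MoaC[j] = boa; MobC[j] = bob;

      // --- X state (gap in B, consumes A; opens from M only) ---
      long xo = (Mp[j] <= NEG / 2) ? NEG : Mp[j] + gap_open + gap_ext;
      long xe = (Xp[j] <= NEG / 2) ? NEG : Xp[j] + gap_ext;
      int xcode;
      if (better(xe, XoaP[j], XobP[j], xo, MoaP[j], MobP[j])) {
        Xc[j] = xe; XoaC[j] = XoaP[j]; XobC[j] = XobP[j]; xcode = 1;
      } else {
        Xc[j] = xo; XoaC[j] = MoaP[j]; XobC[j] = MobP[j]; xcode = 0;
      }

      // --- Y state (gap in A, consumes B; opens from M only) ---
      long yo = (Mc[j - 1] <= NEG / 2) ? NEG : Mc[j - 1] + gap_open + gap_ext;
      long ye = (Yc[j - 1] <= NEG / 2) ? NEG : Yc[j - 1] + gap_ext;
      int ycode;
      if (better(ye, YoaC[j - 1], YobC[j - 1], yo, MoaC[j - 1], MobC[j - 1])) {
        Yc[j] = ye; YoaC[j] = YoaC[j - 1]; YobC[j] = YobC[j - 1]; ycode = 1;
      } else {
        Yc[j] = yo; YoaC[j] = MoaC[j - 1]; YobC[j] = MobC[j - 1]; ycode = 0;
      }

      tbrow[j] = (unsigned char)(mcode | (xcode << 2) | (ycode << 3));

      // local alignments end in M; keep first (smallest end) among
      // equal (score, origin)
      if (better(Mc[j], MoaC[j], MobC[j], bestScore, bestOa, bestOb)) {
        bestScore = Mc[j]; bestOa = MoaC[j]; bestOb = MobC[j];
        bestI = i; bestJ = j;
      }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    std::swap(MoaP, MoaC); std::swap(MobP, MobC);
    std::swap(XoaP, XoaC); std::swap(XobP, XobC);
    std::swap(YoaP, YoaC); std::swap(YobP, YobC);
  }

  if (bestScore <= 0)
    return List::create(_["score"] = 0);

  // traceback; ops: 0 = match column, 1 = mismatch column,
  // 2 = gap in B (A advances), 3 = gap in A (B advances)
  std::vector<int> ops;
  int i = bestI, j = bestJ, state = 0; // 0 M, 1 X, 2 Y
  while (true) {
    unsigned char t = tb[(size_t)i * (m + 1) + j];
    if (state == 0) {
      ops.push_back((a[i - 1] == b[j - 1] && is_acgt(a[i - 1])) ? 0 : 1);
      int code = t & 3;
      --i; --j;
      if (code == 0) break;
      state = code - 1;
    } else if (state == 1) {
      ops.push_back(2);
      int code = (t >> 2) & 1;
      --i;
      state = code ? 1 : 0;
    } else {
      ops.push_back(3);
      int code = (t >> 3) & 1;
      --j;
      state = code ? 2 : 0;
    }
  }
  std::reverse(ops.begin(), ops.end());

  return List::create(
      _["score"] = (double)bestScore,
      _["a_start"] = i + 1, _["a_end"] = bestI,
      _["b_start"] = j + 1, _["b_end"] = bestJ,
      _["ops"] = IntegerVector(ops.begin(), ops.end()));
}
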