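#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global pairwise alignment with affine gaps (Gotoh three-state DP).
// A gap of length g costs gap_open + (g-1)*gap_extend.
// Optional band restricts |j - i - shift| <= band around the main diagonal
// (shift accounts for the length difference); band < 0 disables banding.
// Traceback tie-break: diagonal (M) preferred, then gap-in-b (up), then
// gap-in-a (left); within a gap state, closing the gap is preferred.

static const double NEG = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".align_affine_cpp")]]
List align_affine_cpp(std::string a, std::string b,
                      double match, double mismatch,
                      double gap_open, double gap_extend,
                      int band, bool score_only) {
  const int n = (int)a.size(), m = (int)b.size();
  int lo = std::min(0, m - n), hi = std::max(0, m - n);
  if (band >= 0) { lo -= band; hi += band; } else { lo = -n - 1; hi = m + 1; }

  const size_t W = (size_t)m + 1;
  std::vector<double> Mp(W, NEG), Xp(W, NEG), Yp(W, NEG); // previous row
  std::vector<double> Mc(W), Xc(W), Yc(W);                // current row
  // traceback: predecessor state per (state, cell); 0=M 1=X 2=Y 3=none
  std::vector<uint8_t> tbM, tbX, tbY;
  if (!score_only) {
    tbM.assign((size_t)(n + 1) * W, 3);
    tbX.assign((size_t)(n + 1) * W, 3);
    tbY.assign((size_t)(n + 1) * W, 3);
  }

  Mp[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    if (j - 0 > hi) break;
    Yp[j] = gap_open + (j - 1) * gap_extend;
    if (!score_only) tbY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Xc.begin(), Xc.end(), NEG);
    std::fill(Yc.begin(), Yc.end(), NEG);
    int jlo = std::max(0, i + lo), jhi = std::min(m, i + hi);
    if (jlo == 0) {
      Xc[0] = gap_open + (i - 1) * gap_extend;
      if (!score_only) tbX[(size_t)i * W] = (i == 1) ? 0 : 1;
      jlo = 1;
    }
    for (int j = jlo; j <= jhi; ++j) {
      const size_t off = (size_t)i * W + j;
      // M: consume a[i-1] and b[j-1]
      double dM = Mp[j - 1], dX = Xp[j - 1], dY = Yp[j - 1];
      double best = dM; uint8_t st = 0;
      if (dX > best) { best = dX; st = 1; }
      if (dY > best) { best = dY; st = 2; }
      if (best > NEG) {
        double s = (a[(size_t)i - 1] == b[(size_t)j - 1]) ? match : mismatch;
        Mc[j] = best + s;
        if (!score_only) tbM[off] = st;
      }
      // X: consume a[i-1], gap in b ("up")
      double xM = Mp[j] + gap_open, xX = Xp[j] + gap_extend,
             xY = Yp[j] + gap_open;
      best = xM; st = 0;
      if (xX > best) { best = xX; st = 1; }
      if (xY > best) { best = xY; st = 2; }
      if (best > NEG) { Xc[j] = best; if (!score_only) tbX[off] = st; }
      // Y: consume b[j-1], gap in a ("left")
      double yM = Mc[j - 1] + gap_open, yX = Xc[j - 1] + gap_open,
             yY = Yc[j - 1] + gap_extend;
      best = yM; st = 0;
      if (yX > best) { best = yX; st = 1; }
      if (yY > best) { best = yY; st = 2; }
      if (best > NEG) { Yc[j] = best; if (!score_only) tbY[off] = st; }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  double sM = Mp[m], sX = Xp[m], sY = Yp[m];
  double score = sM; uint8_t state = 0;
  if (sX > score) { score = sX; state = 1; }
  if (sY > score) { score = sY; state = 2; }
  if (score == NEG)
    stop("band too narrow: no alignment path inside the band");
  if (score_only) return List::create(_["score"] = score);

  // traceback
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  uint8_t st = state;
  while (i > 0 || j > 0) {
    const size_t off = (size_t)i * W + j;
    uint8_t prev;
    if (st == 0) {
      prev = tbM[off];
      ra.push_back(a[(size_t)i - 1]); rb.push_back(b[(size_t)j - 1]);
      --i; --j;
    } else if (st == 1) {
      prev = tbX[off];
      ra.push_back(a[(size_t)i - 1]); rb.push_back('-');
      --i;
    } else {
      prev = tbY[off];
      ra.push_back('-'); rb.push_back(b[(size_t)j - 1]);
      --j;
    }
    st = prev;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = score, _["a"] = ra, _["b"] = rb);
}
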