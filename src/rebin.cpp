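#include <Rcpp.h>
using namespace Rcpp;

// Linear-interpolation rebinning onto a uniform axis anchored at `lo` with
// bin width `w`: value at bin centre lo + (i + 0.5) w, zero outside the
// support [mz.front(), mz.back()] of the input.
static void rebin_into(const NumericVector& mz, const NumericVector& inten,
                       double lo, double w, int n, std::vector<double>& out) {
  std::fill(out.begin(), out.end(), 0.0);
  const int m = mz.size();
  if (m < 2) return;
  int seg = 0;  // current input segment [seg, seg+1]
  for (int i = 0; i < n; ++i) {
    double c = lo + (i + 0.5) * w;
    if (c < mz[0] || c > mz[m - 1]) continue;
    while (seg < m - 2 && mz[seg + 1] < c) ++seg;
    double x0 = mz[seg], x1 = mz[seg + 1];
    double t = (x1 > x0) ? (c - x0) / (x1 - x0) : 0.0;
    out[i] = inten[seg] + t * (inten[seg + 1] - inten[seg]);
  }
}

static double rms_of(const std::vector<double>& v) {
  double s = 0.0;
  for (double x : v) s += x * x;
  return std::sqrt(s / v.size());
}

// [[Rcpp::export]]
NumericVector cpp_rebin(NumericVector mz, NumericVector inten,
                        double lo, double w, int n) {
  std::vector<double> out(n);
  rebin_into(mz, inten, lo, w, n, out);
  return NumericVector(out.begin(), out.end());
}

// Accumulate the pixel-wise mean of (optionally RMS-normalised) rebinned
// spectra. All-zero pixels are excluded when normalising.
// Returns list(mean=, rms=, n_used=).
// [[Rcpp::export]]
List cpp_accumulate_mean(List mzs, List ints, double lo, double w, int n,
                         bool normalise) {
  const int npix = mzs.size();
  std::vector<double> acc(n, 0.0), buf(n);
  NumericVector rms(npix);
  int used = 0;
  for (int p = 0; p < npix; ++p) {
    NumericVector mz = mzs[p], in = ints[p];
    rebin_into(mz, in, lo, w, n, buf);
    double r = rms_of(buf);
    rms[p] = r;
    if (normalise) {
      if (r <= 0) continue;
      for (int i = 0; i < n; ++i) acc[i] += buf[i] / r;
    } else {
      for (int i = 0; i < n; ++i) acc[i] += buf[i];
    }
    ++used;
  }
  NumericVector mean(n);
  if (used > 0) for (int i = 0; i < n; ++i) mean[i] = acc[i] / used;
  return List::create(_["mean"] = mean, _["rms"] = rms, _["n_used"] = used);
}

// Integrate per-pixel (optionally RMS-normalised) rebinned intensities over
// inclusive bin-index windows [left[k], right[k]] (0-based indices).
// [[Rcpp::export]]
NumericMatrix cpp_integrate(List mzs, List ints, double lo, double w, int n,
                            IntegerVector left, IntegerVector right,
                            bool normalise) {
  const int npix = mzs.size(), npk = left.size();
  NumericMatrix out(npix, npk);
  std::vector<double> buf(n);
  for (int p = 0; p < npix; ++p) {
    NumericVector mz = mzs[p], in = ints[p];
    rebin_into(mz, in, lo, w, n, buf);
    double scale = 1.0;
    if (normalise) {
      double r = rms_of(buf);
      if (r <= 0) { for (int k = 0; k < npk; ++k) out(p, k) = 0.0; continue; }
      scale = 1.0 / r;
    }
    for (int k = 0; k < npk; ++k) {
      double s = 0.0;
      int a = std::max(left[k], 0), b = std::min(right[k], n - 1);
      for (int i = a; i <= b; ++i) s += buf[i];
      out(p, k) = s * scale;
    }
  }
  return out;
}
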