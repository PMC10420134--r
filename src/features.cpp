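#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/Lapack.h>
#include <vector>
#include <cmath>
#ifndef FCONE
# define FCONE
#endif
using namespace Rcpp;

// Per-direction GLCM features (24 rows x n_dir columns), computed from the
// symmetric count array; the R wrapper averages over directions.  Feature
// row order must match the R reference implementation.
// [[Rcpp::export]]
NumericMatrix cpp_glcm_features(IntegerVector counts, int ng, int nd) {
  NumericMatrix out(24, nd);
  std::vector<double> p(ng * ng), px(ng), pdiff(ng), psum(2 * ng - 1);
  std::vector<double> M, w, work;
  for (int d = 0; d < nd; ++d) {
    const int *C = &counts[d * ng * ng];
    double s = 0;
    for (int t = 0; t < ng * ng; ++t) s += C[t];
    if (s <= 0) stop("a GLCM direction has no co-occurrences");
    std::fill(px.begin(), px.end(), 0.0);
    std::fill(pdiff.begin(), pdiff.end(), 0.0);
    std::fill(psum.begin(), psum.end(), 0.0);
    double maxp = 0, je = 0, hxy = 0, autoc = 0;
    for (int j = 0; j < ng; ++j) for (int i = 0; i < ng; ++i) {
      double v = C[i + ng * j] / s;
      p[i + ng * j] = v;
      if (v > 0) {
        px[i] += v;
        pdiff[std::abs(i - j)] += v;
        psum[i + j] += v;
        if (v > maxp) maxp = v;
        je += v * v;
        hxy -= v * std::log2(v);
        autoc += v * (i + 1.0) * (j + 1.0);
      }
    }
    double mu = 0, hx = 0;
    for (int i = 0; i < ng; ++i) {
      mu += px[i] * (i + 1.0);
      if (px[i] > 0) hx -= px[i] * std::log2(px[i]);
    }
    double va = 0;
    for (int i = 0; i < ng; ++i) va += px[i] * (i + 1.0 - mu) * (i + 1.0 - mu);
    double diff_avg = 0, contrast = 0, dent = 0, id = 0, idm = 0, idmn = 0,
           idn = 0, invvar = 0;
    for (int k = 0; k < ng; ++k) {
      double v = pdiff[k];
      diff_avg += v * k;
      contrast += v * k * k;
      if (v > 0) dent -= v * std::log2(v);
      id += v / (1.0 + k);
      idm += v / (1.0 + k * k);
      idmn += v / (1.0 + (double)k * k / (ng * (double)ng));
      idn += v / (1.0 + (double)k / ng);
      if (k > 0) invvar += v / (k * (double)k);
    }
    double dvar = 0;
    for (int k = 0; k < ng; ++k)
      dvar += pdiff[k] * (k - diff_avg) * (k - diff_avg);
    double savg = 0, sent = 0, cp = 0, cs = 0, ct = 0;
    for (int k = 0; k < 2 * ng - 1; ++k) {
      double v = psum[k], ksv = k + 2.0, c0 = ksv - 2.0 * mu;
      savg += v * ksv;
      if (v > 0) sent -= v * std::log2(v);
      ct += v * c0 * c0;
      cs += v * c0 * c0 * c0;
      cp += v * c0 * c0 * c0 * c0;
    }
    double mi = 2 * hx - hxy; if (mi < 0) mi = 0;
    double imc1 = hx > 0 ? -mi / hx : 0;
    double imc2 = std::sqrt(1.0 - std::exp(-2.0 * mi));
    double corr = va > 0 ? (autoc - mu * mu) / va : 1.0;

    // MCC: sqrt of the second-largest eigenvalue of Q, which for a
    // symmetric GLCM equals B^2 with B(a,b) = p(a,b)/sqrt(px_a px_b)
    // (symmetric, spectral radius 1) -- so MCC is the second-largest
    // absolute eigenvalue of B, restricted to present levels.
    std::vector<int> keep;
    for (int i = 0; i < ng; ++i) if (px[i] > 0) keep.push_back(i);
    const int nk = (int)keep.size();
    double mcc = 1.0;
    if (nk >= 2) {
      M.assign((size_t)nk * nk, 0.0);
      for (int b = 0; b < nk; ++b)
        for (int a = 0; a <= b; ++a) {
          double v = p[keep[a] + ng * keep[b]] /
                     std::sqrt(px[keep[a]] * px[keep[b]]);
          M[a + nk * b] = v;
          M[b + nk * a] = v;
        }
      w.assign(nk, 0.0);
      int info = 0, lwork = 3 * nk + 2;
      work.assign(lwork, 0.0);
      char jobz = 'N', uplo = 'U';
      int n = nk;
      F77_CALL(dsyev)(&jobz, &uplo, &n, &M[0], &n, &w[0], &work[0], &lwork,
                      &info FCONE FCONE);
      if (info != 0) stop("MCC eigenvalue computation failed");
      double l2 = std::max(std::fabs(w[nk - 2]), std::fabs(w[0]));
      if (l2 > 1) l2 = 1;
      mcc = l2;
    }

    out(0, d) = autoc;      out(1, d) = mu;        out(2, d) = cp;
    out(3, d) = cs;         out(4, d) = ct;        out(5, d) = contrast;
    out(6, d) = corr;       out(7, d) = diff_avg;  out(8, d) = dent;
    out(9, d) = dvar;       out(10, d) = id;       out(11, d) = idm;
    out(12, d) = idmn;      out(13, d) = idn;      out(14, d) = imc1;
    out(15, d) = imc2;      out(16, d) = invvar;   out(17, d) = je;
    out(18, d) = hxy;       out(19, d) = mcc;      out(20, d) = maxp;
    out(21, d) = savg;      out(22, d) = sent;     out(23, d) = va;
  }
  return out;
}

// Per-direction GLRLM features (16 rows x n_dir columns); row order must
// match the R size-zone/run-length reference.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm_features(IntegerVector counts, int ng, int mr,
                                 int nd, double np) {
  NumericMatrix out(16, nd);
  std::vector<double> pg(ng), ps(mr);
  for (int d = 0; d < nd; ++d) {
    const int *C = &counts[d * ng * mr];
    double s = 0;
    for (int t = 0; t < ng * mr; ++t) s += C[t];
    if (s <= 0) stop("a GLRLM direction has no runs");
    std::fill(pg.begin(), pg.end(), 0.0);
    std::fill(ps.begin(), ps.end(), 0.0);
    double sre = 0, lre = 0, lgl = 0, hgl = 0, srlgl = 0, srhgl = 0,
           lrlgl = 0, lrhgl = 0, mui = 0, muj = 0, ent = 0;
    for (int j = 0; j < mr; ++j) for (int i = 0; i < ng; ++i) {
      double c = C[i + ng * j];
      if (c == 0) continue;
      double pv = c / s, i1 = i + 1.0, j1 = j + 1.0;
      pg[i] += c; ps[j] += c;
      sre += c / (j1 * j1); lre += c * j1 * j1;
      lgl += c / (i1 * i1); hgl += c * i1 * i1;
      srlgl += c / (i1 * i1 * j1 * j1);
      srhgl += c * i1 * i1 / (j1 * j1);
      lrlgl += c * j1 * j1 / (i1 * i1);
      lrhgl += c * i1 * i1 * j1 * j1;
      mui += pv * i1; muj += pv * j1;
      ent -= pv * std::log2(pv);
    }
    double glv = 0, rv = 0;
    for (int j = 0; j < mr; ++j) for (int i = 0; i < ng; ++i) {
      double c = C[i + ng * j];
      if (c == 0) continue;
      double pv = c / s;
      glv += pv * (i + 1.0 - mui) * (i + 1.0 - mui);
      rv += pv * (j + 1.0 - muj) * (j + 1.0 - muj);
    }
    double gln = 0, rln = 0;
    for (int i = 0; i < ng; ++i) gln += pg[i] * pg[i];
    for (int j = 0; j < mr; ++j) rln += ps[j] * ps[j];
    out(0, d) = sre / s;        out(1, d) = lre / s;
    out(2, d) = gln / s;        out(3, d) = gln / (s * s);
    out(4, d) = rln / s;        out(5, d) = rln / (s * s);
    out(6, d) = s / np;         out(7, d) = glv;
    out(8, d) = rv;             out(9, d) = ent;
    out(10, d) = lgl / s;       out(11, d) = hgl / s;
    out(12, d) = srlgl / s;     out(13, d) = srhgl / s;
    out(14, d) = lrlgl / s;     out(15, d) = lrhgl / s;
  }
  return out;
}

// Intensity statistics in one pass over the ROI values (the discretized
// Entropy/Uniformity terms are added by the R wrapper).
// [[Rcpp::export]]
NumericVector cpp_first_order(NumericVector x, double voxel_volume) {
  const int n = x.size();
  std::vector<double> s(x.begin(), x.end());
  std::sort(s.begin(), s.end());
  auto quant = [&](double q) {           // type-7 quantile on sorted data
    double h = (n - 1) * q;
    int lo = (int)std::floor(h);
    int hi = lo + 1 < n ? lo + 1 : lo;
    return s[lo] + (h - lo) * (s[hi] - s[lo]);
  };
  double q10 = quant(0.10), q25 = quant(0.25), q50 = quant(0.50),
         q75 = quant(0.75), q90 = quant(0.90);
  double sum = 0, sum2 = 0;
  for (int i = 0; i < n; ++i) { sum += s[i]; sum2 += s[i] * s[i]; }
  double mu = sum / n;
  double m2 = 0, m3 = 0, m4 = 0, mad = 0;
  for (int i = 0; i < n; ++i) {
    double dv = s[i] - mu;
    m2 += dv * dv; m3 += dv * dv * dv; m4 += dv * dv * dv * dv;
    mad += std::fabs(dv);
  }
  m2 /= n; m3 /= n; m4 /= n; mad /= n;
  double rsum = 0; int rn = 0;
  for (int i = 0; i < n; ++i)
    if (s[i] >= q10 && s[i] <= q90) { rsum += s[i]; ++rn; }
  double rmu = rn > 0 ? rsum / rn : 0, rmad = 0;
  for (int i = 0; i < n; ++i)
    if (s[i] >= q10 && s[i] <= q90) rmad += std::fabs(s[i] - rmu);
  rmad = rn > 0 ? rmad / rn : 0;
  NumericVector out = NumericVector::create(
      _["Energy"] = sum2,
      _["TotalEnergy"] = voxel_volume * sum2,
      _["Minimum"] = s[0],
      _["P10"] = q10,
      _["P90"] = q90,
      _["Maximum"] = s[n - 1],
      _["Mean"] = mu,
      _["Median"] = q50,
      _["IQR"] = q75 - q25,
      _["Range"] = s[n - 1] - s[0],
      _["MAD"] = mad,
      _["rMAD"] = rmad,
      _["RMS"] = std::sqrt(sum2 / n),
      _["Skewness"] = m2 > 0 ? m3 / std::pow(m2, 1.5) : 0,
      _["Kurtosis"] = m2 > 0 ? m4 / (m2 * m2) : 0,
      _["Variance"] = m2);
  return out;
}
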