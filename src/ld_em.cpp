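#include <Rcpp.h>
using namespace Rcpp;

// Pairwise r2 between the columns of two genotype blocks via maximum-
// likelihood haplotype frequencies (EM on unphased genotypes, pairwise
// deletion of missing calls). Genotypes are allele-B counts 0/1/2, NA for
// missing. When `same` is true the blocks are the same object and only the
// upper triangle (i < j) is filled.
//
// status: 0 = ok, 1 = monomorphic in the complete-case subset (r2 NA),
//         2 = fewer than 2 complete observations (r2 NA).
// [[Rcpp::export]]
List em_r2_block(IntegerMatrix ga, IntegerMatrix gb, bool same,
                 int max_iter, double tol) {
  const int n = ga.nrow(), ma = ga.ncol(), mb = gb.ncol();
  if (gb.nrow() != n) stop("sample counts differ between blocks");
  NumericMatrix r2(ma, mb);
  LogicalMatrix conv(ma, mb);
  IntegerMatrix status(ma, mb), nobs(ma, mb);
  std::fill(r2.begin(), r2.end(), NA_REAL);

  for (int i = 0; i < ma; ++i) {
    const int j0 = same ? i + 1 : 0;
    for (int j = j0; j < mb; ++j) {
      int c[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
      int m = 0;
      for (int k = 0; k < n; ++k) {
        const int gi = ga(k, i), gj = gb(k, j);
        if (gi == NA_INTEGER || gj == NA_INTEGER) continue;
        ++c[gi][gj];
        ++m;
      }
      nobs(i, j) = m;
      if (m < 2) { status(i, j) = 2; continue; }
      const double tot = 2.0 * m;
      // allele-B counts at each locus in the complete-case subset
      const int nB1 = c[1][0] + c[1][1] + c[1][2] +
                      2 * (c[2][0] + c[2][1] + c[2][2]);
      const int nB2 = c[0][1] + c[1][1] + c[2][1] +
                      2 * (c[0][2] + c[1][2] + c[2][2]);
      if (nB1 == 0 || nB1 == 2 * m || nB2 == 0 || nB2 == 2 * m) {
        status(i, j) = 1;
        continue;
      }
      // unambiguous haplotype counts; haplotype (x, y) = allele-B indicators
      const double cAA = 2.0 * c[0][0] + c[0][1] + c[1][0];
      const double cAB = 2.0 * c[0][2] + c[0][1] + c[1][2];
      const double cBA = 2.0 * c[2][0] + c[1][0] + c[2][1];
      const double cBB = 2.0 * c[2][2] + c[2][1] + c[1][2];
      const double dh = c[1][1];
      const double pB1 = nB1 / tot, pB2 = nB2 / tot;
      // start at linkage equilibrium
      double pAA = (1 - pB1) * (1 - pB2), pAB = (1 - pB1) * pB2;
      double pBA = pB1 * (1 - pB2), pBB = pB1 * pB2;
      bool ok = false;
      for (int it = 0; it < max_iter; ++it) {
        const double denom = pAA * pBB + pAB * pBA;
        const double w = denom > 0 ? pAA * pBB / denom : 0.5;
        const double qAA = (cAA + w * dh) / tot;
        const double qBB = (cBB + w * dh) / tot;
        const double qAB = (cAB + (1 - w) * dh) / tot;
        const double qBA = (cBA + (1 - w) * dh) / tot;
        const double delta =
            std::fabs(qAA - pAA) + std::fabs(qAB - pAB) +
            std::fabs(qBA - pBA) + std::fabs(qBB - pBB);
        pAA = qAA; pAB = qAB; pBA = qBA; pBB = qBB;
        if (delta < tol) { ok = true; break; }
      }
      double r;
      if (ok) {
        const double D = pBB - pB1 * pB2;
        r = D * D / (pB1 * (1 - pB1) * pB2 * (1 - pB2));
      } else {
        // composite fallback: squared Pearson correlation of the genotype
        // counts over the complete-case subset, from the count table
        const double s1 = nB1, s2 = nB2;
        const double q1 = c[1][0] + c[1][1] + c[1][2] +
                          4.0 * (c[2][0] + c[2][1] + c[2][2]);
        const double q2 = c[0][1] + c[1][1] + c[2][1] +
                          4.0 * (c[0][2] + c[1][2] + c[2][2]);
        const double cross = c[1][1] + 2.0 * c[1][2] + 2.0 * c[2][1] +
                             4.0 * c[2][2];
        const double num = m * cross - s1 * s2;
        r = num * num / ((m * q1 - s1 * s1) * (m * q2 - s2 * s2));
      }
      if (r > 1) r = 1;
      if (r < 0) r = 0;
      r2(i, j) = r;
      conv(i, j) = ok;
    }
  }
  return List::create(_["r2"] = r2, _["converged"] = conv,
                      _["status"] = status, _["nobs"] = nobs);
}
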