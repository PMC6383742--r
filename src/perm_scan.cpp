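#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Pearson chi-square on a 2 x H table from aligned count vectors with known
// totals; pooled-zero columns contribute nothing and are skipped.
static inline double chi2_pair(const double* a, const double* b, int H,
                               double totA, double totB) {
  const double N = totA + totB;
  double chi2 = 0.0;
  for (int j = 0; j < H; ++j) {
    const double c = a[j] + b[j];
    if (c <= 0.0) continue;
    const double ea = totA * c / N;
    const double eb = totB * c / N;
    const double da = a[j] - ea;
    const double db = b[j] - eb;
    chi2 += da * da / ea + db * db / eb;
  }
  return chi2;
}

// Permutation scan over all windows.
//
// code1, code2: per-individual haplotype codes (M x W), compact 0..H_w-1.
// grp: group per individual (0 = ancestor proxy, 1 = recipient, 2 = donor).
// B: label permutations per window.  The permutation unit is the
// individual — both haplotypes move together — and group sizes stay fixed.
// max_exceed > 0 stops a window's permutations early once that many
// permuted deltas have reached the observed one (the candidate decision,
// which needs zero exceedances, is unaffected; reported p-values become
// anytime estimates).  Uses R's RNG: reproducible under set.seed().
// [[Rcpp::export(name = ".perm_scan_cpp")]]
DataFrame perm_scan_cpp(IntegerMatrix code1, IntegerMatrix code2,
                        IntegerVector grp, int B, int max_exceed) {
  const int M = code1.nrow();
  const int W = code1.ncol();
  if (code2.nrow() != M || code2.ncol() != W || grp.size() != M)
    stop("dimension mismatch");

  int sizes[3] = {0, 0, 0};
  for (int i = 0; i < M; ++i) {
    if (grp[i] < 0 || grp[i] > 2) stop("grp codes must be 0/1/2");
    sizes[grp[i]]++;
  }
  if (sizes[0] == 0 || sizes[1] == 0 || sizes[2] == 0)
    stop("each of the three role populations needs at least one individual");
  const int na = sizes[0], nr = sizes[1];
  const double totA = 2.0 * sizes[0], totR = 2.0 * sizes[1],
               totD = 2.0 * sizes[2];

  NumericVector chi2_anc(W), chi2_donor(W), delta(W);
  IntegerVector n_ge(W), b_done(W);

  std::vector<int> idx(M);
  std::vector<double> c0, c1, c2, tot;

  for (int w = 0; w < W; ++w) {
    int H = 0;
    for (int i = 0; i < M; ++i) {
      if (code1(i, w) >= H) H = code1(i, w) + 1;
      if (code2(i, w) >= H) H = code2(i, w) + 1;
    }
    c0.assign(H, 0.0); c1.assign(H, 0.0); c2.assign(H, 0.0);
    tot.assign(H, 0.0);
    for (int i = 0; i < M; ++i) {
      tot[code1(i, w)] += 1.0;
      tot[code2(i, w)] += 1.0;
      double* c = grp[i] == 0 ? &c0[0] : (grp[i] == 1 ? &c1[0] : &c2[0]);
      c[code1(i, w)] += 1.0;
      c[code2(i, w)] += 1.0;
    }
    const double obs_anc = chi2_pair(&c0[0], &c1[0], H, totA, totR);
    const double obs_don = chi2_pair(&c1[0], &c2[0], H, totR, totD);
    const double obs_delta = obs_anc - obs_don;
    chi2_anc[w] = obs_anc;
    chi2_donor[w] = obs_don;
    delta[w] = obs_delta;

    for (int i = 0; i < M; ++i) idx[i] = i;
    int count = 0, b = 0;
    for (; b < B; ++b) {
      // partial Fisher-Yates: uniformly draw the ancestor and recipient
      // individuals; the rest form the donor group (counted by complement)
      for (int i = 0; i < na + nr; ++i) {
        int j = i + (int)(unif_rand() * (M - i));
        if (j >= M) j = M - 1;
        std::swap(idx[i], idx[j]);
      }
      std::fill(c0.begin(), c0.end(), 0.0);
      std::fill(c1.begin(), c1.end(), 0.0);
      for (int i = 0; i < na; ++i) {
        c0[code1(idx[i], w)] += 1.0;
        c0[code2(idx[i], w)] += 1.0;
      }
      for (int i = na; i < na + nr; ++i) {
        c1[code1(idx[i], w)] += 1.0;
        c1[code2(idx[i], w)] += 1.0;
      }
      double d = chi2_pair(&c0[0], &c1[0], H, totA, totR);
      {  // chi2(recipient, donor) with donor counts by complement
        double chi2 = 0.0;
        for (int j = 0; j < H; ++j) {
          const double c = tot[j] - c0[j];
          if (c <= 0.0) continue;
          const double er = totR * c / (totR + totD);
          const double ed = totD * c / (totR + totD);
          const double dr = c1[j] - er;
          const double dd = (tot[j] - c0[j] - c1[j]) - ed;
          chi2 += dr * dr / er + dd * dd / ed;
        }
        d -= chi2;
      }
      if (d >= obs_delta) {
        ++count;
        if (max_exceed > 0 && count >= max_exceed) { ++b; break; }
      }
    }
    n_ge[w] = count;
    b_done[w] = b;
  }

  return DataFrame::create(_["chi2_anc"] = chi2_anc,
                           _["chi2_donor"] = chi2_donor,
                           _["delta"] = delta,
                           _["n_ge"] = n_ge,
                           _["b_done"] = b_done);
}
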