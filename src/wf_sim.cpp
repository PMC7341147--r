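#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Forward Wright-Fisher diploid evolution of binary haplotypes with an
// interval-wise recombination model: between consecutive markers m-1 and m
// the copied parental strand switches with probability p[m-1] (0.5 between
// chromosomes, ~rate * interval length within them, locally multiplied by
// the suppression factor around a fusion junction once the fusion epoch
// starts). Epoch e applies to generations g with epoch_start[e] <= g.
//
// Switch positions are sampled exactly (independent Bernoulli per
// interval) by inversion on the prefix sums of log(1 - p): the next
// switching interval after k is the smallest i with
// S[i] <= S[k] + log(u), found by binary search, so cost scales with the
// number of switches, not the number of markers.
//
// haps: 2 * pop_size x M matrix of founder haplotypes (0/1).
// interval_probs: n_epochs x (M - 1) switch probabilities.
// epoch_start: 1-based first generation of each epoch, non-decreasing,
//   epoch_start[0] must be 1.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix wf_evolve(IntegerMatrix haps, NumericMatrix interval_probs,
                        IntegerVector epoch_start, int n_generations) {
  const int M = haps.ncol();
  const int H = haps.nrow();
  if (H % 2 != 0) stop("haplotype matrix must have an even row count");
  const int P = H / 2;
  if (interval_probs.ncol() != M - 1)
    stop("interval_probs must have M - 1 columns");
  const int n_epochs = interval_probs.nrow();
  if (epoch_start.size() != n_epochs || epoch_start[0] != 1)
    stop("epoch_start must align with interval_probs rows and begin at 1");

  // transpose to haplotype-major storage for contiguous segment copies
  std::vector<std::vector<int> > cur(H, std::vector<int>(M)),
      nxt(H, std::vector<int>(M));
  for (int r = 0; r < H; ++r)
    for (int m = 0; m < M; ++m) cur[r][m] = haps(r, m);

  // S[k] = sum_{i < k} log(1 - p[i]), k = 0..M-1 (non-increasing)
  std::vector<double> S(M);
  std::vector<int> xo; xo.reserve(64);
  int epoch = -1;

  for (int gen = 1; gen <= n_generations; ++gen) {
    int e = 0;
    while (e + 1 < n_epochs && epoch_start[e + 1] <= gen) ++e;
    if (e != epoch) {
      S[0] = 0.0;
      for (int m = 1; m < M; ++m) {
        const double p = interval_probs(e, m - 1);
        S[m] = S[m - 1] + (p >= 1.0 ? -INFINITY : std::log1p(-p));
      }
      epoch = e;
    }
    for (int ind = 0; ind < P; ++ind) {
      for (int gam = 0; gam < 2; ++gam) {
        const int parent = (int)(unif_rand() * P);
        std::vector<int>& out = nxt[2 * ind + gam];
        const std::vector<int>& h0 = cur[2 * parent];
        const std::vector<int>& h1 = cur[2 * parent + 1];
        // sample switching intervals
        xo.clear();
        int k = 0;
        for (;;) {
          const double target = S[k] + std::log(unif_rand());
          if (target < S[M - 1]) break;
          int lo = k + 1, hi = M - 1;
          while (lo < hi) {  // smallest i with S[i] <= target
            const int mid = (lo + hi) / 2;
            if (S[mid] <= target) hi = mid; else lo = mid + 1;
          }
          xo.push_back(lo);
          k = lo;
          if (k >= M - 1) break;
        }
        int strand = unif_rand() < 0.5 ? 0 : 1;
        int from = 0;
        for (size_t x = 0; x <= xo.size(); ++x) {
          const int to = (x < xo.size()) ? xo[x] : M;
          const std::vector<int>& src = strand ? h1 : h0;
          std::copy(src.begin() + from, src.begin() + to, out.begin() + from);
          from = to;
          strand ^= 1;
        }
      }
    }
    cur.swap(nxt);
  }
  IntegerMatrix res(H, M);
  for (int r = 0; r < H; ++r)
    for (int m = 0; m < M; ++m) res(r, m) = cur[r][m];
  return res;
}
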