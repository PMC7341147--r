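#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test of Hardy-Weinberg proportions: given the observed
#' allele counts, the p-value is the summed probability of all heterozygote
#' counts whose conditional probability does not exceed that of the observed
#' count. This is the standard exact-test behavior of genotype-QC tools
#' (robust at low minor-allele frequency, unlike the chi-square test).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1).
#' @return the exact p-value in (0, 1]; monomorphic samples give 1.
#' @examples
#' hwe_exact_pvalue(25, 50, 25)   # modal heterozygote count -> 1
#' hwe_exact_pvalue(50, 0, 50)    # extreme heterozygote deficit -> ~0
#' @export
hwe_exact_pvalue <- function(n_AA, n_Aa, n_aa) {
  stopifnot(length(n_AA) == 1, length(n_Aa) == 1, length(n_aa) == 1)
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotyped sample required")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  nm <- min(nA, na)                       # minor allele count
  het <- seq(nm %% 2, nm, by = 2)         # feasible heterozygote counts
  # log P(het = k | allele counts), Levene's conditional distribution
  lp <- lfactorial(n) - lfactorial((nA - het) / 2) - lfactorial(het) -
    lfactorial((na - het) / 2) + het * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, het)]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

# Internal, vectorized over markers of a genotype matrix.
hwe_pvalues <- function(g) {
  vapply(seq_len(ncol(g)), function(j) {
    gj <- g[, j]
    hwe_exact_pvalue(sum(gj == 0L, na.rm = TRUE),
                     sum(gj == 1L, na.rm = TRUE),
                     sum(gj == 2L, na.rm = TRUE))
  }, numeric(1))
}
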