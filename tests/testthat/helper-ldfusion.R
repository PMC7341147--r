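# Shared fixtures and independent oracles for the test suite. Everything is
# built in code; simulation-based fixtures are cached per seed so several
# test files can share one run.

# -- tiny deterministic data --------------------------------------------------

tiny_map <- function(n = 3L, chrom = "1", start = 1e6, step = 1e6) {
  marker_map(paste0("m", seq_len(n)), chrom,
             seq(start, by = step, length.out = n),
             allele_a = "A", allele_b = "C")
}

# genotype matrix realizing given diploid rows
geno_matrix <- function(rows, ids = NULL) {
  g <- do.call(rbind, rows)
  storage.mode(g) <- "integer"
  rownames(g) <- ids %||% paste0("s", seq_len(nrow(g)))
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build unphased genotypes for two loci from explicit haplotype pairs so the
# haplotype frequencies are known exactly. `pairs` is a list of c(h1, h2)
# with haplotypes coded "AB" etc., A/a = allele at locus 1, B/b at locus 2.
genotypes_from_hap_pairs <- function(pairs) {
  g <- t(vapply(pairs, function(p) {
    a1 <- substr(p, 1, 1) == "a"   # allele-B indicator, locus 1
    a2 <- substr(p, 2, 2) == "b"
    c(sum(a1), sum(a2))
  }, numeric(2)))
  storage.mode(g) <- "integer"
  colnames(g) <- c("m1", "m2")
  rownames(g) <- paste0("s", seq_len(nrow(g)))
  g
}

# -- independent oracles ------------------------------------------------------

# Exact HWE p-value via the Levene distribution computed with the ratio
# recurrence (an independent route from the lgamma closed form used by the
# implementation).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  nm <- min(nA, na)
  het <- seq(nm %% 2, nm, by = 2)
  pr <- numeric(length(het))
  pr[1] <- 1
  if (length(het) > 1) for (i in 2:length(het)) {
    k <- het[i - 1]
    # P(k+2) / P(k) from the conditional distribution
    pr[i] <- pr[i - 1] * 4 * ((nA - k) / 2) * ((na - k) / 2) /
      ((k + 2) * (k + 1))
  }
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, het)]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

# r2 from phased haplotype frequencies (direct counting oracle)
r2_from_hap_freqs <- function(pAB, pAb, paB, pab) {
  pA <- pAB + pAb; pB <- pAB + paB
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Spearman rho by explicit rank correlation (brute-force oracle)
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# -- small simulation configs -------------------------------------------------

small_sim_config <- function(seed, ...) {
  sim_config(
    n_samples = 60L, pop_size = 60L, n_generations = 120L,
    split_chroms = chrom_table(c("cA", "cB", "cC"), c(2e7, 5e7, 3e7)),
    fusions = list(list(chrom_a = "cA", chrom_b = "cB", time = 120L)),
    n_markers = c(cA = 160L, cB = 400L, cC = 240L),
    seed = seed, ...
  )
}

# cache simulation runs shared between test files
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, maker) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- maker()
  .sim_cache[[key]]
}

default_scenario_run <- function(seed) {
  cached_sim(paste0("default_", seed), function() {
    sim <- simulate_fused_population(sim_config(seed = seed))
    pipe <- run_fusion_pipeline(sim$genotypes, sim$map, sim$chrom_table)
    list(sim = sim, pipe = pipe)
  })
}

# windowed LD and diversity scans of the fused chromosome in true fused
# coordinates (default scenario, or suppression disabled)
junction_scan_run <- function(seed, suppression = 0.01) {
  key <- sprintf("jscan_%d_%s", seed, suppression)
  cached_sim(key, function() {
    sim <- if (suppression == 0.01) default_scenario_run(seed)$sim
           else simulate_fused_population(
             sim_config(seed = seed, suppression_factor = suppression))
    q <- apply_qc(sim$genotypes, sim$map)
    fmap <- sim$truth$fused_map[q$keep, ]
    fc <- "chr1;chr2"
    jn <- sim$truth$junctions[[fc]]
    sel <- fmap$chrom == fc
    pr <- pairwise_r2(q$genotypes[, sel], fmap[sel, ], scope = "intra")
    ld <- window_ld_scan(pr, fmap[sel, ], n = nrow(q$genotypes),
                         chrom_lengths = sim$truth$chrom_table_fused)
    hd <- haplotype_diversity_scan(sim$haplotypes[, q$keep][, sel],
                                   fmap[sel, ],
                                   chrom_lengths = sim$truth$chrom_table_fused)
    list(ld = ld, hd = hd, junction = jn, pairs = pr, sim = sim)
  })
}
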