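# Windowed LD and haplotype-diversity scans, centromere profiling and the
# fusion-age heuristic.

test_that("window tiling steps by exactly step_bp and covers the chromosome", {
  scan_map <- marker_map(paste0("m", 1:10), "1",
                         seq(1e6, 19e6, length.out = 10))
  h <- matrix(rbinom(40 * 10, 1L, 0.5), 40, 10)
  sc <- haplotype_diversity_scan(h, scan_map, window_bp = 1e6, step_bp = 5e5)
  expect_true(all(diff(sc$start) == 5e5))
  expect_equal(sc$start[1], 0)
  expect_gte(max(sc$end), max(scan_map$pos_bp))
  # every interior marker falls into window_bp / step_bp windows
  for (p in scan_map$pos_bp[3:8])
    expect_equal(sum(p > sc$start & p <= sc$end), 2L)
})

test_that("noiseless windows reproduce the generating decay exactly", {
  beta <- 1e-5; n <- 150
  pos <- seq(1e5, 3.9e6, by = 1e5)
  map <- marker_map(paste0("m", seq_along(pos)), "1", pos)
  idx <- t(combn(seq_along(pos), 2))
  pairs <- data.frame(
    marker_i = map$marker_id[idx[, 1]], marker_j = map$marker_id[idx[, 2]],
    chrom_i = "1", pos_i = pos[idx[, 1]], chrom_j = "1", pos_j = pos[idx[, 2]],
    r2 = NA, same_chrom = TRUE,
    dist_bp = abs(pos[idx[, 2]] - pos[idx[, 1]]))
  pairs$r2 <- expected_r2_hill_weir(beta * pairs$dist_bp, n)
  sc <- window_ld_scan(pairs, map, n, window_bp = 4e6, step_bp = 1e6)
  w1 <- sc[sc$start == 0, ]
  expect_true(w1$defined)
  expect_equal(w1$stat_value, expected_r2_hill_weir(beta * 1e5, n),
               tolerance = 1e-6)
  expect_equal(w1$beta, beta, tolerance = 1e-6)
})

test_that("windows below min_pairs are undefined", {
  map <- marker_map(c("a", "b"), "1", c(1e6, 2e6))
  pairs <- data.frame(marker_i = "a", marker_j = "b", chrom_i = "1",
                      pos_i = 1e6, chrom_j = "1", pos_j = 2e6,
                      r2 = 0.4, same_chrom = TRUE, dist_bp = 1e6)
  sc <- window_ld_scan(pairs, map, 100)
  expect_false(any(sc$defined))
  expect_true(all(is.na(sc$stat_value)))
})

test_that("haplotype diversity matches its algebraic anchors", {
  map <- marker_map(paste0("m", 1:4), "1", c(1, 2, 3, 4) * 2e5)
  # all haplotypes identical -> 0
  h0 <- matrix(1L, 12, 4)
  sc0 <- haplotype_diversity_scan(h0, map)
  expect_equal(sc0$stat_value[sc0$defined][1], 0)
  # all M haplotypes distinct -> exactly 1: (M/(M-1)) (1 - 1/M) = 1
  h1 <- diag(4L); storage.mode(h1) <- "integer"
  sc1 <- haplotype_diversity_scan(h1, map)
  expect_equal(sc1$stat_value[sc1$defined][1], 1)
  # two classes at frequency 1/2 among 4 haplotypes -> (4/3)(1 - 0.5)
  h2 <- rbind(c(0L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L),
              c(1L, 1L, 1L, 1L), c(1L, 1L, 1L, 1L))
  sc2 <- haplotype_diversity_scan(h2, map)
  expect_equal(sc2$stat_value[sc2$defined][1], (4 / 3) * 0.5,
               tolerance = 1e-12)
  # literal individual-based correction: (N/(N-1)) (1 - 0.5) with N = 2
  sc2i <- haplotype_diversity_scan(h2, map, correction = "individuals")
  expect_equal(sc2i$stat_value[sc2i$defined][1], (2 / 1) * 0.5)
})

test_that("diversity is invariant to haplotype order and allele relabeling", {
  set.seed(14)
  map <- marker_map(paste0("m", 1:6), "1", seq(2e5, 1.2e6, by = 2e5))
  h <- matrix(rbinom(30 * 6, 1L, 0.5), 30, 6)
  base <- haplotype_diversity_scan(h, map)
  perm <- haplotype_diversity_scan(h[sample(30), ], map)
  expect_equal(perm$stat_value, base$stat_value)
  flip <- h; flip[, 3] <- 1L - flip[, 3]
  expect_equal(haplotype_diversity_scan(flip, map)$stat_value,
               base$stat_value)
})

test_that("unphased input is rejected with guidance", {
  map <- marker_map(c("a", "b"), "1", c(1e5, 2e5))
  h <- matrix(c(NA, 1L, 0L, 1L), 2, 2)
  expect_error(haplotype_diversity_scan(h, map), "phased")
})

test_that("centromere profiles measure peak, baseline and extent", {
  win <- data.frame(chrom = "F", start = seq(0, 49e6, by = 1e6))
  win$end <- win$start + 4e6
  win$stat_value <- 0.1
  win$defined <- TRUE
  jn <- 25e6
  center <- (win$start + win$end) / 2
  single <- win; single$stat_value[which.min(abs(center - jn))] <- 0.9
  pr <- centromere_profile(single, jn)
  expect_equal(pr$peak_value, 0.9)
  expect_equal(pr$baseline_value, 0.1)
  expect_equal(pr$extent_bp, 4e6)  # one window's width
  plateau <- win
  plateau$stat_value[abs(center - jn) <= 4e6] <- 0.8  # elevated plateau
  pr2 <- centromere_profile(plateau, jn)
  i <- which(abs(center - jn) <= 4e6)
  expect_equal(pr2$extent_bp, max(win$end[i]) - min(win$start[i]))
  expect_gt(pr2$extent_bp, pr$extent_bp)
})

test_that("fusion-age ranking follows the documented keys", {
  mk <- function(chrom, peak, ext)
    structure(list(chrom = chrom, junction_bp = 0, peak_value = peak,
                   baseline_value = 0.1, extent_bp = ext),
              class = "centromere_profile")
  # smaller extent ranks older at equal peaks
  r <- rank_fusion_age(list(mk("A", 0.5, 1e7), mk("B", 0.5, 2e6)))
  expect_equal(r$chrom, c("B", "A"))
  # higher peak ranks older at equal extents
  r2 <- rank_fusion_age(list(mk("A", 0.4, 6e6), mk("B", 0.9, 6e6)))
  expect_equal(r2$chrom, c("B", "A"))
  # reversed reading available
  r3 <- rank_fusion_age(list(mk("A", 0.5, 1e7), mk("B", 0.5, 2e6)),
                        older = "larger_extent")
  expect_equal(r3$chrom, c("A", "B"))
  # exact ties are flagged and resolved by label
  r4 <- rank_fusion_age(list(mk("B", 0.5, 5e6), mk("A", 0.5, 5e6)))
  expect_true(all(r4$tie))
  expect_equal(r4$chrom, c("A", "B"))
})

test_that("a staggered two-fusion history ranks the older fusion older", {
  ct <- chrom_table(paste0("chr", 1:6), c(4e7, 1e8, 4.5e7, 9e7, 6e7, 7e7))
  wins <- 0L
  seeds <- 1:10
  for (s in seeds) {
    run <- cached_sim(paste0("staggered_", s), function() {
      cfg <- sim_config(seed = s, split_chroms = ct,
        fusions = list(list(chrom_a = "chr1", chrom_b = "chr2", time = 600L),
                       list(chrom_a = "chr3", chrom_b = "chr4", time = 200L)))
      sim <- simulate_fused_population(cfg)
      q <- apply_qc(sim$genotypes, sim$map)
      fmap <- sim$truth$fused_map[q$keep, ]
      profs <- lapply(names(sim$truth$junctions), function(fc) {
        sel <- fmap$chrom == fc
        pr <- pairwise_r2(q$genotypes[, sel], fmap[sel, ], scope = "intra")
        sc <- window_ld_scan(pr, fmap[sel, ], n = nrow(q$genotypes),
                             chrom_lengths = sim$truth$chrom_table_fused)
        centromere_profile(sc, sim$truth$junctions[[fc]])
      })
      rank_fusion_age(profs, older = "higher_peak")
    })
    wins <- wins + (run$chrom[1] == "chr1;chr2")
  }
  # peak-primary key: 600-generation fusion called older than the
  # 200-generation one (both in the rising-LD regime, where extent is
  # uninformative)
  expect_gte(wins, 8L)
})
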