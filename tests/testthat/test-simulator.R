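# The forward Wright-Fisher simulator: determinism, drift calibration, LD
# structure, split-reference projection and fixture round trips.

test_that("output dimensions and coding match the configuration", {
  sim <- cached_sim("io_small", function()
    simulate_fused_population(small_sim_config(21L)))
  cfg <- sim$truth$config
  expect_equal(nrow(sim$genotypes), cfg$n_samples)
  expect_equal(nrow(sim$haplotypes), 2L * cfg$n_samples)
  expect_lte(ncol(sim$genotypes), sum(cfg$n_markers))
  expect_true(all(sim$haplotypes %in% c(0L, 1L)))
  expect_true(all(sim$genotypes[!is.na(sim$genotypes)] %in% 0:2))
  expect_equal(colnames(sim$genotypes), sim$map$marker_id)
  # every surviving marker clears the ascertainment threshold
  f <- colMeans(sim$haplotypes)
  expect_true(all(pmin(f, 1 - f) > cfg$maf_ascertainment))
})

test_that("the same seed reproduces the run bitwise", {
  a <- simulate_fused_population(small_sim_config(33L))
  b <- simulate_fused_population(small_sim_config(33L))
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$map, b$map)
  c <- simulate_fused_population(small_sim_config(34L))
  expect_false(identical(a$haplotypes, c$haplotypes))
})

test_that("heterozygosity declines at the Wright-Fisher rate", {
  Ne <- 80L; t <- 60L
  ratios <- vapply(1:4, function(s) {
    cfg <- sim_config(
      n_samples = Ne, pop_size = Ne, n_generations = t,
      split_chroms = chrom_table(c("u", "v"), c(3e7, 3e7)),
      fusions = list(), n_markers = c(u = 400L, v = 400L),
      maf_ascertainment = -1, missing_rate = 0, seed = 100 + s)
    sim <- simulate_fused_population(cfg)
    p <- colMeans(sim$haplotypes)
    p0 <- sim$truth$founder_freq
    mean(2 * p * (1 - p)) / mean(2 * p0 * (1 - p0))
  }, numeric(1))
  expected <- (1 - 1 / (2 * Ne))^t
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - expected), 3 * se + 0.02)
})

test_that("r2 decays with distance on chromosome arms", {
  sim <- cached_sim("dense_arm", function() {
    cfg <- sim_config(
      n_samples = 120L, pop_size = 120L, n_generations = 150L,
      split_chroms = chrom_table("w", 5e7), fusions = list(),
      n_markers = c(w = 700L), seed = 55L)
    simulate_fused_population(cfg)
  })
  q <- apply_qc(sim$genotypes, sim$map)
  # arm region only (away from the suppressed centromeric start)
  sel <- q$map$pos_bp > 2e6
  pairs <- pairwise_r2(q$genotypes[, sel], q$map[sel, ], scope = "intra")
  bins <- cut(pairs$dist_bp, breaks = seq(0, 5e5, by = 1e5))
  mr <- tapply(pairs$r2, bins, mean)
  expect_true(all(!is.na(mr)))
  expect_lte(sum(diff(mr) > 0), 1)  # monotone up to one inversion
})

test_that("the recombination map encodes suppression around centromeres", {
  sim <- cached_sim("io_small", function()
    simulate_fused_population(small_sim_config(21L)))
  cfg <- sim$truth$config
  rec <- sim$truth$recomb
  jn <- sim$truth$junctions[["cA;cB"]]
  rad <- cfg$suppression_radius_bp
  # intervals entirely inside the suppressed window: factor x rate x length
  ins <- rec$chrom == "cA;cB" & rec$start_bp >= jn - rad & rec$end_bp <= jn + rad
  expect_gt(sum(ins), 0)
  expect_equal(rec$switch_prob[ins],
               cfg$recomb_rate * cfg$suppression_factor *
                 (rec$end_bp[ins] - rec$start_bp[ins]), tolerance = 1e-12)
  # interior arm intervals: plain rate x length
  out <- rec$chrom == "cA;cB" & rec$start_bp > jn + 2 * rad &
    rec$end_bp < max(rec$end_bp[rec$chrom == "cA;cB"]) - rad
  expect_equal(rec$switch_prob[out],
               pmin(0.5, cfg$recomb_rate *
                      (rec$end_bp[out] - rec$start_bp[out])), tolerance = 1e-12)
  # decoy (acrocentric) centromeres at the chromosome start are suppressed
  dec <- rec$chrom == "cC" & rec$end_bp <= rad
  expect_true(all(rec$switch_prob[dec] <
                    cfg$recomb_rate * (rec$end_bp[dec] - rec$start_bp[dec])))
})

test_that("suppression concentrates LD and depletes diversity at the junction", {
  for (s in 1:2) {
    run <- junction_scan_run(s)
    ld <- run$ld[run$ld$defined, ]
    ctr <- (ld$start + ld$end) / 2
    near <- abs(ctr - run$junction) <= 2e6
    expect_gt(max(ld$stat_value[near]), median(ld$stat_value[!near]))
    hd <- run$hd[run$hd$defined & run$hd$n_markers >= 2, ]
    hctr <- (hd$start + hd$end) / 2
    hnear <- abs(hctr - run$junction) <= 1e6
    expect_lt(mean(hd$stat_value[hnear]), median(hd$stat_value[!hnear]))
  }
})

test_that("the truth maps satisfy the exact liftover identity", {
  sim <- cached_sim("io_small", function()
    simulate_fused_population(small_sim_config(21L)))
  lifted <- liftover_map(sim$truth$split_map, sim$truth$plan)
  expect_identical(lifted$pos_bp, sim$truth$fused_map$pos_bp)
  expect_identical(lifted$chrom, sim$truth$fused_map$chrom)
  proj <- project_to_split_reference(sim$truth)
  expect_identical(proj$pos_bp, sim$truth$split_map$pos_bp)
  expect_identical(proj$chrom, sim$truth$split_map$chrom)
})

test_that("fixtures round-trip and the truth JSON carries the plan verbatim", {
  sim <- cached_sim("io_small", function()
    simulate_fused_population(small_sim_config(21L)))
  dir <- withr::local_tempdir()
  paths <- write_fixture(sim, dir, formats = c("plink-text", "vcf"))
  ord <- order(sim$map$chrom, sim$map$pos_bp, method = "radix")
  # the VCF carries the complete phased haplotypes
  r <- read_genotypes(paths[["vcf"]], "vcf")
  expect_equal(unname(r$haplotypes), unname(sim$haplotypes[, ord]))
  expect_equal(r$map$marker_id, sim$map$marker_id[ord])
  # the ped/map carries the genotype calls including missingness
  rp <- read_genotypes(paths[["plink-text"]], "plink-text")
  expect_equal(unname(rp$genotypes), unname(sim$genotypes[, ord]))
  ct <- read_chrom_table(paths$chrom_table)
  expect_equal(ct$length_bp, sim$chrom_table$length_bp)
  truth <- jsonlite::read_json(paths$truth_json, simplifyVector = TRUE)
  expect_equal(truth$plan$source_chrom, sim$truth$plan$arms$source_chrom)
  expect_equal(truth$plan$junction_bp, sim$truth$plan$arms$junction_bp)
  expect_equal(truth$seed, sim$truth$config$seed)
  plan2 <- read_plan(paths$plan)
  expect_equal(plan2$arms$strand, sim$truth$plan$arms$strand)
})

test_that("ascertainment failure raises a helpful error", {
  cfg <- small_sim_config(3L, maf_ascertainment = 0.5)
  expect_error(simulate_fused_population(cfg), "ascertainment")
})
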