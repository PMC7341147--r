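# Masking scenarios, fold splits, the baseline imputer, accuracy metrics
# and the ANOVA/Tukey group comparison.

test_that("mask scenarios retain every k-th marker from a seeded offset", {
  map <- marker_map(sprintf("m%03d", 1:100), "1", (1:100) * 1e5)
  sc <- make_mask_scenarios(map, fractions = 0.10, seed = 3)[[1]]
  idx <- match(sc$retained_marker_ids, map$marker_id)
  expect_equal(diff(idx), rep(10L, length(idx) - 1L))
  expect_equal(length(idx), 10L)
  expect_lt(idx[1], 11L)
  # fraction 1 retains everything
  all_sc <- make_mask_scenarios(map, fractions = 1, seed = 3)[[1]]
  expect_equal(length(all_sc$masked_marker_ids), 0L)
  # determinism
  again <- make_mask_scenarios(map, fractions = 0.10, seed = 3)[[1]]
  expect_identical(again$retained_marker_ids, sc$retained_marker_ids)
  expect_error(make_mask_scenarios(map, fractions = 1.2), "fractions")
})

test_that("disjoint fourfold splits realize the 262/87 design at n = 349", {
  samples <- sprintf("b%03d", 1:349)
  folds <- split_folds(samples, n_folds = 4, seed = 5)
  sizes <- sort(vapply(folds, function(f) length(f$target), 0L),
                decreasing = TRUE)
  expect_equal(sizes, c(88L, 87L, 87L, 87L))
  expect_equal(sort(vapply(folds, function(f) length(f$reference), 0L)),
               c(261L, 262L, 262L, 262L))
  tests <- unlist(lapply(folds, `[[`, "target"))
  expect_setequal(tests, samples)          # union is everything
  expect_equal(anyDuplicated(tests), 0L)   # pairwise disjoint
  for (f in folds) expect_setequal(c(f$target, f$reference), samples)
  # 8 samples, 4 folds: four disjoint pairs
  f8 <- split_folds(sprintf("s%d", 1:8), 4, seed = 1)
  expect_true(all(vapply(f8, function(f) length(f$target), 0L) == 2L))
})

test_that("repeated random splits honor the reference fraction", {
  folds <- split_folds(sprintf("s%03d", 1:349), 4, seed = 2, mode = "random")
  expect_true(all(vapply(folds, function(f) length(f$reference), 0L) == 262L))
})

test_that("the baseline imputer is exact under perfect flanking LD", {
  # reference haplotypes where the middle marker is determined by its flanks
  set.seed(10)
  map <- tiny_map(3)
  hap_classes <- rbind(c(0L, 0L, 0L), c(1L, 1L, 1L))
  ref <- hap_classes[sample(1:2, 40, replace = TRUE), ]
  colnames(ref) <- map$marker_id
  truth <- haplotypes_to_genotypes(
    hap_classes[sample(1:2, 24, replace = TRUE), ])
  colnames(truth) <- map$marker_id
  masked <- truth; masked[, 2] <- NA_integer_
  imp <- baseline_impute(ref, masked, map, near_k = 2)
  expect_identical(imp[, 2], truth[, 2])
  acc <- accuracy_metrics(truth, imp, marker_ids = "m2")
  expect_equal(acc$r2a, 1)
  expect_equal(acc$perc, 1)
})

test_that("a marker monomorphic in the reference imputes as that allele", {
  map <- tiny_map(3)
  ref <- cbind(m1 = rep(0:1, 10), m2 = rep(1L, 20), m3 = rep(0:1, 10))
  truth <- cbind(m1 = rep(0:2, 4), m2 = rep(1L, 12), m3 = rep(2L, 12))
  masked <- truth; masked[, 2] <- NA_integer_
  imp <- baseline_impute(ref, masked, map, near_k = 1)
  expect_true(all(imp[, 2] == 2L))
})

test_that("self-reference imputation is near-perfect", {
  sim <- cached_sim("io_small", function()
    simulate_fused_population(small_sim_config(21L)))
  keep <- seq_len(min(200L, ncol(sim$haplotypes)))
  h <- sim$haplotypes[, keep]
  map <- sim$map[keep, ]
  g <- haplotypes_to_genotypes(h, sim$sample_ids)
  sc <- make_mask_scenarios(map, fractions = 0.2, seed = 4)[[1]]
  masked <- mask_genotypes(g, sc$masked_marker_ids)
  imp <- baseline_impute(h, masked, map)
  acc <- accuracy_metrics(g, imp, marker_ids = sc$masked_marker_ids)
  # flank matching cannot resolve ties at heterozygous flanks, so exact
  # recovery of one's own haplotypes is not guaranteed — only closely
  # approached
  expect_gt(acc$r2a, 0.9)
  expect_gt(acc$perc, 0.95)
})

test_that("accuracy metrics follow their hand-computed anchors", {
  t1 <- matrix(c(0L, 1L, 2L, 1L), 1)
  i1 <- matrix(c(0L, 1L, 1L, 1L), 1)
  colnames(t1) <- colnames(i1) <- paste0("m", 1:4)
  acc <- accuracy_metrics(t1, i1)
  expect_equal(acc$perc, 7 / 8)  # (2 + 2 + 1 + 2) / 8
  r_hand <- cor(c(0, 1, 2, 1), c(0, 1, 1, 1))^2
  expect_equal(acc$r2a, r_hand)
  # identical matrices
  acc1 <- accuracy_metrics(t1, t1)
  expect_equal(acc1$r2a, 1); expect_equal(acc1$perc, 1)
  # flipped homozygotes: correlation is sign-blind, allele concordance is 0
  t2 <- matrix(rep(c(0L, 2L), 10), 2)
  colnames(t2) <- paste0("m", 1:10)
  accf <- accuracy_metrics(t2, 2L - t2)
  expect_equal(accf$r2a, 1)
  expect_equal(accf$perc, 0)
  # zero-variance truth: undefined, not zero
  tz <- matrix(1L, 2, 3, dimnames = list(NULL, paste0("m", 1:3)))
  expect_true(is.na(accuracy_metrics(tz, tz)$r2a))
  expect_error(accuracy_metrics(t1, matrix(0L, 2, 2)), "mismatch")
})

test_that("frequency-random imputation matches its closed-form concordance", {
  # for independent true and imputed genotypes at frequency p, with
  # r = p (1 - p): E|t - i| = 4 r - 4 r^2, so PERC -> 1 - 2 r + 2 r^2
  # (the naive single-allele match rate p^2 + q^2 ignores the best-pairing
  # credit PERC gives a het-vs-hom discrepancy)
  set.seed(20)
  n <- 400L; m <- 50L
  p <- runif(m, 0.2, 0.8)
  truth <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  imp <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  storage.mode(truth) <- storage.mode(imp) <- "integer"
  colnames(truth) <- colnames(imp) <- paste0("m", seq_len(m))
  acc <- accuracy_metrics(truth, imp)
  r <- p * (1 - p)
  expected <- mean(1 - 2 * r + 2 * r^2)
  se <- sqrt(expected * (1 - expected) / (2 * n * m))
  expect_lt(abs(acc$perc - expected), 3 * se + 5e-3)
})

test_that("ANOVA and Tukey letters match hand computation on two groups", {
  res <- data.frame(
    scenario = 0.1, fold = rep(1:4, 2), region = "centromere",
    map_variant = rep(c("arranged", "split"), each = 4),
    metric = "r2a",
    value = c(0.951, 0.949, 0.950, 0.952, 0.801, 0.799, 0.800, 0.802),
    stringsAsFactors = FALSE)
  cmp <- region_group_comparison(res, metrics = "r2a")
  # hand one-way ANOVA: F = MSB / MSW with k = 2, n = 8
  va <- c(0.951, 0.949, 0.950, 0.952); vb <- c(0.801, 0.799, 0.800, 0.802)
  msb <- 4 * ((mean(va) - mean(c(va, vb)))^2 + (mean(vb) - mean(c(va, vb)))^2)
  msw <- (sum((va - mean(va))^2) + sum((vb - mean(vb))^2)) / 6
  p_hand <- pf(msb / msw, 1, 6, lower.tail = FALSE)
  expect_equal(cmp$f_p_value, p_hand, tolerance = 1e-10)
  expect_lt(cmp$f_p_value, 0.05)
  g <- attr(cmp, "groups")[[1]]
  expect_false(g$letters[g$map_variant == "arranged"] ==
                 g$letters[g$map_variant == "split"])
})

test_that("identical groups share a letter and claim no significance", {
  res <- data.frame(
    scenario = 0.1, fold = rep(1:3, 3), region = "centromere",
    map_variant = rep(c("a", "b", "c"), each = 3), metric = "perc",
    value = 0.9, stringsAsFactors = FALSE)
  cmp <- region_group_comparison(res, metrics = "perc")
  expect_gte(cmp$f_p_value, 0.05)
  g <- attr(cmp, "groups")[[1]]
  expect_equal(length(unique(g$letters)), 1L)
})

test_that("Tukey letters are symmetric under group relabeling", {
  set.seed(30)
  base <- data.frame(
    scenario = 0.1, fold = rep(1:4, 3), region = "centromere",
    map_variant = rep(c("g1", "g2", "g3"), each = 4), metric = "r2a",
    value = c(rnorm(4, 0.95, 0.002), rnorm(4, 0.94, 0.002),
              rnorm(4, 0.70, 0.002)),
    stringsAsFactors = FALSE)
  cmp1 <- region_group_comparison(base, metrics = "r2a")
  relab <- base
  relab$map_variant <- c(g1 = "zz", g2 = "aa", g3 = "mm")[base$map_variant]
  cmp2 <- region_group_comparison(relab, metrics = "r2a")
  g1 <- attr(cmp1, "groups")[[1]]; g2 <- attr(cmp2, "groups")[[1]]
  key1 <- setNames(g1$letters, c(g1 = "zz", g2 = "aa",
                                 g3 = "mm")[g1$map_variant])
  expect_equal(key1[g2$map_variant], setNames(g2$letters, g2$map_variant))
})

test_that("groups with one replicate are excluded with a warning", {
  res <- data.frame(
    scenario = 0.1, fold = c(1, 2, 3, 1, 2, 3, 1), region = "centromere",
    map_variant = c("a", "a", "a", "b", "b", "b", "c"), metric = "r2a",
    value = c(0.9, 0.91, 0.92, 0.8, 0.81, 0.82, 0.5),
    stringsAsFactors = FALSE)
  expect_warning(cmp <- region_group_comparison(res, metrics = "r2a"),
                 "replicates")
  expect_false(any(grepl("c", rownames(attr(cmp, "tukey")[[1]]))))
})
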