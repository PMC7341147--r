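# Fusion detection from inter-chromosomal LD counts, end localization, plan
# construction and the exact coordinate liftover.

fake_pairs <- function(chrom_i, pos_i, chrom_j, pos_j, r2) {
  df <- data.frame(
    marker_i = paste0("a", seq_along(r2)), marker_j = paste0("b", seq_along(r2)),
    chrom_i = as.character(chrom_i), pos_i = pos_i,
    chrom_j = as.character(chrom_j), pos_j = pos_j, r2 = r2,
    stringsAsFactors = FALSE)
  df$same_chrom <- df$chrom_i == df$chrom_j
  df$dist_bp <- ifelse(df$same_chrom, abs(df$pos_j - df$pos_i), NA_real_)
  df
}

test_that("inter-chromosomal counting is strict at the threshold", {
  pairs <- fake_pairs(c("1", "1", "1", "1"), c(1, 2, 3, 4) * 1e6,
                      c("2", "2", "2", "2"), c(1, 2, 3, 4) * 1e6,
                      r2 = c(0.5, 0.3, 0.21, 0.20))
  cnt <- interchrom_ld_counts(pairs, r2_min = 0.2)
  expect_equal(cnt["1", "2"], 3L)   # the pair at exactly 0.20 is excluded
  expect_equal(cnt["2", "1"], 3L)
  expect_equal(cnt["1", "1"], 0L)
})

test_that("detect_fusions keeps a dominant pair and rejects flat backgrounds", {
  chroms <- as.character(1:6)
  counts <- matrix(2L, 6, 6, dimnames = list(chroms, chroms))
  diag(counts) <- 0L
  counts["1", "2"] <- counts["2", "1"] <- 300L
  cand <- detect_fusions(counts)
  expect_equal(nrow(cand), 1L)
  expect_equal(c(cand$chrom_a, cand$chrom_b), c("1", "2"))
  # all counts low: empty candidate list
  flat <- matrix(3L, 4, 4, dimnames = list(chroms[1:4], chroms[1:4]))
  diag(flat) <- 0L
  expect_equal(nrow(detect_fusions(flat, min_count = 20)), 0L)
})

test_that("detect_fusions is invariant to chromosome relabeling", {
  chroms <- as.character(1:5)
  set.seed(8)
  counts <- matrix(rpois(25, 2), 5, 5, dimnames = list(chroms, chroms))
  counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
  diag(counts) <- 0L
  counts["2", "4"] <- counts["4", "2"] <- 120L
  counts["1", "3"] <- counts["3", "1"] <- 90L
  base <- detect_fusions(counts, min_count = 10)
  relab <- setNames(c("w", "x", "y", "z", "v"), chroms)
  counts2 <- counts
  dimnames(counts2) <- list(relab[chroms], relab[chroms])
  perm <- sample(5)
  counts2 <- counts2[perm, perm]
  got <- detect_fusions(counts2, min_count = 10)
  pairs_base <- apply(base[, 1:2], 1, function(r)
    paste(sort(relab[r]), collapse = "-"))
  pairs_got <- apply(got[, 1:2], 1, function(r) paste(sort(r), collapse = "-"))
  expect_setequal(pairs_got, pairs_base)
})

test_that("greedy matching keeps only the stronger pair per chromosome", {
  chroms <- as.character(1:4)
  counts <- matrix(0L, 4, 4, dimnames = list(chroms, chroms))
  counts["1", "2"] <- counts["2", "1"] <- 200L
  counts["2", "3"] <- counts["3", "2"] <- 150L
  suppressMessages(cand <- detect_fusions(counts))
  expect_equal(nrow(cand), 1L)
  expect_equal(c(cand$chrom_a, cand$chrom_b), c("1", "2"))
})

test_that("fusion ends localize to chromosome termini by median position", {
  ct <- chrom_table(c("A", "B"), c(4e7, 1e8))
  pairs <- fake_pairs(rep("A", 25), runif(25, 0, 4e6),
                      rep("B", 25), runif(25, 0, 4e6), r2 = rep(0.5, 25))
  ends <- localize_fusion_ends(pairs, list(chrom_a = "A", chrom_b = "B"), ct)
  expect_equal(ends$end_a, "begin")
  expect_equal(ends$end_b, "begin")
  expect_true(ends$resolved)
  # markers at the far end of B
  pairs2 <- fake_pairs(rep("A", 25), runif(25, 0, 4e6),
                       rep("B", 25), runif(25, 9.6e7, 1e8), r2 = rep(0.5, 25))
  ends2 <- localize_fusion_ends(pairs2, list(chrom_a = "A", chrom_b = "B"), ct)
  expect_equal(ends2$end_b, "end")
  # mid-chromosome medians are unresolvable
  pairs3 <- fake_pairs(rep("A", 25), runif(25, 1.5e7, 2.5e7),
                       rep("B", 25), runif(25, 0, 4e6), r2 = rep(0.5, 25))
  ends3 <- localize_fusion_ends(pairs3, list(chrom_a = "A", chrom_b = "B"), ct)
  expect_false(ends3$resolved)
  expect_true(is.na(ends3$end_a))
})

test_that("the plan realizes the printed coordinate formulas", {
  ct <- chrom_table(c("S", "L"), c(4e7, 1e8))
  cand <- data.frame(chrom_a = "S", chrom_b = "L",
                     end_a = "begin", end_b = "begin",
                     stringsAsFactors = FALSE)
  plan <- build_plan(cand, ct)
  arms <- plan$arms
  expect_equal(unique(arms$junction_bp), 4e7)
  expect_equal(arms$role, c("short", "long"))
  expect_equal(arms$strand, c(-1L, 1L))     # short arm reversed
  map <- marker_map(c("s0", "sj", "l0", "lm"),
                    c("S", "S", "L", "L"),
                    c(4e7, 0, 0, 5e6))
  lifted <- liftover_map(map, plan)
  # short arm: junction - p ; p = short length -> fused 0 (telomere)
  expect_equal(lifted$pos_bp, c(0L, 4e7, 4e7, 4.5e7))
  expect_equal(unique(lifted$chrom), "S;L")
  # the literal mode: shorter_len - p and shorter_len + (longer_len - p)
  plan_lit <- build_plan(cand, ct, orientation_mode = "paper_literal")
  lifted_lit <- liftover_map(map, plan_lit)
  expect_equal(lifted_lit$pos_bp, c(0L, 4e7, 14e7, 13.5e7))
})

test_that("equal arm lengths use the lexicographic tie-break", {
  ct <- chrom_table(c("b", "a"), c(5e7, 5e7))
  cand <- data.frame(chrom_a = "a", chrom_b = "b",
                     end_a = "begin", end_b = "begin",
                     stringsAsFactors = FALSE)
  expect_message(plan <- build_plan(cand, ct), "lexicographically")
  expect_equal(plan$arms$source_chrom[plan$arms$role == "short"], "a")
})

test_that("liftover is a bijection inverted exactly by invert_plan", {
  set.seed(6)
  ct <- chrom_table(c("S", "L", "D"), c(4e7, 1e8, 6e7))
  cand <- data.frame(chrom_a = "S", chrom_b = "L", stringsAsFactors = FALSE)
  for (ends in list(c("begin", "begin"), c("begin", "end"),
                    c("end", "begin"), c("end", "end"))) {
    cand$end_a <- ends[1]; cand$end_b <- ends[2]
    for (mode in c("junction_forward", "paper_literal")) {
      plan <- build_plan(cand, ct, orientation_mode = mode)
      map <- marker_map(paste0("m", 1:600),
                        sample(c("S", "L", "D"), 600, replace = TRUE), 0)
      map$pos_bp <- as.integer(ceiling(runif(600) *
        ct$length_bp[match(map$chrom, ct$chrom)]))
      lifted <- liftover_map(map, plan)
      expect_false(any(duplicated(paste(lifted$chrom, lifted$pos_bp))) &&
                     !any(duplicated(paste(map$chrom, map$pos_bp))))
      back <- liftover_map(lifted, invert_plan(plan))
      expect_identical(back$pos_bp, map$pos_bp)
      expect_identical(back$chrom, map$chrom)
      # markers on the decoy pass through unchanged
      expect_identical(lifted$pos_bp[map$chrom == "D"],
                       map$pos_bp[map$chrom == "D"])
    }
  }
})

test_that("marker adjacency is preserved along each arm", {
  ct <- chrom_table(c("S", "L"), c(4e7, 1e8))
  cand <- data.frame(chrom_a = "S", chrom_b = "L",
                     end_a = "begin", end_b = "begin",
                     stringsAsFactors = FALSE)
  plan <- build_plan(cand, ct)
  map <- marker_map(paste0("m", 1:50), "S",
                    sort(sample.int(4e7, 50)))
  lifted <- liftover_map(map, plan)
  expect_true(all(diff(lifted$pos_bp) < 0))  # reversed, order preserved
  expect_equal(abs(diff(lifted$pos_bp)), abs(diff(map$pos_bp)))
})

test_that("coordinate overflow names the offending marker", {
  ct <- chrom_table(c("S", "L"), c(4e7, 1e8))
  cand <- data.frame(chrom_a = "S", chrom_b = "L",
                     end_a = "begin", end_b = "begin",
                     stringsAsFactors = FALSE)
  plan <- build_plan(cand, ct)
  map <- marker_map("overflow", "S", 4e7 + 1)
  expect_error(liftover_map(map, plan), "overflow")
})
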