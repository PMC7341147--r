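# Imputation-accuracy evaluation: equidistant marker-masking scenarios,
# reference/target sample splits (disjoint k-fold or repeated random),
# a deterministic haplotype-matching baseline imputer, the r2a / PERC
# accuracy metrics, and the ANOVA + Tukey group comparison used to contrast
# map variants in the centromeric region.

#' Equidistant marker-masking scenarios
#'
#' For each retained fraction f, keeps every k-th marker in map order with
#' k = round(1 / f), starting at a seeded random offset in [0, k); all other
#' markers are masked (to be imputed). Deterministic given the seed.
#'
#' @param map a [marker_map()] (masking follows its (chrom, pos) order).
#' @param fractions retained fractions in (0, 1].
#' @param seed integer seed.
#' @return a list of scenarios, each
#'   `list(retained_fraction, retained_marker_ids, masked_marker_ids, seed)`.
#' @export
make_mask_scenarios <- function(map, fractions = c(0.10, 0.15, 0.20, 0.25, 0.30),
                                seed = 1L) {
  if (nrow(map) < 10L) stop("at least 10 markers required")
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  ids <- sort_marker_map(map)$marker_id
  m <- length(ids)
  set.seed(seed)
  lapply(fractions, function(f) {
    k <- max(1L, as.integer(round(1 / f)))
    offset <- sample.int(k, 1L) - 1L
    retained <- ids[seq(1L + offset, m, by = k)]
    list(retained_fraction = f,
         retained_marker_ids = retained,
         masked_marker_ids = setdiff(ids, retained),
         seed = seed)
  })
}

#' Reference/target sample splits
#'
#' `mode = "disjoint"` (default) shuffles the samples once and partitions
#' them into `n_folds` disjoint test (imputation target) sets of near-equal
#' size, each fold's reference being the complement — with 349 samples and
#' 4 folds the test sizes are 88/87/87/87 and the references 261/262/262/262.
#' `mode = "random"` draws `n_folds` independent reference/target splits of
#' ratio `ref_fraction` instead.
#'
#' @param samples character vector of sample ids.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @param mode `"disjoint"` or `"random"`.
#' @param ref_fraction reference fraction for `mode = "random"` (default
#'   262/349).
#' @return a list of folds, each `list(fold, reference, target)`.
#' @export
split_folds <- function(samples, n_folds = 4L, seed = 1L,
                        mode = c("disjoint", "random"),
                        ref_fraction = 262 / 349) {
  mode <- match.arg(mode)
  n <- length(samples)
  if (n < n_folds) stop("need at least n_folds samples")
  set.seed(seed)
  if (mode == "disjoint") {
    shuffled <- sample(samples)
    sizes <- rep(n %/% n_folds, n_folds)
    extra <- n %% n_folds
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    stops <- cumsum(sizes)
    starts <- c(1L, head(stops, -1L) + 1L)
    lapply(seq_len(n_folds), function(k) {
      test <- shuffled[starts[k]:stops[k]]
      list(fold = k, reference = setdiff(samples, test), target = test)
    })
  } else {
    lapply(seq_len(n_folds), function(k) {
      ref <- sample(samples, round(ref_fraction * n))
      list(fold = k, reference = ref, target = setdiff(samples, ref))
    })
  }
}

#' Mask markers in a genotype matrix
#'
#' @param g genotype matrix.
#' @param masked_marker_ids columns to set to NA.
#' @return the masked matrix.
#' @export
mask_genotypes <- function(g, masked_marker_ids) {
  idx <- match(masked_marker_ids, colnames(g))
  if (anyNA(idx)) stop("unknown marker in mask")
  g[, idx] <- NA_integer_
  g
}

#' Baseline haplotype-matching imputer
#'
#' A deterministic nearest-haplotype engine provided so the evaluation
#' pipeline runs end-to-end without external phasing/imputation software
#' (which it does not reimplement). Each masked genotype is imputed by
#' summing the alleles of the two reference haplotypes whose flanking
#' window (the `near_k` nearest retained markers on each side, in map
#' order within the chromosome) best matches the target sample's observed
#' genotypes: the distance between haplotype h and genotype g over the
#' window is sum |h - g / 2| for the first haplotype and the diplotype
#' residual sum |h - (g - h1)| for the second, ties broken by reference
#' window-haplotype frequency and then row index.
#'
#' @param reference phased reference haplotype matrix (2N x markers,
#'   complete at all markers, columns named by marker id).
#' @param target genotype matrix with NA at the masked markers.
#' @param map the matching [marker_map()] (all markers).
#' @param near_k retained flanking markers per side.
#' @param markers optional marker ids: impute only these masked columns
#'   (others keep their NAs); useful when only a region is scored.
#' @return the target matrix with masked cells imputed.
#' @export
baseline_impute <- function(reference, target, map, near_k = 10L,
                            markers = NULL) {
  if (is.null(reference) || nrow(reference) == 0L)
    stop("empty reference")
  validate_haplotypes(reference, map)
  masked <- which(colSums(is.na(target)) > 0L)
  if (!is.null(markers))
    masked <- intersect(masked, match(markers, colnames(target)))
  if (!length(masked)) return(target)
  retained <- which(colSums(is.na(target)) == 0L)
  map_ord <- order(map$chrom, map$pos_bp, method = "radix")
  rank_of <- integer(nrow(map)); rank_of[map_ord] <- seq_along(map_ord)
  for (mcol in masked) {
    chr <- map$chrom[mcol]
    ret_chr <- retained[map$chrom[retained] == chr]
    if (!length(ret_chr)) {
      # no informative flank on this chromosome: reference mean dosage
      fill <- as.integer(round(mean(reference[, mcol]) * 2))
      target[is.na(target[, mcol]), mcol] <- fill
      next
    }
    d <- abs(map$pos_bp[ret_chr] - map$pos_bp[mcol])
    side <- sign(rank_of[ret_chr] - rank_of[mcol])
    left <- ret_chr[side < 0][order(d[side < 0])]
    right <- ret_chr[side > 0][order(d[side > 0])]
    win <- c(rev(head(left, near_k)), head(right, near_k))
    H <- reference[, win, drop = FALSE]
    wstr <- do.call(paste0, as.data.frame(H))
    freq <- tabulate(match(wstr, unique(wstr)))[match(wstr, unique(wstr))]
    ord <- order(-freq, seq_len(nrow(H)))
    Ho <- H[ord, , drop = FALSE]
    need <- which(is.na(target[, mcol]))
    G <- t(target[need, win, drop = FALSE])          # window x samples
    X <- G / 2
    # D[h, s] = sum_m |Ho[h, m] - G[m, s] / 2|, with Ho binary
    D <- rowSums(Ho) + matrix(colSums(X), nrow(Ho), ncol(X), byrow = TRUE) -
      2 * (Ho %*% X)
    a1 <- apply(D, 2, which.min)
    # second haplotype by the diplotype residual: minimize
    # sum_m |h_m - (g_m - h1_m)| given the first pick
    R <- G - t(Ho[a1, , drop = FALSE])               # window x samples
    D2 <- Ho %*% (abs(1 - R) - abs(R)) +
      matrix(colSums(abs(R)), nrow(Ho), ncol(R), byrow = TRUE)
    a2 <- apply(D2, 2, which.min)
    allele <- reference[, mcol][ord]
    target[need, mcol] <- allele[a1] + allele[a2]
  }
  target
}

#' Imputation accuracy: allelic correlation and per-allele concordance
#'
#' `r2a` is the squared Pearson correlation between true and imputed allele
#' counts over all (sample, marker) cells of the subset (or the mean of
#' per-marker values with `per_marker = TRUE`); `perc` is the proportion of
#' correctly imputed alleles, a heterozygote-homozygote discrepancy
#' counting one of two alleles correct. A zero-variance subset leaves
#' `r2a` undefined (NA), not 0.
#'
#' @param true_g,imputed_g genotype matrices of identical dimensions.
#' @param marker_ids columns to score (default all).
#' @param per_marker average per-marker r2a instead of pooling cells.
#' @return `list(r2a, perc, n_markers, n_cells)`.
#' @export
accuracy_metrics <- function(true_g, imputed_g, marker_ids = NULL,
                             per_marker = FALSE) {
  if (!all(dim(true_g) == dim(imputed_g)))
    stop("dimension mismatch between true and imputed matrices")
  if (!is.null(marker_ids)) {
    idx <- match(marker_ids, colnames(true_g))
    if (anyNA(idx)) stop("unknown marker in subset")
    if (!length(idx)) stop("empty marker subset")
    true_g <- true_g[, idx, drop = FALSE]
    imputed_g <- imputed_g[, idx, drop = FALSE]
  }
  tv <- as.numeric(true_g); iv <- as.numeric(imputed_g)
  ok <- !is.na(tv) & !is.na(iv)
  tv <- tv[ok]; iv <- iv[ok]
  perc <- mean(2 - abs(tv - iv)) / 2
  r2a <- if (per_marker) {
    vals <- vapply(seq_len(ncol(true_g)), function(j) {
      x <- true_g[, j]; y <- imputed_g[, j]
      if (stats::sd(x, na.rm = TRUE) == 0 || stats::sd(y, na.rm = TRUE) == 0)
        return(NA_real_)
      suppressWarnings(cor(x, y, use = "complete.obs"))^2
    }, numeric(1))
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  } else {
    if (stats::sd(tv) == 0 || stats::sd(iv) == 0) NA_real_
    else cor(tv, iv)^2
  }
  list(r2a = r2a, perc = perc, n_markers = ncol(true_g),
       n_cells = length(tv))
}

#' Run the full imputation-accuracy design
#'
#' For every masking scenario, fold and map variant: masks the target
#' samples' genotypes, imputes them with [baseline_impute()] using the fold
#' reference haplotypes ordered by that variant's map, and scores r2a and
#' PERC over the masked cells, for the whole marker set and for each
#' marker subset in `regions`.
#'
#' @param g complete genotype matrix (samples x markers).
#' @param haps phased haplotype matrix (2 rows per sample, same order).
#' @param maps named list of [marker_map()] variants (e.g. `arranged`,
#'   `non_arranged`); all must cover the same markers.
#' @param fractions retained fractions of the masking scenarios.
#' @param n_folds number of cross-validation folds.
#' @param seed integer seed (drives scenario offsets and fold split).
#' @param regions named list of marker-id subsets scored in addition to
#'   `whole` (e.g. `centromere` = ids within 1 Mb of the junction).
#' @param near_k imputer flanking-window size.
#' @param fold_mode passed to [split_folds()].
#' @param regions_only impute and score only the markers of `regions`
#'   (skipping the whole-set rows), which is much faster when only a
#'   region contrast is needed.
#' @return a tidy `data.frame`: `scenario`, `fold`, `region`,
#'   `map_variant`, `metric` (`r2a`/`perc`), `value`, `n_markers`.
#' @export
evaluate_imputation <- function(g, haps, maps, fractions = c(0.10, 0.15, 0.20, 0.25, 0.30),
                                n_folds = 4L, seed = 1L,
                                regions = list(), near_k = 10L,
                                fold_mode = "disjoint", regions_only = FALSE) {
  if (regions_only && !length(regions))
    stop("regions_only requires non-empty 'regions'")
  stopifnot(is.list(maps), length(names(maps)) == length(maps))
  samples <- rownames(g)
  if (is.null(samples)) samples <- rownames(g) <- paste0("s", seq_len(nrow(g)))
  scenarios <- make_mask_scenarios(maps[[1]], fractions, seed = seed)
  folds <- split_folds(samples, n_folds = n_folds, seed = seed + 1L,
                       mode = fold_mode)
  hap_rows <- function(ids) {
    i <- match(ids, samples)
    as.vector(rbind(2L * i - 1L, 2L * i))
  }
  out <- list()
  for (sc in scenarios) {
    for (fd in folds) {
      tgt <- g[fd$target, , drop = FALSE]
      masked_tgt <- mask_genotypes(tgt, sc$masked_marker_ids)
      ref_h <- haps[hap_rows(fd$reference), , drop = FALSE]
      for (mv in names(maps)) {
        only <- if (regions_only)
          intersect(unique(unlist(regions)), sc$masked_marker_ids)
        imp <- baseline_impute(ref_h, masked_tgt, maps[[mv]],
                               near_k = near_k, markers = only)
        regs <- c(if (!regions_only) list(whole = sc$masked_marker_ids),
                  lapply(regions, intersect, y = sc$masked_marker_ids))
        for (rg in names(regs)) {
          if (!length(regs[[rg]])) next
          acc <- accuracy_metrics(tgt, imp, marker_ids = regs[[rg]])
          out[[length(out) + 1L]] <- data.frame(
            scenario = sc$retained_fraction, fold = fd$fold, region = rg,
            map_variant = mv,
            metric = c("r2a", "perc"),
            value = c(acc$r2a, acc$perc),
            n_markers = acc$n_markers,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare map variants by one-way ANOVA and Tukey HSD
#'
#' For each (scenario, metric) — or pooled over scenarios — runs a one-way
#' ANOVA of the per-fold values across map variants and the Tukey
#' honestly-significant-difference test, assigning compact letters at the
#' given alpha (groups sharing a letter are not significantly different).
#'
#' @param results tidy results from [evaluate_imputation()].
#' @param region which region's rows to compare.
#' @param metrics metrics to test.
#' @param alpha significance level of the letter display.
#' @param pool_scenarios treat all scenarios as replicates of one
#'   comparison.
#' @return a `data.frame` with one row per comparison: `scenario`,
#'   `metric`, `f_p_value`, plus the group means and letters in the
#'   attribute `groups` (a list of data.frames) and the Tukey tables in
#'   attribute `tukey`.
#' @export
region_group_comparison <- function(results, region = "centromere",
                                    metrics = c("r2a", "perc"),
                                    alpha = 0.05, pool_scenarios = FALSE) {
  sub <- results[results$region == region & results$metric %in% metrics &
                   !is.na(results$value), , drop = FALSE]
  if (!nrow(sub)) stop("no rows for region ", region)
  sub$scenario_key <- if (pool_scenarios) "pooled" else as.character(sub$scenario)
  rows <- list(); groups <- list(); tukeys <- list()
  for (sk in unique(sub$scenario_key)) for (met in metrics) {
    d <- sub[sub$scenario_key == sk & sub$metric == met, , drop = FALSE]
    tab <- table(d$map_variant)
    small <- names(tab)[tab < 2L]
    if (length(small)) {
      warning("excluding group(s) with < 2 replicates: ",
              paste(small, collapse = ", "))
      d <- d[!(d$map_variant %in% small), , drop = FALSE]
    }
    if (length(unique(d$map_variant)) < 2L) next
    d$map_variant <- factor(d$map_variant)
    fit <- aov(value ~ map_variant, data = d)
    an <- summary(fit)[[1]]
    pval <- an[["Pr(>F)"]][1]
    if (is.na(pval)) pval <- 1  # no variation at all: no evidence of difference
    tk <- TukeyHSD(fit)$map_variant
    lv <- levels(d$map_variant)
    sig <- matrix(FALSE, length(lv), length(lv), dimnames = list(lv, lv))
    for (r in rownames(tk)) {
      pr <- strsplit(r, "-", fixed = TRUE)[[1]]
      s <- !is.na(tk[r, "p adj"]) && tk[r, "p adj"] < alpha
      sig[pr[1], pr[2]] <- sig[pr[2], pr[1]] <- s
    }
    means <- tapply(d$value, d$map_variant, mean)
    letters_df <- data.frame(map_variant = lv, mean = as.numeric(means[lv]),
                             letters = tukey_letters(sig, means[lv]),
                             stringsAsFactors = FALSE)
    keyname <- paste(sk, met, sep = ".")
    rows[[keyname]] <- data.frame(scenario = sk, metric = met,
                                  f_p_value = pval, stringsAsFactors = FALSE)
    groups[[keyname]] <- letters_df[order(-letters_df$mean), ]
    tukeys[[keyname]] <- tk
  }
  if (!length(rows)) stop("no comparison had >= 2 groups with >= 2 replicates")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "groups") <- groups
  attr(res, "tukey") <- tukeys
  res
}

# Compact letter display by insert-and-absorb: start from one set holding
# all groups; for each significantly different pair split every set that
# contains both; absorb subsets; letter sets in order of group means.
tukey_letters <- function(sig, means) {
  lv <- rownames(sig)
  sets <- list(lv)
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (j <= i || !sig[i, j]) next
    for (k in seq_along(sets)) {
      s <- sets[[k]]
      if (all(c(lv[i], lv[j]) %in% s)) {
        sets[[k]] <- setdiff(s, lv[i])
        sets[[length(sets) + 1L]] <- setdiff(s, lv[j])
      }
    }
    # absorb duplicated / contained sets
    sets <- sets[!vapply(seq_along(sets), function(a)
      any(vapply(seq_along(sets), function(b)
        a != b && all(sets[[a]] %in% sets[[b]]) &&
          (length(sets[[a]]) < length(sets[[b]]) || a > b),
        logical(1))), logical(1))]
  }
  ord <- order(-unlist(means))
  first <- vapply(sets, function(s) min(match(s, lv[ord])), numeric(1))
  sets <- sets[order(first)]
  out <- vapply(lv, function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
          collapse = "")
  }, "")
  out
}
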