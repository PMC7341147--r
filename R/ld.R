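# Pairwise linkage disequilibrium (r2) between SNP markers.
# r2 = D^2 / (pA qA pB qB) with haplotype frequencies estimated from
# unphased genotypes either by maximum likelihood (EM; the compiled
# engine in src/) or by the composite genotype-correlation estimator.
# Evaluation is chunked so memory grows with the retained output, not
# with markers^2 x samples.

#' Pairwise r2 between markers
#'
#' @param g genotype matrix (samples x markers, allele-B counts, NA missing);
#'   normally quality-controlled first with [apply_qc()].
#' @param map the matching [marker_map()].
#' @param scope which pairs to evaluate: `"all"`, `"intra"` (same chromosome)
#'   or `"inter"` (different chromosomes).
#' @param r2_min optional threshold: only pairs with r2 strictly greater are
#'   returned (a pair at exactly `r2_min` is excluded).
#' @param estimator `"em"` (maximum-likelihood haplotype frequencies via EM,
#'   the default) or `"composite"` (squared Pearson correlation of genotype
#'   counts). If EM fails to converge within `max_iter` iterations at
#'   tolerance `tol` for a pair, the composite value is substituted for that
#'   pair and counted in the diagnostics.
#' @param max_iter,tol EM control.
#' @param chunk_size marker-block size of the chunked evaluation.
#' @return A `data.frame` of class `ld_pair_table` with one row per retained
#'   unordered pair: `marker_i`, `marker_j`, `chrom_i`, `pos_i`, `chrom_j`,
#'   `pos_j`, `r2`, `dist_bp` (NA for inter-chromosomal pairs), `same_chrom`.
#'   Attributes `n_evaluated`, `n_skipped_monomorphic`, `n_em_fallback` and
#'   `estimator` carry diagnostics; markers monomorphic in a pair's
#'   complete-case subset make that pair skip into the tally.
#' @export
pairwise_r2 <- function(g, map, scope = c("all", "intra", "inter"),
                        r2_min = NULL, estimator = c("em", "composite"),
                        max_iter = 100L, tol = 1e-8, chunk_size = 512L) {
  scope <- match.arg(scope)
  estimator <- match.arg(estimator)
  validate_genotypes(g, map)
  m <- ncol(g)
  if (m < 2L) stop("at least 2 markers required")
  storage.mode(g) <- "integer"
  chrom <- map$chrom
  pos <- as.numeric(map$pos_bp)
  starts <- seq(1L, m, by = chunk_size)
  blocks <- lapply(starts, function(s) s:min(s + chunk_size - 1L, m))
  out <- vector("list", length(blocks) * (length(blocks) + 1L) / 2L)
  oi <- 0L
  n_mono <- 0L; n_eval <- 0L; n_fallback <- 0L
  for (bi in seq_along(blocks)) {
    A <- blocks[[bi]]
    ga <- g[, A, drop = FALSE]
    for (bj in bi:length(blocks)) {
      B <- blocks[[bj]]
      same <- bj == bi
      same_chrom <- outer(chrom[A], chrom[B], "==")
      in_scope <- switch(scope, all = TRUE, intra = same_chrom,
                         inter = !same_chrom)
      if (!any(in_scope)) next
      if (estimator == "em") {
        res <- em_r2_block(ga, g[, B, drop = FALSE], same, max_iter, tol)
        r2 <- res$r2
        # non-converged pairs already carry the composite fallback value
        n_fallback <- n_fallback +
          sum(!res$converged & res$status == 0L &
                (if (same) row(r2) < col(r2) else TRUE) & in_scope)
        status <- res$status
      } else {
        r2 <- composite_r2_block(ga, g[, B, drop = FALSE])
        status <- matrix(0L, length(A), length(B))
        status[is.na(r2)] <- 1L
      }
      pair_ok <- if (same) row(r2) < col(r2) else matrix(TRUE, length(A), length(B))
      considered <- pair_ok & (in_scope | FALSE)
      n_eval <- n_eval + sum(considered)
      n_mono <- n_mono + sum(considered & status != 0L)
      keep <- considered & !is.na(r2)
      if (!is.null(r2_min)) keep <- keep & r2 > r2_min
      idx <- which(keep)
      if (!length(idx)) next
      ii <- A[(idx - 1L) %% length(A) + 1L]
      jj <- B[(idx - 1L) %/% length(A) + 1L]
      oi <- oi + 1L
      out[[oi]] <- data.frame(i = ii, j = jj, r2 = r2[idx])
    }
  }
  tab <- if (oi) do.call(rbind, out[seq_len(oi)])
         else data.frame(i = integer(), j = integer(), r2 = numeric())
  res <- data.frame(
    marker_i = map$marker_id[tab$i],
    marker_j = map$marker_id[tab$j],
    chrom_i = chrom[tab$i],
    pos_i = map$pos_bp[tab$i],
    chrom_j = chrom[tab$j],
    pos_j = map$pos_bp[tab$j],
    r2 = tab$r2,
    stringsAsFactors = FALSE
  )
  res$same_chrom <- res$chrom_i == res$chrom_j
  res$dist_bp <- ifelse(res$same_chrom, abs(res$pos_j - res$pos_i), NA_real_)
  attr(res, "n_evaluated") <- n_eval
  attr(res, "n_skipped_monomorphic") <- n_mono
  attr(res, "n_em_fallback") <- n_fallback
  attr(res, "estimator") <- estimator
  attr(res, "n_samples") <- nrow(g)
  class(res) <- c("ld_pair_table", "data.frame")
  res
}

# Composite (genotype-correlation) r2 between two blocks, pairwise-complete.
composite_r2_block <- function(ga, gb) {
  suppressWarnings(stats::cor(ga, gb, use = "pairwise.complete.obs"))^2
}

#' @export
print.ld_pair_table <- function(x, ...) {
  cat("LD pair table:", nrow(x), "pairs (",
      sum(x$same_chrom), "intra-,", sum(!x$same_chrom),
      "inter-chromosomal )\n")
  cat("  estimator:", attr(x, "estimator"),
      "| evaluated:", attr(x, "n_evaluated"),
      "| skipped monomorphic:", attr(x, "n_skipped_monomorphic"),
      "| EM fallbacks:", attr(x, "n_em_fallback"), "\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}
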