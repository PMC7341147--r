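# Concordance between two marker maps (e.g. a rearranged map vs an
# independent assembly): per-chromosome Spearman correlation, ordinary
# least squares of position-on-position, orientation sign and studentized-
# residual outliers.

#' Compare two marker maps chromosome by chromosome
#'
#' Markers are paired by id; for every chromosome of `map_a` with at least
#' `min_shared` shared markers, computes the Spearman rank correlation and
#' the OLS regression of `map_b` positions on `map_a` positions (slope,
#' intercept, R-squared), the orientation sign (sign of the slope; -1 marks
#' a reversed chromosome) and the markers with absolute studentized
#' residual > 3 (candidate discordant placements).
#'
#' @param map_a,map_b [marker_map()] objects sharing marker ids.
#' @param min_shared chromosomes with fewer shared markers are skipped with
#'   a warning.
#' @return a `data.frame` of class `map_comparison` with one row per
#'   compared chromosome: `chrom`, `n_markers`, `spearman_rho`, `ols_slope`,
#'   `ols_intercept_bp`, `r_squared`, `orientation_sign`; attribute
#'   `outliers` holds the per-chromosome outlier marker ids.
#' @export
compare_maps <- function(map_a, map_b, min_shared = 3L) {
  shared <- intersect(map_a$marker_id, map_b$marker_id)
  a <- map_a[match(shared, map_a$marker_id), , drop = FALSE]
  b <- map_b[match(shared, map_b$marker_id), , drop = FALSE]
  rows <- list(); outliers <- list()
  for (chr in unique(a$chrom)) {
    sel <- a$chrom == chr
    if (sum(sel) < min_shared) {
      warning("chromosome ", chr, " skipped: fewer than ", min_shared,
              " shared markers")
      next
    }
    x <- as.numeric(a$pos_bp[sel]); y <- as.numeric(b$pos_bp[sel])
    ids <- a$marker_id[sel]
    rx <- rank(x); ry <- rank(y)
    rxc <- rx - mean(rx); ryc <- ry - mean(ry)
    den <- sqrt(sum(rxc^2)) * sqrt(sum(ryc^2))
    rho <- if (den > 0) sum(rxc * ryc) / den else NA_real_
    if (identical(rx, ry)) rho <- 1  # exact on identical orderings
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    slope <- sxy / sxx
    intercept <- mean(y) - slope * mean(x)
    syy <- sum((y - mean(y))^2)
    r2 <- if (syy > 0) sxy^2 / (sxx * syy) else NA_real_
    # studentized (externally) residuals of the simple regression
    n <- length(x)
    e <- y - intercept - slope * x
    out_ids <- character(0)
    rss <- sum(e^2)
    if (n >= 4L && rss > 0) {
      h <- 1 / n + (x - mean(x))^2 / sxx
      s2i <- (rss - e^2 / (1 - h)) / (n - 3)
      tstud <- e / sqrt(pmax(s2i * (1 - h), .Machine$double.xmin))
      out_ids <- ids[abs(tstud) > 3]
    }
    outliers[[chr]] <- out_ids
    rows[[chr]] <- data.frame(
      chrom = chr, n_markers = sum(sel), spearman_rho = rho,
      ols_slope = slope, ols_intercept_bp = intercept, r_squared = r2,
      orientation_sign = sign(slope), n_outliers = length(out_ids),
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop("no chromosome with enough shared markers")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "outliers") <- outliers
  class(res) <- c("map_comparison", "data.frame")
  res
}
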