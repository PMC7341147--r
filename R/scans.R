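# Windowed scans along chromosomes: decay-adjusted LD profiles, haplotype
# diversity, centromere characterization at a fusion junction, and the
# fusion-chronology heuristic.

# Sliding windows [start, end) on 0-based coordinates; a 1-based marker
# position p belongs to a window when start < p <= end. Consecutive windows
# differ by exactly step_bp, so every interior marker belongs to
# window_bp / step_bp windows.
sliding_windows <- function(length_bp, window_bp, step_bp) {
  starts <- seq(0, max(0, length_bp - 1), by = step_bp)
  data.frame(start = starts, end = starts + window_bp)
}

#' Decay-adjusted windowed LD scan
#'
#' Slides a window along each chromosome and, per window, fits the
#' Hill-Weir decay model to the pairs with both markers inside the window.
#' The window statistic is the fitted expectation evaluated at the
#' reference distance `d_ref` — one comparable number per window regardless
#' of the window's marker spacing — reported alongside the raw mean r2.
#'
#' @param pairs intra-chromosomal [pairwise_r2()] table (un-truncated).
#' @param map the matching [marker_map()].
#' @param n sample size used in the Hill-Weir expectation.
#' @param window_bp,step_bp window size and slide step (default 4 Mb / 1 Mb).
#' @param d_ref reference distance (bp) at which the fitted curve is
#'   evaluated.
#' @param min_pairs windows with fewer pairs are emitted as undefined.
#' @param chrom_lengths optional [chrom_table()]; defaults to max position.
#' @return a `data.frame` of class `ld_window_scan`: `chrom`, `start`,
#'   `end`, `stat_value` (fitted E(r2) at `d_ref`), `mean_r2`, `beta`,
#'   `n_items` (pairs), `defined`.
#' @export
window_ld_scan <- function(pairs, map, n, window_bp = 4e6, step_bp = 1e6,
                           d_ref = 1e5, min_pairs = 10L,
                           chrom_lengths = NULL) {
  out <- list()
  lens <- if (!is.null(chrom_lengths))
    setNames(chrom_lengths$length_bp, chrom_lengths$chrom)
  else tapply(map$pos_bp, map$chrom, max)
  for (chr in unique(map$chrom)) {
    pp <- pairs[pairs$same_chrom & pairs$chrom_i == chr, , drop = FALSE]
    win <- sliding_windows(as.numeric(lens[[chr]]), window_bp, step_bp)
    lo <- pmin(pp$pos_i, pp$pos_j); hi <- pmax(pp$pos_i, pp$pos_j)
    res <- lapply(seq_len(nrow(win)), function(w) {
      sel <- lo > win$start[w] & hi <= win$end[w]
      np <- sum(sel)
      if (np < min_pairs)
        return(data.frame(chrom = chr, start = win$start[w], end = win$end[w],
                          stat_value = NA_real_, mean_r2 = NA_real_,
                          beta = NA_real_, n_items = np, defined = FALSE))
      fit <- tryCatch(
        fit_ld_decay(pp[sel, , drop = FALSE], n, min_pairs = min_pairs),
        error = function(e) NULL)
      if (is.null(fit) || !fit$defined)
        return(data.frame(chrom = chr, start = win$start[w], end = win$end[w],
                          stat_value = NA_real_, mean_r2 = mean(pp$r2[sel]),
                          beta = NA_real_, n_items = np, defined = FALSE))
      data.frame(chrom = chr, start = win$start[w], end = win$end[w],
                 stat_value = expected_r2_hill_weir(fit$beta * d_ref, n),
                 mean_r2 = mean(pp$r2[sel]), beta = fit$beta,
                 n_items = np, defined = TRUE)
    })
    out[[chr]] <- do.call(rbind, res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "window_bp") <- window_bp
  attr(res, "step_bp") <- step_bp
  attr(res, "d_ref") <- d_ref
  attr(res, "stat") <- "adjusted_r2"
  class(res) <- c("ld_window_scan", "data.frame")
  res
}

#' Windowed haplotype diversity
#'
#' Per window, the complete haplotype alleles over the window's markers
#' define haplotype classes with frequencies p_i; the diversity is the
#' unbiased estimator H = (M / (M - 1)) (1 - sum p_i^2), where M is the
#' number of haplotype observations (2N for N diploids; `correction =
#' "individuals"` switches to the literal N-based factor).
#'
#' @param h phased haplotype matrix (2N x markers, entries 0/1).
#' @param map the matching [marker_map()].
#' @param window_bp,step_bp window size and slide step (default 1 Mb with
#'   0.5 Mb overlap).
#' @param correction `"haplotypes"` (M = 2N, default) or `"individuals"`
#'   (M = N).
#' @param chrom_lengths optional [chrom_table()].
#' @return a `data.frame` of class `hdiv_window_scan`: `chrom`, `start`,
#'   `end`, `stat_value` (H between 0 and 1), `n_classes`, `n_items`
#'   (haplotype observations), `n_markers`, `defined` (FALSE for windows
#'   with no markers).
#' @export
haplotype_diversity_scan <- function(h, map, window_bp = 1e6, step_bp = 5e5,
                                     correction = c("haplotypes", "individuals"),
                                     chrom_lengths = NULL) {
  correction <- match.arg(correction)
  if (!is.matrix(h) || anyNA(h))
    stop("fully phased haplotypes required; provide a phased VCF or ",
         "simulator haplotypes")
  validate_haplotypes(h, map)
  n_obs <- nrow(h)
  M <- if (correction == "haplotypes") n_obs else n_obs / 2
  out <- list()
  lens <- if (!is.null(chrom_lengths))
    setNames(chrom_lengths$length_bp, chrom_lengths$chrom)
  else tapply(map$pos_bp, map$chrom, max)
  for (chr in unique(map$chrom)) {
    cols <- which(map$chrom == chr)
    pos <- map$pos_bp[cols]
    win <- sliding_windows(as.numeric(lens[[chr]]), window_bp, step_bp)
    res <- lapply(seq_len(nrow(win)), function(w) {
      inw <- cols[pos > win$start[w] & pos <= win$end[w]]
      if (!length(inw) || M <= 1)
        return(data.frame(chrom = chr, start = win$start[w], end = win$end[w],
                          stat_value = NA_real_, n_classes = NA_integer_,
                          n_items = n_obs, n_markers = length(inw),
                          defined = FALSE))
      classes <- do.call(paste0, as.data.frame(h[, inw, drop = FALSE]))
      p <- tabulate(match(classes, unique(classes))) / n_obs
      hhat <- (M / (M - 1)) * (1 - sum(p^2))
      data.frame(chrom = chr, start = win$start[w], end = win$end[w],
                 stat_value = min(1, max(0, hhat)), n_classes = length(p),
                 n_items = n_obs, n_markers = length(inw), defined = TRUE)
    })
    out[[chr]] <- do.call(rbind, res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "window_bp") <- window_bp
  attr(res, "step_bp") <- step_bp
  attr(res, "stat") <- "haplotype_diversity"
  class(res) <- c("hdiv_window_scan", "data.frame")
  res
}

#' Characterize the centromeric LD profile around a fusion junction
#'
#' @param scan a single-chromosome slice of a [window_ld_scan()] (or any
#'   window table with `start`, `end`, `stat_value`, `defined`).
#' @param junction_bp junction (centromere) position.
#' @param peak_radius_bp windows whose center is within this of the
#'   junction compete for the peak.
#' @param baseline_min_dist_bp windows whose center is farther than this
#'   from the junction form the baseline.
#' @param min_baseline minimum number of defined baseline windows.
#' @return a list of class `centromere_profile`: `chrom`, `junction_bp`,
#'   `peak_value`, `baseline_value` (median of far windows), `extent_bp`
#'   (width of the contiguous region around the peak with stat >= baseline
#'   + 0.5 (peak - baseline)).
#' @export
centromere_profile <- function(scan, junction_bp, peak_radius_bp = 2e6,
                               baseline_min_dist_bp = 1e7,
                               min_baseline = 5L) {
  if (length(unique(scan$chrom)) != 1L)
    stop("pass a single chromosome's windows")
  scan <- scan[order(scan$start), , drop = FALSE]
  center <- (scan$start + scan$end) / 2
  defined <- scan$defined & !is.na(scan$stat_value)
  near <- defined & abs(center - junction_bp) <= peak_radius_bp
  far <- defined & abs(center - junction_bp) > baseline_min_dist_bp
  if (!any(near))
    stop("no defined window within ", peak_radius_bp, " bp of the junction")
  if (sum(far) < min_baseline)
    stop("fewer than ", min_baseline, " defined baseline windows")
  peak_idx <- which(near)[which.max(scan$stat_value[near])]
  peak <- scan$stat_value[peak_idx]
  baseline <- median(scan$stat_value[far])
  thr <- baseline + 0.5 * (peak - baseline)
  qual <- defined & scan$stat_value >= thr
  i0 <- peak_idx; i1 <- peak_idx
  while (i0 > 1L && qual[i0 - 1L]) i0 <- i0 - 1L
  while (i1 < nrow(scan) && qual[i1 + 1L]) i1 <- i1 + 1L
  structure(list(chrom = scan$chrom[1], junction_bp = junction_bp,
                 peak_value = peak, baseline_value = baseline,
                 extent_bp = scan$end[i1] - scan$start[i0]),
            class = "centromere_profile")
}

#' @export
print.centromere_profile <- function(x, ...) {
  cat("Centromere profile of", x$chrom, "( junction at",
      format(x$junction_bp, big.mark = ","), "bp )\n")
  cat("  peak:", format(x$peak_value, digits = 4),
      "| baseline:", format(x$baseline_value, digits = 4),
      "| extent:", format(x$extent_bp, big.mark = ","), "bp\n")
  invisible(x)
}

#' Rank fused chromosomes by apparent fusion age (heuristic)
#'
#' Orders centromere profiles on the (peak, extent) plane, the staging
#' abstracted from the qualitative model of post-fusion LD dynamics: the
#' junction LD peak first rises while still narrow, then the elevated
#' region widens as equilibration spreads outward. The default convention
#' (`older = "smaller_extent"`) ranks oldest -> newest by ascending
#' extent_bp with descending peak as tie key; `older = "larger_extent"` is
#' the reversed reading of the same staging. `older = "higher_peak"` ranks
#' by descending peak with ascending extent as tie key: in the rising
#' phase of junction LD (fusions young relative to 2 Ne, the regime
#' forward simulation reaches) the peak carries the age signal while the
#' half-maximum extent is mostly window-quantization noise, and this key
#' is the one that recovers staggered fusion times in the package's own
#' simulations. The ordering is a heuristic annotation, not an estimator
#' of time.
#'
#' @param profiles a list of [centromere_profile()] objects (>= 2).
#' @param older ranking convention (see above).
#' @return a `data.frame`, oldest first: `chrom`, `peak_value`,
#'   `extent_bp`, `rank`, `stage` (quadrant label relative to profile
#'   medians), `tie` (flagged exact ties, resolved by chromosome label).
#' @export
rank_fusion_age <- function(profiles,
                            older = c("smaller_extent", "larger_extent",
                                      "higher_peak")) {
  older <- match.arg(older)
  if (length(profiles) < 2L) stop("at least 2 profiles required")
  df <- data.frame(
    chrom = vapply(profiles, `[[`, "", "chrom"),
    peak_value = vapply(profiles, `[[`, 0, "peak_value"),
    extent_bp = vapply(profiles, `[[`, 0, "extent_bp"),
    stringsAsFactors = FALSE
  )
  ord <- switch(older,
    smaller_extent = order(df$extent_bp, -df$peak_value, df$chrom),
    larger_extent = order(-df$extent_bp, df$peak_value, df$chrom),
    higher_peak = order(-df$peak_value, df$extent_bp, df$chrom))
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df$tie <- duplicated(df[, c("peak_value", "extent_bp")]) |
    duplicated(df[, c("peak_value", "extent_bp")], fromLast = TRUE)
  hp <- df$peak_value >= median(df$peak_value)
  he <- df$extent_bp >= median(df$extent_bp)
  df$stage <- ifelse(hp & !he, "high-peak/compact",
              ifelse(hp & he, "high-peak/broad",
              ifelse(!hp & he, "low-peak/broad", "low-peak/compact")))
  rownames(df) <- NULL
  attr(df, "heuristic") <- "ordering is a qualitative LD-staging heuristic"
  df
}
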