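# Base-graphics displays for the main result objects.

#' Plot an inter-chromosomal high-LD count matrix
#'
#' @param x an [interchrom_ld_counts()] matrix.
#' @param ... passed to [graphics::image()].
#' @export
plot.interchrom_counts <- function(x, ...) {
  m <- unclass(x)
  n <- nrow(m)
  image(seq_len(n), seq_len(n), log10(t(m[n:1, , drop = FALSE]) + 1),
        axes = FALSE, xlab = "", ylab = "",
        main = "Inter-chromosomal high-LD pair counts (log10)", ...)
  axis(1, seq_len(n), colnames(m), las = 2, cex.axis = 0.8)
  axis(2, seq_len(n), rev(rownames(m)), las = 2, cex.axis = 0.8)
  invisible(x)
}

#' Plot a windowed LD or diversity scan
#'
#' One panel per chromosome; undefined windows are left blank. For LD
#' scans of a fused chromosome, a vertical line can mark the junction.
#'
#' @param x an [window_ld_scan()] or [haplotype_diversity_scan()] result.
#' @param chroms chromosomes to draw (default all in the scan).
#' @param junctions optional named vector (chromosome -> junction bp).
#' @param ... passed to [graphics::plot()].
#' @export
plot.ld_window_scan <- function(x, chroms = unique(x$chrom),
                                junctions = NULL, ...) {
  plot_window_scan(x, chroms, junctions,
                   ylab = expression(adjusted ~ r^2), ...)
}

#' @rdname plot.ld_window_scan
#' @export
plot.hdiv_window_scan <- function(x, chroms = unique(x$chrom),
                                  junctions = NULL, ...) {
  plot_window_scan(x, chroms, junctions, ylab = "haplotype diversity", ...)
}

plot_window_scan <- function(x, chroms, junctions, ylab, ...) {
  op <- par(mfrow = c(length(chroms), 1), mar = c(3.5, 4, 2, 1))
  on.exit(par(op))
  for (chr in chroms) {
    s <- x[x$chrom == chr & x$defined, , drop = FALSE]
    mid <- (s$start + s$end) / 2 / 1e6
    plot(mid, s$stat_value, type = "l", xlab = "position (Mb)", ylab = ylab,
         main = chr, ylim = c(0, max(s$stat_value, na.rm = TRUE)), ...)
    points(mid, s$stat_value, pch = 16, cex = 0.4)
    if (!is.null(junctions) && chr %in% names(junctions))
      abline(v = junctions[[chr]] / 1e6, col = "red", lty = 2)
  }
  invisible(x)
}
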