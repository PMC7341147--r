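#' End-to-end fusion inference pipeline
#'
#' Convenience wrapper chaining the standard stages: genotype QC ->
#' pairwise r2 (all pairs above the threshold) -> inter-chromosomal counts
#' -> fusion detection -> end localization -> rearrangement plan ->
#' coordinate liftover of the marker map.
#'
#' @param g genotype matrix (samples x markers).
#' @param map the matching [marker_map()] (split-reference coordinates).
#' @param chrom_table a [chrom_table()] of the input reference.
#' @param qc apply [apply_qc()] first (default TRUE).
#' @param qc_parameters a [qc_params()] list.
#' @param r2_min high-LD threshold (strict) used for counting and
#'   localization.
#' @param estimator passed to [pairwise_r2()].
#' @param min_count,k_mad passed to [detect_fusions()].
#' @param terminal_fraction passed to [localize_fusion_ends()].
#' @param orientation_mode passed to [build_plan()].
#' @return a list of class `fusion_pipeline`: `qc_report`, `pairs`,
#'   `counts`, `candidates` (with `end_a`/`end_b`/`resolved` columns
#'   added), `plan` (NULL when no candidate resolved), `lifted_map`, and
#'   the QC'd `genotypes`/`map`.
#' @export
run_fusion_pipeline <- function(g, map, chrom_table, qc = TRUE,
                                qc_parameters = qc_params(), r2_min = 0.2,
                                estimator = "em", min_count = 20L,
                                k_mad = 10, terminal_fraction = 0.25,
                                orientation_mode = "junction_forward") {
  qc_report <- NULL
  if (qc) {
    q <- apply_qc(g, map, qc_parameters)
    g <- q$genotypes; map <- q$map; qc_report <- q$report
  }
  pairs <- pairwise_r2(g, map, scope = "all", r2_min = r2_min,
                       estimator = estimator)
  counts <- interchrom_ld_counts(pairs, r2_min = r2_min)
  candidates <- detect_fusions(counts, min_count = min_count, k_mad = k_mad)
  plan <- NULL; lifted <- map
  if (nrow(candidates)) {
    ends <- lapply(seq_len(nrow(candidates)), function(i)
      localize_fusion_ends(pairs, candidates[i, ], chrom_table,
                           r2_min = r2_min,
                           terminal_fraction = terminal_fraction,
                           min_count = min(min_count, candidates$n_pairs[i])))
    candidates$end_a <- vapply(ends, `[[`, "", "end_a")
    candidates$end_b <- vapply(ends, `[[`, "", "end_b")
    candidates$resolved <- vapply(ends, `[[`, TRUE, "resolved")
    candidates$junction_breadth_bp <-
      vapply(ends, `[[`, 0, "junction_breadth_bp")
    resolved <- candidates[candidates$resolved, , drop = FALSE]
    if (nrow(resolved)) {
      plan <- build_plan(resolved, chrom_table,
                         orientation_mode = orientation_mode)
      lifted <- liftover_map(map, plan)
    }
  }
  structure(list(qc_report = qc_report, pairs = pairs, counts = counts,
                 candidates = candidates, plan = plan, lifted_map = lifted,
                 genotypes = g, map = map),
            class = "fusion_pipeline")
}

#' @export
print.fusion_pipeline <- function(x, ...) {
  cat("Fusion inference pipeline\n")
  if (!is.null(x$qc_report))
    cat("  QC: ", x$qc_report$n_retained, "/", x$qc_report$n_input,
        " markers retained\n", sep = "")
  cat("  high-LD pairs:", nrow(x$pairs), "\n")
  if (nrow(x$candidates)) {
    cat("  fusion candidates:\n")
    print(as.data.frame(x$candidates))
  } else cat("  no fusion candidate above background\n")
  if (!is.null(x$plan)) print(x$plan)
  invisible(x)
}
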