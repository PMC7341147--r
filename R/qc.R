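#' Genotype quality-control parameters
#'
#' Defaults follow common SNP-panel practice: markers are retained when
#' call rate > 0.95, minor allele frequency > 0.05 and the exact
#' Hardy-Weinberg p-value > 1e-6 (all inequalities strict).
#'
#' @param min_call_rate minimum fraction of non-missing genotypes.
#' @param min_maf minimum minor allele frequency.
#' @param hwe_p_min minimum Hardy-Weinberg exact p-value.
#' @return a list of class `qc_params`.
#' @export
qc_params <- function(min_call_rate = 0.95, min_maf = 0.05, hwe_p_min = 1e-6) {
  p <- list(min_call_rate = min_call_rate, min_maf = min_maf,
            hwe_p_min = hwe_p_min)
  if (any(unlist(p) < 0) || any(unlist(p) > 1))
    stop("QC thresholds must lie in [0, 1]")
  structure(p, class = "qc_params")
}

#' Apply marker quality control
#'
#' Retains markers passing all three filters (strict inequalities): call
#' rate, minor allele frequency and exact Hardy-Weinberg test. The report
#' counts, per filter, how many markers fail it (filters evaluated
#' independently, so counts can overlap).
#'
#' @param g genotype matrix (samples x markers).
#' @param map optional [marker_map()]; subset alongside when given.
#' @param params a [qc_params()] list.
#' @return `list(genotypes, map, keep, report)`; `keep` is the logical marker
#'   filter, `report` the per-filter removal counts.
#' @export
apply_qc <- function(g, map = NULL, params = qc_params()) {
  if (!is.matrix(g) || ncol(g) == 0L || nrow(g) == 0L)
    stop("nonempty genotype matrix required")
  n <- nrow(g)
  n_obs <- colSums(!is.na(g))
  call_rate <- n_obs / n
  p_b <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p_b, 1 - p_b)
  maf[n_obs == 0L] <- 0
  hwe_p <- hwe_pvalues(g)
  pass_cr <- call_rate > params$min_call_rate
  pass_maf <- !is.na(maf) & maf > params$min_maf
  pass_hwe <- hwe_p > params$hwe_p_min
  keep <- pass_cr & pass_maf & pass_hwe
  if (!any(keep))
    stop("empty after QC: no marker passes all filters")
  report <- list(
    n_input = ncol(g),
    n_fail_call_rate = sum(!pass_cr),
    n_fail_maf = sum(!pass_maf),
    n_fail_hwe = sum(!pass_hwe),
    n_removed = sum(!keep),
    n_retained = sum(keep),
    params = params
  )
  list(genotypes = g[, keep, drop = FALSE],
       map = if (!is.null(map)) {
         out <- map[keep, , drop = FALSE]; rownames(out) <- NULL; out
       },
       keep = keep,
       report = report)
}
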