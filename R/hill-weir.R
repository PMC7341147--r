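# Expected r2 as a function of scaled recombination distance (Hill-Weir
# drift expectation with sample-size term) and its one-dimensional
# nonlinear least-squares fit to observed pair r2 values.

#' Hill-Weir expectation of r2
#'
#' E(r2) = \[(10 + C) / ((2 + C)(11 + C))\] *
#' \[1 + ((3 + C)(12 + 12 C + C^2)) / (n (2 + C)(11 + C))\],
#' where C = 4 Ne c is the population-scaled recombination distance between
#' the two markers and n the sample size. Decreasing in C at fixed n; tends
#' to 1/n as C grows (the finite-sample floor).
#'
#' @param C non-negative scaled recombination distance(s).
#' @param n sample size (>= 2).
#' @return the expectation, in (0, 1); vectorized over `C`.
#' @examples
#' expected_r2_hill_weir(0, 100)   # 0.4619835
#' @export
expected_r2_hill_weir <- function(C, n) {
  if (any(C < 0)) stop("C must be non-negative")
  if (n < 2) stop("sample size n must be >= 2")
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the Hill-Weir decay model to intra-chromosomal pair r2
#'
#' Least-squares estimate of beta = 4 Ne c per base pair (so C = beta *
#' dist_bp) by bounded one-dimensional nonlinear least squares: a 20-point
#' multi-start grid on the log10 scale (plus the beta = 0 boundary) followed
#' by local refinement, which avoids the local minima a single start can
#' fall into.
#'
#' @param pairs an intra-chromosomal [pairwise_r2()] table (needs `r2` and
#'   `dist_bp`), or any data.frame with those columns.
#' @param n the sample size used in the expectation.
#' @param min_pairs fewer pairs than this yield an undefined fit (a signal,
#'   not an error, so window scans can emit missing values).
#' @param beta_max upper bound for beta (per bp).
#' @param grid_points number of multi-start grid points on log10 scale.
#' @return A list of class `ld_decay_fit`: `beta`, `n`, `rss`, `n_pairs`,
#'   `converged`, `defined`.
#' @export
fit_ld_decay <- function(pairs, n, min_pairs = 10L, beta_max = 1,
                         grid_points = 20L) {
  d <- as.numeric(pairs$dist_bp)
  r2 <- as.numeric(pairs$r2)
  ok <- !is.na(d) & !is.na(r2)
  d <- d[ok]; r2 <- r2[ok]
  if (length(d) < min_pairs)
    return(structure(list(beta = NA_real_, n = n, rss = NA_real_,
                          n_pairs = length(d), converged = FALSE,
                          defined = FALSE),
                     class = "ld_decay_fit"))
  if (length(unique(d)) < 2L)
    stop("ill-conditioned decay fit: all pairs at a single distance")
  rss <- function(beta) sum((r2 - expected_r2_hill_weir(beta * d, n))^2)
  lg <- seq(-12, log10(beta_max), length.out = grid_points)
  cand <- c(0, 10^lg)
  vals <- vapply(cand, rss, numeric(1))
  best <- which.min(vals)
  beta <- cand[best]
  if (best > 1L) {
    i <- best - 1L  # index into lg
    lo <- lg[max(1L, i - 1L)] - 0.5
    hi <- min(lg[min(length(lg), i + 1L)] + 0.5, log10(beta_max))
    o <- optimize(function(x) rss(10^x), c(lo, hi), tol = 1e-10)
    # polish on the natural scale around the log-scale optimum
    b0 <- 10^o$minimum
    o2 <- optimize(rss, c(b0 / 3, min(b0 * 3, beta_max)),
                   tol = max(b0 * 1e-11, 1e-300))
    if (o2$objective <= o$objective) beta <- o2$minimum else beta <- b0
    if (rss(0) < rss(beta)) beta <- 0
  }
  structure(list(beta = beta, n = n, rss = rss(beta), n_pairs = length(d),
                 converged = TRUE, defined = TRUE),
            class = "ld_decay_fit")
}

#' @export
print.ld_decay_fit <- function(x, ...) {
  if (!x$defined) {
    cat("Hill-Weir decay fit: undefined (", x$n_pairs, "pairs )\n")
  } else {
    cat("Hill-Weir decay fit: beta =", format(x$beta, digits = 6),
        "per bp ( 4*Ne*c ), n =", x$n, ", pairs =", x$n_pairs,
        ", rss =", format(x$rss, digits = 4), "\n")
  }
  invisible(x)
}
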