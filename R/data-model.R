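# Shared data model: marker maps, chromosome tables, genotype and haplotype
# matrices. Genotypes are integer matrices (samples x markers) holding the
# allele-B count 0/1/2 with NA for missing; haplotypes are integer matrices
# (2 * individuals x markers) over {0, 1}, two consecutive rows per individual.

#' Construct a marker map
#'
#' A marker map is an ordered table of SNP markers with chromosome label,
#' 1-based base-pair position and the two allele codes. It is the object the
#' chromosome rearrangement rewrites.
#'
#' @param marker_id character vector of unique marker identifiers.
#' @param chrom character vector of chromosome labels.
#' @param pos_bp integer vector of 1-based base-pair positions. Positions of 0
#'   can arise at arm boundaries of lifted-over maps and are tolerated.
#' @param allele_a,allele_b single-character allele codes, `"0"` for unknown.
#'   Convention: `allele_b` is the counted allele of the genotype coding.
#'
#' @return A `data.frame` of class `marker_map` with columns `marker_id`,
#'   `chrom`, `pos_bp`, `allele_a`, `allele_b`.
#' @export
marker_map <- function(marker_id, chrom, pos_bp,
                       allele_a = "0", allele_b = "0") {
  map <- data.frame(
    marker_id = as.character(marker_id),
    chrom = as.character(chrom),
    pos_bp = as.integer(round(pos_bp)),
    allele_a = rep_len(as.character(allele_a), length(marker_id)),
    allele_b = rep_len(as.character(allele_b), length(marker_id)),
    stringsAsFactors = FALSE
  )
  class(map) <- c("marker_map", "data.frame")
  validate_marker_map(map)
  map
}

#' Validate a marker map
#'
#' @param map a [marker_map()].
#' @param chrom_table optional [chrom_table()]; when given, every chromosome
#'   label of `map` must be present and no position may exceed its length.
#' @return `map`, invisibly; errors describe the first violated invariant.
#' @export
validate_marker_map <- function(map, chrom_table = NULL) {
  stopifnot(is.data.frame(map))
  need <- c("marker_id", "chrom", "pos_bp")
  if (!all(need %in% names(map)))
    stop("marker map must have columns marker_id, chrom, pos_bp")
  if (anyDuplicated(map$marker_id))
    stop("duplicate marker ids: ",
         paste(head(unique(map$marker_id[duplicated(map$marker_id)]), 3),
               collapse = ", "))
  if (any(is.na(map$pos_bp)) || any(map$pos_bp < 0))
    stop("marker positions must be non-negative integers")
  if (!is.null(chrom_table)) {
    missing_chr <- setdiff(unique(map$chrom), chrom_table$chrom)
    if (length(missing_chr))
      stop("chromosomes absent from chromosome table: ",
           paste(missing_chr, collapse = ", "))
    len <- chrom_table$length_bp[match(map$chrom, chrom_table$chrom)]
    bad <- map$pos_bp > len
    if (any(bad))
      stop("marker position exceeds chromosome length: ",
           paste(head(map$marker_id[bad], 3), collapse = ", "))
  }
  invisible(map)
}

#' Construct a chromosome-length table
#'
#' @param chrom character chromosome labels.
#' @param length_bp integer chromosome lengths in base pairs.
#' @return A `data.frame` of class `chrom_table`.
#' @export
chrom_table <- function(chrom, length_bp) {
  stopifnot(length(chrom) == length(length_bp), !anyDuplicated(chrom))
  ct <- data.frame(chrom = as.character(chrom),
                   length_bp = as.numeric(length_bp),
                   stringsAsFactors = FALSE)
  if (any(ct$length_bp < 1)) stop("chromosome lengths must be >= 1 bp")
  class(ct) <- c("chrom_table", "data.frame")
  ct
}

#' Sort a marker map by (chrom, pos_bp)
#'
#' @param map a [marker_map()].
#' @return the map with rows reordered; chromosome labels in natural order.
#' @export
sort_marker_map <- function(map) {
  ord <- order(map$chrom, map$pos_bp, map$marker_id, method = "radix")
  out <- map[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Internal: check a genotype matrix against its map.
validate_genotypes <- function(g, map = NULL) {
  stopifnot(is.matrix(g))
  vals <- g[!is.na(g)]
  if (length(vals) && (any(vals < 0) || any(vals > 2)))
    stop("genotypes must be allele-B counts in {0, 1, 2} or NA")
  if (!is.null(map)) {
    if (ncol(g) != nrow(map))
      stop("genotype matrix has ", ncol(g), " markers but map has ", nrow(map))
    if (!is.null(colnames(g)) && !identical(colnames(g), map$marker_id))
      stop("genotype column names disagree with map marker ids")
  }
  invisible(g)
}

# Internal: check a phased haplotype matrix (2N x M, entries 0/1, no NA).
validate_haplotypes <- function(h, map = NULL) {
  stopifnot(is.matrix(h))
  if (nrow(h) %% 2L != 0L)
    stop("haplotype matrix must have two rows per individual")
  if (anyNA(h) || !all(h %in% c(0L, 1L)))
    stop("haplotypes must be fully phased binary (0/1) sequences")
  if (!is.null(map) && ncol(h) != nrow(map))
    stop("haplotype matrix and map disagree on marker count")
  invisible(h)
}

#' Collapse a phased haplotype matrix to genotypes
#'
#' @param h haplotype matrix (2 consecutive rows per individual).
#' @param sample_ids optional row names of the result.
#' @return integer genotype matrix (individuals x markers, allele-B counts).
#' @export
haplotypes_to_genotypes <- function(h, sample_ids = NULL) {
  n <- nrow(h) / 2L
  g <- h[seq(1L, by = 2L, length.out = n), , drop = FALSE] +
    h[seq(2L, by = 2L, length.out = n), , drop = FALSE]
  storage.mode(g) <- "integer"
  if (!is.null(sample_ids)) rownames(g) <- sample_ids
  g
}

#' Flip the allele coding of markers
#'
#' Swaps the `allele_a`/`allele_b` labels and replaces genotype counts g by
#' 2 - g for the selected markers. LD statistics are invariant under this
#' relabeling (the coding is strand-agnostic).
#'
#' @param g genotype matrix (samples x markers).
#' @param map the matching [marker_map()].
#' @param markers marker ids (or column indices) to flip; default all.
#' @return `list(genotypes, map)` with the flip applied.
#' @export
flip_alleles <- function(g, map, markers = map$marker_id) {
  idx <- if (is.numeric(markers)) as.integer(markers)
         else match(markers, map$marker_id)
  if (anyNA(idx)) stop("unknown marker in 'markers'")
  g[, idx] <- 2L - g[, idx]
  tmp <- map$allele_a[idx]
  map$allele_a[idx] <- map$allele_b[idx]
  map$allele_b[idx] <- tmp
  list(genotypes = g, map = map)
}
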