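# Plain-text tabular serializations: marker maps, chromosome-length tables,
# LD pair tables and rearrangement plans.

#' Write a marker map as a tab-separated file
#'
#' Columns `chrom`, `marker_id`, `pos_bp`, rows in stable (chrom, pos_bp)
#' order.
#'
#' @param map a [marker_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_marker_map <- function(map, path) {
  validate_marker_map(map)
  out <- sort_marker_map(map)
  write.table(out[, c("chrom", "marker_id", "pos_bp", "allele_a", "allele_b")],
              path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read a marker map written by [write_marker_map()]
#' @param path the file.
#' @return a [marker_map()].
#' @export
read_marker_map <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = "character")
  if (!all(c("chrom", "marker_id", "pos_bp") %in% names(x)))
    stop("not a marker map file: ", path)
  marker_map(x$marker_id, x$chrom, as.integer(x$pos_bp),
             allele_a = if ("allele_a" %in% names(x)) x$allele_a else "0",
             allele_b = if ("allele_b" %in% names(x)) x$allele_b else "0")
}

#' Read / write a chromosome-length table (two-column TSV)
#' @param path the file (columns: chrom, length_bp; header optional).
#' @return a [chrom_table()].
#' @export
read_chrom_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  x <- read.table(path, header = has_header, sep = "\t",
                  stringsAsFactors = FALSE)
  chrom_table(as.character(x[[1]]), as.numeric(x[[2]]))
}

#' @rdname read_chrom_table
#' @param ct a [chrom_table()].
#' @export
write_chrom_table <- function(ct, path) {
  write.table(ct, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Write an LD pair table as TSV
#'
#' Column layout (marker_i, marker_j, chrom_i, pos_i, chrom_j, pos_j, r2) is
#' compatible with the common inter-chromosomal r2 tabular reports.
#'
#' @param pairs an LD pair table from [pairwise_r2()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ld_table <- function(pairs, path) {
  cols <- c("marker_i", "marker_j", "chrom_i", "pos_i", "chrom_j", "pos_j", "r2")
  write.table(pairs[, cols], path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Write / read a rearrangement plan as a chain-style TSV
#'
#' One row per arm: source_chrom, source_start, source_end, strand,
#' target_chrom, target_start, plus the junction and orientation mode needed
#' to reconstruct the plan exactly.
#'
#' @param plan a [build_plan()] result.
#' @param path output file.
#' @return `path` (write) or the plan (read).
#' @export
write_plan <- function(plan, path) {
  arms <- plan$arms
  out <- data.frame(
    source_chrom = arms$source_chrom,
    source_start = 0L,
    source_end = arms$length_bp,
    strand = ifelse(arms$strand > 0, "+", "-"),
    target_chrom = arms$fused_chrom,
    target_start = arms$fused_start,
    role = arms$role,
    fused_end = arms$fused_end,
    junction_bp = arms$junction_bp,
    orientation_mode = attr(plan, "orientation_mode"),
    stringsAsFactors = FALSE
  )
  write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  arms <- data.frame(
    fused_chrom = x$target_chrom,
    source_chrom = x$source_chrom,
    role = x$role,
    length_bp = as.numeric(x$source_end),
    fused_end = x$fused_end,
    strand = ifelse(x$strand == "+", 1L, -1L),
    junction_bp = as.numeric(x$junction_bp),
    fused_start = as.numeric(x$target_start),
    stringsAsFactors = FALSE
  )
  new_rearrangement_plan(arms, orientation_mode = x$orientation_mode[1])
}
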