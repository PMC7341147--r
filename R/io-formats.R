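# Reading and writing genotype data in the standard exchange formats:
# PLINK text (ped/map), PLINK binary (bed/bim/fam, v1.00 SNP-major) and
# VCF v4.2. Biallelic autosomal SNPs only; multi-allelic records are
# rejected. Positions are 1-based inclusive, as in all three formats.

#' Read genotypes, marker map and (for phased VCF) haplotypes
#'
#' @param path for `plink-text` and `plink-bed`, the fileset prefix (i.e.
#'   `path.ped`/`path.map` or `path.bed`/`path.bim`/`path.fam`); for `vcf`,
#'   the VCF file itself.
#' @param format one of `"plink-text"`, `"plink-bed"`, `"vcf"`.
#' @return `list(genotypes, map, haplotypes)`; `genotypes` is a samples x
#'   markers integer matrix of allele-B counts (NA = missing), `map` a
#'   [marker_map()], and `haplotypes` a 2N x markers binary matrix when the
#'   VCF was fully phased, otherwise `NULL`.
#' @export
read_genotypes <- function(path, format = c("plink-text", "plink-bed", "vcf")) {
  format <- match.arg(format)
  switch(format,
    "plink-text" = read_plink_text(path),
    "plink-bed"  = read_plink_bed(path),
    "vcf"        = read_vcf_genotypes(path)
  )
}

#' Write genotypes (and optionally phase) to a standard format
#'
#' Emitted files are re-readable by [read_genotypes()] to an equal object.
#' bim/map positions are written verbatim. For `plink-text`, allele roles are
#' not stored by the format; [read_genotypes()] recovers them by the package
#' convention `allele_a < allele_b` (lexicographic), so maps obeying that
#' convention round-trip exactly.
#'
#' @param g genotype matrix (samples x markers, allele-B counts, NA missing).
#' @param map matching [marker_map()].
#' @param path output prefix (PLINK formats) or file name (VCF).
#' @param format one of `"plink-text"`, `"plink-bed"`, `"vcf"`.
#' @param haplotypes optional phased 2N x markers matrix; written as phased
#'   GT fields when `format = "vcf"`, ignored otherwise.
#' @return the paths written, invisibly.
#' @export
write_genotypes <- function(g, map, path,
                            format = c("plink-text", "plink-bed", "vcf"),
                            haplotypes = NULL) {
  format <- match.arg(format)
  validate_genotypes(g, map)
  bad <- nchar(map$allele_a) != 1L | nchar(map$allele_b) != 1L
  if (any(bad))
    stop("unsupported allele codes (must be single characters): marker ",
         map$marker_id[which(bad)[1]])
  switch(format,
    "plink-text" = write_plink_text(g, map, path),
    "plink-bed"  = write_plink_bed(g, map, path),
    "vcf"        = write_vcf_genotypes(g, map, path, haplotypes)
  )
}

sample_ids_or_default <- function(g) {
  if (!is.null(rownames(g))) rownames(g) else paste0("sample_", seq_len(nrow(g)))
}

# ---- PLINK text (ped/map) ---------------------------------------------------

read_plink_text <- function(prefix) {
  ped_f <- paste0(prefix, ".ped"); map_f <- paste0(prefix, ".map")
  for (f in c(ped_f, map_f)) if (!file.exists(f)) stop("file not found: ", f)
  mp <- read.table(map_f, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("chrom", "marker_id", "cm", "pos_bp"),
                   colClasses = c("character", "character", "numeric", "integer"))
  m <- nrow(mp)
  lines <- readLines(ped_f)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf != 6L + 2L * m)
  if (length(bad))
    stop("malformed ped record in ", ped_f, " line ", bad[1],
         ": expected ", 6L + 2L * m, " fields, found ", nf[bad[1]])
  n <- length(fields)
  ids <- vapply(fields, `[`, "", 2L)
  al <- matrix("0", nrow = n, ncol = 2L * m)
  for (i in seq_len(n)) al[i, ] <- fields[[i]][-(1:6)]
  a1 <- al[, seq_len(m) * 2L - 1L, drop = FALSE]
  a2 <- al[, seq_len(m) * 2L, drop = FALSE]
  g <- matrix(NA_integer_, n, m, dimnames = list(ids, mp$marker_id))
  allele_a <- character(m); allele_b <- character(m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    alle <- sort(setdiff(unique(obs), "0"))
    if (length(alle) > 2L)
      stop("more than two alleles for marker ", mp$marker_id[j], " in ", ped_f)
    aa <- if (length(alle) >= 1L) alle[1] else "0"
    ab <- if (length(alle) == 2L) alle[2] else "0"
    allele_a[j] <- aa; allele_b[j] <- ab
    miss <- a1[, j] == "0" | a2[, j] == "0"
    cnt <- (a1[, j] == ab) + (a2[, j] == ab)
    cnt[miss] <- NA_integer_
    g[, j] <- cnt
  }
  map <- marker_map(mp$marker_id, mp$chrom, mp$pos_bp, allele_a, allele_b)
  list(genotypes = g, map = map, haplotypes = NULL)
}

write_plink_text <- function(g, map, prefix) {
  ids <- sample_ids_or_default(g)
  mp <- data.frame(map$chrom, map$marker_id, rep(0, nrow(map)), map$pos_bp)
  write.table(mp, paste0(prefix, ".map"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  m <- nrow(map); n <- nrow(g)
  a1 <- matrix("0", n, m); a2 <- matrix("0", n, m)
  for (j in seq_len(m)) {
    gj <- g[, j]
    a1[, j] <- ifelse(is.na(gj), "0",
                      ifelse(gj >= 1L, map$allele_b[j], map$allele_a[j]))
    a2[, j] <- ifelse(is.na(gj), "0",
                      ifelse(gj == 2L, map$allele_b[j], map$allele_a[j]))
  }
  geno <- matrix("", n, 2L * m)
  geno[, seq_len(m) * 2L - 1L] <- a1
  geno[, seq_len(m) * 2L] <- a2
  ped <- cbind(ids, ids, "0", "0", "0", "-9", geno)
  write.table(ped, paste0(prefix, ".ped"), quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".ped", ".map")))
}

# ---- PLINK binary (bed/bim/fam) --------------------------------------------
# v1.00 SNP-major layout: magic bytes 0x6c 0x1b 0x01, then ceil(N/4) bytes per
# marker; two bits per sample, least-significant pair first:
# 00 = hom A1, 01 = missing, 10 = het, 11 = hom A2. A1 is the counted allele
# (allele_b), so the allele-B count maps 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01.

read_plink_bed <- function(prefix) {
  bed_f <- paste0(prefix, ".bed"); bim_f <- paste0(prefix, ".bim")
  fam_f <- paste0(prefix, ".fam")
  for (f in c(bed_f, bim_f, fam_f)) if (!file.exists(f)) stop("file not found: ", f)
  bim <- read.table(bim_f, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "marker_id", "cm", "pos_bp", "a1", "a2"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  fam <- read.table(fam_f, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bed_f, what = "raw", n = file.size(bed_f))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK bed file: ", bed_f)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major (v1.00) bed files are supported: ", bed_f)
  bpm <- ceiling(n / 4)
  payload <- raw[-(1:3)]
  if (length(payload) != bpm * m)
    stop("bed payload size inconsistent with bim/fam: ", bed_f,
         " has ", length(payload), " bytes, expected ", bpm * m)
  # decode all two-bit fields at once
  ints <- as.integer(payload)
  codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L, (ints %/% 64L) %% 4L)
  codes <- matrix(codes, nrow = 4L * bpm, ncol = m)[seq_len(n), , drop = FALSE]
  lut <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  g <- matrix(lut[codes + 1L], n, m,
              dimnames = list(as.character(fam[[2]]), bim$marker_id))
  map <- marker_map(bim$marker_id, bim$chrom, bim$pos_bp,
                    allele_a = bim$a2, allele_b = bim$a1)
  list(genotypes = g, map = map, haplotypes = NULL)
}

write_plink_bed <- function(g, map, prefix) {
  ids <- sample_ids_or_default(g)
  n <- nrow(g); m <- ncol(g)
  bim <- data.frame(map$chrom, map$marker_id, 0, map$pos_bp,
                    map$allele_b, map$allele_a)
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(ids, ids, 0, 0, 0, -9)
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  code <- matrix(0L, nrow = 4L * ceiling(n / 4), ncol = m)  # zero padding
  gg <- g
  cmap <- c(3L, 2L, 0L)  # count 0 -> 11, 1 -> 10, 2 -> 00
  code[seq_len(n), ] <- ifelse(is.na(gg), 1L, cmap[gg + 1L])
  bpm <- ceiling(n / 4)
  i4 <- matrix(seq_len(4L * bpm), nrow = 4L)
  bytes <- code[i4[1, ], , drop = FALSE] + 4L * code[i4[2, ], , drop = FALSE] +
    16L * code[i4[3, ], , drop = FALSE] + 64L * code[i4[4, ], , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}
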