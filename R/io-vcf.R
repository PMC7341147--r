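# VCF v4.2 input/output. Reading goes through vcfR; only biallelic SNP
# records are accepted. A fully phased VCF additionally yields the
# haplotype matrix (two rows per sample, in sample order).

read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE, convertNA = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE)))
    stop("multi-allelic VCF records are not supported (biallelic SNPs only): ",
         path)
  ids <- fix[, "ID"]
  if (any(is.na(ids) | ids == "."))
    ids[is.na(ids) | ids == "."] <-
      paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  ref <- fix[, "REF"]; alt[is.na(alt)] <- "0"
  map <- marker_map(ids, fix[, "CHROM"], as.integer(fix[, "POS"]),
                    allele_a = ref, allele_b = alt)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L) stop("VCF has no sample genotypes: ", path)
  samples <- colnames(gt)[-1]
  gtf <- sub(":.*$", "", gt[, -1, drop = FALSE])  # GT is the first field
  gtf[is.na(gtf)] <- "./."
  m <- nrow(map); n <- length(samples)
  known <- c("0/0", "0/1", "1/0", "1/1", "0|0", "0|1", "1|0", "1|1",
             "./.", ".|.", ".")
  bad <- which(!(gtf %in% known))
  if (length(bad)) {
    bi <- arrayInd(bad[1], dim(gtf))
    stop("malformed or non-biallelic GT '", gtf[bad[1]], "' in ", path,
         " record ", bi[1], " sample ", samples[bi[2]])
  }
  cnt <- c(`0/0` = 0L, `0/1` = 1L, `1/0` = 1L, `1/1` = 2L,
           `0|0` = 0L, `0|1` = 1L, `1|0` = 1L, `1|1` = 2L,
           `./.` = NA_integer_, `.|.` = NA_integer_, `.` = NA_integer_)
  g <- t(matrix(cnt[gtf], nrow = m, ncol = n))
  dimnames(g) <- list(samples, map$marker_id)
  haps <- NULL
  if (all(grepl("|", gtf, fixed = TRUE)) && !anyNA(g)) {
    h1 <- t(matrix(as.integer(substr(gtf, 1, 1)), m, n))
    h2 <- t(matrix(as.integer(substr(gtf, 3, 3)), m, n))
    haps <- matrix(0L, 2L * n, m)
    haps[seq(1L, 2L * n, by = 2L), ] <- h1
    haps[seq(2L, 2L * n, by = 2L), ] <- h2
    rownames(haps) <- paste0(rep(samples, each = 2L), c("_1", "_2"))
    colnames(haps) <- map$marker_id
  }
  list(genotypes = g, map = map, haplotypes = haps)
}

write_vcf_genotypes <- function(g, map, path, haplotypes = NULL) {
  ids <- sample_ids_or_default(g)
  n <- nrow(g); m <- ncol(g)
  if (!is.null(haplotypes)) {
    validate_haplotypes(haplotypes, map)
    if (nrow(haplotypes) != 2L * n)
      stop("haplotypes must have exactly two rows per sample")
  }
  ref <- ifelse(map$allele_a == "0", "N", map$allele_a)
  alt <- ifelse(map$allele_b == "0", ".", map$allele_b)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=ldfusion",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  if (is.null(haplotypes)) {
    lut <- c("0/0", "0/1", "1/1")
    gt <- matrix(ifelse(is.na(g), "./.", lut[g + 1L]), n, m)
  } else {
    h1 <- haplotypes[seq(1L, 2L * n, by = 2L), , drop = FALSE]
    h2 <- haplotypes[seq(2L, 2L * n, by = 2L), , drop = FALSE]
    gt <- matrix(paste0(h1, "|", h2), n, m)
  }
  body <- paste(map$chrom, map$pos_bp, map$marker_id, ref, alt, ".", ".",
                ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
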