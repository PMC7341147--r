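# Seeded forward Wright-Fisher simulator of diploid SNP panels on a genome
# containing fused submetacentric chromosomes. Recombination is interval-
# wise (switch probability ~ rate x interval length, capped at 0.5), with
# pericentromeric suppression around each fusion junction; before a
# fusion's time the two arms assort independently (junction interval at
# 0.5). Marker coordinates are also expressed on the split "ancestral
# acrocentric" reference — the inverse of the rearrangement the inference
# modules recover — with optional planted misplacements and a planted
# translocated segment for the misassembly detectors.

#' Simulation configuration
#'
#' Defaults describe the package's standard test scenario: six split
#' acrocentric chromosomes (two of which are the 40 Mb / 100 Mb arms of one
#' centric fusion, fused for the whole simulated history), 300 sampled
#' diploids from a constant population of 600, 600 generations, 1 cM/Mb
#' recombination with 100x suppression within 1 Mb of the junction, founder
#' frequencies Uniform(0.1, 0.9) and panel-like ascertainment at MAF 0.05
#' (~3,000 surviving markers from 4,800 requested at 12 markers/Mb). The
#' drift ratio t / 2Ne = 0.5 keeps panel markers segregating while the
#' fusion is old enough, relative to within-arm LD turnover, for the
#' pericentromeric signature to be established.
#'
#' @param n_samples diploid individuals sampled from the final generation.
#' @param pop_size constant Wright-Fisher population size (Ne).
#' @param n_generations simulated generations.
#' @param split_chroms [chrom_table()] of the split (ancestral acrocentric)
#'   reference; must contain every fusion arm.
#' @param fusions list of fusions, each
#'   `list(chrom_a, chrom_b, time)` with `time` = generations before
#'   present at which the centric fusion happened (joining the two `begin`
#'   ends, where the acrocentric centromeres sit).
#' @param n_markers requested markers per split chromosome (named vector;
#'   default ~9 per Mb).
#' @param recomb_rate recombination rate per bp per generation.
#' @param suppression_factor multiplier of the rate inside the suppressed
#'   region, in (0, 1].
#' @param suppression_radius_bp half-width of the suppressed region around
#'   each junction.
#' @param founder_freq_law `"uniform"` or `"beta"`.
#' @param founder_freq_params law parameters: Uniform(min, max) bounds or
#'   Beta(shape1, shape2).
#' @param centromere_founder_lineages number of distinct founder haplotype
#'   lineages segregating in each arm's pericentromeric region (within the
#'   suppression radius of the junction) at the start of the simulation,
#'   with random lineage frequencies. Emulates the low standing haplotype
#'   diversity of a long-term low-recombination (centromeric) region,
#'   which linkage-equilibrium founders cannot represent. `NULL` (the
#'   default) disables the restriction: few-lineage centromeres lose their
#'   markers to drift plus ascertainment in a sizeable fraction of runs,
#'   which removes the very junction signal the standard scenario studies.
#' @param maf_ascertainment markers with sample MAF not exceeding this are
#'   dropped (panel ascertainment).
#' @param missing_rate genotype missingness rate.
#' @param planted_misplaced number of pericentromeric markers whose
#'   split-map entry is moved to a decoy chromosome interior.
#' @param planted_segment `NULL`, or `list(span_bp, min_markers)`: a run of
#'   markers just long-arm-ward of the first junction is relocated, as a
#'   block, to a decoy chromosome interior in the split map.
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 300L, pop_size = 600L,
                       n_generations = 600L,
                       split_chroms = chrom_table(
                         paste0("chr", 1:6),
                         c(4e7, 1e8, 5e7, 6e7, 7e7, 8e7)),
                       fusions = list(list(chrom_a = "chr1", chrom_b = "chr2",
                                           time = 600L)),
                       n_markers = NULL,
                       recomb_rate = 1e-8,
                       suppression_factor = 0.01,
                       suppression_radius_bp = 1e6,
                       founder_freq_law = c("uniform", "beta"),
                       founder_freq_params = c(0.1, 0.9),
                       centromere_founder_lineages = NULL,
                       maf_ascertainment = 0.05,
                       missing_rate = 0.002,
                       planted_misplaced = 0L,
                       planted_segment = NULL,
                       seed = 1L) {
  founder_freq_law <- match.arg(founder_freq_law)
  if (is.null(n_markers))
    n_markers <- setNames(pmax(10L, as.integer(round(split_chroms$length_bp / 1e6 * 12))),
                          split_chroms$chrom)
  cfg <- list(n_samples = as.integer(n_samples),
              pop_size = as.integer(pop_size),
              n_generations = as.integer(n_generations),
              split_chroms = split_chroms, fusions = fusions,
              n_markers = n_markers, recomb_rate = recomb_rate,
              suppression_factor = suppression_factor,
              suppression_radius_bp = suppression_radius_bp,
              founder_freq_law = founder_freq_law,
              founder_freq_params = founder_freq_params,
              centromere_founder_lineages =
                if (is.null(centromere_founder_lineages)) NULL
                else as.integer(centromere_founder_lineages),
              maf_ascertainment = maf_ascertainment,
              missing_rate = missing_rate,
              planted_misplaced = as.integer(planted_misplaced),
              planted_segment = planted_segment,
              seed = as.integer(seed))
  stopifnot(cfg$n_samples >= 1, cfg$pop_size >= cfg$n_samples,
            cfg$n_generations >= 1,
            cfg$suppression_factor > 0, cfg$suppression_factor <= 1,
            all(vapply(fusions, function(f) f$time <= cfg$n_generations,
                       logical(1))))
  fused_chroms <- unlist(lapply(fusions, function(f) c(f$chrom_a, f$chrom_b)))
  if (anyDuplicated(fused_chroms))
    stop("a chromosome may participate in at most one fusion")
  if (!all(fused_chroms %in% split_chroms$chrom))
    stop("fusion arms must appear in split_chroms")
  structure(cfg, class = "sim_config")
}

# The generating rearrangement plan of a configuration: centric fusions
# join the two `begin` ends (acrocentric centromeres), junction-forward.
generating_plan <- function(cfg) {
  if (!length(cfg$fusions)) {
    arms <- data.frame(fused_chrom = character(), source_chrom = character(),
                       role = character(), length_bp = numeric(),
                       fused_end = character(), strand = integer(),
                       junction_bp = numeric(), fused_start = numeric(),
                       stringsAsFactors = FALSE)
    return(new_rearrangement_plan(arms, "junction_forward"))
  }
  cand <- do.call(rbind, lapply(cfg$fusions, function(f)
    data.frame(chrom_a = f$chrom_a, chrom_b = f$chrom_b,
               end_a = "begin", end_b = "begin", stringsAsFactors = FALSE)))
  build_plan(cand, cfg$split_chroms, orientation_mode = "junction_forward")
}

#' Simulate a diploid SNP panel on a fused-chromosome genome
#'
#' Forward Wright-Fisher simulation (random mating, constant size, founder
#' variation only) over the fused genome, followed by sampling, panel
#' ascertainment, genotype missingness and the split-reference projection.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `fused_sim`:
#'   `haplotypes` (2N x M phased), `genotypes` (N x M with missingness),
#'   `map` (the observed split-reference map, including any planted
#'   misplacements/segment), `chrom_table` (split reference), and `truth`
#'   with the generating `plan`, exact `fused_map` and `split_map`, fused
#'   `chrom_table_fused`, `junctions` (per fused chromosome), per-interval
#'   recombination probabilities (`recomb`), planted records and the
#'   configuration.
#' @export
simulate_fused_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  plan <- generating_plan(cfg)
  arms <- plan$arms
  split_ct <- cfg$split_chroms
  decoys <- setdiff(split_ct$chrom, arms$source_chrom)

  # marker positions on the split reference
  split_rows <- do.call(rbind, lapply(split_ct$chrom, function(ch) {
    L <- split_ct$length_bp[split_ct$chrom == ch]
    n <- cfg$n_markers[[ch]]
    pos <- sort(sample.int(L, min(n, L)))
    ab <- t(vapply(seq_along(pos),
                   function(i) sort(sample(c("A", "C", "G", "T"), 2L)),
                   character(2)))
    data.frame(marker_id = sprintf("%s_%06d", ch, seq_along(pos)),
               chrom = ch, pos_bp = pos,
               allele_a = ab[, 1], allele_b = ab[, 2],
               stringsAsFactors = FALSE)
  }))
  split_map <- marker_map(split_rows$marker_id, split_rows$chrom,
                          split_rows$pos_bp, split_rows$allele_a,
                          split_rows$allele_b)
  fused_map <- liftover_map(split_map, plan)

  # fused chromosome table and simulation order (fused layout)
  fused_names <- unique(arms$fused_chrom)
  fused_len <- vapply(fused_names, function(fc)
    sum(arms$length_bp[arms$fused_chrom == fc]), numeric(1))
  ct_fused <- chrom_table(c(fused_names, decoys),
                         c(fused_len,
                           split_ct$length_bp[match(decoys, split_ct$chrom)]))
  sim_chrom_order <- ct_fused$chrom
  ord <- order(match(fused_map$chrom, sim_chrom_order), fused_map$pos_bp)
  split_map <- split_map[ord, , drop = FALSE]; rownames(split_map) <- NULL
  fused_map <- fused_map[ord, , drop = FALSE]; rownames(fused_map) <- NULL
  M <- nrow(fused_map)

  junctions <- setNames(arms$junction_bp[match(fused_names, arms$fused_chrom)],
                        fused_names)

  # interval switch probabilities per epoch
  pchrom <- fused_map$chrom; ppos <- as.numeric(fused_map$pos_bp)
  same <- pchrom[-1] == pchrom[-M]
  lo <- ppos[-M]; hi <- ppos[-1]
  base_p <- rep(0.5, M - 1)
  suplen <- rep(0, M - 1)
  for (fc in fused_names) {
    j <- junctions[[fc]]
    sel <- same & pchrom[-M] == fc
    ov <- pmax(0, pmin(hi, j + cfg$suppression_radius_bp) -
                    pmax(lo, j - cfg$suppression_radius_bp))
    suplen[sel] <- ov[sel]
  }
  # non-fused chromosomes are acrocentric: their centromere sits at the
  # beginning of the coordinate count and is equally suppressed
  for (dc in decoys) {
    sel <- same & pchrom[-M] == dc
    ov <- pmax(0, pmin(hi, cfg$suppression_radius_bp) - lo)
    suplen[sel] <- ov[sel]
  }
  within_len <- (hi - lo) - suplen
  base_p[same] <- pmin(0.5, cfg$recomb_rate *
                         (within_len + cfg$suppression_factor * suplen))[same]
  # epochs: before each fusion's time, its junction-crossing interval is 0.5
  times <- sort(unique(vapply(cfg$fusions, function(f) as.integer(f$time),
                              integer(1))), decreasing = TRUE)
  epoch_start <- 1L
  probs <- matrix(base_p, nrow = 1)
  junction_interval <- function(fc) {
    j <- junctions[[fc]]
    which(same & pchrom[-M] == fc & lo < j & hi > j)
  }
  if (length(cfg$fusions)) {
    # build epochs chronologically; fusion at time t activates at
    # generation n_generations - t + 1
    cur <- base_p
    for (f in cfg$fusions) {
      fc <- arms$fused_chrom[arms$source_chrom == f$chrom_a][1]
      ji <- junction_interval(fc)
      if (length(ji)) cur[ji] <- 0.5  # pre-fusion: arms assort independently
    }
    starts <- 1L; rows <- list(cur)
    for (t in times) {
      gen_on <- cfg$n_generations - t + 1L
      cur2 <- rows[[length(rows)]]
      for (f in cfg$fusions) {
        if (as.integer(f$time) == t) {
          fc <- arms$fused_chrom[arms$source_chrom == f$chrom_a][1]
          ji <- junction_interval(fc)
          if (length(ji)) cur2[ji] <- base_p[ji]
        }
      }
      if (gen_on <= 1L) {
        rows[[length(rows)]] <- cur2
      } else {
        starts <- c(starts, gen_on)
        rows[[length(rows) + 1L]] <- cur2
      }
    }
    probs <- do.call(rbind, rows)
    epoch_start <- starts
  }

  # founders and evolution
  p0 <- switch(cfg$founder_freq_law,
               uniform = runif(M, cfg$founder_freq_params[1],
                               cfg$founder_freq_params[2]),
               beta = stats::rbeta(M, cfg$founder_freq_params[1],
                                   cfg$founder_freq_params[2]))
  H <- 2L * cfg$pop_size
  founders <- matrix(rbinom(H * M, 1L, rep(p0, each = H)), H, M)
  # pericentromeric standing variation: each arm side of a junction starts
  # from a small number of segregating lineage haplotypes
  k <- cfg$centromere_founder_lineages
  if (!is.null(k) && k >= 1L) {
    for (fc in fused_names) {
      j <- junctions[[fc]]
      for (side in c("short", "long")) {
        cols <- which(fused_map$chrom == fc &
                        (if (side == "short")
                           fused_map$pos_bp >= j - cfg$suppression_radius_bp &
                             fused_map$pos_bp < j
                         else fused_map$pos_bp >= j &
                             fused_map$pos_bp <= j + cfg$suppression_radius_bp))
        if (length(cols) < 2L) next
        lin <- matrix(rbinom(k * length(cols), 1L,
                             rep(p0[cols], each = k)), k, length(cols))
        w <- runif(k); w <- w / sum(w)
        founders[, cols] <- lin[sample.int(k, H, replace = TRUE, prob = w), ,
                                drop = FALSE]
      }
    }
  }
  final <- wf_evolve(founders, probs, as.integer(epoch_start),
                     cfg$n_generations)

  idx <- sort(sample.int(cfg$pop_size, cfg$n_samples))
  hap_rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  haps <- final[hap_rows, , drop = FALSE]
  sample_ids <- sprintf("ind_%04d", seq_len(cfg$n_samples))

  # panel ascertainment on the sampled genotypes
  f_b <- colMeans(haps)
  keep <- pmin(f_b, 1 - f_b) > cfg$maf_ascertainment
  if (!any(keep))
    stop("all markers lost to ascertainment; lower maf_ascertainment")
  haps <- haps[, keep, drop = FALSE]
  p0k <- p0[keep]
  split_map <- split_map[keep, , drop = FALSE]; rownames(split_map) <- NULL
  fused_map <- fused_map[keep, , drop = FALSE]; rownames(fused_map) <- NULL
  colnames(haps) <- fused_map$marker_id
  rownames(haps) <- paste0(rep(sample_ids, each = 2L), c("_1", "_2"))
  geno <- haplotypes_to_genotypes(haps, sample_ids)
  colnames(geno) <- fused_map$marker_id
  if (cfg$missing_rate > 0) {
    miss <- runif(length(geno)) < cfg$missing_rate
    geno[miss] <- NA_integer_
  }

  observed_map <- split_map
  planted_mis <- NULL; planted_seg <- NULL
  if (!length(fused_names) && !is.null(cfg$planted_segment))
    stop("a planted segment requires at least one configured fusion")
  first_fused <- if (length(fused_names)) fused_names[1] else NA_character_
  first_junction <- if (length(fused_names)) junctions[[first_fused]] else NA

  if (cfg$planted_misplaced > 0L) {
    if (length(decoys) < 2L)
      stop("planted misplacements need at least two decoy chromosomes")
    # source markers from decoy centromeres: a pericentromeric marker has an
    # unambiguous high-LD home for the flagger to point back to
    peri <- which(observed_map$chrom %in% decoys &
                    observed_map$pos_bp <= cfg$suppression_radius_bp)
    # a misplacement is only detectable by LD if the marker actually sits in
    # its home LD block: require >= 3 home partners at r2 > 0.2
    anchored <- vapply(peri, function(i) {
      home <- setdiff(which(observed_map$chrom == observed_map$chrom[i] &
                              observed_map$pos_bp <= cfg$suppression_radius_bp),
                      i)
      if (length(home) < 3L) return(FALSE)
      r2 <- suppressWarnings(cor(geno[, i], geno[, home],
                                 use = "pairwise.complete.obs"))^2
      sum(r2 > 0.2, na.rm = TRUE) >= 3L
    }, logical(1))
    peri <- peri[anchored]
    if (length(peri) < cfg$planted_misplaced)
      stop("not enough LD-anchored pericentromeric markers to plant")
    pick <- if (length(peri) == 1L) peri
            else sample(peri, cfg$planted_misplaced)
    dch <- vapply(observed_map$chrom[pick], function(src)
      sample(setdiff(decoys, src), 1L), "")
    dlen <- split_ct$length_bp[match(dch, split_ct$chrom)]
    dpos <- as.integer(round(runif(cfg$planted_misplaced, 0.3, 0.7) * dlen))
    planted_mis <- data.frame(marker_id = observed_map$marker_id[pick],
                              true_chrom = observed_map$chrom[pick],
                              true_pos = observed_map$pos_bp[pick],
                              planted_chrom = dch, planted_pos = dpos,
                              stringsAsFactors = FALSE)
    observed_map$chrom[pick] <- dch
    observed_map$pos_bp[pick] <- dpos
  }

  if (!is.null(cfg$planted_segment)) {
    span <- cfg$planted_segment$span_bp
    minm <- if (is.null(cfg$planted_segment$min_markers)) 3L
            else cfg$planted_segment$min_markers
    seg_decoys <- setdiff(decoys, unique(planted_mis$planted_chrom))
    if (!length(seg_decoys)) seg_decoys <- decoys
    if (!length(seg_decoys)) stop("planted segment needs a decoy chromosome")
    cand <- which(fused_map$chrom == first_fused &
                    fused_map$pos_bp > first_junction &
                    fused_map$pos_bp <= first_junction + span)
    if (length(cand) < minm)
      cand <- which(fused_map$chrom == first_fused &
                      fused_map$pos_bp > first_junction)[seq_len(minm)]
    if (length(cand) < minm || anyNA(cand))
      stop("not enough markers long-arm-ward of the junction for the segment")
    dch <- seg_decoys[length(seg_decoys)]
    L <- split_ct$length_bp[split_ct$chrom == dch]
    start0 <- as.integer(round(0.45 * L))
    newpos <- start0 + fused_map$pos_bp[cand] - fused_map$pos_bp[cand[1]]
    # the planted interval is foreign sequence: it carries no native markers
    native <- which(observed_map$chrom == dch &
                      observed_map$pos_bp >= min(newpos) &
                      observed_map$pos_bp <= max(newpos))
    native <- setdiff(native, cand)
    planted_seg <- list(marker_ids = observed_map$marker_id[cand],
                        planted_chrom = dch,
                        start_bp = min(newpos), end_bp = max(newpos),
                        true_fused_chrom = first_fused,
                        true_fused_start = min(fused_map$pos_bp[cand]),
                        true_fused_end = max(fused_map$pos_bp[cand]))
    observed_map$chrom[cand] <- dch
    observed_map$pos_bp[cand] <- as.integer(newpos)
    if (length(native)) {
      haps <- haps[, -native, drop = FALSE]
      p0k <- p0k[-native]
      geno <- geno[, -native, drop = FALSE]
      observed_map <- observed_map[-native, , drop = FALSE]
      split_map <- split_map[-native, , drop = FALSE]
      fused_map <- fused_map[-native, , drop = FALSE]
      rownames(observed_map) <- rownames(split_map) <- rownames(fused_map) <- NULL
    }
  }

  recomb <- data.frame(chrom = pchrom[-M][same], start_bp = lo[same],
                       end_bp = hi[same], switch_prob = base_p[same],
                       stringsAsFactors = FALSE)

  structure(list(
    haplotypes = haps, genotypes = geno, map = observed_map,
    chrom_table = split_ct, sample_ids = sample_ids,
    truth = list(plan = plan, fused_map = fused_map, split_map = split_map,
                 chrom_table_fused = ct_fused, junctions = junctions,
                 recomb = recomb, founder_freq = p0k,
                 planted_misplaced = planted_mis,
                 planted_segment = planted_seg, config = cfg)
  ), class = "fused_sim")
}

#' Project the true fused marker map back onto the split reference
#'
#' The exact inverse of the generating rearrangement: short-arm positions
#' reversed from the junction, long-arm positions counted from the
#' junction. Round-trip with [liftover_map()] under the generating plan is
#' the integer identity.
#'
#' @param truth the `truth` element of a [simulate_fused_population()]
#'   result (or the result itself).
#' @return the split-reference [marker_map()].
#' @export
project_to_split_reference <- function(truth) {
  if (inherits(truth, "fused_sim")) truth <- truth$truth
  liftover_map(truth$fused_map, invert_plan(truth$plan))
}

#' Write a simulated dataset as standard-format fixture files
#'
#' @param sim a [simulate_fused_population()] result.
#' @param out_dir output directory (created if needed).
#' @param formats subset of `"plink-text"`, `"plink-bed"`, `"vcf"`.
#' @return invisibly, the named list of written paths (genotypes per
#'   format, `chrom_table`, `split_map`, `fused_map`, `truth_json`).
#' @export
write_fixture <- function(sim, out_dir,
                          formats = c("plink-text", "vcf")) {
  stopifnot(inherits(sim, "fused_sim"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ord <- order(sim$map$chrom, sim$map$pos_bp, method = "radix")
  map <- sim$map[ord, , drop = FALSE]; rownames(map) <- NULL
  g <- sim$genotypes[, ord, drop = FALSE]
  h <- sim$haplotypes[, ord, drop = FALSE]
  paths <- list()
  for (fmt in formats) {
    pfx <- file.path(out_dir, if (fmt == "vcf") "genotypes.vcf" else "genotypes")
    write_genotypes(g, map, pfx, format = fmt,
                    haplotypes = if (fmt == "vcf") h)
    paths[[fmt]] <- pfx
  }
  paths$chrom_table <- file.path(out_dir, "chromosomes.tsv")
  write_chrom_table(sim$chrom_table, paths$chrom_table)
  paths$split_map <- file.path(out_dir, "map_split_true.tsv")
  write_marker_map(sim$truth$split_map, paths$split_map)
  paths$fused_map <- file.path(out_dir, "map_fused_true.tsv")
  write_marker_map(sim$truth$fused_map, paths$fused_map)
  paths$plan <- file.path(out_dir, "plan_true.tsv")
  write_plan(sim$truth$plan, paths$plan)
  truth <- list(
    plan = sim$truth$plan$arms,
    orientation_mode = attr(sim$truth$plan, "orientation_mode"),
    junctions = as.list(sim$truth$junctions),
    fusions = sim$truth$config$fusions,
    planted_misplaced = sim$truth$planted_misplaced,
    planted_segment = sim$truth$planted_segment,
    seed = sim$truth$config$seed
  )
  paths$truth_json <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, paths$truth_json, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
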