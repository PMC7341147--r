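# Misassembly signatures in an LD pair table: individual markers whose LD
# partners contradict their mapped position, and runs of markers forming a
# translocated segment (interior block whose high-LD partners sit on
# another chromosome).

#' Flag markers whose mapped position contradicts their LD
#'
#' A marker is flagged when it has at least `min_discordant` partners at
#' r2 > `flag_r2` that are on another chromosome or more than `far_dist`
#' away, AND its mean r2 to its `near_k` nearest mapped neighbors is below
#' `local_r2_max` (a well-placed marker in a high-LD region satisfies the
#' first condition but not the second). The pair table should be computed
#' without an r2 threshold (`r2_min = NULL`): neighbor pairs absent from
#' the table are treated as r2 = 0.
#'
#' @param pairs an [pairwise_r2()] table (un-truncated).
#' @param map the matching [marker_map()].
#' @param flag_r2 discordant-partner r2 threshold (strict).
#' @param min_discordant minimum number of discordant partners.
#' @param far_dist same-chromosome distance beyond which a partner counts
#'   as discordant (bp).
#' @param near_k number of nearest mapped neighbors in the local-LD check.
#' @param local_r2_max flag only markers whose mean neighbor r2 is below
#'   this.
#' @return a `data.frame` of class `misplaced_flags`: `marker_id`,
#'   `evidence` (`"interchrom_ld"`/`"longrange_ld"`), `n_discordant_pairs`,
#'   `best_alternative_chrom` (modal chromosome of the discordant partners,
#'   NA when they are long-range on the marker's own chromosome),
#'   `mean_local_r2`. Empty when nothing is flagged.
#' @export
flag_misplaced_snps <- function(pairs, map, flag_r2 = 0.2,
                                min_discordant = 3L, far_dist = 1e7,
                                near_k = 5L, local_r2_max = 0.05) {
  disc <- pairs$r2 > flag_r2 &
    (!pairs$same_chrom | (!is.na(pairs$dist_bp) & pairs$dist_bp > far_dist))
  dp <- pairs[disc, , drop = FALSE]
  cnt <- table(c(dp$marker_i, dp$marker_j))
  cand <- names(cnt)[cnt >= min_discordant]
  if (!length(cand))
    return(empty_misplaced())
  key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "\r")
  pair_key <- key(pairs$marker_i, pairs$marker_j)
  rows <- list()
  map_s <- sort_marker_map(map)
  for (mk in cand) {
    # local LD to nearest mapped neighbors
    ridx <- which(map_s$marker_id == mk)
    chr <- map_s$chrom[ridx]
    same <- which(map_s$chrom == chr & map_s$marker_id != mk)
    if (!length(same)) next
    dd <- abs(map_s$pos_bp[same] - map_s$pos_bp[ridx])
    nb <- map_s$marker_id[same[order(dd)][seq_len(min(near_k, length(same)))]]
    hit <- match(key(rep(mk, length(nb)), nb), pair_key)
    local_r2 <- ifelse(is.na(hit), 0, pairs$r2[hit])
    mloc <- mean(local_r2)
    if (mloc >= local_r2_max) next
    sel <- dp$marker_i == mk | dp$marker_j == mk
    partner <- ifelse(dp$marker_i[sel] == mk, dp$marker_j[sel], dp$marker_i[sel])
    pchrom <- ifelse(dp$marker_i[sel] == mk, dp$chrom_j[sel], dp$chrom_i[sel])
    other <- pchrom != chr
    best <- if (any(other)) {
      tt <- sort(table(pchrom[other]), decreasing = TRUE)
      names(tt)[1]
    } else NA_character_
    rows[[mk]] <- data.frame(
      marker_id = mk,
      evidence = if (any(other)) "interchrom_ld" else "longrange_ld",
      n_discordant_pairs = length(partner),
      best_alternative_chrom = best,
      mean_local_r2 = mloc,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) return(empty_misplaced())
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("misplaced_flags", "data.frame")
  res
}

empty_misplaced <- function() {
  res <- data.frame(marker_id = character(), evidence = character(),
                    n_discordant_pairs = integer(),
                    best_alternative_chrom = character(),
                    mean_local_r2 = numeric(), stringsAsFactors = FALSE)
  class(res) <- c("misplaced_flags", "data.frame")
  res
}

#' Detect translocated segments from inter-chromosomal LD runs
#'
#' Finds maximal runs of at least `min_run` consecutive mapped markers that
#' each have at least one inter-chromosomal partner at r2 > `r2_min` on the
#' same partner chromosome. Runs lying entirely within `terminal_fraction`
#' of their own chromosome are excluded: terminal high-LD runs are fusion
#' evidence (joined centromeric ends), not translocations.
#'
#' @param pairs an [pairwise_r2()] table with inter-chromosomal pairs.
#' @param map the matching [marker_map()].
#' @param chrom_table optional [chrom_table()]; chromosome lengths default
#'   to the maximum mapped position.
#' @param r2_min partner threshold (strict).
#' @param min_run minimum run length in markers.
#' @param terminal_fraction width of the excluded terminal zones.
#' @return a `data.frame`: `chrom`, `start_bp`, `end_bp`, `partner_chrom`,
#'   `partner_start_bp`, `partner_end_bp`, `n_support` (qualifying pairs),
#'   `n_markers`. Empty when no segment qualifies.
#' @export
detect_translocated_segments <- function(pairs, map, chrom_table = NULL,
                                         r2_min = 0.2, min_run = 3L,
                                         terminal_fraction = 0.25) {
  inter <- pairs[!pairs$same_chrom & pairs$r2 > r2_min, , drop = FALSE]
  out <- list()
  map_s <- sort_marker_map(map)
  lens <- if (!is.null(chrom_table))
    setNames(chrom_table$length_bp, chrom_table$chrom)
  else tapply(map_s$pos_bp, map_s$chrom, max)
  if (!nrow(inter)) return(empty_segments())
  # partner chromosomes per marker
  part <- rbind(
    data.frame(m = inter$marker_i, pc = inter$chrom_j, pp = inter$pos_j,
               stringsAsFactors = FALSE),
    data.frame(m = inter$marker_j, pc = inter$chrom_i, pp = inter$pos_i,
               stringsAsFactors = FALSE)
  )
  for (chr in unique(map_s$chrom)) {
    sel <- map_s$chrom == chr
    ids <- map_s$marker_id[sel]
    pos <- map_s$pos_bp[sel]
    L <- as.numeric(lens[[chr]])
    psub <- part[part$m %in% ids, , drop = FALSE]
    if (!nrow(psub)) next
    for (pchr in unique(psub$pc)) {
      hit <- ids %in% psub$m[psub$pc == pchr]
      r <- rle(hit)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values & r$lengths >= min_run)) {
        i0 <- starts[k]; i1 <- ends[k]
        s_bp <- pos[i0]; e_bp <- pos[i1]
        if (e_bp <= terminal_fraction * L || s_bp >= (1 - terminal_fraction) * L)
          next  # terminal run: fusion evidence, not a translocation
        run_ids <- ids[i0:i1]
        pr <- psub[psub$pc == pchr & psub$m %in% run_ids, , drop = FALSE]
        out[[length(out) + 1L]] <- data.frame(
          chrom = chr, start_bp = s_bp, end_bp = e_bp,
          partner_chrom = pchr,
          partner_start_bp = min(pr$pp), partner_end_bp = max(pr$pp),
          n_support = nrow(pr), n_markers = length(run_ids),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) return(empty_segments())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_segments <- function() {
  data.frame(chrom = character(), start_bp = numeric(), end_bp = numeric(),
             partner_chrom = character(), partner_start_bp = numeric(),
             partner_end_bp = numeric(), n_support = integer(),
             n_markers = integer(), stringsAsFactors = FALSE)
}
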