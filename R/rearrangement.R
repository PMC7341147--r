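# Inference of centric (Robertsonian) fusions from inter-chromosomal LD,
# construction of an invertible rearrangement plan, and the coordinate
# liftover that rewrites a split "ancestral acrocentric" marker map onto
# the fused submetacentric chromosome.

#' Count high-LD marker pairs between chromosomes
#'
#' @param pairs an [pairwise_r2()] table containing inter-chromosomal pairs.
#' @param r2_min count pairs with r2 strictly greater than this (a pair at
#'   exactly the threshold is not counted).
#' @return a symmetric chromosome-pair count matrix (class
#'   `interchrom_counts`), zero diagonal.
#' @export
interchrom_ld_counts <- function(pairs, r2_min = 0.2) {
  chroms <- sort(unique(c(pairs$chrom_i, pairs$chrom_j)))
  cnt <- matrix(0L, length(chroms), length(chroms),
                dimnames = list(chroms, chroms))
  sel <- !pairs$same_chrom & pairs$r2 > r2_min
  if (any(sel)) {
    t <- table(factor(pairs$chrom_i[sel], levels = chroms),
               factor(pairs$chrom_j[sel], levels = chroms))
    cnt <- cnt + t + base::t(t)
  }
  storage.mode(cnt) <- "integer"
  class(cnt) <- c("interchrom_counts", class(cnt))
  cnt
}

#' Detect candidate chromosome fusions from inter-chromosomal LD counts
#'
#' A chromosome pair is a fusion candidate when its high-LD pair count
#' exceeds `max(min_count, median + k_mad * MAD)` of all inter-chromosomal
#' counts (a robust background rule). Candidates are accepted greedily by
#' descending count with each chromosome used at most once (a centric
#' fusion consumes both partners); a chromosome supported in two candidate
#' pairs keeps only the stronger.
#'
#' @param counts matrix from [interchrom_ld_counts()].
#' @param min_count minimum absolute count.
#' @param k_mad MAD multiplier of the robust background threshold.
#' @return a `data.frame` of class `fusion_candidates`: `chrom_a`,
#'   `chrom_b` (chrom_a < chrom_b), `n_pairs`, `background_score` (robust
#'   z-score against the inter-chromosomal background). May be empty.
#' @export
detect_fusions <- function(counts, min_count = 20L, k_mad = 10) {
  chroms <- rownames(counts)
  if (length(chroms) < 2L) stop("at least 2 chromosomes required")
  ut <- upper.tri(counts)
  bg <- counts[ut]
  med <- median(bg)
  s <- mad(bg)
  thr <- max(min_count, med + k_mad * s)
  score <- (counts[ut] - med) / max(s, .Machine$double.eps)
  idx <- which(ut, arr.ind = TRUE)
  cand <- data.frame(chrom_a = chroms[idx[, 1]], chrom_b = chroms[idx[, 2]],
                     n_pairs = counts[ut], background_score = score,
                     stringsAsFactors = FALSE)
  swap <- cand$chrom_a > cand$chrom_b
  tmp <- cand$chrom_a[swap]
  cand$chrom_a[swap] <- cand$chrom_b[swap]; cand$chrom_b[swap] <- tmp
  cand <- cand[cand$n_pairs > thr, , drop = FALSE]
  cand <- cand[order(-cand$n_pairs, cand$chrom_a, cand$chrom_b), , drop = FALSE]
  used <- character(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$chrom_a[i] %in% used || cand$chrom_b[i] %in% used) {
      message("detect_fusions: dropping ", cand$chrom_a[i], "-",
              cand$chrom_b[i], " (a partner already assigned to a stronger pair)")
      next
    }
    keep[i] <- TRUE
    used <- c(used, cand$chrom_a[i], cand$chrom_b[i])
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fusion_candidates", "data.frame")
  out
}

#' Localize which ends of a candidate pair are joined
#'
#' For each chromosome of the pair, takes the supporting markers (those in a
#' high-LD inter-chromosomal pair with the partner) and calls the joined end
#' `begin` when their median position lies within `terminal_fraction` of the
#' chromosome start, `end` within `terminal_fraction` of the chromosome end.
#' Medians in the middle zone make the candidate unresolvable (flagged, not
#' silently placed).
#'
#' @param pairs an [pairwise_r2()] table containing the candidate's pairs.
#' @param candidate one row of [detect_fusions()] output (or a list with
#'   `chrom_a`, `chrom_b`).
#' @param chrom_table a [chrom_table()] with both chromosome lengths.
#' @param r2_min supporting-pair threshold (strict).
#' @param terminal_fraction width of the terminal zones, as a fraction of
#'   chromosome length.
#' @param min_count minimum number of supporting pairs.
#' @return a list: `end_a`, `end_b` (`"begin"`/`"end"`/NA), `resolved`,
#'   `junction_breadth_bp` (90th-percentile span of supporting-marker
#'   positions, maximum over the two chromosomes), `n_support`.
#' @export
localize_fusion_ends <- function(pairs, candidate, chrom_table,
                                 r2_min = 0.2, terminal_fraction = 0.25,
                                 min_count = 20L) {
  ca <- candidate$chrom_a; cb <- candidate$chrom_b
  sel <- !pairs$same_chrom & pairs$r2 > r2_min &
    ((pairs$chrom_i == ca & pairs$chrom_j == cb) |
     (pairs$chrom_i == cb & pairs$chrom_j == ca))
  if (sum(sel) < min_count)
    stop("candidate ", ca, "-", cb, " has fewer than ", min_count,
         " supporting pairs")
  pos_a <- c(pairs$pos_i[sel & pairs$chrom_i == ca],
             pairs$pos_j[sel & pairs$chrom_j == ca])
  pos_b <- c(pairs$pos_i[sel & pairs$chrom_i == cb],
             pairs$pos_j[sel & pairs$chrom_j == cb])
  len <- setNames(chrom_table$length_bp, chrom_table$chrom)
  call_end <- function(pos, L) {
    f <- median(pos) / L
    if (f < terminal_fraction) "begin"
    else if (f > 1 - terminal_fraction) "end"
    else NA_character_
  }
  end_a <- call_end(pos_a, len[[ca]])
  end_b <- call_end(pos_b, len[[cb]])
  span <- function(pos) diff(quantile(pos, c(0.05, 0.95), names = FALSE))
  list(end_a = end_a, end_b = end_b,
       resolved = !is.na(end_a) && !is.na(end_b),
       junction_breadth_bp = max(span(pos_a), span(pos_b)),
       n_support = sum(sel))
}

new_rearrangement_plan <- function(arms, orientation_mode,
                                   direction = "split_to_fused") {
  structure(list(arms = arms, direction = direction),
            class = "rearrangement_plan",
            orientation_mode = orientation_mode)
}

#' Build a rearrangement plan from resolved fusion candidates
#'
#' The shorter source chromosome becomes the short arm; fused coordinate 0
#' is the short-arm telomere (the count starts from the end of the short
#' arm) and the junction (centromere) sits at `junction_bp` = short-arm
#' length. Arm strands are set so that each arm's joined end abuts the
#' junction. Two long-arm orientation conventions are supported:
#' `junction_forward` (default) lets the long arm run forward from the
#' junction when its joined end is its beginning, placing its far end at
#' the fused telomere; `paper_literal` applies the literal transform
#' short_len + (long_len - pos) to every long-arm position (and
#' short_len - pos on the short arm), which instead anchors the long arm's
#' far end at the junction side. The two modes are both exact and
#' invertible; `junction_forward` is the one consistent with an LD peak at
#' the junction of the arranged assembly.
#'
#' @param candidates a `data.frame` with columns `chrom_a`, `chrom_b`,
#'   `end_a`, `end_b` (from [detect_fusions()] + [localize_fusion_ends()]).
#' @param chrom_table a [chrom_table()] covering all source chromosomes.
#' @param orientation_mode `"junction_forward"` or `"paper_literal"`.
#' @param name_sep separator of the fused chromosome name
#'   `"<short><sep><long>"`.
#' @return a `rearrangement_plan` (arms table + direction), usable with
#'   [liftover_map()] and invertible with [invert_plan()].
#' @export
build_plan <- function(candidates, chrom_table,
                       orientation_mode = c("junction_forward", "paper_literal"),
                       name_sep = ";") {
  orientation_mode <- match.arg(orientation_mode)
  len <- setNames(chrom_table$length_bp, chrom_table$chrom)
  arms <- vector("list", nrow(candidates))
  seen <- character(0)
  for (i in seq_len(nrow(candidates))) {
    ca <- candidates$chrom_a[i]; cb <- candidates$chrom_b[i]
    if (any(c(ca, cb) %in% seen))
      stop("chromosome ", intersect(c(ca, cb), seen)[1],
           " appears in more than one fusion")
    seen <- c(seen, ca, cb)
    la <- len[[ca]]; lb <- len[[cb]]
    if (la < lb || (la == lb && ca < cb)) {
      short <- ca; long <- cb
      end_short <- candidates$end_a[i]; end_long <- candidates$end_b[i]
    } else {
      short <- cb; long <- ca
      end_short <- candidates$end_b[i]; end_long <- candidates$end_a[i]
    }
    if (la == lb)
      message("build_plan: equal arm lengths for ", ca, "-", cb,
              "; lexicographically smaller label (", short,
              ") taken as short arm")
    if (is.na(end_short) || is.na(end_long))
      stop("unresolved ends for candidate ", ca, "-", cb)
    junction <- len[[short]]
    fused <- paste0(short, name_sep, long)
    if (orientation_mode == "paper_literal") {
      strand_short <- -1L
      strand_long <- -1L
    } else {
      strand_short <- if (end_short == "begin") -1L else 1L
      strand_long <- if (end_long == "begin") 1L else -1L
    }
    arms[[i]] <- data.frame(
      fused_chrom = fused,
      source_chrom = c(short, long),
      role = c("short", "long"),
      length_bp = c(len[[short]], len[[long]]),
      fused_end = c(end_short, end_long),
      strand = c(strand_short, strand_long),
      junction_bp = junction,
      fused_start = c(0, junction),
      stringsAsFactors = FALSE
    )
  }
  new_rearrangement_plan(do.call(rbind, arms), orientation_mode)
}

#' Invert a rearrangement plan
#'
#' @param plan a [build_plan()] result.
#' @return the plan with its mapping direction reversed, so that
#'   `liftover_map(liftover_map(map, plan), invert_plan(plan))` is the
#'   identity on every marker (exact integer equality).
#' @export
invert_plan <- function(plan) {
  plan$direction <- if (plan$direction == "split_to_fused")
    "fused_to_split" else "split_to_fused"
  plan
}

# Forward transform of positions on one arm (split -> fused), integer exact.
.arm_forward <- function(pos, arm, mode) {
  j <- arm$junction_bp; L <- arm$length_bp
  if (arm$role == "short") {
    if (mode == "paper_literal") j - pos
    else if (arm$fused_end == "begin") j - pos else pos
  } else {
    if (mode == "paper_literal") j + (L - pos)
    else if (arm$fused_end == "begin") j + pos else j + (L - pos)
  }
}

.arm_backward <- function(pos, arm, mode) {
  j <- arm$junction_bp; L <- arm$length_bp
  if (arm$role == "short") {
    if (mode == "paper_literal") j - pos
    else if (arm$fused_end == "begin") j - pos else pos
  } else {
    if (mode == "paper_literal") L - (pos - j)
    else if (arm$fused_end == "begin") pos - j else L - (pos - j)
  }
}

#' Lift marker coordinates across a rearrangement plan
#'
#' Applies the plan's per-arm (strand, offset) transform to every marker on
#' a source chromosome; markers on chromosomes absent from the plan pass
#' through unchanged. The mapping is a bijection on fused chromosomes and
#' is inverted exactly by [invert_plan()].
#'
#' @param map a [marker_map()].
#' @param plan a [build_plan()] result (possibly inverted).
#' @return the lifted [marker_map()], same row order.
#' @export
liftover_map <- function(map, plan) {
  arms <- plan$arms
  mode <- attr(plan, "orientation_mode")
  pos <- as.numeric(map$pos_bp)
  chrom <- map$chrom
  if (plan$direction == "split_to_fused") {
    for (i in seq_len(nrow(arms))) {
      a <- arms[i, ]
      sel <- chrom == a$source_chrom
      if (!any(sel)) next
      over <- map$pos_bp[sel] > a$length_bp
      if (any(over))
        stop("coordinate overflow on arm ", a$source_chrom, ": marker ",
             map$marker_id[sel][which(over)[1]], " at ",
             map$pos_bp[sel][which(over)[1]], " exceeds arm length ",
             a$length_bp)
      pos[sel] <- .arm_forward(map$pos_bp[sel], a, mode)
      chrom[sel] <- a$fused_chrom
    }
  } else {
    # fused -> split: assign positions to arms by fused interval
    for (fc in unique(arms$fused_chrom)) {
      sub <- arms[arms$fused_chrom == fc, , drop = FALSE]
      j <- sub$junction_bp[1]
      sel <- which(chrom == fc)
      if (!length(sel)) next
      short <- sub[sub$role == "short", , drop = FALSE]
      long <- sub[sub$role == "long", , drop = FALSE]
      p <- map$pos_bp[sel]
      total <- j + long$length_bp
      if (any(p > total) || any(p < 0))
        stop("coordinate overflow on fused chromosome ", fc, ": marker ",
             map$marker_id[sel][which(p > total | p < 0)[1]])
      # p == junction can only arise from an arm-boundary position; it goes
      # to the arm whose mapping reaches it from a valid (>= 1) source
      # position under the active convention
      j_to_long <- mode == "paper_literal" ||
        (long$fused_end == "end" && short$fused_end == "begin")
      short_side <- if (j_to_long) p < j else p <= j
      idx_s <- sel[short_side]; idx_l <- sel[!short_side]
      if (length(idx_s)) {
        pos[idx_s] <- .arm_backward(map$pos_bp[idx_s], short, mode)
        chrom[idx_s] <- short$source_chrom
      }
      if (length(idx_l)) {
        pos[idx_l] <- .arm_backward(map$pos_bp[idx_l], long, mode)
        chrom[idx_l] <- long$source_chrom
      }
    }
  }
  out <- map
  out$chrom <- chrom
  out$pos_bp <- as.integer(round(pos))
  out
}

#' @export
print.rearrangement_plan <- function(x, ...) {
  cat("Rearrangement plan (", attr(x, "orientation_mode"), ", direction ",
      x$direction, ")\n", sep = "")
  print(x$arms)
  invisible(x)
}
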