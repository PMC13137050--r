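#' Extract split-read evidence from alignment records
#'
#' One evidence item per qualifying soft clip (length >= `min_clip`) at
#' either end of a mapped primary record with `mapq >= mapq_floor`. The
#' breakpoint is the reference coordinate of the boundary between the
#' aligned segment and the clipped segment: the leftmost aligned base for a
#' left clip, the position one past the rightmost aligned base for a right
#' clip. A record clipped at both ends yields two items.
#'
#' @param records data.table from [read_alignments()].
#' @param min_clip minimum soft-clip length in nt (default 20; shorter
#'   clips are treated as alignment-ambiguity noise).
#' @param mapq_floor records below this mapping quality are excluded
#'   (default 20).
#' @return data.table: `qname`, `contig`, `breakpoint` (0-based),
#'   `clip_side` ("left"/"right"), `clip_len`.
#' @export
extract_split_reads <- function(records, min_clip = 20L, mapq_floor = 20L) {
  empty <- data.table::data.table(
    qname = character(), contig = character(), breakpoint = integer(),
    clip_side = character(), clip_len = integer()
  )
  if (nrow(records) == 0L) return(empty)
  ok <- !records$unmapped & !records$secondary & !records$supplementary &
    records$mapq >= mapq_floor & records$cigar != "*"
  rec <- records[ok]
  if (nrow(rec) == 0L) return(empty)
  cs <- cigar_stats(rec$cigar)
  out <- list()
  li <- cs$left_clip >= min_clip
  if (any(li)) {
    out[[1L]] <- data.table::data.table(
      qname = rec$qname[li], contig = rec$contig[li],
      breakpoint = rec$pos[li], clip_side = "left",
      clip_len = cs$left_clip[li]
    )
  }
  ri <- cs$right_clip >= min_clip
  if (any(ri)) {
    out[[length(out) + 1L]] <- data.table::data.table(
      qname = rec$qname[ri], contig = rec$contig[ri],
      breakpoint = rec$pos[ri] + cs$ref_span[ri], clip_side = "right",
      clip_len = cs$right_clip[ri]
    )
  }
  if (!length(out)) return(empty)
  res <- data.table::rbindlist(out)
  data.table::setorder(res, contig, breakpoint)
  res[]
}

#' Estimate the discordant template-length threshold from proper pairs
#'
#' Mean + 3 SD of |template length| over properly paired records, the
#' standard contract for deletion-supporting pair extraction.
#'
#' @param records data.table from [read_alignments()].
#' @return numeric threshold in bp.
#' @export
estimate_tlen_threshold <- function(records) {
  tl <- abs(records$tlen[records$proper & records$tlen != 0L])
  if (length(tl) < 10L) {
    stop("too few proper pairs to estimate the insert-size distribution; ",
         "supply tlen_threshold explicitly")
  }
  mean(tl) + 3 * stats::sd(tl)
}

#' Extract discordant read pairs
#'
#' A primary, both-mates-mapped, same-contig pair is discordant when its
#' outer span (rightmost aligned end minus leftmost start) exceeds
#' `tlen_threshold`, or when it is not in forward-reverse orientation.
#' The reported span runs from the leftmost mate's aligned end to the
#' rightmost mate's start: for a pair straddling a deletion it covers the
#' deleted gap.
#'
#' @param records data.table from [read_alignments()].
#' @param tlen_threshold |template length| above which a pair is
#'   discordant; `NULL` (default) estimates mean + 3 SD of the proper-pair
#'   insert size via [estimate_tlen_threshold()].
#' @param mapq_floor minimum mapping quality for both mates (default 20).
#' @return data.table: `qname`, `contig`, `left_end`, `right_start`
#'   (0-based inner boundaries), `outer_span`, `fr` (forward-reverse?).
#' @export
extract_discordant_pairs <- function(records, tlen_threshold = NULL,
                                     mapq_floor = 20L) {
  empty <- data.table::data.table(
    qname = character(), contig = character(), left_end = integer(),
    right_start = integer(), outer_span = integer(), fr = logical()
  )
  if (nrow(records) == 0L) return(empty)
  if (is.null(tlen_threshold)) {
    tlen_threshold <- estimate_tlen_threshold(records)
  }
  ok <- records$paired & !records$unmapped & !records$mate_unmapped &
    !records$secondary & !records$supplementary &
    records$mapq >= mapq_floor &
    (records$rnext == "=" | records$rnext == records$contig)
  rec <- records[ok]
  if (nrow(rec) == 0L) return(empty)
  cs <- cigar_stats(rec$cigar)
  rec[, ref_end := pos + cs$ref_span]
  r1 <- rec[first_in_pair == TRUE,
            list(qname, contig, pos1 = pos, end1 = ref_end, rev1 = reverse)]
  r2 <- rec[first_in_pair == FALSE,
            list(qname, pos2 = pos, end2 = ref_end, rev2 = reverse)]
  pr <- merge(r1, r2, by = "qname")
  n_dropped <- (nrow(r1) + nrow(r2)) - 2L * nrow(pr)
  if (n_dropped > 0L) {
    warning(n_dropped, " record(s) without a usable mate dropped")
  }
  if (nrow(pr) == 0L) return(empty)
  one_left <- pr$pos1 <= pr$pos2
  left_pos <- ifelse(one_left, pr$pos1, pr$pos2)
  left_end <- ifelse(one_left, pr$end1, pr$end2)
  left_rev <- ifelse(one_left, pr$rev1, pr$rev2)
  right_pos <- ifelse(one_left, pr$pos2, pr$pos1)
  right_end <- ifelse(one_left, pr$end2, pr$end1)
  right_rev <- ifelse(one_left, pr$rev2, pr$rev1)
  outer <- right_end - left_pos
  fr <- !left_rev & right_rev
  disc <- outer > tlen_threshold | !fr
  out <- data.table::data.table(
    qname = pr$qname[disc], contig = pr$contig[disc],
    left_end = as.integer(left_end[disc]),
    right_start = as.integer(right_pos[disc]),
    outer_span = as.integer(outer[disc]), fr = fr[disc]
  )
  data.table::setorder(out, contig, left_end)
  out[]
}

#' Bin split-read counts over a capture region
#'
#' The region is tiled by non-overlapping `bin_width` bins (the last bin is
#' truncated at the region end); each breakpoint inside the region
#' increments exactly one bin, so bin totals conserve the in-region
#' evidence count.
#'
#' @param treated,control split-read evidence from [extract_split_reads()].
#' @param region one-row list/data.frame with `contig`, `start`, `end`.
#' @param bin_width bin width in bp (default 100).
#' @return data.table: `contig`, `bin_start`, `bin_end`, `treated_count`,
#'   `control_count`.
#' @export
bin_split_counts <- function(treated, control, region, bin_width = 100L) {
  rg <- as.list(region)
  stopifnot(rg$start < rg$end, bin_width >= 1L)
  starts <- seq.int(rg$start, rg$end - 1L, by = bin_width)
  ends <- pmin(starts + bin_width, rg$end)
  count_in <- function(ev) {
    if (nrow(ev) == 0L) return(integer(length(starts)))
    bp <- ev$breakpoint[ev$contig == rg$contig &
                          ev$breakpoint >= rg$start & ev$breakpoint < rg$end]
    tabulate(findInterval(bp, starts), nbins = length(starts))
  }
  data.table::data.table(
    contig = rg$contig, bin_start = as.integer(starts),
    bin_end = as.integer(ends),
    treated_count = count_in(treated), control_count = count_in(control)
  )
}

#' Detect cut points by the treated/control split-read ratio rule
#'
#' A bin is a cut point when treated / max(control, 1) strictly exceeds
#' `ratio_threshold` (a ratio exactly equal to the threshold does not
#' qualify) and the treated count reaches `min_support`. The pseudo-
#' denominator max(control, 1) handles bins with zero control evidence.
#'
#' @param bins data.table from [bin_split_counts()].
#' @param ratio_threshold ratio that must be exceeded (default 5).
#' @param min_support minimum treated split reads in the bin (default 3).
#' @return data.table: `contig`, `bin_start`, `bin_end`, `midpoint`,
#'   `treated_count`, `control_count`, `ratio`.
#' @export
detect_cut_points <- function(bins, ratio_threshold = 5, min_support = 3L) {
  ratio <- bins$treated_count / pmax(bins$control_count, 1L)
  sel <- ratio > ratio_threshold & bins$treated_count >= min_support
  out <- data.table::data.table(
    contig = bins$contig[sel], bin_start = bins$bin_start[sel],
    bin_end = bins$bin_end[sel],
    midpoint = as.integer((bins$bin_start[sel] + bins$bin_end[sel]) %/% 2L),
    treated_count = bins$treated_count[sel],
    control_count = bins$control_count[sel], ratio = ratio[sel]
  )
  out[]
}

# single-linkage 1-D clustering: returns integer cluster ids for sorted-order
# assignment of `x` with linkage tolerance `tol`
.cluster_1d <- function(x, tol) {
  o <- order(x)
  gaps <- c(0L, diff(x[o]))
  cl_sorted <- cumsum(gaps > tol)
  cl <- integer(length(x))
  cl[o] <- cl_sorted
  cl + 1L
}

#' Infer deletion patterns from discordant pairs at cut points
#'
#' For each cut point, discordant pairs with one inner boundary within
#' `merge_tol` of the cut-point midpoint are clustered by their far
#' boundary (single linkage, tolerance `merge_tol`). Each cluster becomes
#' one deletion pattern. Breakpoints are estimated as the tightest inner
#' bounds consistent with every member pair (max of left mate ends, min of
#' right mate starts) -- pair boundaries can only under-reach a deletion
#' breakpoint, so the extremes are the least-biased pair-based estimate --
#' and are then refined to the median of exact split-read breakpoints
#' within `merge_tol` of that bound when split evidence is available.
#' Patterns duplicated across cut points (both breakpoints within
#' `merge_tol`) are collapsed, keeping the best-supported call. Cut points
#' with no supporting pairs yield no pattern.
#'
#' @param cut_points data.table from [detect_cut_points()].
#' @param pairs data.table from [extract_discordant_pairs()].
#' @param splits optional split-read evidence; when given, each pattern is
#'   annotated with the number of split reads within `merge_tol` of either
#'   breakpoint.
#' @param merge_tol clustering/matching tolerance in bp (default 150,
#'   about one read length of breakpoint uncertainty).
#' @return data.table: `contig`, `left_bp`, `right_bp`, `del_len`,
#'   `n_supporting_pairs`, `n_supporting_splits`, `cut_point`.
#' @export
infer_deletion_patterns <- function(cut_points, pairs, splits = NULL,
                                    merge_tol = 150L) {
  empty <- data.table::data.table(
    contig = character(), left_bp = integer(), right_bp = integer(),
    del_len = integer(), n_supporting_pairs = integer(),
    n_supporting_splits = integer(), cut_point = integer()
  )
  if (nrow(cut_points) == 0L || nrow(pairs) == 0L) return(empty)
  split_bp <- if (!is.null(splits) && nrow(splits)) splits else NULL
  # tightest pair-consistent bound, refined by nearby split breakpoints
  refine <- function(bound, ctg) {
    if (is.null(split_bp)) return(as.integer(bound))
    sp <- split_bp[contig == ctg & abs(breakpoint - bound) <= merge_tol]
    if (nrow(sp) == 0L) return(as.integer(bound))
    as.integer(stats::median(sp$breakpoint))
  }
  summarize_cluster <- function(dt, ctg, cp_mid) {
    dt[, list(
      contig = ctg,
      left_bp = refine(max(left_end), ctg),
      right_bp = refine(min(right_start), ctg),
      n_supporting_pairs = .N, cut_point = cp_mid
    ), by = cl][, cl := NULL]
  }
  pats <- list()
  for (i in seq_len(nrow(cut_points))) {
    cp <- cut_points[i]
    px <- pairs[contig == cp$contig]
    if (nrow(px) == 0L) next
    # cut point at the left breakpoint: cluster by right boundary
    lm <- px[abs(left_end - cp$midpoint) <= merge_tol]
    if (nrow(lm)) {
      lm[, cl := .cluster_1d(right_start, merge_tol)]
      pats[[length(pats) + 1L]] <- summarize_cluster(lm, cp$contig,
                                                     cp$midpoint)
    }
    # cut point at the right breakpoint: cluster by left boundary
    rm_ <- px[abs(right_start - cp$midpoint) <= merge_tol]
    if (nrow(rm_)) {
      rm_[, cl := .cluster_1d(left_end, merge_tol)]
      pats[[length(pats) + 1L]] <- summarize_cluster(rm_, cp$contig,
                                                     cp$midpoint)
    }
  }
  if (!length(pats)) return(empty)
  out <- data.table::rbindlist(pats)
  out <- out[left_bp < right_bp]
  if (nrow(out) == 0L) return(empty)
  # collapse duplicates across cut points: greedy by support
  data.table::setorder(out, -n_supporting_pairs, left_bp, right_bp)
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1L]) {
    prev <- which(keep[seq_len(i - 1L)])
    dup <- any(out$contig[prev] == out$contig[i] &
                 abs(out$left_bp[prev] - out$left_bp[i]) <= merge_tol &
                 abs(out$right_bp[prev] - out$right_bp[i]) <= merge_tol)
    if (dup) keep[i] <- FALSE
  }
  out <- out[keep]
  out[, del_len := right_bp - left_bp]
  if (!is.null(splits) && nrow(splits)) {
    out[, n_supporting_splits := {
      sp <- splits[contig == .BY$contig]
      vapply(seq_len(.N), function(k) {
        sum(abs(sp$breakpoint - left_bp[k]) <= merge_tol |
              abs(sp$breakpoint - right_bp[k]) <= merge_tol)
      }, integer(1L))
    }, by = contig]
  } else {
    out[, n_supporting_splits := 0L]
  }
  data.table::setorder(out, contig, left_bp, right_bp)
  data.table::setcolorder(out, c("contig", "left_bp", "right_bp", "del_len",
                                 "n_supporting_pairs",
                                 "n_supporting_splits", "cut_point"))
  out[]
}

#' Summarize maximal deletion extents relative to the PAM
#'
#' Extents are strand-oriented: for a plus-strand guide the 3' direction is
#' increasing coordinates; for a minus-strand guide it is decreasing.
#'
#' @param patterns data.table from [infer_deletion_patterns()].
#' @param pam_pos 0-based PAM coordinate of the guide.
#' @param strand guide strand ("+" or "-").
#' @return one-row data.table: `max_3p_extent`, `max_5p_extent`,
#'   `n_patterns` (zero extents when no patterns).
#' @export
summarize_extents <- function(patterns, pam_pos, strand = "+") {
  if (nrow(patterns) == 0L) {
    return(data.table::data.table(max_3p_extent = 0L, max_5p_extent = 0L,
                                  n_patterns = 0L))
  }
  right <- pmax(patterns$right_bp - pam_pos, 0L)
  left <- pmax(pam_pos - patterns$left_bp, 0L)
  if (strand == "+") {
    ext3 <- right; ext5 <- left
  } else {
    ext3 <- left; ext5 <- right
  }
  data.table::data.table(
    max_3p_extent = as.integer(max(ext3)),
    max_5p_extent = as.integer(max(ext5)),
    n_patterns = nrow(patterns)
  )
}

#' Annotate deletion patterns with neighboring-gene overlap
#'
#' A pattern overlaps a gene when its deleted interval intersects the gene
#' body; the overlap is partial when the gene is not fully contained in the
#' deletion. Fractions are n_overlapping / n_total with the percentage
#' rounded half-up to one decimal.
#'
#' @param patterns data.table from [infer_deletion_patterns()].
#' @param genes data.table of gene bodies (`contig`, `start`, `end`,
#'   `name`), e.g. from [read_bed()].
#' @return data.table: `gene`, `n_overlapping`, `n_partial`, `n_total`,
#'   `fraction`, `percent_1dp`. Empty (zero rows) when there are no
#'   patterns, since the fraction is then undefined.
#' @export
annotate_gene_overlap <- function(patterns, genes) {
  empty <- data.table::data.table(
    gene = character(), n_overlapping = integer(), n_partial = integer(),
    n_total = integer(), fraction = numeric(), percent_1dp = numeric()
  )
  n_total <- nrow(patterns)
  if (n_total == 0L || nrow(genes) == 0L) return(empty)
  res <- lapply(seq_len(nrow(genes)), function(g) {
    gn <- genes[g]
    same <- patterns$contig == gn$contig
    ovl <- same & patterns$left_bp < gn$end & patterns$right_bp > gn$start
    full <- ovl & patterns$left_bp <= gn$start & patterns$right_bp >= gn$end
    frac <- sum(ovl) / n_total
    data.table::data.table(
      gene = gn$name, n_overlapping = sum(ovl),
      n_partial = sum(ovl & !full), n_total = n_total,
      fraction = frac, percent_1dp = round_half_up(100 * frac, 1L)
    )
  })
  data.table::rbindlist(res)
}
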