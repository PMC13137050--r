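#' Score POT sites by control subtraction of split-read counts
#'
#' For each capture region, split-read breakpoints from the treated sample
#' falling inside the region are counted and the corresponding no-crRNA
#' control count is subtracted. Negative scores are retained for
#' diagnostics but never flagged; a site is flagged when its score reaches
#' `flag_threshold`.
#'
#' @param treated,control split-read evidence from [extract_split_reads()]
#'   for the treated and control libraries.
#' @param capture_regions data.table from [build_capture_regions()].
#' @param flag_threshold score at or above which a region is flagged
#'   (default 5).
#' @return data.table: one row per capture region with `kind`,
#'   `anchor_id`, `treated_splits`, `control_splits`, `score`, `flagged`.
#' @export
score_pot_sites <- function(treated, control, capture_regions,
                            flag_threshold = 5L) {
  cr <- data.table::as.data.table(capture_regions)
  if (nrow(cr) == 0L) {
    return(data.table::data.table(
      contig = character(), start = integer(), end = integer(),
      kind = character(), anchor_id = integer(),
      treated_splits = integer(), control_splits = integer(),
      score = integer(), flagged = logical()
    ))
  }
  # overlapping regions double-count shared evidence, by design
  if (nrow(cr) > 1L) {
    o <- cr[order(contig, start)]
    ovl <- any(o$contig[-1L] == o$contig[-nrow(o)] &
                 o$start[-1L] < o$end[-nrow(o)])
    if (ovl) warning("overlapping capture regions: evidence counted in each")
  }
  count_in <- function(ev, i) {
    if (nrow(ev) == 0L) return(0L)
    sum(ev$contig == cr$contig[i] & ev$breakpoint >= cr$start[i] &
          ev$breakpoint < cr$end[i])
  }
  t_n <- vapply(seq_len(nrow(cr)), function(i) count_in(treated, i), integer(1L))
  c_n <- vapply(seq_len(nrow(cr)), function(i) count_in(control, i), integer(1L))
  out <- data.table::data.table(
    contig = cr$contig, start = cr$start, end = cr$end, kind = cr$kind,
    anchor_id = cr$anchor_id, treated_splits = t_n, control_splits = c_n,
    score = t_n - c_n
  )
  out[, flagged := score >= flag_threshold]
  out[]
}

#' Windowed indel quantification with control subtraction (Cas9 mode)
#'
#' A read covers the quantification window when its aligned reference span
#' overlaps the window; it counts as edited when any insertion or deletion
#' CIGAR operation overlaps the window (insertions at a boundary position
#' inside the window count). The adjusted percentage subtracts the control
#' and clamps at zero.
#'
#' @param test_records,control_records data.tables from
#'   [read_alignments()].
#' @param contig contig of the expected cut site.
#' @param cut_pos 0-based coordinate of the expected cut (for Cas9, 3 bp
#'   5' of the PAM).
#' @param window_halfwidth half-width of the quantification window in bp
#'   (default 20).
#' @param mapq_floor minimum mapping quality (default 20).
#' @return list with `window` (contig/start/end), `test_indel_pct`,
#'   `control_indel_pct`, `adjusted_pct`, and per-sample read counts.
#'   Percentages are `NA` for a sample with zero covering reads, and
#'   `adjusted_pct` is `NA` if either side is undefined.
#' @export
adjusted_indel <- function(test_records, control_records, contig, cut_pos,
                           window_halfwidth = 20L, mapq_floor = 20L) {
  w_start <- cut_pos - window_halfwidth
  w_end <- cut_pos + window_halfwidth
  quantify <- function(records) {
    if (nrow(records) == 0L) return(c(covering = 0L, edited = 0L))
    ok <- !records$unmapped & !records$secondary & !records$supplementary &
      records$mapq >= mapq_floor & records$contig == contig &
      records$cigar != "*"
    rec <- records[ok]
    if (nrow(rec) == 0L) return(c(covering = 0L, edited = 0L))
    cs <- cigar_stats(rec$cigar)
    span_end <- rec$pos + cs$ref_span
    cov <- rec$pos < w_end & span_end > w_start
    rec <- rec[cov]
    if (nrow(rec) == 0L) return(c(covering = 0L, edited = 0L))
    ops <- .cigar_ref_ops(rec[, list(pos, cigar)])
    indel <- ops[op %chin% c("I", "D")]
    edited_rows <- unique(indel[
      (op == "D" & ref_start < w_end & ref_end > w_start) |
        (op == "I" & ref_start >= w_start & ref_start <= w_end)
    ]$row)
    c(covering = nrow(rec), edited = length(edited_rows))
  }
  tq <- quantify(test_records)
  cq <- quantify(control_records)
  pct <- function(q) if (q["covering"] == 0L) NA_real_ else
    100 * q[["edited"]] / q[["covering"]]
  test_pct <- pct(tq); control_pct <- pct(cq)
  adj <- if (is.na(test_pct) || is.na(control_pct)) NA_real_ else
    max(test_pct - control_pct, 0)
  list(
    window = list(contig = contig, start = w_start, end = w_end),
    test_covering = unname(tq["covering"]), test_edited = unname(tq["edited"]),
    control_covering = unname(cq["covering"]),
    control_edited = unname(cq["edited"]),
    test_indel_pct = test_pct, control_indel_pct = control_pct,
    adjusted_pct = adj
  )
}
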