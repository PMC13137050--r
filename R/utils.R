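#' Round half-up
#'
#' Deterministic half-up rounding (0.05 at one decimal always rounds to 0.1),
#' unlike [base::round()]'s round-half-even. Used for all reported
#' percentages so printed values never depend on banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  # tiny epsilon guards against binary representation of exact halves
  floor(x * m + 0.5 + 1e-9) / m
}

# --- CIGAR arithmetic ---------------------------------------------------
# CIGARs are parsed once per unique string and broadcast back; libraries of
# hundreds of thousands of records carry only a few thousand distinct CIGARs.

.cigar_op_table <- function(u) {
  toks <- regmatches(u, gregexpr("\\d+[MIDNSHP=X]", u))
  n_ops <- lengths(toks)
  bad <- n_ops == 0L & u != "*"
  if (any(bad)) {
    stop("malformed CIGAR string(s): ", paste(utils::head(u[bad], 3L), collapse = ", "))
  }
  flat <- unlist(toks, use.names = FALSE)
  data.table::data.table(
    cid = rep(seq_along(u), n_ops),
    op  = substr(flat, nchar(flat), nchar(flat)),
    len = as.integer(substr(flat, 1L, nchar(flat) - 1L))
  )
}

#' Per-CIGAR summary statistics
#'
#' @param cigars character vector of CIGAR strings ("*" allowed).
#' @return data.table aligned with `cigars`: `ref_span` (bases consumed on
#'   the reference), `query_len` (bases consumed on the query, excluding hard
#'   clips), `left_clip`, `right_clip` (soft-clip lengths at either end).
#' @keywords internal
cigar_stats <- function(cigars) {
  u <- unique(cigars)
  ops <- .cigar_op_table(u)
  ref_span <- query_len <- left_clip <- right_clip <- integer(length(u))
  if (nrow(ops)) {
    rs <- ops[op %chin% c("M", "D", "N", "=", "X"), list(v = sum(len)), by = cid]
    ref_span[rs$cid] <- rs$v
    ql <- ops[op %chin% c("M", "I", "S", "=", "X"), list(v = sum(len)), by = cid]
    query_len[ql$cid] <- ql$v
    # soft clips: first/last op ignoring hard clips
    soft <- ops[op != "H"]
    if (nrow(soft)) {
      lc <- soft[, list(op = op[1L], len = len[1L]), by = cid][op == "S"]
      left_clip[lc$cid] <- lc$len
      rc <- soft[, list(op = op[.N], len = len[.N]), by = cid][op == "S"]
      right_clip[rc$cid] <- rc$len
    }
  }
  i <- match(cigars, u)
  data.table::data.table(
    ref_span = ref_span[i], query_len = query_len[i],
    left_clip = left_clip[i], right_clip = right_clip[i]
  )
}

# Expand CIGARs of a record table into per-op reference coordinates.
# records needs columns pos (0-based) and cigar; returns one row per op with
# ref_start/ref_end (half-open; zero-width for query-only ops).
.cigar_ref_ops <- function(records) {
  u <- unique(records$cigar)
  ops <- .cigar_op_table(u)
  ops[, consumes_ref := op %chin% c("M", "D", "N", "=", "X")]
  ops[, ref_off := cumsum(data.table::shift(len * consumes_ref, fill = 0L)), by = cid]
  idx <- match(records$cigar, u)
  out <- ops[data.table::data.table(cid = idx, row = seq_along(idx), pos = records$pos),
             on = "cid", allow.cartesian = TRUE]
  out[, ref_start := pos + ref_off]
  out[, ref_end := ref_start + len * consumes_ref]
  out[]
}

.stopifnot_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(what, " must be a non-empty character scalar")
  }
}
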