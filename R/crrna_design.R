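#' Design parameters for Cas3 crRNA screening
#'
#' Defaults implement the screening criteria used throughout the package:
#' a 5'-AAG PAM, a 32-nt protospacer, GC content between 30% and 70%
#' (inclusive), a target site 100-500 bp downstream of the target exon in
#' the transcription direction, a 3-mismatch budget for the genome-wide
#' PAM+protospacer uniqueness scan (PAM exact), and an exact-match
#' PAM + 15-nt seed uniqueness clause.
#'
#' @param pam PAM sequence, 5' of the protospacer (default "AAG").
#' @param spacer_len protospacer length in nt (default 32).
#' @param gc_min,gc_max inclusive GC-content bounds as fractions.
#' @param window_min,window_max candidate window in bp downstream of the
#'   target exon's 3' end, measured to the PAM-proximal end of the
#'   protospacer.
#' @param design_mm_max mismatches tolerated over the protospacer in the
#'   uniqueness scan (PAM must match exactly).
#' @param seed_len PAM-proximal seed length for the exact-match clause.
#' @return a `design_params` list.
#' @export
design_params <- function(pam = "AAG", spacer_len = 32L,
                          gc_min = 0.30, gc_max = 0.70,
                          window_min = 100L, window_max = 500L,
                          design_mm_max = 3L, seed_len = 15L) {
  .stopifnot_scalar_string(pam, "pam")
  pam <- toupper(pam)
  if (grepl("[^ACGT]", pam)) stop("pam must contain only A/C/G/T")
  stopifnot(gc_min >= 0, gc_min <= gc_max, gc_max <= 1,
            window_min < window_max, spacer_len > seed_len,
            design_mm_max >= 0L, seed_len > 0L)
  structure(list(pam = pam, spacer_len = as.integer(spacer_len),
                 gc_min = gc_min, gc_max = gc_max,
                 window_min = as.integer(window_min),
                 window_max = as.integer(window_max),
                 design_mm_max = as.integer(design_mm_max),
                 seed_len = as.integer(seed_len)),
            class = "design_params")
}

#' GC content of a sequence
#'
#' @param seq a non-empty A/C/G/T string (N is an error: spacers containing
#'   N are rejected before this point).
#' @return fraction of G+C bases, in \[0, 1\].
#' @export
gc_content <- function(seq) {
  .stopifnot_scalar_string(seq, "seq")
  up <- toupper(seq)
  if (grepl("[^ACGT]", up)) stop("gc_content: sequence must be A/C/G/T only")
  ch <- strsplit(up, "", fixed = TRUE)[[1]]
  sum(ch %in% c("G", "C")) / length(ch)
}

# vectorised GC over many spacers (no validation; internal)
.gc_vec <- function(seqs) {
  (nchar(gsub("[^GC]", "", seqs))) / nchar(seqs)
}

#' Scan a window downstream of a target exon for crRNA candidates
#'
#' Both genome strands are scanned. A candidate is a PAM + protospacer site
#' whose PAM equals `params$pam` on the candidate's strand, whose
#' protospacer GC content lies within the inclusive bounds, and whose
#' PAM-proximal protospacer end lies `window_min`..`window_max` bp
#' downstream of the exon's 3' end in the gene's transcription direction
#' (taken from `target_exon$strand`). Protospacers containing N are
#' rejected. In audit mode every PAM match in the window is emitted with
#' its rejection reasons.
#'
#' @param genome named `DNAStringSet`.
#' @param target_exon one-row data.frame/list with `contig`, `start`, `end`
#'   (0-based half-open) and `strand` ("+" or "-": transcription direction).
#' @param params a [design_params()] object.
#' @param gene gene symbol carried into the output (default "gene").
#' @param audit if TRUE, also emit failing sites with `rejection_reasons`.
#' @return data.table of candidates: `id`, `target_gene`, `contig`,
#'   `start`, `end`, `strand`, `pam_seq`, `spacer_seq`, `gc`,
#'   `distance_from_exon`, `passes_filters`, `rejection_reasons`.
#' @export
scan_candidates <- function(genome, target_exon, params = design_params(),
                            gene = "gene", audit = FALSE) {
  te <- as.list(target_exon)
  if (!te$strand %in% c("+", "-")) stop("target_exon$strand must be + or -")
  ctg <- te$contig
  Lc <- unname(contig_lengths(genome)[ctg])
  if (is.na(Lc)) stop("target exon on unknown contig: ", ctg)
  if (te$start < 0L || te$end > Lc) stop("target exon outside contig bounds")
  plen <- nchar(params$pam)
  L <- plen + params$spacer_len
  e3 <- if (te$strand == "+") te$end else te$start  # exon 3' boundary
  fwd <- .contig_string(genome, ctg)

  # enumerate site start positions whose PAM-proximal protospacer end falls
  # inside the window, for each site strand
  rows <- list()
  for (std in c("+", "-")) {
    # anchor a = PAM-proximal protospacer boundary (0-based boundary coord)
    if (te$strand == "+") {
      anchors <- (e3 + params$window_min):(e3 + params$window_max)
    } else {
      anchors <- (e3 - params$window_max):(e3 - params$window_min)
    }
    start <- if (std == "+") anchors - plen else anchors - params$spacer_len
    ok <- start >= 0L & start + L <= Lc
    start <- start[ok]; anchors <- anchors[ok]
    if (!length(start)) {
      warning("candidate window extends past contig end; scan truncated")
      next
    }
    if (length(ok) && !all(ok)) {
      warning("candidate window extends past contig end; scan truncated")
    }
    site <- substring(fwd, start + 1L, start + L)
    site_std <- if (std == "+") site else reverse_complement(site)
    pam_seq <- substr(site_std, 1L, plen)
    spacer <- substr(site_std, plen + 1L, L)
    dist <- if (te$strand == "+") anchors - e3 else e3 - anchors
    pam_hit <- pam_seq == params$pam
    if (!any(pam_hit)) next
    has_n <- grepl("N", spacer, fixed = TRUE)
    gc <- ifelse(has_n, NA_real_, .gc_vec(spacer))
    keep <- pam_hit
    dt <- data.table::data.table(
      target_gene = gene, contig = ctg,
      start = start[keep], end = start[keep] + L, strand = std,
      pam_seq = pam_seq[keep], spacer_seq = spacer[keep], gc = gc[keep],
      distance_from_exon = as.integer(dist[keep]),
      has_n = has_n[keep]
    )
    rows[[length(rows) + 1L]] <- dt
  }
  out <- data.table::rbindlist(rows)
  if (nrow(out) == 0L) {
    return(data.table::data.table(
      id = character(), target_gene = character(), contig = character(),
      start = integer(), end = integer(), strand = character(),
      pam_seq = character(), spacer_seq = character(), gc = numeric(),
      distance_from_exon = integer(), passes_filters = logical(),
      rejection_reasons = character()
    ))
  }
  reasons <- vector("list", nrow(out))
  r <- character(nrow(out))
  fail_n <- out$has_n
  fail_lo <- !fail_n & out$gc < params$gc_min
  fail_hi <- !fail_n & out$gc > params$gc_max
  r[fail_n] <- "spacer_contains_N"
  r[fail_lo] <- "gc_below_min"
  r[fail_hi] <- "gc_above_max"
  out[, passes_filters := !(fail_n | fail_lo | fail_hi)]
  out[, rejection_reasons := r]
  out[, has_n := NULL]
  if (!audit) out <- out[passes_filters == TRUE]
  data.table::setorder(out, start, strand)
  if (nrow(out)) {
    out[, id := sprintf("%s_crRNA_%02d", gene, seq_len(.N))]
  } else {
    out[, id := character(0)]
  }
  data.table::setcolorder(out, c("id", "target_gene", "contig", "start",
                                 "end", "strand", "pam_seq", "spacer_seq",
                                 "gc", "distance_from_exon",
                                 "passes_filters", "rejection_reasons"))
  out[]
}

#' Genome-uniqueness check for a crRNA candidate
#'
#' A candidate fails if (a) any locus other than its own matches the full
#' PAM + protospacer with at most `design_mm_max` mismatches over the
#' protospacer and an exact PAM, on either strand, or (b) any other locus
#' carries an exact match of PAM + the PAM-proximal `seed_len` nt of the
#' protospacer. "No significant matches" is operationalised as zero such
#' hits.
#'
#' @param candidate one row of [scan_candidates()] output.
#' @param genome named `DNAStringSet`.
#' @param params a [design_params()] object.
#' @return list with `passes` (logical) and `hits` (data.table of offending
#'   loci with columns `contig`, `start`, `end`, `strand`, `spacer_mm`,
#'   `seed_exact`).
#' @export
uniqueness_check <- function(candidate, genome, params = design_params()) {
  cd <- as.list(candidate)
  plen <- nchar(params$pam)
  pattern <- paste0(cd$pam_seq, cd$spacer_seq)
  full <- .scan_genome(genome, pattern, pam_len = plen, pam_side = "left",
                       mm_max = params$design_mm_max)
  own <- full$contig == cd$contig & full$start == cd$start &
    full$strand == cd$strand
  full <- full[!own]
  seed_pat <- paste0(cd$pam_seq, substr(cd$spacer_seq, 1L, params$seed_len))
  seed <- .scan_genome(genome, seed_pat, pam_len = plen, pam_side = "left",
                       mm_max = 0L)
  # seed hit at the candidate's own PAM position (strand-aware)
  own_seed_start <- if (cd$strand == "+") cd$start else
    cd$end - plen - params$seed_len
  own <- seed$contig == cd$contig & seed$start == own_seed_start &
    seed$strand == cd$strand
  seed <- seed[!own]
  hits <- data.table::rbindlist(list(
    data.table::data.table(
      contig = character(), start = integer(), end = integer(),
      strand = character(), spacer_mm = integer(), seed_exact = logical()),
    if (nrow(full)) data.table::data.table(
      contig = full$contig, start = full$start, end = full$end,
      strand = full$strand, spacer_mm = full$spacer_mm, seed_exact = FALSE),
    if (nrow(seed)) data.table::data.table(
      contig = seed$contig, start = seed$start,
      end = seed$start + plen + params$seed_len,
      strand = seed$strand, spacer_mm = NA_integer_, seed_exact = TRUE)
  ))
  list(passes = nrow(hits) == 0L, hits = hits)
}

#' Full crRNA design screen: window scan plus uniqueness filter
#'
#' @inheritParams scan_candidates
#' @return the [scan_candidates()] table with `passes_uniqueness` and
#'   `n_offsite_hits` columns appended (uniqueness evaluated only for
#'   candidates passing the window filters).
#' @export
design_crrnas <- function(genome, target_exon, params = design_params(),
                          gene = "gene", audit = FALSE) {
  cand <- scan_candidates(genome, target_exon, params, gene, audit)
  cand[, passes_uniqueness := NA]
  cand[, n_offsite_hits := NA_integer_]
  for (i in which(cand$passes_filters)) {
    u <- uniqueness_check(cand[i], genome, params)
    data.table::set(cand, i, "passes_uniqueness", u$passes)
    data.table::set(cand, i, "n_offsite_hits", nrow(u$hits))
  }
  cand[]
}
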