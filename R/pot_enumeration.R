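#' Parameters for potential off-target (POT) enumeration
#'
#' Cas3 POT sites satisfy either rule: a contiguous exact match of at least
#' `consec_min` nt to PAM + protospacer that overlaps at least
#' `consec_pam_bases` PAM base(s), or an exact PAM with at most
#' `mm_max_cas3` mismatches over the full 32-nt protospacer. Cas9 POT sites
#' have an NGG-pattern PAM (N wildcard over A/C/G/T) and at most
#' `mm_max_cas9` mismatches over the 20-nt guide. `consec_max` is recorded
#' for reference only: longer runs always still qualify, so `consec_min` is
#' the single active bound and the observed run length is reported.
#'
#' @param mode "cas3" or "cas9".
#' @param consec_min,consec_max consecutive-match rule bounds in nt.
#' @param mm_max_cas3 mismatch budget over the 32-nt Cas3 spacer.
#' @param mm_max_cas9 mismatch budget over the 20-nt Cas9 guide.
#' @param cas9_pam Cas9 PAM pattern, 3' of the protospacer (default "NGG").
#' @param consec_pam_bases how many PAM bases a qualifying run must include
#'   (1 = overlap any PAM base; 3 = span the whole PAM).
#' @param merge_radius qualifying loci on the same strand offset by less
#'   than this many bp are merged into one site, keeping the best match.
#' @return a `pot_params` list.
#' @export
pot_params <- function(mode = c("cas3", "cas9"), consec_min = 16L,
                       consec_max = 20L, mm_max_cas3 = 7L, mm_max_cas9 = 3L,
                       cas9_pam = "NGG", consec_pam_bases = 1L,
                       merge_radius = 10L) {
  mode <- match.arg(mode)
  stopifnot(consec_min <= consec_max, mm_max_cas3 >= 0L, mm_max_cas9 >= 0L,
            consec_pam_bases >= 1L, merge_radius >= 0L)
  structure(list(mode = mode, consec_min = as.integer(consec_min),
                 consec_max = as.integer(consec_max),
                 mm_max_cas3 = as.integer(mm_max_cas3),
                 mm_max_cas9 = as.integer(mm_max_cas9),
                 cas9_pam = toupper(cas9_pam),
                 consec_pam_bases = as.integer(consec_pam_bases),
                 merge_radius = as.integer(merge_radius)),
            class = "pot_params")
}

# Merge same-strand qualifying loci whose starts differ by < merge_radius,
# keeping the best-matching representative (fewest spacer mismatches among
# PAM-exact loci, then longest PAM-anchored run).
.merge_pot <- function(dt, merge_radius) {
  if (nrow(dt) < 2L || merge_radius <= 0L) return(dt)
  data.table::setorder(dt, contig, strand, start)
  n <- nrow(dt)
  same_block <- c(FALSE, dt$contig[-1L] == dt$contig[-n] &
                    dt$strand[-1L] == dt$strand[-n])
  gap <- c(Inf, diff(dt$start))
  new_grp <- !(same_block & gap < merge_radius)
  dt[, .grp := cumsum(new_grp)]
  dt[, .rank := ifelse(pam_ok, spacer_mm, 999L) * 1000L - pam_run]
  out <- dt[dt[, .I[which.min(.rank)], by = .grp]$V1]
  out[, c(".grp", ".rank") := NULL]
  out[]
}

.finish_pot <- function(hits, genome, params, on_target, merge) {
  if (nrow(hits) == 0L) {
    return(data.table::data.table(
      contig = character(), start = integer(), end = integer(),
      strand = character(), rule = character(),
      longest_pam_anchored_run = integer(), n_mismatches = integer(),
      site_seq = character(), is_on_target = logical()
    ))
  }
  if (merge) hits <- .merge_pot(hits, params$merge_radius)
  hits[, rule := data.table::fcase(
    mm_rule & consec_rule, "both",
    mm_rule, "mismatch_tolerant",
    consec_rule, "consecutive"
  )]
  data.table::setnames(hits, c("pam_run", "spacer_mm"),
                       c("longest_pam_anchored_run", "n_mismatches"))
  hits[, site_seq := .site_seq(genome, contig[1L], start, end, strand),
       by = contig]
  hits[, is_on_target := FALSE]
  if (!is.null(on_target)) {
    ot <- as.list(on_target)
    hits[contig == ot$contig & start == ot$start & strand == ot$strand,
         is_on_target := TRUE]
  }
  hits[, c("pam_ok", "mm_rule", "consec_rule") := NULL]
  data.table::setorder(hits, contig, start, strand)
  hits[]
}

#' Enumerate Cas3 potential off-target sites genome-wide
#'
#' Both strands of every contig are scanned for loci qualifying under the
#' consecutive-match rule (exact run of >= `consec_min` nt overlapping the
#' PAM) or the mismatch-tolerant rule (exact PAM, <= `mm_max_cas3`
#' mismatches over the full 32-nt protospacer). The on-target locus itself
#' qualifies and is flagged when its coordinates are supplied.
#'
#' @param spacer the 32-nt protospacer sequence (guide, genomic top-strand
#'   orientation at the target).
#' @param genome named `DNAStringSet`.
#' @param params a [pot_params()] object.
#' @param pam the guide's PAM (default "AAG").
#' @param on_target optional list/row with `contig`, `start`, `strand` of
#'   the intended target locus, flagged in the output.
#' @param merge merge near-duplicate loci (<`merge_radius` bp offset)?
#'   Disable to compare against per-position oracles.
#' @return data.table of POT sites: `contig`, `start`, `end`, `strand`,
#'   `rule` (consecutive / mismatch_tolerant / both),
#'   `longest_pam_anchored_run`, `n_mismatches`, `site_seq`,
#'   `is_on_target`.
#' @export
find_pot_sites_cas3 <- function(spacer, genome, params = pot_params(),
                                pam = "AAG", on_target = NULL,
                                merge = TRUE) {
  .stopifnot_scalar_string(spacer, "spacer")
  spacer <- toupper(spacer)
  if (nchar(spacer) != 32L) stop("Cas3 spacer must be 32 nt")
  pattern <- paste0(toupper(pam), spacer)
  run_starts <- if (params$consec_pam_bases >= nchar(pam)) 1L else
    seq_len(nchar(pam) - params$consec_pam_bases + 1L)
  hits <- .scan_genome(genome, pattern, pam_len = nchar(pam),
                       pam_side = "left", mm_max = params$mm_max_cas3,
                       consec_min = params$consec_min,
                       run_starts = run_starts)
  .finish_pot(hits, genome, params, on_target, merge)
}

#' Enumerate Cas9 potential off-target sites genome-wide
#'
#' Loci with an `NGG`-pattern PAM 3' of the protospacer and at most
#' `mm_max_cas9` mismatches over the 20-nt guide, on both strands.
#'
#' @param guide20 the 20-nt Cas9 guide sequence.
#' @inheritParams find_pot_sites_cas3
#' @return data.table as in [find_pot_sites_cas3()] (rule is always
#'   "mismatch_tolerant"; `longest_pam_anchored_run` is 0).
#' @export
find_pot_sites_cas9 <- function(guide20, genome, params = pot_params("cas9"),
                                on_target = NULL, merge = TRUE) {
  .stopifnot_scalar_string(guide20, "guide20")
  guide20 <- toupper(guide20)
  if (nchar(guide20) != 20L) stop("Cas9 guide must be 20 nt")
  pattern <- paste0(guide20, params$cas9_pam)
  hits <- .scan_genome(genome, pattern, pam_len = nchar(params$cas9_pam),
                       pam_side = "right", pam_wildcard = TRUE,
                       mm_max = params$mm_max_cas9)
  .finish_pot(hits, genome, params, on_target, merge)
}

#' Build capture regions around on-target and POT anchors
#'
#' On-target regions span 100 kbp upstream and 100 kbp downstream of the
#' PAM. POT regions span 9 kbp on the PAM-upstream side and 1 kbp on the
#' PAM-downstream side in the site's strand orientation (matching the
#' directionality of Cas3 degradation). Regions are clipped at contig
#' edges with a warning.
#'
#' @param anchors data.table of anchor loci (`contig`, `start`, `end`,
#'   `strand`; e.g. POT sites or a target locus).
#' @param genome named `DNAStringSet`.
#' @param kind "on_target" or "pot".
#' @param on_flank half-width of on-target regions (default 100000).
#' @param pot_up,pot_down POT flanks in bp (defaults 9000 and 1000).
#' @return data.table: `contig`, `start`, `end`, `strand`, `kind`,
#'   `anchor_id` (row index into `anchors`).
#' @export
build_capture_regions <- function(anchors, genome,
                                  kind = c("on_target", "pot"),
                                  on_flank = 100000L, pot_up = 9000L,
                                  pot_down = 1000L) {
  kind <- match.arg(kind)
  anchors <- data.table::as.data.table(anchors)
  if (nrow(anchors) == 0L) {
    return(data.table::data.table(
      contig = character(), start = integer(), end = integer(),
      strand = character(), kind = character(), anchor_id = integer()
    ))
  }
  lens <- contig_lengths(genome)
  if (any(!anchors$contig %in% names(lens))) {
    stop("anchor on unknown contig")
  }
  Lc <- unname(lens[anchors$contig])
  if (any(anchors$start < 0L | anchors$end > Lc)) {
    stop("anchor outside contig bounds")
  }
  if (kind == "on_target") {
    # PAM boundary: site start on '+' (PAM is the left end of the locus),
    # site end on '-'
    pam_pt <- ifelse(anchors$strand == "-", anchors$end, anchors$start)
    start <- pam_pt - on_flank
    end <- pam_pt + on_flank
  } else {
    neg <- anchors$strand == "-"
    start <- ifelse(neg, anchors$start - pot_down, anchors$start - pot_up)
    end <- ifelse(neg, anchors$end + pot_up, anchors$end + pot_down)
  }
  clipped <- start < 0L | end > Lc
  if (any(clipped)) {
    warning(sum(clipped), " capture region(s) clipped at contig edges")
  }
  data.table::data.table(
    contig = anchors$contig,
    start = as.integer(pmax(start, 0L)),
    end = as.integer(pmin(end, Lc)),
    strand = anchors$strand, kind = kind,
    anchor_id = seq_len(nrow(anchors))
  )
}
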