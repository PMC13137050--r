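# Hand-built alignment records in the read_alignments() layout, for unit
# tests that need precise CIGAR/flag control without a SAM round trip.
make_records <- function(qname, flag = 0L, contig = "c1", pos = 0L,
                         mapq = 60L, cigar = "100M", rnext = "=",
                         pnext = 0L, tlen = 0L, seq = "*") {
  n <- max(lengths(list(qname, flag, pos, cigar)))
  dt <- data.table::data.table(
    qname = rep_len(qname, n), flag = as.integer(rep_len(flag, n)),
    contig = rep_len(contig, n), pos = as.integer(rep_len(pos, n)),
    mapq = as.integer(rep_len(mapq, n)), cigar = rep_len(cigar, n),
    rnext = rep_len(rnext, n), pnext = as.integer(rep_len(pnext, n)),
    tlen = as.integer(rep_len(tlen, n)), seq = rep_len(seq, n)
  )
  dt[, unmapped := bitwAnd(flag, 4L) > 0L]
  dt[, secondary := bitwAnd(flag, 256L) > 0L]
  dt[, supplementary := bitwAnd(flag, 2048L) > 0L]
  dt[, paired := bitwAnd(flag, 1L) > 0L]
  dt[, proper := bitwAnd(flag, 2L) > 0L]
  dt[, reverse := bitwAnd(flag, 16L) > 0L]
  dt[, mate_reverse := bitwAnd(flag, 32L) > 0L]
  dt[, mate_unmapped := bitwAnd(flag, 8L) > 0L]
  dt[, first_in_pair := bitwAnd(flag, 64L) > 0L]
  dt[, strand := ifelse(reverse, "-", "+")]
  dt[]
}

# one FR read pair: R1 forward at pos1, R2 reverse at pos2 (both 0-based),
# read length rl; tlen = outer span
make_pair <- function(qname, pos1, pos2, rl = 150L, contig = "c1",
                      cigar1 = paste0(rl, "M"), cigar2 = paste0(rl, "M"),
                      proper = FALSE, mapq = 60L) {
  outer <- (pos2 + rl) - pos1
  base <- 1L + ifelse(proper, 2L, 0L)
  rbind(
    make_records(qname, flag = base + 32L + 64L, contig = contig,
                 pos = pos1, cigar = cigar1, pnext = pos2, tlen = outer,
                 mapq = mapq),
    make_records(qname, flag = base + 16L + 128L, contig = contig,
                 pos = pos2, cigar = cigar2, pnext = pos1, tlen = -outer,
                 mapq = mapq)
  )
}

# a batch of proper FR pairs to anchor insert-size estimation at ~400 +/- 60
proper_pair_batch <- function(n = 50L, contig = "c1", start0 = 10000L) {
  set.seed(99)
  flen <- as.integer(round(rnorm(n, 400, 60)))
  pos1 <- start0 + seq_len(n) * 10L
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_pair(sprintf("pp%03d", i), pos1[i], pos1[i] + flen[i] - 150L,
              contig = contig, proper = TRUE)
  }))
}

# split-read evidence table from scratch
make_splits <- function(breakpoints, contig = "c1", clip_side = "right",
                        clip_len = 30L) {
  data.table::data.table(
    qname = sprintf("s%04d", seq_along(breakpoints)), contig = contig,
    breakpoint = as.integer(breakpoints),
    clip_side = rep_len(clip_side, length(breakpoints)),
    clip_len = as.integer(rep_len(clip_len, length(breakpoints)))
  )
}

# deletion-pattern table from explicit breakpoints
make_patterns <- function(left, right, contig = "c1") {
  data.table::data.table(
    contig = contig, left_bp = as.integer(left), right_bp = as.integer(right),
    del_len = as.integer(right - left),
    n_supporting_pairs = 10L, n_supporting_splits = 0L,
    cut_point = as.integer(left)
  )
}

# pattern set with a prescribed number of gene-overlapping members: n_overlap
# deletions clip into the gene from the right (partial), the rest sit clear
overlap_fixture <- function(n_total, n_overlap, gene_start = 10000L,
                            gene_end = 12000L) {
  stopifnot(n_overlap <= n_total)
  lefts <- c(rep(gene_end - 500L, n_overlap),
             rep(gene_end + 5000L, n_total - n_overlap))
  rights <- lefts + 20000L
  list(
    patterns = make_patterns(lefts, rights),
    genes = data.table::data.table(contig = "c1", start = gene_start,
                                   end = gene_end, name = "GENE",
                                   strand = "+")
  )
}
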