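test_that("split-read extraction does CIGAR boundary arithmetic correctly", {
  rec <- rbind(
    make_records("right", pos = 1000L, cigar = "70M30S"),
    make_records("left", pos = 500L, cigar = "25S75M"),
    make_records("short", pos = 2000L, cigar = "90M10S"),
    make_records("both", pos = 3000L, cigar = "40S60M40S")
  )
  ev <- extract_split_reads(rec, min_clip = 20L)
  expect_identical(ev[qname == "right"]$breakpoint, 1070L)
  expect_identical(ev[qname == "right"]$clip_side, "right")
  expect_identical(ev[qname == "left"]$breakpoint, 500L)
  expect_identical(ev[qname == "left"]$clip_side, "left")
  expect_false("short" %in% ev$qname)  # 10 < min_clip
  expect_identical(nrow(ev[qname == "both"]), 2L)
  # deletions consume reference: 30M100D40M10S clips at pos+170
  rec2 <- make_records("del", pos = 0L, cigar = "30M100D40M30S")
  expect_identical(extract_split_reads(rec2, 20L)$breakpoint, 170L)
})

test_that("low-mapq, secondary and unmapped records yield no evidence", {
  rec <- rbind(
    make_records("lowq", pos = 100L, cigar = "50M50S", mapq = 5L),
    make_records("sec", flag = 256L, pos = 100L, cigar = "50M50S"),
    make_records("unm", flag = 4L, pos = 100L, cigar = "*")
  )
  expect_identical(nrow(extract_split_reads(rec, 20L, mapq_floor = 20L)), 0L)
})

test_that("discordant pairs are detected by span and by orientation", {
  anchor <- proper_pair_batch()
  # FR pair with normal insert: concordant
  normal <- make_pair("n1", 5000L, 5100L, proper = TRUE)
  # FR pair straddling a 50-kb deletion: outer span ~50350
  del <- make_pair("d1", 9900L, 60100L)
  # RF pair with small span: discordant by orientation
  rf <- rbind(
    make_records("r1", flag = 1L + 16L + 64L, pos = 7000L, cigar = "150M",
                 pnext = 7200L, tlen = 350L),
    make_records("r1", flag = 1L + 32L + 128L, pos = 7200L, cigar = "150M",
                 pnext = 7000L, tlen = -350L)
  )
  pairs <- extract_discordant_pairs(rbind(anchor, normal, del, rf))
  expect_false("n1" %in% pairs$qname)
  d <- pairs[qname == "d1"]
  expect_identical(d$left_end, 10050L)
  expect_identical(d$right_start, 60100L)
  expect_gt(d$outer_span, 50000L)
  expect_true("r1" %in% pairs$qname)
  expect_false(pairs[qname == "r1"]$fr)
})

test_that("a simulated pair across a planted deletion spans the gap", {
  # fragment of 350 bp crossing a [10000, 60000) deletion through the gap:
  # R1 ends at 9950+150 = 10100 < 10000? place R1 fully left, R2 fully right
  p <- make_pair("x", 9800L, 60050L)  # R1 [9800,9950), R2 [60050,60200)
  pairs <- extract_discordant_pairs(rbind(proper_pair_batch(), p))
  x <- pairs[qname == "x"]
  expect_identical(x$left_end, 9950L)
  expect_identical(x$right_start, 60050L)
  # the reported span covers the deleted interval boundaries
  expect_lte(x$left_end, 10000L)
  expect_gte(x$right_start, 10000L)
})

test_that("binned split counts conserve the in-region evidence total", {
  ev <- make_splits(c(1010, 1020, 1090, 1150, 1160))
  bins <- bin_split_counts(ev, make_splits(integer(0)),
                           list(contig = "c1", start = 1000L, end = 1200L),
                           bin_width = 100L)
  expect_identical(bins$treated_count, c(3L, 2L))
  expect_identical(bins$control_count, c(0L, 0L))

  empty <- bin_split_counts(make_splits(integer(0)), make_splits(integer(0)),
                            list(contig = "c1", start = 0L, end = 1000L))
  expect_true(all(empty$treated_count == 0L))

  set.seed(7)
  bp <- sample(0:49999, 700, replace = TRUE)
  ev2 <- make_splits(bp)
  region <- list(contig = "c1", start = 5000L, end = 30000L)
  bins2 <- bin_split_counts(ev2, ev2, region, 100L)
  direct <- sum(bp >= 5000 & bp < 30000)
  expect_identical(sum(bins2$treated_count), direct)
  expect_identical(sum(bins2$control_count), direct)
  # bins tile the region without overlap
  expect_identical(bins2$bin_start[-1L], bins2$bin_end[-nrow(bins2)])
})

test_that("cut-point rule is strict: ratio must exceed the threshold", {
  bins <- data.table::data.table(
    contig = "c1", bin_start = c(0L, 100L, 200L, 300L),
    bin_end = c(100L, 200L, 300L, 400L),
    treated_count = c(12L, 10L, 8L, 2L),
    control_count = c(2L, 2L, 0L, 0L)
  )
  cp <- detect_cut_points(bins, ratio_threshold = 5, min_support = 3L)
  expect_identical(cp$bin_start, c(0L, 200L))  # 6 > 5; 5 == 5 fails; 8/1 > 5
  # treated 2 fails min_support even at infinite ratio
  expect_false(300L %in% cp$bin_start)
  # monotonicity: raising the threshold never adds cut points
  for (thr in c(3, 5, 7, 11)) {
    lo <- detect_cut_points(bins, thr, 3L)
    hi <- detect_cut_points(bins, thr + 1, 3L)
    expect_true(all(hi$bin_start %in% lo$bin_start))
  }
})

test_that("deletion patterns are recovered from clustered discordant pairs", {
  anchor <- proper_pair_batch()
  # ten pairs across a planted deletion [10000, 60000): inner boundaries
  # scatter within ~100 bp of the true breakpoints
  set.seed(13)
  offs <- sample(0:80, 10)
  pairs_rec <- do.call(rbind, lapply(1:10, function(i) {
    make_pair(sprintf("dp%02d", i), 9850L - offs[i], 60010L + offs[i])
  }))
  pairs <- extract_discordant_pairs(rbind(anchor, pairs_rec))
  cp <- data.table::data.table(contig = "c1", bin_start = 9900L,
                               bin_end = 10000L, midpoint = 9950L,
                               treated_count = 20L, control_count = 0L,
                               ratio = 20)
  pat <- infer_deletion_patterns(cp, pairs, merge_tol = 150L)
  expect_identical(nrow(pat), 1L)
  expect_lte(abs(pat$left_bp - 10000L), 150L)
  expect_lte(abs(pat$right_bp - 60000L), 150L)
  expect_identical(pat$n_supporting_pairs, 10L)

  # two deletions sharing the left breakpoint, far ends 30 kb apart
  pairs_rec2 <- do.call(rbind, lapply(1:6, function(i) {
    make_pair(sprintf("e%02d", i), 9850L - offs[i], 90010L + offs[i])
  }))
  pairs2 <- extract_discordant_pairs(rbind(anchor, pairs_rec, pairs_rec2))
  pat2 <- infer_deletion_patterns(cp, pairs2, merge_tol = 150L)
  expect_identical(nrow(pat2), 2L)
  expect_setequal(round(pat2$right_bp / 10000) * 10000, c(60000, 90000))

  # no discordant pairs -> no patterns
  expect_identical(
    nrow(infer_deletion_patterns(cp, pairs2[0], merge_tol = 150L)), 0L)
})

test_that("extent summary is strand-oriented around the PAM", {
  pam <- 100000L
  one <- make_patterns(pam, pam + 5000L)
  s <- summarize_extents(one, pam, "+")
  expect_identical(s$max_3p_extent, 5000L)
  expect_identical(s$max_5p_extent, 0L)

  many <- make_patterns(pam, pam + c(1000L, 40000L, 7000L))
  expect_identical(summarize_extents(many, pam, "+")$max_3p_extent, 40000L)
  # on a minus-strand guide the same patterns read as 5' extents
  expect_identical(summarize_extents(many, pam, "-")$max_5p_extent, 40000L)

  none <- summarize_extents(make_patterns(integer(0), integer(0)), pam, "+")
  expect_identical(none$n_patterns, 0L)
  expect_identical(none$max_3p_extent, 0L)
})

test_that("gene-overlap fractions and half-up percentages are exact", {
  fx <- overlap_fixture(154L, 8L)
  ov <- annotate_gene_overlap(fx$patterns, fx$genes)
  expect_identical(ov$n_overlapping, 8L)
  expect_identical(ov$n_partial, 8L)
  expect_equal(ov$fraction, 8 / 154)
  expect_equal(ov$percent_1dp, 5.2)

  ov2 <- annotate_gene_overlap(overlap_fixture(746L, 65L)$patterns,
                               overlap_fixture(746L, 65L)$genes)
  expect_equal(ov2$percent_1dp, 8.7)

  ov0 <- annotate_gene_overlap(overlap_fixture(100L, 0L)$patterns,
                               overlap_fixture(100L, 0L)$genes)
  expect_equal(ov0$percent_1dp, 0.0)

  # empty pattern set: fraction undefined, explicit empty result
  expect_identical(nrow(annotate_gene_overlap(fx$patterns[0], fx$genes)), 0L)

  # full containment is overlap but not partial
  pats <- make_patterns(9000L, 13000L)  # spans the whole [10000,12000) gene
  ovf <- annotate_gene_overlap(pats, fx$genes)
  expect_identical(ovf$n_overlapping, 1L)
  expect_identical(ovf$n_partial, 0L)
})

test_that("half-up rounding differs from round-half-even where it matters", {
  expect_equal(round_half_up(2.25, 1), 2.3)
  expect_equal(round_half_up(12 / 174 * 100, 1), 6.9)
  expect_equal(round_half_up(4 / 176 * 100, 1), 2.3)
})
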