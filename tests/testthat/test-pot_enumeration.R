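test_that("an exact planted guide copy qualifies under both rules", {
  g <- random_genome(20000, seed = 31)
  spacer <- random_spacer(32, seed = 32)
  g <- plant(g, 8000, paste0("AAG", spacer))
  pot <- find_pot_sites_cas3(spacer, g,
                             on_target = list(contig = "c1", start = 8000L,
                                              strand = "+"))
  hit <- pot[start == 8000]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$n_mismatches, 0L)
  expect_identical(hit$rule, "both")
  expect_identical(hit$longest_pam_anchored_run, 35L)
  expect_true(hit$is_on_target)
})

test_that("a site failing both Cas3 rules is not reported", {
  g <- random_genome(20000, seed = 33)
  spacer <- random_spacer(32, seed = 34)
  site <- paste0("AAG", spacer)
  # PAM exact, 8 spacer mismatches, longest PAM-anchored run capped at 15:
  # break position 16 of the site (spacer position 13) and beyond
  bad <- mutate_positions(site, c(16, 18, 20, 22, 24, 26, 28, 30))
  g <- plant(g, 9000, bad)
  pot <- find_pot_sites_cas3(spacer, g)
  expect_false(9000 %in% pot$start)
})

test_that("a 16-nt PAM-anchored exact run qualifies even with many mismatches", {
  g <- random_genome(20000, seed = 35)
  spacer <- random_spacer(32, seed = 36)
  site <- paste0("AAG", spacer)
  # keep positions 1..16 exact, scramble 8 positions further out
  consec_only <- mutate_positions(site, c(17, 19, 21, 23, 25, 27, 29, 31))
  g <- plant(g, 7000, consec_only)
  pot <- find_pot_sites_cas3(spacer, g, merge = FALSE)
  hit <- pot[start == 7000]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$rule, "consecutive")
  expect_gte(hit$longest_pam_anchored_run, 16L)
  # a run of only 15 (break at position 16) does not qualify
  run15 <- mutate_positions(site, c(16, 18, 20, 22, 24, 26, 28, 31))
  g2 <- plant(random_genome(20000, seed = 37), 7000, run15)
  expect_false(7000 %in% find_pot_sites_cas3(spacer, g2)$start)
})

test_that("a run inside the spacer that misses the PAM does not qualify", {
  g <- random_genome(20000, seed = 38)
  spacer <- random_spacer(32, seed = 39)
  site <- paste0("AAG", spacer)
  # break PAM contact (position 4 = first spacer base after exact PAM kept,
  # so break position 4) and add spacer mismatches beyond the mm budget
  inside <- mutate_positions(site, c(1, 2, 3, 4, 26, 28, 30, 32, 34))
  # positions 5..25 remain an exact 21-nt run, but it touches no PAM base
  g <- plant(g, 6000, inside)
  pot <- find_pot_sites_cas3(spacer, g)
  expect_false(6000 %in% pot$start)
})

test_that("Cas3 scan equals the exhaustive oracle site-for-site on random genomes", {
  for (sd in 1:2) {
    g <- random_genome(30000, seed = 310 + sd)
    spacer <- random_spacer(32, seed = 320 + sd)
    site <- paste0("AAG", spacer)
    # plant an assortment of near-misses and hits on both strands
    g <- plant(g, 2000, site)
    g <- plant(g, 6000, mutate_positions(site, 3 + sample(1:32, 7)))
    g <- plant(g, 10000, mutate_positions(site, 3 + sample(1:32, 8)))
    g <- plant(g, 14000, reverse_complement(mutate_positions(site, 3 + 1:5)))
    g <- plant(g, 18000, mutate_positions(site, c(17, 20, 23, 26, 29, 32, 34)))
    pot <- find_pot_sites_cas3(spacer, g, merge = FALSE)
    orc <- oracle_pot_cas3(g, "AAG", spacer)
    expect_identical(pot[, list(start, strand)], orc[, list(start, strand)])
    expect_identical(pot$rule == "both" | pot$rule == "mismatch_tolerant",
                     orc$mm_rule)
    expect_identical(pot$rule == "both" | pot$rule == "consecutive",
                     orc$consec_rule)
  }
})

test_that("Cas9 scan matches planted sites and the exhaustive oracle", {
  g <- random_genome(30000, seed = 41)
  guide <- random_spacer(20, seed = 42)
  g <- plant(g, 5000, paste0(guide, "AGG"))                       # exact
  g <- plant(g, 9000, paste0(mutate_positions(guide, c(1, 5, 9, 13)), "TGG"))  # 4 mm
  g <- plant(g, 13000, reverse_complement(paste0(
    mutate_positions(guide, c(2, 8)), "CGG")))                    # 2 mm, minus
  pot <- find_pot_sites_cas9(guide, g, merge = FALSE)
  expect_true(5000 %in% pot[strand == "+"]$start)
  expect_identical(pot[start == 5000]$n_mismatches, 0L)
  expect_false(9000 %in% pot$start)
  expect_true(13000 %in% pot[strand == "-"]$start)
  orc <- oracle_pot_cas9(g, guide)
  expect_identical(pot[, list(start, strand)], orc)
})

test_that("raising the mismatch budget or lowering the run bound never loses sites", {
  g <- random_genome(40000, seed = 43)
  spacer <- random_spacer(32, seed = 44)
  site <- paste0("AAG", spacer)
  for (k in c(2, 5, 7)) g <- plant(g, 4000 * k, mutate_positions(site, 3 + seq_len(k)))
  base <- find_pot_sites_cas3(spacer, g, pot_params(mm_max_cas3 = 5L), merge = FALSE)
  wide <- find_pot_sites_cas3(spacer, g, pot_params(mm_max_cas3 = 7L), merge = FALSE)
  expect_true(all(base$start %in% wide$start))
  tight <- find_pot_sites_cas3(spacer, g, pot_params(consec_min = 18L), merge = FALSE)
  loose <- find_pot_sites_cas3(spacer, g, pot_params(consec_min = 16L), merge = FALSE)
  expect_true(all(tight$start %in% loose$start))
})

test_that("near-duplicate qualifying windows merge into the best site", {
  g <- random_genome(20000, seed = 45)
  # a period-8 guide makes windows 8 bp apart qualify simultaneously:
  # pattern = (AAGTCGCA) repeated, so an embedded 48-mer repeat carries two
  # exact 35-nt matches offset by 8 bp
  unit <- "AAGTCGCA"
  pattern <- substr(strrep(unit, 5), 1, 35)
  spacer <- substr(pattern, 4, 35)
  g <- plant(g, 8000, strrep(unit, 6))
  unmerged <- find_pot_sites_cas3(spacer, g, merge = FALSE)
  merged <- find_pot_sites_cas3(spacer, g)
  close_unmerged <- unmerged[start >= 8000 & start <= 8016 & strand == "+"]
  close_merged <- merged[start >= 8000 & start <= 8016 & strand == "+"]
  expect_gte(nrow(close_unmerged), 2L)
  expect_identical(nrow(close_merged), 1L)
  expect_identical(close_merged$n_mismatches, 0L)
})

test_that("genome N never matches in any scan", {
  g <- random_genome(5000, seed = 47)
  spacer <- random_spacer(32, seed = 48)
  site <- paste0("AAG", spacer)
  withN <- sub("^(.{17}).", "\\1N", site)  # N at position 18 breaks the run
  g <- plant(g, 2000, withN)
  pot <- find_pot_sites_cas3(spacer, g, merge = FALSE)
  hit <- pot[start == 2000]
  # still qualifies via mm rule (1 mismatch) and via 15+? run check
  expect_identical(hit$n_mismatches, 1L)
  # N inside the PAM kills the site entirely
  g2 <- plant(random_genome(5000, seed = 49), 2000, sub("^.", "N", site))
  pot2 <- find_pot_sites_cas3(spacer, g2, merge = FALSE)
  expect_true(nrow(pot2[start == 2000 & (rule %in% c("mismatch_tolerant", "both"))]) == 0L)
})

test_that("capture regions follow the stated on-target and POT geometry", {
  g <- random_genome(400000, seed = 50)
  on <- build_capture_regions(
    data.table::data.table(contig = "c1", start = 150000L, end = 150035L,
                           strand = "+"), g, kind = "on_target")
  expect_identical(on$start, 50000L)
  expect_identical(on$end, 250000L)

  pot_plus <- build_capture_regions(
    data.table::data.table(contig = "c1", start = 20000L, end = 20035L,
                           strand = "+"), g, kind = "pot")
  expect_identical(pot_plus$start, 11000L)
  expect_identical(pot_plus$end, 21035L)

  pot_minus <- build_capture_regions(
    data.table::data.table(contig = "c1", start = 20000L, end = 20035L,
                           strand = "-"), g, kind = "pot")
  expect_identical(pot_minus$start, 19000L)
  expect_identical(pot_minus$end, 29035L)

  expect_warning(
    clipped <- build_capture_regions(
      data.table::data.table(contig = "c1", start = 3000L, end = 3035L,
                             strand = "+"), g, kind = "pot"),
    "clipped")
  expect_identical(clipped$start, 0L)

  expect_error(
    build_capture_regions(
      data.table::data.table(contig = "c1", start = 500000L, end = 500035L,
                             strand = "+"), g, kind = "pot"),
    "outside contig")
})
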