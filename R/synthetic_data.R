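#' Default gene layout for the synthetic genome
#'
#' Emulates the geometry of a Cas3 target locus with neighboring genes at
#' increasing 3' distances (as DAD1 and ABHD4 sit 3' of the TRAC cut, and a
#' further gene on the 5' side): a target gene whose first exon is cut just
#' downstream, one reachable 3' neighbor (~24 kb), one distal 3' neighbor
#' (~60 kb) and a 5' neighbor (~6 kb upstream).
#'
#' @return data.table with `contig`, `start`, `end`, `name`, `strand` and a
#'   `role` column ("target" or "neighbor").
#' @export
default_gene_layout <- function() {
  data.table::data.table(
    contig = "sim1",
    start = c(150000L, 144000L, 175000L, 211000L),
    end = c(156000L, 145200L, 178000L, 214000L),
    name = c("TARGET", "NEIGHBOR_5P", "NEIGHBOR_3P_NEAR", "NEIGHBOR_3P_FAR"),
    strand = c("+", "-", "+", "+"),
    role = c("target", "neighbor", "neighbor", "neighbor")
  )
}

#' Simulation configuration
#'
#' All knobs of the synthetic-data generator, with defaults describing the
#' emulated study conditions: a 400-kb single-contig genome, 200 cell
#' haplotypes of which 60% carry one Cas3-style deletion, one-sided
#' deletions anchored within +/-50 bp of the cut with a heavy-tailed
#' (geometric) length distribution -- mean 20 kb truncated at 100 kb in the
#' 3' direction (probability `direction_bias`), mean 2 kb for the minor 5'
#' direction -- and 2 x 150 bp paired-end capture reads (insert 400 +/- 60)
#' at 200x depth with a 0.2% uniform 5-15 nt noise-clip rate injected into
#' treated and control alike.
#'
#' @param seed mandatory integer seed; every downstream draw derives from
#'   it (no silent nondeterminism).
#' @param genome_len contig length in bp.
#' @param n_cells number of deletion haplotypes.
#' @param editing_rate fraction of haplotypes carrying a deletion.
#' @param direction_bias probability a deletion extends 3' of the PAM.
#' @param del_mean_3p,del_mean_5p geometric mean deletion lengths (bp).
#' @param del_max truncation of the 3' length distribution (bp).
#' @param bp_jitter anchored-breakpoint jitter around the cut site (bp).
#' @param read_len,insert_mean,insert_sd read and fragment-length model.
#' @param depth mean read coverage over each capture region, per library.
#' @param noise_clip_rate fraction of reads receiving a spurious soft clip.
#' @param noise_clip_range clip-length range (nt) for noise clips.
#' @param pot_plants list of `c(n_mismatches, count)` pairs: POT sites
#'   planted as guide copies with exactly that many spacer mismatches.
#' @param gene_layout data.table as in [default_gene_layout()].
#' @param exon first-exon interval of the target gene (0-based half-open).
#' @param guide_offset distance from the exon 3' end to the planted
#'   protospacer's PAM-proximal end (bp downstream).
#' @param design a [design_params()] object for the planted guide.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed, genome_len = 400000L, n_cells = 200L,
                       editing_rate = 0.6, direction_bias = 0.8,
                       del_mean_3p = 20000, del_mean_5p = 2000,
                       del_max = 100000L, bp_jitter = 50L,
                       read_len = 150L, insert_mean = 400, insert_sd = 60,
                       depth = 200, noise_clip_rate = 0.002,
                       noise_clip_range = c(5L, 15L),
                       pot_plants = list(c(2L, 1L), c(5L, 2L), c(7L, 2L)),
                       gene_layout = default_gene_layout(),
                       exon = list(start = 150200L, end = 151000L),
                       guide_offset = 250L,
                       design = design_params()) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  stopifnot(editing_rate >= 0, editing_rate <= 1,
            direction_bias >= 0, direction_bias <= 1,
            genome_len > 0L, n_cells > 0L, del_mean_3p > 0, del_mean_5p > 0,
            del_max > 0L, read_len > 0L, depth > 0,
            noise_clip_rate >= 0, noise_clip_rate <= 1)
  structure(list(
    seed = as.integer(seed), genome_len = as.integer(genome_len),
    n_cells = as.integer(n_cells), editing_rate = editing_rate,
    direction_bias = direction_bias, del_mean_3p = del_mean_3p,
    del_mean_5p = del_mean_5p, del_max = as.integer(del_max),
    bp_jitter = as.integer(bp_jitter), read_len = as.integer(read_len),
    insert_mean = insert_mean, insert_sd = insert_sd, depth = depth,
    noise_clip_rate = noise_clip_rate,
    noise_clip_range = as.integer(noise_clip_range),
    pot_plants = pot_plants, gene_layout = gene_layout,
    exon = lapply(exon, as.integer), guide_offset = as.integer(guide_offset),
    design = design
  ), class = "sim_config")
}

# draw a random ACGT string of length n
.random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate exactly k distinct spacer positions of a PAM+spacer copy
.mutate_spacer <- function(site, pam_len, k) {
  ch <- strsplit(site, "", fixed = TRUE)[[1]]
  if (k > 0L) {
    idx <- pam_len + sample.int(length(ch) - pam_len, k)
    for (i in idx) {
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    }
  }
  paste(ch, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic genome with a planted guide and POT sites
#'
#' Draws an i.i.d. uniform ACGT contig, places the configured genes, plants
#' one designed guide site (AAG PAM + 32-nt protospacer with in-range GC)
#' at `guide_offset` bp downstream of the target exon, and plants POT sites
#' as copies of the guide carrying exactly k spacer mismatches (alternating
#' strands) at fixed, well-separated loci outside the on-target capture
#' window.
#'
#' @param config a [sim_config()] object.
#' @return list with `genome` (DNAStringSet), `genes` (data.table),
#'   `exon` (one-row data.table), `truth` (list: `guide` with locus,
#'   strand, pam, spacer, cut_site; `pots` data.table with planted locus,
#'   strand and mismatch count), and `config`.
#' @export
make_genome <- function(config) {
  set.seed(config$seed)
  dp <- config$design
  plen <- nchar(dp$pam)
  L <- plen + dp$spacer_len
  seq0 <- .random_seq(config$genome_len)

  # planted guide: GC-in-range spacer at guide_offset downstream of the exon
  repeat {
    spacer <- .random_seq(dp$spacer_len)
    gc <- .gc_vec(spacer)
    if (gc >= dp$gc_min && gc <= dp$gc_max) break
  }
  exon <- config$exon
  anchor <- exon$end + config$guide_offset   # PAM-proximal protospacer end
  g_start <- anchor - plen                    # '+' strand site start
  site <- paste0(dp$pam, spacer)
  substr(seq0, g_start + 1L, g_start + L) <- site
  cut_site <- anchor  # Cas3 cleavage initiates at the PAM-proximal spacer end

  # plant POT sites at fixed slots clear of the on-target capture window
  slots <- c(15000L, 40000L, 270000L, 295000L, 320000L, 345000L, 370000L)
  plants <- config$pot_plants
  n_pot <- sum(vapply(plants, function(p) p[2L], numeric(1L)))
  if (n_pot > length(slots)) stop("too many POT plants for the fixed slots")
  pots <- data.table::data.table(contig = character(), start = integer(),
                                 end = integer(), strand = character(),
                                 n_mismatches = integer())
  si <- 0L
  for (p in plants) {
    k <- as.integer(p[1L]); cnt <- as.integer(p[2L])
    for (j in seq_len(cnt)) {
      si <- si + 1L
      pos <- slots[si]
      if (pos + L > config$genome_len) stop("POT plant outside contig")
      mut <- .mutate_spacer(site, plen, k)
      std <- if (si %% 2L == 0L) "-" else "+"
      ins <- if (std == "+") mut else reverse_complement(mut)
      substr(seq0, pos + 1L, pos + L) <- ins
      pots <- rbind(pots, data.table::data.table(
        contig = "sim1", start = pos, end = pos + L, strand = std,
        n_mismatches = k
      ))
    }
  }
  genome <- Biostrings::DNAStringSet(stats::setNames(seq0, "sim1"))
  genes <- data.table::copy(config$gene_layout)
  exon_dt <- data.table::data.table(
    contig = "sim1", start = exon$start, end = exon$end, strand = "+",
    name = "TARGET_exon1"
  )
  truth <- list(
    guide = list(contig = "sim1", start = g_start, end = g_start + L,
                 strand = "+", pam = dp$pam, spacer = spacer,
                 cut_site = cut_site),
    pots = pots
  )
  list(genome = genome, genes = genes, exon = exon_dt, truth = truth,
       config = config)
}

#' Simulate per-cell deletion haplotypes
#'
#' `editing_rate` of the haplotypes receive exactly one deletion with one
#' breakpoint anchored within +/-`bp_jitter` of the cut site, extending 3'
#' with probability `direction_bias` (geometric length, mean `del_mean_3p`,
#' truncated at `del_max`) and otherwise 5' (geometric, mean
#' `del_mean_5p`). Deletions that would leave the contig are redrawn.
#'
#' @param genome_obj output of [make_genome()].
#' @param config a [sim_config()] object (defaults to the one inside
#'   `genome_obj`).
#' @return data.table with one row per haplotype: `hap`, `edited`,
#'   `direction` ("3p"/"5p"/NA), `del_l`, `del_r` (0-based half-open
#'   deleted interval; NA when unedited), `del_len`.
#' @export
simulate_deletions <- function(genome_obj, config = genome_obj$config) {
  set.seed(config$seed + 1L)
  n <- config$n_cells
  cut <- genome_obj$truth$guide$cut_site
  Lc <- config$genome_len
  edited <- stats::runif(n) < config$editing_rate
  dir3 <- stats::runif(n) < config$direction_bias
  anchor <- cut + sample.int(2L * config$bp_jitter + 1L, n, replace = TRUE) -
    config$bp_jitter - 1L
  draw_len <- function(mean_len, m) stats::rgeom(m, 1 / mean_len) + 1L
  del_l <- del_r <- rep(NA_integer_, n)
  dir <- rep(NA_character_, n)
  n_resampled <- 0L
  for (i in which(edited)) {
    repeat {
      if (dir3[i]) {
        len <- draw_len(config$del_mean_3p, 1L)
        if (len > config$del_max) { n_resampled <- n_resampled + 1L; next }
        l <- anchor[i]; r <- anchor[i] + len
      } else {
        len <- draw_len(config$del_mean_5p, 1L)
        if (len > config$del_max) { n_resampled <- n_resampled + 1L; next }
        l <- anchor[i] - len; r <- anchor[i]
      }
      if (l >= 0L && r <= Lc) break
      n_resampled <- n_resampled + 1L
    }
    del_l[i] <- as.integer(l); del_r[i] <- as.integer(r)
    dir[i] <- if (dir3[i]) "3p" else "5p"
  }
  if (n_resampled > 0L) {
    message(n_resampled, " deletion draw(s) resampled (out of bounds)")
  }
  data.table::data.table(
    hap = seq_len(n), edited = edited, direction = dir,
    del_l = del_l, del_r = del_r, del_len = del_r - del_l
  )
}

# Simulate one capture library over `regions` for the given haplotypes.
# Returns an alignment-record table in read_alignments() layout plus a
# per-fragment provenance table used for ground-truth support counts.
.sim_library <- function(contig_seq, contig_name, regions, haps, config,
                         lib_tag) {
  rl <- config$read_len
  frag_rows <- list()
  for (ri in seq_len(nrow(regions))) {
    rg <- regions[ri]
    n_frag <- as.integer(round(config$depth * (rg$end - rg$start) / (2 * rl)))
    if (n_frag == 0L) {
      warning("zero-depth capture region [", rg$start, ",", rg$end, ")")
      next
    }
    hap_id <- sample.int(nrow(haps), n_frag, replace = TRUE)
    flen <- pmax(as.integer(round(stats::rnorm(n_frag, config$insert_mean,
                                               config$insert_sd))), rl)
    dl <- haps$del_l[hap_id]; dr <- haps$del_r[hap_id]
    dlen <- ifelse(is.na(dl), 0L, dr - dl)
    # haplotype-coordinate image of the region: [map_inv(start), map_inv(end))
    map_inv <- function(x) ifelse(is.na(dl), x,
                                  ifelse(x <= dl, x, pmax(dl, x - dlen)))
    a <- map_inv(rep(rg$start, n_frag)); b <- map_inv(rep(rg$end, n_frag))
    span <- pmax(b - a - flen, 1L)
    s <- a + as.integer(floor(stats::runif(n_frag) * span))
    frag_rows[[ri]] <- data.table::data.table(
      region = ri, hap = hap_id, s = s, flen = flen, dl = dl, dr = dr,
      dlen = dlen
    )
  }
  fr <- data.table::rbindlist(frag_rows)
  n <- nrow(fr)
  # haplotype->reference map for a coordinate x (junction at dl): x < dl
  # maps to itself, x >= dl maps to x + dlen
  has_del <- !is.na(fr$dl)
  junction <- ifelse(has_del, fr$dl, NA_integer_)

  read_layout <- function(hs, he) {
    # hs/he: haplotype-coordinate read interval [hs, he)
    cross <- has_del & hs < junction & he > junction
    left_len <- ifelse(cross, junction - hs, he - hs)
    right_len <- ifelse(cross, he - junction, 0L)
    primary_left <- !cross | left_len >= right_len
    pos <- ifelse(!has_del | he <= junction, hs,
           ifelse(hs >= junction, hs + fr$dlen,
           ifelse(primary_left, hs, fr$dr)))
    cigar <- ifelse(!cross, paste0(he - hs, "M"),
             ifelse(primary_left, paste0(left_len, "M", right_len, "S"),
                    paste0(left_len, "S", right_len, "M")))
    ref_span <- ifelse(cross, ifelse(primary_left, left_len, right_len),
                       he - hs)
    list(pos = as.integer(pos), cigar = cigar,
         ref_span = as.integer(ref_span), cross = cross,
         left_len = as.integer(left_len), right_len = as.integer(right_len))
  }
  r1 <- read_layout(fr$s, fr$s + rl)
  r2 <- read_layout(fr$s + fr$flen - rl, fr$s + fr$flen)

  # sequences: forward-reference orientation, so a junction-crossing read is
  # the concatenation of the two reference pieces either side of the gap
  read_seq <- function(hs, he, lay) {
    out <- character(n)
    nc <- !lay$cross
    if (any(nc)) {
      st <- ifelse(!has_del[nc] | (he[nc] <= junction[nc]), hs[nc],
                   hs[nc] + fr$dlen[nc])
      out[nc] <- substring(contig_seq, st + 1L, st + (he - hs)[nc])
    }
    cr <- which(lay$cross)
    if (length(cr)) {
      out[cr] <- paste0(
        substring(contig_seq, hs[cr] + 1L, hs[cr] + lay$left_len[cr]),
        substring(contig_seq, fr$dr[cr] + 1L, fr$dr[cr] + lay$right_len[cr])
      )
    }
    out
  }
  seq1 <- read_seq(fr$s, fr$s + rl, r1)
  seq2 <- read_seq(fr$s + fr$flen - rl, fr$s + fr$flen, r2)

  # pair geometry in reference coordinates
  start1 <- r1$pos; end1 <- r1$pos + r1$ref_span
  start2 <- r2$pos; end2 <- r2$pos + r2$ref_span
  outer_l <- pmin(start1, start2)
  outer_r <- pmax(end1, end2)
  tlen1 <- ifelse(start1 <= start2, outer_r - outer_l,
                  -(outer_r - outer_l))
  frag_cross <- has_del & fr$s < junction & fr$s + fr$flen > junction
  proper <- !frag_cross

  qname <- sprintf("%s_f%07d", lib_tag, seq_len(n))
  flag1 <- .FLAG_PAIRED + .FLAG_MATE_REVERSE + .FLAG_FIRST +
    ifelse(proper, .FLAG_PROPER, 0L)
  flag2 <- .FLAG_PAIRED + .FLAG_REVERSE + .FLAG_SECOND +
    ifelse(proper, .FLAG_PROPER, 0L)

  rec <- data.table::data.table(
    qname = c(qname, qname),
    flag = as.integer(c(flag1, flag2)),
    contig = contig_name,
    pos = c(start1, start2),
    mapq = 60L,
    cigar = c(r1$cigar, r2$cigar),
    rnext = "=",
    pnext = c(start2, start1),
    tlen = as.integer(c(tlen1, -tlen1)),
    seq = c(seq1, seq2)
  )

  # uniform noise clips on otherwise fully aligned reads, both libraries
  pure <- !grepl("S", rec$cigar, fixed = TRUE)
  noise <- which(pure & stats::runif(nrow(rec)) < config$noise_clip_rate)
  if (length(noise)) {
    clen <- sample(seq(config$noise_clip_range[1L],
                       config$noise_clip_range[2L]),
                   length(noise), replace = TRUE)
    left_side <- stats::runif(length(noise)) < 0.5
    m <- rl - clen
    rec$cigar[noise] <- ifelse(left_side, paste0(clen, "S", m, "M"),
                               paste0(m, "M", clen, "S"))
    rec$pos[noise] <- rec$pos[noise] + ifelse(left_side, clen, 0L)
  }

  rec[, unmapped := FALSE]
  rec[, secondary := FALSE]
  rec[, supplementary := FALSE]
  rec[, paired := TRUE]
  rec[, proper := bitwAnd(flag, .FLAG_PROPER) > 0L]
  rec[, reverse := bitwAnd(flag, .FLAG_REVERSE) > 0L]
  rec[, mate_reverse := bitwAnd(flag, .FLAG_MATE_REVERSE) > 0L]
  rec[, mate_unmapped := FALSE]
  rec[, first_in_pair := bitwAnd(flag, .FLAG_FIRST) > 0L]
  rec[, strand := ifelse(reverse, "-", "+")]

  # ground-truth provenance: which fragments yield a discordant pair.
  # A crossing fragment is discordant evidence unless its junction-crossing
  # read aligns primarily on the mate's side of the junction, which happens
  # when the junction falls within read_len/2 of either fragment end.
  u <- junction - fr$s
  supporting <- frag_cross & u >= rl / 2 & u < fr$flen - rl / 2
  frags <- data.table::data.table(
    qname = qname, hap = fr$hap, crossing = frag_cross,
    supporting = supporting
  )
  list(records = rec, fragments = frags)
}

#' Simulate treated and control capture libraries
#'
#' Paired-end reads (2 x `read_len`) are drawn over the capture regions at
#' `depth` mean coverage. Fragments from deleted haplotypes that cross the
#' breakpoint yield soft-clipped records at the junction (split reads) and
#' mate pairs with deletion-inflated outer spans (discordant pairs); the
#' control library is sequenced from wild-type haplotypes only. A small
#' uniform noise-clip rate is injected into both libraries.
#'
#' @param genome_obj output of [make_genome()].
#' @param haps haplotype table from [simulate_deletions()].
#' @param capture_regions data.table from [build_capture_regions()] (or any
#'   table with `contig`, `start`, `end`); regions must lie on the single
#'   simulated contig.
#' @param config a [sim_config()] object.
#' @return list with `treated`, `control` (alignment-record data.tables in
#'   [read_alignments()] layout) and `truth`: per-haplotype crossing and
#'   discordant-supporting fragment counts for the treated library.
#' @export
simulate_reads <- function(genome_obj, haps, capture_regions,
                           config = genome_obj$config) {
  set.seed(config$seed + 2L)
  contig_name <- names(genome_obj$genome)[1L]
  contig_seq <- .contig_string(genome_obj$genome, contig_name)
  regions <- data.table::as.data.table(capture_regions)
  stopifnot(all(regions$contig == contig_name))
  treated <- .sim_library(contig_seq, contig_name, regions, haps, config,
                          "trt")
  wt <- data.table::copy(haps)
  wt[, `:=`(edited = FALSE, direction = NA_character_, del_l = NA_integer_,
            del_r = NA_integer_, del_len = NA_integer_)]
  control <- .sim_library(contig_seq, contig_name, regions, wt, config,
                          "ctl")
  support <- treated$fragments[, list(
    n_crossing = sum(crossing), n_supporting_pairs = sum(supporting)
  ), by = hap]
  truth <- merge(haps, support, by = "hap", all.x = TRUE)
  truth[is.na(n_crossing), `:=`(n_crossing = 0L, n_supporting_pairs = 0L)]
  list(treated = treated$records, control = control$records, truth = truth[])
}
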