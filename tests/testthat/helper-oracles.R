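# Independent brute-force oracles built on Biostrings exact/inexact matching
# (a different code path from the package's running-window scan engine).

# All qualifying Cas3 POT windows (unmerged), as data.table(start, strand)
# with rule flags, for a single-contig genome.
oracle_pot_cas3 <- function(genome, pam, spacer, mm_max = 7L,
                            consec_min = 16L) {
  pattern <- paste0(pam, spacer)
  L <- nchar(pattern)
  plen <- nchar(pam)
  one_strand <- function(subj) {
    Ls <- length(subj)
    W <- Ls - L + 1L
    # mismatch-tolerant rule: <= mm_max total mismatches, then verify exact
    # PAM and spacer budget per hit
    mm_pos <- integer(0)
    m <- Biostrings::matchPattern(pattern, subj, max.mismatch = mm_max)
    for (h in seq_along(m)) {
      hit <- as.character(m[[h]])
      pam_ok <- substr(hit, 1L, plen) == pam
      sp_mm <- sum(strsplit(substr(hit, plen + 1L, L), "")[[1]] !=
                     strsplit(spacer, "")[[1]])
      if (pam_ok && sp_mm <= mm_max) mm_pos <- c(mm_pos, BiocGenerics::start(m)[h] - 1L)
    }
    # consecutive rule: an exact run of >= consec_min nt overlapping a PAM
    # base exists iff the consec_min-mer starting at pattern offset r (r a
    # PAM position) matches exactly at window offset r
    run_pos <- integer(0)
    for (r in seq_len(plen)) {
      sub <- substr(pattern, r, r + consec_min - 1L)
      mh <- Biostrings::matchPattern(sub, subj, max.mismatch = 0L)
      w <- BiocGenerics::start(mh) - 1L - (r - 1L)
      run_pos <- c(run_pos, w[w >= 0L & w <= W - 1L])
    }
    run_pos <- sort(unique(run_pos))
    list(mm = sort(unique(mm_pos)), run = run_pos)
  }
  subj <- genome[[1L]]
  Lc <- length(subj)
  fwd <- one_strand(subj)
  rev <- one_strand(Biostrings::reverseComplement(subj))
  reflect <- function(p) sort(Lc - L - p)
  out <- rbind(
    data.table::data.table(start = fwd$mm, strand = "+", rule = "mm"),
    data.table::data.table(start = fwd$run, strand = "+", rule = "run"),
    data.table::data.table(start = reflect(rev$mm), strand = "-", rule = "mm"),
    data.table::data.table(start = reflect(rev$run), strand = "-", rule = "run")
  )
  out <- out[, list(mm_rule = any(rule == "mm"), consec_rule = any(rule == "run")),
             by = list(start, strand)]
  data.table::setorder(out, start, strand)
  out[]
}

# All qualifying Cas9 POT windows (unmerged): 20-nt guide + NGG, <= mm_max
# guide mismatches. Window start is the guide start (locus of width 23).
oracle_pot_cas9 <- function(genome, guide20, mm_max = 3L) {
  L <- 23L
  one_strand <- function(subj) {
    Ls <- length(subj)
    m <- Biostrings::matchPattern(guide20, subj, max.mismatch = mm_max)
    keep <- integer(0)
    for (h in seq_along(m)) {
      p0 <- BiocGenerics::start(m)[h] - 1L
      if (p0 + L > Ls) next
      pamseq <- as.character(subj[(p0 + 21L):(p0 + 23L)])
      if (substr(pamseq, 1L, 1L) %in% c("A", "C", "G", "T") &&
          substr(pamseq, 2L, 2L) == "G" && substr(pamseq, 3L, 3L) == "G") {
        keep <- c(keep, p0)
      }
    }
    sort(unique(keep))
  }
  subj <- genome[[1L]]
  Lc <- length(subj)
  fwd <- one_strand(subj)
  rev <- one_strand(Biostrings::reverseComplement(subj))
  out <- rbind(
    data.table::data.table(start = fwd, strand = "+"),
    data.table::data.table(start = sort(Lc - L - rev), strand = "-")
  )
  data.table::setorder(out, start, strand)
  out[]
}

# Exhaustive per-position candidate scan downstream of an exon: walks every
# genomic position explicitly and applies the design criteria one by one.
oracle_candidates <- function(genome, exon, params) {
  s <- as.character(genome[[exon$contig]])
  Lc <- nchar(s)
  plen <- nchar(params$pam)
  L <- plen + params$spacer_len
  e3 <- if (exon$strand == "+") exon$end else exon$start
  found <- list()
  for (p in 0:(Lc - L)) {
    win <- substr(s, p + 1L, p + L)
    for (std in c("+", "-")) {
      site <- if (std == "+") win else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(win)))
      if (substr(site, 1L, plen) != params$pam) next
      anchor <- if (std == "+") p + plen else p + params$spacer_len
      dist <- if (exon$strand == "+") anchor - e3 else e3 - anchor
      if (dist < params$window_min || dist > params$window_max) next
      spacer <- substr(site, plen + 1L, L)
      if (grepl("N", spacer)) next
      ch <- strsplit(spacer, "")[[1]]
      gc <- mean(ch %in% c("G", "C"))
      if (gc < params$gc_min || gc > params$gc_max) next
      found[[length(found) + 1L]] <-
        data.table::data.table(start = p, strand = std, gc = gc,
                               distance_from_exon = dist)
    }
  }
  if (!length(found)) {
    return(data.table::data.table(start = integer(), strand = character(),
                                  gc = numeric(),
                                  distance_from_exon = integer()))
  }
  out <- data.table::rbindlist(found)
  data.table::setorder(out, start, strand)
  out[]
}

# random single-contig genome helper
random_genome <- function(len, seed, name = "c1") {
  set.seed(seed)
  Biostrings::DNAStringSet(stats::setNames(
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    name))
}

random_spacer <- function(len = 32L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# plant a sequence into a DNAStringSet genome at 0-based pos (forward strand)
plant <- function(genome, pos, seq) {
  s <- as.character(genome[[1L]])
  substr(s, pos + 1L, pos + nchar(seq)) <- seq
  Biostrings::DNAStringSet(stats::setNames(s, names(genome)[1L]))
}

# mutate exactly k distinct positions within [from, to] (1-based) of a string
mutate_positions <- function(seq, idx) {
  ch <- strsplit(seq, "")[[1]]
  for (i in idx) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1L]
  paste(ch, collapse = "")
}
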