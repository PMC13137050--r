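# Core window-scan engine shared by the crRNA uniqueness filter and the POT
# enumeration modes. A "window" is every length(pattern) substring of a
# contig; for each window we track, fully vectorised across the contig:
#   * spacer_mm : Hamming mismatches over the spacer positions of the pattern
#   * pam_ok    : whether every PAM position matches (pattern N may act as a
#                 wildcard over A/C/G/T when pam_wildcard = TRUE)
#   * pam_run   : longest contiguous exact-match run that starts inside the
#                 PAM (left-anchored patterns only), i.e. a run that overlaps
#                 at least one PAM base
# Genome N never matches anything; pattern N outside a wildcard PAM never
# matches anything.

.scan_windows <- function(subject, pattern, pam_len, pam_side = "left",
                          pam_wildcard = FALSE, want_run = FALSE,
                          run_starts = NULL) {
  L <- nchar(pattern)
  gch <- strsplit(subject, "", fixed = TRUE)[[1]]
  W <- length(gch) - L + 1L
  if (W < 1L) {
    return(list(pos = integer(), spacer_mm = integer(),
                pam_ok = logical(), pam_run = integer()))
  }
  pch <- strsplit(pattern, "", fixed = TRUE)[[1]]
  pam_idx <- if (pam_side == "left") seq_len(pam_len) else (L - pam_len + 1L):L
  if (want_run && is.null(run_starts)) run_starts <- seq_len(pam_len)

  spacer_mm <- integer(W)
  pam_ok <- rep(TRUE, W)
  alive <- list(); run <- list()
  if (want_run) {
    for (k in seq_along(run_starts)) {
      alive[[k]] <- rep(TRUE, W); run[[k]] <- integer(W)
    }
  }
  for (r in seq_len(L)) {
    seg <- gch[r:(r + W - 1L)]
    pc <- pch[r]
    if (pc == "N") {
      eq <- if (pam_wildcard && r %in% pam_idx) seg != "N" else rep(FALSE, W)
    } else {
      eq <- seg == pc
    }
    if (r %in% pam_idx) {
      pam_ok <- pam_ok & eq
    } else {
      spacer_mm <- spacer_mm + !eq
    }
    if (want_run) {
      for (k in seq_along(run_starts)) {
        if (r >= run_starts[k]) {
          alive[[k]] <- alive[[k]] & eq
          run[[k]] <- run[[k]] + alive[[k]]
        }
      }
    }
  }
  pam_run <- if (want_run) Reduce(pmax, run) else integer(W)
  list(pos = 0:(W - 1L), spacer_mm = spacer_mm, pam_ok = pam_ok,
       pam_run = pam_run)
}

# Scan every contig of `genome` on both strands. Minus-strand windows are
# found by scanning the reverse-complemented contig with the same pattern and
# reflecting coordinates; reported loci are always forward-strand 0-based
# half-open intervals of width nchar(pattern).
#
# Returns rows satisfying (pam_ok & spacer_mm <= mm_max) when mm_max is
# given, or pam_run >= consec_min when consec_min is given (union if both).
.scan_genome <- function(genome, pattern, pam_len, pam_side = "left",
                         pam_wildcard = FALSE, mm_max = NULL,
                         consec_min = NULL, run_starts = NULL) {
  L <- nchar(pattern)
  want_run <- !is.null(consec_min)
  res <- vector("list", 2L * length(genome))
  j <- 0L
  for (ctg in names(genome)) {
    fwd <- .contig_string(genome, ctg)
    Lc <- nchar(fwd)
    for (std in c("+", "-")) {
      subj <- if (std == "+") fwd else reverse_complement(fwd)
      s <- .scan_windows(subj, pattern, pam_len, pam_side, pam_wildcard,
                         want_run, run_starts)
      keep <- rep(FALSE, length(s$pos))
      mm_hit <- rep(FALSE, length(s$pos))
      run_hit <- rep(FALSE, length(s$pos))
      if (!is.null(mm_max)) {
        mm_hit <- s$pam_ok & s$spacer_mm <= mm_max
        keep <- keep | mm_hit
      }
      if (want_run) {
        run_hit <- s$pam_run >= consec_min
        keep <- keep | run_hit
      }
      if (!any(keep)) next
      pos <- s$pos[keep]
      start <- if (std == "+") pos else Lc - L - pos
      j <- j + 1L
      res[[j]] <- data.table::data.table(
        contig = ctg, start = start, end = start + L, strand = std,
        spacer_mm = s$spacer_mm[keep], pam_ok = s$pam_ok[keep],
        pam_run = s$pam_run[keep],
        mm_rule = mm_hit[keep], consec_rule = run_hit[keep]
      )
    }
  }
  if (j == 0L) {
    return(data.table::data.table(
      contig = character(), start = integer(), end = integer(),
      strand = character(), spacer_mm = integer(), pam_ok = logical(),
      pam_run = integer(), mm_rule = logical(), consec_rule = logical()
    ))
  }
  out <- data.table::rbindlist(res[seq_len(j)])
  data.table::setorder(out, contig, start, strand)
  out[]
}

# Extract the genomic sequence of a site on its own strand.
.site_seq <- function(genome, contig, start, end, strand) {
  s <- substring(.contig_string(genome, contig), start + 1L, end)
  if (length(strand) == 1L) strand <- rep(strand, length(s))
  neg <- strand == "-"
  if (any(neg)) s[neg] <- reverse_complement(s[neg])
  s
}
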