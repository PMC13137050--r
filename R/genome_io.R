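#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and restricted to the A/C/G/T/N alphabet; any
#' other letter (including IUPAC ambiguity codes) is rejected, as are
#' duplicate contig names and empty records. The returned object is a named
#' [Biostrings::DNAStringSet]; all coordinates elsewhere in the package are
#' 0-based half-open against these sequences.
#'
#' @param path path to a FASTA file.
#' @return a named `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  .stopifnot_scalar_string(path, "path")
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  # read as raw strings first: DNA parsers silently drop invalid letters,
  # and the alphabet rule here is strict
  ss <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("FASTA parse error in '", path, "': ", conditionMessage(e))
  )
  if (length(ss) == 0L) stop("FASTA file '", path, "' contains no records")
  # headers may carry descriptions after whitespace; contig name is field 1
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop("duplicate contig name(s) in '", path, "': ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("contig(s) with characters outside {A,C,G,T,N}: ",
         paste(nm[bad], collapse = ", "))
  }
  if (any(!nzchar(seqs))) stop("empty sequence record(s) in '", path, "'")
  Biostrings::DNAStringSet(seqs)
}

#' Write a reference genome to FASTA
#'
#' @param genome named `DNAStringSet` (or named character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, filepath = path)
  invisible(path)
}

#' Contig lengths of a genome
#' @param genome named `DNAStringSet`.
#' @return named integer vector of lengths in bp.
#' @export
contig_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

# Extract a contig as a plain character string (scan engines work on these).
.contig_string <- function(genome, contig) {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  as.character(genome[[contig]])
}

#' Read gene annotations from BED
#'
#' Intervals are consumed natively as 0-based half-open, exactly as written
#' in BED. Columns beyond the first six are ignored; missing name/strand
#' default to "." . Lines with `start >= end` or negative coordinates are
#' errors. When `genome` is supplied, features on unknown contigs are kept
#' but flagged with a warning.
#'
#' @param path path to a BED file (3+ columns, tab- or space-separated).
#' @param genome optional genome (`DNAStringSet`) used to flag unknown contigs.
#' @return data.table with columns `contig`, `start`, `end`, `name`, `strand`.
#' @export
read_bed <- function(path, genome = NULL) {
  .stopifnot_scalar_string(path, "path")
  if (!file.exists(path)) stop("BED file not found: ", path)
  empty <- data.table::data.table(
    contig = character(), start = integer(), end = integer(),
    name = character(), strand = character()
  )
  if (file.size(path) == 0L) return(empty)
  dt <- data.table::fread(path, header = FALSE, fill = TRUE, quote = "",
                          colClasses = list(character = 1L))
  if (nrow(dt) == 0L) return(empty)
  if (ncol(dt) < 3L) stop("BED file '", path, "' has fewer than 3 columns")
  out <- data.table::data.table(
    contig = as.character(dt[[1L]]),
    start  = as.integer(dt[[2L]]),
    end    = as.integer(dt[[3L]]),
    name   = if (ncol(dt) >= 4L) as.character(dt[[4L]]) else ".",
    strand = if (ncol(dt) >= 6L) as.character(dt[[6L]]) else "."
  )
  out[!strand %chin% c("+", "-", "."), strand := "."]
  if (anyNA(out$start) || anyNA(out$end)) {
    stop("non-numeric coordinates in BED file '", path, "'")
  }
  if (any(out$start < 0L)) stop("negative start coordinate in '", path, "'")
  if (any(out$start >= out$end)) {
    bad <- which(out$start >= out$end)[1L]
    stop("BED interval with start >= end at line ", bad, " of '", path, "'")
  }
  if (!is.null(genome)) {
    unk <- setdiff(unique(out$contig), names(genome))
    if (length(unk)) {
      warning("BED features on contig(s) absent from genome: ",
              paste(unk, collapse = ", "))
    }
  }
  out[]
}

#' Write intervals to BED
#'
#' @param dt data.table with `contig`, `start`, `end` and optionally
#'   `name`, `strand` (a `score` column of 0 is emitted).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(dt, path) {
  out <- data.table::data.table(
    contig = dt$contig, start = dt$start, end = dt$end,
    name = if ("name" %in% names(dt)) dt$name else ".",
    score = 0L,
    strand = if ("strand" %in% names(dt)) dt$strand else "."
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# SAM flag bits
.FLAG_PAIRED <- 1L; .FLAG_PROPER <- 2L; .FLAG_UNMAPPED <- 4L
.FLAG_MATE_UNMAPPED <- 8L; .FLAG_REVERSE <- 16L; .FLAG_MATE_REVERSE <- 32L
.FLAG_FIRST <- 64L; .FLAG_SECOND <- 128L
.FLAG_SECONDARY <- 256L; .FLAG_SUPPLEMENTARY <- 2048L

#' Read alignment records from a plain-text SAM file
#'
#' Positions are converted from SAM 1-based to the package-wide 0-based
#' convention at this boundary; no other operation performs coordinate
#' conversion. Unmapped, secondary and supplementary records are retained
#' but flagged. Records whose CIGAR query length disagrees with the stored
#' sequence length are skipped with a warning.
#'
#' @param path path to a SAM file with a header.
#' @return data.table with one row per record: `qname`, `flag`, `contig`,
#'   `pos` (0-based leftmost aligned base), `mapq`, `cigar`, `rnext`,
#'   `pnext` (0-based), `tlen`, `seq`, plus decoded flag columns
#'   (`unmapped`, `secondary`, `supplementary`, `paired`, `proper`,
#'   `reverse`, `mate_reverse`, `mate_unmapped`, `first_in_pair`) and
#'   `strand`.
#' @export
read_alignments <- function(path) {
  .stopifnot_scalar_string(path, "path")
  if (!file.exists(path)) stop("SAM file not found: ", path)
  # count leading header lines
  con <- file(path, open = "r")
  on.exit(close(con), add = TRUE)
  hdr_n <- 0L
  repeat {
    chunk <- readLines(con, n = 512L)
    if (length(chunk) == 0L) break
    is_hdr <- startsWith(chunk, "@")
    if (all(is_hdr)) hdr_n <- hdr_n + length(chunk)
    else { hdr_n <- hdr_n + which(!is_hdr)[1L] - 1L; break }
  }
  empty <- .empty_alignments()
  n_body <- length(readLines(path)) - hdr_n  # cheap relative to parsing
  if (n_body <= 0L) return(empty)
  dt <- data.table::fread(
    path, header = FALSE, sep = "\t", quote = "", fill = TRUE,
    skip = hdr_n, select = 1:11,
    col.names = c("qname", "flag", "contig", "pos1", "mapq", "cigar",
                  "rnext", "pnext1", "tlen", "seq", "qual")
  )
  out <- data.table::data.table(
    qname = as.character(dt$qname),
    flag = as.integer(dt$flag),
    contig = as.character(dt$contig),
    pos = as.integer(dt$pos1) - 1L,
    mapq = as.integer(dt$mapq),
    cigar = as.character(dt$cigar),
    rnext = as.character(dt$rnext),
    pnext = as.integer(dt$pnext1) - 1L,
    tlen = as.integer(dt$tlen),
    seq = as.character(dt$seq)
  )
  out[, unmapped := bitwAnd(flag, .FLAG_UNMAPPED) > 0L]
  out[, secondary := bitwAnd(flag, .FLAG_SECONDARY) > 0L]
  out[, supplementary := bitwAnd(flag, .FLAG_SUPPLEMENTARY) > 0L]
  out[, paired := bitwAnd(flag, .FLAG_PAIRED) > 0L]
  out[, proper := bitwAnd(flag, .FLAG_PROPER) > 0L]
  out[, reverse := bitwAnd(flag, .FLAG_REVERSE) > 0L]
  out[, mate_reverse := bitwAnd(flag, .FLAG_MATE_REVERSE) > 0L]
  out[, mate_unmapped := bitwAnd(flag, .FLAG_MATE_UNMAPPED) > 0L]
  out[, first_in_pair := bitwAnd(flag, .FLAG_FIRST) > 0L]
  out[, strand := ifelse(reverse, "-", "+")]
  # record-level validation: CIGAR query length vs SEQ length
  check <- !out$unmapped & out$cigar != "*" & out$seq != "*"
  if (any(check)) {
    qlen <- cigar_stats(out$cigar[check])$query_len
    bad <- qlen != nchar(out$seq[check])
    if (any(bad)) {
      warning(sum(bad), " record(s) skipped: CIGAR/sequence length mismatch")
      drop <- which(check)[bad]
      out <- out[-drop]
    }
  }
  out[]
}

.empty_alignments <- function() {
  data.table::data.table(
    qname = character(), flag = integer(), contig = character(),
    pos = integer(), mapq = integer(), cigar = character(),
    rnext = character(), pnext = integer(), tlen = integer(),
    seq = character(), unmapped = logical(), secondary = logical(),
    supplementary = logical(), paired = logical(), proper = logical(),
    reverse = logical(), mate_reverse = logical(),
    mate_unmapped = logical(), first_in_pair = logical(), strand = character()
  )
}

#' Write alignment records as plain-text SAM
#'
#' Inverse of [read_alignments()]: internal 0-based positions are written
#' back as SAM 1-based. A minimal `@HD`/`@SQ` header is emitted from the
#' genome.
#'
#' @param records data.table in the layout produced by [read_alignments()].
#' @param genome named `DNAStringSet` providing `@SQ` lines.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, genome, path) {
  lens <- contig_lengths(genome)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
  writeLines(hdr, path)
  if (nrow(records)) {
    body <- data.table::data.table(
      records$qname, records$flag, records$contig, records$pos + 1L,
      records$mapq, records$cigar, records$rnext, records$pnext + 1L,
      records$tlen, records$seq, "*"
    )
    data.table::fwrite(body, path, sep = "\t", col.names = FALSE,
                       quote = FALSE, append = TRUE)
  }
  invisible(path)
}

#' Reverse complement of a nucleotide sequence
#'
#' Strict alphabet {A,C,G,T,N}; N maps to N. Length-preserving involution.
#'
#' @param seq character vector of sequences.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq)) stop("seq must be character")
  up <- toupper(seq)
  if (any(grepl("[^ACGTN]", up))) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(up)))
}
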