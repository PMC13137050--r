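#' Run configuration for the end-to-end pipeline
#'
#' Bundles every module's parameters with their package-wide defaults:
#' 100-bp split-read bins, cut-point ratio threshold 5 (strictly exceeded)
#' with 3 treated reads minimum support, 150-bp single-linkage merge
#' tolerance, 20-nt minimum soft clip, mapping-quality floor 20, and
#' off-target flag threshold 5.
#'
#' @param seed integer seed driving the whole run.
#' @param sim a [sim_config()] (defaults to `sim_config(seed)`).
#' @param design a [design_params()] object.
#' @param pot a [pot_params()] object.
#' @param bin_width split-read bin width in bp.
#' @param ratio_threshold cut-point treated/control ratio (strict).
#' @param min_support minimum treated split reads per cut-point bin.
#' @param merge_tol breakpoint clustering tolerance in bp.
#' @param min_clip minimum soft-clip length in nt.
#' @param mapq_floor mapping-quality floor for evidence extraction.
#' @param flag_threshold off-target score flag threshold.
#' @param tlen_threshold discordant template-length cutoff (`NULL` =
#'   estimate mean + 3 SD from proper pairs).
#' @return a `run_config` list.
#' @export
run_config <- function(seed, sim = sim_config(seed),
                       design = design_params(), pot = pot_params(),
                       bin_width = 100L, ratio_threshold = 5,
                       min_support = 3L, merge_tol = 150L, min_clip = 20L,
                       mapq_floor = 20L, flag_threshold = 5L,
                       tlen_threshold = NULL) {
  if (missing(seed)) stop("run_config: seed is mandatory")
  structure(list(
    seed = as.integer(seed), sim = sim, design = design, pot = pot,
    bin_width = as.integer(bin_width), ratio_threshold = ratio_threshold,
    min_support = as.integer(min_support), merge_tol = as.integer(merge_tol),
    min_clip = as.integer(min_clip), mapq_floor = as.integer(mapq_floor),
    flag_threshold = as.integer(flag_threshold),
    tlen_threshold = tlen_threshold
  ), class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' YAML round-trip of a [run_config()] (gene layout included).
#'
#' @param config a `run_config` object.
#' @param path output path.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  x <- rapply(unclass(config), how = "replace", function(v) v)
  x$sim <- unclass(x$sim)
  x$sim$design <- unclass(x$sim$design)
  x$sim$gene_layout <- as.list(as.data.frame(x$sim$gene_layout))
  x$design <- unclass(x$design)
  x$pot <- unclass(x$pot)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  gl <- data.table::as.data.table(x$sim$gene_layout)
  sim <- do.call(sim_config, c(
    x$sim[setdiff(names(x$sim), c("design", "gene_layout"))],
    list(design = do.call(design_params, x$sim$design), gene_layout = gl)
  ))
  run_config(
    seed = x$seed, sim = sim,
    design = do.call(design_params, x$design),
    pot = do.call(pot_params, x$pot),
    bin_width = x$bin_width, ratio_threshold = x$ratio_threshold,
    min_support = x$min_support, merge_tol = x$merge_tol,
    min_clip = x$min_clip, mapq_floor = x$mapq_floor,
    flag_threshold = x$flag_threshold,
    tlen_threshold = x$tlen_threshold
  )
}

#' Run the full simulate-design-enumerate-call-score pipeline
#'
#' Generates (or reuses) a synthetic genome, screens crRNA candidates over
#' the target exon, enumerates Cas3 POT sites for the planted guide, builds
#' on-target and POT capture regions, simulates treated and no-crRNA
#' control libraries, calls large deletions from split-read and
#' discordant-pair evidence, summarizes extents and neighboring-gene
#' overlap, and scores every capture region by control subtraction.
#' Deterministic given `config$seed`.
#'
#' @param config a [run_config()] object.
#' @param out_dir optional directory; when given, all artifacts (FASTA,
#'   BED, SAM, TSV tables, config YAML) are written there.
#' @return a `run_report` list: `candidates`, `pot_sites`,
#'   `capture_regions`, `bins`, `cut_points`, `patterns`, `extents`,
#'   `gene_overlap`, `scores`, `truth`, `guide`, `n_pot`, `params`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  g <- make_genome(config$sim)
  guide <- g$truth$guide

  exon <- c(as.list(g$exon[1L]), list())
  candidates <- design_crrnas(g$genome, exon, config$design,
                              gene = "TARGET")

  pot <- find_pot_sites_cas3(guide$spacer, g$genome, config$pot,
                             pam = guide$pam,
                             on_target = guide)
  on_cap <- build_capture_regions(
    data.table::data.table(contig = guide$contig, start = guide$start,
                           end = guide$end, strand = guide$strand),
    g$genome, kind = "on_target")
  pot_cap <- build_capture_regions(pot[is_on_target == FALSE], g$genome,
                                   kind = "pot")
  capture <- rbind(on_cap, pot_cap)
  capture[, region_id := c("on_target",
                           sprintf("pot_%02d", seq_len(nrow(pot_cap))))]

  haps <- simulate_deletions(g, config$sim)
  reads <- simulate_reads(g, haps, capture, config$sim)

  splits_t <- extract_split_reads(reads$treated, config$min_clip,
                                  config$mapq_floor)
  splits_c <- extract_split_reads(reads$control, config$min_clip,
                                  config$mapq_floor)
  pairs_t <- extract_discordant_pairs(reads$treated, config$tlen_threshold,
                                      config$mapq_floor)

  region <- as.list(on_cap[1L])
  bins <- bin_split_counts(splits_t, splits_c, region, config$bin_width)
  cut_points <- detect_cut_points(bins, config$ratio_threshold,
                                  config$min_support)
  patterns <- infer_deletion_patterns(cut_points, pairs_t, splits_t,
                                      config$merge_tol)
  extents <- summarize_extents(patterns, pam_pos = guide$start,
                               strand = guide$strand)
  overlap <- annotate_gene_overlap(patterns,
                                   g$genes[role == "neighbor"])
  scores <- score_pot_sites(splits_t, splits_c, capture,
                            config$flag_threshold)
  scores[, region_id := capture$region_id]

  report <- list(
    candidates = candidates, pot_sites = pot, capture_regions = capture,
    bins = bins, cut_points = cut_points, patterns = patterns,
    extents = extents, gene_overlap = overlap, scores = scores,
    truth = reads$truth, guide = guide, n_pot = nrow(pot),
    params = config
  )
  class(report) <- "run_report"
  if (!is.null(out_dir)) write_report(report, g, reads, out_dir)
  report
}

#' Write all pipeline artifacts to a directory
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param genome_obj the [make_genome()] output of the run.
#' @param reads the [simulate_reads()] output of the run.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, genome_obj, reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_fasta(genome_obj$genome, p("ref.fa"))
  write_bed(genome_obj$genes, p("genes.bed"))
  write_sam(reads$treated, genome_obj$genome, p("treated.sam"))
  write_sam(reads$control, genome_obj$genome, p("control.sam"))
  tsv <- function(x, f) data.table::fwrite(x, p(f), sep = "\t")
  tsv(report$candidates, "candidates.tsv")
  tsv(report$pot_sites, "pot_sites.tsv")
  tsv(report$capture_regions, "capture_regions.tsv")
  tsv(report$cut_points, "cut_points.tsv")
  tsv(report$patterns, "patterns.tsv")
  tsv(report$extents, "extents.tsv")
  tsv(report$gene_overlap, "gene_overlap.tsv")
  tsv(report$scores, "offtarget_scores.tsv")
  tsv(report$truth, "truth.tsv")
  write_run_config(report$params, p("config.yaml"))
  invisible(dir)
}

#' Effective yield of edited cells
#'
#' The fraction of the initial cell input that is both viable and
#' double-knockout: the product of the DKO frequency among viable cells
#' and the overall viability, reported half-up to one decimal percent.
#'
#' @param dko_frequency DKO fraction among viable cells, in \[0, 1\].
#' @param viability viable fraction of the input cells, in \[0, 1\].
#' @return effective yield as a percentage rounded half-up to one decimal.
#' @export
effective_yield <- function(dko_frequency, viability) {
  if (!is.numeric(dko_frequency) || !is.numeric(viability) ||
      any(dko_frequency < 0 | dko_frequency > 1) ||
      any(viability < 0 | viability > 1)) {
    stop("dko_frequency and viability must be fractions in [0, 1]")
  }
  round_half_up(100 * dko_frequency * viability, 1L)
}
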