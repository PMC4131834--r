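#' Simulation parameters
#'
#' Defines the study conditions the synthetic genome generator emulates: a
#' donor genome diverged from a reference by ~1% SNPs, small indels, and
#' large (>= 100 bp) insertions/deletions whose deletion sizes follow a
#' bimodal mixture with modes near 4 kb and 12.5 kb; the donor is sheared
#' into contigs and sequenced with paired-end reads and BAC-end (BES) clone
#' pairs.
#'
#' @param ref_length bp per chromosome.
#' @param n_chroms number of chromosomes.
#' @param snp_rate substitutions per plantable bp (default 0.01).
#' @param small_indel_rate small (< 100 bp) indel events per bp.
#' @param large_del_count,large_ins_count planted large-indel events per
#'   genome (the size distributions below are per-event).
#' @param large_del_sizes list(weights, means, sds, ln_meanlog, ln_sdlog,
#'   min, max): mixture of two normals plus a lognormal tail, truncated.
#' @param large_ins_sizes list(meanlog, sdlog, min, max): lognormal sizes.
#' @param repeat_fraction fraction of large-indel events composed of tandem
#'   copies of a repeat unit (default 0.585).
#' @param repeat_unit_range bp range of the tandem repeat unit.
#' @param contig_n50 target contig N50 after shearing, bp.
#' @param contig_error_rate planted substitution errors per contig bp.
#' @param read_length,read_depth,read_error_rate Illumina-like paired reads:
#'   length (bp), fold coverage, per-base error rate.
#' @param insert_mean,insert_sd paired-end fragment size, bp.
#' @param bes_insert_mean,bes_insert_sd BAC clone insert size, bp.
#' @param bes_read_len BES read length, bp.
#' @param bes_count number of BAC clones (0 = none).
#' @param seed integer RNG seed; fixed seed gives byte-identical outputs.
#' @return a validated list of class `sim_params`.
#' @export
sim_params <- function(ref_length = 1e6,
                       n_chroms = 1,
                       snp_rate = 0.01,
                       small_indel_rate = 2e-4,
                       large_del_count = 0,
                       large_ins_count = 0,
                       large_del_sizes = list(weights = c(0.55, 0.30, 0.15),
                                              means = c(4000, 12500),
                                              sds = c(500, 1000),
                                              ln_meanlog = log(1500),
                                              ln_sdlog = 0.9,
                                              min = 100, max = 50000),
                       large_ins_sizes = list(meanlog = log(400), sdlog = 0.8,
                                              min = 100, max = 10000),
                       repeat_fraction = 0.585,
                       repeat_unit_range = c(300, 500),
                       contig_n50 = 20000,
                       contig_error_rate = 0,
                       read_length = 100,
                       read_depth = 30,
                       read_error_rate = 0.001,
                       insert_mean = 350,
                       insert_sd = 30,
                       bes_insert_mean = 1e5,
                       bes_insert_sd = 1e4,
                       bes_read_len = 600,
                       bes_count = 0,
                       seed = 1L) {
  p <- as.list(environment())
  stopifnot_scalar(p$ref_length, "ref_length", 1)
  stopifnot_scalar(p$n_chroms, "n_chroms", 1)
  for (r in c("snp_rate", "small_indel_rate", "repeat_fraction",
              "read_error_rate", "contig_error_rate"))
    stopifnot_scalar(p[[r]], r, 0, 1)
  for (s in c("contig_n50", "read_length", "read_depth", "insert_mean",
              "bes_insert_mean", "bes_read_len"))
    stopifnot_scalar(p[[s]], s, 1e-9)
  stopifnot_scalar(p$large_del_count, "large_del_count", 0)
  stopifnot_scalar(p$large_ins_count, "large_ins_count", 0)
  if (p$large_del_sizes$min < 100 || p$large_ins_sizes$min < 100)
    stop("large-indel sizes must be >= 100 bp")
  if (p$read_length >= p$insert_mean)
    stop("read_length must be smaller than insert_mean")
  p$seed <- as.integer(p$seed)
  class(p) <- "sim_params"
  p
}

#' Pipeline thresholds
#'
#' All stage thresholds in one validated, JSON-serializable object. Defaults
#' are the published operating point: contig filter 90% identity / 80%
#' coverage with a 500 bp minimum length; BES hits at 90/95 (contig side) and
#' 90/90 (reference side) with mates < 300 kb apart; large indels 100-50,000
#' bp with >= 200 bp aligned flanks and >= 5 spanning reads for validation;
#' polishing Q >= 30, depth >= 10, frequency >= 70%, two rounds; gene absence
#' below 5% exon coverage; transcript mapping at 90% identity / 70% coverage
#' with < 50% coverage marking donor-unique transcripts.
#'
#' @param ... named overrides of any default listed above.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_identity = 0.90, min_coverage = 0.80, contig_min_len = 500,
    ambiguity_margin = 0.05, tiling_overlap_tol = 100,
    anchor_min_len = 20, max_join_gap = 1000, band = 50, max_extend = 5000,
    match = 1, mismatch = -1, gap = -2,
    bes_contig_min_id = 0.90, bes_contig_min_cov = 0.95,
    bes_ref_min_id = 0.90, bes_ref_min_cov = 0.90,
    bes_max_pair_dist = 300000,
    min_links = 3,
    indel_min_size = 100, indel_max_size = 50000, min_flank = 200,
    other_gap_tol = 10, min_span_reads = 5,
    polish_min_qual = 30, polish_min_depth = 10, polish_min_freq = 0.70,
    polish_rounds = 2, polish_min_map_qual = 20, polish_min_base_qual = 20,
    gene_absent_cov = 0.05,
    tx_min_id = 0.90, tx_min_cov = 0.70, tx_unique_cov = 0.50,
    map_min_qual = 20, gap_floor = 100
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  for (f in c("min_identity", "min_coverage", "bes_contig_min_id",
              "bes_contig_min_cov", "bes_ref_min_id", "bes_ref_min_cov",
              "polish_min_freq", "gene_absent_cov", "tx_min_id", "tx_min_cov",
              "tx_unique_cov", "ambiguity_margin"))
    stopifnot_scalar(cfg[[f]], f, 0, 1)
  for (f in c("contig_min_len", "bes_max_pair_dist", "min_links",
              "indel_min_size", "indel_max_size", "min_flank",
              "min_span_reads", "polish_min_qual", "polish_min_depth",
              "polish_rounds", "anchor_min_len"))
    stopifnot_scalar(cfg[[f]], f, 1)
  if (cfg$polish_min_freq <= 0) stop("polish_min_freq must be positive")
  if (cfg$indel_min_size < 100) stop("indel_min_size must be >= 100")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as JSON
#'
#' Round-trips losslessly.
#' @param cfg a `pipeline_config`.
#' @param path file path.
#' @return `read_config` returns a `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, jsonlite::read_json(path, simplifyVector = TRUE))
}
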