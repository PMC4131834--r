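# Pipeline orchestration and printed-statistics verification. The stage
# order mirrors the construction flow: polish -> align -> filter -> rescue
# -> pseudomolecules -> variants -> genes; every stage's outputs are
# written as reloadable text artifacts, and the run manifest records the
# configuration hash and seed.

#' Run the full pseudomolecule pipeline on in-memory inputs
#'
#' @param config a [pipeline_config()].
#' @param inputs list with elements `ref` (named character), `contigs`
#'   (named character), and optionally `reads` (list(seq, qual) or with
#'   `sam`), `bes` (named character), `models` (gene-model table).
#' @param outdir artifact directory (created if missing); NULL skips file
#'   output.
#' @param seed integer recorded in the manifest and used for any stage
#'   randomness.
#' @return list of stage results: polish log, placements, blocks,
#'   pseudomolecules, variant calls and summary, gene coverage (when
#'   models are given), and the manifest.
#' @export
run_pipeline <- function(config, inputs, outdir = NULL, seed = 1L) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(inputs$ref) || is.null(inputs$contigs))
    stop("inputs must provide ref and contigs")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  set.seed(seed)
  res <- list()
  contigs <- inputs$contigs

  if (!is.null(inputs$reads)) {
    pol <- stage("polish", polish_contigs(
      contigs, reads = inputs$reads$seq, quals = inputs$reads$qual,
      sam = inputs$reads$sam,
      rule = correction_rule(config$polish_min_qual, config$polish_min_depth,
                             config$polish_min_freq, config$polish_rounds,
                             config$polish_min_map_qual,
                             config$polish_min_base_qual)))
    contigs <- pol$contigs
    res$polish_log <- pol$log
  }

  al <- stage("align", align_contigs(contigs, inputs$ref, config))
  res$placements <- al$placements
  res$blocks <- al$blocks
  res$rejected <- al$rejected

  placements <- al$placements
  unplaced <- contigs[setdiff(names(contigs), placements$contig_id)]
  unplaced <- unplaced[nchar(unplaced) >= config$contig_min_len]
  if (!is.null(inputs$bes) && length(inputs$bes)) {
    bm <- stage("rescue", map_bes(inputs$bes, contigs, inputs$ref, config))
    resc <- stage("rescue", rescue_anchor(unplaced, bm, placements, config))
    res$bes_maps <- bm
    res$rescued <- resc
    if (nrow(resc)) {
      placements <- rbind(placements, resc)
      unplaced <- unplaced[setdiff(names(unplaced), resc$contig_id)]
    }
  }
  if (!is.null(inputs$reads) && length(unplaced)) {
    links <- stage("rescue", build_pe_links(inputs$reads$seq, contigs,
                                            placements, config))
    pe <- stage("rescue", paired_end_anchor(unplaced, links, placements,
                                            config))
    res$pe_rescued <- pe
    if (nrow(pe)) placements <- rbind(placements, pe)
  }
  res$all_placements <- placements

  pm <- stage("pseudomolecules",
              build_pseudomolecules(placements, contigs, inputs$ref, config))
  res$pseudomolecules <- pm

  sn <- stage("variants", call_snps(al$placements, al$blocks, contigs,
                                    inputs$ref))
  ins <- stage("variants", classify_insertions(
    al$blocks, contigs, config$indel_min_size, config$min_flank,
    config$other_gap_tol))
  del <- stage("variants", classify_deletions(
    al$blocks, contigs, config$indel_min_size, config$indel_max_size,
    config$min_flank, config$other_gap_tol))
  indels <- rbind(ins, del)
  res$snps <- sn$snps
  res$aligned_bp <- sn$aligned_bp
  res$indels <- indels
  res$variant_summary <- stage("variants", summarize_variants(
    sn$snps, indels, sn$aligned_bp, names(inputs$ref)))

  if (!is.null(inputs$models) && nrow(inputs$models)) {
    res$gene_coverage <- stage("genes", exon_coverage(
      inputs$models, al$blocks, config$gene_absent_cov))
    res$snp_effects <- stage("genes", classify_snp_effects(
      sn$snps, inputs$models, inputs$ref))
  }

  res$manifest <- list(
    seed = as.integer(seed),
    config_hash = config_hash(config),
    n_contigs_in = length(inputs$contigs),
    n_placed = length(unique(placements$contig_id)))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(contigs, file.path(outdir, "contigs.fa"))
    write_tsv(placements, file.path(outdir, "placements.tsv"))
    if (!is.null(al$blocks)) write_tsv(al$blocks, file.path(outdir, "blocks.tsv"))
    write_fasta(pm$fasta, file.path(outdir, "pseudomolecules.fa"))
    write_agp(pm$agp, file.path(outdir, "pseudomolecules.agp"))
    write_tsv(pm$stats, file.path(outdir, "assembly_stats.tsv"))
    write_vcf(sn$snps, indels[indels$type %in% c("INS", "DEL"), ],
              inputs$ref, file.path(outdir, "variants.vcf"))
    write_tsv(res$variant_summary$per_chrom,
              file.path(outdir, "variant_summary_per_chrom.tsv"))
    write_tsv(res$variant_summary$totals,
              file.path(outdir, "variant_summary_totals.tsv"))
    if (!is.null(res$gene_coverage))
      write_tsv(res$gene_coverage, file.path(outdir, "gene_coverage.tsv"))
    if (!is.null(res$polish_log))
      write_tsv(res$polish_log, file.path(outdir, "polish_log.tsv"))
    jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x)
    paste(format(x, digits = 12), collapse = ","), character(1)),
    collapse = ";")
  # small stable polynomial hash; avoids external digest dependencies
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Recompute published summary statistics from packaged fixtures
#'
#' Reads the per-chromosome and per-class fixture tables shipped under
#' `inst/extdata/` (transcriptions of the published Tables 1-2 and the
#' per-class indel totals) and recomputes every derived statistic —
#' column totals, SNP frequencies, mean indel lengths, assembly totals and
#' coverage fractions — with the same arithmetic [summarize_variants()]
#' uses, comparing each against its printed value.
#'
#' @param fixture_dir directory with `table1_fixture.tsv`,
#'   `table2_fixture.tsv`, `indel_class_fixture.tsv` and
#'   `printed_stats_fixture.tsv` (defaults to the installed package
#'   fixtures).
#' @return data.frame: target, recomputed, printed, pass. Empty fixture
#'   tables give an empty report.
#' @export
verify_published_stats <- function(fixture_dir = system.file("extdata",
                                                         package = "pseudoref")) {
  t1p <- file.path(fixture_dir, "table1_fixture.tsv")
  t2p <- file.path(fixture_dir, "table2_fixture.tsv")
  icp <- file.path(fixture_dir, "indel_class_fixture.tsv")
  psp <- file.path(fixture_dir, "printed_stats_fixture.tsv")
  for (f in c(t1p, t2p, icp, psp)) if (!file.exists(f))
    stop("fixture file missing: ", f)
  t1 <- read_tsv(t1p); t2 <- read_tsv(t2p); ic <- read_tsv(icp)
  ps <- read_tsv(psp)
  if (!nrow(t2) && !nrow(t1) && !nrow(ic))
    return(data.frame(target = character(0), recomputed = numeric(0),
                      printed = numeric(0), pass = logical(0)))
  need <- function(df, cols, where) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(sprintf("fixture %s lacks column(s): %s", where,
                                   paste(miss, collapse = ", ")))
  }
  need(t2, c("chrom", "snp_kn", "indel_kn", "snp_k93", "indel_k93"),
       "table2")
  need(t1, c("class", "n_contigs", "n50", "max_len", "mean_len",
             "total_len"), "table1")
  need(ic, c("comparison", "type", "sites", "total_bp"), "indel_class")
  need(ps, c("name", "value"), "printed_stats")
  pv <- function(nm) {
    v <- ps$value[ps$name == nm]
    if (!length(v)) stop("printed_stats fixture lacks row: ", nm)
    v
  }
  sites <- function(cmp) sum(ic$sites[ic$comparison == cmp])
  bp <- function(cmp) sum(ic$total_bp[ic$comparison == cmp])
  t1row <- function(cl, col) t1[[col]][t1$class == cl]
  rec <- c(
    kn_snp_total = sum(t2$snp_kn),
    kn_indel_total = sum(t2$indel_kn),
    k93_snp_total = sum(t2$snp_k93),
    k93_indel_total = sum(t2$indel_k93),
    kn_snp_frequency_pct = round(100 * sum(t2$snp_kn) / pv("kn_aligned_bp"), 2),
    k93_snp_frequency_pct = round(100 * sum(t2$snp_k93) / pv("k93_aligned_bp"), 2),
    kn_mean_indel_bp = round(bp("kasalath_nipponbare") /
                               sites("kasalath_nipponbare")),
    k93_mean_indel_bp = round(bp("kasalath_9311") / sites("kasalath_9311")),
    unmapped_mean_len = round(t1row("unmapped", "total_len") /
                                t1row("unmapped", "n_contigs")),
    assembly_total_mb = round(sum(t1$total_len) / 1e6, 2),
    genome_coverage_pct = round(100 * sum(t1$total_len) /
                                  pv("reference_genome_bp"), 1),
    anchored_fraction_pct = round(100 * t1row("mapped", "total_len") /
                                    sum(t1$total_len), 1))
  printed <- vapply(names(rec), function(nm) pv(paste0("printed_", nm)),
                    numeric(1))
  data.frame(target = names(rec), recomputed = unname(rec),
             printed = unname(printed),
             pass = unname(rec == printed))
}
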