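# Gene-level comparative analysis: exon coverage against aligned blocks
# drives presence/absence calls (absent below 5% exon coverage); SNPs are
# classified by position and codon change (premature stop codons and
# altered splice-site motifs are flagged harmful); donor transcripts are
# classified mapped / unmapped / donor-unique by alignment identity and
# coverage thresholds (90/70 and <50% coverage).

#' Exon coverage and presence calls per gene
#'
#' Intersects each gene's exon intervals with the reference intervals of
#' the aligned blocks; a gene is present when the covered fraction reaches
#' `min_cov` (default 0.05 — below it the gene is called absent in the
#' donor). With `per_transcript = FALSE` (default) exons of all transcripts
#' are collapsed per gene; otherwise each transcript is scored and the gene
#' takes its best-covered transcript.
#'
#' @param models gene-model table (see [simulate_genes()] / [read_gff3()]).
#' @param blocks alignment blocks of accepted placements.
#' @param min_cov presence threshold on the covered fraction.
#' @param per_transcript score per transcript instead of collapsed exons.
#' @return data.frame: gene_id, chrom, exon_bp, covered_bp,
#'   coverage_fraction, present.
#' @export
exon_coverage <- function(models, blocks, min_cov = 0.05,
                          per_transcript = FALSE) {
  ex <- models[models$feature == "exon", , drop = FALSE]
  if (!nrow(ex)) stop("no exon rows in gene models")
  known <- unique(blocks$chrom)
  cov_by_chrom <- lapply(setNames(known, known), function(c0) {
    b <- blocks[blocks$chrom == c0, , drop = FALSE]
    IRanges::reduce(IRanges::IRanges(start = b$r_start + 1, end = b$r_end))
  })
  score_set <- function(exons) {
    c0 <- exons$chrom[1]
    ir <- IRanges::reduce(IRanges::IRanges(start = exons$start + 1,
                                           end = exons$end))
    exon_bp <- sum(IRanges::width(ir))
    covered <- if (c0 %in% known)
      sum(IRanges::width(IRanges::intersect(ir, cov_by_chrom[[c0]])))
    else 0
    c(exon_bp = exon_bp, covered_bp = covered)
  }
  rows <- list()
  for (gid in unique(ex$gene_id)) {
    ge <- ex[ex$gene_id == gid, , drop = FALSE]
    if (!ge$chrom[1] %in% names(cov_by_chrom) && !length(known)) {
      # no aligned blocks at all: zero coverage
    }
    if (per_transcript) {
      sc <- sapply(unique(ge$transcript_id), function(tid)
        score_set(ge[ge$transcript_id == tid, , drop = FALSE]))
      best <- which.max(sc["covered_bp", ] / pmax(sc["exon_bp", ], 1))
      s <- sc[, best]
    } else s <- score_set(ge)
    frac <- if (s[["exon_bp"]] > 0) s[["covered_bp"]] / s[["exon_bp"]] else 0
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = gid, chrom = ge$chrom[1], exon_bp = s[["exon_bp"]],
      covered_bp = s[["covered_bp"]], coverage_fraction = frac,
      present = frac >= min_cov)
  }
  do.call(rbind, rows)
}

#' Classify SNP effects on gene models
#'
#' Position-based categories (intergenic, intron, 5'/3' UTR) plus
#' codon-level classes for CDS SNPs: the affected codon is translated
#' in-frame on the coding strand before and after the change, yielding
#' synonymous / missense / nonsense / stop_loss / start_loss. Changes in
#' the first or last two intron bases (the GT..AG donor/acceptor motif)
#' are splice_site. Harmful = nonsense or splice_site. SNPs in CDS models
#' whose length is not a codon multiple get category UNKNOWN.
#'
#' @param snps SNP table (chrom, r_pos, ref_base, alt_base on the forward
#'   reference strand).
#' @param models gene-model table.
#' @param ref named character vector (reference genome the models
#'   annotate).
#' @return `snps` with columns category and harmful added.
#' @export
classify_snp_effects <- function(snps, models, ref) {
  code <- Biostrings::GENETIC_CODE
  n <- nrow(snps)
  category <- rep("intergenic", n)
  if (!n) {
    snps$category <- character(0); snps$harmful <- logical(0)
    return(snps)
  }
  tx <- models[models$feature == "mRNA", , drop = FALSE]
  for (t in seq_len(nrow(tx))) {
    tid <- tx$transcript_id[t]
    chrom <- tx$chrom[t]; strand <- tx$strand[t]
    in_tx <- which(snps$chrom == chrom & snps$r_pos >= tx$start[t] &
                     snps$r_pos < tx$end[t])
    if (!length(in_tx)) next
    ex <- models[models$feature == "exon" & models$transcript_id == tid, ,
                 drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    cds <- models[models$feature == "CDS" & models$transcript_id == tid, ,
                  drop = FALSE]
    cds <- cds[order(cds$start), , drop = FALSE]
    # CDS base positions in genome order, then translation order
    gpos <- unlist(lapply(seq_len(nrow(cds)), function(i)
      seq(cds$start[i], cds$end[i] - 1)))
    sense_pos <- if (strand == "-") rev(gpos) else gpos
    cds_len <- length(gpos)
    valid_cds <- cds_len %% 3 == 0 && cds_len >= 6
    cds_seq <- NULL
    if (valid_cds) {
      cds_seq <- paste(substring(ref[[chrom]], sense_pos + 1, sense_pos + 1),
                       collapse = "")
      if (strand == "-") cds_seq <- chartr("ACGT", "TGCA", cds_seq)
    }
    cds_index <- new.env()
    for (k in seq_along(sense_pos))
      assign(as.character(sense_pos[k]), k, envir = cds_index)
    for (si in in_tx) {
      p <- snps$r_pos[si]
      in_exon <- any(p >= ex$start & p < ex$end)
      if (!in_exon) {
        # intron: splice site when within 2 bp of an intron end
        donor2 <- any(p >= ex$end & p < ex$end + 2) ||
          any(p >= ex$start - 2 & p < ex$start)
        category[si] <- if (donor2) "splice_site" else "intron"
        next
      }
      ci <- mget(as.character(p), envir = cds_index, ifnotfound = NA)[[1]]
      if (is.na(ci)) {
        # exonic but non-coding: UTR side depends on strand
        before_cds <- p < min(cds$start)
        if (strand == "+") category[si] <- if (before_cds) "5'UTR" else "3'UTR"
        else category[si] <- if (before_cds) "3'UTR" else "5'UTR"
        next
      }
      if (!valid_cds) { category[si] <- "UNKNOWN"; next }
      codon_i <- (ci - 1) %/% 3
      off <- (ci - 1) %% 3
      codon <- substr(cds_seq, 3 * codon_i + 1, 3 * codon_i + 3)
      alt <- snps$alt_base[si]
      if (strand == "-") alt <- chartr("ACGT", "TGCA", alt)
      mut <- codon
      substr(mut, off + 1, off + 1) <- alt
      aa_ref <- code[[codon]]; aa_alt <- code[[mut]]
      n_codons <- cds_len / 3
      category[si] <-
        if (codon_i == 0 && !(mut %in% names(code) && aa_alt == "M" &&
                                mut == "ATG")) "start_loss"
        else if (aa_ref != "*" && aa_alt == "*" &&
                 codon_i < n_codons - 1) "nonsense"
        else if (aa_ref == "*" && aa_alt != "*") "stop_loss"
        else if (aa_ref == aa_alt) "synonymous"
        else "missense"
    }
  }
  snps$category <- category
  snps$harmful <- category %in% c("nonsense", "splice_site")
  snps
}

#' Classify donor transcripts as mapped, unmapped or donor-unique
#'
#' A transcript is mapped when its best alignment reaches `min_id` identity
#' and `min_cov` coverage (defaults 0.90 / 0.70); otherwise unmapped; an
#' unmapped transcript whose best coverage stays below `unique_cov`
#' (default 0.50) is donor-unique. Transcripts with no alignment at all
#' have coverage 0 and are donor-unique.
#'
#' @param transcripts named character vector of transcript sequences.
#' @param ref named character vector (the other genome).
#' @param min_id,min_cov,unique_cov thresholds.
#' @param cfg a [pipeline_config()] supplying aligner settings.
#' @return data.frame: transcript_id, identity, coverage, class.
#' @export
transcript_uniqueness <- function(transcripts, ref, min_id = 0.90,
                                  min_cov = 0.70, unique_cov = 0.50,
                                  cfg = pipeline_config()) {
  # spliced mode: reference gaps beyond a typical small-indel size start a
  # new block, so introns never enter the identity denominator
  al <- align_sequences(transcripts, ref, min_len = cfg$anchor_min_len,
                        max_join_gap = 60, band = cfg$band,
                        max_extend = cfg$max_extend)
  rows <- lapply(names(transcripts), function(tid) {
    cc <- al$candidates[al$candidates$contig_id == tid, , drop = FALSE]
    if (!nrow(cc)) return(data.frame(transcript_id = tid, identity = 0,
                                     coverage = 0, class = "unique"))
    best <- cc[which.max(cc$score), , drop = FALSE]
    cl <- if (best$identity >= min_id && best$coverage >= min_cov) "mapped"
    else if (best$coverage < unique_cov) "unique"
    else "unmapped"
    data.frame(transcript_id = tid, identity = best$identity,
               coverage = best$coverage, class = cl)
  })
  do.call(rbind, rows)
}

#' Gene presence matrix across donors and absent-gene densities
#'
#' @param coverages named list of [exon_coverage()] outputs (one per
#'   donor).
#' @param chrom_lengths named numeric vector of chromosome lengths, bp.
#' @return list(matrix = gene x donor logical data.frame with gene_id and
#'   chrom, shared_absent = count absent in every donor, density =
#'   per-chromosome absent-genes-per-Mb for each donor).
#' @export
presence_matrix <- function(coverages, chrom_lengths) {
  stopifnot(length(coverages) >= 1, !is.null(names(coverages)))
  base <- coverages[[1]][, c("gene_id", "chrom")]
  mat <- base
  for (d in names(coverages)) {
    cv <- coverages[[d]]
    mat[[d]] <- cv$present[match(mat$gene_id, cv$gene_id)]
  }
  pres <- as.matrix(mat[, names(coverages), drop = FALSE])
  shared_absent <- sum(rowSums(!pres) == length(coverages))
  dens <- do.call(rbind, lapply(names(coverages), function(d) {
    data.frame(donor = d, chrom = names(chrom_lengths),
               absent = vapply(names(chrom_lengths), function(c0)
                 sum(!mat[[d]][mat$chrom == c0]), numeric(1)),
               per_mb = vapply(names(chrom_lengths), function(c0)
                 sum(!mat[[d]][mat$chrom == c0]) /
                   (chrom_lengths[[c0]] / 1e6), numeric(1)))
  }))
  list(matrix = mat, shared_absent = shared_absent, density = dens)
}
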