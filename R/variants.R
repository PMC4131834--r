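# Inter-genome variant calling from split/gapped contig alignments. SNPs
# come from mismatching alignment columns of one-to-one placements; large
# indels from the gap pattern between consecutive blocks of one candidate:
# a query-only gap of >= 100 bp with >= 200 bp aligned flanks is an
# insertion, a reference-only gap of 100-50,000 bp with >= 200 bp flanks a
# deletion; events gapped on both sides are classified COMPLEX and excluded
# from the INS/DEL counts. Breakpoints are validated by read support
# (>= 5 spanning reads plus a straddling pair).

# oriented query segment of a block (the sequence its CIGAR runs along)
block_query_seq <- function(block, contig) {
  if (block$strand == "+") substr(contig, block$q_start + 1, block$q_end)
  else revcomp(substr(contig, block$q_start + 1, block$q_end))
}

#' Call SNPs between two genomes from accepted placements
#'
#' Walks every alignment block of the accepted (one-to-one) placements and
#' emits a SNP at each column where both bases are unambiguous and differ.
#' `aligned_bp` counts reference columns where both genomes contribute a
#' base (M columns). Duplicate sites from tolerated placement overlaps are
#' deduplicated.
#'
#' @param placements accepted placements from [align_contigs()] /
#'   [filter_placements()].
#' @param blocks their alignment blocks (same `cand_id`).
#' @param contigs named character vector (donor contigs).
#' @param ref named character vector.
#' @return list(snps = data.frame(chrom, r_pos, ref_base, alt_base,
#'   contig_id), aligned_bp).
#' @export
call_snps <- function(placements, blocks, contigs, ref) {
  if (nrow(placements) && (is.null(blocks) || !nrow(blocks)))
    stop("placements have no alignment blocks")
  rows <- list(); aligned_bp <- 0
  bl <- if (is.null(blocks)) NULL else
    blocks[blocks$cand_id %in% placements$cand_id, , drop = FALSE]
  if (is.null(bl)) bl <- data.frame()
  for (i in seq_len(nrow(bl))) {
    b <- bl[i, ]
    qseq <- block_query_seq(b, contigs[[b$contig_id]])
    rseq <- substr(ref[[b$chrom]], b$r_start + 1, b$r_end)
    mm <- cpp_block_mismatches(qseq, rseq, b$cigar)
    aligned_bp <- aligned_bp + mm$m_columns
    if (length(mm$r_off)) {
      r_pos <- b$r_start + mm$r_off
      rows[[length(rows) + 1]] <- data.frame(
        chrom = b$chrom, r_pos = r_pos,
        ref_base = substring(rseq, mm$r_off + 1, mm$r_off + 1),
        alt_base = substring(qseq, mm$q_off + 1, mm$q_off + 1),
        contig_id = b$contig_id)
    }
  }
  snps <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), r_pos = numeric(0),
               ref_base = character(0), alt_base = character(0),
               contig_id = character(0))
  snps <- snps[!duplicated(paste(snps$chrom, snps$r_pos)), , drop = FALSE]
  snps <- snps[order(snps$chrom, snps$r_pos), , drop = FALSE]
  list(snps = snps, aligned_bp = aligned_bp)
}

# consecutive-block gap table for one candidate, in frame (oriented-query)
# space so query gaps are meaningful on either strand
block_gaps <- function(cand_blocks) {
  cb <- cand_blocks[order(cand_blocks$f_start), , drop = FALSE]
  n <- nrow(cb)
  if (n < 2) return(NULL)
  i <- seq_len(n - 1)
  data.frame(
    contig_id = cb$contig_id[1], chrom = cb$chrom[1], strand = cb$strand[1],
    q_gap = cb$f_start[i + 1] - cb$f_end[i],
    r_gap = cb$r_start[i + 1] - cb$r_end[i],
    r_pos = cb$r_end[i],
    f_break = cb$f_end[i],
    left_flank = pmin(cb$f_end[i] - cb$f_start[i],
                      cb$r_end[i] - cb$r_start[i]),
    right_flank = pmin(cb$f_end[i + 1] - cb$f_start[i + 1],
                       cb$r_end[i + 1] - cb$r_start[i + 1]))
}

#' Classify large insertions from split alignments
#'
#' Between consecutive blocks of one candidate: a query gap >= `min_unaligned`
#' with a reference gap <= `other_gap_tol` and both flanking blocks >=
#' `min_flank` aligned bp is an insertion of the query-gap size. Contig-
#' terminal unaligned tails are never called. Gaps large on both sides are
#' returned as COMPLEX (excluded from INS counts downstream).
#'
#' @param blocks alignment blocks of accepted placements.
#' @param contigs named character vector (for the inserted sequence).
#' @param min_unaligned minimum inserted size, bp (default 100).
#' @param min_flank minimum aligned flank, bp (default 200).
#' @param other_gap_tol largest reference-side gap still called INS.
#' @return large-indel table: chrom, r_pos, type, size, left_flank,
#'   right_flank, seq, contig_id.
#' @export
classify_insertions <- function(blocks, contigs, min_unaligned = 100,
                                min_flank = 200, other_gap_tol = 10) {
  classify_gaps(blocks, contigs, "INS", min_unaligned, Inf, min_flank,
                other_gap_tol)
}

#' Classify large deletions from gapped alignments
#'
#' Reference gap in [`min_size`, `max_size`] with query gap <=
#' `other_gap_tol` and >= `min_flank` aligned flanks.
#'
#' @inheritParams classify_insertions
#' @param min_size,max_size deletion size window, bp (defaults 100 and
#'   50,000).
#' @return large-indel table (type DEL / COMPLEX).
#' @export
classify_deletions <- function(blocks, contigs, min_size = 100,
                               max_size = 50000, min_flank = 200,
                               other_gap_tol = 10) {
  classify_gaps(blocks, contigs, "DEL", min_size, max_size, min_flank,
                other_gap_tol)
}

classify_gaps <- function(blocks, contigs, want, min_size, max_size,
                          min_flank, other_gap_tol) {
  empty <- data.frame(chrom = character(0), r_pos = numeric(0),
                      type = character(0), size = numeric(0),
                      left_flank = numeric(0), right_flank = numeric(0),
                      seq = character(0), contig_id = character(0))
  if (is.null(blocks) || !nrow(blocks)) return(empty)
  rows <- list()
  want_op <- if (want == "INS") "I" else "D"
  for (cid in unique(blocks$cand_id)) {
    cb <- blocks[blocks$cand_id == cid, , drop = FALSE]
    # between-block gaps (split alignments)
    g <- block_gaps(cb)
    if (!is.null(g)) for (i in seq_len(nrow(g))) {
      gi <- g[i, ]
      if (gi$left_flank < min_flank || gi$right_flank < min_flank) next
      main_gap <- if (want == "INS") gi$q_gap else gi$r_gap
      other_gap <- if (want == "INS") gi$r_gap else gi$q_gap
      if (main_gap < min_size || main_gap > max_size) next
      type <- if (other_gap > other_gap_tol) "COMPLEX" else want
      seq_out <- ""
      if (type == "INS") {
        ctg <- contigs[[gi$contig_id]]
        oq <- if (gi$strand == "+") ctg else revcomp(ctg)
        seq_out <- substr(oq, gi$f_break + 1, gi$f_break + gi$q_gap)
      }
      rows[[length(rows) + 1]] <- data.frame(
        chrom = gi$chrom, r_pos = gi$r_pos, type = type, size = main_gap,
        left_flank = gi$left_flank, right_flank = gi$right_flank,
        seq = seq_out, contig_id = gi$contig_id)
    }
    # within-block gap runs (gapped alignments)
    for (bi in seq_len(nrow(cb))) {
      b <- cb[bi, ]
      n <- as.numeric(regmatches(b$cigar, gregexpr("[0-9]+", b$cigar))[[1]])
      op <- regmatches(b$cigar, gregexpr("[MID]", b$cigar))[[1]]
      hits <- which(op == want_op & n >= min_size & n <= max_size)
      if (!length(hits)) next
      ref_adv <- ifelse(op %in% c("M", "D"), n, 0)
      q_adv <- ifelse(op %in% c("M", "I"), n, 0)
      m_cum <- cumsum(ifelse(op == "M", n, 0))
      m_tot <- m_cum[length(m_cum)]
      for (h in hits) {
        left <- if (h > 1) m_cum[h - 1] else 0
        right <- m_tot - m_cum[h]
        if (left < min_flank || right < min_flank) next
        # immediate opposite-type neighbours flag complex events
        other <- sum(n[intersect(c(h - 1, h + 1),
                                 which(op == setdiff(c("I", "D"), want_op)))])
        type <- if (other > other_gap_tol) "COMPLEX" else want
        r_pos <- b$r_start + if (h > 1) sum(ref_adv[seq_len(h - 1)]) else 0
        seq_out <- ""
        if (type == "INS") {
          ctg <- contigs[[b$contig_id]]
          oq <- if (b$strand == "+") ctg else revcomp(ctg)
          q_off <- b$f_start + if (h > 1) sum(q_adv[seq_len(h - 1)]) else 0
          seq_out <- substr(oq, q_off + 1, q_off + n[h])
        }
        rows[[length(rows) + 1]] <- data.frame(
          chrom = b$chrom, r_pos = r_pos, type = type, size = n[h],
          left_flank = left, right_flank = right, seq = seq_out,
          contig_id = b$contig_id)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$r_pos), , drop = FALSE]
}

#' Validate indel breakpoints by read support
#'
#' A call is validated when each of its breakpoints on the donor
#' pseudomolecule is crossed by at least `min_span_reads` read alignments
#' extending `min_anchor` bp on both sides, and at least one read pair
#' straddles the event. Breakpoints are located by projecting the flanking
#' contig coordinates through the AGP. Calls in regions without coverage
#' are flagged `NO_DATA`.
#'
#' @param indels large-indel table (INS/DEL rows).
#' @param sam read alignments against the pseudomolecules (pos 0-based;
#'   pair naming `<id>/1`, `<id>/2` or proper SAM flags).
#' @param agp AGP of the pseudomolecules (for contig -> object projection).
#' @param blocks alignment blocks of the calls' candidates.
#' @param min_span_reads spanning reads required per breakpoint (default 5).
#' @param min_anchor bp a spanning read must extend past the breakpoint.
#' @return `indels` with `validated` (logical) and `support` columns;
#'   uncovered calls get `validated = NA` (NO_DATA).
#' @export
validate_boundaries <- function(indels, sam, agp, blocks,
                                min_span_reads = 5, min_anchor = 20) {
  if (!nrow(indels)) {
    indels$validated <- logical(0); indels$support <- numeric(0)
    return(indels)
  }
  # contig -> (object, offset, strand) from AGP W rows
  w <- agp[agp$component_type == "W", , drop = FALSE]
  comp <- setNames(split(w, seq_len(nrow(w))), w$component_id)
  to_object <- function(contig_id, cpos) {
    r <- comp[[contig_id]]
    if (is.null(r)) return(NULL)
    if (r$orientation == "+") list(obj = r$object,
                                   pos = r$object_beg - 1 + cpos)
    else list(obj = r$object, pos = r$object_end - cpos)
  }
  keep <- bitwAnd(sam$flag, 4L) == 0
  sam <- sam[keep, , drop = FALSE]
  sam$end <- sam$pos + cigar_ref_span(sam$cigar)
  sam$pair <- sub("/[12]$", "", sam$qname)
  # per-object read tables sorted by position, for windowed lookup
  by_obj <- lapply(split(sam[, c("pos", "end", "pair")], sam$rname),
                   function(d) d[order(d$pos), , drop = FALSE])
  near <- function(obj, at, win = 5000) {
    d <- by_obj[[obj]]
    if (is.null(d) || !nrow(d)) return(d)
    lo <- findInterval(at - win, d$pos) + 1
    hi <- findInterval(at + win, d$pos)
    if (hi < lo) return(d[0, , drop = FALSE])
    d[lo:hi, , drop = FALSE]
  }
  validated <- rep(NA, nrow(indels))
  support <- rep(0, nrow(indels))
  for (i in seq_len(nrow(indels))) {
    v <- indels[i, ]
    cb <- blocks[blocks$contig_id == v$contig_id & blocks$chrom == v$chrom, ,
                 drop = FALSE]
    if (!nrow(cb)) next
    # donor-side breakpoints in contig frame coordinates
    left_f <- cb$f_end[which.min(abs(cb$r_end - v$r_pos))]
    bks <- if (v$type == "INS") c(left_f, left_f + v$size) else left_f
    # convert frame coords back to contig coords
    ctg_len <- max(cb$q_end)
    strand <- cb$strand[1]
    cpos <- if (strand == "+") bks else ctg_len - bks
    ok_all <- TRUE; sup_min <- Inf; cover <- FALSE
    straddle <- FALSE
    for (bp in cpos) {
      o <- to_object(v$contig_id, bp)
      if (is.null(o)) { ok_all <- FALSE; break }
      on_obj <- near(o$obj, o$pos)
      if (is.null(on_obj)) { ok_all <- FALSE; next }
      span <- on_obj$pos + min_anchor <= o$pos &
        on_obj$end - min_anchor >= o$pos
      cover <- cover || any(on_obj$pos <= o$pos & on_obj$end >= o$pos)
      sup_min <- min(sup_min, sum(span))
      if (sum(span) < min_span_reads) ok_all <- FALSE
      # straddling pair: the fragment (both mates) crosses the breakpoint
      if (!straddle && nrow(on_obj)) {
        frag_lo <- tapply(on_obj$pos, on_obj$pair, min)
        frag_hi <- tapply(on_obj$end, on_obj$pair, max)
        n_ends <- tapply(on_obj$pos, on_obj$pair, length)
        straddle <- any(n_ends >= 2 & frag_lo + min_anchor <= o$pos &
                          frag_hi - min_anchor >= o$pos)
      }
    }
    if (!cover) { validated[i] <- NA; support[i] <- 0; next }
    support[i] <- if (is.finite(sup_min)) sup_min else 0
    validated[i] <- ok_all && straddle
  }
  indels$validated <- validated
  indels$support <- support
  indels
}

# reference span consumed by a CIGAR (M/D/=/X advance; I/S/H do not)
cigar_ref_span <- function(cigars) {
  vapply(cigars, function(cg) {
    if (cg == "*") return(0)
    n <- as.numeric(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    op <- regmatches(cg, gregexpr("[MIDSH=X]", cg))[[1]]
    sum(n[op %in% c("M", "D", "=", "X")])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Summarize SNP and large-indel calls
#'
#' Per-chromosome counts with totals, SNP frequency in percent (2
#' decimals), and INS/DEL splits with total nucleotides and the mean indel
#' length (total indel bp / indel sites, rounded to bp).
#'
#' @param snps SNP table from [call_snps()].
#' @param indels large-indel table (COMPLEX rows are excluded here).
#' @param aligned_bp reference columns compared.
#' @param chroms chromosome names (row order of the summary).
#' @return list(per_chrom, totals): `per_chrom` has snps/indels columns per
#'   chromosome; `totals` holds snp_total, indel_total, aligned_bp,
#'   snp_frequency_pct, ins_sites, ins_bp, del_sites, del_bp,
#'   mean_indel_len.
#' @export
summarize_variants <- function(snps, indels, aligned_bp, chroms) {
  indels <- indels[indels$type %in% c("INS", "DEL"), , drop = FALSE]
  per_chrom <- data.frame(
    chrom = chroms,
    snps = vapply(chroms, function(c0) sum(snps$chrom == c0), numeric(1)),
    indels = vapply(chroms, function(c0) sum(indels$chrom == c0), numeric(1)))
  snp_total <- sum(per_chrom$snps)
  indel_total <- sum(per_chrom$indels)
  ins <- indels[indels$type == "INS", , drop = FALSE]
  del <- indels[indels$type == "DEL", , drop = FALSE]
  totals <- data.frame(
    snp_total = snp_total, indel_total = indel_total,
    aligned_bp = aligned_bp,
    snp_frequency_pct = if (aligned_bp > 0)
      round(100 * snp_total / aligned_bp, 2) else 0,
    ins_sites = nrow(ins), ins_bp = sum(ins$size),
    del_sites = nrow(del), del_bp = sum(del$size),
    mean_indel_len = if (indel_total > 0)
      round(sum(indels$size) / indel_total) else 0)
  list(per_chrom = per_chrom, totals = totals)
}
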