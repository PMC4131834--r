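# Pileup-based contig error correction: reads aligned to the draft contigs
# are tallied per column; a correction is applied where the majority
# non-contig allele is effectively homozygous — frequency >= 70% of
# quality-filtered reads, depth >= 10, and consensus quality >= Q30 — and
# the whole procedure runs twice. The consensus quality is a Phred-scaled
# surrogate, min(999, sum of supporting base qualities - sum of conflicting
# base qualities); it is monotone in support like the samtools model it
# stands in for, but simpler.

#' Correction-rule thresholds
#'
#' @param min_qual minimum consensus quality (default 30).
#' @param min_depth minimum quality-filtered depth (default 10).
#' @param min_freq minimum allele frequency among quality-filtered reads
#'   (default 0.70).
#' @param rounds correction rounds (default 2).
#' @param min_map_qual reads below this MAPQ are excluded (default 20).
#' @param min_base_qual bases below this quality are not tallied
#'   (default 20).
#' @return a validated list of class `correction_rule`.
#' @export
correction_rule <- function(min_qual = 30, min_depth = 10, min_freq = 0.70,
                            rounds = 2, min_map_qual = 20,
                            min_base_qual = 20) {
  stopifnot_scalar(min_freq, "min_freq", 1e-9, 1)
  stopifnot_scalar(rounds, "rounds", 1)
  r <- list(min_qual = min_qual, min_depth = min_depth, min_freq = min_freq,
            rounds = as.integer(rounds), min_map_qual = min_map_qual,
            min_base_qual = min_base_qual)
  class(r) <- "correction_rule"
  r
}

#' Build per-position pileups from SAM records
#'
#' One pileup per contig: base/deletion tallies and summed Phred qualities
#' per allele, plus inserted-sequence observations anchored to the contig
#' position they follow. Records that are unmapped, secondary,
#' supplementary or duplicate-flagged, or below `rule$min_map_qual`, are
#' skipped; bases below `rule$min_base_qual` are not tallied.
#'
#' @param sam SAM-subset data.frame (see [read_sam()]; pos 0-based).
#' @param contigs named character vector.
#' @param rule a [correction_rule()].
#' @return named list (per contig): list(counts, qsum, ins) where counts and
#'   qsum are position x allele (A,C,G,T,del) matrices and ins is a
#'   data.frame(pos, seq, qual).
#' @export
build_pileup <- function(sam, contigs, rule = correction_rule()) {
  drop <- bitwAnd(sam$flag, 4L) != 0 |       # unmapped
    bitwAnd(sam$flag, 256L) != 0 |           # secondary
    bitwAnd(sam$flag, 2048L) != 0 |          # supplementary
    bitwAnd(sam$flag, 1024L) != 0 |          # PCR duplicate
    sam$mapq < rule$min_map_qual
  sam <- sam[!drop & sam$rname %in% names(contigs), , drop = FALSE]
  out <- list()
  for (ctg in names(contigs)) {
    rows <- sam[sam$rname == ctg, , drop = FALSE]
    len <- nchar(contigs[[ctg]])
    if (any(rows$pos >= len)) {
      warning(sprintf("%d record(s) start beyond contig %s; skipped",
                      sum(rows$pos >= len), ctg))
      rows <- rows[rows$pos < len, , drop = FALSE]
    }
    p <- cpp_pileup(as.integer(len), as.integer(rows$pos), rows$cigar,
                    rows$seq, rows$qual, as.integer(rule$min_base_qual))
    colnames(p$counts) <- colnames(p$qsum) <- c("A", "C", "G", "T", "del")
    out[[ctg]] <- list(counts = p$counts, qsum = p$qsum,
                       ins = data.frame(pos = p$ins_pos, seq = p$ins_seq,
                                        qual = p$ins_qual))
  }
  out
}

#' Call corrections from pileups
#'
#' Emits a correction where the majority allele differs from the contig
#' base and passes all rule thresholds: frequency >= `min_freq` of the
#' quality-filtered depth, depth >= `min_depth`, and consensus quality
#' (supporting minus conflicting base-quality sums, capped at 999)
#' >= `min_qual`. Exact 50/50 ties never call. Insertions take the most
#' frequent inserted sequence, ties broken lexicographically.
#'
#' @param pileup output of [build_pileup()].
#' @param contigs named character vector.
#' @param rule a [correction_rule()].
#' @return data.frame: contig_id, pos, type (SUB/DEL/INS), old_base,
#'   new_base, depth, freq, qual.
#' @export
call_corrections <- function(pileup, contigs, rule = correction_rule()) {
  rows <- list()
  alleles <- c("A", "C", "G", "T", "del")
  for (ctg in names(pileup)) {
    p <- pileup[[ctg]]
    depth <- rowSums(p$counts)
    cand <- which(depth >= rule$min_depth)
    if (length(cand)) {
      ctg_bases <- substring(contigs[[ctg]], cand, cand)
      top_i <- max.col(p$counts[cand, , drop = FALSE], ties.method = "first")
      top_allele <- alleles[top_i]
      top_n <- p$counts[cbind(cand, top_i)]
      freq <- top_n / depth[cand]
      qual <- pmin(999, p$qsum[cbind(cand, top_i)] -
                     (rowSums(p$qsum[cand, , drop = FALSE]) -
                        p$qsum[cbind(cand, top_i)]))
      hit <- top_allele != ctg_bases & freq >= rule$min_freq &
        qual >= rule$min_qual & top_n > depth[cand] / 2
      if (any(hit)) {
        rows[[length(rows) + 1]] <- data.frame(
          contig_id = ctg, pos = cand[hit] - 1,
          type = ifelse(top_allele[hit] == "del", "DEL", "SUB"),
          old_base = ctg_bases[hit],
          new_base = ifelse(top_allele[hit] == "del", "", top_allele[hit]),
          depth = depth[cand][hit], freq = freq[hit], qual = qual[hit])
      }
    }
    # insertions: support = observations at an anchor; conflict = covering
    # reads without the insertion
    if (nrow(p$ins)) {
      for (a in unique(p$ins$pos)) {
        obs <- p$ins[p$ins$pos == a, , drop = FALSE]
        d <- depth[a + 1]
        if (is.na(d) || d < rule$min_depth) next
        n_sup <- nrow(obs)
        freq <- n_sup / d
        if (freq < rule$min_freq) next
        tab <- sort(table(obs$seq), decreasing = TRUE)
        best <- names(tab)[tab == max(tab)]
        best <- sort(best)[1]
        qual <- min(999, sum(obs$qual[obs$seq == best]) -
                      sum(obs$qual[obs$seq != best]))
        if (qual < rule$min_qual) next
        rows[[length(rows) + 1]] <- data.frame(
          contig_id = ctg, pos = a, type = "INS", old_base = "",
          new_base = best, depth = d, freq = freq, qual = qual)
      }
    }
  }
  if (!length(rows))
    return(data.frame(contig_id = character(0), pos = numeric(0),
                      type = character(0), old_base = character(0),
                      new_base = character(0), depth = numeric(0),
                      freq = numeric(0), qual = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$contig_id, out$pos), , drop = FALSE]
}

# apply corrections to one contig (positions descending so indels do not
# shift pending coordinates)
apply_corrections <- function(contig, corr) {
  corr <- corr[order(-corr$pos), , drop = FALSE]
  for (i in seq_len(nrow(corr))) {
    pos <- corr$pos[i]
    contig <- switch(corr$type[i],
      SUB = paste0(substr(contig, 1, pos), corr$new_base[i],
                   substr(contig, pos + 2, nchar(contig))),
      DEL = paste0(substr(contig, 1, pos),
                   substr(contig, pos + 2, nchar(contig))),
      INS = paste0(substr(contig, 1, pos + 1), corr$new_base[i],
                   substr(contig, pos + 2, nchar(contig))))
  }
  contig
}

#' Polish contigs by iterated pileup correction
#'
#' Runs `rule$rounds` correction rounds; each round maps the reads to the
#' current contigs (self-contained mode via [map_reads()]), or uses the
#' supplied SAM for round one, builds pileups, calls and applies
#' corrections. Round r+1 always operates on round-r output; later rounds
#' remap the reads extracted from the SAM when no read set is given.
#'
#' @param contigs named character vector.
#' @param reads named character vector of read sequences (optional when
#'   `sam` is given).
#' @param quals named quality strings matching `reads`.
#' @param sam SAM-subset data.frame of read-to-contig alignments for round
#'   one.
#' @param rule a [correction_rule()].
#' @return list(contigs, log): corrected contigs and the per-round
#'   correction log (column `round` added to [call_corrections()] output,
#'   empty rounds still listed in `rounds_run`).
#' @export
polish_contigs <- function(contigs, reads = NULL, quals = NULL, sam = NULL,
                           rule = correction_rule()) {
  if (is.null(reads) && is.null(sam))
    stop("either reads or sam must be supplied")
  if (is.null(reads)) {
    keep <- bitwAnd(sam$flag, 4L) == 0 & bitwAnd(sam$flag, 256L) == 0 &
      bitwAnd(sam$flag, 2048L) == 0
    src <- sam[keep, , drop = FALSE]
    src <- src[!duplicated(paste(src$qname, bitwAnd(src$flag, 192L))), ,
               drop = FALSE]
    rc_mask <- bitwAnd(src$flag, 16L) != 0
    reads <- ifelse(rc_mask, revcomp(src$seq), src$seq)
    quals <- ifelse(rc_mask, vapply(src$qual, function(q)
      paste(rev(strsplit(q, "")[[1]]), collapse = ""), character(1),
      USE.NAMES = FALSE), src$qual)
    names(reads) <- names(quals) <-
      paste0(src$qname, "/", ifelse(bitwAnd(src$flag, 128L) != 0, "2", "1"))
  }
  logs <- list()
  for (r in seq_len(rule$rounds)) {
    aln <- if (r == 1 && !is.null(sam)) sam
    else map_reads(reads, contigs, quals = quals)
    if (!nrow(aln) || all(bitwAnd(aln$flag, 4L) != 0))
      warning("no mapped reads; zero corrections in round ", r)
    pl <- build_pileup(aln, contigs, rule)
    corr <- call_corrections(pl, contigs, rule)
    if (nrow(corr)) {
      for (ctg in unique(corr$contig_id))
        contigs[ctg] <- apply_corrections(contigs[[ctg]],
                                          corr[corr$contig_id == ctg, ,
                                               drop = FALSE])
    }
    corr$round <- if (nrow(corr)) r else integer(0)
    logs[[r]] <- corr
  }
  log <- do.call(rbind, logs)
  list(contigs = contigs, log = log, rounds_run = rule$rounds)
}
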