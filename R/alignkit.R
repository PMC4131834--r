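# Anchor-based whole-genome alignment: maximal-exact-match (MEM) seeding,
# max-weight collinear chaining, banded inter-anchor extension, and
# identity/coverage filtering with one-to-one placement tiling.
#
# Conventions: anchors and blocks report query coordinates in the ORIGINAL
# contig frame (0-based half-open). For minus-strand hits the aligned
# sequence is revcomp(contig)[frame coords], where frame coords are
# (len - q_end, len - q_start); block CIGARs run along that oriented query
# (ops M/I/D; I consumes query). Identity = matches / alignment columns,
# gap columns included in the denominator.

#' Build a reusable k-mer index of a reference genome
#'
#' @param ref named character vector of chromosome sequences.
#' @param k seed (and minimum MEM) length, 12-31.
#' @return an opaque index object for [find_anchors()] and [map_reads()].
#' @export
ref_index <- function(ref, k = 20) {
  stopifnot(is.character(ref), !is.null(names(ref)))
  structure(list(ptr = cpp_ref_index(ref, as.integer(k)),
                 names = names(ref),
                 lengths = setNames(nchar(ref), names(ref)), k = k),
            class = "ref_index")
}

#' Find all maximal exact matches between a contig and a reference
#'
#' Every returned anchor is an exact match of length >= `min_len`,
#' extendable in neither direction; both strands are searched.
#'
#' @param contig a single sequence (character scalar).
#' @param ref named character vector, or a prebuilt [ref_index()].
#' @param min_len minimum MEM length (>= 12). Ignored when `ref` is a
#'   prebuilt index (its `k` applies).
#' @param max_hits skip seeds whose k-mer occurs more often than this in the
#'   reference (0 = no limit).
#' @param contig_id id stored in the output.
#' @return data.frame: contig_id, q_start, q_end, chrom, r_start, r_end,
#'   strand, length.
#' @export
find_anchors <- function(contig, ref, min_len = 20, max_hits = 0,
                         contig_id = "query") {
  if (min_len < 12) stop("min_len must be >= 12")
  idx <- if (inherits(ref, "ref_index")) ref else ref_index(ref, min_len)
  if (!nzchar(contig))
    return(data.frame(contig_id = character(0), q_start = numeric(0),
                      q_end = numeric(0), chrom = character(0),
                      r_start = numeric(0), r_end = numeric(0),
                      strand = character(0), length = numeric(0)))
  m <- cpp_find_mems(idx$ptr, contig, as.integer(max_hits))
  data.frame(contig_id = rep(contig_id, nrow(m)),
             q_start = m$q_start, q_end = m$q_end,
             chrom = idx$names[m$chrom_i], r_start = m$r_start,
             r_end = m$r_end, strand = m$strand,
             length = m$q_end - m$q_start)
}

# frame (oriented-query) coordinates of anchors: identical to q coords on
# "+", mirrored on "-"
anchor_frame <- function(anchors, contig_len) {
  fs <- ifelse(anchors$strand == "-", contig_len - anchors$q_end,
               anchors$q_start)
  fe <- ifelse(anchors$strand == "-", contig_len - anchors$q_start,
               anchors$q_end)
  cbind(fs = fs, fe = fe)
}

#' Chain anchors into collinear placement candidates
#'
#' Per (chromosome, strand) group, extracts maximum-weight collinear anchor
#' subsets (anchor-length weighted, no anchor in two chains). Consecutive
#' chain members separated by more than `max_join_gap` on either the
#' reference or the query start separate blocks but stay within one
#' candidate — the split-alignment signature of a large indel.
#'
#' @param anchors anchor table from [find_anchors()] (one contig).
#' @param max_join_gap bp gap beyond which a new block starts.
#' @param contig_len contig length in bp (needed for minus-strand frames).
#' @param min_chain_weight discard chains lighter than this many matched bp.
#' @param max_chains cap on chains per (chromosome, strand) group.
#' @return list of candidates; each is a data.frame of chain anchors (in
#'   chain order, with frame coords `fs`,`fe`) carrying a `block` column.
#' @export
chain_anchors <- function(anchors, max_join_gap = 1000, contig_len = NULL,
                          min_chain_weight = 40, max_chains = 20) {
  if (!nrow(anchors)) return(list())
  if (length(unique(anchors$contig_id)) > 1)
    stop("chain_anchors expects anchors from a single contig")
  if (is.null(contig_len)) contig_len <- max(anchors$q_end)
  fr <- anchor_frame(anchors, contig_len)
  anchors$fs <- fr[, "fs"]; anchors$fe <- fr[, "fe"]
  out <- list()
  for (key in unique(paste(anchors$chrom, anchors$strand))) {
    grp <- anchors[paste(anchors$chrom, anchors$strand) == key, , drop = FALSE]
    chains <- cpp_chain(as.integer(grp$fs), as.integer(grp$fe),
                        grp$r_start, grp$r_end, min_chain_weight,
                        as.integer(max_chains))
    for (ch in chains) {
      cand <- grp[ch, , drop = FALSE]
      qgap <- c(0, cand$fs[-1] - cand$fe[-nrow(cand)])
      rgap <- c(0, cand$r_start[-1] - cand$r_end[-nrow(cand)])
      cand$block <- cumsum(qgap > max_join_gap | rgap > max_join_gap) + 1L
      out[[length(out) + 1]] <- cand
    }
  }
  out
}

# trim chain anchors so consecutive members do not overlap on either axis
# (trimming an exact match keeps it exact); drops anchors consumed entirely
trim_chain <- function(cand) {
  keep <- rep(TRUE, nrow(cand))
  last_fe <- cand$fe[1]; last_re <- cand$r_end[1]
  for (i in seq_len(nrow(cand))[-1]) {
    cut <- max(last_fe - cand$fs[i], last_re - cand$r_start[i], 0)
    if (cand$fe[i] - cand$fs[i] <= cut) { keep[i] <- FALSE; next }
    cand$fs[i] <- cand$fs[i] + cut
    cand$r_start[i] <- cand$r_start[i] + cut
    last_fe <- cand$fe[i]; last_re <- cand$r_end[i]
  }
  cand[keep, , drop = FALSE]
}

#' Extend a chained candidate into scored alignment blocks
#'
#' Inter-anchor segments up to `max_extend` bp are aligned by banded global
#' alignment (match +1, mismatch -1, gap -2 by default; the band widens once
#' if the optimal path touches it, then the block is split). Larger
#' segments, and the gaps flagged at chaining time, delimit block
#' boundaries. Contig tails outside the chain stay unaligned.
#'
#' @param cand one candidate from [chain_anchors()].
#' @param contig the contig sequence.
#' @param ref named character vector (reference genome).
#' @param band extra band half-width in bp beyond the length difference.
#' @param max_extend largest inter-anchor segment to align, bp.
#' @param scores list(match, mismatch, gap).
#' @return data.frame of alignment blocks: contig_id, chrom, strand,
#'   q_start, q_end (original frame), r_start, r_end, matches, aln_columns,
#'   identity, cigar.
#' @export
extend_and_score <- function(cand, contig, ref, band = 50, max_extend = 5000,
                             scores = list(match = 1, mismatch = -1, gap = -2)) {
  contig_len <- nchar(contig)
  strand <- cand$strand[1]; chrom <- cand$chrom[1]
  oq <- if (strand == "+") contig else revcomp(contig)
  rseq <- ref[[chrom]]
  cand <- trim_chain(cand)
  blocks <- list()
  cur <- NULL  # list(fs, fe, rs, re, matches, cols, cigar_parts)
  flush <- function() {
    if (is.null(cur)) return()
    cig <- paste(cur$cigar_parts, collapse = "")
    blocks[[length(blocks) + 1]] <<- data.frame(
      contig_id = cand$contig_id[1], chrom = chrom, strand = strand,
      q_start = if (strand == "+") cur$fs else contig_len - cur$fe,
      q_end = if (strand == "+") cur$fe else contig_len - cur$fs,
      f_start = cur$fs, f_end = cur$fe,
      r_start = cur$rs, r_end = cur$re,
      matches = cur$matches, aln_columns = cur$cols,
      identity = cur$matches / cur$cols, cigar = cig)
    cur <<- NULL
  }
  for (i in seq_len(nrow(cand))) {
    a <- cand[i, ]
    alen <- a$fe - a$fs
    if (is.null(cur)) {
      cur <- list(fs = a$fs, fe = a$fe, rs = a$r_start, re = a$r_end,
                  matches = alen, cols = alen,
                  cigar_parts = sprintf("%dM", alen))
      next
    }
    qgap <- a$fs - cur$fe
    rgap <- a$r_start - cur$re
    new_block <- (i > 1 && cand$block[i] != cand$block[i - 1]) ||
      max(qgap, rgap) > max_extend
    if (!new_block && (qgap > 0 || rgap > 0)) {
      qseg <- substr(oq, cur$fe + 1, a$fs)
      rseg <- substr(rseq, cur$re + 1, a$r_start)
      seg <- align_segment(qseg, rseg, band, scores)
      if (is.null(seg)) new_block <- TRUE
      else {
        cur$matches <- cur$matches + seg$matches
        cur$cols <- cur$cols + seg$columns
        cur$cigar_parts <- c(cur$cigar_parts, seg$cigar)
      }
    }
    if (new_block) { flush(); cur <- list(fs = a$fs, fe = a$fe, rs = a$r_start,
                                          re = a$r_end, matches = alen,
                                          cols = alen,
                                          cigar_parts = sprintf("%dM", alen)) }
    else {
      cur$fe <- a$fe; cur$re <- a$r_end
      cur$matches <- cur$matches + alen
      cur$cols <- cur$cols + alen
      cur$cigar_parts <- c(cur$cigar_parts, sprintf("%dM", alen))
    }
  }
  flush()
  out <- do.call(rbind, blocks)
  out$cigar <- vapply(out$cigar, collapse_cigar, character(1), USE.NAMES = FALSE)
  out
}

# banded alignment of one inter-anchor segment; widen once on band contact,
# then give up (caller splits the block). Zero-length sides are pure gaps.
align_segment <- function(qseg, rseg, band, scores) {
  lq <- nchar(qseg); lr <- nchar(rseg)
  if (lq == 0 && lr == 0) return(list(matches = 0, columns = 0, cigar = ""))
  if (lq == 0) return(list(matches = 0, columns = lr,
                           cigar = sprintf("%dD", lr)))
  if (lr == 0) return(list(matches = 0, columns = lq,
                           cigar = sprintf("%dI", lq)))
  if (lq == lr && lq <= 2) {  # fast path: tiny equal-length segment
    m <- sum(strsplit(qseg, "")[[1]] == strsplit(rseg, "")[[1]])
    return(list(matches = m, columns = lq, cigar = sprintf("%dM", lq)))
  }
  al <- cpp_banded_global(qseg, rseg, as.integer(band), scores$match,
                          scores$mismatch, scores$gap)
  if (al$band_hit) {
    al <- cpp_banded_global(qseg, rseg, as.integer(band * 4), scores$match,
                            scores$mismatch, scores$gap)
    if (al$band_hit) return(NULL)
  }
  list(matches = al$matches, columns = al$columns, cigar = al$cigar)
}

# merge adjacent same-op CIGAR runs ("10M5M" -> "15M")
collapse_cigar <- function(cig) {
  if (!nzchar(cig)) return(cig)
  n <- as.numeric(regmatches(cig, gregexpr("[0-9]+", cig))[[1]])
  op <- regmatches(cig, gregexpr("[MID]", cig))[[1]]
  keep_n <- numeric(0); keep_op <- character(0)
  for (i in seq_along(op)) {
    if (length(keep_op) && keep_op[length(keep_op)] == op[i])
      keep_n[length(keep_n)] <- keep_n[length(keep_n)] + n[i]
    else { keep_n <- c(keep_n, n[i]); keep_op <- c(keep_op, op[i]) }
  }
  paste0(sprintf("%d", as.integer(keep_n)), keep_op, collapse = "")
}

# summarize one candidate's blocks into a scoring row
candidate_row <- function(blocks, cand_id, contig_len) {
  cov <- interval_union_len(blocks$q_start, blocks$q_end) / contig_len
  mat <- sum(blocks$matches); cols <- sum(blocks$aln_columns)
  data.frame(cand_id = cand_id, contig_id = blocks$contig_id[1],
             chrom = blocks$chrom[1], strand = blocks$strand[1],
             r_lo = min(blocks$r_start), r_hi = max(blocks$r_end),
             coverage = cov, identity = mat / cols, score = mat,
             contig_len = contig_len)
}

#' Align a set of sequences to a reference
#'
#' Full seeding/chaining/extension for every query: the shared engine behind
#' contig placement, BES mapping and transcript classification. Queries
#' shorter than `min_query_len` are skipped.
#'
#' @param queries named character vector.
#' @param ref named character vector (a shared [ref_index()] is built
#'   internally).
#' @param min_len MEM seed length.
#' @param max_hits seed frequency cap (0 = none).
#' @param max_join_gap,band,max_extend see [chain_anchors()] /
#'   [extend_and_score()].
#' @param scores alignment scores list.
#' @param min_query_len skip shorter queries.
#' @return list(candidates = data.frame, blocks = data.frame); blocks carry
#'   `cand_id` linking them to candidates.
#' @export
align_sequences <- function(queries, ref, min_len = 20, max_hits = 1000,
                            max_join_gap = 1000, band = 50, max_extend = 5000,
                            scores = list(match = 1, mismatch = -1, gap = -2),
                            min_query_len = 0) {
  if (inherits(ref, "ref_index"))
    stop("align_sequences needs raw reference sequences, not an index")
  idx <- ref_index(ref, min_len)
  refseq <- ref
  cand_rows <- list(); block_rows <- list(); cid <- 0
  for (qid in names(queries)) {
    q <- queries[[qid]]
    if (nchar(q) < min_query_len) next
    anchors <- find_anchors(q, idx, max_hits = max_hits, contig_id = qid)
    if (!nrow(anchors)) next
    cands <- chain_anchors(anchors, max_join_gap, nchar(q))
    for (cand in cands) {
      blocks <- extend_and_score(cand, q, refseq, band, max_extend, scores)
      if (is.null(blocks) || !nrow(blocks)) next
      cid <- cid + 1
      blocks$cand_id <- cid
      cand_rows[[cid]] <- candidate_row(blocks, cid, nchar(q))
      block_rows[[cid]] <- blocks
    }
  }
  list(candidates = if (length(cand_rows)) do.call(rbind, cand_rows) else
    data.frame(cand_id = integer(0), contig_id = character(0),
               chrom = character(0), strand = character(0), r_lo = numeric(0),
               r_hi = numeric(0), coverage = numeric(0), identity = numeric(0),
               score = numeric(0), contig_len = numeric(0)),
    blocks = if (length(block_rows)) do.call(rbind, block_rows) else NULL)
}

#' Filter placement candidates to accepted one-to-one placements
#'
#' Candidates below the identity/coverage thresholds are removed; contigs
#' whose top two surviving candidates score within `ambiguity_margin` of
#' each other are rejected as non-unique; the rest are tiled greedily by
#' score so no contig has two placements and no reference interval is
#' claimed twice (small overlaps up to `overlap_tol` bp are tolerated).
#'
#' @param candidates candidate table from [align_sequences()].
#' @param min_identity,min_coverage acceptance thresholds (defaults 0.90 /
#'   0.80).
#' @param ambiguity_margin reject a contig when its runner-up candidate
#'   scores within this fraction of the best (default 0.05).
#' @param overlap_tol bp of reference overlap tolerated during tiling.
#' @return list(accepted, rejected): placement rows with `method = "ALIGN"`;
#'   rejected rows carry a `reason`.
#' @export
filter_placements <- function(candidates, min_identity = 0.90,
                              min_coverage = 0.80, ambiguity_margin = 0.05,
                              overlap_tol = 100) {
  rej <- list()
  note <- function(rows, why) {
    if (nrow(rows)) { rows$reason <- why; rej[[length(rej) + 1]] <<- rows }
  }
  ok <- candidates$identity >= min_identity &
    candidates$coverage >= min_coverage
  note(candidates[!ok, , drop = FALSE], "below_threshold")
  cands <- candidates[ok, , drop = FALSE]
  keep <- list()
  for (ctg in unique(cands$contig_id)) {
    cc <- cands[cands$contig_id == ctg, , drop = FALSE]
    cc <- cc[order(-cc$score), , drop = FALSE]
    if (nrow(cc) >= 2 && cc$score[2] >= (1 - ambiguity_margin) * cc$score[1]) {
      note(cc, "ambiguous")
      next
    }
    keep[[length(keep) + 1]] <- cc[1, , drop = FALSE]
    note(cc[-1, , drop = FALSE], "secondary")
  }
  accepted <- list()
  claimed <- list()  # per chrom matrix of claimed [lo, hi)
  if (length(keep)) {
    best <- do.call(rbind, keep)
    best <- best[order(-best$score), , drop = FALSE]
    for (i in seq_len(nrow(best))) {
      b <- best[i, ]
      cl <- claimed[[b$chrom]]
      conflict <- !is.null(cl) &&
        any(pmin(cl[, 2], b$r_hi) - pmax(cl[, 1], b$r_lo) > overlap_tol)
      if (conflict) { note(b, "reference_claimed"); next }
      claimed[[b$chrom]] <- rbind(cl, c(b$r_lo, b$r_hi))
      accepted[[length(accepted) + 1]] <- b
    }
  }
  acc <- if (length(accepted)) do.call(rbind, accepted) else
    candidates[0, , drop = FALSE]
  if (nrow(acc)) {
    acc <- data.frame(contig_id = acc$contig_id, chrom = acc$chrom,
                      r_start = acc$r_lo, r_end = acc$r_hi,
                      strand = acc$strand, identity = acc$identity,
                      coverage = acc$coverage, score = acc$score,
                      method = "ALIGN", cand_id = acc$cand_id)
  } else {
    acc <- data.frame(contig_id = character(0), chrom = character(0),
                      r_start = numeric(0), r_end = numeric(0),
                      strand = character(0), identity = numeric(0),
                      coverage = numeric(0), score = numeric(0),
                      method = character(0), cand_id = integer(0))
  }
  list(accepted = acc,
       rejected = if (length(rej)) do.call(rbind, rej) else
         cbind(candidates[0, , drop = FALSE], reason = character(0)))
}

#' Align contigs to a reference and select one-to-one placements
#'
#' The main contig-anchoring driver: shared index, alignment of every contig
#' of at least `cfg$contig_min_len` bp, candidate filtering at
#' `cfg$min_identity` / `cfg$min_coverage`, and one-to-one tiling.
#'
#' @param contigs named character vector.
#' @param ref named character vector.
#' @param cfg a [pipeline_config()].
#' @return list(placements, blocks, candidates, rejected). `blocks` are the
#'   alignment blocks of accepted placements only.
#' @export
align_contigs <- function(contigs, ref, cfg = pipeline_config()) {
  al <- align_sequences(contigs, ref, min_len = cfg$anchor_min_len,
                        max_hits = 1000, max_join_gap = cfg$max_join_gap,
                        band = cfg$band, max_extend = cfg$max_extend,
                        scores = list(match = cfg$match,
                                      mismatch = cfg$mismatch, gap = cfg$gap),
                        min_query_len = cfg$contig_min_len)
  fp <- filter_placements(al$candidates, cfg$min_identity, cfg$min_coverage,
                          cfg$ambiguity_margin, cfg$tiling_overlap_tol)
  blocks <- if (!is.null(al$blocks))
    al$blocks[al$blocks$cand_id %in% fp$accepted$cand_id, , drop = FALSE]
  else NULL
  list(placements = fp$accepted, blocks = blocks,
       candidates = al$candidates, rejected = fp$rejected)
}

#' Map short reads to a target genome by MEM voting
#'
#' Light-weight mapper for polishing, rescue links, indel validation and
#' mapping-rate reports: MEMs of each read vote for (chromosome, strand,
#' diagonal) buckets; the best bucket places the read, the runner-up drives
#' the uniqueness call (MAPQ 60 unique, 0 ambiguous). Alignments are
#' reported gapless (all-M with soft clips at target edges).
#'
#' @param reads named character vector of read sequences.
#' @param target named character vector, or a [ref_index()].
#' @param quals optional named quality strings (defaults to Q35).
#' @param min_len MEM seed length (use smaller for short reads).
#' @param min_score minimum vote weight (matched bp) to call a read mapped.
#' @param unique_frac runner-up weight must stay below this fraction of the
#'   best to call the read unique.
#' @return SAM-subset data.frame (pos 0-based; unmapped reads keep flag 4).
#' @export
map_reads <- function(reads, target, quals = NULL, min_len = 20,
                      min_score = 40, unique_frac = 0.9) {
  idx <- if (inherits(target, "ref_index")) target else ref_index(target, min_len)
  if (is.null(quals))
    quals <- setNames(vapply(nchar(reads), function(n)
      strrep(rawToChar(as.raw(35 + 33)), n), character(1)), names(reads))
  mp <- cpp_map_reads(idx$ptr, unname(reads), 1000L, 16L)
  n <- length(reads)
  lens <- nchar(reads)
  mapped <- !is.na(mp$chrom_i) & mp$score >= min_score
  unique_hit <- mapped & (mp$score2 < unique_frac * mp$score)
  chrom <- ifelse(mapped, idx$names[mp$chrom_i], "*")
  tlen <- ifelse(mapped, idx$lengths[mp$chrom_i], 0)
  is_minus <- !is.na(mp$strand_i) & mp$strand_i == 1
  diag <- ifelse(mapped, mp$diag, 0)
  lead <- pmax(0, -diag)
  tail_clip <- pmax(0, diag + lens - tlen)
  mlen <- pmax(0, lens - lead - tail_clip)
  pos <- ifelse(mapped, pmax(diag, 0), 0)
  cigar <- ifelse(!mapped, "*",
                  paste0(ifelse(lead > 0, paste0(lead, "S"), ""),
                         mlen, "M",
                         ifelse(tail_clip > 0, paste0(tail_clip, "S"), "")))
  seq_out <- ifelse(is_minus, revcomp(unname(reads)), unname(reads))
  qual_out <- ifelse(is_minus,
                     vapply(unname(quals), function(q)
                       paste(rev(strsplit(q, "")[[1]]), collapse = ""),
                       character(1)),
                     unname(quals))
  data.frame(qname = names(reads),
             flag = ifelse(!mapped, 4L, ifelse(is_minus, 16L, 0L)),
             rname = chrom, pos = pos,
             mapq = ifelse(!mapped, 0L, ifelse(unique_hit, 60L, 0L)),
             cigar = cigar, rnext = "*", pnext = 0, tlen = 0,
             seq = seq_out, qual = qual_out,
             score = mp$score, score2 = mp$score2)
}
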