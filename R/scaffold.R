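# Pseudomolecule construction: accepted alignment placements are ordered
# along each chromosome; contigs the aligner could not place are rescued by
# BAC-end-sequence (BES) evidence — rule (i): a uniquely aligned BES hits an
# unclaimed reference region; rule (ii): the mate of a BES on the contig
# lies on an already-placed contig — or by consistent paired-end read
# links. Gaps between consecutive contigs take the reference-projected
# distance with a 100 N floor; rescues with unknown spacing get fixed 100 N
# "U" gaps.

#' Map BES reads onto contigs and the reference
#'
#' BES hits are aligned with the package aligner and kept at >= 90%
#' identity with >= 95% coverage (contig side) or >= 90% coverage
#' (reference side); only uniquely aligned BES survive, and reference-side
#' clone pairs must map uniquely at a distance below `cfg$bes_max_pair_dist`
#' (300 kb). Clones without exactly two ends are skipped with a warning.
#'
#' @param bes named character vector of BES reads (`<clone>_F` / `<clone>_R`
#'   naming).
#' @param contigs named character vector.
#' @param ref named character vector.
#' @param cfg a [pipeline_config()].
#' @return list(contig_side, ref_side, ref_pairs): mapping tables with
#'   columns bes_id, clone_id, end, target_id, start, end_pos, strand,
#'   identity, coverage; `ref_pairs` adds the pair distance.
#' @export
map_bes <- function(bes, contigs, ref, cfg = pipeline_config()) {
  if (!length(bes))
    return(list(contig_side = NULL, ref_side = NULL, ref_pairs = NULL))
  if (any(nchar(bes) < 100)) {
    warning("dropping BES reads shorter than 100 bp")
    bes <- bes[nchar(bes) >= 100]
  }
  clone_id <- sub("_[FR]$", "", names(bes))
  ends_per_clone <- table(clone_id)
  bad <- names(ends_per_clone)[ends_per_clone != 2]
  if (length(bad)) {
    warning(sprintf("%d clone(s) without exactly two ends skipped",
                    length(bad)))
    bes <- bes[!clone_id %in% bad]
  }
  side <- function(target) {
    al <- align_sequences(bes, target, min_len = cfg$anchor_min_len,
                          max_join_gap = cfg$max_join_gap, band = cfg$band,
                          max_extend = cfg$max_extend)
    al$candidates
  }
  unique_best <- function(cands, min_id, min_cov) {
    cands <- cands[cands$identity >= min_id & cands$coverage >= min_cov, ,
                   drop = FALSE]
    out <- list()
    for (id in unique(cands$contig_id)) {
      cc <- cands[cands$contig_id == id, , drop = FALSE]
      cc <- cc[order(-cc$score), , drop = FALSE]
      if (nrow(cc) >= 2 &&
          cc$score[2] >= (1 - cfg$ambiguity_margin) * cc$score[1]) next
      out[[length(out) + 1]] <- cc[1, , drop = FALSE]
    }
    if (!length(out)) return(NULL)
    b <- do.call(rbind, out)
    data.frame(bes_id = b$contig_id,
               clone_id = sub("_[FR]$", "", b$contig_id),
               end = sub("^.*_", "", b$contig_id),
               target_id = b$chrom, start = b$r_lo, end_pos = b$r_hi,
               strand = b$strand, identity = b$identity,
               coverage = b$coverage)
  }
  contig_side <- unique_best(side(contigs), cfg$bes_contig_min_id,
                             cfg$bes_contig_min_cov)
  ref_side <- unique_best(side(ref), cfg$bes_ref_min_id, cfg$bes_ref_min_cov)
  ref_pairs <- NULL
  if (!is.null(ref_side)) {
    both <- table(ref_side$clone_id)
    cl <- names(both)[both == 2]
    if (length(cl)) {
      rows <- lapply(cl, function(c0) {
        p <- ref_side[ref_side$clone_id == c0, , drop = FALSE]
        if (length(unique(p$target_id)) != 1) return(NULL)
        d <- max(p$end_pos) - min(p$start)
        if (d >= cfg$bes_max_pair_dist) return(NULL)
        data.frame(clone_id = c0, chrom = p$target_id[1],
                   lo = min(p$start), hi = max(p$end_pos), dist = d)
      })
      rows <- rows[!vapply(rows, is.null, logical(1))]
      if (length(rows)) ref_pairs <- do.call(rbind, rows)
    }
  }
  list(contig_side = contig_side, ref_side = ref_side, ref_pairs = ref_pairs)
}

#' Rescue unplaced contigs with BES evidence
#'
#' Rule (i): an unplaced contig carrying a uniquely aligned BES whose
#' reference hit falls in a region no placed contig claims is placed at
#' that hit, oriented by the BES strands. Rule (ii): an unplaced contig
#' carrying one end of a clone whose mate BES lies on a placed contig is
#' placed adjacent to that contig, offset by the clone insert estimate.
#' Conflicting rescues for one region resolve to the higher BES support;
#' rescues never overwrite ALIGN placements.
#'
#' @param unplaced named character vector of unplaced contigs.
#' @param bes_maps output of [map_bes()].
#' @param placements accepted placements from [align_contigs()].
#' @param cfg a [pipeline_config()].
#' @param insert_mean clone insert estimate in bp for rule-(ii) offsets.
#' @return placement rows with `method = "BES"`.
#' @export
rescue_anchor <- function(unplaced, bes_maps, placements,
                          cfg = pipeline_config(), insert_mean = 1e5) {
  empty <- placements[0, , drop = FALSE]
  if (!length(unplaced) || is.null(bes_maps$contig_side)) return(empty)
  cs <- bes_maps$contig_side[bes_maps$contig_side$target_id %in%
                               names(unplaced), , drop = FALSE]
  if (!nrow(cs)) return(empty)
  proposals <- list()
  # rule (i): BES on an unplaced contig also maps uniquely to the reference
  if (!is.null(bes_maps$ref_side)) {
    for (i in seq_len(nrow(cs))) {
      b <- cs[i, ]
      rh <- bes_maps$ref_side[bes_maps$ref_side$bes_id == b$bes_id, ,
                              drop = FALSE]
      if (nrow(rh) != 1) next
      ctg_len <- nchar(unplaced[[b$target_id]])
      # orientation: BES strand on contig vs on reference
      strand <- if (b$strand == rh$strand) "+" else "-"
      off <- if (strand == "+") b$start else ctg_len - b$end_pos
      r_start <- rh$start - off
      proposals[[length(proposals) + 1]] <- data.frame(
        contig_id = b$target_id, chrom = rh$target_id,
        r_start = r_start, r_end = r_start + ctg_len, strand = strand,
        identity = NA_real_, coverage = NA_real_,
        score = b$identity * b$coverage, method = "BES",
        cand_id = NA_integer_, rule = "i")
    }
  }
  # rule (ii): the clone mate sits on an already placed contig
  placed_ids <- placements$contig_id
  for (i in seq_len(nrow(cs))) {
    b <- cs[i, ]
    mate_end <- if (b$end == "F") "R" else "F"
    mate_id <- paste0(b$clone_id, "_", mate_end)
    mh <- bes_maps$contig_side[bes_maps$contig_side$bes_id == mate_id, ,
                               drop = FALSE]
    if (nrow(mh) != 1 || !(mh$target_id %in% placed_ids)) next
    mp <- placements[placements$contig_id == mh$target_id, , drop = FALSE][1, ]
    ctg_len <- nchar(unplaced[[b$target_id]])
    # mate's reference coordinate estimate: its position on the placed
    # contig projected through that contig's placement
    mate_ref <- if (mp$strand == "+") mp$r_start + mh$start
    else mp$r_end - mh$end_pos
    # the clone spans ~insert_mean; place the unplaced contig one insert
    # away, on the side the mate strand points to
    mate_dir_fwd <- (mh$strand == "+") == (mp$strand == "+")
    center <- if (mate_dir_fwd) mate_ref + insert_mean else
      mate_ref - insert_mean
    r_start <- center - round(ctg_len / 2)
    strand <- if ((b$strand == "+") == mate_dir_fwd) "-" else "+"
    proposals[[length(proposals) + 1]] <- data.frame(
      contig_id = b$target_id, chrom = mp$chrom, r_start = r_start,
      r_end = r_start + ctg_len, strand = strand, identity = NA_real_,
      coverage = NA_real_, score = b$identity * b$coverage, method = "BES",
      cand_id = NA_integer_, rule = "ii")
  }
  if (!length(proposals)) return(empty)
  prop <- do.call(rbind, proposals)
  # one proposal per contig (highest support), rule (i) preferred
  prop <- prop[order(prop$contig_id, prop$rule, -prop$score), , drop = FALSE]
  prop <- prop[!duplicated(prop$contig_id), , drop = FALSE]
  # rule (i) placements must land in unclaimed reference regions; conflicts
  # between rescues resolve by support
  prop <- prop[order(-prop$score), , drop = FALSE]
  claimed <- lapply(split(placements, placements$chrom), function(p)
    cbind(p$r_start, p$r_end))
  keep <- rep(TRUE, nrow(prop))
  for (i in seq_len(nrow(prop))) {
    p <- prop[i, ]
    cl <- claimed[[p$chrom]]
    if (p$rule == "i" && !is.null(cl) &&
        any(pmin(cl[, 2], p$r_end) - pmax(cl[, 1], p$r_start) > 0)) {
      keep[i] <- FALSE
      next
    }
    claimed[[p$chrom]] <- rbind(cl, c(p$r_start, p$r_end))
  }
  prop <- prop[keep, , drop = FALSE]
  prop$rule <- NULL
  prop
}

#' Anchor unplaced contigs with paired-end read links
#'
#' A link is a read pair with one end uniquely mapped on a placed contig
#' and the other uniquely on an unplaced contig. A contig is placed when at
#' least `cfg$min_links` links agree on chromosome, position window and
#' orientation; inconsistent link sets leave it unplaced.
#'
#' @param unplaced named character vector of unplaced contigs.
#' @param links data.frame of read-pair links: columns unplaced_id, chrom,
#'   ref_pos (mate's reference-projected position), same_strand (logical:
#'   link implies the unplaced contig keeps its forward orientation).
#' @param placements accepted placements (used only to guard against
#'   overwriting).
#' @param cfg a [pipeline_config()].
#' @param window bp window within which link positions must agree.
#' @return placement rows with `method = "PAIRED_END"`.
#' @export
paired_end_anchor <- function(unplaced, links, placements,
                              cfg = pipeline_config(), window = 10000) {
  empty <- placements[0, , drop = FALSE]
  if (is.null(links) || !nrow(links)) return(empty)
  links <- links[links$unplaced_id %in% names(unplaced), , drop = FALSE]
  out <- list()
  for (id in unique(links$unplaced_id)) {
    lk <- links[links$unplaced_id == id, , drop = FALSE]
    if (nrow(lk) < cfg$min_links) next
    if (length(unique(lk$chrom)) != 1) next
    if (max(lk$ref_pos) - min(lk$ref_pos) > window) next
    fwd <- sum(lk$same_strand); rev_ <- nrow(lk) - fwd
    if (fwd == rev_) next  # orientation evidence split: stay unplaced
    strand <- if (fwd > rev_) "+" else "-"
    ctg_len <- nchar(unplaced[[id]])
    pos <- round(median(lk$ref_pos))
    out[[length(out) + 1]] <- data.frame(
      contig_id = id, chrom = lk$chrom[1], r_start = pos,
      r_end = pos + ctg_len, strand = strand, identity = NA_real_,
      coverage = NA_real_, score = nrow(lk), method = "PAIRED_END",
      cand_id = NA_integer_)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Build read-pair links between placed and unplaced contigs
#'
#' Maps reads to the contig set and extracts pairs with both ends uniquely
#' mapped, one on a placed and one on an unplaced contig, projecting the
#' placed-side position through its placement. Pair naming follows the
#' simulator convention (`<id>/1`, `<id>/2`).
#'
#' @param reads named character vector of reads.
#' @param contigs all contigs (placed and unplaced).
#' @param placements accepted placements.
#' @param cfg a [pipeline_config()].
#' @return link table for [paired_end_anchor()].
#' @export
build_pe_links <- function(reads, contigs, placements,
                           cfg = pipeline_config()) {
  aln <- map_reads(reads, contigs)
  aln <- aln[aln$mapq >= cfg$map_min_qual, , drop = FALSE]
  aln$pair <- sub("/[12]$", "", aln$qname)
  placed <- placements$contig_id
  rows <- list()
  for (pr in unique(aln$pair[duplicated(aln$pair)])) {
    p <- aln[aln$pair == pr, , drop = FALSE]
    if (nrow(p) != 2) next
    on_placed <- p$rname %in% placed
    if (sum(on_placed) != 1) next
    pm <- p[on_placed, ]; pu <- p[!on_placed, ]
    pl <- placements[placements$contig_id == pm$rname, , drop = FALSE][1, ]
    ref_pos <- if (pl$strand == "+") pl$r_start + pm$pos else
      pl$r_end - pm$pos
    mate_rc <- bitwAnd(pm$flag, 16L) != 0
    self_rc <- bitwAnd(pu$flag, 16L) != 0
    # proper pairs map on opposite genome strands, so a forward-oriented
    # unplaced contig shows mate_rc != self_rc
    rows[[length(rows) + 1]] <- data.frame(
      unplaced_id = pu$rname, chrom = pl$chrom, ref_pos = ref_pos,
      same_strand = mate_rc != self_rc)
  }
  if (!length(rows))
    return(data.frame(unplaced_id = character(0), chrom = character(0),
                      ref_pos = numeric(0), same_strand = logical(0)))
  do.call(rbind, rows)
}

#' Assemble pseudomolecules and AGP from placements
#'
#' Per chromosome, contigs are ordered by reference start and
#' reverse-complemented when placed on the minus strand; consecutive
#' contigs are separated by the reference-projected gap with a 100 N floor
#' (N rows), rescue placements by fixed 100 N "U" gaps. Overlapping
#' placements are resolved by trimming the lower-score placement's
#' coordinates (the contig sequence itself is never cut). The emitted AGP
#' reconstructs the FASTA byte-for-byte via [assemble_from_agp()].
#'
#' @param placements combined placement table (ALIGN + rescues).
#' @param contigs named character vector (all contigs).
#' @param ref named character vector (chromosome order and naming).
#' @param cfg a [pipeline_config()].
#' @return list(fasta, agp, stats, placements): pseudomolecule sequences,
#'   AGP v2.0 table, Table-1-style statistics for placed/unplaced contigs,
#'   and the placements as tiled.
#' @export
build_pseudomolecules <- function(placements, contigs, ref,
                                  cfg = pipeline_config()) {
  stopifnot(all(placements$contig_id %in% names(contigs)))
  fasta <- character(0)
  agp_rows <- list()
  placements <- placements[order(placements$chrom, placements$r_start,
                                 -placements$score), , drop = FALSE]
  for (chrom in names(ref)) {
    pl <- placements[placements$chrom == chrom, , drop = FALSE]
    if (!nrow(pl)) next
    # resolve residual overlaps: higher score keeps its interval
    if (nrow(pl) > 1) {
      for (i in seq_len(nrow(pl))[-1]) {
        ov <- pl$r_end[i - 1] - pl$r_start[i]
        if (ov > 0) {
          if (pl$score[i] >= pl$score[i - 1]) pl$r_end[i - 1] <- pl$r_start[i]
          else pl$r_start[i] <- pl$r_end[i - 1]
        }
      }
    }
    obj <- paste0(chrom, "_pseudo")
    pieces <- character(0)
    pos1 <- 0  # 0-based running length of the object
    part <- 0
    for (i in seq_len(nrow(pl))) {
      if (i > 1) {
        refgap <- pl$r_start[i] - pl$r_end[i - 1]
        unknown <- pl$method[i] != "ALIGN" || pl$method[i - 1] != "ALIGN"
        gap <- if (unknown) cfg$gap_floor else
          max(refgap, cfg$gap_floor)
        part <- part + 1
        agp_rows[[length(agp_rows) + 1]] <- data.frame(
          object = obj, object_beg = pos1 + 1, object_end = pos1 + gap,
          part_number = part,
          component_type = if (unknown) "U" else "N",
          component_id = NA_character_, component_beg = NA_real_,
          component_end = NA_real_, orientation = NA_character_,
          gap_length = gap)
        pieces <- c(pieces, strrep("N", gap))
        pos1 <- pos1 + gap
      }
      s <- contigs[[pl$contig_id[i]]]
      if (pl$strand[i] == "-") s <- revcomp(s)
      part <- part + 1
      agp_rows[[length(agp_rows) + 1]] <- data.frame(
        object = obj, object_beg = pos1 + 1, object_end = pos1 + nchar(s),
        part_number = part, component_type = "W",
        component_id = pl$contig_id[i], component_beg = 1,
        component_end = nchar(contigs[[pl$contig_id[i]]]),
        orientation = pl$strand[i], gap_length = NA_real_)
      pieces <- c(pieces, s)
      pos1 <- pos1 + nchar(s)
    }
    fasta[obj] <- paste(pieces, collapse = "")
  }
  agp <- if (length(agp_rows)) do.call(rbind, agp_rows) else
    data.frame(object = character(0), object_beg = numeric(0),
               object_end = numeric(0), part_number = integer(0),
               component_type = character(0), component_id = character(0),
               component_beg = numeric(0), component_end = numeric(0),
               orientation = character(0), gap_length = numeric(0))
  placed_ids <- unique(placements$contig_id)
  unplaced_ids <- setdiff(names(contigs), placed_ids)
  stats <- rbind(
    cbind(class = "mapped", assembly_stats(nchar(contigs[placed_ids]))),
    cbind(class = "unmapped", assembly_stats(nchar(contigs[unplaced_ids]))))
  list(fasta = fasta, agp = agp, stats = stats, placements = placements)
}
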