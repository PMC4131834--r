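# Synthetic genome simulator with machine-readable truth. The generator
# emulates two diverged rice-like genomes: a reference and a donor carrying
# ~1% SNPs, small indels, and large (>=100 bp) indels whose deletion sizes
# follow a bimodal mixture (modes near 4 kb and 12.5 kb); a configurable
# fraction of large indels is composed of tandem repeat copies. The donor is
# sheared into contigs and sequenced with paired-end reads and BAC-end pairs.

#' Generate a random reference genome with tandem-repeat tracts
#'
#' Chromosomes are uniform random DNA with embedded tandem-repeat tracts
#' (random 300-500 bp units repeated to a tract size drawn from the
#' large-deletion size mixture). Tracts are later used by
#' [mutate_reference()] as targets for repeat-tagged deletions, emulating
#' transposon presence/absence polymorphisms with clean breakpoints.
#'
#' @param params a [sim_params()] object.
#' @return list(genome = named character, repeat_tracts = data.frame(chrom,
#'   start, end, unit)).
#' @export
random_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n_tracts_total <- ceiling(params$repeat_fraction * params$large_del_count)
  genome <- character(params$n_chroms)
  names(genome) <- sprintf("chr%02d", seq_len(params$n_chroms))
  tracts <- list()
  per_chrom <- diff(round(seq(0, n_tracts_total, length.out = params$n_chroms + 1)))
  for (c in seq_len(params$n_chroms)) {
    L <- params$ref_length
    seq_c <- random_dna(L)
    nt <- per_chrom[c]
    if (nt > 0) {
      sizes <- draw_del_sizes(nt, params$large_del_sizes)
      if (sum(sizes) > 0.5 * L)
        stop("reference too short for requested repeat tracts")
      # place tracts without overlap, margin 2 kb
      taken <- matrix(numeric(0), ncol = 2)
      for (i in seq_len(nt)) {
        ok <- FALSE
        for (try in seq_len(100)) {
          s <- sample.int(L - sizes[i] - 4000, 1) + 2000
          if (!nrow(taken) ||
              all(s + sizes[i] + 2000 < taken[, 1] | s > taken[, 2] + 2000)) {
            ok <- TRUE; break
          }
        }
        if (!ok) stop("could not place repeat tract after 100 retries")
        taken <- rbind(taken, c(s, s + sizes[i]))
        ulen <- sample(seq(params$repeat_unit_range[1],
                           params$repeat_unit_range[2]), 1)
        unit <- random_dna(ulen)
        tract <- substr(strrep(unit, ceiling(sizes[i] / ulen)), 1, sizes[i])
        substr(seq_c, s + 1, s + sizes[i]) <- tract
        tracts[[length(tracts) + 1]] <-
          data.frame(chrom = names(genome)[c], start = s, end = s + sizes[i],
                     unit = unit)
      }
    }
    genome[c] <- seq_c
  }
  list(genome = genome,
       repeat_tracts = if (length(tracts)) do.call(rbind, tracts) else
         data.frame(chrom = character(0), start = numeric(0),
                    end = numeric(0), unit = character(0)))
}

# deletion sizes from the bimodal mixture (two normals + lognormal tail),
# truncated to [min, max]
draw_del_sizes <- function(n, spec) {
  if (n == 0) return(numeric(0))
  comp <- sample.int(3, n, replace = TRUE, prob = spec$weights)
  s <- numeric(n)
  s[comp == 1] <- rnorm(sum(comp == 1), spec$means[1], spec$sds[1])
  s[comp == 2] <- rnorm(sum(comp == 2), spec$means[2], spec$sds[2])
  s[comp == 3] <- rlnorm(sum(comp == 3), spec$ln_meanlog, spec$ln_sdlog)
  round(pmin(pmax(s, spec$min), spec$max))
}

draw_ins_sizes <- function(n, spec) {
  if (n == 0) return(numeric(0))
  round(pmin(pmax(rlnorm(n, spec$meanlog, spec$sdlog), spec$min), spec$max))
}

#' Plant SNPs and indels into a reference to create a donor genome
#'
#' Events are planted non-overlapping on reference coordinates (0-based,
#' half-open, forward strand, sorted). Repeat-tagged deletions remove whole
#' tandem-repeat tracts of the reference (see [random_genome()]);
#' repeat-tagged insertions are built from tandem copies of a fresh repeat
#' unit. Applying the truth events to the reference reproduces the donor
#' byte-for-byte.
#'
#' @param ref named character vector (reference genome).
#' @param params a [sim_params()] object.
#' @param repeat_tracts tract table from [random_genome()] (NULL = no
#'   repeat-tagged deletions).
#' @return list(donor = named character, truth = `truth_set`). The truth set
#'   carries `snps` (chrom, ref_pos, ref_base, alt_base), `indels` (chrom,
#'   ref_pos, type, size, repeat_tag, large, donor_pos, seq), and reference /
#'   donor lengths.
#' @export
mutate_reference <- function(ref, params, repeat_tracts = NULL) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 1L)
  chroms <- names(ref)
  if (is.null(chroms)) stop("reference must be a named character vector")
  if (any(!nzchar(ref))) stop("reference chromosomes must be non-empty")
  lens <- nchar(ref)
  w <- lens / sum(lens)
  n_del_c <- drop(stats::rmultinom(1, params$large_del_count, w))
  n_ins_c <- drop(stats::rmultinom(1, params$large_ins_count, w))
  donor <- character(length(ref)); names(donor) <- chroms
  snps_all <- list(); indels_all <- list()
  for (ci in seq_along(chroms)) {
    L <- lens[ci]
    chrom <- chroms[ci]
    ev <- plan_events(ref[[ci]], L, chrom, params, n_del_c[ci], n_ins_c[ci],
                      if (!is.null(repeat_tracts))
                        repeat_tracts[repeat_tracts$chrom == chrom, , drop = FALSE]
                      else NULL)
    built <- build_donor_chrom(ref[[ci]], ev)
    donor[ci] <- built$seq
    snps_all[[ci]] <- built$snps
    indels_all[[ci]] <- built$indels
  }
  truth <- list(
    snps = do.call(rbind, snps_all),
    indels = do.call(rbind, indels_all),
    placements = NULL,
    contig_errors = NULL,
    ref_lengths = setNames(as.numeric(lens), chroms),
    donor_lengths = setNames(as.numeric(nchar(donor)), chroms)
  )
  class(truth) <- "truth_set"
  list(donor = donor, truth = truth)
}

# Plan one chromosome's events as a table: type (SNP/DEL/INS), ref_pos,
# ref_len (ref bases consumed), ins_seq, size, repeat_tag. Large events are
# kept >= 1 kb from chromosome ends and >= 500 bp apart; SNPs and small
# indels avoid all claimed intervals. Rejection sampling, 100x retry cap.
plan_events <- function(seq_c, L, chrom, params, n_del, n_ins, tracts) {
  claimed <- matrix(numeric(0), ncol = 2)   # [start, end) + margins baked in
  claim <- function(s, e, margin) rbind(claimed, c(s - margin, e + margin))
  free <- function(s, e) !nrow(claimed) ||
    all(e <= claimed[, 1] | s >= claimed[, 2])
  ev <- list()
  add <- function(x) ev[[length(ev) + 1]] <<- x

  n_rep_del <- min(round(params$repeat_fraction * n_del),
                   if (is.null(tracts)) 0 else nrow(tracts))
  if (n_del > 0 && sum(nchar(seq_c)) < 4 * sum(draw_del_sizes(1, params$large_del_sizes)))
    NULL
  # repeat-tagged deletions: remove whole tracts
  if (n_rep_del > 0) {
    pick <- sample.int(nrow(tracts), n_rep_del)
    for (i in pick) {
      s <- tracts$start[i]; e <- tracts$end[i]
      if (!free(s, e)) next
      claimed <- claim(s, e, 500)
      add(data.frame(type = "DEL", ref_pos = s, ref_len = e - s,
                     ins_seq = "", size = e - s, repeat_tag = TRUE))
    }
  }
  n_plain_del <- n_del - sum(vapply(ev, function(x) x$type == "DEL", logical(1)))
  if (n_plain_del > 0) {
    sizes <- draw_del_sizes(n_plain_del, params$large_del_sizes)
    if (max(c(0, sizes)) + 2000 >= L) stop("reference too short for requested large deletions")
    for (sz in sizes) {
      placed <- FALSE
      for (try in seq_len(100)) {
        s <- sample.int(L - sz - 2000, 1) + 1000
        if (free(s, s + sz)) {
          claimed <- claim(s, s + sz, 500)
          add(data.frame(type = "DEL", ref_pos = s, ref_len = sz,
                         ins_seq = "", size = sz, repeat_tag = FALSE))
          placed <- TRUE; break
        }
      }
      if (!placed) stop("event collision: could not place large deletion after 100 retries")
    }
  }
  if (n_ins > 0) {
    sizes <- draw_ins_sizes(n_ins, params$large_ins_sizes)
    rep_flag <- runif(n_ins) < params$repeat_fraction
    for (i in seq_len(n_ins)) {
      placed <- FALSE
      for (try in seq_len(100)) {
        s <- sample.int(L - 2000, 1) + 1000
        if (free(s, s + 1)) {
          claimed <- claim(s, s + 1, 500)
          content <- if (rep_flag[i]) {
            ulen <- sample(seq(params$repeat_unit_range[1],
                               params$repeat_unit_range[2]), 1)
            substr(strrep(random_dna(ulen), ceiling(sizes[i] / ulen)), 1, sizes[i])
          } else random_dna(sizes[i])
          add(data.frame(type = "INS", ref_pos = s, ref_len = 0,
                         ins_seq = content, size = sizes[i],
                         repeat_tag = rep_flag[i]))
          placed <- TRUE; break
        }
      }
      if (!placed) stop("event collision: could not place large insertion after 100 retries")
    }
  }
  # small indels
  n_small <- rbinom(1, L, params$small_indel_rate)
  if (n_small > 0) {
    sizes <- sample(1:20, n_small, replace = TRUE, prob = 0.75 ^ (0:19))
    is_del <- runif(n_small) < 0.5
    pos <- sample.int(L - 100, n_small) + 50
    keep <- order(pos); pos <- pos[keep]; sizes <- sizes[keep]; is_del <- is_del[keep]
    for (i in seq_len(n_small)) {
      e <- pos[i] + if (is_del[i]) sizes[i] else 1
      if (!free(pos[i] - 5, e + 5)) next
      claimed <- claim(pos[i], e, 5)
      if (is_del[i])
        add(data.frame(type = "DEL", ref_pos = pos[i], ref_len = sizes[i],
                       ins_seq = "", size = sizes[i], repeat_tag = FALSE))
      else
        add(data.frame(type = "INS", ref_pos = pos[i], ref_len = 0,
                       ins_seq = random_dna(sizes[i]), size = sizes[i],
                       repeat_tag = FALSE))
    }
  }
  # SNPs on remaining free bases
  n_snp <- rbinom(1, L, params$snp_rate)
  snp_rows <- NULL
  if (n_snp > 0) {
    pos <- sort(sample.int(L, n_snp) - 1)
    if (nrow(claimed)) {
      cl <- claimed[order(claimed[, 1]), , drop = FALSE]
      idx <- findInterval(pos, cl[, 1])
      inside <- idx >= 1 & pos < cl[pmax(idx, 1), 2]
      pos <- pos[!inside]
    }
    if (length(pos)) {
      refb <- substring(seq_c, pos + 1, pos + 1)
      ok <- refb %in% c("A", "C", "G", "T")
      pos <- pos[ok]; refb <- refb[ok]
      altb <- other_base(refb)
      snp_rows <- data.frame(type = "SNP", ref_pos = pos, ref_len = 1,
                             ins_seq = altb, size = 1, repeat_tag = FALSE)
    }
  }
  out <- do.call(rbind, c(ev, list(snp_rows)))
  if (is.null(out))
    out <- data.frame(type = character(0), ref_pos = numeric(0),
                      ref_len = numeric(0), ins_seq = character(0),
                      size = numeric(0), repeat_tag = logical(0))
  out$chrom <- rep(chrom, nrow(out))
  out[order(out$ref_pos), , drop = FALSE]
}

# splice planned events into a chromosome; returns donor sequence plus truth
# rows annotated with donor coordinates
build_donor_chrom <- function(seq_c, ev) {
  n <- nrow(ev)
  if (!n) {
    return(list(seq = seq_c,
                snps = data.frame(chrom = character(0), ref_pos = numeric(0),
                                  ref_base = character(0), alt_base = character(0),
                                  donor_pos = numeric(0)),
                indels = data.frame(chrom = character(0), ref_pos = numeric(0),
                                    type = character(0), size = numeric(0),
                                    repeat_tag = logical(0), large = logical(0),
                                    donor_pos = numeric(0), seq = character(0))))
  }
  keep_start <- c(0, ev$ref_pos + ev$ref_len)
  keep_end <- c(ev$ref_pos, nchar(seq_c))
  kept <- substring(seq_c, keep_start + 1, keep_end)
  repl <- ifelse(ev$type == "SNP", ev$ins_seq,
                 ifelse(ev$type == "INS", ev$ins_seq, ""))
  pieces <- character(2 * n + 1)
  pieces[seq(1, 2 * n + 1, by = 2)] <- kept
  pieces[seq(2, 2 * n, by = 2)] <- repl
  donor <- paste(pieces, collapse = "")
  plens <- nchar(pieces)
  cum <- cumsum(c(0, plens))
  donor_pos <- cum[seq(2, 2 * n, by = 2)]  # donor coord where event lands
  is_snp <- ev$type == "SNP"
  snps <- if (any(is_snp)) {
    data.frame(chrom = ev$chrom[is_snp], ref_pos = ev$ref_pos[is_snp],
               ref_base = substring(seq_c, ev$ref_pos[is_snp] + 1,
                                    ev$ref_pos[is_snp] + 1),
               alt_base = ev$ins_seq[is_snp],
               donor_pos = donor_pos[is_snp])
  } else data.frame(chrom = character(0), ref_pos = numeric(0),
                    ref_base = character(0), alt_base = character(0),
                    donor_pos = numeric(0))
  ind <- !is_snp
  indels <- if (any(ind)) {
    data.frame(chrom = ev$chrom[ind], ref_pos = ev$ref_pos[ind],
               type = ev$type[ind], size = ev$size[ind],
               repeat_tag = ev$repeat_tag[ind],
               large = ev$size[ind] >= 100,
               donor_pos = donor_pos[ind],
               seq = ifelse(ev$type[ind] == "INS", ev$ins_seq[ind], ""))
  } else data.frame(chrom = character(0), ref_pos = numeric(0),
                    type = character(0), size = numeric(0),
                    repeat_tag = logical(0), large = logical(0),
                    donor_pos = numeric(0), seq = character(0))
  list(seq = donor, snps = snps, indels = indels)
}

#' Map donor coordinates to reference coordinates
#'
#' Positions inside donor-only insertions map to the insertion point.
#'
#' @param truth a `truth_set` from [mutate_reference()].
#' @param chrom chromosome name (scalar).
#' @param pos numeric vector of 0-based donor positions.
#' @return numeric vector of 0-based reference positions.
#' @export
lift_donor_to_ref <- function(truth, chrom, pos) {
  ind <- truth$indels[truth$indels$chrom == chrom, , drop = FALSE]
  if (!nrow(ind)) return(pos)
  ind <- ind[order(ind$donor_pos), , drop = FALSE]
  # segment starts in donor space and matching ref anchors
  is_ins <- ind$type == "INS"
  seg_donor <- c(0, ifelse(is_ins, ind$donor_pos + ind$size, ind$donor_pos))
  seg_ref <- c(0, ifelse(is_ins, ind$ref_pos, ind$ref_pos + ind$size))
  idx <- findInterval(pos, seg_donor)
  out <- seg_ref[idx] + (pos - seg_donor[idx])
  # clamp positions inside insertions to the insertion point
  if (any(is_ins)) {
    ins <- ind[is_ins, , drop = FALSE]
    j <- findInterval(pos, ins$donor_pos)
    inside <- j >= 1 & pos < (ins$donor_pos + ins$size)[pmax(j, 1)]
    out[inside] <- ins$ref_pos[pmax(j, 1)][inside]
  }
  out
}

#' Shear a donor genome into contigs
#'
#' Fragment lengths are exponential with the scale chosen so the empirical
#' N50 lands near `params$contig_n50`; contigs partition the donor exactly.
#' With `isolate_insertions = TRUE`, contig boundaries are forced at the
#' donor-side edges of planted large insertions, so insertion interiors
#' become their own (alignment-unmappable) contigs for rescue testing.
#' Planted contig substitution errors (rate `params$contig_error_rate`) are
#' recorded in the returned truth tables.
#'
#' @param donor named character vector.
#' @param params a [sim_params()] object.
#' @param truth optional `truth_set` (required for placements on reference
#'   coordinates and for `isolate_insertions`).
#' @param isolate_insertions force cuts at large-insertion edges.
#' @return list(contigs, placements, contig_errors). Placements carry chrom,
#'   ref_start, ref_end, strand, and the donor interval of each contig.
#' @export
shear_contigs <- function(donor, params, truth = NULL,
                          isolate_insertions = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 2L)
  if (any(!nzchar(donor))) stop("donor chromosomes must be non-empty")
  if (params$contig_n50 > max(nchar(donor)))
    stop("contig_n50 exceeds chromosome length")
  theta <- params$contig_n50 / 1.6783  # N50 of exp fragments ~ 1.678 * mean
  contigs <- character(0); plac <- list(); errs <- list()
  k <- 0
  for (ci in seq_along(donor)) {
    L <- nchar(donor[[ci]])
    chrom <- names(donor)[ci]
    cuts <- numeric(0)
    if (params$contig_n50 < L) {
      p <- 0
      while (TRUE) {
        p <- p + max(200, round(stats::rexp(1, 1 / theta)))
        if (p >= L) break
        cuts <- c(cuts, p)
      }
    }
    if (isolate_insertions && !is.null(truth)) {
      ins <- truth$indels[truth$indels$chrom == chrom &
                            truth$indels$type == "INS" & truth$indels$large, ,
                          drop = FALSE]
      if (nrow(ins)) {
        forced <- c(ins$donor_pos, ins$donor_pos + ins$size)
        # drop random cuts inside insertions, keep the forced edges
        inside <- vapply(cuts, function(x)
          any(x > ins$donor_pos & x < ins$donor_pos + ins$size), logical(1))
        cuts <- sort(unique(c(cuts[!inside], forced)))
        cuts <- cuts[cuts > 0 & cuts < L]
      }
    }
    bnd <- c(0, cuts, L)
    for (i in seq_len(length(bnd) - 1)) {
      k <- k + 1
      id <- sprintf("ctg%05d", k)
      s <- bnd[i]; e <- bnd[i + 1]
      contigs[id] <- substr(donor[[ci]], s + 1, e)
      rs <- if (!is.null(truth)) lift_donor_to_ref(truth, chrom, s) else NA_real_
      re <- if (!is.null(truth)) lift_donor_to_ref(truth, chrom, e) else NA_real_
      plac[[k]] <- data.frame(contig_id = id, chrom = chrom, ref_start = rs,
                              ref_end = re, strand = "+", donor_start = s,
                              donor_end = e)
    }
  }
  placements <- do.call(rbind, plac)
  # planted contig errors (substitutions)
  err_rows <- list()
  if (params$contig_error_rate > 0) {
    for (id in names(contigs)) {
      len <- nchar(contigs[[id]])
      n_err <- rbinom(1, len, params$contig_error_rate)
      if (n_err == 0) next
      pos <- sort(sample.int(len, n_err)) - 1
      true_base <- substring(contigs[[id]], pos + 1, pos + 1)
      wrong <- other_base(true_base)
      s <- contigs[[id]]
      for (i in seq_along(pos)) substr(s, pos[i] + 1, pos[i] + 1) <- wrong[i]
      contigs[id] <- s
      err_rows[[length(err_rows) + 1]] <-
        data.frame(contig_id = id, pos = pos, true_base = true_base)
    }
  }
  contig_errors <- if (length(err_rows)) do.call(rbind, err_rows) else
    data.frame(contig_id = character(0), pos = numeric(0),
               true_base = character(0))
  list(contigs = contigs, placements = placements,
       contig_errors = contig_errors)
}

#' Simulate paired-end reads from a genome
#'
#' Fragments are uniform over each chromosome with normal insert sizes; read
#' 1 is the forward fragment prefix, read 2 the reverse complement of the
#' fragment suffix. Substitution errors at `read_error_rate` get quality
#' Q15; correct bases Q35. Truth SAM records (both mates, CIGAR all-M)
#' carry the generating coordinates.
#'
#' @param genome named character vector (usually the donor).
#' @param params a [sim_params()] object.
#' @return list(seq, qual, sam): `seq`/`qual` named vectors (names
#'   `rdNNNNNN/1` and `/2`), `sam` the truth alignment table (see
#'   [read_sam()] for columns; pos 0-based).
#' @export
simulate_reads <- function(genome, params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 3L)
  rl <- params$read_length
  if (rl >= params$insert_mean) stop("read_length must be below insert_mean")
  seqs <- character(0); quals <- character(0); sam <- list()
  pair0 <- 0
  for (ci in seq_along(genome)) {
    L <- nchar(genome[[ci]])
    n_pairs <- round(params$read_depth * L / (2 * rl))
    if (n_pairs <= 0) next
    ins <- round(rnorm(n_pairs, params$insert_mean, params$insert_sd))
    ins <- pmin(pmax(ins, 2 * rl), L)
    start <- floor(runif(n_pairs, 0, L - ins + 1))
    r1 <- substring(genome[[ci]], start + 1, start + rl)
    fwd2 <- substring(genome[[ci]], start + ins - rl + 1, start + ins)
    ids <- sprintf("rd%07d", pair0 + seq_len(n_pairs))
    q35 <- strrep(rawToChar(as.raw(35 + 33)), rl)
    q1 <- rep(q35, n_pairs); q2fwd <- rep(q35, n_pairs)
    if (params$read_error_rate > 0) {
      inject <- function(reads, quals) {
        nerr <- rbinom(length(reads), rl, params$read_error_rate)
        hit <- which(nerr > 0)
        for (i in hit) {
          at <- sample.int(rl, nerr[i])
          for (p in at) {
            b <- substr(reads[i], p, p)
            if (b %in% c("A", "C", "G", "T")) {
              substr(reads[i], p, p) <- other_base(b)
              substr(quals[i], p, p) <- rawToChar(as.raw(15 + 33))
            }
          }
        }
        list(reads, quals)
      }
      tmp <- inject(r1, q1); r1 <- tmp[[1]]; q1 <- tmp[[2]]
      tmp <- inject(fwd2, q2fwd); fwd2 <- tmp[[1]]; q2fwd <- tmp[[2]]
    }
    r2 <- revcomp(fwd2)
    q2 <- vapply(q2fwd, function(q)
      paste(rev(strsplit(q, "")[[1]]), collapse = ""), character(1),
      USE.NAMES = FALSE)
    seqs <- c(seqs, setNames(r1, paste0(ids, "/1")),
              setNames(r2, paste0(ids, "/2")))
    quals <- c(quals, setNames(q1, paste0(ids, "/1")),
               setNames(q2, paste0(ids, "/2")))
    cig <- sprintf("%dM", rl)
    sam[[ci]] <- rbind(
      data.frame(qname = ids, flag = 99L, rname = names(genome)[ci],
                 pos = start, mapq = 60L, cigar = cig, rnext = "=",
                 pnext = start + ins - rl, tlen = ins, seq = r1, qual = q1),
      data.frame(qname = ids, flag = 147L, rname = names(genome)[ci],
                 pos = start + ins - rl, mapq = 60L, cigar = cig,
                 rnext = "=", pnext = start, tlen = -ins, seq = fwd2,
                 qual = q2fwd))
    pair0 <- pair0 + n_pairs
  }
  list(seq = seqs, qual = quals,
       sam = if (length(sam)) do.call(rbind, sam) else NULL)
}

#' Simulate BAC-end sequence (BES) pairs
#'
#' Each clone yields two end reads on opposite strands separated by
#' approximately the clone insert size; the truth distance is recorded.
#' Names follow the `cloneNNNNN_F` / `_R` pairing convention.
#'
#' @param genome named character vector (usually the donor).
#' @param params a [sim_params()] object (`bes_count`, `bes_insert_mean`,
#'   `bes_insert_sd`, `bes_read_len`).
#' @return list(seq = named character, truth = data.frame(clone_id, chrom,
#'   start, end, dist)).
#' @export
simulate_bes <- function(genome, params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 4L)
  n <- params$bes_count
  empty <- list(seq = setNames(character(0), character(0)),
                truth = data.frame(clone_id = character(0), chrom = character(0),
                                   start = numeric(0), end = numeric(0),
                                   dist = numeric(0)))
  if (n == 0) return(empty)
  bl <- params$bes_read_len
  if (params$bes_insert_mean >= min(nchar(genome)))
    stop("bes_insert_mean must be below the chromosome length")
  lens <- nchar(genome)
  chrom_i <- sample.int(length(genome), n, replace = TRUE,
                        prob = lens / sum(lens))
  seqs <- character(0); rows <- list()
  for (i in seq_len(n)) {
    ci <- chrom_i[i]; L <- lens[ci]
    ins <- round(rnorm(1, params$bes_insert_mean, params$bes_insert_sd))
    ins <- min(max(ins, 2 * bl + 100), L)
    s <- floor(runif(1, 0, L - ins + 1))
    id <- sprintf("clone%05d", i)
    fseq <- substr(genome[[ci]], s + 1, s + bl)
    rseq <- revcomp(substr(genome[[ci]], s + ins - bl + 1, s + ins))
    seqs[paste0(id, "_F")] <- fseq
    seqs[paste0(id, "_R")] <- rseq
    rows[[i]] <- data.frame(clone_id = id, chrom = names(genome)[ci],
                            start = s, end = s + ins, dist = ins)
  }
  list(seq = seqs, truth = do.call(rbind, rows))
}

#' Simulate gene models and embed their sequences in a genome
#'
#' Writes multi-exon protein-coding genes (valid ATG..stop CDS, GT..AG
#' introns, short UTRs, both strands) into non-overlapping loci of the given
#' genome and returns the modified genome plus a gene-model table in the
#' layout [write_gff3()] consumes. Intended to run on the reference before
#' [mutate_reference()].
#'
#' @param genome named character vector.
#' @param n_genes number of genes to place.
#' @param params a [sim_params()] object (seed only).
#' @return list(genome, models).
#' @export
simulate_genes <- function(genome, n_genes, params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 5L)
  models <- list()
  if (n_genes == 0)
    return(list(genome = genome,
                models = data.frame(gene_id = character(0),
                                    transcript_id = character(0),
                                    chrom = character(0), strand = character(0),
                                    feature = character(0), start = numeric(0),
                                    end = numeric(0), phase = integer(0))))
  lens <- nchar(genome)
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  taken <- lapply(genome, function(x) matrix(numeric(0), ncol = 2))
  for (g in seq_len(n_genes)) {
    n_ex <- sample(2:5, 1)
    cds_parts <- 3 * sample(40:130, n_ex)
    intron_len <- sample(100:800, max(n_ex - 1, 0), replace = TRUE)
    utr5 <- sample(30:150, 1); utr3 <- sample(30:150, 1)
    locus_len <- utr5 + utr3 + sum(cds_parts) + sum(intron_len)
    ci <- sample.int(length(genome), 1, prob = lens / sum(lens))
    placed <- FALSE
    for (try in seq_len(100)) {
      s <- sample.int(lens[ci] - locus_len - 400, 1) + 200
      tk <- taken[[ci]]
      if (!nrow(tk) || all(s + locus_len + 200 < tk[, 1] | s > tk[, 2] + 200)) {
        placed <- TRUE; break
      }
    }
    if (!placed) stop("gene placement failed: loci overcrowded")
    taken[[ci]] <- rbind(taken[[ci]], c(s, s + locus_len))
    strand <- sample(c("+", "-"), 1)
    n_codons <- sum(cds_parts) / 3
    cds_seq <- paste0("ATG",
                      paste(sample(sense, n_codons - 2, replace = TRUE),
                            collapse = ""),
                      sample(c("TAA", "TAG", "TGA"), 1))
    # assemble locus in sense orientation; record local sense coordinates
    pos <- 0; locus_seq <- character(0)
    exon_loc <- matrix(numeric(0), ncol = 2)
    cds_loc <- matrix(numeric(0), ncol = 2)
    cds_off <- cumsum(c(0, cds_parts))
    for (e in seq_len(n_ex)) {
      ex_start <- pos
      if (e == 1) { locus_seq <- c(locus_seq, random_dna(utr5)); pos <- pos + utr5 }
      cs <- pos
      locus_seq <- c(locus_seq,
                     substr(cds_seq, cds_off[e] + 1, cds_off[e + 1]))
      pos <- pos + cds_parts[e]
      cds_loc <- rbind(cds_loc, c(cs, pos))
      if (e == n_ex) { locus_seq <- c(locus_seq, random_dna(utr3)); pos <- pos + utr3 }
      exon_loc <- rbind(exon_loc, c(ex_start, pos))
      if (e < n_ex) {
        il <- intron_len[e]
        locus_seq <- c(locus_seq, paste0("GT", random_dna(il - 4), "AG"))
        pos <- pos + il
      }
    }
    locus_seq <- paste(locus_seq, collapse = "")
    stopifnot(nchar(locus_seq) == locus_len)
    if (strand == "+") {
      seg <- locus_seq
      to_genome <- function(m) cbind(s + m[, 1], s + m[, 2])
    } else {
      seg <- revcomp(locus_seq)
      to_genome <- function(m) cbind(s + locus_len - m[, 2],
                                     s + locus_len - m[, 1])
    }
    x <- genome[[ci]]
    substr(x, s + 1, s + locus_len) <- seg
    genome[[ci]] <- x
    ex_g <- to_genome(exon_loc); cds_g <- to_genome(cds_loc)
    gid <- sprintf("gene%04d", g); tid <- paste0(gid, ".1")
    chrom <- names(genome)[ci]
    phase <- (3 - (cds_off[-length(cds_off)] %% 3)) %% 3
    ord <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    models[[g]] <- rbind(
      data.frame(gene_id = gid, transcript_id = NA_character_, chrom = chrom,
                 strand = strand, feature = "gene", start = s,
                 end = s + locus_len, phase = NA_integer_),
      data.frame(gene_id = gid, transcript_id = tid, chrom = chrom,
                 strand = strand, feature = "mRNA", start = s,
                 end = s + locus_len, phase = NA_integer_),
      data.frame(gene_id = gid, transcript_id = tid, chrom = chrom,
                 strand = strand, feature = "exon",
                 start = ex_g[ord, 1], end = ex_g[ord, 2], phase = NA_integer_),
      data.frame(gene_id = gid, transcript_id = tid, chrom = chrom,
                 strand = strand, feature = "CDS",
                 start = cds_g[ord, 1], end = cds_g[ord, 2],
                 phase = phase[seq_len(n_ex)]))
  }
  list(genome = genome, models = do.call(rbind, models))
}

#' Craft SNPs with guaranteed harmful effects
#'
#' Enumerates CDS positions where a single substitution creates a premature
#' stop codon, and intron donor/acceptor positions where a substitution
#' destroys the GT/AG motif, then samples the requested numbers. Used to
#' score harmful-SNP recall against a known answer.
#'
#' @param genome genome carrying the gene sequences.
#' @param models gene-model table from [simulate_genes()].
#' @param n_nonsense,n_splice how many of each to sample.
#' @return SNP table (chrom, r_pos, ref_base, alt_base, expect) where
#'   `expect` is "nonsense" or "splice_site".
#' @export
sample_harmful_snps <- function(genome, models, n_nonsense = 5, n_splice = 5) {
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  txs <- unique(models$transcript_id[models$feature == "CDS"])
  cand_non <- list(); cand_spl <- list()
  for (tid in txs) {
    cds <- models[models$feature == "CDS" & models$transcript_id == tid, ,
                  drop = FALSE]
    strand <- cds$strand[1]; chrom <- cds$chrom[1]
    cds <- cds[order(cds$start), , drop = FALSE]
    # genomic positions of CDS bases in translation order
    gpos <- unlist(lapply(seq_len(nrow(cds)), function(i)
      seq(cds$start[i], cds$end[i] - 1)))
    if (strand == "-") gpos <- rev(gpos)
    seq_sense <- paste(substring(genome[[chrom]], gpos + 1, gpos + 1),
                       collapse = "")
    if (strand == "-") seq_sense <- chartr("ACGT", "TGCA", seq_sense)
    n_cod <- nchar(seq_sense) %/% 3
    for (cd in seq_len(n_cod - 1)[-1]) {  # skip start codon and stop codon
      codon <- substr(seq_sense, 3 * cd - 2, 3 * cd)
      if (codon %in% stops) next
      for (p in 1:3) {
        for (b in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
          mut <- codon
          substr(mut, p, p) <- b
          if (mut %in% stops) {
            g <- gpos[3 * (cd - 1) + p]
            sense_ref <- substr(codon, p, p); sense_alt <- b
            if (strand == "-") {
              sense_ref <- chartr("ACGT", "TGCA", sense_ref)
              sense_alt <- chartr("ACGT", "TGCA", sense_alt)
            }
            cand_non[[length(cand_non) + 1]] <-
              data.frame(chrom = chrom, r_pos = g, ref_base = sense_ref,
                         alt_base = sense_alt, expect = "nonsense")
          }
        }
      }
    }
    # splice sites: first/last 2 bases of each intron (between sorted exons)
    ex <- models[models$feature == "exon" & models$transcript_id == tid, ,
                 drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1) {
      for (i in seq_len(nrow(ex) - 1)) {
        int_s <- ex$end[i]; int_e <- ex$start[i + 1]
        for (g in c(int_s, int_s + 1, int_e - 2, int_e - 1)) {
          rb <- substr(genome[[chrom]], g + 1, g + 1)
          if (!rb %in% c("A", "C", "G", "T")) next
          cand_spl[[length(cand_spl) + 1]] <-
            data.frame(chrom = chrom, r_pos = g, ref_base = rb,
                       alt_base = setdiff(c("A", "C", "G", "T"), rb)[1],
                       expect = "splice_site")
        }
      }
    }
  }
  pick <- function(cand, n) {
    if (!length(cand)) return(NULL)
    df <- do.call(rbind, cand)
    df[sample.int(nrow(df), min(n, nrow(df))), , drop = FALSE]
  }
  rbind(pick(cand_non, n_nonsense), pick(cand_spl, n_splice))
}

#' One-call synthetic dataset
#'
#' Convenience driver: reference (with repeat tracts and optional genes),
#' donor, contigs, reads, and BES pairs, all under one seed.
#'
#' @param params a [sim_params()] object.
#' @param n_genes genes to embed in the reference before mutating.
#' @param isolate_insertions see [shear_contigs()].
#' @param reads,bes logical: simulate reads / BES pairs.
#' @return list(ref, donor, truth, contigs, models, reads, bes).
#' @export
simulate_dataset <- function(params, n_genes = 0, isolate_insertions = FALSE,
                             reads = FALSE, bes = FALSE) {
  rg <- random_genome(params)
  ref <- rg$genome
  models <- NULL
  if (n_genes > 0) {
    sg <- simulate_genes(ref, n_genes, params)
    ref <- sg$genome
    models <- sg$models
  }
  mt <- mutate_reference(ref, params, rg$repeat_tracts)
  sh <- shear_contigs(mt$donor, params, mt$truth, isolate_insertions)
  truth <- mt$truth
  truth$placements <- sh$placements
  truth$contig_errors <- sh$contig_errors
  list(ref = ref, donor = mt$donor, truth = truth, contigs = sh$contigs,
       models = models,
       reads = if (reads) simulate_reads(mt$donor, params) else NULL,
       bes = if (bes) simulate_bes(mt$donor, params) else NULL)
}
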