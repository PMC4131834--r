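# Independent oracles used to pin down expected values: brute-force MEM
# enumeration by diagonal scan, full (unbanded) Needleman-Wunsch in plain R,
# exhaustive collinear-chain search, and a per-base bitmap interval
# intersection. These deliberately share no code with the package kernels.

rc_chars <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# all maximal exact matches >= min_len between q and r (both strands),
# enumerated by scanning every diagonal for equal-character runs
mem_oracle <- function(q, r, min_len) {
  one <- function(qs, rs) {
    qc <- strsplit(qs, "")[[1]]; rcv <- strsplit(rs, "")[[1]]
    lq <- length(qc); lr <- length(rcv)
    out <- list()
    for (d in (-(lq - 1)):(lr - 1)) {
      qi <- max(1, 1 - d):min(lq, lr - d)
      if (!length(qi)) next
      ri <- qi + d
      eq <- qc[qi] == rcv[ri] & qc[qi] %in% c("A", "C", "G", "T")
      rl <- rle(eq)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1
      for (k in which(rl$values & rl$lengths >= min_len)) {
        out[[length(out) + 1]] <- data.frame(
          q_start = qi[starts[k]] - 1, q_end = qi[ends[k]],
          r_start = ri[starts[k]] - 1, r_end = ri[ends[k]])
      }
    }
    if (!length(out)) data.frame(q_start = numeric(0), q_end = numeric(0),
                                 r_start = numeric(0), r_end = numeric(0))
    else do.call(rbind, out)
  }
  plus <- one(q, r)
  if (nrow(plus)) plus$strand <- "+"
  qrc <- rc_chars(q)
  minus <- one(qrc, r)
  if (nrow(minus)) {
    lq <- nchar(q)
    tmp <- minus
    minus$q_start <- lq - tmp$q_end
    minus$q_end <- lq - tmp$q_start
    minus$strand <- "-"
  }
  out <- rbind(plus, if (nrow(minus)) minus else NULL)
  if (is.null(out) || !nrow(out))
    return(data.frame(q_start = numeric(0), q_end = numeric(0),
                      r_start = numeric(0), r_end = numeric(0),
                      strand = character(0)))
  out[order(out$strand, out$q_start, out$r_start), , drop = FALSE]
}

# full Needleman-Wunsch with linear gaps and the package's tie-break order
# (M over D over I); returns score, matches, columns
nw_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  S <- matrix(-Inf, la + 1, lb + 1)
  D <- matrix(0L, la + 1, lb + 1)  # 1=M 2=D(left) 3=I(up)
  S[1, ] <- gap * (0:lb); D[1, -1] <- 2L
  S[, 1] <- gap * (0:la); D[-1, 1] <- 3L
  for (i in 1:la) for (j in 1:lb) {
    sm <- S[i, j] + if (av[i] == bv[j] && av[i] %in% c("A", "C", "G", "T"))
      match else mismatch
    sd <- S[i + 1, j] + gap
    si <- S[i, j + 1] + gap
    best <- sm; dir <- 1L
    if (sd > best) { best <- sd; dir <- 2L }
    if (si > best) { best <- si; dir <- 3L }
    S[i + 1, j + 1] <- best; D[i + 1, j + 1] <- dir
  }
  i <- la + 1; j <- lb + 1
  matches <- 0; columns <- 0
  while (i > 1 || j > 1) {
    d <- D[i, j]
    if (i > 1 && j > 1 && d == 1L) {
      if (av[i - 1] == bv[j - 1] && av[i - 1] %in% c("A", "C", "G", "T"))
        matches <- matches + 1
      i <- i - 1; j <- j - 1
    } else if (j > 1 && (d == 2L || i == 1)) j <- j - 1
    else i <- i - 1
    columns <- columns + 1
  }
  list(score = S[la + 1, lb + 1], matches = matches, columns = columns)
}

# exhaustive maximum-weight collinear subset over <= 20 anchors
chain_oracle <- function(qs, qe, rs, re) {
  n <- length(qs)
  stopifnot(n <= 20)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (!length(idx)) next
    o <- idx[order(qs[idx])]
    ok <- TRUE
    if (length(o) > 1) for (k in seq_len(length(o) - 1)) {
      i <- o[k]; j <- o[k + 1]
      if (!(qs[i] < qs[j] && qe[i] < qe[j] && rs[i] < rs[j] && re[i] < re[j])) {
        ok <- FALSE; break
      }
    }
    if (ok) best <- max(best, sum(qe[idx] - qs[idx]))
  }
  best
}

# per-base bitmap intersection of interval sets (0-based half-open)
bitmap_intersect_len <- function(a_starts, a_ends, b_starts, b_ends, n) {
  a <- rep(FALSE, n); b <- rep(FALSE, n)
  for (i in seq_along(a_starts))
    if (a_ends[i] > a_starts[i]) a[(a_starts[i] + 1):a_ends[i]] <- TRUE
  for (i in seq_along(b_starts))
    if (b_ends[i] > b_starts[i]) b[(b_starts[i] + 1):b_ends[i]] <- TRUE
  sum(a & b)
}

# random DNA under the current RNG
rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")

# apply truth events to a reference chromosome by direct splicing —
# independent reconstruction used for round-trip checks
splice_truth <- function(refseq, snps, indels) {
  ev <- rbind(
    if (nrow(snps)) data.frame(pos = snps$ref_pos, ref_len = 1,
                               repl = snps$alt_base) else NULL,
    if (nrow(indels)) data.frame(
      pos = indels$ref_pos,
      ref_len = ifelse(indels$type == "DEL", indels$size, 0),
      repl = ifelse(indels$type == "DEL", "", indels$seq)) else NULL)
  if (is.null(ev) || !nrow(ev)) return(refseq)
  ev <- ev[order(ev$pos), , drop = FALSE]
  out <- character(0); at <- 0
  for (i in seq_len(nrow(ev))) {
    out <- c(out, substr(refseq, at + 1, ev$pos[i]), ev$repl[i])
    at <- ev$pos[i] + ev$ref_len[i]
  }
  paste(c(out, substr(refseq, at + 1, nchar(refseq))), collapse = "")
}

# small shared simulation for alignment-level tests
tiny_divergent_pair <- function(seed = 42, len = 2000, snps = 20) {
  set.seed(seed)
  r <- rdna(len)
  q <- r
  at <- sample(seq_len(len), snps)
  for (p in at) {
    b <- substr(q, p, p)
    substr(q, p, p) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }
  list(q = q, r = r)
}
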