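test_that("an exact substring yields a single full-length plus anchor", {
  set.seed(1)
  ref <- c(chr01 = rdna(3000))
  contig <- substr(ref[[1]], 1001, 1500)
  a <- find_anchors(contig, ref, min_len = 20)
  a <- a[a$length == max(a$length), ]
  expect_equal(nrow(a), 1)
  expect_equal(a$q_start, 0)
  expect_equal(a$q_end, 500)
  expect_equal(a$r_start, 1000)
  expect_equal(a$r_end, 1500)
  expect_equal(a$strand, "+")
})

test_that("a point substitution splits the match symmetrically", {
  set.seed(2)
  ref <- c(chr01 = rdna(3000))
  contig <- substr(ref[[1]], 1001, 1500)
  b <- substr(contig, 251, 251)
  substr(contig, 251, 251) <- setdiff(c("A", "C", "G", "T"), b)[1]
  a <- find_anchors(contig, ref, min_len = 20)
  a <- a[a$length >= 100, ]
  expect_equal(sort(a$length), c(249, 250))
})

test_that("MEM enumeration equals the brute-force oracle", {
  for (seed in c(3, 17, 29)) {
    set.seed(seed)
    r <- rdna(2000)
    # a query sharing segments with r (forward and reverse complement)
    q <- paste0(substr(r, 501, 900), rdna(150),
                rc_chars(substr(r, 1201, 1500)), rdna(100))
    got <- find_anchors(q, c(chr01 = r), min_len = 15)
    got <- got[order(got$strand, got$q_start, got$r_start),
               c("q_start", "q_end", "r_start", "r_end", "strand")]
    want <- mem_oracle(q, r, 15)[, c("q_start", "q_end", "r_start",
                                     "r_end", "strand")]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("chain weight equals exhaustive collinear search on small instances", {
  for (seed in c(5, 23)) {
    set.seed(seed)
    n <- 12
    qs <- sort(sample(0:500, n)); qe <- qs + sample(10:40, n, TRUE)
    rs <- sort(sample(0:800, n)) + sample(-50:50, n, TRUE); re <- rs + (qe - qs)
    got <- cpp_chain(as.integer(qs), as.integer(qe), rs, re, 1, 1L)
    got_w <- sum(qe[got[[1]]] - qs[got[[1]]])
    expect_equal(got_w, chain_oracle(qs, qe, rs, re))
  }
})

test_that("a large reference gap splits blocks within one candidate", {
  set.seed(6)
  ref <- c(chr01 = rdna(12000))
  # contig = two ref segments with 4 kb deleted between them
  contig <- paste0(substr(ref[[1]], 2001, 4000), substr(ref[[1]], 8001, 10000))
  anchors <- find_anchors(contig, ref, 20)
  cands <- chain_anchors(anchors, max_join_gap = 1000,
                         contig_len = nchar(contig))
  expect_equal(length(cands), 1)
  expect_equal(length(unique(cands[[1]]$block)), 2)
  blocks <- extend_and_score(cands[[1]], contig, ref)
  expect_equal(nrow(blocks), 2)
  expect_equal(blocks$identity, c(1, 1))
})

test_that("extension identity equals full DP and the Biostrings score", {
  set.seed(7)
  pair <- tiny_divergent_pair(seed = 7, len = 500, snps = 10)
  al <- cpp_banded_global(pair$q, pair$r, 600L, 1, -1, -2)  # band >= len: full
  or <- nw_oracle(pair$q, pair$r)
  expect_equal(al$score, or$score)
  expect_equal(al$matches, or$matches)
  expect_equal(al$columns, or$columns)
  expect_equal(al$matches / al$columns, (500 - 10) / 500)
  bs <- Biostrings::pairwiseAlignment(
    pair$q, pair$r, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 0, gapExtension = 2)
  expect_equal(al$score, Biostrings::score(bs))
  # with indels: optimal score still agrees with the full-DP oracle
  q2 <- paste0(substr(pair$q, 1, 200), substr(pair$q, 226, 500))
  al2 <- cpp_banded_global(q2, pair$r, 600L, 1, -1, -2)
  or2 <- nw_oracle(q2, pair$r)
  expect_equal(al2$score, or2$score)
  expect_equal(al2$matches, or2$matches)
  expect_equal(al2$columns, or2$columns)
})

test_that("a query-only gap adds gap columns but no matches", {
  set.seed(8)
  ref <- c(chr01 = rdna(4000))
  contig <- paste0(substr(ref[[1]], 1001, 1800), rdna(300),
                   substr(ref[[1]], 1801, 2600))
  al <- align_sequences(c(ctg = contig), ref)
  b <- al$blocks
  expect_equal(nrow(b), 1)
  expect_equal(b$matches, 1600)
  expect_equal(b$aln_columns, 1900)  # 1600 M + 300 I
  expect_match(b$cigar, "I")
})

test_that("placement filtering applies the published thresholds", {
  cand <- data.frame(cand_id = 1:4, contig_id = c("a", "b", "c", "c"),
                     chrom = "chr01", strand = "+",
                     r_lo = c(0, 5000, 10000, 40000),
                     r_hi = c(1000, 6000, 11000, 41000),
                     coverage = c(0.95, 1.0, 0.9, 0.9),
                     identity = c(0.89, 1.0, 0.99, 0.99),
                     score = c(900, 1000, 100, 40),
                     contig_len = 1000)
  fp <- filter_placements(cand)
  # identity 0.89 rejected despite coverage 0.95
  expect_false("a" %in% fp$accepted$contig_id)
  expect_true("below_threshold" %in%
                fp$rejected$reason[fp$rejected$contig_id == "a"])
  # perfect unique candidate accepted
  expect_true("b" %in% fp$accepted$contig_id)
  # two disjoint candidates for one contig: higher score kept
  cc <- fp$accepted[fp$accepted$contig_id == "c", ]
  expect_equal(nrow(cc), 1)
  expect_equal(cc$r_start, 10000)
  # ambiguity: two near-equal scores reject the contig
  cand2 <- cand[3:4, ]
  cand2$score <- c(100, 97)
  fp2 <- filter_placements(cand2)
  expect_equal(nrow(fp2$accepted), 0)
  expect_true(all(fp2$rejected$reason == "ambiguous"))
})

test_that("reverse-complement queries mirror coordinates at equal identity", {
  set.seed(9)
  ref <- c(chr01 = rdna(6000))
  contig <- substr(ref[[1]], 2001, 3500)
  at <- sample(1500, 12)
  for (p in at) {
    b <- substr(contig, p, p)
    substr(contig, p, p) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  fwd <- align_sequences(c(x = contig), ref)
  rev_ <- align_sequences(c(x = revcomp(contig)), ref)
  expect_equal(fwd$candidates$identity, rev_$candidates$identity)
  expect_equal(fwd$candidates$r_lo, rev_$candidates$r_lo)
  expect_equal(fwd$candidates$r_hi, rev_$candidates$r_hi)
  expect_equal(fwd$candidates$strand, "+")
  expect_equal(rev_$candidates$strand, "-")
  expect_equal(fwd$blocks$q_start, rev_$blocks$f_start)
})

test_that("accepted placements are internally consistent and recoverable", {
  p <- sim_params(ref_length = 5e5, snp_rate = 0.01, small_indel_rate = 2e-4,
                  large_del_count = 3, large_ins_count = 2, contig_n50 = 2e4,
                  seed = 51)
  ds <- simulate_dataset(p)
  al <- align_contigs(ds$contigs, ds$ref)
  # stored identity/coverage re-derivable from blocks and above thresholds
  for (i in seq_len(nrow(al$placements))) {
    pl <- al$placements[i, ]
    b <- al$blocks[al$blocks$cand_id == pl$cand_id, ]
    expect_equal(pl$identity, sum(b$matches) / sum(b$aln_columns))
    expect_gte(pl$identity, 0.90)
    expect_gte(pl$coverage, 0.80)
  }
  # >= 95% of contigs >= 5 kb accepted at the true locus within +-50 bp
  truth <- ds$truth$placements
  big <- truth[truth$donor_end - truth$donor_start >= 5000 &
                 truth$ref_end > truth$ref_start, ]
  hit <- vapply(seq_len(nrow(big)), function(i) {
    pl <- al$placements[al$placements$contig_id == big$contig_id[i], ]
    nrow(pl) == 1 && pl$chrom == big$chrom[i] &&
      abs(pl$r_start - big$ref_start[i]) <= 50
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})
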