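# small deterministic world shared by the scaffold tests
scaffold_world <- function(seed = 12) {
  p <- sim_params(ref_length = 6e5, snp_rate = 0.003, small_indel_rate = 0,
                  large_del_count = 0, large_ins_count = 3,
                  large_ins_sizes = list(meanlog = log(5000), sdlog = 0.2,
                                         min = 3000, max = 9000),
                  repeat_fraction = 0, contig_n50 = 5e4,
                  bes_count = 500, bes_insert_mean = 6e4, bes_insert_sd = 6e3,
                  seed = seed)
  ds <- simulate_dataset(p, isolate_insertions = TRUE, bes = TRUE)
  al <- align_contigs(ds$contigs, ds$ref)
  list(p = p, ds = ds, al = al)
}

test_that("BES pair and coverage rules drop disqualified hits", {
  set.seed(1)
  ref <- c(chr01 = rdna(700000))
  contigs <- c(c1 = substr(ref[[1]], 100001, 140000))
  # clean clone: ends 50 kb apart
  bes <- c(cl1_F = substr(ref[[1]], 200001, 200600),
           cl1_R = rc_chars(substr(ref[[1]], 249401, 250000)),
           # pair at 310 kb separation: dropped from ref_pairs
           cl2_F = substr(ref[[1]], 300001, 300600),
           cl2_R = rc_chars(substr(ref[[1]], 609401, 610000)),
           # low contig-side coverage: 600 bp read, only 500 bp from contig
           cl3_F = paste0(substr(ref[[1]], 100501, 101000), rdna(100)),
           cl3_R = rc_chars(substr(ref[[1]], 160001, 160600)))
  bm <- map_bes(bes, contigs, ref)
  expect_true("cl1" %in% bm$ref_pairs$clone_id)
  expect_false("cl2" %in% bm$ref_pairs$clone_id)  # 310 kb > 300 kb
  # cl3_F coverage ~0.83 on the contig (< 0.95): dropped from contig side
  expect_false("cl3_F" %in% bm$contig_side$bes_id)
  expect_true("cl1_F" %in% bm$ref_side$bes_id)
})

test_that("a BES with two equal contig hits is non-unique and dropped", {
  set.seed(2)
  seg <- rdna(5000)
  ref <- c(chr01 = paste0(rdna(2000), seg, rdna(3000), seg, rdna(2000)))
  contigs <- c(dup1 = seg, dup2 = seg)
  bes <- c(clx_F = substr(seg, 1001, 1600),
           clx_R = rc_chars(substr(seg, 3001, 3600)))
  bm <- map_bes(bes, contigs, ref)
  expect_false("clx_F" %in% bm$contig_side$bes_id)
})

test_that("rule (i) places a contig at its unique BES reference hit", {
  set.seed(3)
  ref <- c(chr01 = rdna(400000))
  # the "unplaced" contig matches ref 200k-240k but we pretend alignment
  # missed it; its BES maps uniquely to that empty region
  ctg <- substr(ref[[1]], 200001, 240000)
  unplaced <- c(ux = ctg)
  bes <- c(cla_F = substr(ctg, 5001, 5600),
           cla_R = rc_chars(substr(ctg, 35001, 35600)))
  placements <- data.frame(contig_id = "other", chrom = "chr01",
                           r_start = 0, r_end = 100000, strand = "+",
                           identity = 1, coverage = 1, score = 1e5,
                           method = "ALIGN", cand_id = 1L)
  bm <- map_bes(bes, c(unplaced, other = substr(ref[[1]], 1, 100000)), ref)
  resc <- rescue_anchor(unplaced, bm, placements)
  expect_equal(nrow(resc), 1)
  expect_equal(resc$contig_id, "ux")
  expect_equal(resc$method, "BES")
  expect_lt(abs(resc$r_start - 200000), 100)
  # a contig with zero BES hits stays unplaced
  resc0 <- rescue_anchor(c(uy = rdna(5000)), bm, placements)
  expect_equal(nrow(resc0), 0)
})

test_that("rule (ii) rescues insertion-only contigs near the mate locus", {
  w <- scaffold_world()
  ds <- w$ds; al <- w$al
  pl_truth <- ds$truth$placements
  ins_ctg <- pl_truth$contig_id[pl_truth$ref_start == pl_truth$ref_end]
  expect_gte(length(ins_ctg), 2)
  expect_false(any(ins_ctg %in% al$placements$contig_id))
  unplaced <- ds$contigs[setdiff(names(ds$contigs),
                                 al$placements$contig_id)]
  unplaced <- unplaced[nchar(unplaced) >= 500]
  bm <- map_bes(ds$bes$seq, ds$contigs, ds$ref)
  resc <- rescue_anchor(unplaced, bm, al$placements,
                        insert_mean = w$p$bes_insert_mean)
  eligible <- intersect(ins_ctg, names(unplaced))
  hits <- vapply(eligible, function(cid) {
    r <- resc[resc$contig_id == cid, ]
    tr <- pl_truth[pl_truth$contig_id == cid, ]
    nrow(r) == 1 && r$chrom == tr$chrom &&
      abs((r$r_start + r$r_end) / 2 - tr$ref_start) <
        3 * w$p$bes_insert_mean  # clone-geometry window
  }, logical(1))
  expect_gte(mean(hits), 0.5)
  # rescues never overwrite ALIGN placements
  expect_equal(length(intersect(resc$contig_id,
                                al$placements$contig_id)), 0)
})

test_that("paired-end anchoring needs enough consistent links", {
  unplaced <- c(uz = strrep("A", 4000))
  placements <- data.frame(contig_id = "p1", chrom = "chr01", r_start = 0,
                           r_end = 50000, strand = "+", identity = 1,
                           coverage = 1, score = 5e4, method = "ALIGN",
                           cand_id = 1L)
  mklinks <- function(n, chroms = "chr01", pos = 51000, fwd = TRUE)
    data.frame(unplaced_id = "uz", chrom = chroms, ref_pos = pos,
               same_strand = fwd)
  # 5 concordant links: placed
  pe <- paired_end_anchor(unplaced, mklinks(5)[rep(1, 5), ], placements)
  expect_equal(nrow(pe), 1)
  expect_equal(pe$method, "PAIRED_END")
  expect_equal(pe$strand, "+")
  # 2 links with min_links = 3: unplaced
  pe2 <- paired_end_anchor(unplaced, mklinks(1)[rep(1, 2), ], placements)
  expect_equal(nrow(pe2), 0)
  # 3 links across two chromosomes: inconsistent, unplaced
  lk <- rbind(mklinks(1), mklinks(1), mklinks(1))
  lk$chrom <- c("chr01", "chr01", "chr02")
  expect_equal(nrow(paired_end_anchor(unplaced, lk, placements)), 0)
  # orientation evidence split 50/50: unplaced
  lk2 <- rbind(mklinks(1), mklinks(1), mklinks(1), mklinks(1))
  lk2$same_strand <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(nrow(paired_end_anchor(unplaced, lk2, placements)), 0)
})

test_that("pseudomolecule FASTA and AGP round-trip byte-identically", {
  w <- scaffold_world(seed = 17)
  pm <- build_pseudomolecules(w$al$placements, w$ds$contigs, w$ds$ref)
  expect_gt(length(pm$fasta), 0)
  rebuilt <- assemble_from_agp(pm$agp, w$ds$contigs)
  expect_identical(rebuilt[names(pm$fasta)], pm$fasta)
  # file-level round trip too
  f <- tempfile()
  write_agp(pm$agp, f)
  agp2 <- read_agp(f)
  rebuilt2 <- assemble_from_agp(agp2, w$ds$contigs)
  expect_identical(rebuilt2[names(pm$fasta)], pm$fasta)
  # no reference base claimed twice after tiling
  pl <- pm$placements
  for (chrom in unique(pl$chrom)) {
    x <- pl[pl$chrom == chrom, ]
    x <- x[order(x$r_start), ]
    if (nrow(x) > 1) expect_true(all(x$r_start[-1] >= x$r_end[-nrow(x)]))
  }
  # inter-contig gaps respect the 100 N floor
  gaps <- pm$agp[pm$agp$component_type %in% c("N", "U"), ]
  expect_true(all(gaps$gap_length >= 100))
})

test_that("a single placed contig becomes the whole pseudomolecule", {
  set.seed(5)
  ref <- c(chr01 = rdna(50000))
  contigs <- c(solo = substr(ref[[1]], 10001, 30000))
  placements <- data.frame(contig_id = "solo", chrom = "chr01",
                           r_start = 10000, r_end = 30000, strand = "+",
                           identity = 1, coverage = 1, score = 2e4,
                           method = "ALIGN", cand_id = 1L)
  pm <- build_pseudomolecules(placements, contigs, ref)
  expect_identical(pm$fasta[["chr01_pseudo"]], contigs[["solo"]])
  expect_equal(nrow(pm$agp), 1)
  expect_equal(pm$agp$component_type, "W")
})

test_that("N50 and assembly statistics follow their definitions", {
  expect_equal(n50(c(100, 200, 300, 400)), 300)
  expect_equal(n50(c(5, 5, 5, 5)), 5)
  expect_equal(n50(numeric(0)), 0)
  st <- assembly_stats(c(100, 200, 300, 400))
  expect_equal(st$n, 4)
  expect_equal(st$n50, 300)
  expect_equal(st$max_len, 400)
  expect_equal(st$mean_len, 250)
  expect_equal(st$total_len, 1000)
})
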