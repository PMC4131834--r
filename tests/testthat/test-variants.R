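test_that("identical genomes give zero SNPs over the full aligned length", {
  set.seed(1)
  ref <- c(chr01 = rdna(30000))
  contigs <- c(c1 = ref[[1]])
  al <- align_contigs(contigs, ref)
  sn <- call_snps(al$placements, al$blocks, contigs, ref)
  expect_equal(nrow(sn$snps), 0)
  expect_equal(sn$aligned_bp, 30000)
})

test_that("swapping genome roles exchanges ref and alt alleles", {
  p <- sim_params(ref_length = 1e5, snp_rate = 0.005, small_indel_rate = 0,
                  contig_n50 = 1e5, seed = 2)
  rg <- random_genome(p)
  mt <- mutate_reference(rg$genome, p)
  fwd_ctg <- c(donor = mt$donor[["chr01"]])
  a1 <- align_contigs(fwd_ctg, rg$genome)
  s1 <- call_snps(a1$placements, a1$blocks, fwd_ctg, rg$genome)
  rev_ctg <- c(refseq = rg$genome[["chr01"]])
  donor_as_ref <- c(chr01 = mt$donor[["chr01"]])
  a2 <- align_contigs(rev_ctg, donor_as_ref)
  s2 <- call_snps(a2$placements, a2$blocks, rev_ctg, donor_as_ref)
  expect_equal(nrow(s1$snps), nrow(s2$snps))
  expect_equal(sort(paste(s1$snps$ref_base, s1$snps$alt_base)),
               sort(paste(s2$snps$alt_base, s2$snps$ref_base)))
})

test_that("called SNPs match the planted truth on simulated data", {
  p <- sim_params(ref_length = 2e5, snp_rate = 0.01, small_indel_rate = 1e-4,
                  large_del_count = 2, contig_n50 = 3e4, seed = 3)
  ds <- simulate_dataset(p)
  al <- align_contigs(ds$contigs, ds$ref)
  sn <- call_snps(al$placements, al$blocks, ds$contigs, ds$ref)
  key <- function(ch, po, rb, ab) paste(ch, po, rb, ab)
  called <- key(sn$snps$chrom, sn$snps$r_pos, sn$snps$ref_base,
                sn$snps$alt_base)
  tp <- ds$truth$snps
  planted <- key(tp$chrom, tp$ref_pos, tp$ref_base, tp$alt_base)
  expect_gte(mean(called %in% planted), 0.99)
  covered <- rep(FALSE, nrow(tp))
  for (i in seq_len(nrow(al$placements)))
    covered <- covered | (tp$chrom == al$placements$chrom[i] &
                            tp$ref_pos >= al$placements$r_start[i] &
                            tp$ref_pos < al$placements$r_end[i])
  expect_gte(mean(planted[covered] %in% called), 0.90)
  # placements without blocks are an error
  expect_error(call_snps(al$placements, NULL, ds$contigs, ds$ref),
               "blocks")
})

# hand-built block tables exercising the split-alignment thresholds
mk_blocks <- function(q_gap, r_gap, flank = 400) {
  data.frame(contig_id = "c1", chrom = "chr01", strand = "+",
             q_start = c(0, flank + q_gap),
             q_end = c(flank, 2 * flank + q_gap),
             f_start = c(0, flank + q_gap),
             f_end = c(flank, 2 * flank + q_gap),
             r_start = c(1000, 1000 + flank + r_gap),
             r_end = c(1000 + flank, 1000 + 2 * flank + r_gap),
             matches = flank, aln_columns = flank, identity = 1,
             cigar = sprintf("%dM", flank), cand_id = 1L)
}

test_that("insertion calls follow the unaligned-fragment thresholds", {
  contigs <- c(c1 = strrep("A", 2000))
  # query gap 150, ref gap 0, flanks 250/300
  b <- mk_blocks(150, 0)
  b$q_end[1] <- b$f_end[1] <- 250
  b$r_end[1] <- 1250
  b$matches[1] <- b$aln_columns[1] <- 250
  b$q_start[2] <- b$f_start[2] <- 400
  b$q_end[2] <- b$f_end[2] <- 700
  b$r_start[2] <- 1250; b$r_end[2] <- 1550
  b$matches[2] <- b$aln_columns[2] <- 300
  b$cigar <- c("250M", "300M")
  ins <- classify_insertions(b, contigs)
  expect_equal(nrow(ins), 1)
  expect_equal(ins$type, "INS")
  expect_equal(ins$size, 150)
  expect_equal(ins$r_pos, 1250)
  # query gap 99: below the 100 bp floor, no call
  expect_equal(nrow(classify_insertions(mk_blocks(99, 0), contigs)), 0)
  # flank below 200: no call
  expect_equal(nrow(classify_insertions(mk_blocks(150, 0, flank = 150),
                                        contigs)), 0)
})

test_that("deletion calls follow the gapped-alignment thresholds", {
  contigs <- c(c1 = strrep("A", 2000))
  d <- classify_deletions(mk_blocks(0, 4000), contigs)
  expect_equal(d$type, "DEL")
  expect_equal(d$size, 4000)
  # 60 kb exceeds the 50 kb ceiling
  expect_equal(nrow(classify_deletions(mk_blocks(0, 60000), contigs)), 0)
  # both sides gapped beyond tolerance: COMPLEX, not DEL
  cx <- classify_deletions(mk_blocks(500, 4000), contigs)
  expect_equal(cx$type, "COMPLEX")
  # size/flank invariants hold on every emitted record
  all_calls <- rbind(classify_deletions(mk_blocks(0, 4000), contigs),
                     classify_insertions(mk_blocks(150, 0), contigs))
  keep <- all_calls$type %in% c("INS", "DEL")
  expect_true(all(all_calls$size[keep] >= 100))
  expect_true(all(all_calls$left_flank[keep] >= 200))
  expect_true(all(all_calls$right_flank[keep] >= 200))
})

test_that("planted large indels are recovered with tight breakpoints", {
  p <- sim_params(ref_length = 1.2e6, snp_rate = 0.002,
                  small_indel_rate = 5e-5, large_del_count = 12,
                  large_ins_count = 6, contig_n50 = 6e4, seed = 4)
  ds <- simulate_dataset(p)
  al <- align_contigs(ds$contigs, ds$ref)
  calls <- rbind(classify_deletions(al$blocks, ds$contigs),
                 classify_insertions(al$blocks, ds$contigs))
  truth <- ds$truth$indels[ds$truth$indels$large, ]
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    tt <- truth[i, ]
    any(calls$type == tt$type & calls$chrom == tt$chrom &
          abs(calls$r_pos - tt$ref_pos) <= 20 &
          abs(calls$size - tt$size) <= 20)
  }, logical(1))
  expect_gte(mean(hit), 0.8)
  # anti-symmetry on a planted 4 kb deletion: swapping roles makes it an
  # insertion of the same size at the homologous position
  del1 <- truth[truth$type == "DEL", ][1, ]
  donor_ref <- setNames(ds$donor, names(ds$ref))
  ctg2 <- c(x = ds$ref[["chr01"]])
  al2 <- align_contigs(ctg2, donor_ref)
  ins2 <- classify_insertions(al2$blocks, ctg2)
  expect_true(any(ins2$type == "INS" & abs(ins2$size - del1$size) <= 20 &
                    abs(ins2$r_pos - del1$donor_pos) <= 20))
})

test_that("breakpoint validation needs five spanning reads and a pair", {
  set.seed(5)
  obj_seq <- rdna(4000)
  contigs <- c(c1 = obj_seq)
  agp <- data.frame(object = "chr01_pseudo", object_beg = 1,
                    object_end = 4000, part_number = 1L,
                    component_type = "W", component_id = "c1",
                    component_beg = 1, component_end = 4000,
                    orientation = "+", gap_length = NA_real_)
  blocks <- data.frame(contig_id = "c1", chrom = "chr01", strand = "+",
                       q_start = c(0, 2000), q_end = c(2000, 4000),
                       f_start = c(0, 2000), f_end = c(2000, 4000),
                       r_start = c(0, 6000), r_end = c(2000, 8000),
                       matches = 2000, aln_columns = 2000, identity = 1,
                       cigar = "2000M", cand_id = 1L)
  indel <- data.frame(chrom = "chr01", r_pos = 2000, type = "DEL",
                      size = 4000, left_flank = 2000, right_flank = 2000,
                      seq = "", contig_id = "c1")
  mk_sam <- function(n_span) {
    # n_span reads crossing object position 2000, plus a straddling pair
    starts <- round(seq(1920, 1980, length.out = n_span))
    rbind(
      data.frame(qname = sprintf("s%02d/1", seq_len(n_span)), flag = 0L,
                 rname = "chr01_pseudo", pos = starts, mapq = 60L,
                 cigar = "100M", rnext = "*", pnext = 0, tlen = 0,
                 seq = substring(obj_seq, starts + 1, starts + 100),
                 qual = strrep("D", 100)),
      data.frame(qname = c("pp/1", "pp/2"), flag = c(0L, 16L),
                 rname = "chr01_pseudo", pos = c(1700, 2200), mapq = 60L,
                 cigar = "100M", rnext = "*", pnext = 0, tlen = 0,
                 seq = c(substr(obj_seq, 1701, 1800),
                         substr(obj_seq, 2201, 2300)),
                 qual = strrep("D", 100)))
  }
  v6 <- validate_boundaries(indel, mk_sam(6), agp, blocks)
  expect_true(v6$validated)
  v4 <- validate_boundaries(indel, mk_sam(4), agp, blocks)
  expect_false(v4$validated)
  # zero coverage: flagged NO_DATA (validated NA)
  empty_sam <- mk_sam(6)[0, ]
  v0 <- validate_boundaries(indel, empty_sam, agp, blocks)
  expect_true(is.na(v0$validated))
})

test_that("variant summaries reproduce the published arithmetic", {
  snps <- data.frame(chrom = rep("chr01", 3), r_pos = 1:3,
                     ref_base = "A", alt_base = "C", contig_id = "c")
  indels <- data.frame(chrom = "chr01", r_pos = 10, type = "DEL",
                       size = 4000, left_flank = 300, right_flank = 300,
                       seq = "", contig_id = "c")
  sm <- summarize_variants(snps, indels, 300, "chr01")
  expect_equal(sm$totals$snp_frequency_pct, 1.00)
  expect_equal(sm$per_chrom$snps, 3)
  # the published frequency: 2,787,250 SNPs over 278.75 Mb -> 1.00%
  expect_equal(round(100 * 2787250 / 278750000, 2), 1.00)
  # the published mean indel length: 14.78 Mb over 7,393 sites -> 1999 bp
  expect_equal(round(14780000 / 7393), 1999)
  # zero calls: all-zero summary
  sm0 <- summarize_variants(snps[0, ], indels[0, ], 0, c("chr01", "chr02"))
  expect_true(all(sm0$per_chrom$snps == 0))
  expect_equal(sm0$totals$snp_frequency_pct, 0)
  expect_equal(sm0$totals$mean_indel_len, 0)
  # COMPLEX rows never enter the counts
  cx <- indels; cx$type <- "COMPLEX"
  expect_equal(summarize_variants(snps, cx, 300, "chr01")$totals$indel_total,
               0)
})
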