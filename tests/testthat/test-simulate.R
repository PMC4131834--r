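test_that("zero rates leave the donor identical to the reference", {
  p <- sim_params(ref_length = 5e4, snp_rate = 0, small_indel_rate = 0,
                  contig_n50 = 2e4, seed = 1)
  rg <- random_genome(p)
  mt <- mutate_reference(rg$genome, p)
  expect_identical(mt$donor, rg$genome)
  expect_equal(nrow(mt$truth$snps), 0)
  expect_equal(nrow(mt$truth$indels), 0)
})

test_that("planted SNP count is binomial at the requested rate", {
  p <- sim_params(ref_length = 1e6, snp_rate = 0.01, small_indel_rate = 0,
                  contig_n50 = 2e4, seed = 7)
  rg <- random_genome(p)
  mt <- mutate_reference(rg$genome, p)
  n <- nrow(mt$truth$snps)
  mu <- 1e6 * 0.01
  sd3 <- 3 * sqrt(1e6 * 0.01 * 0.99)
  expect_gt(n, mu - sd3)
  expect_lt(n, mu + sd3)
  # all positions in bounds, sorted, alleles differ
  expect_true(all(diff(mt$truth$snps$ref_pos) > 0))
  expect_true(all(mt$truth$snps$ref_pos >= 0 &
                    mt$truth$snps$ref_pos < 1e6))
  expect_true(all(mt$truth$snps$ref_base != mt$truth$snps$alt_base))
})

test_that("a single deletion conserves length and downstream sequence", {
  set.seed(2)
  refseq <- rdna(20000)
  ref <- c(chr01 = refseq)
  p <- sim_params(ref_length = 20000, snp_rate = 0, small_indel_rate = 0,
                  large_del_count = 1,
                  large_del_sizes = list(weights = c(1, 0, 0), means = c(4000, 0),
                                         sds = c(1e-9, 1), ln_meanlog = 0,
                                         ln_sdlog = 1, min = 100, max = 50000),
                  contig_n50 = 1e4, seed = 3)
  mt <- mutate_reference(ref, p)
  ind <- mt$truth$indels
  expect_equal(nrow(ind), 1)
  expect_equal(ind$type, "DEL")
  expect_equal(ind$size, 4000)
  expect_equal(nchar(mt$donor), nchar(refseq) - 4000,
               ignore_attr = TRUE)
  pos <- ind$ref_pos
  expect_identical(substr(mt$donor[[1]], pos + 1, nchar(mt$donor[[1]])),
                   substr(refseq, pos + 4000 + 1, nchar(refseq)))
})

test_that("applying truth events to the reference reproduces the donor", {
  p <- sim_params(ref_length = 2e5, snp_rate = 0.01, small_indel_rate = 3e-4,
                  large_del_count = 3, large_ins_count = 3,
                  contig_n50 = 5e4, seed = 11)
  rg <- random_genome(p)
  mt <- mutate_reference(rg$genome, p)
  rebuilt <- splice_truth(rg$genome[["chr01"]],
                          mt$truth$snps, mt$truth$indels)
  expect_identical(rebuilt, mt$donor[["chr01"]])
})

test_that("deletion sizes reproduce the bimodal mixture structure", {
  p <- sim_params(ref_length = 9e6, snp_rate = 0, small_indel_rate = 0,
                  large_del_count = 250, contig_n50 = 5e4, seed = 13)
  rg <- random_genome(p)
  mt <- mutate_reference(rg$genome, p, rg$repeat_tracts)
  sizes <- mt$truth$indels$size[mt$truth$indels$type == "DEL" &
                                  mt$truth$indels$large]
  expect_gte(length(sizes), 200)
  peak1 <- sum(sizes >= 3000 & sizes < 5000)
  peak2 <- sum(sizes >= 11000 & sizes < 14000)
  expect_gt(peak1, sum(sizes >= 1000 & sizes < 3000))
  expect_gt(peak1, sum(sizes >= 5000 & sizes < 7000))
  expect_gt(peak2, sum(sizes >= 8000 & sizes < 11000))
  expect_gt(peak2, sum(sizes >= 14000 & sizes < 17000))
  # repeat-tagged share near the configured fraction
  tags <- mt$truth$indels$repeat_tag[mt$truth$indels$large &
                                       mt$truth$indels$type == "DEL"]
  expect_gt(mean(tags), 0.40)
  expect_lt(mean(tags), 0.75)
})

test_that("shearing partitions the donor and hits the target N50", {
  p <- sim_params(ref_length = 5e5, snp_rate = 0.005, large_del_count = 2,
                  contig_n50 = 2e4, seed = 5)
  ds <- simulate_dataset(p)
  expect_equal(sum(nchar(ds$contigs)), sum(nchar(ds$donor)))
  emp <- n50(nchar(ds$contigs))
  expect_gt(emp, 0.8 * 2e4)
  expect_lt(emp, 1.2 * 2e4)
  # every contig has exactly one placement and reconstruction works
  expect_equal(sort(names(ds$contigs)),
               sort(ds$truth$placements$contig_id))
  pl <- ds$truth$placements
  rebuilt <- paste(vapply(order(pl$donor_start), function(i)
    ds$contigs[[pl$contig_id[i]]], character(1)), collapse = "")
  expect_identical(rebuilt, ds$donor[["chr01"]])
})

test_that("contig N50 equal to donor length yields one contig per chromosome", {
  p <- sim_params(ref_length = 3e4, snp_rate = 0, small_indel_rate = 0,
                  contig_n50 = 3e4, seed = 2)
  rg <- random_genome(p)
  sh <- shear_contigs(rg$genome, p)
  expect_equal(length(sh$contigs), 1)
  expect_error(shear_contigs(rg$genome,
                             sim_params(ref_length = 3e4, contig_n50 = 4e4)),
               "exceeds")
})

test_that("simulation is deterministic under a fixed seed", {
  p <- sim_params(ref_length = 1e5, snp_rate = 0.01, large_del_count = 2,
                  contig_n50 = 2e4, read_depth = 5, bes_count = 10,
                  bes_insert_mean = 3e4, bes_insert_sd = 3e3, seed = 99)
  a <- simulate_dataset(p, reads = TRUE, bes = TRUE)
  b <- simulate_dataset(p, reads = TRUE, bes = TRUE)
  expect_identical(a$donor, b$donor)
  expect_identical(a$contigs, b$contigs)
  expect_identical(a$reads$seq, b$reads$seq)
  expect_identical(a$bes$seq, b$bes$seq)
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(a$reads$seq, a$reads$qual, f1)
  write_fastq(b$reads$seq, b$reads$qual, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("error-free reads are exact substrings at the recorded coordinates", {
  p <- sim_params(ref_length = 5e4, snp_rate = 0, small_indel_rate = 0,
                  contig_n50 = 2e4, read_depth = 3, read_error_rate = 0,
                  seed = 21)
  rg <- random_genome(p)
  rd <- simulate_reads(rg$genome, p)
  sam <- rd$sam
  for (i in sample(nrow(sam), 50)) {
    r <- sam[i, ]
    expect_identical(r$seq, substr(rg$genome[[r$rname]], r$pos + 1,
                                   r$pos + nchar(r$seq)))
  }
  # coverage arithmetic: pair count ~ depth * len / (2 * read_len)
  n_pairs <- length(unique(sam$qname))
  expect_equal(n_pairs, round(3 * 5e4 / (2 * p$read_length)), tolerance = 0.1)
})

test_that("BES geometry matches the truth distances", {
  p <- sim_params(ref_length = 2e5, snp_rate = 0, small_indel_rate = 0,
                  contig_n50 = 5e4, bes_count = 20, bes_insert_mean = 5e4,
                  bes_insert_sd = 0, seed = 31)
  rg <- random_genome(p)
  bs <- simulate_bes(rg$genome, p)
  expect_equal(nrow(bs$truth), 20)
  expect_true(all(bs$truth$dist == 5e4))
  # end reads recoverable at the truth coordinates (error-free)
  tr <- bs$truth[1, ]
  f <- bs$seq[[paste0(tr$clone_id, "_F")]]
  r <- bs$seq[[paste0(tr$clone_id, "_R")]]
  g <- rg$genome[[tr$chrom]]
  expect_identical(f, substr(g, tr$start + 1, tr$start + p$bes_read_len))
  expect_identical(r, revcomp(substr(g, tr$end - p$bes_read_len + 1, tr$end)))
  # zero clones: empty set, no error
  p0 <- sim_params(ref_length = 2e5, bes_count = 0, contig_n50 = 5e4)
  expect_equal(length(simulate_bes(rg$genome, p0)$seq), 0)
})

test_that("simulated gene models are structurally valid", {
  p <- sim_params(ref_length = 3e5, contig_n50 = 5e4, seed = 41)
  rg <- random_genome(p)
  sg <- simulate_genes(rg$genome, 15, p)
  m <- sg$models
  expect_equal(length(unique(m$gene_id)), 15)
  for (tid in unique(m$transcript_id[m$feature == "CDS"])) {
    cds <- m[m$feature == "CDS" & m$transcript_id == tid, ]
    cds <- cds[order(cds$start), ]
    expect_true(all(diff(cds$start) > 0))
    s <- paste(substring(sg$genome[[cds$chrom[1]]], cds$start + 1, cds$end),
               collapse = "")
    if (cds$strand[1] == "-") s <- rc_chars(s)
    expect_equal(nchar(s) %% 3, 0)
    aa <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(s))), "")[[1]]
    expect_equal(aa[1], "M")
    expect_equal(aa[length(aa)], "*")
    expect_false("*" %in% aa[-length(aa)])
    # introns carry GT..AG in the transcript orientation
    ex <- m[m$feature == "exon" & m$transcript_id == tid, ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) > 1) for (i in seq_len(nrow(ex) - 1)) {
      intron <- substr(sg$genome[[ex$chrom[1]]], ex$end[i] + 1,
                       ex$start[i + 1])
      if (ex$strand[1] == "-") intron <- rc_chars(intron)
      expect_identical(substr(intron, 1, 2), "GT")
      expect_identical(substr(intron, nchar(intron) - 1, nchar(intron)), "AG")
    }
  }
  # n_genes = 0 gives an empty, well-formed table
  expect_equal(nrow(simulate_genes(rg$genome, 0, p)$models), 0)
})
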