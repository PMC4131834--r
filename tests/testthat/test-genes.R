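gene_world <- function(seed = 21, n_genes = 12) {
  p <- sim_params(ref_length = 3e5, contig_n50 = 5e4, seed = seed)
  rg <- random_genome(p)
  sg <- simulate_genes(rg$genome, n_genes, p)
  list(p = p, ref = sg$genome, models = sg$models)
}

test_that("exon coverage applies the 5% presence rule", {
  models <- data.frame(
    gene_id = "g1", transcript_id = "g1.1", chrom = "chr01", strand = "+",
    feature = c("gene", "mRNA", "exon", "exon"),
    start = c(1000, 1000, 1000, 2500), end = c(3000, 3000, 1500, 3000),
    phase = NA_integer_)
  blk <- function(lo, hi) data.frame(
    contig_id = "c", chrom = "chr01", strand = "+", q_start = 0,
    q_end = hi - lo, f_start = 0, f_end = hi - lo, r_start = lo, r_end = hi,
    matches = hi - lo, aln_columns = hi - lo, identity = 1, cigar = "1M",
    cand_id = 1L)
  # 40 covered bp of 1000 exon bp: fraction 0.04 -> absent
  cv <- exon_coverage(models, blk(1000, 1040))
  expect_equal(cv$exon_bp, 1000)
  expect_equal(cv$coverage_fraction, 0.04)
  expect_false(cv$present)
  # full overlap -> present at fraction 1
  cv2 <- exon_coverage(models, blk(0, 5000))
  expect_equal(cv2$coverage_fraction, 1)
  expect_true(cv2$present)
  # boundary: exactly 5% counts as present
  cv3 <- exon_coverage(models, blk(1000, 1050))
  expect_true(cv3$present)
})

test_that("interval intersection equals a per-base bitmap count", {
  set.seed(2)
  for (rep in 1:5) {
    ex_start <- sort(sample(0:8000, 4)) * 1
    ex_end <- ex_start + sample(100:800, 4)
    models <- data.frame(
      gene_id = "g", transcript_id = "g.1", chrom = "chr01", strand = "+",
      feature = c("gene", "mRNA", rep("exon", 4)),
      start = c(min(ex_start), min(ex_start), ex_start),
      end = c(max(ex_end), max(ex_end), ex_end), phase = NA_integer_)
    b_start <- sort(sample(0:9000, 3))
    b_end <- b_start + sample(200:1500, 3)
    blocks <- data.frame(
      contig_id = "c", chrom = "chr01", strand = "+", q_start = 0,
      q_end = 1, f_start = 0, f_end = 1, r_start = b_start, r_end = b_end,
      matches = 1, aln_columns = 1, identity = 1, cigar = "1M", cand_id = 1L)
    cv <- exon_coverage(models, blocks)
    # oracle on collapsed exon intervals
    ex <- IRanges::reduce(IRanges::IRanges(ex_start + 1, ex_end))
    want <- bitmap_intersect_len(IRanges::start(ex) - 1, IRanges::end(ex),
                                 b_start, b_end, 12000)
    expect_equal(cv$covered_bp, want)
  }
})

test_that("codon-level classification matches exhaustive enumeration", {
  # single-exon plus-strand gene: CDS = ATG | codon | TAA at known offsets
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons <- names(code)
  set.seed(3)
  flank5 <- rdna(100); flank3 <- rdna(100)
  for (codon in codons) {
    cds <- paste0("ATG", codon, "AAATAA")   # middle codon at CDS pos 4-6
    ref <- c(chr01 = paste0(flank5, cds, flank3))
    models <- data.frame(
      gene_id = "g", transcript_id = "g.1", chrom = "chr01", strand = "+",
      feature = c("gene", "mRNA", "exon", "CDS"),
      start = 100, end = 100 + nchar(cds), phase = c(NA, NA, NA, 0L))
    snps <- do.call(rbind, lapply(0:2, function(off) {
      rb <- substr(codon, off + 1, off + 1)
      data.frame(chrom = "chr01", r_pos = 103 + off, ref_base = rb,
                 alt_base = setdiff(bases, rb))
    }))
    got <- classify_snp_effects(snps, models, ref)
    # oracle: translate mutated codon directly
    want <- vapply(seq_len(nrow(snps)), function(i) {
      off <- snps$r_pos[i] - 103
      mut <- codon
      substr(mut, off + 1, off + 1) <- snps$alt_base[i]
      aa0 <- code[[codon]]; aa1 <- code[[mut]]
      if (aa0 != "*" && aa1 == "*") "nonsense"
      else if (aa0 == "*" && aa1 != "*") "stop_loss"
      else if (aa0 == aa1) "synonymous"
      else "missense"
    }, character(1))
    expect_equal(got$category, want, info = codon)
    expect_equal(got$harmful, want == "nonsense")
  }
})

test_that("known intron and UTR positions classify by location", {
  set.seed(4)
  w <- gene_world()
  m <- w$models
  tid <- m$transcript_id[m$feature == "mRNA"][1]
  ex <- m[m$feature == "exon" & m$transcript_id == tid, ]
  ex <- ex[order(ex$start), ]
  # first 2 intron bases after exon 1: splice site (GT motif)
  sp_pos <- ex$end[1]
  rb <- substr(w$ref[[ex$chrom[1]]], sp_pos + 1, sp_pos + 1)
  snp <- data.frame(chrom = ex$chrom[1], r_pos = sp_pos, ref_base = rb,
                    alt_base = setdiff(c("A", "C", "G", "T"), rb)[1])
  got <- classify_snp_effects(snp, m, w$ref)
  expect_equal(got$category, "splice_site")
  expect_true(got$harmful)
  # deep intron position: intron, not harmful
  mid <- round((ex$end[1] + ex$start[2]) / 2)
  rb2 <- substr(w$ref[[ex$chrom[1]]], mid + 1, mid + 1)
  got2 <- classify_snp_effects(
    data.frame(chrom = ex$chrom[1], r_pos = mid, ref_base = rb2,
               alt_base = setdiff(c("A", "C", "G", "T"), rb2)[1]),
    m, w$ref)
  expect_equal(got2$category, "intron")
  # intergenic far outside any gene
  got3 <- classify_snp_effects(
    data.frame(chrom = "chr01", r_pos = 10, ref_base = "A",
               alt_base = "C"), m, w$ref)
  expect_equal(got3$category, "intergenic")
})

test_that("minus-strand genes classify identically to their mirror", {
  w <- gene_world(seed = 31, n_genes = 16)
  hs <- sample_harmful_snps(w$ref, w$models, 20, 20)
  strands <- w$models$strand[match(
    vapply(seq_len(nrow(hs)), function(i) {
      g <- w$models[w$models$feature == "gene" &
                      w$models$chrom == hs$chrom[i] &
                      w$models$start <= hs$r_pos[i] &
                      w$models$end > hs$r_pos[i], ]
      g$gene_id[1]
    }, character(1)), w$models$gene_id)]
  expect_true(all(c("+", "-") %in% strands))  # both strands exercised
  got <- classify_snp_effects(
    data.frame(chrom = hs$chrom, r_pos = hs$r_pos, ref_base = hs$ref_base,
               alt_base = hs$alt_base), w$models, w$ref)
  expect_equal(got$category, hs$expect)
  expect_true(all(got$harmful))
})

test_that("transcript classes follow the identity/coverage thresholds", {
  set.seed(5)
  ref <- c(chr01 = rdna(60000))
  tx <- c(
    mapped_tx = substr(ref[[1]], 10001, 11000),        # id 1, cov 1
    partial_tx = paste0(substr(ref[[1]], 20001, 20600), rdna(400)),
    unique_tx = rdna(1000))                            # no alignment
  cls <- transcript_uniqueness(tx, ref)
  expect_equal(cls$class[cls$transcript_id == "mapped_tx"], "mapped")
  # 600/1000 aligned: coverage ~0.6 fails 0.70 but exceeds 0.50
  expect_equal(cls$class[cls$transcript_id == "partial_tx"], "unmapped")
  expect_equal(cls$class[cls$transcript_id == "unique_tx"], "unique")
  expect_equal(cls$coverage[cls$transcript_id == "unique_tx"], 0)
})

test_that("presence matrix counts shared absences and densities", {
  cov1 <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr01",
                     exon_bp = 100, covered_bp = c(100, 0, 0),
                     coverage_fraction = c(1, 0, 0),
                     present = c(TRUE, FALSE, FALSE))
  cov2 <- cov1
  cov2$present <- c(TRUE, FALSE, TRUE)
  pm <- presence_matrix(list(d1 = cov1, d2 = cov2),
                        c(chr01 = 2e6))
  expect_equal(pm$shared_absent, 1)  # g2 absent in both
  d1 <- pm$density[pm$density$donor == "d1", ]
  expect_equal(d1$per_mb, 2 / 2)  # 2 absent genes over 2 Mb
  # single donor still works
  pm1 <- presence_matrix(list(solo = cov1), c(chr01 = 2e6))
  expect_equal(pm1$shared_absent, 2)
  expect_equal(pm1$density$per_mb, 1)
})
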