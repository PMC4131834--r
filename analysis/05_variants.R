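#!/usr/bin/env Rscript
# Call SNPs and large indels between donor contigs and the reference from
# the accepted split alignments, validate indel breakpoints with read
# support, and summarize in the per-chromosome table layout.
source("analysis/common.R")

ref <- read_fasta(file.path(data_dir, "reference.fa"))
contigs <- read_fasta(file.path(data_dir, "contigs_polished.fa"))
placements <- read_tsv(file.path(res_dir, "placements.tsv"))
blocks <- read_tsv(file.path(res_dir, "blocks.tsv"))
agp <- read_agp(file.path(res_dir, "pseudomolecules.agp"))
truth_snps <- read_tsv(file.path(data_dir, "truth_snps.tsv"))
truth_ind <- read_tsv(file.path(data_dir, "truth_indels.tsv"))

sn <- call_snps(placements, blocks, contigs, ref)
ins <- classify_insertions(blocks, contigs, study_config$indel_min_size,
                           study_config$min_flank,
                           study_config$other_gap_tol)
del <- classify_deletions(blocks, contigs, study_config$indel_min_size,
                          study_config$indel_max_size,
                          study_config$min_flank,
                          study_config$other_gap_tol)
indels <- rbind(ins, del)

# breakpoint validation with reads mapped to the pseudomolecules
pm_fa <- read_fasta(file.path(res_dir, "pseudomolecules.fa"))
reads <- read_fastq(file.path(data_dir, "reads.fq"))
sam_pm <- map_reads(reads$seq, pm_fa, quals = reads$qual)
indels <- validate_boundaries(indels[indels$type %in% c("INS", "DEL"), ],
                              sam_pm, agp, blocks,
                              min_span_reads = study_config$min_span_reads)

write_vcf(sn$snps, indels, ref, file.path(res_dir, "variants.vcf"))
write_tsv(indels, file.path(res_dir, "large_indels.tsv"))
sm <- summarize_variants(sn$snps, indels, sn$aligned_bp, names(ref))
write_tsv(sm$per_chrom, file.path(res_dir, "variant_summary_per_chrom.tsv"))
write_tsv(sm$totals, file.path(res_dir, "variant_summary_totals.tsv"))
print(sm$totals)

key <- function(ch, po, rb, ab) paste(ch, po, rb, ab)
called <- key(sn$snps$chrom, sn$snps$r_pos, sn$snps$ref_base,
              sn$snps$alt_base)
planted <- key(truth_snps$chrom, truth_snps$ref_pos, truth_snps$ref_base,
               truth_snps$alt_base)
cat(sprintf("SNP precision %.2f%%, recall (all planted) %.2f%%\n",
            100 * mean(called %in% planted),
            100 * mean(planted %in% called)))
tl <- truth_ind[truth_ind$large, ]
hit <- vapply(seq_len(nrow(tl)), function(i) {
  tt <- tl[i, ]
  any(indels$type == tt$type & indels$chrom == tt$chrom &
        abs(indels$r_pos - tt$ref_pos) <= 20 &
        abs(indels$size - tt$size) <= 20)
}, logical(1))
cat(sprintf("large-indel recall (+-20 bp): %d/%d; validated calls: %d/%d\n",
            sum(hit), nrow(tl), sum(indels$validated, na.rm = TRUE),
            nrow(indels)))
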