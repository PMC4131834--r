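#!/usr/bin/env Rscript
# Gene-level comparison: exon coverage and presence/absence of the
# reference gene models in the donor assembly, SNP effect classes with
# harmful flags, and transcript-uniqueness classification of donor
# transcripts against the reference.
source("analysis/common.R")

ref <- read_fasta(file.path(data_dir, "reference.fa"))
donor <- read_fasta(file.path(data_dir, "donor.fa"))
models <- read_gff3(file.path(data_dir, "genes.gff3"))
blocks <- read_tsv(file.path(res_dir, "blocks.tsv"))
snps <- read.delim(file.path(res_dir, "variant_summary_per_chrom.tsv"))

vc <- read_tsv(file.path(res_dir, "placements.tsv"))
snp_calls <- {
  contigs <- read_fasta(file.path(data_dir, "contigs_polished.fa"))
  call_snps(vc, blocks, contigs, ref)$snps
}

cov <- exon_coverage(models, blocks, study_config$gene_absent_cov)
write_tsv(cov, file.path(res_dir, "gene_coverage.tsv"))
cat(sprintf("genes: %d; present in donor: %d; absent (<%.0f%% exon cov): %d\n",
            nrow(cov), sum(cov$present), 100 * study_config$gene_absent_cov,
            sum(!cov$present)))

eff <- classify_snp_effects(snp_calls, models, ref)
write_tsv(eff, file.path(res_dir, "snp_effects.tsv"))
print(table(eff$category))
cat(sprintf("harmful SNPs (nonsense or splice-site): %d\n",
            sum(eff$harmful)))

# donor transcripts: spliced exon sequences lifted from conserved genes,
# plus donor-only sequence drawn from planted insertions
truth_ind <- read_tsv(file.path(data_dir, "truth_indels.tsv"))
tx <- list()
for (tid in unique(models$transcript_id[models$feature == "exon"])[1:10]) {
  ex <- models[models$feature == "exon" & models$transcript_id == tid, ]
  ex <- ex[order(ex$start), ]
  tx[[tid]] <- paste(substring(ref[[ex$chrom[1]]], ex$start + 1, ex$end),
                     collapse = "")
}
big_ins <- truth_ind[truth_ind$type == "INS" & truth_ind$size >= 600, ]
for (i in seq_len(min(5, nrow(big_ins))))
  tx[[sprintf("donor_only_%d", i)]] <-
    substr(big_ins$seq[i], 1, min(1500, big_ins$size[i]))
cls <- transcript_uniqueness(unlist(tx), ref,
                             study_config$tx_min_id, study_config$tx_min_cov,
                             study_config$tx_unique_cov, study_config)
write_tsv(cls, file.path(res_dir, "transcript_uniqueness.tsv"))
print(table(cls$class))

dens <- presence_matrix(list(donor = cov), setNames(nchar(ref), names(ref)))
write_tsv(dens$density, file.path(res_dir, "absent_gene_density.tsv"))
cat(sprintf("absent genes per Mb: %.1f\n", dens$density$per_mb[1]))
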