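#!/usr/bin/env Rscript
# Generate the synthetic study dataset: reference with embedded gene models
# and tandem-repeat tracts, a mutated donor with planted truth, sheared
# contigs (with planted errors), paired-end reads, and BES clone pairs.
source("analysis/common.R")

ds <- simulate_dataset(study_params, n_genes = n_study_genes,
                       reads = TRUE, bes = TRUE)

write_fasta(ds$ref, file.path(data_dir, "reference.fa"))
write_fasta(ds$donor, file.path(data_dir, "donor.fa"))
write_fasta(ds$contigs, file.path(data_dir, "contigs_raw.fa"))
write_gff3(ds$models, file.path(data_dir, "genes.gff3"))
write_fastq(ds$reads$seq, ds$reads$qual, file.path(data_dir, "reads.fq"))
write_fasta(ds$bes$seq, file.path(data_dir, "bes.fa"))
write_sam(ds$reads$sam, setNames(nchar(ds$donor), names(ds$donor)),
          file.path(data_dir, "reads_truth.sam"))
write_tsv(ds$truth$snps, file.path(data_dir, "truth_snps.tsv"))
write_tsv(ds$truth$indels, file.path(data_dir, "truth_indels.tsv"))
write_tsv(ds$truth$placements, file.path(data_dir, "truth_placements.tsv"))
write_tsv(ds$truth$contig_errors,
          file.path(data_dir, "truth_contig_errors.tsv"))

cat(sprintf(
  "simulated %d bp reference, donor %d bp, %d contigs (N50 %d bp),\n",
  sum(nchar(ds$ref)), sum(nchar(ds$donor)), length(ds$contigs),
  n50(nchar(ds$contigs))))
cat(sprintf(
  "planted %d SNPs, %d large indels (%d DEL / %d INS), %d contig errors,\n",
  nrow(ds$truth$snps), sum(ds$truth$indels$large),
  sum(ds$truth$indels$large & ds$truth$indels$type == "DEL"),
  sum(ds$truth$indels$large & ds$truth$indels$type == "INS"),
  nrow(ds$truth$contig_errors)))
cat(sprintf("%d read pairs and %d BES clones written under %s\n",
            length(ds$reads$seq) / 2, nrow(ds$bes$truth), data_dir))
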