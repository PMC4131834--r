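#!/usr/bin/env Rscript
# Two-round pileup polishing of the raw contigs with the simulated reads,
# scored against the planted contig errors.
source("analysis/common.R")

contigs <- read_fasta(file.path(data_dir, "contigs_raw.fa"))
reads <- read_fastq(file.path(data_dir, "reads.fq"))
truth_err <- read_tsv(file.path(data_dir, "truth_contig_errors.tsv"))

rule <- correction_rule(
  min_qual = study_config$polish_min_qual,
  min_depth = study_config$polish_min_depth,
  min_freq = study_config$polish_min_freq,
  rounds = study_config$polish_rounds)
pol <- polish_contigs(contigs, reads = reads$seq, quals = reads$qual,
                      rule = rule)

write_fasta(pol$contigs, file.path(data_dir, "contigs_polished.fa"))
write_tsv(pol$log, file.path(res_dir, "polish_log.tsv"))

fixed <- paste(pol$log$contig_id, pol$log$pos)
planted <- paste(truth_err$contig_id, truth_err$pos)
cat(sprintf("rounds run: %d; corrections applied: %d\n", pol$rounds_run,
            nrow(pol$log)))
cat(sprintf("planted errors: %d; reverted: %d (%.1f%%)\n",
            length(planted), sum(planted %in% fixed),
            100 * mean(planted %in% fixed)))
cat(sprintf("corrections outside the planted set: %d\n",
            sum(!fixed %in% planted)))
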