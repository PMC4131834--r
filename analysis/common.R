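# Shared settings for the numbered analysis drivers. Every script can be
# run from the repository root with:  Rscript analysis/<script>.R
# Artifacts accumulate under results/.

library(pseudoref)

res_dir <- "results"
data_dir <- file.path(res_dir, "data")
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)

# Study conditions for the worked dataset: a 1.5 Mb single-chromosome
# reference diverged from its donor by 1% SNPs, small indels, and 30 large
# indels (20 deletions from the bimodal mixture, 10 insertions), sheared to
# a 30 kb contig N50 with 0.05% contig errors, sequenced at 20x with 0.1%
# read error, plus 800 BAC clones of ~100 kb.
study_params <- sim_params(
  ref_length = 1.5e6, n_chroms = 1, snp_rate = 0.01,
  small_indel_rate = 2e-4, large_del_count = 20, large_ins_count = 10,
  repeat_fraction = 0.585, contig_n50 = 3e4, contig_error_rate = 5e-4,
  read_length = 100, read_depth = 20, read_error_rate = 0.001,
  bes_count = 800, bes_insert_mean = 1e5, bes_insert_sd = 1e4,
  seed = 20260927L)

study_config <- pipeline_config()
n_study_genes <- 40
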