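#!/usr/bin/env Rscript
# Recompute the published assembly and variant summary statistics from the
# packaged per-chromosome / per-class fixture tables and compare each
# against its printed value.
source("analysis/common.R")

rep <- verify_published_stats()
write_tsv(rep, file.path(res_dir, "published_stats_verification.tsv"))
print(rep)
cat(sprintf("%d/%d recomputed statistics match the printed values\n",
            sum(rep$pass), nrow(rep)))
if (!all(rep$pass)) quit(status = 1)
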