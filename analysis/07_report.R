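#!/usr/bin/env Rscript
# Consistency report: recompute the published derived quantities from the
# printed primary counts alone (pure arithmetic, no data needed).
suppressPackageStartupMessages(library(oncoatlas))
rep <- consistency_report()
print(rep[, c("quantity", "value")], row.names = FALSE)
write.table(rep, "results/consistency.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
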