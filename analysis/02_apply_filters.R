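#!/usr/bin/env Rscript
# Apply the sample-selection chain (term, vertex, spontaneous onset, vaginal
# birth, no scar, no severe adverse outcome or malformation, >= 2 first-stage
# assessments) and write the included cohort, the flow counts and the
# parity/admission stratum sizes.

library(labourflow)

cohort <- read_cohort("results/cohort.csv")
res <- apply_inclusion(cohort)
print(res$flow_counts)
writeLines(flow_counts_json(res$flow_counts), "results/flow_counts.json")
write_cohort(res$cohort, "results/cohort_included.csv")

ws <- woman_summary(res$cohort)
sizes <- as.data.frame(table(ws$parity_group, ws$admission_dilatation))
names(sizes) <- c("parity_group", "admission_dilatation", "n")
readr::write_csv(sizes, "results/stratum_sizes.csv")
message("included ", res$flow_counts$n_included, " of ",
        res$flow_counts$n_input, " records; stratum sizes written")
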