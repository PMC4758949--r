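#!/usr/bin/env Rscript

# Arbitrate between two rival conformations of one protein: build
# inter-helical contact maps for both, select candidate
# parent-inactive-mutant positions from the differential contacts, and
# judge which conformation the planted suppressor pairs support.

suppressMessages(library(supprox))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1
out <- "results"

tp <- generate_toy_conformation_pair(seed = seed)

map_A <- contact_map(tp$A, cutoff = 7, inter_helical_only = TRUE)
map_B <- contact_map(tp$B, cutoff = 7, inter_helical_only = TRUE)
write.table(map_A, file.path(out, "contact_map_A.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(map_B, file.path(out, "contact_map_B.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("inter-helical contacts: %d in A, %d in B",
                nrow(map_A), nrow(map_B)))

report <- select_pim_candidates(map_A, map_B, tp$sequence)
write.table(report, file.path(out, "pim_candidates.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("%d differential-contact positions, %d pass all criteria: %s",
                nrow(report), sum(report$selected),
                paste(report$position[report$selected], collapse = ", ")))

support <- evaluate_suppressor_support(tp$planted, tp$A, tp$B, cutoff = 7)
write.table(support, file.path(out, "suppressor_support.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
tab <- table(support$verdict)
message("suppressor verdicts: ",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
message(sprintf("fraction supporting the generating conformation: %.2f",
                mean(support$verdict == "supports_A")))
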