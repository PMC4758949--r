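#!/usr/bin/env Rscript

# From read counts to residue-level burial calls: simulate a saturation
# mutagenesis screen whose sensitivity tracks residue depth on the packed
# globule, recover MS_seq from the read counts, aggregate to RankScores,
# and classify positions and suppressors.

suppressMessages(library(supprox))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1
out <- "results"
dir.create(out, showWarnings = FALSE)

depths <- read.table(file.path(out, "globule_depth.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)

message("simulating depth-linked mutational sensitivity, seed ", seed)
ms_truth <- generate_ms_from_depth(depths, seed = seed + 2)
reads <- simulate_reads(ms_truth, seed = seed + 3)
write.table(reads, file.path(out, "read_counts.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

ms <- ms_seq_from_reads(reads)
agree <- mean(ms$ms_seq == ms_truth$ms_seq)
message(sprintf("MS_seq recovered from noisy reads for %.1f%% of mutants",
                100 * agree))
write.table(ms, file.path(out, "ms_seq.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

ranks <- rank_scores(ms)
dep <- tapply(depths$depth, depths$resno, mean)
r <- cor(ranks$rank_score, dep[as.character(ranks$position)])
message(sprintf("RankScore vs residue depth: Pearson r = %.3f over %d positions",
                r, nrow(ranks)))

ranks$depth <- as.vector(dep[as.character(ranks$position)])
ranks$suppressor_call <- vapply(ranks$position, function(p)
  classify_suppressor(p, ranks)$call, character(1))
ranks$pattern_class <- vapply(ranks$position, function(p)
  tryCatch(classify_position(p, ms), error = function(e) NA_character_),
  character(1))
write.table(ranks, file.path(out, "rank_scores.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

tab <- table(ranks$pattern_class, useNA = "ifany")
message("pattern classes: ",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
buried <- ranks$position[!is.na(ranks$pattern_class) &
                           ranks$pattern_class == "buried"]
message(sprintf("mean depth of buried-pattern positions: %.1f A vs %.1f A overall",
                mean(dep[as.character(buried)]), mean(dep)))
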