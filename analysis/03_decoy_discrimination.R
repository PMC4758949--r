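#!/usr/bin/env Rscript

# Score the decoy set against the planted contact constraints and compare
# the three discriminators: ContactScore, rdepthscore and R_s. Writes
# per-model scores and the ContactScore recovery histogram.

suppressMessages(library(supprox))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1
out <- "results"

native <- read_pdb(file.path(out, "structures", "native.pdb"))$models[[1]]
pairs <- contact_pairs(read_table_schema(file.path(out, "planted_pairs.tsv"),
                                         "pairs"))
dec <- generate_decoys(native, n_models = 150,
                       amplitudes = c(0.5, 1, 1.5, 2, 3, 4, 6, 8),
                       seed = seed + 1)

message("scoring ", length(dec$models), " decoys with ContactScore")
sc <- score_decoys(dec$models, native, pairs)
write.table(sc, file.path(out, "decoy_scores.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

hist6 <- recovery_histogram(sc, function(s) s$contact_score == pairs$n)
write.table(hist6, file.path(out, "recovery_csc.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
low <- hist6[hist6$models_total > 0 & hist6$bin_upper <= 2, ]
message(sprintf(
  "full-constraint recovery at RMSD <= 2 A: %.0f%%; %d/%d models with CSc=%d below 4 A",
  100 * sum(low$models_selected) / sum(low$models_total),
  sum(sc$contact_score == pairs$n & sc$rmsd < 4), nrow(sc), pairs$n))

# rdepthscore and R_s on a thinned decoy subset of the packed globule
# (surface/depth profiles are the expensive step)
glob <- generate_helix_bundle(n_helices = 7, helix_len = 14,
                              layout = "packed", seed = seed)
depths <- residue_depth(glob$model, n_points = 120)
ranks <- rank_scores(generate_ms_from_depth(depths, seed = seed + 2))
ref_asa <- mean_asa_reference(list(glob$model), n_points = 120)

gdec <- generate_decoys(glob$model, n_models = 30,
                        amplitudes = c(1, 2, 4, 8), seed = seed + 3)
pool <- c(list(native = glob$model), gdec$models)
message("profiling ", length(pool), " globule models for rdepthscore and R_s")
prof <- do.call(rbind, lapply(names(pool), function(id) {
  m <- pool[[id]]
  data.frame(model = id,
             rmsd = if (id == "native") 0
                    else superpose(m, glob$model)$rmsd,
             rdepth_score = rdepth_score(ranks,
                                         residue_depth(m, n_points = 120)),
             r_s = rs_score(sasa(m, n_points = 120), ref_asa),
             stringsAsFactors = FALSE)
}))
class(prof) <- c("model_scores", "data.frame")
write.table(prof, file.path(out, "globule_decoy_scores.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

by_rs <- rank_models_by(prof, "r_s")
by_rd <- rank_models_by(prof, "rdepth_score")
message(sprintf("native rank: %d/%d by R_s, %d/%d by rdepthscore",
                by_rs$rank[by_rs$model == "native"], nrow(by_rs),
                by_rd$rank[by_rd$model == "native"], nrow(by_rd)))
message(sprintf("native rdepthscore %.2f; RMSD-R_s correlation %.2f",
                prof$rdepth_score[prof$model == "native"],
                cor(prof$rmsd, prof$r_s)))
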