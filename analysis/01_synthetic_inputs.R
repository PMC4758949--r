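#!/usr/bin/env Rscript

# Build every synthetic input the downstream analyses consume: a ring
# bundle "native" with six planted contact constraints, a decoy set of
# known RMSD around it, a packed globule with a realistic burial gradient,
# and the rival-conformation toy pair. Everything is seeded; structures go
# to results/structures/ as PDB text, truth tables as TSV.

suppressMessages(library(supprox))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1
out <- "results"
dir.create(file.path(out, "structures"), showWarnings = FALSE,
           recursive = TRUE)

message("native ring bundle (4 helices x 16 residues), seed ", seed)
bun <- generate_helix_bundle(seed = seed)
write_pdb(structure_ensemble(list(bun$model), bun$helices, id = "native"),
          file.path(out, "structures", "native.pdb"))

# six tightest well-separated side-chain contacts are the planted
# constraint set, mirroring a small suppressor screen
cen <- sidechain_centroids(bun$model)
X <- as.matrix(cen[, c("x", "y", "z")])
D <- as.matrix(dist(X))
idx <- which(upper.tri(D) & D < 6 &
               abs(outer(cen$resno, cen$resno, "-")) > 5, arr.ind = TRUE)
idx <- idx[order(D[idx]), , drop = FALSE][1:6, , drop = FALSE]
pairs <- data.frame(pos_x = cen$resno[idx[, 1]],
                    pos_y = cen$resno[idx[, 2]])
write.table(pairs, file.path(out, "planted_pairs.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message("planted ", nrow(pairs), " contact constraints")

message("decoy set: 150 models, amplitudes 0.5-8 A")
dec <- generate_decoys(bun$model, n_models = 150,
                       amplitudes = c(0.5, 1, 1.5, 2, 3, 4, 6, 8),
                       seed = seed + 1)
write.table(dec$truth, file.path(out, "decoy_truth.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("decoy RMSD span %.2f-%.2f A",
                min(dec$truth$rmsd), max(dec$truth$rmsd)))

message("packed globule (1 + 6 helices x 14 residues) for burial analyses")
glob <- generate_helix_bundle(n_helices = 7, helix_len = 14,
                              layout = "packed", seed = seed)
write_pdb(structure_ensemble(list(glob$model), glob$helices, id = "globule"),
          file.path(out, "structures", "globule.pdb"))
depths <- residue_depth(glob$model, n_points = 120)
write.table(depths, file.path(out, "globule_depth.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("globule depth span %.1f-%.1f A",
                min(depths$depth), max(depths$depth)))

message("rival conformation pair (domain-swap toy)")
tp <- generate_toy_conformation_pair(seed = seed)
write_pdb(tp$A, file.path(out, "structures", "conformer_A.pdb"))
write_pdb(tp$B, file.path(out, "structures", "conformer_B.pdb"))
write.table(tp$planted, file.path(out, "toy_planted_pairs.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message(nrow(tp$planted), " differential pairs planted (close in A, far in B)")
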