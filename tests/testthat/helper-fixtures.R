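# Shared fixtures and independent oracles, all built in code.

# Minimal atom-table builder: each row of `spec` is
# list(resno, aa, elety, x, y, z); chain defaults to "A".
toy_atoms <- function(spec, chain = "A") {
  do.call(rbind, lapply(spec, function(s) {
    data.frame(chain = if (!is.null(s$chain)) s$chain else chain,
               resno = s$resno, insert = "",
               aa = s$aa,
               resid = {
                 r3 <- unname(supprox:::AA_123[s$aa])
                 if (is.na(r3)) "UNK" else r3
               },
               elety = s$elety,
               elesy = if (!is.null(s$elesy)) s$elesy
                       else substr(gsub("[0-9]", "", s$elety), 1, 1),
               x = s$x, y = s$y, z = s$z, o = 1,
               stringsAsFactors = FALSE)
  }))
}

toy_model <- function(spec, chain = "A") {
  structure_model(toy_atoms(spec, chain))
}

# one residue with backbone + arbitrary side-chain atoms at given coords
toy_residue_model <- function(resno, aa, side_xyz,
                              ca = c(0, 0, 0), chain = "A") {
  spec <- list(list(resno = resno, aa = aa, elety = "N",
                    x = ca[1] - 1.4, y = ca[2], z = ca[3]),
               list(resno = resno, aa = aa, elety = "CA",
                    x = ca[1], y = ca[2], z = ca[3]),
               list(resno = resno, aa = aa, elety = "C",
                    x = ca[1] + 1.5, y = ca[2], z = ca[3]),
               list(resno = resno, aa = aa, elety = "O",
                    x = ca[1] + 1.5, y = ca[2] + 1.2, z = ca[3]))
  if (!is.null(side_xyz))
    for (i in seq_len(nrow(side_xyz)))
      spec <- c(spec, list(list(resno = resno, aa = aa,
                                elety = paste0("CB", if (i > 1) i else ""),
                                x = side_xyz[i, 1], y = side_xyz[i, 2],
                                z = side_xyz[i, 3])))
  lapply(spec, function(s) { s$chain <- chain; s })
}

# Brute-force RankScore oracle: explicit cumulative-percentage enumeration,
# independent of the implementation's stratum arithmetic.
rank_scores_oracle <- function(ms) {
  obs <- ms[ms$ms_seq >= 2, , drop = FALSE]
  if (!is.null(obs$wt_aa)) obs <- obs[obs$wt_aa != obs$mut_aa, , drop = FALSE]
  n <- nrow(obs)
  ranks <- numeric(n)
  for (i in seq_len(n)) {
    below <- 0
    for (j in seq_len(n)) if (obs$ms_seq[j] < obs$ms_seq[i]) below <- below + 1
    ranks[i] <- 100 * below / n + 1
  }
  out <- data.frame(position = sort(unique(obs$position)))
  out$rank_score <- vapply(out$position, function(p)
    mean(ranks[obs$position == p]), numeric(1))
  out
}

random_ms_table <- function(n_mutants, n_positions, seed) {
  set.seed(seed)
  data.frame(position = sample(seq_len(n_positions), n_mutants,
                               replace = TRUE),
             wt_aa = "L",
             mut_aa = sample(setdiff(unname(supprox:::AA_321), "L"),
                             n_mutants, replace = TRUE),
             ms_seq = sample(c(0, 2:9), n_mutants, replace = TRUE,
                             prob = c(0.1, rep(0.9 / 8, 8))),
             stringsAsFactors = FALSE)
}

# Paths where reference PDB structures may be deposited by a user with
# network access; the geometry assertions against published structures run
# only when the files are present.
ref_pdb_path <- function(id) {
  file.path(system.file("extdata", "pdb", package = "supprox"),
            paste0(tolower(id), ".pdb"))
}

# The six experimentally determined (parent-inactive-mutant, proximal
# suppressor) pairs for CcdB.
ccdb_pairs <- function() {
  contact_pairs(data.frame(
    pos_x = c(5, 5, 18, 18, 36, 83),
    pos_y = c(36, 81, 63, 90, 63, 54)))
}
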