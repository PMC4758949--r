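# Seeded synthetic-data generators: idealized helix-bundle natives, decoy
# model sets with known RMSD, read-count tables encoding known MS_seq
# values, depth-linked mutational sensitivity, rival-conformation toys with
# planted differential contacts, and melt curves with known Tm. Every
# generator is a pure function of its arguments and seed, and returns its
# ground truth alongside the data.

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

HYDROPHOBIC_AA <- c("V", "L", "I", "M", "F", "A")
SURFACE_AA <- c("S", "T", "N", "Q", "D", "E", "K", "R", "G", "H", "Y", "W",
                "P", "C")

#' Generate an idealized antiparallel helix-bundle model
#'
#' A single-chain bundle of `n_helices` ideal alpha-helices (2.3 Angstrom
#' helix radius, 1.5 Angstrom rise, 100 degrees per residue), alternating
#' up/down. Each residue carries backbone N, CA, C, O and a two-atom
#' pseudo side chain (CB, CG) pointing radially away from its helix axis,
#' so inward-facing residues pack the bundle interior. Two layouts:
#' \describe{
#'   \item{ring}{helices on a circle (adjacent axis distance `spacing`);
#'     permuting `slots` rearranges the packing interfaces, which is how
#'     rival conformations are built.}
#'   \item{packed}{one central helix surrounded by a ring at axis distance
#'     `spacing`; the tight core gives a realistic burial gradient
#'     (residue depths of roughly 3-8 Angstrom) for depth-linked
#'     analyses.}
#' }
#' Residue identities are assigned by burial (inward faces hydrophobic,
#' outward polar), with all 20 types guaranteed present so reference-ASA
#' tables can be built from the model. Coarse-grained on purpose: contact,
#' accessibility and depth operations see realistic burial structure
#' without a folding engine.
#'
#' @param n_helices number of helices (>= 2; for "packed", 1 + ring size).
#' @param helix_len residues per helix.
#' @param layout "ring" or "packed".
#' @param spacing axis-to-axis distance in Angstrom between adjacent
#'   helices (default 10 for ring, 7.6 for packed; the packed default is
#'   tight because the two-atom side chains fill less space than real
#'   ones).
#' @param slots permutation of 1..n_helices assigning each helix (in
#'   sequence order) to a layout position; swapping entries creates rival
#'   packing arrangements.
#' @param seed RNG seed (residue identity assignment).
#' @return list with `model` (`structure_model`), `helices` (data.frame),
#'   `sequence` (one-letter vector indexed by position).
#' @export
generate_helix_bundle <- function(n_helices = 4, helix_len = 16,
                                  layout = c("ring", "packed"),
                                  spacing = NULL,
                                  slots = seq_len(n_helices), seed = 1) {
  layout <- match.arg(layout)
  stopifnot(n_helices >= 2, length(slots) == n_helices,
            setequal(slots, seq_len(n_helices)))
  if (is.null(spacing)) spacing <- if (layout == "ring") 10 else 7.6
  centers <- if (layout == "ring") {
    R <- spacing / (2 * sin(pi / n_helices))
    t(vapply(seq_len(n_helices) - 1, function(k)
      R * c(cos(2 * pi * k / n_helices), sin(2 * pi * k / n_helices)),
      numeric(2)))
  } else {
    rbind(c(0, 0), t(vapply(seq_len(n_helices - 1) - 1, function(k)
      spacing * c(cos(2 * pi * k / (n_helices - 1)),
                  sin(2 * pi * k / (n_helices - 1))), numeric(2))))
  }
  with_seed(seed, {
    rows <- list()
    nres <- n_helices * helix_len
    seq_aa <- character(nres)
    helices <- data.frame(chain = character(), start = integer(),
                          end = integer())
    for (h in seq_len(n_helices)) {
      center <- centers[slots[h], ]
      central <- layout == "packed" && slots[h] == 1
      updown <- if (h %% 2 == 1) 1 else -1
      for (k in seq_len(helix_len)) {
        resno <- (h - 1) * helix_len + k
        phi <- (k - 1) * 100 * pi / 180 + h  # phase offset per helix
        z <- updown * ((k - 1) * 1.5 - (helix_len - 1) * 0.75)
        ca <- c(center + 2.3 * c(cos(phi), sin(phi)), z)
        axis_pt <- c(center, z)
        out_dir <- (ca - axis_pt) / sqrt(sum((ca - axis_pt)^2))
        cb <- ca + 1.5 * out_dir
        cg <- cb + 1.5 * out_dir
        n_at <- ca + c(0, 0, updown * -0.75) + 0.8 * c(-sin(phi), cos(phi), 0)
        c_at <- ca + c(0, 0, updown * 0.75) + 0.6 * c(-sin(phi), cos(phi), 0)
        o_at <- c_at + 0.4 * out_dir + c(0, 0, updown * 0.9)
        # burial: does the side chain point toward the bundle centre?
        inward <- central ||
          sum(out_dir[1:2] * (-center)) / max(sqrt(sum(center^2)), 1e-9) > 0.3
        aa <- if (inward) sample(HYDROPHOBIC_AA, 1) else sample(SURFACE_AA, 1)
        seq_aa[resno] <- aa
        at <- data.frame(
          elety = c("N", "CA", "C", "O", "CB", "CG"),
          elesy = c("N", "C", "C", "O", "C", "C"),
          x = c(n_at[1], ca[1], c_at[1], o_at[1], cb[1], cg[1]),
          y = c(n_at[2], ca[2], c_at[2], o_at[2], cb[2], cg[2]),
          z = c(n_at[3], ca[3], c_at[3], o_at[3], cb[3], cg[3]),
          stringsAsFactors = FALSE)
        at$chain <- "A"; at$resno <- resno; at$insert <- ""
        at$aa <- aa; at$resid <- AA_123[aa]; at$o <- 1
        rows[[length(rows) + 1]] <- at
      }
      helices <- rbind(helices, data.frame(
        chain = "A", start = (h - 1) * helix_len + 1, end = h * helix_len,
        stringsAsFactors = FALSE))
    }
    atoms <- do.call(rbind, rows)
    # guarantee all 20 residue types occur (reference-ASA tables need them)
    missing <- setdiff(names(MAX_ASA), unique(seq_aa))
    for (aa_add in missing) {
      counts <- table(seq_aa)
      cand_pos <- which(seq_aa %in% SURFACE_AA &
                          counts[seq_aa] > 1)
      if (length(cand_pos) == 0) break
      seq_aa[cand_pos[sample.int(length(cand_pos), 1)]] <- aa_add
    }
    atoms$aa <- seq_aa[atoms$resno]
    atoms$resid <- unname(AA_123[atoms$aa])
    # glycine has no side-chain heavy atoms; alanine stops at CB
    atoms <- atoms[!(atoms$aa == "G" & atoms$elety %in% c("CB", "CG")) &
                     !(atoms$aa == "A" & atoms$elety == "CG"), , drop = FALSE]
    atoms <- atoms[, c("chain", "resno", "insert", "aa", "resid", "elety",
                       "elesy", "x", "y", "z", "o")]
    list(model = structure_model(atoms), helices = helices,
         sequence = seq_aa)
  })
}

#' Generate a decoy model set around a native structure
#'
#' Each decoy is the native plus spatially correlated Gaussian displacement:
#' per-residue iid normal 3-vectors smoothed with a moving-average window of
#' `correlation_length` residues, rescaled so the root-mean-square
#' displacement equals the model's amplitude (amplitudes recycled over
#' `n_models`), applied rigidly to all atoms of a residue. Backbone RMSD to
#' the native is computed by Kabsch superposition and returned as truth.
#'
#' @param native `structure_model`.
#' @param n_models number of decoys.
#' @param amplitudes displacement amplitudes in Angstrom (recycled).
#' @param correlation_length smoothing window in residues.
#' @param seed RNG seed.
#' @return list with `models` (named list of `structure_model`) and `truth`
#'   (data.frame model, amplitude, rmsd).
#' @export
generate_decoys <- function(native, n_models = 100,
                            amplitudes = c(0.5, 1, 2, 4, 8),
                            correlation_length = 5, seed = 1) {
  stopifnot(all(amplitudes > 0), n_models >= 1)
  keys <- unique(residue_keys(native))
  if (length(keys) < 20) stop("native structure needs at least 20 residues")
  amp <- rep_len(amplitudes, n_models)
  with_seed(seed, {
    models <- vector("list", n_models)
    rmsd <- numeric(n_models)
    key_all <- residue_keys(native)
    for (m in seq_len(n_models)) {
      raw <- matrix(rnorm(length(keys) * 3), ncol = 3)
      w <- max(1, correlation_length)
      sm <- apply(raw, 2, function(v)
        as.vector(stats::filter(v, rep(1 / w, w), sides = 2,
                                circular = TRUE)))
      sm <- sm * amp[m] / sqrt(mean(rowSums(sm^2)))
      disp <- sm[match(key_all, keys), , drop = FALSE]
      dm <- native
      dm$atoms$x <- dm$atoms$x + disp[, 1]
      dm$atoms$y <- dm$atoms$y + disp[, 2]
      dm$atoms$z <- dm$atoms$z + disp[, 3]
      dm$model_index <- m
      models[[m]] <- dm
      rmsd[m] <- superpose(dm, native, "backbone")$rmsd
    }
    names(models) <- sprintf("decoy_%04d", seq_len(n_models))
    list(models = models,
         truth = data.frame(model = names(models), amplitude = amp,
                            rmsd = rmsd, stringsAsFactors = FALSE))
  })
}

#' Generate a pair of rival bundle conformations with planted differential
#' contacts
#'
#' Conformation A is an idealized helix bundle; conformation B is the same
#' chain rebuilt with two helices exchanged between packing interfaces
#' (slots 3 and `n_helices` swapped, so a given helix face contacts a
#' sequence-distant partner region in A and a different one in B),
#' emulating a domain-swap style rearrangement. The planted truth lists residue pairs from different
#' helices whose side-chain centroids are within 6.5 Angstrom in A but
#' beyond 8 Angstrom in B, so every planted pair is a contact in A and a
#' non-contact in B at the conventional 7 Angstrom cutoff.
#'
#' @param n_helices number of helices (>= 3 for a meaningful swap).
#' @param helix_len residues per helix.
#' @param swap if FALSE, B is identical to A and no pairs are planted.
#' @param seed RNG seed.
#' @return list with `A`, `B` (`structure_ensemble`), `sequence`, and
#'   `planted` (data.frame pim_pos, sup_pos, dist_A, dist_B).
#' @export
generate_toy_conformation_pair <- function(n_helices = 4, helix_len = 16,
                                           swap = TRUE, seed = 1) {
  stopifnot(n_helices >= 2)
  bunA <- generate_helix_bundle(n_helices, helix_len, seed = seed)
  slotsB <- seq_len(n_helices)
  if (swap) {
    sw <- if (n_helices >= 4) c(3, n_helices) else c(2, n_helices)
    slotsB[sw] <- slotsB[rev(sw)]
  }
  bunB <- generate_helix_bundle(n_helices, helix_len, slots = slotsB,
                                seed = seed)
  A <- structure_ensemble(list(bunA$model), bunA$helices, id = "toy_A")
  B <- structure_ensemble(list(bunB$model), bunB$helices, id = "toy_B")
  planted <- data.frame(pim_pos = integer(), sup_pos = integer(),
                        dist_A = numeric(), dist_B = numeric())
  if (swap) {
    cenA <- sidechain_centroids(bunA$model)
    cenB <- sidechain_centroids(bunB$model)
    XA <- atom_xyz(cenA); XB <- atom_xyz(cenB)
    dA <- as.matrix(dist(XA)); dB <- as.matrix(dist(XB))
    helix_of <- (cenA$resno - 1) %/% helix_len + 1
    cand <- which(upper.tri(dA) & dA <= 6.5 & dB > 8 &
                    outer(helix_of, helix_of, "!="), arr.ind = TRUE)
    if (nrow(cand) > 0)
      planted <- data.frame(pim_pos = cenA$resno[cand[, 1]],
                            sup_pos = cenA$resno[cand[, 2]],
                            dist_A = dA[cand], dist_B = dB[cand])
  }
  list(A = A, B = B, sequence = bunA$sequence, planted = planted)
}

#' Simulate MID read counts encoding known MS_seq values
#'
#' Counts are flat at `depth_of_coverage` across MIDs below the planted
#' MS_seq and drop tenfold from that MID on (safely past the fivefold
#' rule); MS_seq 0 rows are all-zero; MS_seq 9 rows stay flat (never
#' active). An optional negative-binomial overdispersion emulates
#' sequencing sampling noise. The emitted table includes the pre-selection
#' mid_1 baseline so MS_seq = 2 is recoverable.
#'
#' @param ms_truth `mutsens_table` (position, wt_aa, mut_aa, ms_seq).
#' @param depth_of_coverage baseline read count per mutant per MID.
#' @param noise negative-binomial overdispersion (variance =
#'   mu + noise * mu^2); 0 gives exact counts.
#' @param seed RNG seed.
#' @return data.frame in read_counts schema (mid_1..mid_9).
#' @export
simulate_reads <- function(ms_truth, depth_of_coverage = 1000, noise = 0.05,
                           seed = 1) {
  stopifnot(all(ms_truth$ms_seq %in% c(0, 2:9)))
  levels <- 1:9
  with_seed(seed, {
    mu <- t(vapply(ms_truth$ms_seq, function(ms) {
      if (ms == 0) rep(0, length(levels))
      else if (ms == 9) rep(depth_of_coverage, length(levels))
      else ifelse(levels < ms, depth_of_coverage, depth_of_coverage / 10)
    }, numeric(length(levels))))
    cnt <- if (noise > 0) {
      obs <- matrix(rnbinom(length(mu), mu = mu, size = 1 / noise),
                    nrow = nrow(mu))
      obs[mu == 0] <- 0
      obs
    } else mu
    out <- data.frame(position = ms_truth$position, wt_aa = ms_truth$wt_aa,
                      mut_aa = ms_truth$mut_aa, stringsAsFactors = FALSE)
    for (i in seq_along(levels)) out[[paste0("mid_", levels[i])]] <- cnt[, i]
    out
  })
}

#' Generate depth-linked mutational sensitivity values
#'
#' Emulates the burial-sensitivity relationship: at each position the
#' probability that a polar/charged substitution is poorly tolerated grows
#' linearly with residue depth (p = intercept + slope * depth, clamped to
#' \[0, 1\]), aliphatic substitutions stay tolerated, aromatic substitutions
#' sit in between. At `noise_sd = 0` the per-substitution MS_seq is a
#' deterministic function of depth, making the RankScore-depth relation
#' exact up to class composition.
#'
#' @param depths data.frame from [residue_depth()] (resno, aa, depth).
#' @param slope,intercept linear map from depth (Angstrom) to the
#'   sensitivity probability of a full-weight substitution; the defaults
#'   make polar/charged substitutions lethal (MS_seq >= 8) at core depths
#'   (>= 6 Angstrom) and tolerated at surface depths (~3 Angstrom).
#' @param noise_sd Gaussian jitter on the sensitivity probability per
#'   substitution.
#' @param mutants_per_position substitutions drawn per position (<= 19).
#' @param class_weights multiplier on the sensitivity probability per
#'   substitution class; the default encodes the burial motif (aliphatic
#'   substitutions tolerated in cores, polar/charged not). Setting all
#'   weights to 1 gives a pure linear depth-sensitivity map.
#' @param seed RNG seed.
#' @return `mutsens_table` with position, wt_aa, mut_aa, ms_seq.
#' @export
generate_ms_from_depth <- function(depths, slope = 0.25, intercept = -0.65,
                                   noise_sd = 0.1,
                                   mutants_per_position = 15,
                                   class_weights = c(aliphatic = 0.05,
                                                     aromatic = 0.5,
                                                     polar = 1, charged = 1,
                                                     gly_pro = 1),
                                   seed = 1) {
  stopifnot(nrow(depths) > 0, mutants_per_position <= 19)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(depths)), function(i) {
      pos <- depths$resno[i]; wt <- depths$aa[i]
      p0 <- min(max(intercept + slope * depths$depth[i], 0), 1)
      muts <- sample(setdiff(names(MAX_ASA), wt), mutants_per_position)
      ms <- vapply(muts, function(m) {
        cls <- names(AA_GROUPS)[vapply(AA_GROUPS, function(g) m %in% g,
                                       logical(1))][1]
        p <- p0 * class_weights[[cls]]
        if (noise_sd > 0) p <- p + rnorm(1, 0, noise_sd)
        p <- min(max(p, 0), 1)
        as.integer(2 + round(7 * p))
      }, integer(1))
      data.frame(position = pos, wt_aa = wt, mut_aa = muts, ms_seq = ms,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("mutsens_table", "data.frame")
    out
  })
}

#' Simulate a thermal melt curve
#'
#' @param LL,UL,a,Tm four-parameter sigmoid parameters (see
#'   [melt_sigmoid()]).
#' @param T_grid ascending temperatures (degrees C).
#' @param noise_sd Gaussian noise sd in signal units.
#' @param seed RNG seed.
#' @return data.frame with temperature_C, signal.
#' @export
simulate_melt <- function(LL = 0, UL = 1, a = 2, Tm = 55,
                          T_grid = seq(20, 90, by = 0.5), noise_sd = 0,
                          seed = 1) {
  stopifnot(all(diff(T_grid) > 0))
  with_seed(seed, {
    y <- melt_sigmoid(T_grid, LL, UL, a, Tm)
    if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
    data.frame(temperature_C = T_grid, signal = y)
  })
}
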