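# Differential contacts between two rival structures of one protein:
# contact maps, selection of candidate parent-inactive-mutant (PIM)
# positions, and arbitration of which structure a set of experimental
# suppressor pairs supports.

helix_segment_of <- function(helices, chain, resno) {
  hit <- which(helices$chain == chain & helices$start <= resno &
                 helices$end >= resno)
  if (length(hit) == 0) NA_integer_ else hit[1]
}

sidechain_no_atoms <- function(model) {
  a <- model$atoms
  a[is_heavy(a) & !(a$elety %in% BACKBONE_ATOMS) & a$elesy %in% c("N", "O"), ,
    drop = FALSE]
}

pair_hbond <- function(model, pos_x, pos_y, dmax = 3.5) {
  no <- sidechain_no_atoms(model)
  ax <- no[no$resno == pos_x, , drop = FALSE]
  ay <- no[no$resno == pos_y, , drop = FALSE]
  if (nrow(ax) == 0 || nrow(ay) == 0) return(FALSE)
  min_pairing_dist(atom_xyz(ax), atom_xyz(ay)) <= dmax
}

#' Residue-residue contact map from side-chain centroid distances
#'
#' All position pairs whose minimum side-chain centroid distance over chain
#' pairings is at or below the cutoff. With `inter_helical_only`, both
#' residues must lie in helix segments (from the ensemble's helix
#' definitions) and pairs within one helix instance are removed. Pairs
#' touching `exclude_range` (e.g. a mobile N-terminal region) are dropped.
#' Each retained pair is annotated with a side-chain hydrogen-bond flag
#' (side-chain N/O donor-acceptor heavy-atom distance <= 3.5 Angstrom).
#'
#' @param ensemble `structure_ensemble` (or a single `structure_model`).
#' @param cutoff contact cutoff in Angstrom (default 7, inclusive).
#' @param pose model index to use, or "min" for the closest distance over
#'   all poses.
#' @param inter_helical_only keep only inter-helical pairs.
#' @param exclude_range integer vector of positions to exclude (any pair
#'   touching one is dropped), or NULL.
#' @return data.frame (class `contact_map`) with pos_x < pos_y, dist,
#'   chain_x, chain_y (chains realising the minimum), hbond.
#' @export
contact_map <- function(ensemble, cutoff = 7, pose = 1,
                        inter_helical_only = FALSE, exclude_range = NULL) {
  if (inherits(ensemble, "structure_model"))
    ensemble <- structure_ensemble(list(ensemble))
  nmod <- length(ensemble$models)
  poses <- if (identical(pose, "min")) seq_len(nmod) else as.integer(pose)
  if (any(poses < 1 | poses > nmod)) stop("pose out of range (1..", nmod, ")")
  helices <- ensemble$helices
  if (inter_helical_only && nrow(helices) == 0)
    stop("inter_helical_only requires helix definitions in the ensemble")

  entries <- list()
  for (p in poses) {
    cen <- sidechain_centroids(ensemble$models[[p]])
    X <- atom_xyz(cen)
    d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * X %*% t(X)
    idx <- which(upper.tri(d2) & d2 <= cutoff^2 + 1e-9, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    e <- data.frame(pos_i = cen$resno[idx[, 1]], pos_j = cen$resno[idx[, 2]],
                    chain_i = cen$chain[idx[, 1]], chain_j = cen$chain[idx[, 2]],
                    dist = sqrt(pmax(d2[idx], 0)), pose = p,
                    stringsAsFactors = FALSE)
    entries[[length(entries) + 1]] <- e
  }
  e <- do.call(rbind, entries)
  empty <- data.frame(pos_x = integer(), pos_y = integer(), dist = numeric(),
                      chain_x = character(), chain_y = character(),
                      hbond = logical())
  if (is.null(e) || nrow(e) == 0) {
    class(empty) <- c("contact_map", "data.frame")
    attr(empty, "cutoff") <- cutoff
    return(empty)
  }
  e <- e[e$pos_i != e$pos_j, , drop = FALSE]
  if (!is.null(exclude_range))
    e <- e[!(e$pos_i %in% exclude_range | e$pos_j %in% exclude_range), ,
           drop = FALSE]
  if (inter_helical_only && nrow(e) > 0) {
    hi <- mapply(helix_segment_of, e$chain_i, e$pos_i,
                 MoreArgs = list(helices = helices))
    hj <- mapply(helix_segment_of, e$chain_j, e$pos_j,
                 MoreArgs = list(helices = helices))
    e <- e[!is.na(hi) & !is.na(hj) & hi != hj, , drop = FALSE]
  }
  if (nrow(e) == 0) {
    class(empty) <- c("contact_map", "data.frame")
    attr(empty, "cutoff") <- cutoff
    return(empty)
  }
  px <- pmin(e$pos_i, e$pos_j); py <- pmax(e$pos_i, e$pos_j)
  key <- paste(px, py)
  best <- tapply(seq_len(nrow(e)), key, function(ii) ii[which.min(e$dist[ii])])
  b <- e[unname(best), , drop = FALSE]
  out <- data.frame(pos_x = pmin(b$pos_i, b$pos_j),
                    pos_y = pmax(b$pos_i, b$pos_j),
                    dist = b$dist, chain_x = b$chain_i, chain_y = b$chain_j,
                    stringsAsFactors = FALSE)
  out <- out[order(out$pos_x, out$pos_y), , drop = FALSE]
  hb_model <- ensemble$models[[poses[1]]]
  out$hbond <- vapply(seq_len(nrow(out)), function(i)
    pair_hbond(hb_model, out$pos_x[i], out$pos_y[i]), logical(1))
  rownames(out) <- NULL
  class(out) <- c("contact_map", "data.frame")
  attr(out, "cutoff") <- cutoff
  out
}

map_partners <- function(map, position) {
  sort(unique(c(map$pos_y[map$pos_x == position],
                map$pos_x[map$pos_y == position])))
}

#' Select candidate parent-inactive-mutant positions from two contact maps
#'
#' Candidates are positions contacting in both structures but with
#' differing partner sets, filtered in order:
#' (i) charged positions (D, E, K, R) removed; (ii) positions whose side
#' chain hydrogen-bonds a contact partner removed; (iii) at least
#' `min_partners` partners in one structure; (iv) partners restricted to
#' sequence separation |X - Y| > `min_sep` (applied per structure);
#' (v) partner sets positionally divergent: the minimum over partner
#' combinations of |y_B - y_A| must exceed `min_partner_shift`.
#'
#' @param map_A,map_B `contact_map` objects over the same sequence.
#' @param sequence one-letter amino-acid vector indexed by position.
#' @param min_partners criterion (iii) threshold (default 2).
#' @param min_sep criterion (iv) threshold (default 30).
#' @param min_partner_shift criterion (v) threshold (default 6).
#' @return data.frame (class `diffcontact_report`): one row per candidate
#'   with partner sets (comma-separated), criteria flags and `selected`.
#' @export
select_pim_candidates <- function(map_A, map_B, sequence, min_partners = 2,
                                  min_sep = 30, min_partner_shift = 6) {
  maxpos <- suppressWarnings(max(c(map_A$pos_x, map_A$pos_y,
                                   map_B$pos_x, map_B$pos_y, 0)))
  if (maxpos > length(sequence))
    stop("sequence length mismatch: maps reference position ", maxpos,
         " but sequence has ", length(sequence), " residues")
  pos_A <- unique(c(map_A$pos_x, map_A$pos_y))
  pos_B <- unique(c(map_B$pos_x, map_B$pos_y))
  cand <- sort(intersect(pos_A, pos_B))
  cand <- cand[vapply(cand, function(p)
    !setequal(map_partners(map_A, p), map_partners(map_B, p)), logical(1))]
  rows <- lapply(cand, function(p) {
    pa <- map_partners(map_A, p); pb <- map_partners(map_B, p)
    charged_removed <- !(sequence[p] %in% AA_GROUPS$charged)
    hb <- c(map_A$hbond[map_A$pos_x == p | map_A$pos_y == p],
            map_B$hbond[map_B$pos_x == p | map_B$pos_y == p])
    hbond_excluded <- !any(hb)
    min_partner_count <- length(pa) >= min_partners ||
      length(pb) >= min_partners
    pa_sep <- pa[abs(pa - p) > min_sep]
    pb_sep <- pb[abs(pb - p) > min_sep]
    seq_separation <- length(pa_sep) > 0 && length(pb_sep) > 0
    partner_divergence <- seq_separation &&
      min(abs(outer(pb_sep, pa_sep, "-"))) > min_partner_shift
    data.frame(position = p, aa = sequence[p],
               partners_A = paste(pa_sep, collapse = ","),
               partners_B = paste(pb_sep, collapse = ","),
               charged_removed = charged_removed,
               hbond_excluded = hbond_excluded,
               min_partner_count = min_partner_count,
               seq_separation = seq_separation,
               partner_divergence = partner_divergence,
               selected = charged_removed && hbond_excluded &&
                 min_partner_count && seq_separation && partner_divergence,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0) do.call(rbind, rows)
  else data.frame(position = integer(), aa = character(),
                  partners_A = character(), partners_B = character(),
                  charged_removed = logical(), hbond_excluded = logical(),
                  min_partner_count = logical(), seq_separation = logical(),
                  partner_divergence = logical(), selected = logical())
  rownames(out) <- NULL
  class(out) <- c("diffcontact_report", "data.frame")
  out
}

min_centroid_distance <- function(ensemble, pos_x, pos_y, pose = 1) {
  if (inherits(ensemble, "structure_model"))
    ensemble <- structure_ensemble(list(ensemble))
  poses <- if (identical(pose, "min")) seq_along(ensemble$models)
  else as.integer(pose)
  min(vapply(poses, function(p)
    centroid_distance(ensemble$models[[p]], pos_x, pos_y), numeric(1)))
}

#' Judge which of two structures a set of suppressor pairs supports
#'
#' For each (parent-inactive-mutant, suppressor) position pair, the minimum
#' side-chain centroid distance over chain pairings is compared with the
#' cutoff in each structure. A pair close only in A supports A, close only
#' in B supports B, close in both "both", close in neither "neither".
#'
#' @param pairs data.frame with pim_pos, sup_pos.
#' @param struct_A,struct_B `structure_ensemble` objects (A conventionally
#'   the X-ray structure, B the rival, e.g. NMR, structure).
#' @param cutoff contact cutoff in Angstrom (default 7, inclusive).
#' @param pose pose selection for each ensemble (index or "min").
#' @return data.frame (class `suppressor_support`) with pim_pos, sup_pos,
#'   dist_A, dist_B, verdict; per-pair failures get verdict "error".
#' @export
evaluate_suppressor_support <- function(pairs, struct_A, struct_B,
                                        cutoff = 7, pose = 1) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs$pim_pos[i]; s <- pairs$sup_pos[i]
    tryCatch({
      da <- min_centroid_distance(struct_A, p, s, pose)
      db <- min_centroid_distance(struct_B, p, s, pose)
      verdict <- if (da <= cutoff && db <= cutoff) "both"
      else if (da <= cutoff) "supports_A"
      else if (db <= cutoff) "supports_B"
      else "neither"
      data.frame(pim_pos = p, sup_pos = s, dist_A = da, dist_B = db,
                 verdict = verdict, stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(pim_pos = p, sup_pos = s, dist_A = NA_real_,
                 dist_B = NA_real_, verdict = "error",
                 stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("suppressor_support", "data.frame")
  out
}

#' @export
print.suppressor_support <- function(x, ...) {
  cat("suppressor support verdicts:\n")
  print(as.data.frame(x))
  tab <- table(x$verdict)
  cat("summary:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}
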