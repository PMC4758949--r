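# Decoy model discrimination: ContactScore against experimentally derived
# residue pairs, rdepthscore (RankScore vs model depth correlation), the
# R_s packing-deviation statistic, recovery histograms and model ranking.

#' Construct a contact-pair constraint set
#'
#' @param pairs data.frame with pos_x, pos_y (author residue numbers) and
#'   optional chain_x, chain_y columns.
#' @param cutoff centroid-centroid contact cutoff in Angstrom (default 7;
#'   applied strictly, distance < cutoff).
#' @return object of class `contact_pairs`.
#' @export
contact_pairs <- function(pairs, cutoff = 7) {
  stopifnot(all(c("pos_x", "pos_y") %in% names(pairs)))
  if (nrow(pairs) < 1) stop("need at least one contact pair")
  if (any(pairs$pos_x == pairs$pos_y))
    stop("a contact pair cannot join a position to itself")
  structure(list(pairs = as.data.frame(pairs), n = nrow(pairs),
                 cutoff = cutoff),
            class = "contact_pairs")
}

#' @export
print.contact_pairs <- function(x, ...) {
  cat(sprintf("contact_pairs: %d pair(s), cutoff %g A\n", x$n, x$cutoff))
  invisible(x)
}

#' ContactScore of a model
#'
#' The number of constraint pairs whose side-chain centroids lie within the
#' cutoff (strictly < cutoff) in the model, an integer in 0..n. Distances
#' use the homo-oligomer convention (minimum over chain pairings) unless
#' the pair carries explicit chains.
#'
#' @param model `structure_model`.
#' @param pairs `contact_pairs`.
#' @return integer ContactScore.
#' @export
contact_score <- function(model, pairs) {
  stopifnot(inherits(pairs, "contact_pairs"))
  p <- pairs$pairs
  d <- vapply(seq_len(nrow(p)), function(i) {
    centroid_distance(model, p$pos_x[i], p$pos_y[i],
                      chain_x = p$chain_x[i], chain_y = p$chain_y[i])
  }, numeric(1))
  sum(d < pairs$cutoff)
}

#' rdepthscore: correlation of RankScore with model-derived residue depth
#'
#' Computed over positions present in both tables after removing an
#' exclusion set (typically active-site positions, where sensitivity tracks
#' function rather than burial). Higher in native-like models.
#'
#' @param ranks `rankscore_table`.
#' @param depths data.frame from [residue_depth()] (multi-chain depth
#'   profiles are averaged per position).
#' @param exclude positions to drop before correlating.
#' @param method "pearson" (default) or "spearman".
#' @return correlation coefficient.
#' @export
rdepth_score <- function(ranks, depths, exclude = integer(0),
                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  dep <- tapply(depths$depth, depths$resno, mean)
  pos <- intersect(ranks$position, as.integer(names(dep)))
  pos <- setdiff(pos, exclude)
  if (length(pos) < 3)
    stop("need at least 3 shared positions after exclusions")
  x <- ranks$rank_score[match(pos, ranks$position)]
  y <- dep[as.character(pos)]
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined rdepthscore: zero variance in RankScore or depth")
  unname(cor(x, y, method = method))
}

#' Mean per-residue-type ASA reference table from a set of structures
#'
#' Averages absolute per-residue accessible surface area by residue type
#' over the supplied models, for use as the reference in [rs_score()]. All
#' 20 types must be observed.
#'
#' @param models list of `structure_model` objects.
#' @param probe,n_points passed to [sasa()].
#' @return named numeric vector (one-letter residue type -> mean ASA).
#' @export
mean_asa_reference <- function(models, probe = 1.4, n_points = 240) {
  profs <- lapply(models, sasa, probe = probe, n_points = n_points)
  all <- do.call(rbind, lapply(profs, function(p) p[, c("aa", "asa")]))
  all <- all[all$aa != "X", , drop = FALSE]
  ref <- tapply(all$asa, all$aa, mean)
  missing <- setdiff(names(MAX_ASA), names(ref))
  if (length(missing) > 0)
    stop("residue type(s) absent from reference structures: ",
         paste(missing, collapse = ", "))
  ref[names(MAX_ASA)]
}

#' R_s packing-deviation score
#'
#' Summed relative deviation of per-residue accessible surface area from
#' reference mean values over the whole chain:
#' sum_i |ASA_i - <ASA_type(i)>| / <ASA_type(i)>. Lower values indicate
#' packing closer to the reference average; the native structure should
#' score low.
#'
#' @param sasa_profile `sasa_profile` from [sasa()].
#' @param ref named vector of mean reference ASA per residue type.
#' @return nonnegative score.
#' @export
rs_score <- function(sasa_profile, ref) {
  p <- sasa_profile[sasa_profile$aa != "X", , drop = FALSE]
  m <- ref[p$aa]
  if (anyNA(m))
    stop("missing reference ASA for residue type(s): ",
         paste(unique(p$aa[is.na(m)]), collapse = ", "))
  sum(abs(p$asa - m) / m)
}

#' Score a decoy set against a reference structure
#'
#' Per model: backbone RMSD to the reference after Kabsch superposition,
#' ContactScore, and optionally rdepthscore (RankScore vs that model's
#' residue depth) and R_s. Per-model failures are recorded and the run
#' continues.
#'
#' @param decoys list of `structure_model` objects, a `structure_ensemble`,
#'   or a directory of PDB files.
#' @param reference `structure_model`.
#' @param pairs `contact_pairs`.
#' @param ranks optional `rankscore_table` to add rdepthscore.
#' @param ref_asa optional reference ASA vector to add R_s.
#' @param exclude positions excluded from rdepthscore.
#' @param atom_set RMSD atom set ("backbone" or "CA").
#' @param n_points sphere points used for depth/SASA when requested.
#' @return data.frame (class `model_scores`) with model, rmsd,
#'   contact_score and, when requested, rdepth_score and r_s; failures in
#'   `attr(, "failures")`.
#' @export
score_decoys <- function(decoys, reference, pairs, ranks = NULL,
                         ref_asa = NULL, exclude = integer(0),
                         atom_set = "backbone", n_points = 240) {
  if (inherits(decoys, "structure_ensemble")) decoys <- decoys$models
  if (is.character(decoys) && length(decoys) == 1 && dir.exists(decoys)) {
    files <- sort(list.files(decoys, pattern = "\\.(pdb|ent)$",
                             full.names = TRUE))
    decoys <- lapply(files, function(f) read_pdb(f)$models[[1]])
    names(decoys) <- basename(files)
  }
  ids <- if (!is.null(names(decoys)) && all(nzchar(names(decoys))))
    names(decoys) else sprintf("model_%04d", seq_along(decoys))
  rows <- vector("list", length(decoys))
  failures <- character(0)
  for (i in seq_along(decoys)) {
    rows[[i]] <- tryCatch({
      m <- decoys[[i]]
      row <- data.frame(model = ids[i],
                        rmsd = superpose(m, reference, atom_set)$rmsd,
                        contact_score = contact_score(m, pairs),
                        stringsAsFactors = FALSE)
      if (!is.null(ranks))
        row$rdepth_score <- rdepth_score(
          ranks, residue_depth(m, n_points = n_points), exclude = exclude)
      if (!is.null(ref_asa))
        row$r_s <- rs_score(sasa(m, n_points = n_points), ref_asa)
      row
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", ids[i], conditionMessage(e)))
      NULL
    })
  }
  out <- do.call(rbind, rows)
  if (length(failures) > 0)
    warning(length(failures), " model(s) failed scoring")
  attr(out, "failures") <- failures
  class(out) <- c("model_scores", "data.frame")
  out
}

#' Recovery histogram over RMSD bins
#'
#' Fraction of models selected by a predicate within each RMSD bin.
#' Bins are half-open (lower, upper] of fixed width starting at 0; the
#' upper edge labels the bin. Bins without models are flagged empty and
#' have undefined (NA) recovery.
#'
#' @param scores `model_scores`.
#' @param select predicate function taking the scores frame and returning a
#'   logical vector (e.g. `function(s) s$contact_score == 6`).
#' @param bin_width bin width in Angstrom (default 0.5).
#' @return data.frame with bin_lower, bin_upper, models_total,
#'   models_selected, recovery.
#' @export
recovery_histogram <- function(scores, select, bin_width = 0.5) {
  if (nrow(scores) == 0) stop("no model scores")
  sel <- select(scores)
  stopifnot(is.logical(sel), length(sel) == nrow(scores))
  upper_max <- ceiling(max(scores$rmsd) / bin_width) * bin_width
  edges <- seq(0, upper_max, by = bin_width)
  bin <- cut(scores$rmsd, breaks = edges, include.lowest = FALSE,
             right = TRUE)
  total <- as.vector(table(bin))
  selected <- as.vector(tapply(sel, bin, sum))
  selected[is.na(selected)] <- 0
  data.frame(bin_lower = edges[-length(edges)], bin_upper = edges[-1],
             models_total = total, models_selected = selected,
             recovery = ifelse(total > 0, selected / total, NA_real_))
}

#' Rank models by a score
#'
#' Ascending for `r_s` (lower deviation from average packing is better),
#' descending for `contact_score` and `rdepth_score`; ties broken by model
#' id. Models with an undefined key value are excluded with a warning.
#'
#' @param scores `model_scores`.
#' @param key one of "r_s", "contact_score", "rdepth_score".
#' @return the scores frame reordered, with a `rank` column.
#' @export
rank_models_by <- function(scores,
                           key = c("r_s", "contact_score", "rdepth_score")) {
  key <- match.arg(key)
  if (!key %in% names(scores)) stop("score '", key, "' not present")
  v <- scores[[key]]
  if (anyNA(v)) {
    warning(sum(is.na(v)), " model(s) with undefined ", key, " excluded")
    scores <- scores[!is.na(v), , drop = FALSE]
    v <- scores[[key]]
  }
  ord <- if (key == "r_s") order(v, scores$model)
  else order(-v, scores$model)
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
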