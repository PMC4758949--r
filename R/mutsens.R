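# Mutational sensitivity: MS_seq from read counts, per-position RankScore,
# position-type classification from substitution patterns, and
# proximal/distal suppressor calls.

#' Amino-acid property groups used in substitution-pattern analysis
#'
#' The five classes: (G,P); aliphatic A,C,V,L,I,M; aromatic H,F,Y,W;
#' polar S,T,N,Q; charged D,E,K,R.
#' @export
AA_GROUPS <- list(
  gly_pro   = c("G", "P"),
  aliphatic = c("A", "C", "V", "L", "I", "M"),
  aromatic  = c("H", "F", "Y", "W"),
  polar     = c("S", "T", "N", "Q"),
  charged   = c("D", "E", "K", "R")
)

mid_levels <- function(reads) {
  mids <- grep("^mid_[0-9]+$", names(reads), value = TRUE)
  mids[order(as.integer(sub("mid_", "", mids)))]
}

#' Mutational sensitivity score (MS_seq) from read counts
#'
#' A mutant's MS_seq is the expression level (MID) at which it first shows
#' an active (lethal) phenotype: scanning MIDs in ascending order, the first
#' level at which the read count drops by `drop_factor`-fold or more
#' relative to the previous level. A drop from positive counts to zero
#' qualifies (complete killing); zero to zero does not. Mutants with zero
#' reads everywhere get the absent-mutant sentinel 0; mutants that never
#' drop get 9, the least-active end of the scale (they survive every
#' expression level, i.e. are never active).
#'
#' @param reads data.frame with columns position, wt_aa, mut_aa and MID
#'   count columns mid_<level> (level 2..9; an optional mid_1 column, the
#'   pre-selection library, makes MS_seq = 2 detectable).
#' @param drop_factor fold-change defining a qualifying drop (default 5).
#' @return data.frame (class `mutsens_table`) with position, wt_aa, mut_aa,
#'   ms_seq in \{0\} U \{2..9\}.
#' @export
ms_seq_from_reads <- function(reads, drop_factor = 5) {
  mids <- mid_levels(reads)
  if (length(mids) < 2) stop("need at least two MID columns")
  cnt <- as.matrix(reads[, mids, drop = FALSE])
  if (!is.numeric(cnt)) stop("non-numeric read counts")
  if (any(cnt < 0, na.rm = TRUE)) stop("negative read counts")
  levels <- as.integer(sub("mid_", "", mids))
  ms <- apply(cnt, 1, function(x) {
    if (all(x == 0)) return(0L)
    for (m in 2:length(x)) {
      prev <- x[m - 1]; cur <- x[m]
      if (prev > 0 && (cur == 0 || prev / cur >= drop_factor))
        return(levels[m])
    }
    9L
  })
  out <- data.frame(position = reads$position, wt_aa = reads$wt_aa,
                    mut_aa = reads$mut_aa, ms_seq = as.integer(ms),
                    stringsAsFactors = FALSE)
  class(out) <- c("mutsens_table", "data.frame")
  out
}

#' Per-position RankScore from MS_seq values
#'
#' Mutants are ranked by MS_seq stratum: mutants with MS_seq = 2 get rank 1;
#' mutants of stratum k get rank (cumulative percentage of mutants with
#' MS_seq < k) + 1, with percentages taken over all observed mutants
#' (MS_seq >= 2) and used unrounded. A position's RankScore is the mean
#' rank of its observed mutants. Absent mutants (MS_seq = 0) and wild-type
#' self substitutions are excluded.
#'
#' @param ms `mutsens_table` (or data.frame with position, ms_seq, and
#'   optionally wt_aa/mut_aa).
#' @return data.frame (class `rankscore_table`) with position, rank_score,
#'   n_mutants.
#' @export
rank_scores <- function(ms) {
  if (nrow(ms) == 0) stop("empty mutational sensitivity table")
  obs <- ms[ms$ms_seq >= 2, , drop = FALSE]
  if (!is.null(obs$wt_aa) && !is.null(obs$mut_aa))
    obs <- obs[obs$wt_aa != obs$mut_aa, , drop = FALSE]
  if (nrow(obs) == 0) stop("no observed mutants (all MS_seq < 2)")
  n <- nrow(obs)
  rank_of <- vapply(2:9, function(k) 100 * sum(obs$ms_seq < k) / n + 1,
                    numeric(1))
  names(rank_of) <- as.character(2:9)
  r <- rank_of[as.character(obs$ms_seq)]
  agg <- rowsum(r, obs$position, reorder = TRUE)
  cnt <- as.vector(table(factor(obs$position, levels = rownames(agg))))
  out <- data.frame(position = as.integer(rownames(agg)),
                    rank_score = as.vector(agg) / cnt, n_mutants = cnt)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rankscore_table", "data.frame")
  out
}

#' Classify a suppressor position as proximal or distal
#'
#' Positions with RankScore at the bottom of the scale sit on the protein
#' surface and act as distal (global) suppressors; positions above the
#' proximal cutoff are buried and act through direct contact.
#'
#' @param position residue position.
#' @param ranks `rankscore_table`.
#' @param distal_max RankScore at or below which the call is distal
#'   (default 1).
#' @param proximal_min RankScore at or above which the call is proximal
#'   (default 25).
#' @return list (class `suppressor_call`): position, call
#'   ("distal"/"proximal"/"ambiguous"), rank_score, cutoffs.
#' @export
classify_suppressor <- function(position, ranks, distal_max = 1,
                                proximal_min = 25) {
  i <- match(position, ranks$position)
  if (is.na(i)) stop("position ", position, " absent from RankScore table")
  rs <- ranks$rank_score[i]
  call <- if (rs <= distal_max) "distal"
  else if (rs >= proximal_min) "proximal"
  else "ambiguous"
  structure(list(position = position, call = call, rank_score = rs,
                 cutoffs = c(distal_max = distal_max,
                             proximal_min = proximal_min)),
            class = "suppressor_call")
}

#' @export
print.suppressor_call <- function(x, ...) {
  cat(sprintf("position %d: %s (RankScore %.2f; distal <= %g, proximal >= %g)\n",
              x$position, x$call, x$rank_score, x$cutoffs[1], x$cutoffs[2]))
  invisible(x)
}

#' Classify a position from its substitution sensitivity pattern
#'
#' Rule-based call using the sensitivity pattern of substitution classes:
#' \itemize{
#'   \item buried: most aliphatic substitutions are tolerated
#'     (MS_seq < `high_ms`) while most polar and charged substitutions are
#'     not;
#'   \item active_site: both aliphatic and polar/charged substitutions are
#'     mostly poorly tolerated;
#'   \item exposed: most substitutions (G and P excepted) are tolerated;
#'   \item ambiguous otherwise.
#' }
#'
#' @param position residue position.
#' @param ms `mutsens_table`.
#' @param high_ms MS_seq at or above which a substitution counts as poorly
#'   tolerated (default 7).
#' @param tol_fraction fraction of a class required to meet a rule
#'   (default 0.5).
#' @return one of "buried", "active_site", "exposed", "ambiguous".
#' @export
classify_position <- function(position, ms, high_ms = 7, tol_fraction = 0.5) {
  rows <- ms[ms$position == position & ms$ms_seq >= 2, , drop = FALSE]
  if (nrow(rows) < 5)
    stop("position ", position, ": fewer than 5 observed mutants")
  grp <- function(aas) rows$ms_seq[rows$mut_aa %in% aas]
  ali <- grp(AA_GROUPS$aliphatic)
  pc <- grp(c(AA_GROUPS$polar, AA_GROUPS$charged))
  all_non_gp <- rows$ms_seq[!(rows$mut_aa %in% AA_GROUPS$gly_pro)]
  frac <- function(x, sensitive) {
    if (length(x) == 0) return(NA_real_)
    mean(if (sensitive) x >= high_ms else x < high_ms)
  }
  if (isTRUE(frac(ali, FALSE) >= tol_fraction) &&
      isTRUE(frac(pc, TRUE) >= tol_fraction)) return("buried")
  if (isTRUE(frac(ali, TRUE) >= tol_fraction) &&
      isTRUE(frac(pc, TRUE) >= tol_fraction)) return("active_site")
  if (isTRUE(frac(all_non_gp, FALSE) >= tol_fraction)) return("exposed")
  "ambiguous"
}
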