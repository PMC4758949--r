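# Residue-level geometry: centroids, inter-residue distances, Kabsch
# superposition, per-residue RMSF, Shrake-Rupley solvent accessibility and
# residue depth.

# van der Waals radii (Angstrom, Bondi) by element; protein heavy atoms plus
# hydrogen for the hydrogen_policy = "keep" case.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, SE = 1.90,
               P = 1.80, H = 1.20, D = 1.20)

# Theoretical maximum accessible surface areas per residue type (Angstrom^2),
# Tien et al. 2013. Used to express per-residue ASA as a percentage of the
# fully extended reference; values can exceed 100% for extended termini.
MAX_ASA <- c(A = 129, R = 274, N = 195, D = 193, C = 167,
             Q = 225, E = 223, G = 104, H = 224, I = 197,
             L = 201, K = 236, M = 224, F = 240, P = 159,
             S = 155, T = 172, W = 285, Y = 263, V = 174)

atom_xyz <- function(atoms) cbind(atoms$x, atoms$y, atoms$z)

#' Extract one residue's atoms from a model
#'
#' @param model `structure_model`.
#' @param resno author residue number.
#' @param chain chain id, or NULL for the first chain containing `resno`.
#' @param insert insertion code.
#' @return data.frame of atom records.
#' @export
get_residue <- function(model, resno, chain = NULL, insert = "") {
  a <- model$atoms
  sel <- a$resno == resno & a$insert == insert
  if (!is.null(chain)) sel <- sel & a$chain == chain
  else sel <- sel & a$chain == a$chain[which(sel)[1]]
  res <- a[sel, , drop = FALSE]
  if (nrow(res) == 0)
    stop("residue ", resno, if (!is.null(chain)) paste0(" chain ", chain),
         " not found in model")
  res
}

is_heavy <- function(atoms) !(atoms$elesy %in% c("H", "D"))

#' Side-chain centroid of a residue
#'
#' Unweighted mean of the heavy side-chain atom coordinates (all heavy atoms
#' except N, CA, C, O, OXT). Glycine, having no heavy side-chain atoms, falls
#' back to its CA position so that contact scoring is defined at every
#' position.
#'
#' @param res data.frame of one residue's atoms (see [get_residue()]).
#' @return numeric length-3 coordinate vector.
#' @export
sidechain_centroid <- function(res) {
  heavy <- res[is_heavy(res), , drop = FALSE]
  if (nrow(heavy) == 0) stop("residue has no heavy atoms")
  sc <- heavy[!(heavy$elety %in% BACKBONE_ATOMS), , drop = FALSE]
  if (nrow(sc) == 0) sc <- heavy[heavy$elety == "CA", , drop = FALSE]
  if (nrow(sc) == 0) stop("residue has neither side-chain heavy atoms nor CA")
  colMeans(atom_xyz(sc))
}

#' Side-chain centroids for every residue of a model
#'
#' @param model `structure_model`.
#' @param drop_unknown drop residues with aa == "X" (default TRUE).
#' @return data.frame with chain, resno, insert, aa, x, y, z.
#' @export
sidechain_centroids <- function(model, drop_unknown = TRUE) {
  a <- model$atoms
  heavy <- is_heavy(a)
  side <- heavy & !(a$elety %in% BACKBONE_ATOMS)
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  use <- side
  # glycine (or side-chain-less residues): fall back to CA
  no_side <- setdiff(unique(key[heavy]), unique(key[side]))
  use[key %in% no_side & a$elety == "CA"] <- TRUE
  a2 <- a[use, , drop = FALSE]
  k2 <- key[use]
  ord <- match(unique(k2), k2)
  cx <- rowsum(a2$x, k2, reorder = FALSE) / as.vector(table(factor(k2, levels = unique(k2))))
  cy <- rowsum(a2$y, k2, reorder = FALSE) / as.vector(table(factor(k2, levels = unique(k2))))
  cz <- rowsum(a2$z, k2, reorder = FALSE) / as.vector(table(factor(k2, levels = unique(k2))))
  out <- data.frame(chain = a2$chain[ord], resno = a2$resno[ord],
                    insert = a2$insert[ord], aa = a2$aa[ord],
                    x = as.vector(cx), y = as.vector(cy), z = as.vector(cz),
                    stringsAsFactors = FALSE)
  if (drop_unknown) out <- out[out$aa != "X", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distance between two residues' side-chain centroids
#'
#' With `chain` unspecified on either side, the residue is looked up in all
#' chains and the minimum distance over chain pairings is returned (the
#' homo-oligomer convention: contacts may be within a protomer or across
#' protomers).
#'
#' @param model `structure_model`.
#' @param pos_x,pos_y author residue numbers.
#' @param chain_x,chain_y optional chain ids restricting the lookup.
#' @return distance in Angstrom.
#' @export
centroid_distance <- function(model, pos_x, pos_y,
                              chain_x = NULL, chain_y = NULL) {
  cen <- sidechain_centroids(model)
  cx <- cen[cen$resno == pos_x &
              (is.null(chain_x) | cen$chain %in% chain_x), , drop = FALSE]
  cy <- cen[cen$resno == pos_y &
              (is.null(chain_y) | cen$chain %in% chain_y), , drop = FALSE]
  if (nrow(cx) == 0) stop("position ", pos_x, " not resolvable in model")
  if (nrow(cy) == 0) stop("position ", pos_y, " not resolvable in model")
  min_pairing_dist(atom_xyz(cx), atom_xyz(cy),
                   same = pos_x == pos_y & paste(cx$chain) %in% paste(cy$chain),
                   keys_a = paste(cx$chain, cx$resno),
                   keys_b = paste(cy$chain, cy$resno))
}

min_pairing_dist <- function(A, B, same = FALSE, keys_a = NULL, keys_b = NULL) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  if (!is.null(keys_a) && !is.null(keys_b)) {
    ident <- outer(keys_a, keys_b, "==")
    if (all(ident)) return(0)          # residue against itself
    d2[ident] <- Inf
  }
  sqrt(max(min(d2), 0))
}

#' Shortest heavy-atom distance between two residues
#'
#' Minimum pairwise Euclidean distance over the heavy atoms of the two
#' residues; with unspecified chains the minimum over equivalent chain
#' pairings is reported (homo-oligomer convention).
#'
#' @inheritParams centroid_distance
#' @return distance in Angstrom; 0 when the same residue is given twice.
#' @export
shortest_heavy_atom_distance <- function(model, pos_x, pos_y,
                                         chain_x = NULL, chain_y = NULL) {
  a <- model$atoms[is_heavy(model$atoms), , drop = FALSE]
  ax <- a[a$resno == pos_x & (is.null(chain_x) | a$chain %in% chain_x), ,
          drop = FALSE]
  ay <- a[a$resno == pos_y & (is.null(chain_y) | a$chain %in% chain_y), ,
          drop = FALSE]
  if (nrow(ax) == 0) stop("position ", pos_x, " has no heavy atoms in model")
  if (nrow(ay) == 0) stop("position ", pos_y, " has no heavy atoms in model")
  min_pairing_dist(atom_xyz(ax), atom_xyz(ay),
                   keys_a = paste(ax$chain, ax$resno),
                   keys_b = paste(ay$chain, ay$resno))
}

kabsch <- function(P, Q) {
  # optimal rotation mapping centred P onto centred Q (least squares)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(t(Pc) %*% Qc)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- Pc %*% t(R)
  list(rotation = R, translation = as.vector(cq - R %*% cp),
       rmsd = sqrt(mean(rowSums((moved - Qc)^2))))
}

#' Superpose one model onto another (Kabsch)
#'
#' Least-squares optimal rigid-body superposition over shared residues,
#' matched by (chain, resno, insert, atom name). The backbone atom set is
#' N, CA, C.
#'
#' @param mobile,reference `structure_model` objects.
#' @param atom_set "backbone" (N, CA, C) or "CA".
#' @return object of class `superposition`: rotation (3x3, det +1),
#'   translation (3-vector), rmsd (Angstrom), n_atoms used.
#' @export
superpose <- function(mobile, reference, atom_set = c("backbone", "CA")) {
  atom_set <- match.arg(atom_set)
  sel <- if (atom_set == "CA") "CA" else c("N", "CA", "C")
  am <- mobile$atoms[mobile$atoms$elety %in% sel, , drop = FALSE]
  ar <- reference$atoms[reference$atoms$elety %in% sel, , drop = FALSE]
  km <- paste(am$chain, am$resno, am$insert, am$elety, sep = "|")
  kr <- paste(ar$chain, ar$resno, ar$insert, ar$elety, sep = "|")
  shared <- intersect(km, kr)
  if (length(unique(sub("\\|[^|]+$", "", shared))) < 3)
    stop("superposition needs at least 3 shared residues")
  if (length(shared) < length(km) || length(shared) < length(kr))
    warning("atoms missing in one of the models were skipped")
  P <- atom_xyz(am)[match(shared, km), , drop = FALSE]
  Q <- atom_xyz(ar)[match(shared, kr), , drop = FALSE]
  k <- kabsch(P, Q)
  structure(c(k, list(n_atoms = length(shared), atom_set = atom_set)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition (%s, %d atoms): rmsd %.3f A\n",
              x$atom_set, x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a superposition to a model
#'
#' @param model `structure_model`.
#' @param sp `superposition` from [superpose()].
#' @return transformed `structure_model`.
#' @export
apply_superposition <- function(model, sp) {
  xyz <- atom_xyz(model$atoms) %*% t(sp$rotation)
  xyz <- sweep(xyz, 2, sp$translation, "+")
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

#' Per-residue RMSF of an ensemble (CA atoms)
#'
#' Each model is first superposed onto model 1 on CA atoms; the root mean
#' square fluctuation of each residue's CA about the mean (average)
#' structure is then reported.
#'
#' @param ensemble `structure_ensemble` with >= 2 models.
#' @return data.frame with chain, resno, aa, rmsf (Angstrom).
#' @export
ensemble_rmsf <- function(ensemble) {
  if (length(ensemble$models) < 2)
    stop("RMSF needs an ensemble of at least 2 models")
  ref <- ensemble$models[[1]]
  ca_ref <- ref$atoms[ref$atoms$elety == "CA", , drop = FALSE]
  key_ref <- paste(ca_ref$chain, ca_ref$resno, ca_ref$insert, sep = "|")
  coords <- lapply(ensemble$models, function(m) {
    m2 <- if (identical(m, ref)) m else apply_superposition(m, superpose(m, ref, "CA"))
    ca <- m2$atoms[m2$atoms$elety == "CA", , drop = FALSE]
    atom_xyz(ca)[match(key_ref, paste(ca$chain, ca$resno, ca$insert, sep = "|")), ,
                 drop = FALSE]
  })
  arr <- simplify2array(coords)           # nres x 3 x nmodels
  meanxyz <- apply(arr, c(1, 2), mean)
  dev2 <- apply(arr, 3, function(x) rowSums((x - meanxyz)^2))
  data.frame(chain = ca_ref$chain, resno = ca_ref$resno, aa = ca_ref$aa,
             rmsf = sqrt(rowMeans(dev2)), stringsAsFactors = FALSE)
}

golden_spiral <- function(n) {
  # deterministic quasi-uniform points on the unit sphere
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(atoms) {
  r <- VDW_RADII[atoms$elesy]
  if (anyNA(r)) {
    bad <- which(is.na(r))[1]
    stop(sprintf("unknown element '%s' for atom %s %s%d",
                 atoms$elesy[bad], atoms$elety[bad], atoms$chain[bad],
                 atoms$resno[bad]))
  }
  unname(r)
}

sr_accessibility <- function(xyz, radii, probe, n_points,
                             keep_points = FALSE) {
  n <- nrow(xyz)
  sp <- golden_spiral(n_points)
  R <- radii + probe
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  frac <- numeric(n)
  pts <- if (keep_points) vector("list", n) else NULL
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    p <- sweep(sp * R[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- rowSums(sweep(p, 2, xyz[j, ], "-")^2)
      acc <- acc & dj2 >= R[j]^2
      if (!any(acc)) break
    }
    frac[i] <- sum(acc) / n_points
    if (keep_points && any(acc)) pts[[i]] <- p[acc, , drop = FALSE]
  }
  area <- frac * 4 * pi * R^2
  list(area = area, frac = frac, points = pts)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom accessible surface area with a rolling probe, summed per
#' residue; relative ASA is the percentage of the theoretical maximum for
#' that residue type (Tien et al. reference values).
#'
#' @param model `structure_model` (heavy atoms are used; hydrogens, if
#'   present, are ignored).
#' @param probe probe radius in Angstrom (water, 1.4).
#' @param n_points test points per atom sphere.
#' @return object of class `sasa_profile`: data.frame with chain, resno,
#'   insert, aa, asa (Angstrom^2), rel_asa (%); per-atom areas in
#'   `attr(, "atom_area")`.
#' @export
sasa <- function(model, probe = 1.4, n_points = 960) {
  a <- model$atoms[is_heavy(model$atoms), , drop = FALSE]
  r <- atom_radii(a)
  sr <- sr_accessibility(atom_xyz(a), r, probe, n_points)
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  ord <- match(unique(key), key)
  tot <- rowsum(sr$area, key, reorder = FALSE)
  out <- data.frame(chain = a$chain[ord], resno = a$resno[ord],
                    insert = a$insert[ord], aa = a$aa[ord],
                    asa = as.vector(tot), stringsAsFactors = FALSE)
  out$rel_asa <- 100 * out$asa / unname(MAX_ASA[out$aa])
  attr(out, "atom_area") <- sr$area
  attr(out, "probe") <- probe
  class(out) <- c("sasa_profile", "data.frame")
  out
}

#' Residue depth
#'
#' Depth of burial: for each heavy atom, the distance to the nearest
#' solvent-accessible surface point, where the surface is approximated by
#' the probe-inflated Shrake-Rupley sphere points of atoms with nonzero
#' accessibility (i.e. the positions of closest bulk-water centres).
#' Per-residue depth aggregates atom depths by mean (default) or min.
#'
#' @param model `structure_model`.
#' @param probe probe radius in Angstrom.
#' @param n_points test points per atom sphere.
#' @param aggregate "mean" (default) or "min" over the residue's atoms.
#' @return data.frame with chain, resno, insert, aa, depth (Angstrom).
#' @export
residue_depth <- function(model, probe = 1.4, n_points = 240,
                          aggregate = c("mean", "min")) {
  aggregate <- match.arg(aggregate)
  a <- model$atoms[is_heavy(model$atoms), , drop = FALSE]
  r <- atom_radii(a)
  xyz <- atom_xyz(a)
  sr <- sr_accessibility(xyz, r, probe, n_points, keep_points = TRUE)
  surf <- do.call(rbind, sr$points[!vapply(sr$points, is.null, logical(1))])
  if (is.null(surf) || nrow(surf) == 0)
    stop("structure has zero accessible surface; cannot define depth")
  s2 <- rowSums(surf^2)
  depth_atom <- vapply(seq_len(nrow(xyz)), function(i) {
    sqrt(max(min(s2 - 2 * drop(surf %*% xyz[i, ]) + sum(xyz[i, ]^2)), 0))
  }, numeric(1))
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  ord <- match(unique(key), key)
  agg <- if (aggregate == "mean") rowsum(depth_atom, key, reorder = FALSE) /
    as.vector(table(factor(key, levels = unique(key))))
  else tapply(depth_atom, factor(key, levels = unique(key)), min)
  data.frame(chain = a$chain[ord], resno = a$resno[ord],
             insert = a$insert[ord], aa = a$aa[ord],
             depth = as.vector(agg), stringsAsFactors = FALSE)
}
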