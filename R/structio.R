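#' @importFrom stats complete.cases cor median quantile sd setNames rnorm runif
#'   rnbinom coef resid predict
#' @importFrom utils read.table write.table
NULL

# Three-letter -> one-letter amino acid map (standard 20 only; everything
# else becomes "X" and is excluded from centroid/contact operations).
AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
AA_123 <- setNames(names(AA_321), unname(AA_321))

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Construct a structure model
#'
#' A structure model is one pose of a protein: a table of heavy (or all)
#' atoms with chain, author residue number, insertion code, residue identity
#' and coordinates in Angstrom.
#'
#' @param atoms data.frame with columns chain, resno, insert, aa (one-letter),
#'   resid (three-letter), elety (atom name), elesy (element), x, y, z, o
#'   (occupancy).
#' @param model_index integer model number (>= 1).
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, model_index = 1L) {
  need <- c("chain", "resno", "insert", "aa", "resid", "elety", "elesy",
            "x", "y", "z", "o")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stop("atoms table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("structure model has zero atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in structure model")
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate atom records (chain, resno, insert, elety must be unique)")
  structure(list(atoms = atoms, model_index = as.integer(model_index)),
            class = "structure_model")
}

#' Construct a structure ensemble
#'
#' @param models list of `structure_model` objects sharing one residue set.
#' @param helices data.frame with columns chain, start, end (author residue
#'   numbers of helical segments), possibly empty.
#' @param id identifier string.
#' @return object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(models, helices = NULL, id = "structure") {
  if (length(models) < 1) stop("ensemble needs at least one model")
  if (is.null(helices))
    helices <- data.frame(chain = character(), start = integer(),
                          end = integer())
  rid <- lapply(models, function(m)
    sort(unique(residue_keys(m))))
  if (length(models) > 1 && !all(vapply(rid[-1], identical, logical(1), rid[[1]])))
    stop("all models in an ensemble must share the same residue set")
  structure(list(models = models, helices = helices, id = id),
            class = "structure_ensemble")
}

residue_keys <- function(model) {
  with(model$atoms, paste(chain, resno, insert, sep = "|"))
}

#' @export
print.structure_model <- function(x, ...) {
  nres <- length(unique(residue_keys(x)))
  cat(sprintf("structure_model: %d atoms, %d residues, %d chain(s)\n",
              nrow(x$atoms), nres, length(unique(x$atoms$chain))))
  invisible(x)
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("structure_ensemble '%s': %d model(s), %d helix segment(s)\n",
              x$id, length(x$models), nrow(x$helices)))
  print(x$models[[1]])
  invisible(x)
}

infer_element <- function(elety) {
  e <- gsub("[0-9'\"]", "", elety)
  e <- sub("^\\s+", "", e)
  two <- toupper(substr(e, 1, 2))
  ifelse(two %in% c("SE", "FE", "ZN", "MG"), two, toupper(substr(e, 1, 1)))
}

#' Read a PDB file into a structure ensemble
#'
#' Parses all MODEL blocks (a single implicit model if none), HELIX header
#' records, and ATOM records. HETATM records (waters, ligands, ions) are
#' skipped: every downstream distance in this package is inter-residue.
#' Alternate locations are resolved to the highest-occupancy conformer
#' (first listed on ties). Residue types outside the standard 20 are mapped
#' to "X" with a warning and excluded from centroid-based operations.
#'
#' @param path PDB file path.
#' @param hydrogen_policy "drop" (default) removes hydrogens/deuteriums.
#' @return `structure_ensemble`.
#' @export
read_pdb <- function(path, hydrogen_policy = c("drop", "keep")) {
  hydrogen_policy <- match.arg(hydrogen_policy)
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  keep <- at$type == "ATOM"
  if (!any(keep)) stop("empty structure: no ATOM records in ", path)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$elesy[is.na(at$elesy) | at$elesy == ""] <- NA
  at$elesy <- ifelse(is.na(at$elesy), infer_element(at$elety), toupper(at$elesy))
  if (hydrogen_policy == "drop") keep <- keep & !(at$elesy %in% c("H", "D"))
  idx <- which(keep)
  # altloc: highest occupancy wins, first listed breaks ties
  sub <- at[idx, , drop = FALSE]
  occ <- ifelse(is.na(sub$o), 1, sub$o)
  akey <- paste(sub$chain, sub$resno, sub$insert, sub$elety)
  ord <- order(akey, -occ, seq_along(idx))
  first <- !duplicated(akey[ord])
  idx <- sort(idx[ord][first])

  at2 <- at[idx, , drop = FALSE]
  aa <- unname(AA_321[at2$resid])
  if (anyNA(aa)) {
    warning("non-standard residue type(s) mapped to 'X': ",
            paste(unique(at2$resid[is.na(aa)]), collapse = ", "))
    aa[is.na(aa)] <- "X"
  }
  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1)
  cols <- bio3d::atom2xyz(idx)
  models <- lapply(seq_len(nmod), function(m) {
    co <- matrix(xyz[m, cols], ncol = 3, byrow = TRUE)
    atoms <- data.frame(
      chain = at2$chain, resno = at2$resno, insert = at2$insert,
      aa = aa, resid = at2$resid, elety = at2$elety, elesy = at2$elesy,
      x = co[, 1], y = co[, 2], z = co[, 3],
      o = ifelse(is.na(at2$o), 1, at2$o),
      stringsAsFactors = FALSE)
    structure_model(atoms, model_index = m)
  })
  helices <- data.frame(chain = character(), start = integer(),
                        end = integer())
  if (!is.null(pdb$helix) && length(pdb$helix$start) > 0)
    helices <- data.frame(chain = pdb$helix$chain,
                          start = as.integer(pdb$helix$start),
                          end = as.integer(pdb$helix$end),
                          stringsAsFactors = FALSE)
  structure_ensemble(models, helices,
                     id = sub("\\.(pdb|ent)$", "", basename(path)))
}

fmt_atom_name <- function(elety, elesy) {
  # names of <4 chars for 1-letter elements start in column 14
  ifelse(nchar(elety) >= 4 | nchar(elesy) == 2,
         sprintf("%-4s", elety), sprintf(" %-3s", elety))
}

#' Write a structure ensemble as PDB text
#'
#' Emits HELIX records, then ATOM records per model; MODEL/ENDMDL wrappers
#' are written only when the ensemble holds more than one model.
#' Coordinates at 3 decimals.
#'
#' @param ensemble `structure_ensemble`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_pdb <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  h <- ensemble$helices
  if (nrow(h) > 0) {
    m1 <- ensemble$models[[1]]$atoms
    for (i in seq_len(nrow(h))) {
      r3 <- function(resno) {
        hit <- m1$resid[m1$chain == h$chain[i] & m1$resno == resno]
        if (length(hit) > 0) hit[1] else "ALA"
      }
      line <- sprintf("HELIX  %3d %3s %3s %1s %4d  %3s %1s %4d %2d%30s %5d",
                      i, sprintf("%d", i %% 1000),
                      r3(h$start[i]), h$chain[i], h$start[i],
                      r3(h$end[i]), h$chain[i], h$end[i], 1L, "",
                      h$end[i] - h$start[i] + 1L)
      writeLines(line, con)
    }
  }
  multi <- length(ensemble$models) > 1
  for (m in ensemble$models) {
    if (multi) writeLines(sprintf("MODEL     %4d", m$model_index), con)
    a <- m$atoms
    lines <- sprintf(
      "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)) %% 100000, fmt_atom_name(a$elety, a$elesy), "",
      a$resid, a$chain, a$resno,
      ifelse(a$insert == "", " ", a$insert),
      a$x, a$y, a$z, a$o, 0, a$elesy)
    writeLines(lines, con)
    writeLines(if (multi) "ENDMDL" else "TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

TABLE_SCHEMAS <- list(
  read_counts = c("position", "wt_aa", "mut_aa"),
  ms_seq      = c("position", "wt_aa", "mut_aa", "ms_seq"),
  pairs       = c("pos_x", "pos_y"),
  melt        = c("temperature_C", "signal")
)

#' Read a pipeline table (TSV or CSV)
#'
#' Validates the header against one of the documented schemas:
#' \describe{
#'   \item{read_counts}{position, wt_aa, mut_aa, mid_1..mid_9 (at least two
#'     mid_ columns; mid_1, the pre-selection library count, is optional).}
#'   \item{ms_seq}{position, wt_aa, mut_aa, ms_seq.}
#'   \item{pairs}{pos_x, pos_y, optional chain_x, chain_y.}
#'   \item{melt}{temperature_C, signal.}
#' }
#' Unknown columns are preserved. Separator is sniffed from the header line.
#'
#' @param path file path.
#' @param schema one of "read_counts", "ms_seq", "pairs", "melt".
#' @return data.frame; zero-row input returns an empty frame with a warning.
#' @export
read_table_schema <- function(path,
                              schema = c("read_counts", "ms_seq", "pairs",
                                         "melt")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- readLines(path, n = 1)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  need <- TABLE_SCHEMAS[[schema]]
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(sprintf("schema '%s': missing required column(s): %s",
                 schema, paste(miss, collapse = ", ")))
  if (schema == "read_counts") {
    mids <- grep("^mid_[0-9]+$", names(df), value = TRUE)
    if (length(mids) < 2)
      stop("schema 'read_counts': need at least two mid_<level> columns")
  }
  if (nrow(df) == 0) warning("empty data section in ", path)
  attr(df, "schema") <- schema
  df
}
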