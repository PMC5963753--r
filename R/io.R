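## Library input/output: SMILES (.smi) and SDF (V2000).

#' Create a molecule record
#'
#' @param id compound identifier (non-empty string).
#' @param smiles SMILES string (may be `NA` for SDF-derived records).
#' @param mol parsed `pn_mol`; parsed from `smiles` when omitted.
#' @param conformers list of n x 3 coordinate matrices (Angstrom).
#' @param ic50_uM optional positive IC50 in micromolar.
#' @param source free-text provenance tag.
#' @return an object of class `pn_molrec`.
#' @export
molecule_record <- function(id, smiles = NA_character_, mol = NULL,
                            conformers = list(), ic50_uM = NULL,
                            source = "user") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("molecule id must be a non-empty string")
  }
  if (is.null(mol)) {
    if (is.na(smiles)) stop("either smiles or mol required for '", id, "'")
    mol <- parse_smiles(smiles)
  }
  if (!is.null(ic50_uM)) {
    if (!is.numeric(ic50_uM) || length(ic50_uM) != 1L || is.na(ic50_uM) ||
        ic50_uM <= 0) {
      stop("ic50_uM must be a positive number for '", id, "'")
    }
  }
  for (cf in conformers) {
    if (!is.matrix(cf) || ncol(cf) != 3L || nrow(cf) != nrow(mol$atoms) ||
        !all(is.finite(cf))) {
      stop("conformer of '", id, "' must be a finite ", nrow(mol$atoms),
           " x 3 matrix")
    }
  }
  structure(list(id = id, smiles = smiles, mol = mol, conformers = conformers,
                 ic50_uM = ic50_uM, source = source),
            class = "pn_molrec")
}

#' @export
print.pn_molrec <- function(x, ...) {
  cat("<pn_molrec> ", x$id, ": ", nrow(x$mol$atoms), " atoms, ",
      length(x$conformers), " conformer(s)\n", sep = "")
  invisible(x)
}

#' Read a molecule library from disk
#'
#' `.smi` files hold one whitespace-separated `SMILES id` pair per line; SDF
#' files are V2000 multi-record molfiles.  Unparsable entries are skipped with
#' a warning naming the line/record; a file with zero parsable entries is an
#' error.
#'
#' @param path file path.
#' @param format `"smiles"` or `"sdf"`; guessed from the extension when `NULL`.
#' @return list of [molecule_record()] objects.
#' @export
read_library <- function(path, format = NULL) {
  if (!file.exists(path)) stop("library file not found: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     smi = "smiles", smiles = "smiles", sdf = "sdf", mol = "sdf",
                     stop("cannot guess format of ", path,
                          "; pass format = 'smiles' or 'sdf'"))
  }
  format <- match.arg(format, c("smiles", "sdf"))
  recs <- if (format == "smiles") .read_smi(path) else .read_sdf(path)
  ids <- vapply(recs, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate molecule ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  recs
}

.read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  recs <- list()
  n_bad <- 0L
  for (i in seq_along(lines)) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    smi <- fields[1]
    id <- if (length(fields) >= 2L) fields[2] else paste0("mol", lineno[i])
    rec <- tryCatch(
      molecule_record(id, smiles = smi, source = basename(path)),
      error = function(e) {
        warning("skipping line ", lineno[i], " of ", basename(path), ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(rec)) n_bad <- n_bad + 1L else recs[[length(recs) + 1L]] <- rec
  }
  if (length(lines) && !length(recs)) {
    stop("no parsable entries in ", path, " (", n_bad, " skipped)")
  }
  recs
}

.read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # split into records on $$$$
  ends <- grep("^\\$\\$\\$\\$\\s*$", lines)
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  recs <- list()
  n_bad <- 0L
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    block <- block[!grepl("^\\$\\$\\$\\$\\s*$", block)]
    if (!length(trimws(block)) || all(!nzchar(trimws(block)))) next
    rec <- tryCatch(.parse_molfile(block, record_index = r, src = basename(path)),
                    error = function(e) {
                      warning("skipping SDF record ", r, " of ", basename(path),
                              ": ", conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (is.null(rec)) n_bad <- n_bad + 1L else recs[[length(recs) + 1L]] <- rec
  }
  if (!length(recs)) stop("no parsable entries in ", path, " (", n_bad,
                          " skipped)")
  recs
}

.parse_molfile <- function(block, record_index, src) {
  if (length(block) < 4L) stop("truncated molfile")
  name <- trimws(block[1])
  counts <- block[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 1L) stop("bad counts line")
  if (length(block) < 4L + natoms + nbonds) stop("truncated atom/bond block")
  coords <- matrix(0, natoms, 3)
  element <- character(natoms)
  for (i in seq_len(natoms)) {
    ln <- block[4L + i]
    coords[i, ] <- c(as.numeric(substr(ln, 1, 10)),
                     as.numeric(substr(ln, 11, 20)),
                     as.numeric(substr(ln, 21, 30)))
    element[i] <- trimws(substr(ln, 32, 34))
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  b1 <- integer(nbonds); b2 <- integer(nbonds); bo <- numeric(nbonds)
  for (k in seq_len(nbonds)) {
    ln <- block[4L + natoms + k]
    b1[k] <- as.integer(substr(ln, 1, 3))
    b2[k] <- as.integer(substr(ln, 4, 6))
    t <- as.integer(substr(ln, 7, 9))
    bo[k] <- if (t == 4L) 1.5 else as.numeric(t)
  }
  if (any(is.na(b1)) || any(is.na(b2)) || any(b1 < 1) || any(b2 < 1) ||
      any(b1 > natoms) || any(b2 > natoms)) stop("bad bond block")
  # charges from M  CHG lines
  charge <- integer(natoms)
  for (ln in grep("^M  CHG", block, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    nset <- f[1]
    for (j in seq_len(nset)) {
      charge[f[2 * j]] <- f[2 * j + 1]
    }
  }
  # drop explicit hydrogens, keep heavy atoms
  heavy <- element != "H"
  map <- cumsum(heavy)
  h_on <- integer(sum(heavy))
  keep_bond <- heavy[b1] & heavy[b2]
  for (k in which(!keep_bond)) {
    hv <- if (heavy[b1[k]]) b1[k] else if (heavy[b2[k]]) b2[k] else next
    h_on[map[hv]] <- h_on[map[hv]] + 1L
  }
  aromatic <- rep(FALSE, sum(heavy))
  bdf <- data.frame(a1 = map[b1[keep_bond]], a2 = map[b2[keep_bond]],
                    order = bo[keep_bond])
  for (k in seq_len(nrow(bdf))) {
    if (bdf$order[k] == 1.5) aromatic[c(bdf$a1[k], bdf$a2[k])] <- TRUE
  }
  adf <- data.frame(element = element[heavy], aromatic = aromatic,
                    charge = charge[heavy], h_explicit = 0L,
                    stringsAsFactors = FALSE)
  mol <- structure(list(atoms = adf, bonds = bdf), class = "pn_mol")
  mol$atoms$h_count <- pmax(.implicit_h(mol), h_on)
  id <- if (nzchar(name)) name else paste0("sdf", record_index)
  molecule_record(id, smiles = NA_character_, mol = mol,
                  conformers = list(coords[heavy, , drop = FALSE]), source = src)
}

#' Write a library as a `.smi` file
#'
#' One `SMILES id` line per record; records lacking a SMILES string (e.g. read
#' from SDF) are rejected.
#'
#' @param records list of [molecule_record()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_library <- function(records, path) {
  smi <- vapply(records, `[[`, "", "smiles")
  ids <- vapply(records, `[[`, "", "id")
  if (anyNA(smi)) {
    stop("records without SMILES cannot be written: ",
         paste(ids[is.na(smi)], collapse = ", "))
  }
  writeLines(paste(smi, ids), path)
  invisible(path)
}
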