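## Pharmacophore feature perception.
##
## Features live on a closed vocabulary: HYD_ARO (aromatic-ring centroid,
## aromatic rings are also hydrophobic), HYD (non-aromatic carbocycle centroid
## or centroid of a maximal aliphatic-carbon cluster of >= 3 carbons), HBA
## (N/O acceptor atoms) and HBD (O-H/N-H donor heavy atoms).  The rule table
## is plain data so that reports can state exactly which definitions were
## used; it is this package's own (vendor tools never publish theirs).

FEATURE_TYPES <- c("HYD_ARO", "HYD", "HBA", "HBD")

#' Default feature-perception rule table
#'
#' @return a named list describing each rule; can be serialised to JSON for
#'   audit with [jsonlite::toJSON()].
#' @export
default_feature_rules <- function() {
  list(
    HYD_ARO = list(
      description = "centroid of each aromatic ring",
      min_ring_size = 3L
    ),
    HYD = list(
      description = paste("centroid of each non-aromatic carbocycle and of",
                          "each maximal cluster of >= min_cluster aliphatic",
                          "carbons not bound to N/O and not in a ring"),
      min_cluster = 3L
    ),
    HBA = list(
      description = paste("N or O bearing a lone pair: excludes amide N,",
                          "pyrrole-type aromatic N-H, and positively charged",
                          "atoms"),
      elements = c("N", "O")
    ),
    HBD = list(
      description = "O or N carrying at least one hydrogen",
      elements = c("N", "O")
    )
  )
}

.is_amide_n <- function(mol, i, adj) {
  if (mol$atoms$element[i] != "N") return(FALSE)
  for (cnb in adj[[i]]) {
    if (mol$atoms$element[cnb] != "C") next
    b <- mol$bonds
    for (k in which((b$a1 == cnb | b$a2 == cnb) & b$order == 2)) {
      other <- if (b$a1[k] == cnb) b$a2[k] else b$a1[k]
      if (mol$atoms$element[other] == "O") return(TRUE)
    }
  }
  FALSE
}

.is_acceptor <- function(mol, i, adj) {
  a <- mol$atoms
  if (!(a$element[i] %in% c("N", "O"))) return(FALSE)
  if (a$charge[i] > 0) return(FALSE)
  if (a$element[i] == "N") {
    if (.is_amide_n(mol, i, adj)) return(FALSE)
    # pyrrole-type aromatic N-H contributes its lone pair to the ring
    if (a$aromatic[i] && a$h_count[i] > 0) return(FALSE)
    # aromatic N with three ring/substituent bonds has no free lone pair
    if (a$aromatic[i] && length(adj[[i]]) >= 3L) return(FALSE)
  }
  TRUE
}

.is_donor <- function(mol, i) {
  mol$atoms$element[i] %in% c("N", "O") && mol$atoms$h_count[i] > 0
}

#' Perceive pharmacophore feature points on one conformer
#'
#' @param record a [molecule_record()]; a conformer is embedded on the fly
#'   (seeded) when the record carries none.
#' @param conformer_index 1-based conformer index.
#' @param rules rule table, see [default_feature_rules()].
#' @return object of class `pn_featureset`: list with `molecule_id`,
#'   `conformer_index` and `points` (data.frame `type`, `x`, `y`, `z`,
#'   `atoms` = "/"-separated provenance atom indices).
#' @export
perceive_features <- function(record, conformer_index = 1L,
                              rules = default_feature_rules()) {
  stopifnot(inherits(record, "pn_molrec"))
  record <- .ensure_conformer(record)
  if (conformer_index < 1L || conformer_index > length(record$conformers)) {
    stop("conformer ", conformer_index, " does not exist for '", record$id, "'")
  }
  mol <- record$mol
  xyz <- record$conformers[[conformer_index]]
  adj <- .mol_adj(mol)
  a <- mol$atoms

  pts <- list()
  add <- function(type, pos, atoms) {
    pts[[length(pts) + 1L]] <<- data.frame(
      type = type, x = pos[1], y = pos[2], z = pos[3],
      atoms = paste(sort(atoms), collapse = "/"), stringsAsFactors = FALSE)
  }

  rings <- perceive_rings(mol)
  ring_atom <- .ring_atoms(mol)
  for (ring in rings) {
    centroid <- colMeans(xyz[ring, , drop = FALSE])
    if (all(a$aromatic[ring]) && length(ring) >= rules$HYD_ARO$min_ring_size) {
      add("HYD_ARO", centroid, ring)
    } else if (all(a$element[ring] == "C")) {
      add("HYD", centroid, ring)
    }
  }

  # maximal clusters of acyclic aliphatic carbons not bound to N/O
  hydro <- which(a$element == "C" & !a$aromatic & !ring_atom)
  polar_bound <- vapply(hydro, function(i)
    any(a$element[adj[[i]]] %in% c("N", "O", "S", "P")), FALSE)
  hydro <- hydro[!polar_bound]
  if (length(hydro)) {
    seen <- setNames(rep(FALSE, length(hydro)), hydro)
    for (s in hydro) {
      if (seen[as.character(s)]) next
      comp <- s; queue <- s
      seen[as.character(s)] <- TRUE
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        for (w in adj[[v]]) {
          if (w %in% hydro && !seen[as.character(w)]) {
            seen[as.character(w)] <- TRUE
            comp <- c(comp, w); queue <- c(queue, w)
          }
        }
      }
      if (length(comp) >= rules$HYD$min_cluster) {
        add("HYD", colMeans(xyz[comp, , drop = FALSE]), comp)
      }
    }
  }

  for (i in seq_len(nrow(a))) {
    if (.is_acceptor(mol, i, adj)) add("HBA", xyz[i, ], i)
    if (.is_donor(mol, i)) add("HBD", xyz[i, ], i)
  }

  points <- if (length(pts)) do.call(rbind, pts) else
    data.frame(type = character(0), x = numeric(0), y = numeric(0),
               z = numeric(0), atoms = character(0), stringsAsFactors = FALSE)
  feature_set(record$id, points, conformer_index = conformer_index)
}

#' Construct a feature point set
#'
#' @param molecule_id compound identifier.
#' @param points data.frame with columns `type`, `x`, `y`, `z` and optional
#'   `atoms` provenance.
#' @param conformer_index 1-based conformer index the points came from.
#' @return object of class `pn_featureset`.
#' @export
feature_set <- function(molecule_id, points, conformer_index = 1L) {
  stopifnot(is.data.frame(points))
  if (nrow(points)) {
    bad <- setdiff(unique(points$type), FEATURE_TYPES)
    if (length(bad)) stop("unknown feature type(s): ", paste(bad, collapse = ", "))
    if (!all(is.finite(as.matrix(points[, c("x", "y", "z")])))) {
      stop("feature positions must be finite")
    }
  }
  if (is.null(points$atoms)) points$atoms <- rep(NA_character_, nrow(points))
  structure(list(molecule_id = molecule_id,
                 conformer_index = as.integer(conformer_index),
                 points = points[, c("type", "x", "y", "z", "atoms")]),
            class = "pn_featureset")
}

#' @export
print.pn_featureset <- function(x, ...) {
  cat("<pn_featureset> ", x$molecule_id, " (conformer ", x$conformer_index,
      "): ", nrow(x$points), " points\n", sep = "")
  if (nrow(x$points)) print(x$points, ...)
  invisible(x)
}

# coordinates of a feature set as a matrix
.feature_coords <- function(fs) {
  as.matrix(fs$points[, c("x", "y", "z")])
}

#' Write feature points of a library to CSV
#'
#' @param feature_sets list of `pn_featureset` objects.
#' @param path output CSV path (one row per feature point).
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(feature_sets, path) {
  rows <- lapply(feature_sets, function(fs) {
    if (!nrow(fs$points)) return(NULL)
    cbind(molecule_id = fs$molecule_id, conformer = fs$conformer_index,
          fs$points)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) {
    out <- data.frame(molecule_id = character(0), conformer = integer(0),
                      type = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), atoms = character(0))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
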