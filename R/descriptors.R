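## Screening descriptors: HBD/HBA counts, rotatable bonds, ring count, TPSA.
##
## HBD/HBA are counted from the same donor/acceptor rules as feature
## perception, so filters and features cannot disagree.  TPSA uses the
## published fragment-contribution scheme restricted to N/O fragments (the
## original parameterisation); S/P contributions are not included and that
## restriction is reported here rather than hidden.

# fragment contributions (Angstrom^2) keyed by a local-environment signature
.tpsa_contribution <- function(mol, i, adj) {
  a <- mol$atoms
  el <- a$element[i]
  if (!(el %in% c("N", "O"))) return(0)
  b <- mol$bonds
  ks <- which(b$a1 == i | b$a2 == i)
  orders <- b$order[ks]
  nh <- a$h_count[i]
  chg <- a$charge[i]
  arom <- a$aromatic[i]
  deg <- length(ks)
  n1 <- sum(orders == 1); n2 <- sum(orders == 2); n3 <- sum(orders == 3)
  in3ring <- FALSE
  rings <- perceive_rings(mol)
  for (r in rings) if (length(r) == 3L && i %in% r) in3ring <- TRUE

  if (el == "O") {
    if (arom) return(13.14)
    if (chg < 0 && deg == 1 && n1 == 1) return(23.06)
    if (nh >= 1) return(20.23)
    if (n2 >= 1) return(17.07)
    if (deg == 2 && in3ring) return(12.53)
    if (deg == 2) return(9.23)
    return(9.23)
  }
  # nitrogen
  if (arom) {
    narom <- sum(a$aromatic[c(b$a1[ks], b$a2[ks])[c(b$a1[ks], b$a2[ks]) != i]])
    if (chg > 0) {
      if (nh >= 1) return(14.14)
      if (deg == 3 && n1 >= 1) return(3.88)
      return(4.10)
    }
    if (nh >= 1) return(15.79)
    if (deg == 3 && n2 >= 1) return(8.39)
    if (deg == 3 && n1 >= 1) return(4.93)
    if (deg == 3) return(4.41)
    return(12.89)
  }
  if (chg > 0) {
    if (nh >= 3) return(27.64)
    if (nh == 2 && n2 >= 1) return(25.59)
    if (nh == 2) return(16.61)
    if (nh == 1 && n2 >= 1) return(13.97)
    if (nh == 1) return(4.44)
    if (n3 >= 1) return(4.36)
    if (n2 >= 1) return(3.01)
    return(0.00)
  }
  if (nh >= 2) return(26.02)
  if (nh == 1 && n2 >= 1) return(23.85)
  if (nh == 1 && in3ring) return(21.94)
  if (nh == 1) return(12.03)
  if (n3 >= 1) return(23.79)
  if (n2 >= 2) return(11.68)   # nitro-type
  if (n2 >= 1) return(12.36)
  if (in3ring) return(3.01)
  3.24
}

#' Compute screening descriptors for a molecule
#'
#' Rotatable bonds are acyclic single bonds between two non-terminal heavy
#' atoms, excluding amide C-N; ring count is the cyclomatic number; TPSA is
#' fragment-additive over N/O environments.
#'
#' @param record a [molecule_record()].
#' @param rules feature rule table (drives the donor/acceptor definitions).
#' @return object of class `pn_descriptors`: list with `molecule_id`,
#'   `hbd_count`, `hba_count`, `rotatable_bonds`, `ring_count`, `tpsa`.
#' @export
compute_descriptors <- function(record, rules = default_feature_rules()) {
  stopifnot(inherits(record, "pn_molrec"))
  mol <- record$mol
  if (is.null(mol) || !nrow(mol$atoms)) {
    stop("unparsable structure for molecule '", record$id, "'")
  }
  adj <- .mol_adj(mol)
  hbd <- sum(vapply(seq_len(nrow(mol$atoms)), function(i) .is_donor(mol, i),
                    FALSE))
  hba <- sum(vapply(seq_len(nrow(mol$atoms)),
                    function(i) .is_acceptor(mol, i, adj), FALSE))

  b <- mol$bonds
  ringb <- if (nrow(b)) .ring_bonds(mol) else logical(0)
  deg <- lengths(adj)
  rot <- 0L
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != 1 || ringb[k]) next
    i <- b$a1[k]; j <- b$a2[k]
    if (deg[i] < 2L || deg[j] < 2L) next
    # amide C-N exclusion (either direction)
    amide <- (mol$atoms$element[i] == "N" && .is_amide_via(mol, j, i)) ||
             (mol$atoms$element[j] == "N" && .is_amide_via(mol, i, j))
    if (amide) next
    rot <- rot + 1L
  }

  tpsa <- sum(vapply(seq_len(nrow(mol$atoms)),
                     function(i) .tpsa_contribution(mol, i, adj), 0))

  structure(list(molecule_id = record$id,
                 hbd_count = as.integer(hbd),
                 hba_count = as.integer(hba),
                 rotatable_bonds = rot,
                 ring_count = as.integer(max(0L, .cyclomatic_number(mol))),
                 tpsa = tpsa),
            class = "pn_descriptors")
}

# is atom `cidx` a carbonyl carbon whose amide partner is `nidx`?
.is_amide_via <- function(mol, cidx, nidx) {
  if (mol$atoms$element[cidx] != "C") return(FALSE)
  b <- mol$bonds
  for (k in which((b$a1 == cidx | b$a2 == cidx) & b$order == 2)) {
    other <- if (b$a1[k] == cidx) b$a2[k] else b$a1[k]
    if (mol$atoms$element[other] == "O") return(TRUE)
  }
  FALSE
}

#' Construct a descriptor record directly
#'
#' Used for synthetic compounds whose descriptors are stated rather than
#' computed from a structure.
#'
#' @param molecule_id compound identifier.
#' @param hbd_count,hba_count,rotatable_bonds,ring_count non-negative integers.
#' @param tpsa topological polar surface area (Angstrom^2, >= 0).
#' @return object of class `pn_descriptors`.
#' @export
descriptor_record <- function(molecule_id, hbd_count, hba_count,
                              rotatable_bonds, ring_count, tpsa) {
  vals <- c(hbd_count, hba_count, rotatable_bonds, ring_count, tpsa)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("descriptor values must be non-negative for '", molecule_id, "'")
  }
  structure(list(molecule_id = molecule_id,
                 hbd_count = as.integer(hbd_count),
                 hba_count = as.integer(hba_count),
                 rotatable_bonds = as.integer(rotatable_bonds),
                 ring_count = as.integer(ring_count),
                 tpsa = as.numeric(tpsa)),
            class = "pn_descriptors")
}

#' @export
print.pn_descriptors <- function(x, ...) {
  cat("<pn_descriptors> ", x$molecule_id,
      ": HBD ", x$hbd_count, ", HBA ", x$hba_count,
      ", rotatable ", x$rotatable_bonds, ", rings ", x$ring_count,
      ", TPSA ", round(x$tpsa, 2), " A^2\n", sep = "")
  invisible(x)
}

#' Descriptor table for a library
#'
#' @param records list of [molecule_record()] objects.
#' @return data.frame, one row per molecule.
#' @export
descriptor_table <- function(records) {
  rows <- lapply(records, function(r) {
    d <- compute_descriptors(r)
    data.frame(molecule_id = d$molecule_id, hbd_count = d$hbd_count,
               hba_count = d$hba_count, rotatable_bonds = d$rotatable_bonds,
               ring_count = d$ring_count, tpsa = d$tpsa,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
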