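## Minimal SMILES reader.
##
## Supports the organic subset (B C N O P S F Cl Br I and aromatic b c n o p s),
## bracket atoms with charge/explicit H, branches, ring closures (including %nn)
## and explicit bond symbols - = # :.  Stereo markers (/ \ @) are accepted and
## ignored.  Multi-fragment SMILES ('.') are rejected: screening operates on
## single connected structures.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

# smallest standard valence(s) used for implicit-H assignment
.default_valences <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles a single SMILES string.
#' @return an object of class `pn_mol`: a list with `atoms` (data.frame:
#'   `element`, `aromatic`, `charge`, `h_count`) and `bonds` (data.frame:
#'   `a1`, `a2`, `order`; aromatic bonds have order 1.5).
#' @examples
#' m <- parse_smiles("CCO")
#' nrow(m$atoms)  # 3 heavy atoms
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("smiles must be a single non-empty string")
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)

  atoms <- list()   # each: list(element, aromatic, charge, h_explicit, bracket)
  bonds <- list()   # each: c(a1, a2, order)  order 0 = "default"
  prev <- NA_integer_
  pending_bond <- NA_real_   # explicit bond order awaiting next atom
  stack <- integer(0)
  ring_open <- list()        # closure digit -> list(atom, order)

  add_atom <- function(element, aromatic, charge = 0L, h_explicit = 0L,
                       bracket = FALSE) {
    atoms[[length(atoms) + 1L]] <<- list(element = element, aromatic = aromatic,
                                         charge = charge,
                                         h_explicit = h_explicit,
                                         bracket = bracket)
    idx <- length(atoms)
    if (!is.na(prev)) {
      ord <- pending_bond
      bonds[[length(bonds) + 1L]] <<- c(prev, idx, if (is.na(ord)) 0 else ord)
    }
    pending_bond <<- NA_real_
    prev <<- idx
    invisible(idx)
  }

  close_ring <- function(key) {
    if (is.null(ring_open[[key]])) {
      ring_open[[key]] <<- list(atom = prev, order = pending_bond)
      pending_bond <<- NA_real_
    } else {
      op <- ring_open[[key]]
      ord <- if (!is.na(pending_bond)) pending_bond else
             if (!is.na(op$order)) op$order else 0
      bonds[[length(bonds) + 1L]] <<- c(op$atom, prev, ord)
      ring_open[[key]] <<- NULL
      pending_bond <<- NA_real_
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom in SMILES: ", smiles)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- .parse_bracket_atom(body, smiles)
      add_atom(at$element, at$aromatic, at$charge, at$h_explicit, bracket = TRUE)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      add_atom(paste0(ch, chars[i + 1L]), FALSE)
      i <- i + 2L
    } else if (ch %in% ORGANIC_SUBSET) {
      add_atom(ch, FALSE)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), TRUE)
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stop("branch before any atom in SMILES: ", smiles)
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced ')' in SMILES: ", smiles)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pending_bond <- 1; i <- i + 1L
    } else if (ch == "=") {
      pending_bond <- 2; i <- i + 1L
    } else if (ch == "#") {
      pending_bond <- 3; i <- i + 1L
    } else if (ch == ":") {
      pending_bond <- 1.5; i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      close_ring(ch); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("truncated %% ring closure in SMILES: ", smiles)
      close_ring(paste(chars[(i + 1L):(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (ch == ".") {
      stop("multi-fragment SMILES not supported: ", smiles)
    } else if (ch == "@" || ch == "+") {
      stop("unexpected character '", ch, "' outside brackets in SMILES: ", smiles)
    } else {
      stop("unrecognised SMILES character '", ch, "' in: ", smiles)
    }
  }
  if (length(stack) > 0L) stop("unbalanced '(' in SMILES: ", smiles)
  if (length(Filter(Negate(is.null), ring_open)) > 0L) {
    stop("unclosed ring bond in SMILES: ", smiles)
  }
  if (length(atoms) == 0L) stop("SMILES contains no atoms: ", smiles)

  adf <- data.frame(
    element  = vapply(atoms, `[[`, "", "element"),
    aromatic = vapply(atoms, `[[`, FALSE, "aromatic"),
    charge   = vapply(atoms, function(a) as.integer(a$charge), 0L),
    h_explicit = vapply(atoms, function(a) as.integer(a$h_explicit), 0L),
    bracket  = vapply(atoms, `[[`, FALSE, "bracket"),
    stringsAsFactors = FALSE
  )
  if (length(bonds)) {
    bm <- do.call(rbind, bonds)
    bdf <- data.frame(a1 = as.integer(bm[, 1]), a2 = as.integer(bm[, 2]),
                      order = bm[, 3])
    # default bond: aromatic between two aromatic atoms, else single
    dft <- bdf$order == 0
    arom_pair <- adf$aromatic[bdf$a1] & adf$aromatic[bdf$a2]
    bdf$order[dft] <- ifelse(arom_pair[dft], 1.5, 1)
  } else {
    bdf <- data.frame(a1 = integer(0), a2 = integer(0), order = numeric(0))
  }

  mol <- structure(list(atoms = adf, bonds = bdf), class = "pn_mol")
  mol$atoms$h_count <- .implicit_h(mol)
  mol
}

.parse_bracket_atom <- function(body, smiles) {
  # [isotope? symbol chiral? Hcount? charge? class?]
  m <- regexec(
    "^([0-9]*)([A-Za-z][a-z]?)(@[@A-Z0-9]*)?(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?(:[0-9]+)?$",
    body)
  g <- regmatches(body, m)[[1]]
  if (length(g) == 0L) stop("cannot parse bracket atom [", body, "] in: ", smiles)
  sym <- g[3]
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
  element <- if (aromatic) {
    paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
  } else sym
  hspec <- g[5]
  h <- if (is.na(hspec) || !nzchar(hspec)) 0L
       else if (hspec == "H") 1L
       else as.integer(substring(hspec, 2))
  cspec <- g[6]
  charge <- 0L
  if (!is.na(cspec) && nzchar(cspec)) {
    if (grepl("^[+]+$", cspec)) charge <- nchar(cspec)
    else if (grepl("^[-]+$", cspec)) charge <- -nchar(cspec)
    else charge <- as.integer(paste0(substr(cspec, 1, 1),
                                     if (nchar(cspec) > 1) substring(cspec, 2) else "1"))
  }
  list(element = element, aromatic = aromatic, charge = charge, h_explicit = h)
}

# implicit hydrogen counts; bracket atoms use their explicit H
.implicit_h <- function(mol) {
  a <- mol$atoms
  b <- mol$bonds
  n <- nrow(a)
  bsum <- numeric(n)
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      bsum[b$a1[k]] <- bsum[b$a1[k]] + b$order[k]
      bsum[b$a2[k]] <- bsum[b$a2[k]] + b$order[k]
    }
  }
  h <- integer(n)
  bracket <- if (!is.null(a$bracket)) a$bracket else a$h_explicit > 0L
  for (i in seq_len(n)) {
    if (bracket[i]) { h[i] <- a$h_explicit[i]; next }
    val <- .default_valences[[a$element[i]]]
    if (is.null(val)) { h[i] <- 0L; next }
    bs <- bsum[i]
    # an aromatic atom's delocalised system: round 1.5-bonds up as in Daylight
    bs <- if (a$aromatic[i]) ceiling(bs) else bs
    v <- val[val >= bs]
    h[i] <- if (length(v)) as.integer(v[1] - bs) else 0L
  }
  h
}

#' @export
print.pn_mol <- function(x, ...) {
  cat("<pn_mol> ", nrow(x$atoms), " heavy atoms, ", nrow(x$bonds), " bonds\n",
      sep = "")
  invisible(x)
}

# adjacency list of heavy atoms
.mol_adj <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  b <- mol$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      adj[[b$a1[k]]] <- c(adj[[b$a1[k]]], b$a2[k])
      adj[[b$a2[k]]] <- c(adj[[b$a2[k]]], b$a1[k])
    }
  }
  adj
}

# number of connected components
.mol_components <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- .mol_adj(mol)
  seen <- logical(n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  comp
}
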