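## Ring perception.
##
## The ring count descriptor is the cyclomatic number E - V + C (the size of a
## smallest set of smallest rings).  Individual rings are enumerated with the
## classic approximation: for every edge inside the 2-core, take the shortest
## cycle through that edge, deduplicate, and keep the smallest rings until the
## cyclomatic number is reached and all cyclic edges are covered.  Exact SSSR
## corner cases (fused cage systems) are out of scope for screening-sized
## molecules.

.cyclomatic_number <- function(mol) {
  nrow(mol$bonds) - nrow(mol$atoms) + .mol_components(mol)
}

# shortest path between from/to avoiding one edge, NULL if none
.bfs_path <- function(adj, from, to, forbid) {
  n <- length(adj)
  prev <- rep(NA_integer_, n)
  seen <- logical(n)
  seen[from] <- TRUE
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if ((v == forbid[1] && w == forbid[2]) || (v == forbid[2] && w == forbid[1]))
        next
      if (!seen[w]) {
        seen[w] <- TRUE
        prev[w] <- v
        if (w == to) {
          path <- w
          while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
          return(path)
        }
        queue <- c(queue, w)
      }
    }
  }
  NULL
}

#' Enumerate the smallest rings of a molecule
#'
#' @param mol a `pn_mol`.
#' @return list of integer vectors of atom indices, one per ring, ordered
#'   around the cycle.  Empty list for acyclic molecules.
#' @export
perceive_rings <- function(mol) {
  target <- .cyclomatic_number(mol)
  if (target <= 0L) return(list())
  adj <- .mol_adj(mol)
  b <- mol$bonds
  candidates <- list()
  for (k in seq_len(nrow(b))) {
    path <- .bfs_path(adj, b$a1[k], b$a2[k], c(b$a1[k], b$a2[k]))
    if (!is.null(path)) candidates[[length(candidates) + 1L]] <- path
  }
  if (!length(candidates)) return(list())
  keys <- vapply(candidates, function(p) paste(sort(p), collapse = ","), "")
  candidates <- candidates[!duplicated(keys)]
  candidates <- candidates[order(lengths(candidates))]

  ring_edge_key <- function(p) {
    e <- cbind(p, c(p[-1], p[1]))
    paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "-")
  }
  chosen <- list()
  covered <- character(0)
  for (p in candidates) {
    ek <- ring_edge_key(p)
    if (all(ek %in% covered)) next
    chosen[[length(chosen) + 1L]] <- p
    covered <- union(covered, ek)
    if (length(chosen) == target) break
  }
  chosen
}

# logical vector: atom is in some ring (2-core membership)
.ring_atoms <- function(mol) {
  n <- nrow(mol$atoms)
  deg <- integer(n)
  b <- mol$bonds
  alive_bond <- rep(TRUE, nrow(b))
  for (k in seq_len(nrow(b))) {
    deg[b$a1[k]] <- deg[b$a1[k]] + 1L
    deg[b$a2[k]] <- deg[b$a2[k]] + 1L
  }
  alive <- rep(TRUE, n)
  repeat {
    leaves <- which(alive & deg <= 1L)
    if (!length(leaves)) break
    for (v in leaves) {
      alive[v] <- FALSE
      ks <- which(alive_bond & (b$a1 == v | b$a2 == v))
      for (k in ks) {
        alive_bond[k] <- FALSE
        other <- if (b$a1[k] == v) b$a2[k] else b$a1[k]
        deg[other] <- deg[other] - 1L
      }
      deg[v] <- 0L
    }
  }
  alive & deg >= 2L
}

# logical vector over bonds: bond is part of a ring
.ring_bonds <- function(mol) {
  ra <- .ring_atoms(mol)
  b <- mol$bonds
  inring <- ra[b$a1] & ra[b$a2]
  # bridges between two ring systems are not ring bonds; verify by edge-removal
  for (k in which(inring)) {
    adj <- .mol_adj(mol)
    path <- .bfs_path(adj, b$a1[k], b$a2[k], c(b$a1[k], b$a2[k]))
    if (is.null(path)) inring[k] <- FALSE
  }
  inring
}
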