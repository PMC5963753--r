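## Seeded conformer embedding.
##
## Feature perception needs plausible, deterministic 3-D coordinates, not
## minimum-energy ones.  A distance-geometry-style stress function is built
## from ideal bond lengths (covalent-radius sums scaled by bond order), 1-3
## distances from idealised hybridisation angles, and a soft lower bound on
## all other pairs, then minimised by BFGS from a seeded random start.  Energy
## minimisation and force fields are explicit non-goals.

.covalent_radius <- c(B = 0.84, C = 0.77, N = 0.75, O = 0.73, P = 1.10,
                      S = 1.04, F = 0.71, Cl = 0.99, Br = 1.14, I = 1.33)

.bond_order_scale <- function(order) {
  ifelse(order >= 3, 0.78, ifelse(order >= 2, 0.87, ifelse(order > 1, 0.93, 1)))
}

# sp = 1, sp2 = 2, sp3 = 3 per atom
.hybridisation <- function(mol) {
  n <- nrow(mol$atoms)
  hyb <- rep(3L, n)
  b <- mol$bonds
  ndouble <- integer(n); ntriple <- integer(n)
  for (k in seq_len(nrow(b))) {
    for (v in c(b$a1[k], b$a2[k])) {
      if (b$order[k] == 2) ndouble[v] <- ndouble[v] + 1L
      if (b$order[k] == 3) ntriple[v] <- ntriple[v] + 1L
    }
  }
  hyb[ndouble >= 1L | mol$atoms$aromatic] <- 2L
  hyb[ntriple >= 1L | ndouble >= 2L] <- 1L
  hyb
}

#' Embed one 3-D conformer for a molecule
#'
#' @param mol a `pn_mol`.
#' @param seed integer seed; identical seeds give identical coordinates.
#' @return n x 3 matrix of Cartesian coordinates in Angstrom.
#' @export
embed_conformer <- function(mol, seed = 1L) {
  n <- nrow(mol$atoms)
  if (n == 1L) return(matrix(0, 1, 3))
  b <- mol$bonds
  el <- mol$atoms$element
  rad <- .covalent_radius[el]
  rad[is.na(rad)] <- 0.9
  hyb <- .hybridisation(mol)
  angle <- c(pi, 2 * pi / 3, acos(-1 / 3))[hyb]   # sp, sp2, sp3

  # constrained pairs: bonds and 1-3 paths
  tgt_i <- integer(0); tgt_j <- integer(0); tgt_d <- numeric(0)
  blen <- numeric(nrow(b))
  for (k in seq_len(nrow(b))) {
    blen[k] <- (rad[b$a1[k]] + rad[b$a2[k]]) * .bond_order_scale(b$order[k])
    tgt_i <- c(tgt_i, b$a1[k]); tgt_j <- c(tgt_j, b$a2[k]); tgt_d <- c(tgt_d, blen[k])
  }
  adj <- .mol_adj(mol)
  bond_len <- function(u, v) {
    k <- which((b$a1 == u & b$a2 == v) | (b$a1 == v & b$a2 == u))[1]
    blen[k]
  }
  for (c0 in seq_len(n)) {
    nb <- adj[[c0]]
    if (length(nb) < 2L) next
    for (p in seq_len(length(nb) - 1L)) {
      for (q in seq((p + 1L), length(nb))) {
        u <- nb[p]; v <- nb[q]
        d1 <- bond_len(u, c0); d2 <- bond_len(v, c0)
        th <- angle[c0]
        if (length(nb) >= 3L && hyb[c0] == 1L) th <- 2 * pi / 3
        d13 <- sqrt(d1^2 + d2^2 - 2 * d1 * d2 * cos(th))
        tgt_i <- c(tgt_i, u); tgt_j <- c(tgt_j, v); tgt_d <- c(tgt_d, d13)
      }
    }
  }
  keyed <- paste(pmin(tgt_i, tgt_j), pmax(tgt_i, tgt_j))
  dup <- duplicated(keyed)
  tgt_i <- tgt_i[!dup]; tgt_j <- tgt_j[!dup]; tgt_d <- tgt_d[!dup]
  constrained <- unique(keyed)

  allpairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  free <- !(paste(allpairs[, 1], allpairs[, 2]) %in% constrained)
  rep_i <- allpairs[free, 1]; rep_j <- allpairs[free, 2]
  dmin <- 2.6

  stress <- function(x) {
    xyz <- matrix(x, n, 3)
    di <- sqrt(rowSums((xyz[tgt_i, , drop = FALSE] - xyz[tgt_j, , drop = FALSE])^2))
    s <- sum((di - tgt_d)^2)
    if (length(rep_i)) {
      dr <- sqrt(rowSums((xyz[rep_i, , drop = FALSE] - xyz[rep_j, , drop = FALSE])^2))
      viol <- pmax(0, dmin - dr)
      s <- s + 0.3 * sum(viol^2)
    }
    s
  }

  .with_seed(seed, {
    best <- NULL
    for (trial in 1:3) {
      x0 <- stats::rnorm(3 * n, sd = 1.5 + 0.5 * sqrt(n))
      fit <- stats::optim(x0, stress, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12))
      if (is.null(best) || fit$value < best$value) best <- fit
      if (best$value < 1e-8) break
    }
    xyz <- matrix(best$par, n, 3)
    sweep(xyz, 2, colMeans(xyz))
  })
}

# ensure a record carries at least one conformer
.ensure_conformer <- function(record, seed = 1L) {
  if (length(record$conformers) == 0L) {
    record$conformers <- list(embed_conformer(record$mol, seed = seed))
  }
  record
}
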