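# Independent oracles used to cross-check the package's fast paths.
# These deliberately re-derive everything from first principles: plain
# nested loops, no pruning, numeric optimisation instead of closed forms.

# brute-force matcher: enumerate every ordered k-tuple of distinct,
# type-compatible points and test all pairwise constraints
oracle_match <- function(points, model, hyd_accepts_aromatic = TRUE) {
  k <- nrow(model$features)
  pts <- as.matrix(points$points[, c("x", "y", "z")])
  ptype <- points$points$type
  np <- nrow(pts)
  if (np < k) return(list(matched = FALSE, assignment = NULL))
  D <- model$distances
  radii <- model$features$radius
  compat <- function(slot, p) {
    st <- model$features$type[slot]
    st == ptype[p] || (st == "HYD" && ptype[p] == "HYD_ARO" && hyd_accepts_aromatic)
  }
  best <- NULL
  idx <- seq_len(np)
  tuples <- expand.grid(rep(list(idx), k))
  for (r in seq_len(nrow(tuples))) {
    tp <- as.integer(tuples[r, ])
    if (anyDuplicated(tp)) next
    ok <- all(vapply(seq_len(k), function(s) compat(s, tp[s]), FALSE))
    if (!ok) next
    dev <- 0; mx <- 0; valid <- TRUE
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      d <- sqrt(sum((pts[tp[i], ] - pts[tp[j], ])^2))
      e <- abs(d - D[i, j])
      if (e > radii[i] + radii[j]) valid <- FALSE
      dev <- dev + e; mx <- max(mx, e)
    }
    if (!valid) next
    if (is.null(best) || dev < best$dev - 1e-12 ||
        (abs(dev - best$dev) <= 1e-12 && .oracle_lex_less(tp, best$tp))) {
      best <- list(tp = tp, dev = dev, mx = mx)
    }
  }
  if (is.null(best)) list(matched = FALSE, assignment = NULL)
  else list(matched = TRUE, assignment = best$tp, sum_deviation = best$dev,
            max_pair_deviation = best$mx)
}

.oracle_lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

# superposition RMSD by numeric optimisation over Euler angles
# (proper rotations only), multi-start to dodge local minima
oracle_rmsd <- function(x, ref) {
  xc <- sweep(x, 2, colMeans(x))
  rc <- sweep(ref, 2, colMeans(ref))
  rot <- function(ang) {
    ca <- cos(ang[1]); sa <- sin(ang[1])
    cb <- cos(ang[2]); sb <- sin(ang[2])
    cg <- cos(ang[3]); sg <- sin(ang[3])
    Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
    Rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(ang) sqrt(mean(rowSums((xc %*% t(rot(ang)) - rc)^2)))
  starts <- expand.grid(a = c(0, pi / 2, pi, 3 * pi / 2),
                        b = c(0.01, pi / 2, pi - 0.01),
                        g = c(0, pi))
  best <- Inf
  for (r in seq_len(nrow(starts))) {
    fit <- stats::optim(as.numeric(starts[r, ]), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# feature set placed exactly on the embedded model (optionally transformed)
model_point_set <- function(model, rotate = diag(3), shift = c(0, 0, 0),
                            id = "exact") {
  emb <- embed_model(model)
  pts <- emb %*% t(rotate) + matrix(shift, nrow(emb), 3, byrow = TRUE)
  feature_set(id, data.frame(type = model$features$type,
                             x = pts[, 1], y = pts[, 2], z = pts[, 3],
                             stringsAsFactors = FALSE))
}

# tiny two-place chain net A -> B used in several engine tests
chain_net <- function(k = 1, a0 = 5) {
  hybrid_petri_net(
    places = data.frame(name = c("A", "B"), initial = c(a0, 0)),
    transitions = data.frame(name = "t", type = "mass_action", k = k),
    arcs = data.frame(place = c("A", "B"), transition = "t",
                      direction = c("pre", "post"), weight = 1))
}
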