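## Pharmacophore model, distance-constraint matcher, RMSD scoring,
## activity classification, model evaluation and the screening cascade.

#' Construct a pharmacophore model
#'
#' A model is an ordered list of k typed feature spheres plus a symmetric
#' k x k matrix of pairwise feature distances (Angstrom).  A candidate triple
#' of feature points matches when every inter-point distance agrees with the
#' model distance to within the sum of the two feature radii
#' (sphere-intersection tolerance).
#'
#' @param features data.frame with columns `label`, `type` (one of
#'   `r paste(FEATURE_TYPES, collapse = ", ")`) and `radius` (Angstrom > 0).
#' @param distances symmetric k x k numeric matrix, zero diagonal.
#' @return object of class `pn_pharmacophore`.
#' @export
pharmacophore_model <- function(features, distances) {
  stopifnot(is.data.frame(features))
  k <- nrow(features)
  if (k < 2L) stop("a pharmacophore model needs at least 2 features")
  if (!all(c("label", "type", "radius") %in% names(features))) {
    stop("features must have columns label, type, radius")
  }
  bad <- setdiff(features$type, FEATURE_TYPES)
  if (length(bad)) stop("unknown feature type(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(features$radius)) || any(features$radius <= 0)) {
    stop("feature radii must be strictly positive")
  }
  distances <- as.matrix(distances)
  if (!all(dim(distances) == c(k, k))) stop("distance matrix must be ", k, " x ", k)
  if (max(abs(distances - t(distances))) > 1e-12) {
    stop("distance matrix must be symmetric")
  }
  if (any(abs(diag(distances)) > 1e-12)) stop("distance matrix diagonal must be 0")
  if (any(distances < 0)) stop("distances must be non-negative")
  if (k == 3L) {
    d <- c(distances[1, 2], distances[1, 3], distances[2, 3])
    if (2 * max(d) > sum(d) + 1e-12) {
      stop("model infeasible: distances violate the triangle inequality")
    }
  }
  dimnames(distances) <- list(features$label, features$label)
  structure(list(features = features[, c("label", "type", "radius")],
                 distances = distances),
            class = "pn_pharmacophore")
}

#' @export
print.pn_pharmacophore <- function(x, ...) {
  cat("<pn_pharmacophore> ", nrow(x$features), " features\n", sep = "")
  print(cbind(x$features, x$distances), ...)
  invisible(x)
}

#' Read / write a pharmacophore model spec (JSON)
#'
#' The spec format is `{"features": [{"label","type","radius"}...],
#' "distances": [[...]]}`.  The packaged 3-feature IGF-1R model lives at
#' `system.file("models", "igf1r_3pt.json", package = "pharmnet")`.
#'
#' @param path JSON file path.
#' @return [pharmacophore_model()] object.
#' @export
read_pharmacophore_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  spec <- jsonlite::fromJSON(path)
  pharmacophore_model(as.data.frame(spec$features), spec$distances)
}

#' @rdname read_pharmacophore_model
#' @param model a `pn_pharmacophore`.
#' @export
write_pharmacophore_model <- function(model, path) {
  jsonlite::write_json(
    list(features = model$features,
         distances = unname(model$distances)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' The packaged 3-feature IGF-1R pharmacophore model
#'
#' Aromatic-hydrophobic (radius 1.4 A), hydrophobic (0.8 A) and hydrogen-bond
#' acceptor (0.9 A) features with pairwise distances 3.75 / 4.99 / 6.79 A.
#'
#' @return [pharmacophore_model()] object.
#' @export
igf1r_model <- function() {
  read_pharmacophore_model(
    system.file("models", "igf1r_3pt.json", package = "pharmnet",
                mustWork = TRUE))
}

#' Embed a pharmacophore model into canonical 3-D coordinates
#'
#' Canonical placement: feature 1 at the origin, feature 2 on the +x axis,
#' feature 3 in the xy half-plane with y >= 0 (k = 3).  For k > 3 a classical
#' multidimensional-scaling embedding is used and verified.
#'
#' @param model a [pharmacophore_model()].
#' @return k x 3 matrix of coordinates whose pairwise distances reproduce the
#'   model distance matrix to <= 1e-9 Angstrom.
#' @export
embed_model <- function(model) {
  stopifnot(inherits(model, "pn_pharmacophore"))
  D <- model$distances
  k <- nrow(D)
  if (k == 2L) {
    X <- rbind(c(0, 0, 0), c(D[1, 2], 0, 0))
  } else if (k == 3L) {
    d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
    if (d12 <= 0) stop("model infeasible: coincident features 1 and 2")
    x3 <- (d12^2 + d13^2 - d23^2) / (2 * d12)
    y3sq <- d13^2 - x3^2
    if (y3sq < -1e-12) stop("model infeasible: distances violate the triangle inequality")
    X <- rbind(c(0, 0, 0), c(d12, 0, 0), c(x3, sqrt(max(0, y3sq)), 0))
  } else {
    G <- -0.5 * (D^2 - rowMeans(D^2) -
                   rep(colMeans(D^2), each = k) + mean(D^2))
    eg <- eigen(G, symmetric = TRUE)
    if (sum(eg$values > 1e-9) > 3L) stop("model infeasible: not embeddable in 3-D")
    vals <- pmax(eg$values[1:3], 0)
    X <- eg$vectors[, 1:3, drop = FALSE] %*% diag(sqrt(vals), 3)
    X <- sweep(X, 2, X[1, ])
  }
  rec <- .pairwise_dist(X)
  if (max(abs(rec - D)) > 1e-9) {
    stop("model infeasible: distances not reproducible in 3-D (max error ",
         format(max(abs(rec - D))), " A)")
  }
  rownames(X) <- model$features$label
  X
}

# slot/point type compatibility; HYD slots accept HYD_ARO unless strict
.type_compatible <- function(slot_type, point_type, hyd_accepts_aromatic = TRUE) {
  if (slot_type == point_type) return(TRUE)
  if (slot_type == "HYD" && point_type == "HYD_ARO") return(hyd_accepts_aromatic)
  FALSE
}

#' Match a feature point set against a pharmacophore model
#'
#' Enumerates assignments of k distinct, type-compatible points to the model
#' slots; an assignment is valid when every pairwise point distance deviates
#' from the model distance by at most the sum of the two feature radii.
#' Among valid assignments the one minimising the total pairwise deviation is
#' returned, ties broken lexicographically on point indices.
#'
#' @param points a `pn_featureset` (see [feature_set()]).
#' @param model a [pharmacophore_model()].
#' @param hyd_accepts_aromatic should plain HYD slots accept HYD_ARO points?
#' @param tol_scale multiplier on the radius-sum tolerances (1 = spec default).
#' @return object of class `pn_match`: list with `matched`, `assignment`
#'   (point indices per model slot, or NULL), `max_pair_deviation`, `rmsd`
#'   (rigid-superposition RMSD onto the embedded model) and `sum_deviation`.
#' @export
match_features <- function(points, model, hyd_accepts_aromatic = TRUE,
                           tol_scale = 1) {
  stopifnot(inherits(points, "pn_featureset"), inherits(model, "pn_pharmacophore"))
  k <- nrow(model$features)
  np <- nrow(points$points)
  no_match <- structure(list(matched = FALSE, assignment = NULL,
                             max_pair_deviation = NA_real_, rmsd = NA_real_,
                             sum_deviation = NA_real_),
                        class = "pn_match")
  if (np < k) return(no_match)

  xyz <- .feature_coords(points)
  ptype <- points$points$type
  D <- model$distances
  radii <- model$features$radius
  tol <- (outer(radii, radii, `+`)) * tol_scale

  cand <- lapply(seq_len(k), function(s) {
    which(vapply(ptype, .type_compatible, FALSE,
                 slot_type = model$features$type[s],
                 hyd_accepts_aromatic = hyd_accepts_aromatic))
  })
  if (any(lengths(cand) == 0L)) return(no_match)

  pd <- .pairwise_dist(xyz)
  best <- NULL
  # depth-first enumeration with pairwise pruning
  assign_next <- function(slot, chosen) {
    if (slot > k) {
      dev <- 0; mx <- 0
      for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
        d <- abs(pd[chosen[i], chosen[j]] - D[i, j])
        dev <- dev + d
        mx <- max(mx, d)
      }
      if (is.null(best) || dev < best$dev - 1e-12 ||
          (abs(dev - best$dev) <= 1e-12 &&
           .lex_less(chosen, best$chosen))) {
        best <<- list(chosen = chosen, dev = dev, mx = mx)
      }
      return(invisible())
    }
    for (p in cand[[slot]]) {
      if (p %in% chosen) next
      ok <- TRUE
      for (s in seq_len(slot - 1L)) {
        if (abs(pd[chosen[s], p] - D[s, slot]) > tol[s, slot]) { ok <- FALSE; break }
      }
      if (ok) assign_next(slot + 1L, c(chosen, p))
    }
  }
  assign_next(1L, integer(0))
  if (is.null(best)) return(no_match)

  emb <- embed_model(model)
  rmsd <- if (k >= 3L) {
    match_rmsd(xyz[best$chosen, , drop = FALSE], emb)
  } else NA_real_
  structure(list(matched = TRUE,
                 assignment = stats::setNames(best$chosen, model$features$label),
                 max_pair_deviation = best$mx,
                 rmsd = rmsd,
                 sum_deviation = best$dev),
            class = "pn_match")
}

.lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' @export
print.pn_match <- function(x, ...) {
  if (x$matched) {
    cat("<pn_match> matched; max pair deviation ",
        format(x$max_pair_deviation, digits = 4), " A; RMSD ",
        format(x$rmsd, digits = 4), " A\n", sep = "")
  } else cat("<pn_match> no match\n")
  invisible(x)
}

#' RMSD after optimal rigid superposition (Kabsch)
#'
#' Proper rotations only: reflections are not allowed, so the mirror image of
#' a chiral arrangement keeps a non-zero RMSD.
#'
#' @param x,ref m x 3 coordinate matrices in correspondence (m >= 3).
#' @return RMSD in Angstrom (0 iff congruent).
#' @export
match_rmsd <- function(x, ref) {
  x <- as.matrix(x); ref <- as.matrix(ref)
  if (nrow(x) < 3L || nrow(ref) < 3L) {
    stop("undefined orientation: need at least 3 points for superposition")
  }
  if (nrow(x) != nrow(ref)) stop("point sets must have equal size")
  xc <- sweep(x, 2, colMeans(x))
  rc <- sweep(ref, 2, colMeans(ref))
  s <- svd(crossprod(xc, rc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fit <- xc %*% t(R)
  sqrt(mean(rowSums((fit - rc)^2)))
}

#' Classify a compound's activity from its IC50
#'
#' Thresholds (inclusive toward the more-active class): most active
#' <= 0.5 uM, moderately active <= 20 uM, less active <= 60 uM, inactive
#' > 60 uM.
#'
#' @param ic50_uM positive IC50 in micromolar (vectorised).
#' @return character vector over `MOST_ACTIVE`, `MODERATELY_ACTIVE`,
#'   `LESS_ACTIVE`, `INACTIVE`.
#' @export
classify_activity <- function(ic50_uM) {
  if (any(!is.finite(ic50_uM)) || any(ic50_uM <= 0)) {
    stop("ic50_uM must be positive and finite")
  }
  ifelse(ic50_uM <= 0.5, "MOST_ACTIVE",
         ifelse(ic50_uM <= 20, "MODERATELY_ACTIVE",
                ifelse(ic50_uM <= 60, "LESS_ACTIVE", "INACTIVE")))
}

# predicted positive iff any conformer's feature set matches
.compound_matches <- function(item, model, ...) {
  if (inherits(item, "pn_featureset")) {
    return(match_features(item, model, ...)$matched)
  }
  if (inherits(item, "pn_molrec")) {
    item <- .ensure_conformer(item)
    for (ci in seq_along(item$conformers)) {
      fs <- perceive_features(item, conformer_index = ci)
      if (match_features(fs, model, ...)$matched) return(TRUE)
    }
    return(FALSE)
  }
  if (is.list(item) && !is.null(item$features)) {   # synthetic compound
    return(.compound_matches(item$features, model, ...))
  }
  if (is.list(item) && all(vapply(item, inherits, FALSE, "pn_featureset"))) {
    return(any(vapply(item, function(f) match_features(f, model, ...)$matched,
                      FALSE)))
  }
  stop("library items must be pn_molrec or pn_featureset objects")
}

#' Evaluate a pharmacophore model against a labeled library
#'
#' A compound is predicted positive iff any of its conformers matches.  Rates
#' with a zero denominator are reported as `NA` (undefined), never as 0.
#'
#' @param model a [pharmacophore_model()].
#' @param library list of [molecule_record()] or `pn_featureset` objects (an
#'   item may also be a list of feature sets = conformers of one compound).
#' @param labels character/logical vector: `"active"`/`TRUE` vs
#'   `"inactive"`/`FALSE`, one per library item.
#' @param ... passed to [match_features()].
#' @return object of class `pn_evaluation`: tp, fp, tn, fn, sensitivity,
#'   specificity, accuracy, and the per-compound prediction table.
#' @export
evaluate_model <- function(model, library, labels, ...) {
  if (!length(library)) stop("empty library")
  if (length(labels) != length(library)) {
    stop("labels must have one entry per library item")
  }
  truth <- if (is.logical(labels)) labels else {
    lv <- tolower(as.character(labels))
    if (!all(lv %in% c("active", "inactive"))) {
      stop("labels must be 'active'/'inactive' or logical")
    }
    lv == "active"
  }
  pred <- vapply(library, .compound_matches, FALSE, model = model, ...)
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  ids <- vapply(seq_along(library), function(i) {
    it <- library[[i]]
    if (inherits(it, "pn_molrec") || inherits(it, "pn_featureset"))
      it$molecule_id %||% it$id else paste0("compound", i)
  }, "")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = rate(tp, tp + fn),
                 specificity = rate(tn, tn + fp),
                 accuracy = rate(tp + tn, length(library)),
                 predictions = data.frame(id = ids, truth = truth, pred = pred,
                                          stringsAsFactors = FALSE)),
            class = "pn_evaluation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pn_evaluation <- function(x, ...) {
  cat("<pn_evaluation> tp ", x$tp, " fp ", x$fp, " tn ", x$tn, " fn ", x$fn,
      "\n  sensitivity ", format(x$sensitivity, digits = 4),
      "  specificity ", format(x$specificity, digits = 4),
      "  accuracy ", format(x$accuracy, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Default screening-cascade configuration
#'
#' Lipinski counts use the strict `<` operators as applied in the original
#' cascade (HBD < 5, HBA < 10); `lipinski_inclusive = TRUE` switches to the
#' canonical `<=` rule of five.  Drug-likeness defaults: rotatable bonds
#' <= 10, ring count in [1, 6], TPSA <= 140 A^2.
#'
#' @param lipinski_inclusive use `<=` instead of `<` for the Lipinski counts.
#' @param hbd_max,hba_max Lipinski count bounds.
#' @param rot_max,ring_min,ring_max,tpsa_max drug-likeness bounds.
#' @return named list.
#' @export
default_filter_config <- function(lipinski_inclusive = FALSE, hbd_max = 5,
                                  hba_max = 10, rot_max = 10, ring_min = 1,
                                  ring_max = 6, tpsa_max = 140) {
  list(lipinski_inclusive = lipinski_inclusive, hbd_max = hbd_max,
       hba_max = hba_max, rot_max = rot_max, ring_min = ring_min,
       ring_max = ring_max, tpsa_max = tpsa_max)
}

#' Run the full screening cascade
#'
#' Stage order: pharmacophore match, then Lipinski HBD/HBA counts, then
#' drug-likeness (rotatable bonds, ring count, TPSA).  Every rejection
#' carries a machine-readable reason; stage survivor counts are monotone
#' non-increasing.
#'
#' @param library list of [molecule_record()] objects.
#' @param model a [pharmacophore_model()].
#' @param config see [default_filter_config()].
#' @param ... passed to [match_features()].
#' @return object of class `pn_screening`: `report` (per-compound data.frame
#'   with stage outcomes and reasons), `stage_counts`, `hits`.
#' @export
screen_library <- function(library, model, config = default_filter_config(),
                           ...) {
  if (!length(library)) stop("empty library")
  known <- names(default_filter_config())
  extra <- setdiff(names(config), known)
  if (length(extra)) stop("unknown filter key(s): ", paste(extra, collapse = ", "))
  config <- utils::modifyList(default_filter_config(), config)
  cmp <- if (config$lipinski_inclusive) `<=` else `<`

  rows <- lapply(library, function(rec) {
    id <- (rec$id %||% rec$molecule_id) %||% "?"
    phm <- .compound_matches(rec, model, ...)
    reason <- character(0)
    lip <- NA; dl <- NA
    hbd <- hba <- rot <- rings <- tpsa <- NA_real_
    d <- if (inherits(rec, "pn_molrec")) compute_descriptors(rec)
         else rec$descriptors   # synthetic compounds carry descriptors
    if (!is.null(d)) {
      hbd <- d$hbd_count; hba <- d$hba_count; rot <- d$rotatable_bonds
      rings <- d$ring_count; tpsa <- d$tpsa
    }
    if (!phm) reason <- c(reason, "pharmacophore")
    if (phm && !is.na(hbd)) {
      lip_hbd <- cmp(hbd, config$hbd_max)
      lip_hba <- cmp(hba, config$hba_max)
      lip <- lip_hbd && lip_hba
      if (!lip_hbd) reason <- c(reason, "hbd")
      if (!lip_hba) reason <- c(reason, "hba")
      if (lip) {
        dl_rot <- rot <= config$rot_max
        dl_ring <- rings >= config$ring_min && rings <= config$ring_max
        dl_tpsa <- tpsa <= config$tpsa_max
        dl <- dl_rot && dl_ring && dl_tpsa
        if (!dl_rot) reason <- c(reason, "rotatable_bonds")
        if (!dl_ring) reason <- c(reason, "ring_count")
        if (!dl_tpsa) reason <- c(reason, "tpsa")
      }
    }
    data.frame(id = id, pharmacophore = phm,
               lipinski = lip, druglike = dl,
               hbd = hbd, hba = hba, rotatable = rot, rings = rings,
               tpsa = tpsa,
               pass = isTRUE(phm) && isTRUE(lip) && isTRUE(dl),
               reason = if (length(reason)) paste(reason, collapse = ";") else "",
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  stage_counts <- c(input = nrow(report),
                    pharmacophore = sum(report$pharmacophore),
                    lipinski = sum(report$lipinski %in% TRUE),
                    druglike = sum(report$druglike %in% TRUE))
  structure(list(report = report, stage_counts = stage_counts,
                 hits = report$id[report$pass], config = config),
            class = "pn_screening")
}

#' @export
print.pn_screening <- function(x, ...) {
  cat("<pn_screening> survivors:",
      paste(names(x$stage_counts), x$stage_counts, sep = "=", collapse = " "),
      "\n")
  if (length(x$hits)) cat("hits:", paste(x$hits, collapse = ", "), "\n")
  invisible(x)
}
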