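# pharmacophore model, matcher, RMSD, activity classes, evaluation, cascade

test_that("embed_model reproduces distance matrices in canonical placement", {
  m <- igf1r_model()
  X <- embed_model(m)
  D <- as.matrix(dist(X))
  expect_lt(max(abs(D - m$distances)), 1e-9)
  expect_equal(X[1, ], c(F1 = 0, F1 = 0, F1 = 0), ignore_attr = TRUE)
  expect_equal(X[2, 2:3], c(0, 0), ignore_attr = TRUE)
  expect_gte(X[3, 2], 0)
  expect_equal(unname(X[3, 3]), 0)

  eq <- pharmacophore_model(
    data.frame(label = c("a", "b", "c"), type = c("HYD", "HYD", "HYD"),
               radius = 0.5),
    matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  expect_equal(unname(embed_model(eq)),
               rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
               tolerance = 1e-12)

  expect_error(pharmacophore_model(
    data.frame(label = c("a", "b", "c"), type = "HYD", radius = 0.5),
    matrix(c(0, 1, 3, 1, 0, 1, 3, 1, 0), 3)), "triangle inequality")
})

test_that("matcher handles identity placement, emptiness and typing", {
  m <- igf1r_model()
  res <- match_features(model_point_set(m), m)
  expect_true(res$matched)
  expect_equal(res$max_pair_deviation, 0, tolerance = 1e-12)
  expect_equal(res$rmsd, 0, tolerance = 1e-9)

  empty <- feature_set("none", data.frame(type = character(0), x = numeric(0),
                                          y = numeric(0), z = numeric(0)))
  expect_false(match_features(empty, m)$matched)

  # HYD slot accepts HYD_ARO points unless strict
  fs <- model_point_set(m)
  fs$points$type[2] <- "HYD_ARO"
  expect_true(match_features(fs, m)$matched)
  expect_false(match_features(fs, m, hyd_accepts_aromatic = FALSE)$matched)
  # HYD_ARO slot never accepts plain HYD
  fs2 <- model_point_set(m)
  fs2$points$type[1] <- "HYD"
  expect_false(match_features(fs2, m)$matched)
})

test_that("matcher agrees with the brute-force oracle on random sets", {
  m <- igf1r_model()
  sets <- generate_random_feature_sets(40, 8, seed = 11)
  for (fs in sets) {
    got <- match_features(fs, m)
    want <- oracle_match(fs, m)
    expect_identical(got$matched, want$matched, info = fs$molecule_id)
    if (got$matched) {
      expect_equal(unname(got$assignment), want$assignment,
                   info = fs$molecule_id)
      expect_equal(got$sum_deviation, want$sum_deviation, tolerance = 1e-9)
      expect_equal(got$max_pair_deviation, want$max_pair_deviation,
                   tolerance = 1e-9)
    }
  }
})

test_that("jitter along a fixed ray never re-matches after first failure", {
  m <- igf1r_model()
  base <- model_point_set(m)
  dir <- matrix(c(0.3, -1, 0.2, 1, 0.4, -0.8, -0.5, 0.7, 1), 3, 3)
  dir <- dir / sqrt(sum(dir^2))
  matched <- vapply(seq(0, 6, by = 0.25), function(amp) {
    fs <- base
    fs$points[, c("x", "y", "z")] <- fs$points[, c("x", "y", "z")] + amp * dir
    match_features(fs, m)$matched
  }, FALSE)
  # no FALSE -> TRUE transition along the ray
  expect_false(any(diff(matched) > 0))
  expect_true(matched[1])
  expect_false(matched[length(matched)])
})

test_that("match_rmsd is rigid-motion invariant and reflection-sensitive", {
  m <- igf1r_model()
  emb <- embed_model(m)
  rot <- pharmnet:::.with_seed(5, pharmnet:::.random_rotation())
  moved <- emb %*% t(rot) + matrix(c(1, -2, 3), 3, 3, byrow = TRUE)
  expect_equal(match_rmsd(moved, emb), 0, tolerance = 1e-9)

  displaced <- emb
  displaced[2, ] <- displaced[2, ] + c(0.3, 0, 0)
  expect_equal(match_rmsd(displaced, emb), oracle_rmsd(displaced, emb),
               tolerance = 1e-6)

  mirrored <- emb %*% diag(c(1, 1, -1))
  mirrored[2, ] <- mirrored[2, ] + c(0.1, 0.2, 0.4)  # make it truly chiral-shifted
  expect_equal(match_rmsd(mirrored, emb), oracle_rmsd(mirrored, emb),
               tolerance = 1e-6)

  expect_error(match_rmsd(emb[1:2, ], emb[1:2, ]), "undefined orientation")
})

test_that("classify_activity applies the printed thresholds inclusively", {
  expect_equal(classify_activity(0.04), "MOST_ACTIVE")
  expect_equal(classify_activity(0.5), "MOST_ACTIVE")
  expect_equal(classify_activity(0.500001), "MODERATELY_ACTIVE")
  expect_equal(classify_activity(20), "MODERATELY_ACTIVE")
  expect_equal(classify_activity(60), "LESS_ACTIVE")
  expect_equal(classify_activity(60.1), "INACTIVE")
  expect_equal(classify_activity(200), "INACTIVE")
  expect_error(classify_activity(0), "positive")
  expect_error(classify_activity(-1), "positive")
})

test_that("evaluate_model builds a correct confusion matrix", {
  m <- igf1r_model()
  lib <- generate_matching_library(library_spec(n_positive = 6, n_negative = 3,
                                                jitter_sigma = 0.1, seed = 9), m)
  ev <- evaluate_model(m, lib$sets, lib$labels)
  expect_equal(ev$tp, 6L); expect_equal(ev$tn, 3L)
  expect_equal(ev$fp, 0L); expect_equal(ev$fn, 0L)
  expect_equal(ev$accuracy, 1.0)
  expect_equal(ev$tp + ev$fn, sum(lib$labels == "active"))
  expect_equal(ev$tn + ev$fp, sum(lib$labels == "inactive"))

  # degenerate tolerance: everything matches -> sensitivity 1, specificity 0
  ev2 <- evaluate_model(m, lib$sets, lib$labels, tol_scale = 1e6)
  expect_equal(ev2$sensitivity, 1)
  expect_equal(ev2$specificity, 0)

  expect_error(evaluate_model(m, list(), character(0)), "empty library")
  # all items one class -> undefined rate is NA, not 0
  ev3 <- evaluate_model(m, lib$sets[1:2], c("active", "active"))
  expect_true(is.na(ev3$specificity))
})

test_that("screen_library applies the cascade with reasons and monotone counts", {
  m <- igf1r_model()
  # ethanol cannot present three features
  scr <- screen_library(list(molecule_record("ethanol", "CCO")), m)
  expect_equal(unname(scr$stage_counts["pharmacophore"]), 0L)
  expect_length(scr$hits, 0L)
  expect_equal(scr$report$reason, "pharmacophore")

  # synthetic positive with hbd = 5 fails strict Lipinski with reason "hbd"
  pos <- generate_matching_library(
    library_spec(n_positive = 1, n_negative = 0, jitter_sigma = 0,
                 decoy_points_range = c(0, 0), seed = 7), m)$sets[[1]]
  comp <- synthetic_compound(pos, descriptor_record("s1", hbd_count = 5,
                                                    hba_count = 4,
                                                    rotatable_bonds = 3,
                                                    ring_count = 2, tpsa = 80))
  scr2 <- screen_library(list(comp), m)
  expect_true(scr2$report$pharmacophore)
  expect_false(scr2$report$lipinski)
  expect_equal(scr2$report$reason, "hbd")
  # inclusive mode turns the same compound into a hit
  scr3 <- screen_library(list(comp), m,
                         default_filter_config(lipinski_inclusive = TRUE))
  expect_equal(scr3$hits, "s1")

  expect_error(screen_library(list(comp), m, list(bogus_key = 1)),
               "unknown filter key")
})

test_that("cascade hits equal the intersection of standalone stage passes", {
  m <- igf1r_model()
  lib <- generate_matching_library(library_spec(n_positive = 12, n_negative = 13,
                                                jitter_sigma = 0.15, seed = 21), m)
  compounds <- pharmnet:::.with_seed(77, lapply(seq_along(lib$sets), function(i) {
    synthetic_compound(lib$sets[[i]], descriptor_record(
      lib$sets[[i]]$molecule_id,
      hbd_count = sample(0:6, 1), hba_count = sample(0:12, 1),
      rotatable_bonds = sample(0:14, 1), ring_count = sample(0:8, 1),
      tpsa = stats::runif(1, 0, 200)))
  }))
  cfg <- default_filter_config()
  scr <- screen_library(compounds, m, cfg)

  pass_ph <- vapply(compounds, function(c0) oracle_match(c0$features, m)$matched, FALSE)
  pass_lip <- vapply(compounds, function(c0)
    c0$descriptors$hbd_count < cfg$hbd_max && c0$descriptors$hba_count < cfg$hba_max, FALSE)
  pass_dl <- vapply(compounds, function(c0)
    c0$descriptors$rotatable_bonds <= cfg$rot_max &&
      c0$descriptors$ring_count >= cfg$ring_min &&
      c0$descriptors$ring_count <= cfg$ring_max &&
      c0$descriptors$tpsa <= cfg$tpsa_max, FALSE)
  ids <- vapply(compounds, `[[`, "", "id")
  expect_setequal(scr$hits, ids[pass_ph & pass_lip & pass_dl])

  # survivor counts monotone, and permutation invariant
  expect_true(all(diff(scr$stage_counts) <= 0))
  perm <- rev(seq_along(compounds))
  scr_p <- screen_library(compounds[perm], m, cfg)
  expect_identical(scr_p$stage_counts, scr$stage_counts)
  expect_setequal(scr_p$hits, scr$hits)
})

test_that("pharmacophore model specs round-trip through JSON", {
  m <- igf1r_model()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_pharmacophore_model(m, tmp)
  m2 <- read_pharmacophore_model(tmp)
  expect_equal(m2$features, m$features, ignore_attr = TRUE)
  expect_equal(unname(m2$distances), unname(m$distances))
})
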