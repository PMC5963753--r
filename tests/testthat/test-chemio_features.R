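# molecule I/O, feature perception and descriptors

test_that("read_library handles empty, well-formed and partly corrupt .smi", {
  tmp <- withr::local_tempfile(fileext = ".smi")

  writeLines(character(0), tmp)
  expect_length(read_library(tmp), 0L)

  writeLines("CCO ethanol", tmp)
  lib <- read_library(tmp)
  expect_length(lib, 1L)
  expect_equal(lib[[1]]$id, "ethanol")
  expect_equal(lib[[1]]$smiles, "CCO")

  good <- c("CCO m1", "c1ccccc1 m2", "CC(C)=O m3", "CCC m4", "OCC(O)CO m5",
            "CCN m6", "CCCC m7", "c1ccncc1 m8")
  bad <- c("C1CC m9", "CC((C m10")          # unclosed ring, broken branch
  writeLines(c(good[1:5], bad[1], good[6:8], bad[2]), tmp)
  expect_warning(expect_warning(lib <- read_library(tmp), "skipping line"),
                 "skipping line")
  expect_length(lib, 8L)
  expect_setequal(vapply(lib, `[[`, "", "id"), paste0("m", 1:8))
})

test_that("zero parsable entries and duplicate ids are fatal", {
  tmp <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("xx]] a", "(((( b"), tmp)
  expect_error(suppressWarnings(read_library(tmp)), "no parsable entries")
  writeLines(c("CCO a", "CCC a"), tmp)
  expect_error(read_library(tmp), "duplicate molecule ids")
})

test_that("SDF records round-trip coordinates and corrupt ones are skipped", {
  # hand-built V2000 molfile: acetone with known coordinates
  mk_molfile <- function(name, atoms, bonds) {
    c(name, "  pharmnet", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
              nrow(atoms), nrow(bonds)),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              atoms$x, atoms$y, atoms$z, atoms$el),
      sprintf("%3d%3d%3d  0  0  0  0", bonds$a1, bonds$a2, bonds$t),
      "M  END")
  }
  acetone <- mk_molfile(
    "acetone",
    data.frame(el = c("C", "C", "C", "O"),
               x = c(-1.3, 0, 1.3, 0), y = c(0.2, 0, 0.2, -1.2), z = 0),
    data.frame(a1 = c(1, 2, 2), a2 = c(2, 3, 4), t = c(1, 1, 2)))
  broken <- c("broken", "  pharmnet", "", "bad counts line", "M  END")
  tmp <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(acetone, "$$$$", broken, "$$$$"), tmp)
  expect_warning(lib <- read_library(tmp), "skipping SDF record")
  expect_length(lib, 1L)
  rec <- lib[[1]]
  expect_equal(rec$id, "acetone")
  expect_equal(rec$conformers[[1]][4, ], c(0, -1.2, 0))
  fs <- perceive_features(rec)
  expect_equal(fs$points$type, "HBA")
  expect_equal(unlist(fs$points[1, c("x", "y", "z")], use.names = FALSE),
               c(0, -1.2, 0))
})

test_that("write_library / read_library round-trips (id, smiles)", {
  lib <- lapply(c(eth = "CCO", benz = "c1ccccc1", gly = "OCC(O)CO"),
                function(s) molecule_record(paste0("id_", s), s))
  tmp <- withr::local_tempfile(fileext = ".smi")
  write_library(lib, tmp)
  back <- read_library(tmp)
  expect_equal(vapply(back, `[[`, "", "id"),
               unname(vapply(lib, `[[`, "", "id")))
  expect_equal(vapply(back, `[[`, "", "smiles"),
               unname(vapply(lib, `[[`, "", "smiles")))
})

test_that("feature perception follows the rule table", {
  # methane: no rings, no heteroatoms, cluster < 3
  expect_equal(nrow(perceive_features(molecule_record("m", "C"))$points), 0L)

  # benzene: exactly one HYD_ARO at the ring centroid
  benz <- molecule_record("benzene", "c1ccccc1")
  fs <- perceive_features(benz)
  expect_equal(fs$points$type, "HYD_ARO")
  centroid <- colMeans(pharmnet:::.ensure_conformer(benz)$conformers[[1]])
  expect_equal(as.numeric(fs$points[1, c("x", "y", "z")]), as.numeric(centroid),
               tolerance = 1e-9)

  # acetone: exactly one HBA at the carbonyl oxygen
  ac <- molecule_record("acetone", "CC(C)=O")
  fsa <- perceive_features(ac)
  expect_equal(fsa$points$type, "HBA")
  o_idx <- which(ac$mol$atoms$element == "O")
  expect_equal(as.numeric(fsa$points[1, c("x", "y", "z")]),
               as.numeric(pharmnet:::.ensure_conformer(ac)$conformers[[1]][o_idx, ]))

  # propane: one aliphatic-carbon cluster of size 3 -> HYD at its centroid
  fsp <- perceive_features(molecule_record("propane", "CCC"))
  expect_equal(fsp$points$type, "HYD")

  # pyridine N accepts, pyrrole NH donates but does not accept
  expect_true("HBA" %in% perceive_features(molecule_record("py", "c1ccncc1"))$points$type)
  pyr <- perceive_features(molecule_record("pyr", "c1cc[nH]c1"))
  expect_true("HBD" %in% pyr$points$type)
  expect_false("HBA" %in% pyr$points$type)

  # amide N is not an acceptor; carbonyl O is
  am <- perceive_features(molecule_record("am", "CC(=O)NC"))
  expect_equal(sum(am$points$type == "HBA"), 1L)
  expect_equal(sum(am$points$type == "HBD"), 1L)

  # missing conformer index
  expect_error(perceive_features(benz, conformer_index = 5), "does not exist")
})

test_that("descriptors match hand counts", {
  d <- compute_descriptors(molecule_record("ethane", "CC"))
  expect_equal(unlist(d[c("hbd_count", "hba_count", "rotatable_bonds",
                          "ring_count", "tpsa")], use.names = FALSE),
               c(0, 0, 0, 0, 0))

  g <- compute_descriptors(molecule_record("glycerol", "OCC(O)CO"))
  expect_equal(g$hbd_count, 3L)
  expect_equal(g$hba_count, 3L)
  expect_equal(g$tpsa, 3 * 20.23)

  b <- compute_descriptors(molecule_record("benzene", "c1ccccc1"))
  expect_equal(b$ring_count, 1L)
  expect_equal(b$rotatable_bonds, 0L)

  # amide C-N exclusion: N-methylacetamide has no rotatable bonds
  expect_equal(compute_descriptors(molecule_record("nma", "CC(=O)NC"))$rotatable_bonds, 0L)
  # butane: one non-terminal C-C
  expect_equal(compute_descriptors(molecule_record("bu", "CCCC"))$rotatable_bonds, 1L)
  # naphthalene: two fused rings
  expect_equal(compute_descriptors(molecule_record("naph", "c1ccc2ccccc2c1"))$ring_count, 2L)
})

test_that("feature perception is invariant under atom reordering", {
  for (smi in c("CC(C)=O", "OCC(O)CO", "c1ccncc1", "CCCC(=O)O")) {
    rec <- pharmnet:::.ensure_conformer(molecule_record("x", smi))
    n <- nrow(rec$mol$atoms)
    perm <- rev(seq_len(n))
    inv <- order(perm)
    mol2 <- rec$mol
    mol2$atoms <- mol2$atoms[perm, , drop = FALSE]
    rownames(mol2$atoms) <- NULL
    mol2$bonds$a1 <- inv[mol2$bonds$a1]
    mol2$bonds$a2 <- inv[mol2$bonds$a2]
    rec2 <- rec
    rec2$mol <- mol2
    rec2$conformers <- list(rec$conformers[[1]][perm, , drop = FALSE])
    f1 <- perceive_features(rec)$points
    f2 <- perceive_features(rec2)$points
    key <- function(df) {
      k <- paste(df$type, round(df$x, 6), round(df$y, 6), round(df$z, 6))
      sort(k)
    }
    expect_equal(key(f1), key(f2), info = smi)
  }
})

test_that("hbd equals HBD point count and hba bounds HBA point count", {
  for (smi in c("CCO", "OCC(O)CO", "CC(=O)NC", "c1cc[nH]c1", "CC(C)=O",
                "NCCO", "c1ccncc1")) {
    rec <- molecule_record("x", smi)
    d <- compute_descriptors(rec)
    fs <- perceive_features(rec)
    expect_equal(d$hbd_count, sum(fs$points$type == "HBD"), info = smi)
    expect_gte(d$hba_count, sum(fs$points$type == "HBA"))
  }
})

test_that("conformer embedding is seeded and reproduces bond geometry", {
  mol <- parse_smiles("CCO")
  c1 <- embed_conformer(mol, seed = 3)
  c2 <- embed_conformer(mol, seed = 3)
  expect_identical(c1, c2)
  # bonded distances near covalent-radius sums
  d12 <- sqrt(sum((c1[1, ] - c1[2, ])^2))
  expect_equal(d12, 2 * 0.77, tolerance = 0.05)
})
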