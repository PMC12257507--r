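test_that("loading converts Angstrom to nm and filters waters", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  three_atom_fixture(pdb, with_water = TRUE)

  cl <- load_structure(pdb)  # default policy excludes waters
  expect_equal(n_atoms(cl), 3)
  expect_equal(coords(cl),
               rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
               ignore_attr = TRUE)

  with_water <- load_structure(pdb, selection_policy(include_waters = TRUE))
  expect_equal(n_atoms(with_water), 4)
  expect_true(any(with_water$atoms$is_hetero))
})

test_that("atom counts per policy flag match a line-by-line oracle", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  rec <- rbind(
    pdb_record(1, " N  ", "ALA", "A", 1, 0, 0, 0, element = "N"),
    pdb_record(2, " H  ", "ALA", "A", 1, 0.5, 0, 0, element = "H"),
    pdb_record(3, " CA ", "ALA", "A", 1, 1, 0, 0, element = "C"),
    pdb_record(4, " CB ", "VAL", "B", 2, 2, 0, 0, element = "C"),
    pdb_record(5, "FE  ", "HEM", "B", 3, 3, 0, 0, type = "HETATM",
               element = "FE"),
    pdb_record(6, " O  ", "HOH", "B", 9, 4, 0, 0, type = "HETATM",
               element = "O")
  )
  write_fixture_pdb(pdb, rec)
  lines <- readLines(pdb)
  lines <- lines[grepl("^(ATOM|HETATM)", lines)]
  n_oracle <- function(waters, hetero, hydrogens, chain = NULL) {
    keep <- rep(TRUE, length(lines))
    is_w <- grepl("HOH", lines)
    is_h <- grepl("^HETATM", lines)
    is_hyd <- substr(lines, 77, 78) == " H"
    if (!waters) keep <- keep & !is_w
    if (!hetero) keep <- keep & !(is_h & !is_w)
    if (!hydrogens) keep <- keep & !is_hyd
    if (!is.null(chain)) keep <- keep & substr(lines, 22, 22) == chain
    sum(keep)
  }
  cases <- expand.grid(w = c(TRUE, FALSE), h = c(TRUE, FALSE),
                       hy = c(TRUE, FALSE))
  for (i in seq_len(nrow(cases))) {
    pol <- selection_policy(include_waters = cases$w[i],
                            include_hetero = cases$h[i],
                            include_hydrogens = cases$hy[i])
    expect_equal(n_atoms(load_structure(pdb, pol)),
                 n_oracle(cases$w[i], cases$h[i], cases$hy[i]),
                 info = paste(unlist(cases[i, ]), collapse = "/"))
  }
  expect_equal(n_atoms(load_structure(
    pdb, selection_policy(chains = "B", include_hetero = TRUE))),
    n_oracle(FALSE, TRUE, TRUE, chain = "B"))
})

test_that("each altloc rule picks its documented conformer", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  rec <- rbind(
    pdb_record(1, " CA ", "ALA", "A", 1, 0, 0, 0, element = "C"),
    pdb_record(2, " CB ", "ALA", "A", 1, 0.0, 10, 0, alt = "A",
               occ = 0.4, element = "C"),
    pdb_record(3, " CB ", "ALA", "A", 1, 2.0, 10, 0, alt = "B",
               occ = 0.6, element = "C")
  )
  write_fixture_pdb(pdb, rec)

  hi <- load_structure(pdb,
                       selection_policy(altloc_rule = "keep-highest-occupancy"))
  expect_equal(n_atoms(hi), 2)  # count matches a single-conformer file
  expect_equal(unname(coords(hi)[2, 1]), 0.2)  # B conformer (occ 0.6)

  first <- load_structure(pdb,
                          selection_policy(altloc_rule = "keep-first-by-label"))
  expect_equal(n_atoms(first), 2)
  expect_equal(unname(coords(first)[2, 1]), 0.0)  # A conformer

  # occupancy tie falls back to first label
  rec$occ[2:3] <- 0.5
  write_fixture_pdb(pdb, rec)
  tie <- load_structure(pdb,
                        selection_policy(altloc_rule = "keep-highest-occupancy"))
  expect_equal(unname(coords(tie)[2, 1]), 0.0)
})

test_that("describe reports counts, chains and bounding box", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  three_atom_fixture(pdb, with_water = FALSE)
  d <- describe(load_structure(pdb))
  expect_equal(d$n_atoms, 3)
  expect_equal(unname(d$bounding_box["min", ]), c(0, 0, 0))
  expect_equal(unname(d$bounding_box["max", ]), c(1, 1, 0))

  single <- atom_cloud(matrix(c(1, 2, 3), 1), element = "C")
  ds <- describe(single)
  expect_equal(unname(ds$bounding_box["max", ] - ds$bounding_box["min", ]),
               c(0, 0, 0))

  rec <- rbind(pdb_record(1, " CA ", "ALA", "A", 1, 0, 0, 0, element = "C"),
               pdb_record(2, " CA ", "GLY", "B", 2, 5, 0, 0, element = "C"))
  write_fixture_pdb(pdb, rec)
  expect_equal(describe(load_structure(pdb))$chains, c("A", "B"))
})

test_that("PDB round trip preserves coordinates to fixed-width precision", {
  set.seed(5)
  cl <- atom_cloud(matrix(runif(90, -3, 3), ncol = 3), element = "C",
                   resno = rep(1:10, each = 3), resid = "ALA")
  out <- withr::local_tempfile(fileext = ".pdb")
  write_structure(cl, out)
  back <- load_structure(out)
  expect_equal(n_atoms(back), n_atoms(cl))
  expect_lt(max(abs(coords(back) - coords(cl))), 1e-4 + 1e-12)
})

test_that("loading is deterministic and errors are informative", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  three_atom_fixture(pdb)
  a <- load_structure(pdb)
  b <- load_structure(pdb)
  expect_identical(a$atoms, b$atoms)

  expect_error(load_structure(file.path(tempdir(), "absent.pdb")),
               "not found")
  only_water <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(only_water,
                    pdb_record(1, " O  ", "HOH", "A", 1, 0, 0, 0,
                               type = "HETATM", element = "O"))
  expect_error(load_structure(only_water), "empty selection")
  expect_error(selection_policy(model_index = 0), "positive")
})
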