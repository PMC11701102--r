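test_that("write/read round-trip preserves atoms to PDB column precision", {
  ring <- make_ring(n_spokes = 14, noise_sd = 0.3, seed = 7, decorated = TRUE)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ring$model, f)
  back <- read_structure(f)
  expect_equal(nrow(back$atoms), nrow(ring$model$atoms))
  expect_equal(back$atoms$chain, ring$model$atoms$chain)
  expect_equal(back$atoms$resno, ring$model$atoms$resno)
  expect_equal(back$atoms$atom, ring$model$atoms$atom)
  expect_equal(back$atoms$x, ring$model$atoms$x, tolerance = 1e-3)
  expect_equal(back$atoms$y, ring$model$atoms$y, tolerance = 1e-3)
  expect_equal(back$atoms$z, ring$model$atoms$z, tolerance = 1e-3)
  # and against generator truth (noise-free anchors + stored noise)
  anchors <- extract_anchors(back, chains = ring$chains)
  expect_equal(anchors$points, ring$anchors$points,
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("generated ring file parses into one single-atom chain per spoke", {
  ring <- make_ring(n_spokes = 14, seed = 1)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ring$model, f)
  m <- read_structure(f)
  expect_identical(length(unique(m$atoms$chain)), 14L)
  expect_identical(as.integer(table(m$atoms$chain)), rep(1L, 14))
})

test_that("only MODEL 1 of a multi-model PDB is read, altloc A kept, b-factors formatted", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  N   ALA A  12      11.104  13.207   2.100  1.00 20.00           N",
    "ATOM      2  CA  ALA A  12      12.560  13.300   2.200  1.00100.00           C",
    "ATOM      3  CA ALEU A  13      13.000  14.000   3.000  0.50 10.00           C",
    "ATOM      4  CA BLEU A  13      13.500  14.500   3.500  0.50 10.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ALA A  12      99.000  99.000  99.000  1.00 20.00           N",
    "ENDMDL",
    "END"), f)
  m <- suppressWarnings(read_structure(f))
  expect_equal(nrow(m$atoms), 3L)            # MODEL 2 and altloc B dropped
  expect_false(any(m$atoms$x > 90))
  expect_equal(m$atoms$x[m$atoms$resno == 13], 13.0)
  # b-factor of 100 written back with two decimals in columns 61-66
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f2)
  ln <- grep("^ATOM", readLines(f2), value = TRUE)
  expect_identical(substr(ln[2], 61, 66), "100.00")
})

test_that("mmCIF atom_site loops are read with author numbering", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_test", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . GLN A 1 1 ? 11.104 13.207 2.100 1.00 20.00 ? 12 GLN G N 1",
    "ATOM 2 C CA . GLN A 1 1 ? 12.560 13.300 2.200 1.00 21.50 ? 12 GLN G CA 1"), f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 2L)
  expect_identical(unique(m$atoms$chain), "G")
  expect_identical(unique(m$atoms$resno), 12L)
  expect_equal(m$atoms$x[m$atoms$atom == "CA"], 12.560)
})

test_that("read errors name the offending path or condition", {
  expect_error(read_structure("/nonexistent/file.pdb"), "does not exist")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK empty", "END"), f)
  expect_error(suppressWarnings(read_structure(f)), "atoms|parse")
})

test_that("select_atoms matches all criteria, preserves order, is idempotent", {
  ring <- make_ring(n_spokes = 8, seed = 3, decorated = TRUE)
  m <- ring$model
  sel <- selection(chains = "A", residues = 12, atoms = "CA")
  hit <- select_atoms(m, sel)
  expect_equal(nrow(hit), 1L)
  expect_equal(as.numeric(hit[1, c("x", "y", "z")]),
               as.numeric(ring$anchors$points[1, ]))
  # empty criteria -> all (protein heavy) atoms
  expect_equal(nrow(select_atoms(m)), nrow(m$atoms))
  # range selection counts match what the generator placed there
  in_range <- select_atoms(m, selection(residues = c(13, 20), atoms = "CA"))
  expect_equal(nrow(in_range), 8 * 8)  # 8 decorated residues per spoke
  # idempotence
  again <- select_atoms(m, sel)
  expect_identical(hit, again)
  # empty result is valid, not an error
  expect_equal(nrow(select_atoms(m, selection(chains = "ZZ"))), 0L)
})

test_that("HETATM, waters and hydrogens are excluded from defaults but readable", {
  m <- fixture_model(
    list(chain = "A", resno = 1, resname = "ALA", atom = "CA", element = "C",
         xyz = c(0, 0, 0)),
    list(chain = "A", resno = 2, resname = "HOH", atom = "O", element = "O",
         xyz = c(5, 0, 0), het = TRUE),
    list(chain = "A", resno = 1, resname = "ALA", atom = "HA", element = "H",
         xyz = c(1, 0, 0)))
  expect_equal(nrow(select_atoms(m)), 1L)
  expect_equal(nrow(select_atoms(m, include_het = TRUE)), 3L)
})

test_that("structure_model validates invariants", {
  bad <- fixture_atoms(
    list(chain = "A", resno = 1, resname = "ALA", atom = "CA",
         element = "C", xyz = c(0, 0, 0)),
    list(chain = "A", resno = 1, resname = "ALA", atom = "CA",
         element = "C", xyz = c(1, 1, 1)))
  expect_error(structure_model(bad), "duplicate")
  bad2 <- fixture_atoms(list(chain = "A", resno = 1, resname = "ALA",
                             atom = "CA", element = "C", xyz = c(0, 0, 0)))
  bad2$occ <- 1.5
  expect_error(structure_model(bad2), "occupanc")
})

test_that("set_bfactor paints per-residue values into the b column", {
  ring <- make_ring(n_spokes = 4, seed = 2, decorated = TRUE)
  vals <- rep(NA_real_, 20)
  vals[13] <- 62.5
  painted <- set_bfactor(ring$model, vals, missing_value = -1)
  expect_true(all(painted$atoms$b[painted$atoms$resno == 13] == 62.5))
  expect_true(all(painted$atoms$b[painted$atoms$resno != 13] == -1))
})
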