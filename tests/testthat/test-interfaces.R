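# constructed two-chain fixtures with hand-computed distances

test_that("distant atoms yield no contacts", {
  m <- fixture_model(
    list(chain = "A", resno = 1, resname = "ALA", atom = "N", element = "N",
         xyz = c(0, 0, 0)),
    list(chain = "B", resno = 2, resname = "ALA", atom = "O", element = "O",
         xyz = c(10, 0, 0)))
  expect_equal(nrow(find_contacts(m, "A", "B")), 0L)
})

test_that("a backbone N...O pair at 2.9 A is one backbone-backbone hydrogen bond", {
  m <- fixture_model(
    list(chain = "A", resno = 234, resname = "THR", atom = "N",
         element = "N", xyz = c(0, 0, 0)),
    list(chain = "A", resno = 234, resname = "THR", atom = "CA",
         element = "C", xyz = c(1.5, 0, 0)),
    list(chain = "B", resno = 500, resname = "VAL", atom = "O",
         element = "O", xyz = c(0, 2.9, 0)),
    list(chain = "B", resno = 500, resname = "VAL", atom = "C",
         element = "C", xyz = c(0, 4.2, 0)))
  ct <- find_contacts(m, "A", "B")
  expect_equal(nrow(ct), 1L)
  expect_identical(ct$kind, "hbond_backbone_backbone")
  expect_equal(ct$distance, 2.9, tolerance = 1e-9)
  expect_identical(c(ct$resno1, ct$resno2), c(234L, 500L))
})

test_that("sidechain hydrogen bonds and salt bridges classify with precedence", {
  m <- fixture_model(
    # Thr OG1 vs Asp OD1 at 3.0: sidechain hbond (O..O, not a salt bridge pair)
    list(chain = "A", resno = 236, resname = "THR", atom = "OG1",
         element = "O", xyz = c(0, 0, 0)),
    list(chain = "B", resno = 497, resname = "ASP", atom = "OD1",
         element = "O", xyz = c(3.0, 0, 0)),
    # Lys NZ vs Glu OE1 at 3.2: within both hbond and salt cutoffs -> salt wins
    list(chain = "A", resno = 300, resname = "LYS", atom = "NZ",
         element = "N", xyz = c(0, 20, 0)),
    list(chain = "B", resno = 400, resname = "GLU", atom = "OE1",
         element = "O", xyz = c(3.2, 20, 0)))
  ct <- find_contacts(m, "A", "B")
  expect_equal(nrow(ct), 2L)
  expect_identical(ct$kind[ct$resno1 == 236], "hbond_sidechain")
  expect_identical(ct$kind[ct$resno1 == 300], "salt_bridge")
  # histidine donor is switchable
  m2 <- fixture_model(
    list(chain = "A", resno = 10, resname = "HIS", atom = "NE2",
         element = "N", xyz = c(0, 0, 0)),
    list(chain = "B", resno = 20, resname = "ASP", atom = "OD2",
         element = "O", xyz = c(3.4, 0, 0)))
  expect_identical(find_contacts(m2, "A", "B")$kind, "salt_bridge")
  no_his <- contact_criteria(his_salt_bridge = FALSE)
  expect_identical(find_contacts(m2, "A", "B", no_his)$kind,
                   "hbond_sidechain")
})

test_that("contact lists are symmetric in chain order and monotone in cutoffs", {
  set.seed(4)
  # two short strands of mixed residues a few Angstrom apart
  mk <- function(chain, x0) {
    lapply(1:4, function(i) {
      res <- c("LEU", "LYS", "ASP", "THR")[i]
      at <- c("CD1", "NZ", "OD1", "OG1")[i]
      el <- c("C", "N", "O", "O")[i]
      list(chain = chain, resno = i, resname = res, atom = at, element = el,
           xyz = c(x0, i * 3.0, rnorm(1, sd = 0.3)))
    })
  }
  m <- do.call(fixture_model, c(mk("A", 0), mk("B", 3.3)))
  ab <- find_contacts(m, "A", "B")
  ba <- find_contacts(m, "B", "A")
  expect_equal(nrow(ab), nrow(ba))
  key_ab <- sort(paste(ab$resno1, ab$atom1, ab$resno2, ab$atom2, ab$kind))
  key_ba <- sort(paste(ba$resno2, ba$atom2, ba$resno1, ba$atom1, ba$kind))
  expect_identical(key_ab, key_ba)
  # enlarging a cutoff never removes contacts of that kind
  wide <- find_contacts(m, "A", "B", contact_criteria(hydrophobic_max = 6))
  expect_true(all(
    paste(ab$atom1, ab$atom2)[ab$kind == "hydrophobic"] %in%
      paste(wide$atom1, wide$atom2)[wide$kind == "hydrophobic"]))
  expect_gte(sum(wide$kind == "hydrophobic"), sum(ab$kind == "hydrophobic"))
  # distances recomputable from coordinates
  for (i in seq_len(nrow(ab))) {
    a1 <- m$atoms[m$atoms$chain == "A" & m$atoms$resno == ab$resno1[i] &
                    m$atoms$atom == ab$atom1[i], ]
    a2 <- m$atoms[m$atoms$chain == "B" & m$atoms$resno == ab$resno2[i] &
                    m$atoms$atom == ab$atom2[i], ]
    d <- sqrt((a1$x - a2$x)^2 + (a1$y - a2$y)^2 + (a1$z - a2$z)^2)
    expect_equal(ab$distance[i], d, tolerance = 1e-6)
  }
})

test_that("missing chains raise errors", {
  m <- fixture_model(list(chain = "A", resno = 1, resname = "ALA",
                          atom = "CA", element = "C", xyz = c(0, 0, 0)))
  expect_error(find_contacts(m, "A", "Q"), "chain 'Q'")
})

test_that("a phenylalanine probe finds its constructed hydrophobic pocket", {
  # Phe side-chain ring carbon surrounded by three Leu CD1 atoms at 4.0 A
  # and one polar Ser OG that must not appear in the pocket
  m <- fixture_model(
    list(chain = "A", resno = 721, resname = "PHE", atom = "CZ",
         element = "C", xyz = c(0, 0, 0)),
    list(chain = "A", resno = 721, resname = "PHE", atom = "CA",
         element = "C", xyz = c(0, 0, 5)),
    list(chain = "B", resno = 10, resname = "LEU", atom = "CD1",
         element = "C", xyz = c(4.0, 0, 0)),
    list(chain = "B", resno = 20, resname = "LEU", atom = "CD1",
         element = "C", xyz = c(-4.0, 0, 0)),
    list(chain = "B", resno = 30, resname = "LEU", atom = "CD1",
         element = "C", xyz = c(0, 4.0, 0)),
    list(chain = "B", resno = 40, resname = "SER", atom = "OG",
         element = "O", xyz = c(0, -3.0, 0)))
  pk <- pocket_contacts(m, "A", 721, "B")
  expect_identical(sort(pk$pocket$resno), c(10L, 20L, 30L))
  expect_true(all(pk$pocket$apolar))
  expect_true(all(pk$contacts$atom1 == "CZ"))
  # probe with nothing in range
  far <- pocket_contacts(m, "A", 721, "B",
                         contact_criteria(hydrophobic_max = 1))
  expect_equal(nrow(far$contacts), 0L)
  expect_error(pocket_contacts(m, "A", 999, "B"), "residue 999")
})
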