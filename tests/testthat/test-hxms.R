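test_that("uptake fraction implements the two-control back-exchange correction", {
  expect_equal(as.numeric(uptake_fraction(1000, 1000, 1010)), 0)
  expect_equal(as.numeric(uptake_fraction(1010, 1000, 1010)), 1)
  expect_equal(as.numeric(uptake_fraction(1005, 1000, 1010)), 0.5)
  # clamped with raw value retained
  u <- uptake_fraction(1011, 1000, 1010)
  expect_equal(as.numeric(u), 1)
  expect_equal(attr(u, "raw"), 1.1)
  expect_error(uptake_fraction(1005, 1000, 1000), "m100 must exceed m0")
})

pep <- function(id, start, end, m0, m_t, m100, charge = 2L) {
  data.frame(peptide_id = id, start = start, end = end, sequence = "",
             condition = NA, charge = charge, m0 = m0, m_t = m_t,
             m100 = m100, stringsAsFactors = FALSE)
}

test_that("relative protection spans full protection, no protection and partial", {
  m0 <- 1000; m100 <- 1010
  b <- pep("p", 1, 10, m0, m0 + 4.0, m100)      # baseline 40 %
  cases <- list(
    list(lig_mt = m0 + 0.0, prot = 100, ex = 0),    # full protection
    list(lig_mt = m0 + 4.0, prot = 0, ex = 100),    # unchanged
    list(lig_mt = m0 + 3.0, prot = 25, ex = 75))    # partial
  for (cs in cases) {
    tab <- protection_table(b, pep("p", 1, 10, m0, cs$lig_mt, m100))
    expect_equal(tab$baseline_exchange, 40)
    expect_equal(tab$relative_protection, cs$prot)
    expect_equal(tab$relative_exchange, cs$ex)
  }
  # deprotection is allowed: protection negative, identity still holds
  tab <- protection_table(b, pep("p", 1, 10, m0, m0 + 5.0, m100))
  expect_lt(tab$relative_protection, 0)
  expect_equal(tab$relative_exchange + tab$relative_protection, 100,
               tolerance = 1e-9)
})

test_that("charge states are averaged per condition before scoring", {
  b <- rbind(pep("p", 1, 10, 1000, 1004, 1010, charge = 2L),
             pep("p", 1, 10, 1000, 1006, 1010, charge = 3L))
  l <- pep("p", 1, 10, 1000, 1002.5, 1010)
  tab <- protection_table(b, l)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$baseline_exchange, 50)   # mean of 40 and 60
  expect_equal(tab$relative_protection, 50)
})

test_that("the 10% baseline filter is inclusive, idempotent and non-destructive", {
  m0 <- 1000; m100 <- 1100
  b <- rbind(pep("below", 1, 5, m0, m0 + 9.9, m100),
             pep("at", 6, 10, m0, m0 + 10.0, m100),
             pep("above", 11, 15, m0, m0 + 30.0, m100))
  l <- rbind(pep("below", 1, 5, m0, m0 + 5, m100),
             pep("at", 6, 10, m0, m0 + 5, m100),
             pep("above", 11, 15, m0, m0 + 15, m100))
  tab <- protection_table(b, l)
  expect_identical(tab$shown[match(c("below", "at", "above"),
                                   tab$peptide_id)],
                   c(FALSE, TRUE, TRUE))
  expect_equal(nrow(tab), 3L)  # flagged, never deleted
  again <- apply_baseline_filter(apply_baseline_filter(tab))
  expect_identical(again$shown, tab$shown)
  stricter <- apply_baseline_filter(tab, threshold = 20)
  expect_identical(stricter$shown[stricter$peptide_id == "above"], TRUE)
  expect_equal(sum(stricter$shown), 1L)
})

test_that("synthetic tables round-trip generator truth at zero noise", {
  hx <- make_hx_tables(seed = 11, noise_sd = 0)
  tab <- protection_table(hx$baseline, hx$ligand)
  truth <- hx$truth$peptides
  ix <- match(paste(tab$start, tab$end), paste(truth$start, truth$end))
  expect_equal(tab$baseline_exchange, truth$baseline_pct[ix],
               tolerance = 1e-9)
  expect_equal(tab$relative_protection, truth$protection_pct[ix],
               tolerance = 1e-9)
  expect_identical(tab$shown, truth$shown[ix])
  # a peptide built with 5% true baseline is flagged not shown
  low <- make_hx_tables(protein_length = 20, peptide_length = 10,
                        peptide_step = 10,
                        baseline_profile = rep(5, 20),
                        protection_profile = rep(50, 20), seed = 1)
  lt <- protection_table(low$baseline, low$ligand)
  expect_false(any(lt$shown))
})

test_that("residue consolidation averages overlapping shown peptides", {
  m0 <- 1000; m100 <- 1010
  b <- rbind(pep("p1", 5, 8, m0, m0 + 4, m100),
             pep("p2", 7, 10, m0, m0 + 4, m100))
  l <- rbind(pep("p1", 5, 8, m0, m0 + 2.4, m100),    # rel exchange 60
             pep("p2", 7, 10, m0, m0 + 3.2, m100))   # rel exchange 80
  tab <- protection_table(b, l)
  cons <- residue_consolidation(tab, length = 12)
  expect_equal(cons$value[5:6], c(60, 60))
  expect_equal(cons$value[7:8], c(70, 70))
  expect_equal(cons$value[9:10], c(80, 80))
  expect_true(all(is.na(cons$value[c(1:4, 11:12)])))
  expect_identical(cons$covered, c(rep(FALSE, 4), rep(TRUE, 6),
                                   rep(FALSE, 2)))
  # constant-protection profile consolidates to that constant
  hx <- make_hx_tables(protein_length = 40, baseline_profile = rep(50, 40),
                       protection_profile = rep(30, 40), seed = 2)
  ct <- residue_consolidation(protection_table(hx$baseline, hx$ligand), 40)
  expect_equal(unique(round(ct$value[ct$covered], 9)), 70)
  # generator truth for the default overlapping plan, via analytic means
  hx2 <- make_hx_tables(seed = 11)
  tab2 <- protection_table(hx2$baseline, hx2$ligand)
  cons2 <- residue_consolidation(tab2, 100)
  truth2 <- hx2$truth$peptides
  shown <- truth2[truth2$shown, ]
  for (res in c(10, 45, 77)) {
    cover <- shown[shown$start <= res & shown$end >= res, ]
    if (nrow(cover) > 0) {
      expect_equal(cons2$value[res], mean(cover$relative_exchange),
                   tolerance = 1e-9)
    }
  }
})

test_that("exchange tables read from disk with required-column validation", {
  hx <- make_hx_tables(seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(hx$baseline, f, sep = "\t", row.names = FALSE, quote = FALSE)
  tab <- read_hx_table(f)
  expect_equal(nrow(tab), nrow(hx$baseline))
  expect_equal(tab$m_t, hx$baseline$m_t)
  bad <- withr::local_tempfile(fileext = ".tsv")
  write.table(hx$baseline[, 1:4], bad, sep = "\t", row.names = FALSE)
  expect_error(read_hx_table(bad), "lacks columns")
})
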