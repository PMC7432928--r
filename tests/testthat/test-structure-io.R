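test_that("a toy complex round-trips through PDB text to 3 decimals", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_complex(toy_docked, f)
  back <- read_complex(f)
  expect_equal(nrow(back$atom), nrow(toy_docked$atom))
  expect_equal(back$atom$elety, toy_docked$atom$elety)
  expect_equal(back$atom$resid, toy_docked$atom$resid)
  expect_equal(back$atom$uid, toy_docked$atom$uid)
  expect_equal(as.matrix(back$atom[, c("x", "y", "z")]),
               as.matrix(toy_docked$atom[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_identical(back$partner1, "A")
  expect_identical(back$partner2, "B")
})

test_that("multi-model files default to model 1 and honour the index", {
  f1 <- withr::local_tempfile(fileext = ".pdb")
  write_complex(toy_docked, f1)
  lines1 <- grep("^ATOM", readLines(f1), value = TRUE)
  shifted <- toy_docked
  shifted$atom$x <- shifted$atom$x + 5
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_complex(shifted, f2)
  lines2 <- grep("^ATOM", readLines(f2), value = TRUE)
  multi <- c("MODEL     1", lines1, "ENDMDL",
             "MODEL     2", lines2, "ENDMDL", "END")
  m1 <- load_complex(multi)
  m2 <- load_complex(multi, model = 2)
  expect_equal(m1$atom$x, toy_docked$atom$x, tolerance = 1e-3)
  expect_equal(m2$atom$x, toy_docked$atom$x + 5, tolerance = 1e-3)
  expect_error(load_complex(multi, model = 3), "model")
})

test_that("composition errors name the missing partner type", {
  pep <- make_peptide("ACDEFGHIKL")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_complex(pep, f)
  expect_error(read_complex(f), "no RNA chain")
})

test_that("chain classification follows the majority of residue kinds", {
  expect_identical(classify_chain(rep(c("ALA", "GLY"), 10)), "protein")
  expect_identical(classify_chain(c("A", "U", "G", "C")), "RNA")
  expect_identical(classify_chain(c("DA", "DT", "DG")), "other")
  expect_error(classify_chain(character(0)), "empty")
  # invariant to order
  expect_identical(classify_chain(c("ALA", "A", "GLY")),
                   classify_chain(c("A", "GLY", "ALA")))
})

test_that("partner extraction is rigid and partitions the residues", {
  p1 <- extract_partner(toy_docked, 1)
  p2 <- extract_partner(toy_docked, 2)
  expect_equal(
    as.matrix(p1$atom[, c("x", "y", "z")]),
    as.matrix(toy_docked$atom[toy_docked$atom$chain == "A",
                              c("x", "y", "z")]),
    tolerance = 0, ignore_attr = TRUE)
  expect_equal(nrow(residue_table(p1)) + nrow(residue_table(p2)),
               nrow(residue_table(toy_docked)))
  expect_error(extract_partner(p1, 2), "empty")
})

test_that("alternate locations resolve to the highest-occupancy copy", {
  txt <- c(
    "ATOM      1  N   ALA A   1      11.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      4  C   ALA A   1       3.000   0.000   0.000  1.00  0.00           C",
    "ATOM      5  O   ALA A   1       4.000   0.000   0.000  1.00  0.00           O",
    "ATOM      6  CB  ALA A   1       5.000   0.000   0.000  1.00  0.00           C",
    "ATOM      7  P     U B   1       8.000   0.000   0.000  1.00  0.00           P",
    "END")
  cx <- load_complex(txt)
  ca <- cx$atom[cx$atom$elety == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 2.000)  # the 0.60-occupancy B copy wins
})

test_that("waters are stripped and chain typing ignores them", {
  txt <- c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       3.100   1.900   0.000  1.00  0.00           O",
    "ATOM      5  P     A B   1       9.000   0.000   0.000  1.00  0.00           P",
    "HETATM    6  O   HOH A 100      20.000  20.000  20.000  1.00  0.00           O",
    "END")
  cx <- load_complex(txt)
  expect_false(any(cx$atom$resid == "HOH"))
  expect_identical(cx$chains$type[cx$chains$chain == "A"], "protein")
})

test_that("missing side-chain atoms are reported and rebuildable", {
  cx <- toy_docked
  # drop one side-chain atom
  drop_row <- which(cx$atom$elety == "CB" & cx$atom$resno == 5 &
                      cx$atom$chain == "A")[1]
  cx$atom <- cx$atom[-drop_row, ]
  miss <- find_missing_atoms(cx)
  expect_true(any(miss$uid == "A:5:" & miss$atom == "CB"))
  fixed <- complete_residues(cx)
  expect_equal(nrow(find_missing_atoms(fixed)), 0)
  # untouched residues keep their coordinates
  other <- fixed$atom$uid != "A:5:"
  expect_identical(fixed$atom$x[other],
                   cx$atom$x[cx$atom$uid != "A:5:"])
})
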