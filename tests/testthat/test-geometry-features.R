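test_that("docked complexes have RNA-facing interface residues, separated ones none", {
  ifr <- interface_residues(toy_docked)
  expect_gt(length(ifr), 0)
  expect_gt(n_inter(toy_docked), 0)
  expect_identical(interface_residues(toy_far), character(0))
  expect_identical(n_inter(toy_far), 0L)
  expect_lte(n_inter(toy_docked),
             sum(residue_table(toy_docked)$kind == "amino-acid"))
})

test_that("interface membership is brute-force SASA burial and order-invariant", {
  s_cx <- compute_sasa(toy_docked)$residue_area
  s_p1 <- compute_sasa(extract_partner(toy_docked, 1))$residue_area
  s_p2 <- compute_sasa(extract_partner(toy_docked, 2))$residue_area
  unb <- c(s_p1, s_p2)
  oracle <- names(unb)[unb - s_cx[names(unb)] > 0.1]
  expect_setequal(interface_residues(toy_docked), oracle)
  # permute chain order in the atom table
  perm <- toy_docked
  perm$atom <- perm$atom[order(perm$atom$chain == "A"), ]
  perm <- priddg:::new_pri_complex(perm$atom, "A", "B")
  expect_setequal(interface_residues(perm), interface_residues(toy_docked))
})

test_that("length/surface ratio follows its arithmetic definition", {
  prot <- extract_partner(toy_docked, 1)
  r <- ratio_length_sasa(prot)
  expect_equal(r, 12 / compute_sasa(prot)$total)
  # invariant under rigid rotation
  rot <- prot
  xyz <- as.matrix(rot$atom[, c("x", "y", "z")])
  th <- 1.1
  R <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3)
  xyz <- xyz %*% R
  rot$atom$x <- xyz[, 1]; rot$atom$y <- xyz[, 2]; rot$atom$z <- xyz[, 3]
  expect_equal(ratio_length_sasa(rot), r, tolerance = 5e-3)
})

test_that("duplicating the chain far away leaves the ratio unchanged within 1%", {
  prot <- extract_partner(toy_docked, 1)
  dup <- prot$atom
  dup$chain <- "C"
  dup$x <- dup$x + 200
  both <- priddg:::new_pri_complex(rbind(prot$atom, dup), c("A", "C"),
                                   character(0))
  expect_lt(abs(ratio_length_sasa(both) / ratio_length_sasa(prot) - 1),
            0.01)
})

test_that("delta SA is zero for identical structures and negative for Trp to Ala", {
  expect_equal(delta_sa(toy_docked, toy_docked, "A:6:"), 0)
  seqs <- chain_sequence(toy_docked, "A")
  # put a Trp at an exposed site, then shrink it to Ala
  w_cx <- build_mutant(toy_docked, paste0("A:", substr(seqs, 6, 6), "6W"))
  a_cx <- build_mutant(w_cx, "A:W6A")
  expect_lt(delta_sa(w_cx, a_cx, "A:6:"), 0)
  expect_error(delta_sa(toy_docked, toy_docked, "A:99:"), "not in")
})

test_that("delta SA is identical for the complex and the pre-extracted protein", {
  p1 <- extract_partner(toy_docked, 1)
  seqs <- chain_sequence(toy_docked, "A")
  mut <- build_mutant(toy_docked, paste0("A:", substr(seqs, 6, 6), "6A"))
  mut_p1 <- extract_partner(mut, 1)
  expect_equal(delta_sa(toy_docked, mut, "A:6:"),
               delta_sa(p1, mut_p1, "A:6:"))
})

test_that("ideal helices, extended chains and tiny chains get the right labels", {
  hel <- make_peptide("AAAAAAAAAAAA", "helix")
  ss <- assign_secondary_structure(hel)
  expect_true(all(ss$label[3:9] == "helix"))
  ext <- make_peptide("AAAAAAAAAAAA", "extended")
  expect_true(all(assign_secondary_structure(ext)$label == "coil"))
  tiny <- make_peptide("AAA", "helix")
  expect_true(all(assign_secondary_structure(tiny)$label == "coil"))
})

test_that("an ideal antiparallel hairpin contains strand residues", {
  hp <- make_peptide("AVAVAVAVAVAVAV", "hairpin")
  ss <- assign_secondary_structure(hp)
  expect_gt(sum(ss$label == "strand"), 3)
})

test_that("Pcoil counts exposed coil residues against brute-force classification", {
  cx <- toy_docked
  sasa <- compute_sasa(cx)
  ss <- assign_secondary_structure(cx)
  rt <- residue_table(cx)
  uids <- rt$uid[rt$chain == "A" & rt$kind == "amino-acid"]
  ref <- max_asa_table()[rt$res1[match(uids, rt$uid)]]
  exposed <- sasa$residue_area[uids] / ref > 0.25
  coil <- ss$label[match(uids, ss$uid)] == "coil"
  expect_equal(p_coil(cx, "A"), sum(exposed & coil) / length(uids))
  # an all-helix fully buried chain scores zero: use the helical peptide's
  # own helical core by restricting exposure with a tiny threshold
  hel <- make_peptide("LLLLLLLLLLLL", "helix")
  expect_equal(p_coil(hel, "A", ss = within(assign_secondary_structure(hel),
                                            label <- "helix")), 0)
})

test_that("a fully extended solvated chain's Pcoil equals its coil fraction", {
  ext <- make_peptide("AAAAAAAAAAAA", "extended")
  ss <- assign_secondary_structure(ext)
  expect_equal(p_coil(ext, "A"), mean(ss$label == "coil"))
})
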