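params <- ff_params()

test_that("neutral residues carry zero net charge and LJ parameters exist", {
  at <- params$atoms
  sums <- tapply(at$charge, at$resid, sum)
  formal <- ifelse(names(sums) %in% c("ASP", "GLU", "A", "C", "G", "U"), -1,
                   ifelse(names(sums) %in% c("LYS", "ARG"), 1, 0))
  expect_true(all(abs(sums - formal) < 0.01))
  expect_true(all(params$types$epsilon >= 0))
})

test_that("two identical atoms at the LJ minimum give exactly -epsilon", {
  cx <- complex_from_atoms(list(
    list("CB", "ALA", "A", 1, c(0, 0, 0), "amino-acid"),
    list("CB", "ALA", "A", 2, c(4.0, 0, 0), "amino-acid")))
  ty <- type_atoms(cx, params)
  expect_equal(lj_energy(cx, 1, 2, params), -ty$epsilon[1], tolerance = 1e-12)
  far <- complex_from_atoms(list(
    list("CB", "ALA", "A", 1, c(0, 0, 0), "amino-acid"),
    list("CB", "ALA", "A", 2, c(500, 0, 0), "amino-acid")))
  expect_lt(abs(lj_energy(far, 1, 2, params)), 1e-10)
  expect_error(lj_energy(cx, 1, 1, params), "disjoint")
})

test_that("LJ, repulsive and Coulomb sums match brute-force double loops", {
  ia <- which(toy_docked$atom$chain == "A")
  ib <- which(toy_docked$atom$chain == "B")
  expect_equal(lj_energy(toy_docked, ia, ib, params),
               oracle_lj(toy_docked, ia, ib, params), tolerance = 1e-8)
  site <- "A:6:"
  is_site <- which(toy_docked$atom$uid == site)
  expect_equal(lj_repulsive_energy(toy_docked, site, params),
               oracle_lj_rep(toy_docked, is_site, ib, params),
               tolerance = 1e-8)
  cs <- contact_set(toy_docked, site)
  ic <- which(toy_docked$atom$uid %in% cs)
  expect_equal(elec_energy(toy_docked, site, cs, params),
               oracle_coulomb(toy_docked, is_site, ic, params),
               tolerance = 1e-8)
})

test_that("two unit charges at 3.32 A give the textbook Coulomb energy", {
  # NZ of LYS carries +0.75 in the bundled set; use explicit charges via a
  # one-off parameter table to realize exactly +1/+1
  cx <- complex_from_atoms(list(
    list("NZ", "LYS", "A", 1, c(0, 0, 0), "amino-acid"),
    list("NZ", "LYS", "A", 2, c(3.32, 0, 0), "amino-acid")))
  ty <- data.frame(epsilon = c(0.2, 0.2), rmin_half = c(1.85, 1.85),
                   charge = c(1, 1))
  e <- elec_energy(cx, "A:1:", "A:2:", params, typed = ty)
  expect_equal(e, 332.0716 * 1 * 1 / 3.32, tolerance = 1e-12)
  expect_equal(round(e, 2), 100.02)
  ty0 <- ty; ty0$charge <- c(0, 0)
  expect_equal(elec_energy(cx, "A:1:", "A:2:", params, typed = ty0), 0)
})

test_that("contact sets are symmetric and match an all-pairs oracle", {
  rt <- residue_table(toy_docked)
  sites <- rt$uid[rt$kind == "amino-acid"]
  a <- toy_docked$atom
  xyz <- as.matrix(a[, c("x", "y", "z")])
  sc_idx <- function(uid) {
    w <- which(a$uid == uid & a$is_sidechain)
    if (length(w) == 0) w <- which(a$uid == uid & a$elety == "CA")
    w
  }
  oracle_contacts <- function(site) {
    out <- character(0)
    for (uid in unique(a$uid)) {
      if (uid == site) next
      dmin <- Inf
      for (i in sc_idx(site)) for (j in sc_idx(uid))
        dmin <- min(dmin, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
      if (dmin < 10) out <- c(out, uid)
    }
    out
  }
  for (site in sites[c(1, 6, 12)]) {
    expect_setequal(contact_set(toy_docked, site), oracle_contacts(site))
  }
  # symmetry on a residue pair
  expect_true("A:6:" %in% contact_set(toy_docked, "A:5:") ==
                ("A:5:" %in% contact_set(toy_docked, "A:6:")))
  # isolation
  far_site <- complex_from_atoms(list(
    list("CB", "ALA", "A", 1, c(500, 0, 0), "amino-acid"),
    list("CB", "ALA", "A", 2, c(0, 0, 0), "amino-acid")))
  expect_identical(contact_set(far_site, "A:1:"), character(0))
})

test_that("delta-delta energy terms vanish for identical structures", {
  expect_equal(dd_evdw(toy_docked, toy_docked, params), 0)
  expect_equal(dd_evdw_rep(toy_docked, toy_docked, "A:6:", params), 0)
  expect_equal(dd_eelec(toy_docked, toy_docked, "A:6:", params), 0)
})

test_that("cross-partner LJ equals the complex-minus-partners difference", {
  ia <- which(toy_docked$atom$chain == "A")
  ib <- which(toy_docked$atom$chain == "B")
  expect_equal(cross_partner_vdw(toy_docked, params),
               oracle_lj(toy_docked, ia, ib, params), tolerance = 1e-8)
})

test_that("energies are invariant under rigid-body rotation", {
  rot <- toy_docked
  xyz <- as.matrix(rot$atom[, c("x", "y", "z")])
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz2 <- xyz %*% R
  rot$atom$x <- xyz2[, 1]; rot$atom$y <- xyz2[, 2]; rot$atom$z <- xyz2[, 3]
  expect_equal(cross_partner_vdw(rot, params),
               cross_partner_vdw(toy_docked, params), tolerance = 1e-8)
  expect_equal(lj_repulsive_energy(rot, "A:6:", params),
               lj_repulsive_energy(toy_docked, "A:6:", params),
               tolerance = 1e-8)
})

test_that("site-RNA repulsion grows when the RNA moves toward the site", {
  base <- make_toy_complex(8, 4, "helix", separation = 6, seed = 3)
  closer <- base
  bidx <- closer$atom$chain == "B"
  # move the RNA 0.5 A along the -y direction (toward the peptide)
  closer$atom$y[bidx] <- closer$atom$y[bidx] - 0.5
  site <- residue_table(base)$uid[4]
  expect_gt(lj_repulsive_energy(closer, site, params),
            lj_repulsive_energy(base, site, params))
})

test_that("glycine mutation reduces site-RNA repulsion magnitude", {
  rt <- residue_table(toy_docked)
  ifr <- interface_residues(toy_docked)
  site <- intersect(ifr, rt$uid[rt$kind == "amino-acid" &
                                  !rt$res1 %in% c("G", "A")])[1]
  wt1 <- rt$res1[rt$uid == site]
  pos <- rt$resno[rt$uid == site]
  mut <- build_mutant(toy_docked, paste0("A:", wt1, pos, "G"))
  expect_lte(lj_repulsive_energy(mut, site, params),
             lj_repulsive_energy(toy_docked, site, params))
})
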