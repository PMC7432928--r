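# Deterministic toy-structure and synthetic-dataset generators.
#
# Toy complexes are ideal-geometry peptides (helix, extended strand or a
# two-stranded antiparallel hairpin) docked against an idealized A-form
# single-stranded RNA at a chosen separation.  They are small, valid,
# fully standard-residue structures that exercise every feature module
# without any external input.  The synthetic dataset emulates the
# statistical shape of the curated training set (about 50 complexes with
# ~5 mutations each and residual noise sigma ~0.76 kcal/mol) for testing
# the regression and cross-validation machinery.

#' @noRd
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @noRd
# Backbone dihedral sets for the peptide geometries
.geometry_phipsi <- function(geometry, n) {
  if (geometry == "helix") {
    list(phi = rep(-57, n), psi = rep(-47, n))
  } else if (geometry == "extended") {
    list(phi = rep(-139, n), psi = rep(135, n))
  } else stop("unknown geometry: ", geometry)
}

#' @noRd
# Build peptide backbone (N, CA, C, O per residue) from phi/psi, omega=180.
.build_backbone <- function(phi, psi) {
  n <- length(phi)
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- place_atom(c(0, 1, 0), N[1, ], CA[1, ], 1.525, 111.0, -60)
  for (i in 2:max(2, n)) {
    if (i > n) break
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         1.329, 116.2, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          1.458, 121.7, 180)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.0, phi[i])
  }
  for (i in seq_len(n)) {
    ref_psi <- if (i < n) psi[i] else psi[i]
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.5,
                         ref_psi + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

#' @noRd
.atoms_row <- function(elety, resid, chain, resno, xyz, kind) {
  data.frame(type = "ATOM", eleno = NA_integer_, elety = elety,
             resid = resid, chain = chain, resno = resno,
             insert = NA_character_, x = xyz[1], y = xyz[2], z = xyz[3],
             o = 1, elesy = .element_from_name(elety), kind = kind,
             res1 = .res1_code(resid),
             is_sidechain = .is_sidechain_atom(elety, kind),
             stringsAsFactors = FALSE)
}

#' @noRd
# peptide atom data frame for a 1-letter sequence and geometry
.build_peptide_atoms <- function(seq1, geometry, chain = "A",
                                 resno_start = 1L) {
  s <- strsplit(seq1, "")[[1]]
  n <- length(s)
  if (geometry == "hairpin") {
    # two antiparallel extended strands; the second is the first rotated
    # 180 degrees about z, rolled about x and offset to the placement that
    # realizes the cross-strand backbone hydrogen-bond registry
    n1 <- ceiling(n / 2)
    n2 <- n - n1
    bb1 <- .build_backbone(rep(-139, n1), rep(135, n1))
    bb2 <- .build_backbone(rep(-139, n2), rep(135, n2))
    place2 <- function(m) {
      m2 <- rotate_about_axis(m, c(0, 0, 1), pi)
      m2 <- rotate_about_axis(m2, c(1, 0, 0), 4.31969)
      sweep(m2, 2, c(15, 9, -5), "+")
    }
    bb <- list(N = rbind(bb1$N, place2(bb2$N)),
               CA = rbind(bb1$CA, place2(bb2$CA)),
               C = rbind(bb1$C, place2(bb2$C)),
               O = rbind(bb1$O, place2(bb2$O)))
  } else {
    pp <- .geometry_phipsi(geometry, n)
    bb <- .build_backbone(pp$phi, pp$psi)
  }
  rows <- list()
  for (i in seq_len(n)) {
    r3 <- aa_123(s[i])
    resno <- resno_start + i - 1L
    rows[[length(rows) + 1]] <-
      rbind(.atoms_row("N", r3, chain, resno, bb$N[i, ], "amino-acid"),
            .atoms_row("CA", r3, chain, resno, bb$CA[i, ], "amino-acid"),
            .atoms_row("C", r3, chain, resno, bb$C[i, ], "amino-acid"),
            .atoms_row("O", r3, chain, resno, bb$O[i, ], "amino-acid"))
    sc <- .place_sidechain(r3, list(N = bb$N[i, ], CA = bb$CA[i, ],
                                    C = bb$C[i, ]))
    if (!is.null(sc)) {
      for (nm in rownames(sc))
        rows[[length(rows) + 1]] <-
          .atoms_row(nm, r3, chain, resno, sc[nm, ], "amino-acid")
    }
  }
  do.call(rbind, rows)
}

#' @noRd
# single-stranded A-form-like RNA atom data frame
.build_rna_atoms <- function(seq1, chain = "B", resno_start = 1L) {
  s <- strsplit(seq1, "")[[1]]
  twist <- deg2rad(-32.7)
  rise <- 2.81
  rows <- list()
  for (i in seq_along(s)) {
    tm <- nt_template(s[i])
    # orient: base centroid toward the helix axis (-x), C1' at radius 9.2
    gly <- if (s[i] %in% c("A", "G")) "N9" else "N1"
    base_ctr <- colMeans(tm[nt_base_atoms(s[i]), , drop = FALSE])
    v <- base_ctr - tm["C1'", ]
    ax <- cross3(v, c(-1, 0, 0))
    m <- sweep(tm, 2, tm["C1'", ])
    if (vnorm(ax) > 1e-8) {
      ang <- acos(max(-1, min(1, sum(unit(v) * c(-1, 0, 0)))))
      m <- rotate_about_axis(m, ax, ang)
    }
    m <- sweep(m, 2, c(9.2, 0, 0), "+")
    th <- (i - 1) * twist
    m <- rotate_about_axis(m, c(0, 0, 1), th)
    m[, 3] <- m[, 3] + (i - 1) * rise
    for (nm in rownames(tm))
      rows[[length(rows) + 1]] <-
        .atoms_row(nm, s[i], chain, resno_start + i - 1L,
                   m[rownames(tm) == nm, , drop = TRUE], "nucleotide")
  }
  do.call(rbind, rows)
}

#' Deterministic toy protein-RNA complex
#'
#' An ideal-geometry peptide (chain A) plus a single-stranded A-form-like
#' RNA (chain B) rigidly translated so the smallest protein-RNA heavy-atom
#' distance equals `separation`.  Sequences are drawn from the seed;
#' identical seeds give identical structures.
#'
#' @param n_res number of peptide residues (>= 3)
#' @param n_nt number of RNA nucleotides (>= 2)
#' @param geometry peptide geometry: "helix", "extended" or "hairpin"
#' @param separation minimal protein-RNA heavy-atom distance in Angstrom
#' @param seed integer seed controlling the sequences
#' @param protein_seq,rna_seq optional explicit sequences overriding the
#'   seeded draw
#' @return a `pri_complex`
#' @export
make_toy_complex <- function(n_res = 12, n_nt = 6, geometry = "helix",
                             separation = 4, seed = 1,
                             protein_seq = NULL, rna_seq = NULL) {
  if (n_res < 3) stop("n_res must be >= 3")
  if (n_nt < 2) stop("n_nt must be >= 2")
  if (separation <= 0) stop("separation must be positive")
  seqs <- .with_seed(seed, {
    list(p = paste(sample(setdiff(AA1, "P"), n_res, replace = TRUE),
                   collapse = ""),
         r = paste(sample(NT_CODES, n_nt, replace = TRUE), collapse = ""))
  })
  if (!is.null(protein_seq)) seqs$p <- toupper(protein_seq)
  if (!is.null(rna_seq)) seqs$r <- toupper(rna_seq)
  if (nchar(seqs$p) != n_res || nchar(seqs$r) != n_nt)
    stop("explicit sequences must match n_res / n_nt")
  pa <- .build_peptide_atoms(seqs$p, geometry)
  ra <- .build_rna_atoms(seqs$r)
  # place the RNA along +y of the peptide at the requested separation
  pxyz <- as.matrix(pa[, c("x", "y", "z")])
  rxyz <- as.matrix(ra[, c("x", "y", "z")])
  rxyz <- sweep(rxyz, 2, colMeans(rxyz))
  ctr <- colMeans(pxyz)
  dirv <- c(0, 1, 0)
  mind <- function(t) {
    rr <- sweep(rxyz, 2, ctr + t * dirv, "+")
    min(.pair_dist(pxyz, rr))
  }
  lo <- 0; hi <- 200
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (mind(mid) < separation) lo <- mid else hi <- mid
  }
  rxyz <- sweep(rxyz, 2, ctr + hi * dirv, "+")
  ra$x <- rxyz[, 1]; ra$y <- rxyz[, 2]; ra$z <- rxyz[, 3]
  atoms <- rbind(pa, ra)
  atoms$eleno <- seq_len(nrow(atoms))
  new_pri_complex(atoms, partner1 = "A", partner2 = "B")
}

#' Toy peptide without an RNA partner
#'
#' Convenience fixture for testing secondary-structure and SASA code on a
#' lone chain.
#'
#' @param seq1 1-letter sequence
#' @param geometry "helix", "extended" or "hairpin"
#' @return a `pri_complex` with an empty partner 2
#' @export
make_peptide <- function(seq1, geometry = "helix") {
  atoms <- .build_peptide_atoms(toupper(seq1), geometry)
  atoms$eleno <- seq_len(nrow(atoms))
  new_pri_complex(atoms, partner1 = "A", partner2 = character(0))
}

# Default generative coefficients for the synthetic dataset: intercept
# followed by one coefficient per feature (natural units).  Together with
# the feature spreads below they give a signal standard deviation around
# 0.8 kcal/mol, so at noise_sd = 0.76 the true-model correlation sits in
# the realistic ~0.7 range.
SYNTH_TRUE_MODEL <- c(intercept = 0.45,
                      dd_evdw = 0.17, dd_evdw_rep = 0.085, dd_eelec = 0.021,
                      n_inter = 0.028, r_l_sa = 42, closeness = 2.1,
                      delta_sa = -0.0085, p_coil = -1.1,
                      delta_omh = -0.49, delta_p_fwy = -8.5,
                      delta_p_krde = 5.6)

#' Synthetic feature/ddG dataset grouped by complex
#'
#' Draws feature vectors with realistic spreads (complex-level centres plus
#' mutation-level scatter) and generates ddG = linear model + Gaussian
#' noise, grouped by synthetic complex id so leave-one-complex-out
#' validation is exercised.  The default shape mirrors the curated training
#' set: 50 complexes, ~5 mutations each, residual sigma 0.76 kcal/mol.
#'
#' @param true_model named vector: intercept + 11 feature coefficients
#' @param n_complexes number of synthetic complexes
#' @param muts_per_complex average mutations per complex
#' @param noise_sd residual standard deviation, kcal/mol
#' @param seed integer seed
#' @return data.frame with complex_id, mutation id, the 11 features,
#'   ddg_true (noiseless) and ddg_exp
#' @export
make_synthetic_dataset <- function(true_model = SYNTH_TRUE_MODEL,
                                   n_complexes = 50, muts_per_complex = 5,
                                   noise_sd = 0.76, seed = 1) {
  stopifnot(noise_sd >= 0, length(true_model) == 12)
  feats <- names(SYNTH_TRUE_MODEL)[-1]
  .with_seed(seed, {
    rows <- list()
    for (ci in seq_len(n_complexes)) {
      nm <- max(1, stats::rpois(1, muts_per_complex))
      # complex-level feature centres
      ctr <- c(dd_evdw = stats::rnorm(1, 0, 1.0),
               dd_evdw_rep = stats::rnorm(1, 0, 1.5),
               dd_eelec = stats::rnorm(1, 0, 4),
               n_inter = stats::runif(1, 4, 30),
               r_l_sa = stats::runif(1, 0.005, 0.012),
               closeness = stats::runif(1, 0.15, 0.45),
               delta_sa = stats::rnorm(1, 0, 25),
               p_coil = stats::runif(1, 0.05, 0.6),
               delta_omh = 0, delta_p_fwy = 0, delta_p_krde = 0)
      for (mi in seq_len(nm)) {
        f <- c(dd_evdw = stats::rnorm(1, ctr["dd_evdw"], 1.5),
               dd_eelec = stats::rnorm(1, ctr["dd_eelec"], 6),
               n_inter = round(ctr[["n_inter"]]),
               r_l_sa = ctr[["r_l_sa"]],
               closeness = max(0.02, stats::rnorm(1, ctr["closeness"], 0.06)),
               delta_sa = stats::rnorm(1, ctr["delta_sa"], 30),
               p_coil = ctr[["p_coil"]],
               delta_omh = stats::rnorm(1, 0, 1.1),
               delta_p_fwy = sample(c(-1, 0, 0, 0, 1), 1) / 100,
               delta_p_krde = sample(c(-2, -1, 0, 0, 1, 2), 1) / 100)
        f["dd_evdw_rep"] <- abs(stats::rnorm(1, ctr["dd_evdw_rep"], 2))
        f <- f[feats]
        names(f) <- feats
        ddg_true <- true_model[["intercept"]] +
          sum(true_model[feats] * f)
        rows[[length(rows) + 1]] <- data.frame(
          complex_id = sprintf("CPLX%02d", ci),
          mutation = sprintf("CPLX%02d_m%d", ci, mi),
          t(f), ddg_true = ddg_true,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    out$ddg_exp <- out$ddg_true + stats::rnorm(nrow(out), 0, noise_sd)
    out
  })
}
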