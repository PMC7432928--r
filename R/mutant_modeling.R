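# Mutant structure building and backbone-restrained energy minimization.
#
# The mutated residue keeps its backbone; the new side chain comes from an
# ideal-geometry template oriented to the wild-type side chain (CB kept
# when both residue types have one, chi1 matched when both have a gamma
# atom).  Minimization uses the bundled heavy-atom force field: harmonic
# bond and 1-3 (Urey-Bradley style) terms that preserve the input covalent
# geometry, Lennard-Jones and Coulomb nonbonded terms inside a cutoff, and
# harmonic positional restraints on all backbone atoms.

#' Single-point mutation specification
#'
#' @param chain chain id
#' @param position author residue number
#' @param wt_aa,mut_aa 1-letter codes; must differ and be standard
#' @param icode insertion code ("" when absent)
#' @return object of class `mutation_spec`
#' @export
mutation_spec <- function(chain, position, wt_aa, mut_aa, icode = "") {
  wt_aa <- toupper(wt_aa); mut_aa <- toupper(mut_aa)
  if (!wt_aa %in% AA1 || !mut_aa %in% AA1)
    stop("amino-acid codes must be standard 1-letter codes (got ",
         wt_aa, " -> ", mut_aa, ")")
  if (wt_aa == mut_aa)
    stop("wild-type and mutant residues are identical: ", wt_aa)
  structure(list(chain = as.character(chain), position = as.integer(position),
                 icode = icode, wt_aa = wt_aa, mut_aa = mut_aa),
            class = "mutation_spec")
}

#' Parse a mutation string of the form "A:T217A"
#'
#' @param x character scalar `<chain>:<wt><pos><mut>`
#' @return a `mutation_spec`
#' @export
parse_mutation <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([A-Za-z])([0-9]+)([A-Za-z])$", x))[[1]]
  if (length(m) != 5) stop("cannot parse mutation string: ", x,
                           " (expected e.g. A:T217A)")
  mutation_spec(m[2], as.integer(m[4]), m[3], m[5])
}

#' @export
format.mutation_spec <- function(x, ...) {
  paste0(x$chain, ":", x$wt_aa, x$position, x$icode, x$mut_aa)
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat("mutation", format(x), "\n")
  invisible(x)
}

#' @noRd
.mutation_uid <- function(m) .residue_uid(m$chain, m$position, m$icode)

#' @noRd
# Template side chain placed on a backbone.  bb: list with N, CA, C and
# optionally the wild-type CB and gamma atom for orientation matching.
.place_sidechain <- function(res3, bb) {
  tmpl <- aa_template(res3)
  sc_names <- aa_sidechain_atoms(res3)
  if (length(sc_names) == 0) return(NULL)
  fit <- kabsch_fit(tmpl[c("N", "CA", "C"), , drop = FALSE],
                    rbind(bb$N, bb$CA, bb$C))
  sc <- apply_kabsch(tmpl[sc_names, , drop = FALSE], fit)
  rownames(sc) <- sc_names
  ca <- bb$CA
  if (!is.null(bb$CB) && "CB" %in% sc_names) {
    v_t <- sc["CB", ] - ca
    v_w <- bb$CB - ca
    ax <- cross3(v_t, v_w)
    if (vnorm(ax) > 1e-8) {
      ang <- acos(max(-1, min(1, sum(unit(v_t) * unit(v_w)))))
      sc <- sweep(rotate_about_axis(sweep(sc, 2, ca), ax, ang), 2, ca, "+")
    }
    sc["CB", ] <- bb$CB
    # chi1 matching about the CA-CB axis
    gamma_t <- intersect(c("CG", "CG1", "OG", "OG1", "SG"), sc_names)
    if (!is.null(bb$gamma) && length(gamma_t) > 0) {
      g <- gamma_t[1]
      chi_w <- dihedral_angle(bb$N, ca, bb$CB, bb$gamma)
      chi_t <- dihedral_angle(bb$N, ca, bb$CB, sc[g, ])
      rot <- deg2rad(chi_w - chi_t)
      axis <- bb$CB - ca
      beyond <- setdiff(sc_names, "CB")
      sc[beyond, ] <- sweep(
        rotate_about_axis(sweep(sc[beyond, , drop = FALSE], 2, bb$CB),
                          axis, rot), 2, bb$CB, "+")
    }
  }
  sc
}

#' @noRd
.residue_bb <- function(cx, uid) {
  a <- cx$atom
  g <- function(nm) {
    w <- which(a$uid == uid & a$elety == nm)
    if (length(w) == 0) return(NULL)
    as.numeric(a[w[1], c("x", "y", "z")])
  }
  gam <- NULL
  for (nm in c("CG", "CG1", "OG", "OG1", "SG")) {
    gam <- g(nm)
    if (!is.null(gam)) break
  }
  list(N = g("N"), CA = g("CA"), C = g("C"), O = g("O"),
       CB = g("CB"), gamma = gam)
}

#' Build a mutant complex from the wild type
#'
#' All residues except the mutated site are untouched; the site keeps its
#' backbone (and CB, when both residue types have one) and receives an
#' ideal-geometry side chain of the mutant type oriented to the wild-type
#' side-chain direction (chi1 matched when possible).
#'
#' @param wt a `pri_complex`
#' @param m a `mutation_spec` (or a string parseable by [parse_mutation()])
#' @return the mutant `pri_complex`
#' @export
build_mutant <- function(wt, m) {
  if (is.character(m)) m <- parse_mutation(m)
  uid <- .mutation_uid(m)
  a <- wt$atom
  ridx <- which(a$uid == uid)
  if (length(ridx) == 0)
    stop("no residue ", uid, " in the structure")
  found <- a$res1[ridx[1]]
  if (is.na(found) || found != m$wt_aa)
    stop("wild-type identity mismatch at ", uid, ": structure has ",
         ifelse(is.na(found), a$resid[ridx[1]], found),
         ", mutation says ", m$wt_aa)
  mut3 <- aa_123(m$mut_aa)
  bb <- .residue_bb(wt, uid)
  if (is.null(bb$N) || is.null(bb$CA) || is.null(bb$C))
    stop("incomplete backbone at ", uid)
  sc <- .place_sidechain(mut3, bb)
  # backbone rows stay as-is; side-chain rows are replaced
  bb_rows <- a[ridx, , drop = FALSE]
  bb_rows <- bb_rows[bb_rows$elety %in% PROTEIN_BACKBONE, , drop = FALSE]
  new_rows <- bb_rows
  if (!is.null(sc)) {
    scdf <- bb_rows[rep(1, nrow(sc)), , drop = FALSE]
    scdf$elety <- rownames(sc)
    scdf$x <- sc[, 1]; scdf$y <- sc[, 2]; scdf$z <- sc[, 3]
    scdf$elesy <- .element_from_name(rownames(sc))
    scdf$is_sidechain <- TRUE
    new_rows <- rbind(bb_rows, scdf)
  }
  new_rows$resid <- mut3
  new_rows$res1 <- m$mut_aa
  out <- rbind(a[seq_len(min(ridx) - 1), , drop = FALSE],
               new_rows,
               a[setdiff(seq(max(ridx) + 1, length.out =
                               nrow(a) - max(ridx)), ridx), , drop = FALSE])
  rownames(out) <- NULL
  cx <- new_pri_complex(out, wt$partner1, wt$partner2, wt$model)
  cx
}

#' Rebuild missing heavy side-chain atoms from the ideal templates
#'
#' Amino-acid residues missing side-chain heavy atoms get a full template
#' side chain re-placed on their backbone (existing CB / gamma orientation
#' preserved when present).  Missing backbone atoms are an error.
#'
#' @param cx a `pri_complex`
#' @return completed `pri_complex`
#' @export
complete_residues <- function(cx) {
  miss <- find_missing_atoms(cx)
  if (nrow(miss) == 0) return(cx)
  bb_miss <- miss[miss$atom %in% c("N", "CA", "C", "O", RNA_BACKBONE), ]
  if (nrow(bb_miss) > 0)
    stop("missing backbone atoms cannot be rebuilt: ",
         paste(unique(bb_miss$uid), collapse = ", "))
  for (uid in unique(miss$uid)) {
    res3 <- miss$resid[miss$uid == uid][1]
    if (!res3 %in% AA3) {
      warning("cannot complete non-amino-acid residue ", uid)
      next
    }
    bb <- .residue_bb(cx, uid)
    sc <- .place_sidechain(res3, bb)
    a <- cx$atom
    ridx <- which(a$uid == uid)
    bb_rows <- a[ridx, , drop = FALSE]
    bb_rows <- bb_rows[bb_rows$elety %in% PROTEIN_BACKBONE, , drop = FALSE]
    new_rows <- bb_rows
    if (!is.null(sc)) {
      scdf <- bb_rows[rep(1, nrow(sc)), , drop = FALSE]
      scdf$elety <- rownames(sc)
      scdf$x <- sc[, 1]; scdf$y <- sc[, 2]; scdf$z <- sc[, 3]
      scdf$elesy <- .element_from_name(rownames(sc))
      scdf$is_sidechain <- TRUE
      new_rows <- rbind(bb_rows, scdf)
    }
    out <- rbind(a[seq_len(min(ridx) - 1), , drop = FALSE],
                 new_rows,
                 a[setdiff(seq(max(ridx) + 1, length.out =
                                 nrow(a) - max(ridx)), ridx), , drop = FALSE])
    rownames(out) <- NULL
    cx <- new_pri_complex(out, cx$partner1, cx$partner2, cx$model)
  }
  cx
}

#' Minimization settings
#'
#' Defaults follow the structural-optimization protocol: 1000 steps,
#' harmonic backbone restraints of 5 kcal/(mol A^2), 12 A nonbonded cutoff.
#'
#' @param n_steps number of minimization steps (0 = return input unchanged)
#' @param restraint_k backbone positional restraint force constant,
#'   kcal/(mol A^2)
#' @param nonbonded_cutoff nonbonded cutoff distance in Angstrom
#' @return object of class `minimization_settings`
#' @export
minimization_settings <- function(n_steps = 1000, restraint_k = 5,
                                  nonbonded_cutoff = 12) {
  stopifnot(n_steps >= 0, restraint_k >= 0, nonbonded_cutoff > 0)
  structure(list(n_steps = as.integer(n_steps), restraint_k = restraint_k,
                 nonbonded_cutoff = nonbonded_cutoff),
            class = "minimization_settings")
}

BOND_K <- 300   # kcal/(mol A^2)
UB_K <- 60      # 1-3 (angle-preserving) force constant

#' @noRd
# Covalent bonds detected from the input geometry (heavy atoms): a pair is
# bonded when closer than 1.85 A (2.25 A when S or P is involved).
.detect_bonds <- function(xyz, elesy) {
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  lim <- matrix(1.85, n, n)
  sp <- elesy %in% c("S", "P")
  lim[sp, ] <- 2.25; lim[, sp] <- 2.25
  hit <- which(upper.tri(d) & d < lim & d > 0.5, arr.ind = TRUE)
  hit
}

#' @noRd
# Bonded-topology pair sets: 1-2 bonds, 1-3 pairs (for exclusion and for
# the angle-preserving harmonic terms).
.bonded_pairs <- function(bonds, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  p13 <- list()
  for (b in seq_len(n)) {
    nb <- adj[[b]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(sort(nb), 2)
      p13[[length(p13) + 1]] <- t(cmb)
    }
  }
  p13 <- if (length(p13) > 0) unique(do.call(rbind, p13)) else
    matrix(integer(0), 0, 2)
  # drop 1-3 pairs that are also bonds (rings)
  if (nrow(p13) > 0 && nrow(bonds) > 0) {
    bkey <- paste(bonds[, 1], bonds[, 2])
    p13 <- p13[!paste(p13[, 1], p13[, 2]) %in% bkey, , drop = FALSE]
  }
  list(b12 = bonds, b13 = p13)
}

#' @noRd
# Precompute the energy model for a structure: harmonic terms that keep the
# input covalent geometry + nonbonded pair list inside the cutoff.
.energy_model <- function(cx, settings, params) {
  xyz <- coords_matrix(cx)
  n <- nrow(xyz)
  typed <- type_atoms(cx, params)
  bonds <- .detect_bonds(xyz, cx$atom$elesy)
  bp <- .bonded_pairs(bonds, n)
  rlen <- function(p) sqrt(rowSums((xyz[p[, 1], , drop = FALSE] -
                                      xyz[p[, 2], , drop = FALSE])^2))
  harm_i <- c(bp$b12[, 1], bp$b13[, 1])
  harm_j <- c(bp$b12[, 2], bp$b13[, 2])
  harm_k <- c(rep(BOND_K, nrow(bp$b12)), rep(UB_K, nrow(bp$b13)))
  harm_r0 <- c(if (nrow(bp$b12)) rlen(bp$b12) else numeric(0),
               if (nrow(bp$b13)) rlen(bp$b13) else numeric(0))
  # nonbonded: all pairs within cutoff, excluding 1-2 and 1-3
  d <- as.matrix(stats::dist(xyz))
  excl <- matrix(FALSE, n, n)
  if (nrow(bp$b12)) excl[bp$b12] <- TRUE
  if (nrow(bp$b13)) excl[bp$b13] <- TRUE
  excl <- excl | t(excl)
  hit <- which(upper.tri(d) & d < settings$nonbonded_cutoff & !excl,
               arr.ind = TRUE)
  nb_i <- hit[, 1]; nb_j <- hit[, 2]
  list(n = n,
       harm_i = harm_i, harm_j = harm_j, harm_k = harm_k, harm_r0 = harm_r0,
       nb_i = nb_i, nb_j = nb_j,
       nb_eps = sqrt(typed$epsilon[nb_i] * typed$epsilon[nb_j]),
       nb_rmin = typed$rmin_half[nb_i] + typed$rmin_half[nb_j],
       nb_qq = COULOMB_K * typed$charge[nb_i] * typed$charge[nb_j],
       backbone = which(!cx$atom$is_sidechain),
       x0 = xyz)
}

#' @noRd
.model_energy_grad <- function(x, em, restraint_k, want_grad = TRUE) {
  xm <- matrix(x, ncol = 3)
  g <- if (want_grad) matrix(0, em$n, 3) else NULL
  e <- 0
  acc <- function(i, j, coefs, dvec) {
    # coefs = dE/dr / r for each pair
    contrib <- dvec * coefs
    gi <- rowsum(contrib, group = i, reorder = FALSE)
    gj <- rowsum(-contrib, group = j, reorder = FALSE)
    g[as.integer(rownames(gi)), ] <<- g[as.integer(rownames(gi)), ] + gi
    g[as.integer(rownames(gj)), ] <<- g[as.integer(rownames(gj)), ] + gj
  }
  if (length(em$harm_i) > 0) {
    dvec <- xm[em$harm_i, , drop = FALSE] - xm[em$harm_j, , drop = FALSE]
    r <- sqrt(rowSums(dvec^2))
    e <- e + sum(em$harm_k * (r - em$harm_r0)^2)
    if (want_grad) acc(em$harm_i, em$harm_j,
                       2 * em$harm_k * (r - em$harm_r0) / pmax(r, 1e-8), dvec)
  }
  if (length(em$nb_i) > 0) {
    dvec <- xm[em$nb_i, , drop = FALSE] - xm[em$nb_j, , drop = FALSE]
    r <- pmax(sqrt(rowSums(dvec^2)), 0.3)
    s6 <- (em$nb_rmin / r)^6
    e <- e + sum(em$nb_eps * (s6^2 - 2 * s6)) + sum(em$nb_qq / r)
    if (want_grad) {
      dEdr <- em$nb_eps * (-12 * s6^2 / r + 12 * s6 / r) - em$nb_qq / r^2
      acc(em$nb_i, em$nb_j, dEdr / r, dvec)
    }
  }
  if (restraint_k > 0) {
    dvec <- xm[em$backbone, , drop = FALSE] - em$x0[em$backbone, , drop = FALSE]
    e <- e + restraint_k * sum(dvec^2)
    if (want_grad) g[em$backbone, ] <- g[em$backbone, ] + 2 * restraint_k * dvec
  }
  list(e = e, g = if (want_grad) as.numeric(g) else NULL)
}

#' Total force-field energy of a structure
#'
#' Bonded (input-geometry harmonic) + Lennard-Jones + Coulomb terms of the
#' minimization energy model, without positional restraints.  Useful as an
#' independent before/after check of [minimize_complex()].
#'
#' @param cx a `pri_complex`
#' @param settings a `minimization_settings` (cutoff is taken from here)
#' @param params an `ff_params`
#' @return energy in kcal/mol
#' @export
system_energy <- function(cx, settings = minimization_settings(),
                          params = ff_params()) {
  em <- .energy_model(cx, settings, params)
  .model_energy_grad(as.numeric(coords_matrix(cx)), em, 0,
                     want_grad = FALSE)$e
}

#' Backbone-restrained energy minimization
#'
#' L-BFGS minimization of the heavy-atom force-field energy with harmonic
#' positional restraints (force constant `restraint_k`) on the backbone
#' atoms of all residues.  Deterministic; the returned structure never has
#' higher objective energy than the input.
#'
#' @param cx a `pri_complex` with all heavy atoms present
#' @param settings a `minimization_settings`
#' @param params an `ff_params`
#' @return the minimized `pri_complex`
#' @export
minimize_complex <- function(cx, settings = minimization_settings(),
                             params = ff_params()) {
  miss <- find_missing_atoms(cx)
  if (nrow(miss) > 0)
    stop("missing atoms: ",
         paste(paste0(miss$uid, "/", miss$atom), collapse = ", "))
  if (settings$n_steps == 0) return(cx)
  em <- .energy_model(cx, settings, params)
  x0 <- as.numeric(coords_matrix(cx))
  fn <- function(x) .model_energy_grad(x, em, settings$restraint_k,
                                       want_grad = FALSE)$e
  gr <- function(x) .model_energy_grad(x, em, settings$restraint_k)$g
  res <- tryCatch(
    stats::optim(x0, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = settings$n_steps)),
    error = function(e) list(par = x0, value = fn(x0)))
  if (res$value > fn(x0)) res$par <- x0
  set_coords(cx, matrix(res$par, ncol = 3))
}
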