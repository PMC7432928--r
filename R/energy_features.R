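# Pairwise force-field energies and the three energy features:
# ddE_vdw (cross-partner van der Waals difference), ddE_vdw.re (site-vs-RNA
# repulsion difference) and ddE_elec (site-vs-contacts electrostatics
# difference), each evaluated as mutant minus wild type.
#
# Conventions: Lorentz-Berthelot combination, Coulomb constant 332.0716
# kcal A / (mol e^2), relative dielectric 1 (gas phase), no cutoff (the
# interaction sets themselves define the sums; only the contact rule uses
# an explicit 10 A criterion).

COULOMB_K <- 332.0716

#' Assign force-field types and charges to every atom
#'
#' @param cx a `pri_complex`
#' @param params an `ff_params` object
#' @return data.frame (epsilon, rmin_half, charge) aligned with `cx$atom`
#' @export
type_atoms <- function(cx, params = ff_params()) {
  a <- cx$atom
  key <- paste(a$resid, a$elety)
  pk <- paste(params$atoms$resid, params$atoms$atom)
  idx <- match(key, pk)
  type <- params$atoms$type[idx]
  charge <- params$atoms$charge[idx]
  # terminal carboxylate oxygen: type as carbonyl O with zero extra charge
  oxt <- is.na(idx) & a$elety == "OXT"
  type[oxt] <- "OA"; charge[oxt] <- 0
  # 5'-terminal nucleotides may lack the phosphate; nothing to do, but any
  # other unmatched atom is an error
  bad <- is.na(type)
  if (any(bad)) {
    b <- a[which(bad)[1], ]
    stop("cannot type atom ", b$elety, " of ", b$resid, " ", b$uid)
  }
  ti <- match(type, params$types$type)
  data.frame(epsilon = params$types$epsilon[ti],
             rmin_half = params$types$rmin_half[ti],
             charge = charge)
}

#' @noRd
.pair_dist <- function(xa, xb) {
  # nA x nB Euclidean distance matrix
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sqrt(pmax(d2, 0))
}

#' Lennard-Jones interaction energy between two atom groups
#'
#' Sum over cross pairs of eps_ij * ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6) with
#' Lorentz-Berthelot combination; no cutoff.
#'
#' @param cx a `pri_complex`
#' @param groupA,groupB disjoint integer row indices into `cx$atom`
#' @param params an `ff_params` object
#' @param typed optional precomputed `type_atoms(cx, params)`
#' @return energy in kcal/mol
#' @export
lj_energy <- function(cx, groupA, groupB, params = ff_params(),
                      typed = NULL) {
  if (length(intersect(groupA, groupB)) > 0)
    stop("atom groups must be disjoint")
  if (length(groupA) == 0 || length(groupB) == 0) return(0)
  if (is.null(typed)) typed <- type_atoms(cx, params)
  xyz <- coords_matrix(cx)
  r <- .pair_dist(xyz[groupA, , drop = FALSE], xyz[groupB, , drop = FALSE])
  eps <- sqrt(typed$epsilon[groupA] %o% typed$epsilon[groupB])
  rmin <- outer(typed$rmin_half[groupA], typed$rmin_half[groupB], "+")
  q <- (rmin / r)^6
  sum(eps * (q^2 - 2 * q))
}

#' Repulsive (r^-12) Lennard-Jones energy between a site residue and the RNA
#'
#' Only the positive r^-12 component is summed, over all atoms of the
#' mutated-site residue against all nucleotide atoms.
#'
#' @param cx a `pri_complex`
#' @param site residue uid of the mutated site
#' @param params an `ff_params` object
#' @param typed optional precomputed typing
#' @return non-negative energy in kcal/mol
#' @export
lj_repulsive_energy <- function(cx, site, params = ff_params(),
                                typed = NULL) {
  a <- cx$atom
  gs <- which(a$uid == site)
  if (length(gs) == 0) stop("site ", site, " not found")
  gr <- which(a$kind == "nucleotide")
  if (length(gr) == 0) return(0)
  if (is.null(typed)) typed <- type_atoms(cx, params)
  xyz <- coords_matrix(cx)
  r <- .pair_dist(xyz[gs, , drop = FALSE], xyz[gr, , drop = FALSE])
  eps <- sqrt(typed$epsilon[gs] %o% typed$epsilon[gr])
  rmin <- outer(typed$rmin_half[gs], typed$rmin_half[gr], "+")
  sum(eps * (rmin / r)^12)
}

#' @noRd
# side-chain atom indices of a residue; glycine (and any residue without
# side-chain heavy atoms) falls back to its CA so the set is never empty
.sidechain_idx <- function(cx, uid) {
  a <- cx$atom
  w <- which(a$uid == uid & a$is_sidechain)
  if (length(w) == 0) w <- which(a$uid == uid & a$elety == "CA")
  w
}

#' Contact residues/nucleotides of a mutated site
#'
#' A residue (or nucleotide) is a contact when any of its side-chain (base)
#' atoms lies within `cutoff` of any side-chain atom of the site.  The site
#' itself is excluded; glycine's side-chain set is its CA.
#'
#' @param cx a `pri_complex`
#' @param site residue uid
#' @param cutoff distance cutoff in Angstrom
#' @return character vector of contact residue uids
#' @export
contact_set <- function(cx, site, cutoff = 10) {
  a <- cx$atom
  gs <- .sidechain_idx(cx, site)
  if (length(gs) == 0) stop("site ", site, " not found")
  xyz <- coords_matrix(cx)
  cand <- which(a$uid != site &
                  (a$is_sidechain | (a$kind == "amino-acid" &
                                       a$resid == "GLY" & a$elety == "CA")))
  if (length(cand) == 0) return(character(0))
  d <- .pair_dist(xyz[cand, , drop = FALSE], xyz[gs, , drop = FALSE])
  hit <- apply(d, 1, min) < cutoff
  unique(a$uid[cand[hit]])
}

#' Electrostatic interaction energy between a site and its contacts
#'
#' Coulomb sum 332.0716 q_i q_j / r over all atom pairs between the
#' mutated-site residue and the given contact residues (gas phase,
#' relative dielectric 1).
#'
#' @param cx a `pri_complex`
#' @param site residue uid
#' @param contacts character vector of contact residue uids (from
#'   [contact_set()])
#' @param params an `ff_params` object
#' @param typed optional precomputed typing
#' @return energy in kcal/mol
#' @export
elec_energy <- function(cx, site, contacts, params = ff_params(),
                        typed = NULL) {
  a <- cx$atom
  gs <- which(a$uid == site)
  gc <- which(a$uid %in% setdiff(contacts, site))
  if (length(gs) == 0) stop("site ", site, " not found")
  if (length(gc) == 0) return(0)
  if (is.null(typed)) typed <- type_atoms(cx, params)
  xyz <- coords_matrix(cx)
  r <- .pair_dist(xyz[gs, , drop = FALSE], xyz[gc, , drop = FALSE])
  qq <- typed$charge[gs] %o% typed$charge[gc]
  COULOMB_K * sum(qq / r)
}

#' @noRd
.partner_idx <- function(cx, partner) {
  chains <- if (partner == 1) cx$partner1 else cx$partner2
  which(cx$atom$chain %in% chains)
}

#' Cross-partner van der Waals energy of a complex
#'
#' With rigid partner extraction, the complex-minus-partners van der Waals
#' difference reduces to the LJ energy across the partner interface; this
#' helper computes that sum directly.
#'
#' @param cx a `pri_complex` with both partners assigned
#' @param params an `ff_params` object
#' @return energy in kcal/mol
#' @export
cross_partner_vdw <- function(cx, params = ff_params()) {
  lj_energy(cx, .partner_idx(cx, 1), .partner_idx(cx, 2), params)
}

#' Energy features: mutant-minus-wild-type differences
#'
#' `dd_evdw()` is the change in the complex-minus-partners van der Waals
#' energy; `dd_evdw_rep()` the change in site-vs-nucleotide repulsion;
#' `dd_eelec()` the change in site-vs-contacts electrostatics, with the
#' contact set recomputed independently for each structure.
#'
#' @param wt,mut minimized wild-type and mutant `pri_complex` objects
#' @param site residue uid of the mutated site
#' @param params an `ff_params` object
#' @return energy difference in kcal/mol
#' @export
dd_evdw <- function(wt, mut, params = ff_params()) {
  cross_partner_vdw(mut, params) - cross_partner_vdw(wt, params)
}

#' @rdname dd_evdw
#' @export
dd_evdw_rep <- function(wt, mut, site, params = ff_params()) {
  lj_repulsive_energy(mut, site, params) -
    lj_repulsive_energy(wt, site, params)
}

#' @rdname dd_evdw
#' @export
dd_eelec <- function(wt, mut, site, params = ff_params()) {
  e_mut <- elec_energy(mut, site, contact_set(mut, site), params)
  e_wt <- elec_energy(wt, site, contact_set(wt, site), params)
  e_mut - e_wt
}
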