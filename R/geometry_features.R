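# SASA-derived structural features: interface membership, interface size
# (Ninter), length/surface ratio, the mutated-site accessibility change
# (delta SA), exposure classification and the exposed-coil fraction Pcoil.

# tolerance (A^2) above which a burial counts as real rather than lattice
# noise when deciding interface membership
INTERFACE_SASA_TOL <- 0.1

#' Interface residues of a protein-RNA complex
#'
#' A residue (of either partner) is interfacial when its solvent-accessible
#' surface area in the rigidly extracted unbound partner exceeds its SASA in
#' the complex by more than a small numerical tolerance.
#'
#' @param cx a `pri_complex` with both partners assigned
#' @param probe,n_points SASA parameters
#' @return character vector of interfacial residue uids
#' @export
interface_residues <- function(cx, probe = 1.4, n_points = 960) {
  if (length(cx$partner1) == 0 || length(cx$partner2) == 0)
    stop("both partners must be non-empty")
  s_cx <- compute_sasa(cx, probe, n_points)$residue_area
  s_p1 <- compute_sasa(extract_partner(cx, 1), probe, n_points)$residue_area
  s_p2 <- compute_sasa(extract_partner(cx, 2), probe, n_points)$residue_area
  unb <- c(s_p1, s_p2)
  common <- intersect(names(unb), names(s_cx))
  common[unb[common] - s_cx[common] > INTERFACE_SASA_TOL]
}

#' Number of amino acids at the protein-RNA binding interface
#'
#' Counts protein residues only (nucleotides are never counted).
#'
#' @inheritParams interface_residues
#' @return non-negative integer
#' @export
n_inter <- function(cx, probe = 1.4, n_points = 960) {
  ifr <- interface_residues(cx, probe, n_points)
  rt <- residue_table(cx)
  sum(rt$kind[match(ifr, rt$uid)] == "amino-acid")
}

#' Ratio of protein length to its surface area
#'
#' Total residue count of the unbound protein divided by its total SASA
#' (residues per A^2).  The unbound protein is the rigid extraction of
#' partner 1.
#'
#' @param cx a `pri_complex` (either a full complex, from which partner 1 is
#'   extracted, or an already-extracted protein)
#' @param probe,n_points SASA parameters
#' @return numeric scalar (residues / A^2)
#' @export
ratio_length_sasa <- function(cx, probe = 1.4, n_points = 960) {
  prot <- if (length(cx$partner2) > 0) extract_partner(cx, 1) else cx
  len <- sum(residue_table(prot)$kind == "amino-acid")
  sa <- compute_sasa(prot, probe, n_points)$total
  if (sa <= 0) stop("degenerate structure: zero surface area")
  len / sa
}

#' Accessibility change of the mutated site
#'
#' SASA of the mutated residue in the unbound mutant protein minus that in
#' the unbound wild-type protein (both rigidly extracted from their
#' minimized complexes).
#'
#' @param wt,mut wild-type and mutant `pri_complex` objects
#' @param site residue uid of the mutated site (see [residue_uid()])
#' @param probe,n_points SASA parameters
#' @return numeric scalar in A^2
#' @export
delta_sa <- function(wt, mut, site, probe = 1.4, n_points = 960) {
  p_wt <- if (length(wt$partner2) > 0) extract_partner(wt, 1) else wt
  p_mut <- if (length(mut$partner2) > 0) extract_partner(mut, 1) else mut
  s_wt <- compute_sasa(p_wt, probe, n_points)$residue_area
  s_mut <- compute_sasa(p_mut, probe, n_points)$residue_area
  if (!site %in% names(s_wt)) stop("site ", site, " not in wild type")
  if (!site %in% names(s_mut)) stop("site ", site, " not in mutant")
  unname(s_mut[site] - s_wt[site])
}

#' Build a residue uid from its components
#' @param chain chain id
#' @param resno author residue number
#' @param insert insertion code ("" when absent)
#' @return character uid "chain:resno:icode"
#' @export
residue_uid <- function(chain, resno, insert = "") {
  .residue_uid(chain, resno, insert)
}

#' Exposed-residue classification
#'
#' A residue is exposed when its SASA in the complex divided by the
#' maximum-ASA reference of its residue type exceeds `threshold` (0.25).
#'
#' @param cx a `pri_complex`
#' @param sasa optional precomputed `sasa_result` for `cx`
#' @param threshold relative accessibility cutoff
#' @return logical vector named by residue uid (protein residues only)
#' @export
exposed_residues <- function(cx, sasa = NULL, threshold = 0.25) {
  if (is.null(sasa)) sasa <- compute_sasa(cx)
  rt <- residue_table(cx)
  rt <- rt[rt$kind == "amino-acid", ]
  ref <- max_asa_table()[rt$res1]
  rel <- sasa$residue_area[rt$uid] / ref
  stats::setNames(rel > threshold, rt$uid)
}

#' Fraction of exposed coil residues in the mutated protein chain
#'
#' Pcoil = N_exposed_coil / N_all over the residues of one protein chain,
#' with exposure judged in the complex against the maximum-ASA reference
#' and coil meaning neither helix nor strand.
#'
#' @param cx a `pri_complex`
#' @param chain the mutated protein chain id
#' @param sasa optional precomputed `sasa_result` for `cx`
#' @param ss optional precomputed `ss_assignment` for `cx`
#' @return fraction in [0, 1]
#' @export
p_coil <- function(cx, chain, sasa = NULL, ss = NULL) {
  if (is.null(sasa)) sasa <- compute_sasa(cx)
  if (is.null(ss)) ss <- assign_secondary_structure(cx)
  exp_flag <- exposed_residues(cx, sasa)
  rt <- residue_table(cx)
  uids <- rt$uid[rt$chain == chain & rt$kind == "amino-acid"]
  if (length(uids) == 0) stop("no protein residues in chain ", chain)
  is_coil <- ss$label[match(uids, ss$uid)] == "coil"
  sum(is_coil & exp_flag[uids], na.rm = TRUE) / length(uids)
}
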