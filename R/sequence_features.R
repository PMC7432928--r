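# Sequence-based features: hydrophobicity-scale difference (delta OMH) and
# the two composition differences over the mutated protein chain
# (delta P_FWY for aromatics, delta P_KR-DE for net charge class).

#' Hydrophobicity-scale difference of a substitution
#'
#' OMH(mutant) - OMH(wild type).
#'
#' @param wt_aa,mut_aa 1-letter amino-acid codes
#' @param scale named hydrophobicity vector; defaults to the bundled OMH
#' @return numeric scalar
#' @export
delta_omh <- function(wt_aa, mut_aa, scale = omh_scale()) {
  if (!wt_aa %in% names(scale)) stop("unknown amino acid: ", wt_aa)
  if (!mut_aa %in% names(scale)) stop("unknown amino acid: ", mut_aa)
  unname(scale[mut_aa] - scale[wt_aa])
}

#' Composition differences induced by a substitution
#'
#' Over the mutated chain's resolved sequence of length N: P_FWY is the
#' aromatic fraction and P_KR-DE = (N_KR - N_DE)/N the net charged-class
#' fraction.  Both deltas are mutant minus wild type; a single substitution
#' changes each by a multiple of 1/N (up to 2/N for P_KR-DE when a K/R
#' swaps with a D/E).
#'
#' @param chain_seq wild-type 1-letter sequence of the mutated chain
#' @param position 1-based position in `chain_seq`
#' @param wt_aa,mut_aa 1-letter codes of the substitution
#' @return named numeric vector c(delta_p_fwy, delta_p_krde)
#' @export
composition_deltas <- function(chain_seq, position, wt_aa, mut_aa) {
  s <- strsplit(chain_seq, "")[[1]]
  n <- length(s)
  if (position < 1 || position > n)
    stop("position ", position, " outside sequence of length ", n)
  if (s[position] != wt_aa)
    stop("wild-type mismatch at position ", position, ": sequence has ",
         s[position], ", mutation says ", wt_aa)
  p <- function(seq) {
    c(fwy = sum(seq %in% c("F", "W", "Y")) / n,
      krde = (sum(seq %in% c("K", "R")) - sum(seq %in% c("D", "E"))) / n)
  }
  s2 <- s
  s2[position] <- mut_aa
  d <- p(s2) - p(s)
  c(delta_p_fwy = unname(d["fwy"]), delta_p_krde = unname(d["krde"]))
}
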