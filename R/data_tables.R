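# Loaders for the versioned plain-text parameter tables shipped under
# inst/extdata.  Users may point each loader at their own file of the same
# layout to swap parameter sets.

.table_cache <- new.env(parent = emptyenv())

.read_cached <- function(name, file = NULL) {
  if (is.null(file)) {
    if (!is.null(.table_cache[[name]])) return(.table_cache[[name]])
    file <- system.file("extdata", name, package = "priddg", mustWork = TRUE)
  }
  tab <- utils::read.delim(file, stringsAsFactors = FALSE,
                           check.names = FALSE, quote = "")
  .table_cache[[name]] <- tab
  tab
}

#' Bundled hydrophobicity scale (OMH)
#'
#' Per-amino-acid optimal matching hydrophobicity values, derived from
#' observed amino-acid replacement frequencies in homologous structures.
#'
#' @param file optional path to an alternative two-column (aa, omh) TSV
#' @return named numeric vector of length 20 (names = 1-letter codes)
#' @export
omh_scale <- function(file = NULL) {
  tab <- .read_cached("omh_scale.tsv", file)
  stats::setNames(tab$omh, tab$aa)
}

#' Maximum accessible-surface-area reference values
#'
#' Per-residue-type maximum ASA (A^2) of X in an extended Gly-X-Gly
#' tripeptide, used as the fully solvated reference state when classifying
#' residues as exposed.
#'
#' @param file optional path to an alternative (aa, max_asa) TSV
#' @return named numeric vector (names = 1-letter codes)
#' @export
max_asa_table <- function(file = NULL) {
  tab <- .read_cached("max_asa.tsv", file)
  stats::setNames(tab$max_asa, tab$aa)
}

#' van der Waals radii used for solvent-accessible surface area
#'
#' @param file optional path to an alternative (element, radius) TSV
#' @return named numeric vector of radii in Angstrom, keyed by element
#' @export
vdw_radii <- function(file = NULL) {
  tab <- .read_cached("vdw_radii.tsv", file)
  stats::setNames(tab$radius, tab$element)
}

#' Bundled force-field parameter set
#'
#' A heavy-atom (united-atom style) Lennard-Jones plus partial-charge
#' parameter set covering the 20 standard amino acids and the 4
#' ribonucleotides.  Hydrogen charges are folded into their parent heavy
#' atoms, so each neutral residue's charges sum to zero and charged
#' residues (Asp/Glu, Lys/Arg, nucleotide phosphates) carry their formal
#' charge.
#'
#' @param params_file optional path to an alternative per-atom
#'   (resid, atom, type, charge) TSV
#' @param types_file optional path to an alternative per-type
#'   (type, epsilon, rmin_half) TSV
#' @return object of class `ff_params`: list with `atoms` (data.frame) and
#'   `types` (data.frame)
#' @export
ff_params <- function(params_file = NULL, types_file = NULL) {
  atoms <- .read_cached("ff_params.tsv", params_file)
  types <- .read_cached("lj_types.tsv", types_file)
  miss <- setdiff(atoms$type, types$type)
  if (length(miss) > 0)
    stop("atom types without LJ parameters: ", paste(miss, collapse = ", "))
  structure(list(atoms = atoms, types = types), class = "ff_params")
}
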