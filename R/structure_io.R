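# Reading, writing and partner bookkeeping for protein-RNA complexes.
#
# A complex is held as a `pri_complex`: a data frame of heavy atoms plus
# chain typing and the two binding partners (partner 1 = protein chains,
# partner 2 = RNA chains).  Parsing and writing of the PDB format go
# through bio3d; this module owns model selection, alternate-location
# resolution, water stripping, modified-residue mapping and chain typing.

WATER_RESIDS <- c("HOH", "WAT", "DOD", "H2O", "TIP", "TIP3", "SOL")
DNA_CODES <- c("DA", "DC", "DG", "DT", "DI", "T")

#' @noRd
.element_from_name <- function(elety) {
  e <- sub("^[0-9']*", "", toupper(elety))
  two <- substr(e, 1, 2)
  one <- substr(e, 1, 1)
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "BR", "CL", "NA", "SE"), two, one)
}

.residue_kind <- function(resid) {
  ifelse(resid %in% AA3, "amino-acid",
         ifelse(resid %in% NT_CODES, "nucleotide", "other"))
}

.res1_code <- function(resid) {
  ifelse(resid %in% AA3, aa_321(resid),
         ifelse(resid %in% NT_CODES, resid, NA_character_))
}

#' @noRd
.residue_uid <- function(chain, resno, insert) {
  ic <- ifelse(is.na(insert) | insert == "", "", insert)
  paste(chain, resno, ic, sep = ":")
}

.is_sidechain_atom <- function(elety, kind) {
  ifelse(kind == "amino-acid", !(elety %in% PROTEIN_BACKBONE),
         ifelse(kind == "nucleotide", !(elety %in% RNA_BACKBONE), FALSE))
}

new_pri_complex <- function(atom, partner1, partner2, model = 1L) {
  atom$uid <- .residue_uid(atom$chain, atom$resno, atom$insert)
  chains <- unique(atom$chain)
  # one code per residue, then majority vote inside classify_chain
  ctype <- vapply(chains, function(ch) {
    sub <- atom[atom$chain == ch, ]
    classify_chain(sub$resid[!duplicated(sub$uid)], quiet = TRUE)
  }, character(1))
  structure(list(
    atom = atom,
    chains = data.frame(chain = chains, type = unname(ctype),
                        stringsAsFactors = FALSE),
    partner1 = partner1,
    partner2 = partner2,
    model = model
  ), class = "pri_complex")
}

#' Classify a chain as protein, RNA or other
#'
#' A chain is protein if the majority of its residues are standard amino
#' acids, RNA if the majority are A/C/G/U ribonucleotides, otherwise
#' "other" (this includes DNA).  Deterministic; invariant to residue order.
#'
#' @param resids vector of 3-letter (or nucleotide 1-letter) residue codes,
#'   one entry per residue
#' @param quiet suppress the empty-chain error and return NA instead
#' @return one of "protein", "RNA", "other"
#' @export
classify_chain <- function(resids, quiet = FALSE) {
  resids <- resids[!resids %in% WATER_RESIDS]
  if (length(resids) == 0) {
    if (quiet) return(NA_character_)
    stop("cannot classify an empty chain")
  }
  kinds <- .residue_kind(resids)
  n <- length(resids)
  if (sum(kinds == "amino-acid") > n / 2) return("protein")
  if (sum(kinds == "nucleotide") > n / 2) return("RNA")
  "other"
}

#' Load a protein-RNA complex from PDB text or file
#'
#' Selects one model (the first by default, matching the convention of
#' using the first NMR model; crystal structures should be supplied as the
#' biological-assembly file), strips waters and hydrogens, resolves
#' alternate locations to the highest-occupancy copy (ties broken by
#' alphabetically first altLoc code), maps known modified residues to
#' their parent with a warning, types every chain, and assigns partner 1 =
#' protein chains and partner 2 = RNA chains unless given explicitly.
#'
#' @param file path to a PDB-format file
#' @param text PDB-format text (alternative to `file`)
#' @param model 1-based model index for multi-model files
#' @param partner1,partner2 optional chain-id vectors overriding the
#'   automatic partner assignment
#' @param reject_modified_interface error when a mapped modified residue
#'   sits at the protein-RNA interface (curation rule); default TRUE
#' @return a `pri_complex`
#' @export
read_complex <- function(file = NULL, text = NULL, model = 1L,
                         partner1 = NULL, partner2 = NULL,
                         reject_modified_interface = TRUE) {
  if (is.null(file) && is.null(text)) stop("supply `file` or `text`")
  if (is.null(file)) {
    file <- tempfile(fileext = ".pdb")
    on.exit(unlink(file), add = TRUE)
    writeLines(text, file)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(file, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("not parsable as PDB format: ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  nmodels <- nrow(pdb$xyz)
  if (is.null(nmodels) || is.na(nmodels)) nmodels <- 1L
  if (model < 1 || model > nmodels)
    stop("model ", model, " requested but file has ", nmodels, " model(s)")
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]

  a$resid <- toupper(a$resid)
  a <- a[!a$resid %in% WATER_RESIDS, , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms left after water stripping")
  # element + hydrogen stripping
  a$elesy <- ifelse(is.na(a$elesy) | a$elesy == "",
                    .element_from_name(a$elety), toupper(a$elesy))
  a <- a[!a$elesy %in% c("H", "D"), , drop = FALSE]

  # modified residue mapping
  is_mod <- a$resid %in% names(MODRES_PARENT)
  modified_uids <- character(0)
  if (any(is_mod)) {
    modified_uids <- unique(.residue_uid(a$chain[is_mod], a$resno[is_mod],
                                         a$insert[is_mod]))
    warning("mapped modified residue(s) to parent type: ",
            paste(unique(a$resid[is_mod]), collapse = ", "))
    a$resid[is_mod] <- unname(MODRES_PARENT[a$resid[is_mod]])
  }

  # alternate locations: highest occupancy, tie -> first altLoc code;
  # original file order is restored afterwards
  a$o[is.na(a$o)] <- 1
  a$.orig <- seq_len(nrow(a))
  alt <- ifelse(is.na(a$alt), "", a$alt)
  key <- paste(a$chain, a$resno, ifelse(is.na(a$insert), "", a$insert),
               a$elety, sep = "|")
  ord <- order(key, -a$o, alt)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(key[ord]), , drop = FALSE]
  a <- a[order(a$.orig), , drop = FALSE]

  a$kind <- .residue_kind(a$resid)
  a$res1 <- .res1_code(a$resid)
  a$is_sidechain <- .is_sidechain_atom(a$elety, a$kind)
  keep <- c("type", "eleno", "elety", "resid", "chain", "resno", "insert",
            "x", "y", "z", "o", "elesy", "kind", "res1", "is_sidechain")
  a <- a[, keep]
  rownames(a) <- NULL

  cx <- new_pri_complex(a, partner1 = NULL, partner2 = NULL, model = model)
  prot <- cx$chains$chain[cx$chains$type == "protein"]
  rna <- cx$chains$chain[cx$chains$type == "RNA"]
  if (is.null(partner1)) partner1 <- prot
  if (is.null(partner2)) partner2 <- rna
  if (length(partner1) == 0 || !any(partner1 %in% prot))
    stop("composition error: no protein chain in the complex")
  if (length(partner2) == 0)
    stop("composition error: no RNA chain in the complex")
  bad <- setdiff(partner2, rna)
  if (length(bad) > 0)
    stop("partner 2 must be pure RNA; chain(s) ",
         paste(bad, collapse = ", "), " are not RNA")
  if (length(intersect(partner1, partner2)) > 0)
    stop("partners must be disjoint chain sets")
  cx$partner1 <- partner1
  cx$partner2 <- partner2

  if (reject_modified_interface && length(modified_uids) > 0) {
    at_if <- intersect(modified_uids, interface_residues(cx))
    if (length(at_if) > 0)
      stop("modified residue(s) at the protein-RNA binding interface: ",
           paste(at_if, collapse = ", "))
  }
  cx
}

#' @rdname read_complex
#' @param ... passed on to `read_complex()`
#' @export
load_complex <- function(text, ...) read_complex(text = text, ...)

#' Write a complex to a PDB file
#'
#' @param cx a `pri_complex`
#' @param file output path
#' @return `file`, invisibly
#' @export
write_complex <- function(cx, file) {
  a <- cx$atom
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = a$type, resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, insert = a$insert, o = a$o,
                   b = rep(0, nrow(a)), elesy = a$elesy)
  invisible(file)
}

#' Rigid extraction of one binding partner
#'
#' Returns the unbound partner in its bound conformation: only the selected
#' partner's chains are retained and no coordinate is changed.
#'
#' @param cx a `pri_complex`
#' @param partner 1 (protein) or 2 (RNA)
#' @return a `pri_complex` holding only that partner's chains
#' @export
extract_partner <- function(cx, partner) {
  stopifnot(inherits(cx, "pri_complex"), partner %in% c(1, 2))
  chains <- if (partner == 1) cx$partner1 else cx$partner2
  if (length(chains) == 0) stop("partner ", partner, " is empty")
  a <- cx$atom[cx$atom$chain %in% chains, , drop = FALSE]
  rownames(a) <- NULL
  out <- new_pri_complex(a,
                         partner1 = if (partner == 1) chains else character(0),
                         partner2 = if (partner == 2) chains else character(0),
                         model = cx$model)
  out
}

#' Residue-level view of a complex
#'
#' @param cx a `pri_complex`
#' @return data.frame with one row per residue: uid, chain, resno, insert,
#'   resid, res1, kind, n_atoms
#' @export
residue_table <- function(cx) {
  a <- cx$atom
  first <- !duplicated(a$uid)
  data.frame(uid = a$uid[first], chain = a$chain[first],
             resno = a$resno[first], insert = a$insert[first],
             resid = a$resid[first], res1 = a$res1[first],
             kind = a$kind[first],
             n_atoms = as.vector(table(factor(a$uid, levels = a$uid[first]))),
             stringsAsFactors = FALSE)
}

#' One-letter sequence of a chain as resolved in the structure
#' @param cx a `pri_complex`
#' @param chain chain id
#' @return character scalar
#' @export
chain_sequence <- function(cx, chain) {
  rt <- residue_table(cx)
  rt <- rt[rt$chain == chain, ]
  if (nrow(rt) == 0) stop("no such chain: ", chain)
  paste(ifelse(is.na(rt$res1), "X", rt$res1), collapse = "")
}

#' Report heavy side-chain atoms missing relative to the ideal templates
#'
#' @param cx a `pri_complex`
#' @return data.frame (uid, resid, missing atom name); zero rows if complete
#' @export
find_missing_atoms <- function(cx) {
  rt <- residue_table(cx)
  out <- list()
  for (i in seq_len(nrow(rt))) {
    if (rt$kind[i] == "amino-acid") {
      want <- setdiff(rownames(aa_template(rt$resid[i])), "OXT")
    } else if (rt$kind[i] == "nucleotide") {
      want <- rownames(nt_template(rt$resid[i]))
    } else next
    have <- cx$atom$elety[cx$atom$uid == rt$uid[i]]
    miss <- setdiff(want, have)
    if (length(miss) > 0)
      out[[length(out) + 1]] <- data.frame(uid = rt$uid[i],
                                           resid = rt$resid[i],
                                           atom = miss,
                                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(uid = character(0), resid = character(0),
                      atom = character(0)))
  do.call(rbind, out)
}

#' @export
print.pri_complex <- function(x, ...) {
  rt <- residue_table(x)
  cat("pri_complex:", nrow(x$atom), "atoms,", nrow(rt), "residues,",
      nrow(x$chains), "chain(s)\n")
  cat("  partner 1 (protein):", paste(x$partner1, collapse = " "), "\n")
  cat("  partner 2 (RNA):    ", paste(x$partner2, collapse = " "), "\n")
  invisible(x)
}

# coordinates as a matrix
coords_matrix <- function(cx) as.matrix(cx$atom[, c("x", "y", "z")])

set_coords <- function(cx, m) {
  cx$atom$x <- m[, 1]; cx$atom$y <- m[, 2]; cx$atom$z <- m[, 3]
  cx
}
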