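# Ideal-geometry residue templates.
#
# Amino-acid side chains are defined by internal coordinates (bond, angle,
# dihedral relative to three previously placed atoms) and realized with the
# NeRF construction.  The default rotamer is extended (chi = 180 where
# chemically sensible); branched and planar groups use fixed offsets.
# Ribonucleotides combine a NeRF-built sugar-phosphate unit (A-form torsions)
# with planar base rings generated from idealized polygon geometry.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")
names(AA1) <- AA3

NT_CODES <- c("A", "C", "G", "U")

#' Convert residue codes between 3-letter and 1-letter forms
#' @param x character vector of residue codes
#' @return character vector of converted codes (NA for unknown)
#' @keywords internal
aa_321 <- function(x) unname(AA1[match(toupper(x), AA3)])

#' @rdname aa_321
#' @keywords internal
aa_123 <- function(x) unname(AA3[match(toupper(x), AA1)])

PROTEIN_BACKBONE <- c("N", "CA", "C", "O", "OXT")
RNA_BACKBONE <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'",
                  "O3'", "C2'", "O2'", "C1'")

# Modified-residue parent mapping applied on load (warning emitted).
MODRES_PARENT <- c(MSE = "MET", SEP = "SER", TPO = "THR", PTR = "TYR",
                   HYP = "PRO", CSO = "CYS", MLY = "LYS", PCA = "GLU",
                   PSU = "U", "5MC" = "C", "5MU" = "U", "4SU" = "U",
                   "1MA" = "A", "2MG" = "G", "7MG" = "G", M2G = "G",
                   OMG = "G", OMC = "C", OMU = "U", H2U = "U", I = "G")

# Side-chain internal coordinates.  Columns: atom, three reference atoms,
# bond length (A), bond angle (deg, a2-a3-atom), dihedral (deg, a1-a2-a3-atom).
.sc_row <- function(name, a1, a2, a3, b, ang, dih) {
  data.frame(name = name, a1 = a1, a2 = a2, a3 = a3, bond = b,
             angle = ang, dihedral = dih, stringsAsFactors = FALSE)
}

.sidechain_zmat <- function() {
  cb <- function() .sc_row("CB", "C", "N", "CA", 1.530, 110.5, 122.7)
  z <- list()
  z$ALA <- cb()
  z$SER <- rbind(cb(), .sc_row("OG",  "N", "CA", "CB", 1.417, 110.8, 180))
  z$CYS <- rbind(cb(), .sc_row("SG",  "N", "CA", "CB", 1.808, 113.5, 180))
  z$THR <- rbind(cb(),
                 .sc_row("OG1", "N", "CA", "CB", 1.433, 109.5, 180),
                 .sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, -60))
  z$VAL <- rbind(cb(),
                 .sc_row("CG1", "N", "CA", "CB", 1.521, 110.5, 180),
                 .sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, -60))
  z$ILE <- rbind(cb(),
                 .sc_row("CG1", "N", "CA", "CB", 1.530, 110.4, 180),
                 .sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, -60),
                 .sc_row("CD1", "CA", "CB", "CG1", 1.513, 113.8, 180))
  z$LEU <- rbind(cb(),
                 .sc_row("CG",  "N", "CA", "CB", 1.530, 116.3, 180),
                 .sc_row("CD1", "CA", "CB", "CG", 1.521, 110.7, 180),
                 .sc_row("CD2", "CA", "CB", "CG", 1.521, 110.7, 60))
  z$MET <- rbind(cb(),
                 .sc_row("CG",  "N", "CA", "CB", 1.520, 114.1, 180),
                 .sc_row("SD",  "CA", "CB", "CG", 1.803, 112.7, 180),
                 .sc_row("CE",  "CB", "CG", "SD", 1.791, 100.9, 180))
  z$ASP <- rbind(cb(),
                 .sc_row("CG",  "N", "CA", "CB", 1.516, 112.6, 180),
                 .sc_row("OD1", "CA", "CB", "CG", 1.249, 118.4, 90),
                 .sc_row("OD2", "CA", "CB", "CG", 1.249, 118.4, -90))
  z$ASN <- rbind(cb(),
                 .sc_row("CG",  "N", "CA", "CB", 1.516, 112.6, 180),
                 .sc_row("OD1", "CA", "CB", "CG", 1.231, 120.8, 90),
                 .sc_row("ND2", "CA", "CB", "CG", 1.328, 116.4, -90))
  z$GLU <- rbind(cb(),
                 .sc_row("CG",  "N", "CA", "CB", 1.530, 114.1, 180),
                 .sc_row("CD",  "CA", "CB", "CG", 1.516, 112.6, 180),
                 .sc_row("OE1", "CB", "CG", "CD", 1.249, 118.4, 90),
                 .sc_row("OE2", "CB", "CG", "CD", 1.249, 118.4, -90))
  z$GLN <- rbind(cb(),
                 .sc_row("CG",  "N", "CA", "CB", 1.530, 114.1, 180),
                 .sc_row("CD",  "CA", "CB", "CG", 1.516, 112.6, 180),
                 .sc_row("OE1", "CB", "CG", "CD", 1.231, 120.8, 90),
                 .sc_row("NE2", "CB", "CG", "CD", 1.328, 116.4, -90))
  z$LYS <- rbind(cb(),
                 .sc_row("CG",  "N", "CA", "CB", 1.530, 114.1, 180),
                 .sc_row("CD",  "CA", "CB", "CG", 1.530, 111.3, 180),
                 .sc_row("CE",  "CB", "CG", "CD", 1.530, 111.3, 180),
                 .sc_row("NZ",  "CG", "CD", "CE", 1.489, 112.0, 180))
  z$ARG <- rbind(cb(),
                 .sc_row("CG",  "N", "CA", "CB", 1.530, 114.1, 180),
                 .sc_row("CD",  "CA", "CB", "CG", 1.530, 111.3, 180),
                 .sc_row("NE",  "CB", "CG", "CD", 1.461, 112.0, 180),
                 .sc_row("CZ",  "CG", "CD", "NE", 1.329, 124.2, 180),
                 .sc_row("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0),
                 .sc_row("NH2", "CD", "NE", "CZ", 1.326, 120.0, 180))
  z$PHE <- rbind(cb(),
                 .sc_row("CG",  "N", "CA", "CB", 1.502, 113.8, 180),
                 .sc_row("CD1", "CA", "CB", "CG", 1.391, 120.8, 90),
                 .sc_row("CD2", "CA", "CB", "CG", 1.391, 120.8, -90),
                 .sc_row("CE1", "CB", "CG", "CD1", 1.391, 120.8, 180),
                 .sc_row("CE2", "CB", "CG", "CD2", 1.391, 120.8, 180),
                 .sc_row("CZ",  "CG", "CD1", "CE1", 1.391, 120.0, 0))
  z$TYR <- rbind(z$PHE,
                 .sc_row("OH",  "CD1", "CE1", "CZ", 1.377, 120.0, 180))
  z$HIS <- rbind(cb(),
                 .sc_row("CG",  "N", "CA", "CB", 1.504, 113.8, 180),
                 .sc_row("ND1", "CA", "CB", "CG", 1.378, 122.7, 90),
                 .sc_row("CD2", "CA", "CB", "CG", 1.354, 131.0, -90),
                 .sc_row("CE1", "CB", "CG", "ND1", 1.323, 109.0, 180),
                 .sc_row("NE2", "CB", "CG", "CD2", 1.374, 107.2, 180))
  z$TRP <- rbind(cb(),
                 .sc_row("CG",  "N", "CA", "CB", 1.498, 113.6, 180),
                 .sc_row("CD1", "CA", "CB", "CG", 1.365, 126.9, 90),
                 .sc_row("CD2", "CA", "CB", "CG", 1.433, 126.6, -90),
                 .sc_row("NE1", "CB", "CG", "CD1", 1.374, 110.2, 180),
                 .sc_row("CE2", "CB", "CG", "CD2", 1.409, 107.2, 180),
                 .sc_row("CE3", "CB", "CG", "CD2", 1.398, 133.9, 0),
                 .sc_row("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, 180),
                 .sc_row("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, 180),
                 .sc_row("CH2", "CD2", "CE3", "CZ3", 1.368, 121.1, 0))
  z$PRO <- rbind(cb(),
                 .sc_row("CG",  "N", "CA", "CB", 1.492, 104.5, 30),
                 .sc_row("CD",  "CA", "CB", "CG", 1.503, 106.1, -35))
  z$GLY <- .sc_row("CB", "C", "N", "CA", 1.53, 110.5, 122.7)[0, ]
  z
}

.template_cache <- new.env(parent = emptyenv())

#' Ideal-geometry amino-acid residue template
#'
#' Builds the heavy atoms of one residue (backbone N, CA, C, O plus side
#' chain) in a local frame with CA at the origin.
#'
#' @param res3 3-letter residue code
#' @return numeric matrix (atoms x 3) with atom-name rownames
#' @keywords internal
aa_template <- function(res3) {
  res3 <- toupper(res3)
  key <- paste0("AA_", res3)
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  if (!res3 %in% AA3) stop("unknown amino acid: ", res3)
  coords <- list(
    N  = c(1.458, 0, 0),
    CA = c(0, 0, 0),
    C  = 1.525 * c(cos(deg2rad(111)), sin(deg2rad(111)), 0)
  )
  coords$O <- place_atom(coords$N, coords$CA, coords$C, 1.231, 120.5, 135)
  zmat <- .sidechain_zmat()[[res3]]
  if (nrow(zmat) > 0) {
    for (i in seq_len(nrow(zmat))) {
      r <- zmat[i, ]
      coords[[r$name]] <- place_atom(coords[[r$a1]], coords[[r$a2]],
                                     coords[[r$a3]], r$bond, r$angle,
                                     r$dihedral)
    }
  }
  m <- do.call(rbind, coords)
  rownames(m) <- names(coords)
  .template_cache[[key]] <- m
  m
}

#' Side-chain heavy atom names of an amino acid (template order)
#' @keywords internal
aa_sidechain_atoms <- function(res3) {
  setdiff(rownames(aa_template(res3)), PROTEIN_BACKBONE)
}

# Planar base ring coordinates in a 2D frame (glycosidic N at origin).
# Rings are generated as near-regular polygons; exocyclic substituents point
# radially outward from the attached ring atom.
.base_atoms_2d <- function(base) {
  poly <- function(n, side, start_angle) {
    rad <- side / (2 * sin(pi / n))
    ang <- start_angle + 2 * pi * (seq_len(n) - 1) / n
    cbind(rad * cos(ang), rad * sin(ang))
  }
  out_from <- function(center, pt, dist) pt + dist * unit(c(pt - center, 0))[1:2]
  if (base %in% c("A", "G")) {
    # five-ring: N9 C8 N7 C5 C4 (N9 at origin, ring toward +x)
    p5 <- poly(5, 1.38, pi)
    p5 <- sweep(p5, 2, p5[1, ])
    rownames(p5) <- c("N9", "C8", "N7", "C5", "C4")
    # six-ring fused on C4-C5 edge: C4 C5 C6 N1 C2 N3
    c4 <- p5["C4", ]; c5 <- p5["C5", ]
    mid <- (c4 + c5) / 2
    edge <- unit(c(c5 - c4, 0))[1:2]
    perp <- c(edge[2], -edge[1])
    ctr5 <- colMeans(p5)
    if (sum((mid + perp - ctr5)^2) < sum((mid - perp - ctr5)^2)) perp <- -perp
    rad6 <- 1.38 / (2 * sin(pi / 6))
    apo6 <- rad6 * cos(pi / 6)
    ctr6 <- mid + perp * apo6
    ang0 <- atan2(c5[2] - ctr6[2], c5[1] - ctr6[1])
    p6 <- t(vapply(0:5, function(k) {
      a <- ang0 + k * 2 * pi / 6
      ctr6 + rad6 * c(cos(a), sin(a))
    }, numeric(2)))
    # walk the hexagon starting at C5: C5 C6 N1 C2 N3 C4; pick the walk
    # direction whose final vertex lands on the shared C4
    if (sum((p6[6, ] - c4)^2) > sum((p6[2, ] - c4)^2)) {
      p6 <- p6[c(1, 6:2), ]
    }
    rownames(p6) <- c("C5", "C6", "N1", "C2", "N3", "C4")
    ring <- rbind(p5, p6[c("C6", "N1", "C2", "N3"), ])
    if (base == "A") {
      ring <- rbind(ring, N6 = out_from(ctr6, p6["C6", ], 1.34))
    } else {
      ring <- rbind(ring,
                    O6 = out_from(ctr6, p6["C6", ], 1.24),
                    N2 = out_from(ctr6, p6["C2", ], 1.34))
    }
    ring
  } else {
    p6 <- poly(6, 1.38, pi)
    p6 <- sweep(p6, 2, p6[1, ])
    rownames(p6) <- c("N1", "C2", "N3", "C4", "C5", "C6")
    ctr <- colMeans(p6)
    ring <- rbind(p6, O2 = out_from(ctr, p6["C2", ], 1.24))
    if (base == "C") {
      ring <- rbind(ring, N4 = out_from(ctr, p6["C4", ], 1.34))
    } else {
      ring <- rbind(ring, O4 = out_from(ctr, p6["C4", ], 1.24))
    }
    ring
  }
}

#' Ideal ribonucleotide template (A-form backbone torsions, anti base)
#'
#' @param base one of "A","C","G","U"
#' @return numeric matrix (atoms x 3) with atom-name rownames
#' @keywords internal
nt_template <- function(base) {
  base <- toupper(base)
  key <- paste0("NT_", base)
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  if (!base %in% NT_CODES) stop("unknown ribonucleotide: ", base)
  co <- list(
    P     = c(0, 0, 0),
    `O5'` = c(1.593, 0, 0)
  )
  co$`C5'` <- place_atom(c(0, 1, 0), co$P, co$`O5'`, 1.440, 120.9, -60)
  co$OP1 <- place_atom(co$`C5'`, co$`O5'`, co$P, 1.485, 108.1, 115)
  co$OP2 <- place_atom(co$`C5'`, co$`O5'`, co$P, 1.485, 108.1, -115)
  co$`C4'` <- place_atom(co$P, co$`O5'`, co$`C5'`, 1.510, 111.5, 178)
  # furanose modelled as a planar five-ring (ideal toy geometry): vertices
  # C4' O4' C1' C2' C3' on a regular pentagon of side 1.48 in a plane tilted
  # off the C5'-C4' bond
  u <- unit(co$`C4'` - co$`C5'`)
  ref <- unit(co$`O5'` - co$`C5'`)
  w <- unit(ref - sum(ref * u) * u)
  prad <- 1.48 / (2 * sin(pi / 5))
  ctr <- co$`C4'` + prad * unit(u * cos(deg2rad(35)) + w * sin(deg2rad(35)))
  ang0 <- atan2(sum((co$`C4'` - ctr) * w), sum((co$`C4'` - ctr) * u))
  ring_names <- c("C4'", "O4'", "C1'", "C2'", "C3'")
  for (k in 1:4) {
    a <- ang0 + k * 2 * pi / 5
    co[[ring_names[k + 1]]] <- ctr + prad * (cos(a) * u + sin(a) * w)
  }
  co$`O3'` <- place_atom(co$`C1'`, co$`C2'`, co$`C3'`, 1.423, 110.0, 115)
  co$`O2'` <- place_atom(co$`C4'`, co$`C3'`, co$`C2'`, 1.413, 110.0, 115)
  gly <- if (base %in% c("A", "G")) "N9" else "N1"
  ngly <- place_atom(co$`C3'`, co$`C2'`, co$`C1'`, 1.470, 113.0, -115)
  # Base plane frame: e1 points from the glycosidic nitrogen away from C1',
  # e2 orthogonal in a plane tilted off the sugar.
  e1 <- unit(ngly - co$`C1'`)
  ref <- unit(co$`O4'` - co$`C1'`)
  e2 <- unit(ref - sum(ref * e1) * e1)
  b2d <- .base_atoms_2d(base)
  # local 2D frame: the ring body lies on +x of the glycosidic atom; map +x
  # to e1 so the ring points away from the sugar
  for (nm in rownames(b2d)) {
    xy <- b2d[nm, ]
    co[[nm]] <- ngly + xy[1] * e1 + xy[2] * e2
  }
  m <- do.call(rbind, co)
  rownames(m) <- names(co)
  .template_cache[[key]] <- m
  m
}

#' Base (side-chain analog) atom names of a ribonucleotide
#' @keywords internal
nt_base_atoms <- function(base) {
  setdiff(rownames(nt_template(base)), RNA_BACKBONE)
}
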