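# Hydrogen-bond based secondary-structure assignment, collapsed to three
# classes (helix / strand / coil).
#
# Backbone N-H...O=C hydrogen bonds are detected with the Kabsch-Sander
# electrostatic criterion (E < -0.5 kcal/mol, amide H rebuilt from the
# backbone since the structures carry heavy atoms only).  n-turn patterns
# give helices (4-turns first, then 3- and 5-turns), bridge patterns give
# strands, everything else is coil.

KS_Q1Q2F <- 0.42 * 0.20 * 332  # kcal/mol * A, Kabsch-Sander constant
KS_CUTOFF <- -0.5

#' @noRd
# Backbone table per protein residue: N, CA, C, O coordinates and a virtual
# amide H.  Residues are "connected" to the previous one when the peptide
# bond C(i-1)-N(i) is intact.
.bb_table <- function(cx) {
  a <- cx$atom[cx$atom$kind == "amino-acid", ]
  uids <- unique(a$uid)
  get1 <- function(uid, name) {
    w <- which(a$uid == uid & a$elety == name)
    if (length(w) == 0) return(c(NA, NA, NA))
    as.numeric(a[w[1], c("x", "y", "z")])
  }
  n <- length(uids)
  out <- list(uid = uids, chain = a$chain[match(uids, a$uid)],
              N = matrix(NA_real_, n, 3), CA = matrix(NA_real_, n, 3),
              C = matrix(NA_real_, n, 3), O = matrix(NA_real_, n, 3),
              H = matrix(NA_real_, n, 3), has_prev = logical(n))
  for (i in seq_len(n)) {
    out$N[i, ] <- get1(uids[i], "N")
    out$CA[i, ] <- get1(uids[i], "CA")
    out$C[i, ] <- get1(uids[i], "C")
    out$O[i, ] <- get1(uids[i], "O")
  }
  for (i in seq_len(n)) {
    if (i == 1 || out$chain[i] != out$chain[i - 1]) next
    d <- sqrt(sum((out$N[i, ] - out$C[i - 1, ])^2))
    if (!is.na(d) && d < 2.5) out$has_prev[i] <- TRUE
  }
  # virtual amide H: along the bisector opposite to C(i-1) and CA
  for (i in seq_len(n)) {
    if (!out$has_prev[i]) next
    v1 <- unit(out$N[i, ] - out$C[i - 1, ])
    v2 <- unit(out$N[i, ] - out$CA[i, ])
    out$H[i, ] <- out$N[i, ] + unit(v1 + v2) * 1.0
  }
  out
}

#' @noRd
# Kabsch-Sander H-bond energy, donor N-H of residue i, acceptor C=O of j.
.hbond_energy <- function(bb, i, j) {
  if (!bb$has_prev[i]) return(Inf)  # no amide H (chain start / Pro-like gap)
  h <- bb$H[i, ]; nn <- bb$N[i, ]
  o <- bb$O[j, ]; cc <- bb$C[j, ]
  if (anyNA(c(h, nn, o, cc))) return(Inf)
  rON <- sqrt(sum((o - nn)^2)); rCH <- sqrt(sum((cc - h)^2))
  rOH <- sqrt(sum((o - h)^2));  rCN <- sqrt(sum((cc - nn)^2))
  if (min(rON, rCH, rOH, rCN) < 0.5) return(Inf)
  KS_Q1Q2F * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
}

#' Assign three-class secondary structure to the protein residues
#'
#' @param cx a `pri_complex` with protein backbone atoms present
#' @return object of class `ss_assignment`: data.frame (uid, chain, label)
#'   with label in helix/strand/coil; RNA residues are not labelled
#' @export
assign_secondary_structure <- function(cx) {
  bb <- .bb_table(cx)
  n <- length(bb$uid)
  lab <- rep("coil", n)
  if (n >= 3) {
    # H-bond matrix: hb[i, j] TRUE when N-H(i) donates to C=O(j)
    hb <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (abs(i - j) < 2 && bb$chain[i] == bb$chain[j]) next
        if (.hbond_energy(bb, i, j) < KS_CUTOFF) hb[i, j] <- TRUE
      }
    }
    same_chain <- outer(bb$chain, bb$chain, "==")
    turn <- function(k) {
      t <- rep(FALSE, n)
      if (n <= k) return(t)
      for (i in seq_len(n - k)) {
        if (same_chain[i, i + k] && hb[i + k, i]) t[i] <- TRUE
      }
      t
    }
    t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)
    helix <- rep(FALSE, n)
    for (i in 2:max(2, n)) {
      if (i <= n - 4 && t4[i - 1] && t4[i]) helix[i:(i + 3)] <- TRUE
    }
    # bridges
    bridge <- rep(FALSE, n)
    for (i in 2:(n - 1)) {
      for (j in 2:(n - 1)) {
        if (abs(i - j) < 3 && same_chain[i, j]) next
        par <- (hb[i, j - 1] && hb[j + 1, i]) || (hb[j, i - 1] && hb[i + 1, j])
        anti <- (hb[i, j] && hb[j, i]) || (hb[i + 1, j - 1] && hb[j + 1, i - 1])
        if (par || anti) { bridge[i] <- TRUE; bridge[j] <- TRUE }
      }
    }
    helix310 <- rep(FALSE, n)
    for (i in 2:max(2, n)) {
      if (i <= n - 3 && t3[i - 1] && t3[i]) helix310[i:(i + 2)] <- TRUE
      if (i <= n - 5 && t5[i - 1] && t5[i]) helix310[i:(i + 4)] <- TRUE
    }
    lab[helix] <- "helix"
    lab[!helix & bridge] <- "strand"
    lab[!helix & !bridge & helix310] <- "helix"
  }
  structure(data.frame(uid = bb$uid, chain = bb$chain, label = lab,
                       stringsAsFactors = FALSE),
            class = c("ss_assignment", "data.frame"))
}
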