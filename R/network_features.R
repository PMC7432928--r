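# Residue interaction network (RIN) and closeness centrality of the
# mutated site.  Nodes are the Calpha atoms of all protein residues
# (partner 1 by default, spanning all protein chains); an edge joins two
# residues whose Calpha-Calpha distance is strictly below the threshold.

#' Build the residue interaction network of the protein
#'
#' @param cx a `pri_complex` (the protein partner; a full complex is
#'   reduced to its protein chains)
#' @param threshold Calpha-Calpha distance threshold in Angstrom (strict
#'   inequality)
#' @param chains optional chain subset; default all protein chains
#' @return object of class `residue_network`: list with `nodes` (residue
#'   uids) and `edges` (two-column matrix of uid pairs)
#' @export
build_network <- function(cx, threshold = 6, chains = NULL) {
  a <- cx$atom
  ca <- a[a$kind == "amino-acid" & a$elety == "CA", , drop = FALSE]
  if (!is.null(chains)) ca <- ca[ca$chain %in% chains, , drop = FALSE]
  rt <- residue_table(cx)
  prot <- rt$uid[rt$kind == "amino-acid" &
                   (is.null(chains) | rt$chain %in% (chains %||% rt$chain))]
  no_ca <- setdiff(prot, ca$uid)
  if (length(no_ca) > 0)
    warning("residue(s) without Calpha excluded from the network: ",
            paste(no_ca, collapse = ", "))
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  n <- nrow(ca)
  edges <- NULL
  if (n >= 2) {
    d <- as.matrix(stats::dist(xyz))
    hit <- which(upper.tri(d) & d < threshold, arr.ind = TRUE)
    if (nrow(hit) > 0)
      edges <- cbind(ca$uid[hit[, 1]], ca$uid[hit[, 2]])
  }
  if (is.null(edges)) edges <- matrix(character(0), 0, 2)
  structure(list(nodes = ca$uid, edges = edges, threshold = threshold),
            class = "residue_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Closeness centrality of a node in the residue network
#'
#' C(u) = (n - 1) / sum of shortest-path hop distances from u to every
#' other node.  On disconnected graphs the sum runs over u's connected
#' component (size k) and the value is scaled by (k - 1)/(n - 1)
#' (Wasserman-Faust convention); an isolated node has closeness 0.  For
#' connected graphs this reduces exactly to the plain formula.
#'
#' @param g a `residue_network`
#' @param u node id (residue uid); omit to get all nodes
#' @return named numeric vector of closeness values in [0, 1]
#' @export
closeness_centrality <- function(g, u = NULL) {
  n <- length(g$nodes)
  ig <- igraph::graph_from_data_frame(
    d = as.data.frame(g$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = g$nodes, stringsAsFactors = FALSE))
  d <- igraph::distances(ig, weights = NA)
  vals <- vapply(g$nodes, function(v) {
    dv <- d[v, ]
    reach <- is.finite(dv) & g$nodes != v
    k <- sum(reach) + 1
    if (k == 1) return(0)
    ((k - 1) / sum(dv[reach])) * ((k - 1) / (n - 1))
  }, numeric(1))
  names(vals) <- g$nodes
  if (!is.null(u)) {
    if (!u %in% g$nodes) stop("node ", u, " not in the network")
    return(vals[u])
  }
  vals
}
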