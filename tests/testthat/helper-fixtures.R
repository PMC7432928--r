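# Shared fixtures, built once per test run.  Fast minimization settings
# keep per-mutation pipeline tests quick; feature values are still fully
# exercised because the pipeline is identical apart from the step count.

fast_settings <- minimization_settings(n_steps = 30)

toy_docked <- make_toy_complex(n_res = 12, n_nt = 6, geometry = "helix",
                               separation = 4, seed = 1)
toy_far <- make_toy_complex(n_res = 12, n_nt = 6, geometry = "helix",
                            separation = 100, seed = 1)

# a tiny complex from arbitrary atom rows (for closed-form SASA/energy
# checks); each entry: list(elety, resid, chain, resno, xyz, kind)
complex_from_atoms <- function(entries, partner1 = "A",
                               partner2 = character(0)) {
  rows <- lapply(entries, function(e)
    priddg:::.atoms_row(e[[1]], e[[2]], e[[3]], e[[4]], e[[5]], e[[6]]))
  at <- do.call(rbind, rows)
  at$eleno <- seq_len(nrow(at))
  priddg:::new_pri_complex(at, partner1, partner2)
}

# brute-force double-loop energy oracles (independent of the vectorized
# implementation)
oracle_lj <- function(cx, ia, ib, params = ff_params()) {
  ty <- type_atoms(cx, params)
  xyz <- as.matrix(cx$atom[, c("x", "y", "z")])
  e <- 0
  for (i in ia) for (j in ib) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    eps <- sqrt(ty$epsilon[i] * ty$epsilon[j])
    rmin <- ty$rmin_half[i] + ty$rmin_half[j]
    e <- e + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
  }
  e
}

oracle_lj_rep <- function(cx, ia, ib, params = ff_params()) {
  ty <- type_atoms(cx, params)
  xyz <- as.matrix(cx$atom[, c("x", "y", "z")])
  e <- 0
  for (i in ia) for (j in ib) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    e <- e + sqrt(ty$epsilon[i] * ty$epsilon[j]) *
      ((ty$rmin_half[i] + ty$rmin_half[j]) / r)^12
  }
  e
}

oracle_coulomb <- function(cx, ia, ib, params = ff_params()) {
  ty <- type_atoms(cx, params)
  xyz <- as.matrix(cx$atom[, c("x", "y", "z")])
  e <- 0
  for (i in ia) for (j in ib) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    e <- e + 332.0716 * ty$charge[i] * ty$charge[j] / r
  }
  e
}

# breadth-first-search shortest-path oracle over an edge list
oracle_bfs_dist <- function(nodes, edges, from) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  d <- setNames(rep(Inf, length(nodes)), nodes)
  d[from] <- 0
  queue <- from
  while (length(queue) > 0) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) if (!is.finite(d[v])) {
      d[v] <- d[u] + 1
      queue <- c(queue, v)
    }
  }
  d
}
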