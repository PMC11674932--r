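# Independent oracles and hand-built fixtures shared across the suite.

# Brute-force all-pairs shortest paths (Floyd-Warshall), independent of the
# Dijkstra-based implementation under test.
floyd_warshall <- function(edge_length) {
  d <- ifelse(edge_length > 0, edge_length, Inf)
  diag(d) <- 0
  n <- nrow(d)
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

mean_spl_oracle <- function(edge_length) {
  d <- floyd_warshall(edge_length)[upper.tri(edge_length)]
  mean(d[is.finite(d)])
}

efficiency_oracle <- function(edge_length) {
  d <- floyd_warshall(edge_length)[upper.tri(edge_length)]
  mean(ifelse(is.finite(d), 1 / d, 0))
}

make_distance_graph <- function(edge_length,
                                hemisphere = rep("L", nrow(edge_length))) {
  structure(list(labels = paste0("n", seq_len(nrow(edge_length))),
                 hemisphere = hemisphere, edge_length = edge_length),
            class = "distance_graph")
}

# Random connected weighted graph on n nodes (spanning tree + extra edges),
# returned as a dense edge-length matrix. Uses the ambient RNG state.
random_edge_lengths <- function(n, extra = n) {
  el <- matrix(0, n, n)
  ord <- sample.int(n)
  for (k in 2:n) {
    i <- ord[k]
    j <- ord[sample.int(k - 1, 1)]
    el[i, j] <- el[j, i] <- runif(1, 0.1, 3)
  }
  for (e in seq_len(extra)) {
    ij <- sample.int(n, 2)
    if (el[ij[1], ij[2]] == 0) {
      el[ij[1], ij[2]] <- el[ij[2], ij[1]] <- runif(1, 0.1, 3)
    }
  }
  el
}

# 4-node hand fixture: L1L2 = 30, R1R2 = 30, L1R1 = 20, L2R2 = 20
# (inter = 40, total = 100), unit lengths.
fixture_4node <- function() {
  w <- matrix(0, 4, 4,
              dimnames = list(c("L1", "L2", "R1", "R2"),
                              c("L1", "L2", "R1", "R2")))
  w["L1", "L2"] <- w["L2", "L1"] <- 30
  w["R1", "R2"] <- w["R2", "R1"] <- 30
  w["L1", "R1"] <- w["R1", "L1"] <- 20
  w["L2", "R2"] <- w["R2", "L2"] <- 20
  len <- matrix(1, 4, 4)
  diag(len) <- 0
  connectome(w, len, c("L1", "L2", "R1", "R2"), c("L", "L", "R", "R"),
             rep(TRUE, 4))
}

# Mirror-symmetric 6-node fixture (3 nodes per hemisphere), used for the
# algebraic scaling checks.
fixture_6node <- function() {
  lab <- c("L1", "L2", "L3", "R1", "R2", "R3")
  hemi <- c("L", "L", "L", "R", "R", "R")
  w <- matrix(0, 6, 6, dimnames = list(lab, lab))
  set_edge <- function(a, b, v) w[a, b] <<- w[b, a] <<- v
  set_edge("L1", "L2", 4); set_edge("L2", "L3", 2); set_edge("L1", "L3", 1)
  set_edge("R1", "R2", 4); set_edge("R2", "R3", 2); set_edge("R1", "R3", 1)
  set_edge("L1", "R1", 3); set_edge("L3", "R3", 0.5)
  len <- matrix(1, 6, 6)
  diag(len) <- 0
  connectome(w, len, lab, hemi, rep(TRUE, 6))
}

# Quick commissural ratio on the length-normalized cortical graph, skipping
# the (slow) path-length measures; used by generator-level statistics tests.
quick_commissural <- function(cohort) {
  vapply(cohort$connectomes, function(cn) {
    b <- hemisphere_blocks(cortical_subgraph(normalize_by_length(cn)))
    commissural_ratio(b$inter_weight_sum, b$total_weight_sum)
  }, numeric(1))
}
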