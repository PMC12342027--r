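# Hand-built miniature networks and brute-force oracles used across tests.

make_net <- function(role, substrate = 20, h2o2 = 0, ai1 = 0, gfp = 0,
                     edges = matrix(integer(0), ncol = 2), mobile = TRUE) {
  n <- length(role)
  consortnet:::new_network(
    role = role,
    substrate = rep_len(substrate, n),
    h2o2 = rep_len(h2o2, n),
    ai1 = rep_len(ai1, n),
    gfp = rep_len(gfp, n),
    mobile = rep_len(mobile, n),
    edges = edges
  )
}

line_edges <- function(n) cbind(seq_len(n - 1), seq_len(n - 1) + 1L)

star_edges <- function(n_leaves) cbind(1L, 1L + seq_len(n_leaves))

clique_edges <- function(ids) {
  t(utils::combn(ids, 2))
}

# Combinatorial graph Laplacian of an edge matrix over n nodes.
laplacian_matrix_of <- function(edges, n) {
  A <- matrix(0, n, n)
  A[edges] <- 1
  A[edges[, c(2, 1), drop = FALSE]] <- 1
  diag(rowSums(A)) - A
}

# All set partitions of 1..n as lists of integer membership vectors.
set_partitions <- function(n) {
  out <- list()
  recurse <- function(i, memb, k) {
    if (i > n) {
      out[[length(out) + 1]] <<- memb
      return(invisible())
    }
    for (g in seq_len(k + 1)) {
      memb[i] <- g
      recurse(i + 1, memb, max(k, g))
    }
  }
  recurse(1, integer(n), 0)
  out
}

# Newman-Girvan modularity of a given membership vector.
modularity_of <- function(membership, edges, n) {
  m <- nrow(edges)
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  q <- 0
  for (g in unique(membership)) {
    idx <- which(membership == g)
    within <- sum(membership[edges[, 1]] == g & membership[edges[, 2]] == g)
    q <- q + within / m - (sum(deg[idx]) / (2 * m))^2
  }
  q
}

# Exhaustive-search modularity maximum (feasible for n <= 8).
brute_force_modularity <- function(edges, n) {
  max(vapply(set_partitions(n), modularity_of, numeric(1),
             edges = edges, n = n))
}
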