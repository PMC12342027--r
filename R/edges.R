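#' Per-step edge rewiring: stirred, static and partially fixed cultures
#'
#' Implements the culture-mixing models.  `"static"` leaves the edge set
#' untouched (a biofilm or otherwise immobilized culture).  `"randomized"`
#' (a stirred batch culture) resamples the current number of cell-cell
#' edges as distinct non-loop pairs placed uniformly at random over all
#' cell nodes.  `"partial"` keeps every edge whose two endpoints are both
#' immobile verbatim and replaces every other edge by a uniformly sampled
#' pair with at least one mobile endpoint.  The edge count is preserved in
#' every mode, keeping stirred and static cultures comparable; electrode
#' links are managed by [electrode_step()], never here.
#'
#' @param network a `consortnet_network`.
#' @param mode `"randomized"`, `"static"` or `"partial"`.
#' @param keep_fixed_endpoint in `"partial"` mode, retain the immobile
#'   endpoint of a mixed edge and resample only the mobile side.
#' @return The network with a rewired cell-cell edge set.
#' @export
randomize_edges <- function(network,
                            mode = c("randomized", "static", "partial"),
                            keep_fixed_endpoint = FALSE) {
  mode <- match.arg(mode)
  if (mode == "static") {
    return(network)
  }
  cells <- cell_ids(network)
  m <- nrow(network$edges)
  if (m == 0) {
    return(network)
  }
  if (mode == "randomized") {
    network$edges <- sample_distinct_pairs(cells, m)
    return(network)
  }
  # partial: immobile-immobile edges persist bitwise
  mob <- network$mobile
  e <- network$edges
  fixed_edge <- !mob[e[, 1L]] & !mob[e[, 2L]]
  kept <- e[fixed_edge, , drop = FALSE]
  m_rewire <- m - nrow(kept)
  if (m_rewire == 0 || !any(mob[cells])) {
    return(network)
  }
  if (keep_fixed_endpoint) {
    rewired <- rewire_keeping_fixed(e[!fixed_edge, , drop = FALSE],
                                    cells, mob)
  } else {
    rewired <- sample_mixed_pairs(cells, mob, m_rewire)
  }
  network$edges <- rbind(kept, rewired)
  network
}

# Uniformly sample m distinct pairs over `cells` with >= 1 mobile endpoint,
# by batched rejection from the full pair universe.
sample_mixed_pairs <- function(cells, mob, m) {
  nn <- length(cells)
  total <- nn * (nn - 1) / 2
  got <- integer(0)
  guard <- 0L
  while (length(got) < m) {
    guard <- guard + 1L
    if (guard > 50L) {
      stop("could not sample enough mobile-incident pairs", call. = FALSE)
    }
    k <- sample.int(total, min(total, 2L * m))
    ij <- decode_pair_index(k, nn)
    ok <- mob[cells[ij[, 1L]]] | mob[cells[ij[, 2L]]]
    got <- unique(c(got, k[ok]))
  }
  got <- got[seq_len(m)]
  ij <- decode_pair_index(got, nn)
  u <- cells[ij[, 1L]]
  v <- cells[ij[, 2L]]
  cbind(pmin(u, v), pmax(u, v))
}

# Alternative partial-mode policy: a mixed edge keeps its immobile endpoint
# and redraws the other endpoint among mobile cells.
rewire_keeping_fixed <- function(edges, cells, mob) {
  mobile_cells <- cells[mob[cells]]
  u <- edges[, 1L]
  v <- edges[, 2L]
  keep <- ifelse(!mob[u], u, ifelse(!mob[v], v, NA_integer_))
  out <- matrix(NA_integer_, nrow = nrow(edges), ncol = 2)
  for (i in seq_len(nrow(edges))) {
    anchor <- keep[i]
    if (is.na(anchor)) {
      pair <- resample(mobile_cells, 2L)
    } else {
      other <- resample(setdiff(mobile_cells, anchor), 1L)
      pair <- c(anchor, other)
    }
    out[i, ] <- c(min(pair), max(pair))
  }
  canonical_edges(out[, 1L], out[, 2L])
}
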