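#' Fraction of active nodes
#'
#' A cell counts as active when its GFP strictly exceeds the threshold
#' (default 1000, the activation threshold used for all percent-active
#' summaries).  The electrode is excluded.
#'
#' @param x a numeric GFP vector, a `consortnet_network`, a
#'   `consortnet_run`, or a `consortnet_replicates` (pooled endpoint).
#' @param threshold activation threshold (> 0).
#' @return Fraction in `[0, 1]`.
#' @export
percent_active <- function(x, threshold = 1000) {
  stopifnot(threshold > 0)
  g <- gfp_pool(x)
  if (!length(g)) stop("empty network: percent_active undefined",
                       call. = FALSE)
  mean(g > threshold)
}

#' Median GFP over pooled nodes
#'
#' Sample median over all cell nodes, pooled across replicates when given a
#' replicate set.
#'
#' @inheritParams percent_active
#' @return The median GFP.
#' @export
median_gfp <- function(x) {
  g <- gfp_pool(x)
  if (!length(g)) stop("empty network: median undefined", call. = FALSE)
  stats::median(g)
}

gfp_pool <- function(x) {
  if (is.numeric(x)) {
    x
  } else if (inherits(x, "consortnet_network")) {
    cell_values(x, "gfp")
  } else if (inherits(x, "consortnet_run") ||
             inherits(x, "consortnet_replicates")) {
    pooled_values(x, "gfp")
  } else {
    stop("cannot extract GFP values from this object", call. = FALSE)
  }
}

#' Fold change between matched edge-mode conditions
#'
#' Ratio of mean GFP (pooled over replicates) of an edge-randomized
#' condition to its static-edge twin, the summary used to quantify the
#' benefit of stirring over biofilm-like fixed topologies.
#'
#' @param randomized,static numeric vectors of pooled node GFP (or objects
#'   accepted by [median_gfp()]) from matched configurations differing only
#'   in their edge dynamics.
#' @return The ratio `mean(randomized) / mean(static)`.
#' @export
fold_change <- function(randomized, static) {
  num <- mean(gfp_pool(randomized))
  den <- mean(gfp_pool(static))
  if (den == 0) stop("fold change undefined: zero denominator", call. = FALSE)
  num / den
}

#' Convert to an igraph graph
#'
#' @param network a `consortnet_network`.
#' @param include_electrode keep the electrode node and its links?
#' @return An undirected `igraph` graph with node attributes `role`,
#'   `substrate`, `h2o2`, `ai1`, `gfp`, `mobile`.
#' @export
as_igraph <- function(network, include_electrode = TRUE) {
  e <- if (include_electrode) all_edges(network) else network$edges
  keep <- if (include_electrode || is.na(network$electrode_id)) {
    seq_len(network$n)
  } else {
    cell_ids(network)
  }
  idx <- match(seq_len(network$n), keep)
  g <- igraph::make_empty_graph(length(keep), directed = FALSE)
  if (nrow(e)) {
    g <- igraph::add_edges(g, rbind(idx[e[, 1L]], idx[e[, 2L]]))
  }
  igraph::V(g)$name <- as.character(keep)
  igraph::V(g)$role <- network$role[keep]
  igraph::V(g)$substrate <- network$substrate[keep]
  igraph::V(g)$h2o2 <- network$h2o2[keep]
  igraph::V(g)$ai1 <- network$ai1[keep]
  igraph::V(g)$gfp <- network$gfp[keep]
  igraph::V(g)$mobile <- network$mobile[keep]
  g
}

#' Louvain modularity of the cell-cell graph
#'
#' Newman-Girvan modularity of the partition found by the Louvain
#' community-detection heuristic.  The heuristic is order-dependent, so the
#' best of `restarts` runs over random vertex permutations is reported; a
#' near-random single community scores about 0 and strong community
#' structure approaches 1.  The electrode node is excluded by default.
#'
#' @param network a `consortnet_network` (or an `igraph` graph).
#' @param resolution Louvain resolution parameter.
#' @param restarts number of random-permutation restarts.
#' @param include_electrode include the electrode node and its links?
#' @return The best modularity value found.
#' @export
louvain_modularity <- function(network, resolution = 1, restarts = 10,
                               include_electrode = FALSE) {
  g <- if (inherits(network, "igraph")) network
       else as_igraph(network, include_electrode = include_electrode)
  if (igraph::ecount(g) == 0) {
    stop("modularity undefined on an edgeless graph", call. = FALSE)
  }
  n <- igraph::vcount(g)
  best <- -Inf
  for (r in seq_len(restarts)) {
    perm <- sample.int(n)
    gp <- igraph::permute(g, perm)
    cl <- igraph::cluster_louvain(gp, resolution = resolution)
    q <- max(cl$modularity)
    if (q > best) best <- q
  }
  best
}
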