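#' Substrate-gated stochastic division
#'
#' Every cell node whose substrate strictly exceeds the threshold `k`
#' divides independently with probability `p_div`.  On division the parent
#' persists as one daughter and a fresh node is appended as the other:
#' substrate, hydrogen peroxide and AI-1 are halved between the two, GFP is
#' copied unchanged to both (daughters maintain their parent's
#' fluorescence; protein degradation is neglected), and role and mobility
#' are inherited.  All division decisions of a step are drawn first; edge
#' inheritance is then resolved against the pre-division topology so that
#' same-step daughters are available as neighbor candidates.  The electrode
#' never divides.
#'
#' @param network a `consortnet_network`.
#' @param p_div division probability per eligible node per step.
#' @param k substrate threshold (division requires `substrate > k`).
#' @param max_neighbors cap on inherited neighbors per daughter.
#' @return A list with elements `network` (updated) and `events`
#'   (data.frame `timestep`, `parent`, `daughter`).
#' @export
growth_step <- function(network, p_div, k, max_neighbors = 10L) {
  no_events <- data.frame(timestep = integer(0), parent = integer(0),
                          daughter = integer(0))
  if (p_div <= 0) {
    return(list(network = network, events = no_events))
  }
  eligible <- which(network$role != "electrode" & network$substrate > k)
  if (!length(eligible)) {
    return(list(network = network, events = no_events))
  }
  dividing <- eligible[stats::runif(length(eligible)) < p_div]
  nd <- length(dividing)
  if (!nd) {
    return(list(network = network, events = no_events))
  }

  n_old <- network$n
  daughters <- n_old + seq_len(nd)
  daughter_of <- integer(n_old)
  daughter_of[dividing] <- daughters

  # halve the partitioned weights; copy GFP, role, mobility
  half_s <- network$substrate[dividing] / 2
  half_h <- network$h2o2[dividing] / 2
  half_a <- network$ai1[dividing] / 2
  network$substrate[dividing] <- half_s
  network$h2o2[dividing] <- half_h
  network$ai1[dividing] <- half_a
  network$substrate <- c(network$substrate, half_s)
  network$h2o2 <- c(network$h2o2, half_h)
  network$ai1 <- c(network$ai1, half_a)
  network$gfp <- c(network$gfp, network$gfp[dividing])
  network$role <- c(network$role, network$role[dividing])
  network$mobile <- c(network$mobile, network$mobile[dividing])
  network$n <- n_old + nd

  # frozen pre-division neighborhoods of the dividing nodes
  e <- network$edges
  div_mask <- rep(FALSE, n_old)
  div_mask[dividing] <- TRUE
  touched <- div_mask[e[, 1L]] | div_mask[e[, 2L]]
  et <- e[touched, , drop = FALSE]

  new_edges <- vector("list", nd + 1L)
  new_edges[[1L]] <- e[!touched, , drop = FALSE]
  for (i in seq_len(nd)) {
    p <- dividing[i]
    d <- daughters[i]
    nb <- c(et[et[, 1L] == p, 2L], et[et[, 2L] == p, 1L])
    new_edges[[i + 1L]] <- inherited_edge_rows(nb, daughter_of, p, d,
                                               max_neighbors)
  }
  ne <- do.call(rbind, new_edges)
  network$edges <- canonical_edges(ne[, 1L], ne[, 2L])

  list(network = network,
       events = data.frame(timestep = network$time, parent = dividing,
                           daughter = daughters))
}

# Edge rows for one division event given the parent's frozen pre-division
# neighborhood `nb` and the step's parent -> daughter map.
inherited_edge_rows <- function(nb, daughter_of, parent, daughter,
                                max_neighbors) {
  extra <- daughter_of[nb]
  cand <- c(nb, extra[extra > 0L])
  pick <- function() {
    if (length(cand) <= max_neighbors) cand
    else resample(cand, max_neighbors)
  }
  rbind(
    if (length(cand)) cbind(parent, pick()) else NULL,
    if (length(cand)) cbind(daughter, pick()) else NULL,
    cbind(parent, daughter)
  )
}

#' Edge inheritance for a single division event
#'
#' Parent and daughter share an edge; each of the two receives edges to at
#' most `max_neighbors` nodes sampled uniformly without replacement from the
#' parent's pre-division neighborhood augmented by that neighborhood's
#' same-step daughters (a neighbor set of at most `max_neighbors` candidates
#' is kept in full).  The parent's previous edges are replaced by its
#' sampled set.  [growth_step()] applies the same rule to all of a step's
#' divisions against a common frozen topology; this single-event form is
#' exposed for targeted construction and testing.
#'
#' @param network a `consortnet_network` already containing the daughter
#'   node (with inherited attributes).
#' @param parent_id,daughter_id the division pair.
#' @param max_neighbors cap on inherited neighbors per daughter.
#' @param same_step_daughters named integer vector mapping ids of neighbors
#'   that divided this step to their daughters.
#' @return The network with the parent's edges replaced and the daughter
#'   wired in.
#' @export
inherit_edges <- function(network, parent_id, daughter_id,
                          max_neighbors = 10L,
                          same_step_daughters = integer(0)) {
  stopifnot(parent_id >= 1, parent_id <= network$n,
            daughter_id >= 1, daughter_id <= network$n)
  e <- network$edges
  touch <- e[, 1L] == parent_id | e[, 2L] == parent_id
  nb <- c(e[e[, 1L] == parent_id, 2L], e[e[, 2L] == parent_id, 1L])
  daughter_of <- integer(network$n)
  if (length(same_step_daughters)) {
    daughter_of[as.integer(names(same_step_daughters))] <-
      as.integer(same_step_daughters)
  }
  rows <- inherited_edge_rows(nb, daughter_of, parent_id, daughter_id,
                              max_neighbors)
  ne <- rbind(e[!touch, , drop = FALSE], rows)
  network$edges <- canonical_edges(ne[, 1L], ne[, 2L])
  network
}

#' Maximum attainable network size
#'
#' Substrate halves at every division and division requires substrate
#' strictly above `k`, so each founder lineage supports a bounded number of
#' generations: the node count can never exceed `n0 * 2^d`, where `d` is the
#' number of successive halvings of `s0` that start strictly above `k`.
#' Computed by iterated halving.
#'
#' @param n0 initial node count.
#' @param s0 initial substrate per node.
#' @param k division threshold (`s0 > k > 0`).
#' @return Integer upper bound on the node count.
#' @examples
#' max_network_size(50, 20, 1)   # 1600: five halvings
#' max_network_size(100, 20, 1)  # 3200
#' @export
max_network_size <- function(n0, s0, k) {
  stopifnot(k > 0)
  d <- 0L
  s <- s0
  while (s > k) {
    s <- s / 2
    d <- d + 1L
  }
  as.integer(n0 * 2^d)
}
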