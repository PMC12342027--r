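#' @rdname init_network
#' @format NULL
#' @export
NODE_ROLES <- c("monoculture_receiver", "transmitter", "ai1_receiver",
                "electrode")

#' Simulation configuration
#'
#' Bundles every kinetic, growth, induction and topology parameter of the
#' simulator.  Defaults are the calibrated values used throughout the
#' chemically and electrically induced Monoculture and Transmitter/Receiver
#' scenarios: an initial population of 100 cells with an average of four
#' communication channels per cell, initial substrate `s0 = 20` against a
#' division threshold `k = 1` (so each founder lineage can divide five
#' times), per-step division probability `p_div = 0.015`, and diffusion
#' coefficient `alpha = 1` on a unit timestep.
#'
#' @param n_initial integer, initial number of cell nodes (>= 2).
#' @param mean_degree average number of edges per node at initialization;
#'   the edge count is `round(n_initial * mean_degree / 2)`.
#' @param s0 initial substrate weight per cell (model units).
#' @param k substrate threshold; a cell divides only while `substrate > k`.
#' @param p_div per-cell, per-step division probability in `[0, 1]`.
#' @param alpha diffusion coefficient of the discrete graph diffusion.
#' @param dt timestep length (the model is calibrated for `dt = 1`).
#' @param transmitter_fraction fraction of cells assigned the transmitter
#'   role (0 for Monoculture, 0.10 for Transmitter/Receiver).
#' @param gfp_init_mean,gfp_init_sd parameters of the initial GFP Gaussian
#'   (truncated below at zero; fluorescence cannot be negative).
#' @param h2o2_initial micromolar hydrogen peroxide added uniformly to every
#'   cell at `t = 0` (chemical induction; 0 under electrical induction).
#' @param induction `"chemical"` or `"electrical"`.
#' @param charge_duration integer number of initial steps the electrode is
#'   on (electrical induction).
#' @param electrode_production micromolar hydrogen peroxide deposited at the
#'   electrode node per on-step (fitted for a 100-cell network; not
#'   auto-scaled for other sizes).
#' @param electrode_cap_fraction maximum fraction of cell nodes linked to
#'   the electrode at any time.
#' @param growth_resume_step timestep at which division resumes under
#'   electrical induction; `NULL` means at charge end.
#' @param max_neighbors_on_division cap on inherited neighbors per daughter.
#' @param activation_threshold_gfp GFP level above which a node counts as
#'   active.
#' @param edge_mode `"randomized"` (stirred culture), `"static"` (biofilm)
#'   or `"partial"` (only edges between two immobile nodes persist).
#' @param fixed_roles roles whose nodes are immobile in `"partial"` mode.
#' @param rewire_keep_fixed_endpoint in `"partial"` mode, keep the immobile
#'   endpoint of a mixed edge and resample only the mobile one.
#' @param steps total number of timesteps to simulate.
#' @param transmitter_gfp should transmitters also accumulate GFP (they
#'   carry the same peroxide-driven circuit as Monoculture receivers)?
#' @param deterministic_expectation replace the Bernoulli activation gate by
#'   its expectation (deterministic mean-field update), for comparison runs.
#' @param diffusion_mode `"limit"` (mass-conserving outflux limiter, the
#'   default), `"clamp"` (clamp negatives to zero, logging the created
#'   mass) or `"none"` (raw update, may go negative).
#' @param kinetics a [kinetic_params()] object.
#' @param topology one of `"fully_mixed"`,
#'   `"fixed_transmitters_mixed_receivers"`,
#'   `"fixed_transmitters_fixed_receivers"`, `"fully_static"`.
#' @param snapshot_stride store a full network snapshot every this many
#'   steps (0 = endpoint only).
#'
#' @return A validated list of class `consortnet_config`.
#' @seealso [init_network()], [run_simulation()], [scenario_config()]
#' @export
sim_config <- function(n_initial = 100L,
                       mean_degree = 4,
                       s0 = 20,
                       k = 1,
                       p_div = 0.015,
                       alpha = 1,
                       dt = 1,
                       transmitter_fraction = 0,
                       gfp_init_mean = 500,
                       gfp_init_sd = 250,
                       h2o2_initial = 0,
                       induction = c("chemical", "electrical"),
                       charge_duration = 0L,
                       electrode_production = 46,
                       electrode_cap_fraction = 0.05,
                       growth_resume_step = NULL,
                       max_neighbors_on_division = 10L,
                       activation_threshold_gfp = 1000,
                       edge_mode = c("randomized", "static", "partial"),
                       fixed_roles = character(0),
                       rewire_keep_fixed_endpoint = FALSE,
                       steps = 180L,
                       transmitter_gfp = TRUE,
                       deterministic_expectation = FALSE,
                       diffusion_mode = c("limit", "clamp", "none"),
                       kinetics = kinetic_params(),
                       topology = c("fully_mixed",
                                    "fixed_transmitters_mixed_receivers",
                                    "fixed_transmitters_fixed_receivers",
                                    "fully_static"),
                       snapshot_stride = 0L) {
  cfg <- list(
    n_initial = as.integer(n_initial),
    mean_degree = mean_degree,
    s0 = s0,
    k = k,
    p_div = p_div,
    alpha = alpha,
    dt = dt,
    transmitter_fraction = transmitter_fraction,
    gfp_init_mean = gfp_init_mean,
    gfp_init_sd = gfp_init_sd,
    h2o2_initial = h2o2_initial,
    induction = match.arg(induction),
    charge_duration = as.integer(charge_duration),
    electrode_production = electrode_production,
    electrode_cap_fraction = electrode_cap_fraction,
    growth_resume_step = if (is.null(growth_resume_step)) NULL
                         else as.integer(growth_resume_step),
    max_neighbors_on_division = as.integer(max_neighbors_on_division),
    activation_threshold_gfp = activation_threshold_gfp,
    edge_mode = match.arg(edge_mode),
    fixed_roles = fixed_roles,
    rewire_keep_fixed_endpoint = isTRUE(rewire_keep_fixed_endpoint),
    steps = as.integer(steps),
    transmitter_gfp = isTRUE(transmitter_gfp),
    deterministic_expectation = isTRUE(deterministic_expectation),
    diffusion_mode = match.arg(diffusion_mode),
    kinetics = kinetics,
    topology = match.arg(topology),
    snapshot_stride = as.integer(snapshot_stride)
  )
  class(cfg) <- "consortnet_config"
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the parameter invariants (probabilities within `[0, 1]`,
#' `alpha > 0`, `s0 > k > 0`, realizable edge count, ...).  Called by
#' [sim_config()] and [load_config()]; exported so that manually edited
#' configurations can be re-checked.
#'
#' @param cfg a `consortnet_config` object.
#' @return `cfg`, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(cfg) {
  fail <- function(...) stop("invalid config: ", ..., call. = FALSE)
  if (cfg$n_initial < 2) fail("n_initial must be >= 2")
  m <- round(cfg$n_initial * cfg$mean_degree / 2)
  if (m > cfg$n_initial * (cfg$n_initial - 1) / 2) {
    fail("mean_degree implies more edges than distinct node pairs")
  }
  if (cfg$p_div < 0 || cfg$p_div > 1) fail("p_div must lie in [0, 1]")
  if (cfg$transmitter_fraction < 0 || cfg$transmitter_fraction > 1) {
    fail("transmitter_fraction must lie in [0, 1]")
  }
  if (cfg$alpha <= 0) fail("alpha must be positive")
  if (cfg$dt <= 0) fail("dt must be positive")
  if (!(cfg$s0 > cfg$k) || cfg$k <= 0) fail("need s0 > k > 0")
  if (cfg$h2o2_initial < 0) fail("h2o2_initial must be nonnegative")
  if (cfg$charge_duration < 0) fail("charge_duration must be nonnegative")
  if (cfg$electrode_production < 0) {
    fail("electrode_production must be nonnegative")
  }
  if (cfg$electrode_cap_fraction <= 0 || cfg$electrode_cap_fraction > 1) {
    fail("electrode_cap_fraction must lie in (0, 1]")
  }
  if (cfg$max_neighbors_on_division < 1) fail("max_neighbors_on_division < 1")
  if (cfg$steps < 0) fail("steps must be nonnegative")
  if (cfg$edge_mode == "partial" && length(cfg$fixed_roles) == 0) {
    fail("partial edge mode requires a nonempty fixed_roles")
  }
  if (!all(cfg$fixed_roles %in% NODE_ROLES)) fail("unknown role in fixed_roles")
  validate_kinetics(cfg$kinetics)
  invisible(cfg)
}

new_network <- function(role, substrate, h2o2, ai1, gfp, mobile, edges,
                        time = 0L, electrode_id = NA_integer_,
                        electrode_links = integer(0)) {
  structure(
    list(
      n = length(role),
      role = role,
      substrate = substrate,
      h2o2 = h2o2,
      ai1 = ai1,
      gfp = gfp,
      mobile = mobile,
      edges = edges,
      electrode_id = electrode_id,
      electrode_links = electrode_links,
      time = as.integer(time),
      audit = list(limited_flux = 0, clamped_mass = 0)
    ),
    class = "consortnet_network"
  )
}

#' Initialize a random consortium network
#'
#' Builds a G(n, m) random graph (m distinct non-loop edges placed uniformly
#' at random over `n_initial` cell nodes), assigns roles via
#' [assign_roles()], and sets the initial node weights: substrate `s0`,
#' hydrogen peroxide `h2o2_initial` (zero under electrical induction), zero
#' AI-1, and GFP drawn from a Gaussian truncated below at zero.
#'
#' @param config a [sim_config()] object.
#' @return A `consortnet_network` at time 0.
#' @examples
#' set.seed(1)
#' net <- init_network(sim_config(n_initial = 100, mean_degree = 4))
#' net$n                # 100
#' nrow(net$edges)      # 200
#' @export
init_network <- function(config) {
  validate_config(config)
  n <- config$n_initial
  m <- as.integer(round(n * config$mean_degree / 2))
  edges <- sample_distinct_pairs(seq_len(n), m)
  h0 <- if (config$induction == "electrical") 0 else config$h2o2_initial
  net <- new_network(
    role = rep("monoculture_receiver", n),
    substrate = rep(config$s0, n),
    h2o2 = rep(h0, n),
    ai1 = rep(0, n),
    gfp = rnorm_trunc0(n, config$gfp_init_mean, config$gfp_init_sd),
    mobile = rep(TRUE, n),
    edges = edges
  )
  assign_roles(net, config$transmitter_fraction)
}

#' Assign transmitter and receiver roles
#'
#' Uniformly chooses `round(fraction * n)` cell nodes as transmitters
#' (peroxide-sensing, AI-1 producing); the remainder become AI-1 receivers.
#' A fraction of zero yields a Monoculture in which every node is a
#' peroxide-sensing, GFP-producing receiver.
#'
#' @param network a `consortnet_network` without an electrode node.
#' @param fraction transmitter fraction in `[0, 1]`.
#' @return The network with roles reassigned.
#' @export
assign_roles <- function(network, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (!is.na(network$electrode_id)) {
    stop("roles must be assigned before the electrode is attached",
         call. = FALSE)
  }
  n <- network$n
  n_trans <- round(fraction * n)
  if (n_trans == 0) {
    network$role <- rep("monoculture_receiver", n)
  } else {
    role <- rep("ai1_receiver", n)
    role[resample(seq_len(n), n_trans)] <- "transmitter"
    network$role <- role
  }
  network
}

# All edges (cell-cell plus electrode links) as one matrix.
all_edges <- function(net) {
  if (length(net$electrode_links)) {
    rbind(net$edges,
          cbind(pmin(net$electrode_links, net$electrode_id),
                pmax(net$electrode_links, net$electrode_id)))
  } else {
    net$edges
  }
}

#' Node degree and neighbor set
#'
#' Degree and neighbors are derived from the current edge set, counting the
#' electrode link if the node is wired to the electrode.
#'
#' @param network a `consortnet_network`.
#' @param node_id integer node id (or vector of ids for `net_degree`).
#' @return `net_degree`: integer degree(s); `net_neighbors`: integer vector
#'   of neighbor ids.
#' @export
net_degree <- function(network, node_id = NULL) {
  e <- all_edges(network)
  deg <- tabulate(c(e[, 1L], e[, 2L]), nbins = network$n)
  if (is.null(node_id)) {
    return(deg)
  }
  if (any(node_id < 1 | node_id > network$n)) {
    stop("unknown node id", call. = FALSE)
  }
  deg[node_id]
}

#' @rdname net_degree
#' @export
net_neighbors <- function(network, node_id) {
  if (length(node_id) != 1 || node_id < 1 || node_id > network$n) {
    stop("unknown node id", call. = FALSE)
  }
  e <- all_edges(network)
  sort(c(e[e[, 1L] == node_id, 2L], e[e[, 2L] == node_id, 1L]))
}

#' Cell-node ids (the biological population, electrode excluded)
#'
#' @param network a `consortnet_network`.
#' @return Integer vector of node ids whose role is not `electrode`.
#' @export
cell_ids <- function(network) {
  which(network$role != "electrode")
}

#' Extract a node weight over the cell population
#'
#' @param network a `consortnet_network`.
#' @param what one of `"substrate"`, `"h2o2"`, `"ai1"`, `"gfp"`.
#' @return Numeric vector over cell nodes (electrode excluded).
#' @export
cell_values <- function(network, what = c("gfp", "h2o2", "ai1", "substrate")) {
  what <- match.arg(what)
  network[[what]][cell_ids(network)]
}

#' @export
as.data.frame.consortnet_network <- function(x, ...) {
  data.frame(
    node_id = seq_len(x$n),
    role = x$role,
    substrate = x$substrate,
    h2o2 = x$h2o2,
    ai1 = x$ai1,
    gfp = x$gfp,
    mobile = x$mobile
  )
}

#' @export
print.consortnet_network <- function(x, ...) {
  cells <- cell_ids(x)
  cat("<consortnet_network> t =", x$time, "\n")
  cat("  nodes:", x$n,
      if (!is.na(x$electrode_id)) "(incl. 1 electrode)" else "", "\n")
  cat("  cell-cell edges:", nrow(x$edges),
      " electrode links:", length(x$electrode_links), "\n")
  cat("  roles:", paste(names(table(x$role)), table(x$role),
                        sep = "=", collapse = ", "), "\n")
  cat(sprintf("  median GFP %.1f | mean H2O2 %.3f | mean AI-1 %.3f | mean substrate %.3f\n",
              stats::median(x$gfp[cells]), mean(x$h2o2[cells]),
              mean(x$ai1[cells]), mean(x$substrate[cells])))
  invisible(x)
}
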