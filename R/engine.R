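#' One full simulation timestep
#'
#' Applies, in order: (i) gene activation fused with molecular production
#' ([production_step()]); (ii) electrode production and link reset under
#' electrical induction ([electrode_step()], placed before diffusion so
#' deposited peroxide spreads the same step); (iii) discrete diffusion of
#' hydrogen peroxide and then AI-1 ([diffusion_step()]); (iv) substrate-
#' gated division with edge inheritance ([growth_step()]), with division
#' suspended while the electrode is charged; (v) edge rewiring
#' ([randomize_edges()]).  Increments the network time by one.
#'
#' @param network a `consortnet_network`.
#' @param config a [sim_config()] object.
#' @return A list with elements `network` and `events` (division events of
#'   this step).
#' @export
simulation_step <- function(network, config) {
  t <- network$time
  network <- production_step(network, config$kinetics,
                             transmitter_gfp = config$transmitter_gfp,
                             deterministic = config$deterministic_expectation)
  if (config$induction == "electrical") {
    sched <- config_electrode_schedule(config)
    network <- electrode_step(
      network, sched, t,
      stirred = config$edge_mode == "randomized",
      link_pool = electrode_pool(config)
    )
  }
  network <- diffusion_step(network, "h2o2", config$alpha, config$dt,
                            config$diffusion_mode)
  network <- diffusion_step(network, "ai1", config$alpha, config$dt,
                            config$diffusion_mode)
  pd <- if (config$induction == "electrical") {
    effective_p_div(config_electrode_schedule(config), t, config$p_div)
  } else {
    config$p_div
  }
  gs <- growth_step(network, pd, config$k, config$max_neighbors_on_division)
  network <- randomize_edges(gs$network, config$edge_mode,
                             config$rewire_keep_fixed_endpoint)
  network$time <- t + 1L
  list(network = network, events = gs$events)
}

config_electrode_schedule <- function(config) {
  electrode_schedule(config$charge_duration, config$electrode_production,
                     config$electrode_cap_fraction,
                     config$growth_resume_step)
}

electrode_pool <- function(config) {
  if (startsWith(config$topology, "fixed_transmitters")) "transmitters"
  else "all"
}

# Build the t = 0 network for a configuration: roles, mobility flags per
# topology variant, the electrode node under electrical induction.
setup_network <- function(config) {
  net <- init_network(config)
  if (startsWith(config$topology, "fixed_transmitters")) {
    net$mobile[net$role == "transmitter"] <- FALSE
  }
  if (config$topology == "fixed_transmitters_fixed_receivers" ||
      config$topology == "fully_static") {
    net$mobile[] <- FALSE
  }
  if (config$induction == "electrical") {
    net <- add_electrode(net)
  }
  net
}

metrics_row <- function(net, threshold, n_div) {
  cells <- cell_ids(net)
  g <- net$gfp[cells]
  data.frame(
    timestep = net$time,
    node_count = length(cells),
    n_divisions = n_div,
    median_gfp = stats::median(g),
    percent_active = mean(g > threshold),
    mean_gfp = mean(g),
    sd_gfp = stats::sd(g),
    mean_h2o2 = mean(net$h2o2[cells]),
    sd_h2o2 = stats::sd(net$h2o2[cells]),
    mean_ai1 = mean(net$ai1[cells]),
    sd_ai1 = stats::sd(net$ai1[cells]),
    mean_substrate = mean(net$substrate[cells]),
    sd_substrate = stats::sd(net$substrate[cells])
  )
}

#' Run a seeded simulation
#'
#' Initializes the network for the configuration (roles, mobility,
#' electrode and initial doses), iterates [simulation_step()] for
#' `config$steps` timesteps, and records a [MetricsRecord][metrics_row]
#' row per timestep plus full snapshots at the configured stride.  A fixed
#' seed makes the trajectory bit-reproducible: all randomness flows through
#' R's generator seeded once at entry.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed for the single random stream of the run.
#' @param record_events keep the full division-event log?
#' @return An object of class `consortnet_run`: list with `metrics`
#'   (one row per timestep 0..steps), `network` (final state), `snapshots`
#'   (named list, possibly empty), `events`, `config`, `seed`.
#' @examples
#' cfg <- scenario_config("monoculture_chemical", dose = 100, steps_post = 20)
#' run <- run_simulation(cfg, seed = 1)
#' tail(run$metrics[, c("timestep", "node_count", "median_gfp")], 3)
#' @export
run_simulation <- function(config, seed = 1L, record_events = FALSE) {
  validate_config(config)
  set.seed(as.integer(seed))
  net <- setup_network(config)
  steps <- config$steps
  thr <- config$activation_threshold_gfp
  rows <- vector("list", steps + 1L)
  rows[[1L]] <- metrics_row(net, thr, 0L)
  snapshots <- list()
  events <- if (record_events) vector("list", steps) else NULL
  for (i in seq_len(steps)) {
    st <- simulation_step(net, config)
    net <- st$network
    rows[[i + 1L]] <- metrics_row(net, thr, nrow(st$events))
    if (record_events) {
      events[[i]] <- st$events
    }
    if (config$snapshot_stride > 0 && net$time %% config$snapshot_stride == 0) {
      snapshots[[as.character(net$time)]] <- net
    }
  }
  structure(
    list(
      metrics = do.call(rbind, rows),
      network = net,
      snapshots = snapshots,
      events = if (record_events) do.call(rbind, events) else NULL,
      config = config,
      seed = as.integer(seed)
    ),
    class = "consortnet_run"
  )
}

#' @export
print.consortnet_run <- function(x, ...) {
  endpoint <- x$metrics[nrow(x$metrics), ]
  cat("<consortnet_run> seed", x$seed, "|", x$config$induction,
      "induction |", x$config$edge_mode, "edges\n")
  cat(sprintf("  %d steps, final nodes %d, median GFP %.1f, %.1f%% active\n",
              x$config$steps, endpoint$node_count, endpoint$median_gfp,
              100 * endpoint$percent_active))
  invisible(x)
}

#' Run independent replicates
#'
#' Runs one simulation per seed; replicates are independent and their
#' node-level endpoint values can be pooled for distribution-level
#' summaries, mirroring the aggregate-of-10-replicates analyses.
#'
#' @param config a [sim_config()] object.
#' @param seeds integer vector of seeds (>= 1 seed).
#' @return An object of class `consortnet_replicates` (list of runs plus
#'   the shared config).
#' @export
run_replicates <- function(config, seeds) {
  stopifnot(length(seeds) >= 1)
  runs <- lapply(seeds, function(s) run_simulation(config, seed = s))
  structure(list(runs = runs, config = config, seeds = as.integer(seeds)),
            class = "consortnet_replicates")
}

#' Pool endpoint node values across replicates
#'
#' Concatenates a per-node weight over all cell nodes of every replicate's
#' final network.
#'
#' @param replicates a `consortnet_replicates` object (or a single run).
#' @param what node weight to pool (`"gfp"`, `"h2o2"`, `"ai1"`,
#'   `"substrate"`).
#' @return Numeric vector of pooled node values.
#' @export
pooled_values <- function(replicates, what = "gfp") {
  runs <- if (inherits(replicates, "consortnet_run")) list(replicates)
          else replicates$runs
  unlist(lapply(runs, function(r) cell_values(r$network, what)),
         use.names = FALSE)
}

#' Mean time course across replicates
#'
#' Averages one metrics column over replicates at each timestep.
#'
#' @param replicates a `consortnet_replicates` object.
#' @param column a column of the per-run metrics table, e.g. `"mean_ai1"`.
#' @return Data frame with `timestep` and the replicate-mean column.
#' @export
mean_timecourse <- function(replicates, column = "mean_ai1") {
  mats <- vapply(replicates$runs, function(r) r$metrics[[column]],
                 numeric(nrow(replicates$runs[[1]]$metrics)))
  data.frame(timestep = replicates$runs[[1]]$metrics$timestep,
             value = rowMeans(mats))
}

#' @export
plot.consortnet_run <- function(x, y = "median_gfp", ...) {
  graphics::plot(x$metrics$timestep, x$metrics[[y]], type = "l",
                 xlab = "timestep", ylab = y, ...)
  invisible(x)
}
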