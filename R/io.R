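#' Save and load network snapshots
#'
#' Snapshots round-trip through GraphML (typed node attributes via igraph)
#' or through a pair of plain CSV tables (nodes, edges).  Both dialects are
#' lossless for all node attributes and the edge set; the electrode node
#' and its links are reconstructed from the `role` attribute.
#'
#' @param network a `consortnet_network`.
#' @param path GraphML file path.
#' @return `save_network` returns `path` invisibly; `read_network` returns
#'   a `consortnet_network`.
#' @export
save_network <- function(network, path) {
  g <- as_igraph(network, include_electrode = TRUE)
  igraph::V(g)$time <- network$time
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname save_network
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ord <- order(as.integer(igraph::V(g)$name))
  role <- igraph::V(g)$role[ord]
  e <- igraph::as_edgelist(g, names = TRUE)
  e <- matrix(as.integer(e), ncol = 2)
  network_from_parts(
    role = role,
    substrate = igraph::V(g)$substrate[ord],
    h2o2 = igraph::V(g)$h2o2[ord],
    ai1 = igraph::V(g)$ai1[ord],
    gfp = igraph::V(g)$gfp[ord],
    mobile = as.logical(igraph::V(g)$mobile[ord]),
    edges = e,
    time = if (!is.null(igraph::V(g)$time)) igraph::V(g)$time[1] else 0L
  )
}

# Assemble a network from raw parts, splitting electrode links out of the
# plain edge list.
network_from_parts <- function(role, substrate, h2o2, ai1, gfp, mobile,
                               edges, time = 0L) {
  eid <- which(role == "electrode")
  if (length(eid) > 1) {
    stop("at most one electrode node is allowed", call. = FALSE)
  }
  eid <- if (length(eid)) eid else NA_integer_
  links <- integer(0)
  if (!is.na(eid) && nrow(edges)) {
    touch <- edges[, 1L] == eid | edges[, 2L] == eid
    links <- setdiff(as.integer(edges[touch, ]), eid)
    edges <- edges[!touch, , drop = FALSE]
  }
  edges <- canonical_edges(edges[, 1L], edges[, 2L])
  net <- new_network(role, substrate, h2o2, ai1, gfp, mobile, edges,
                     time = time, electrode_id = eid,
                     electrode_links = links)
  net
}

#' @rdname save_network
#' @param nodes_path,edges_path CSV file paths for the node and edge tables.
#' @export
write_network_csv <- function(network, nodes_path, edges_path) {
  utils::write.csv(as.data.frame(network), nodes_path, row.names = FALSE)
  e <- all_edges(network)
  utils::write.csv(data.frame(u = e[, 1L], v = e[, 2L]), edges_path,
                   row.names = FALSE)
  invisible(c(nodes_path, edges_path))
}

#' @rdname save_network
#' @export
read_network_csv <- function(nodes_path, edges_path) {
  nodes <- utils::read.csv(nodes_path)
  nodes <- nodes[order(nodes$node_id), ]
  e <- utils::read.csv(edges_path)
  network_from_parts(
    role = nodes$role,
    substrate = nodes$substrate,
    h2o2 = nodes$h2o2,
    ai1 = nodes$ai1,
    gfp = nodes$gfp,
    mobile = nodes$mobile,
    edges = cbind(as.integer(e$u), as.integer(e$v))
  )
}

#' Load a scenario configuration file
#'
#' Reads a YAML configuration: either a bare parameter map (passed to
#' [sim_config()]) or a map with a `preset` key plus overrides (passed to
#' [scenario_config()]).  Unknown keys are rejected by name and all values
#' are validated against the parameter invariants, so a loaded
#' configuration is always a fully defaulted, checked `consortnet_config`.
#'
#' @param path YAML file path.
#' @return A `consortnet_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  preset <- raw$preset
  raw$preset <- NULL
  allowed <- names(formals(sim_config))
  allowed <- setdiff(allowed, "...")
  if (!is.null(preset)) {
    allowed <- c(allowed, "dose", "charge_duration", "steps_post")
  }
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$kinetics)) {
    raw$kinetics <- do.call(kinetic_params, raw$kinetics)
  }
  if (is.null(preset)) {
    do.call(sim_config, raw)
  } else {
    do.call(scenario_config, c(list(preset = preset), raw))
  }
}

#' Write a run to disk
#'
#' Emits the tidy outputs of a simulation run into a directory:
#' `metrics.csv` (one row per timestep), `nodes.csv` / `edges.csv` (final
#' state), `summary.json` (endpoint metrics, seed, audit totals) and
#' GraphML snapshots under `snapshots/` when the run recorded any.
#'
#' @param run a `consortnet_run`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  write_network_csv(run$network, file.path(dir, "nodes.csv"),
                    file.path(dir, "edges.csv"))
  endpoint <- run$metrics[nrow(run$metrics), ]
  summary <- list(
    seed = run$seed,
    steps = run$config$steps,
    induction = run$config$induction,
    edge_mode = run$config$edge_mode,
    topology = run$config$topology,
    endpoint = as.list(endpoint),
    audit = run$network$audit
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (length(run$snapshots)) {
    snapdir <- file.path(dir, "snapshots")
    dir.create(snapdir, showWarnings = FALSE)
    for (nm in names(run$snapshots)) {
      save_network(run$snapshots[[nm]],
                   file.path(snapdir, paste0("t", nm, ".graphml")))
    }
  }
  if (!is.null(run$events)) {
    utils::write.csv(run$events, file.path(dir, "divisions.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
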