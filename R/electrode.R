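#' Electrode schedule
#'
#' The biased electrode is a single source node that deposits hydrogen
#' peroxide while it is on ("charged") and is wired to at most a fixed
#' fraction of the cell population at any time.  The per-step production of
#' 46 uM is the value fitted for an initial network of 100 cells and is
#' deliberately not rescaled for other network sizes.  While charged, cell
#' division is suspended (the experimental cultures showed negligible
#' growth during induction) and resumes at `growth_resume_step`.
#'
#' @param charge_duration integer number of on-steps counted from `t = 0`.
#' @param production_per_step uM hydrogen peroxide deposited per on-step.
#' @param cap_fraction maximum fraction of cell nodes linked to the
#'   electrode, in `(0, 1]`.
#' @param growth_resume_step timestep at which division resumes; defaults
#'   to the charge end.
#' @return A list of class `consortnet_electrode`.
#' @export
electrode_schedule <- function(charge_duration,
                               production_per_step = 46,
                               cap_fraction = 0.05,
                               growth_resume_step = NULL) {
  stopifnot(charge_duration >= 0, production_per_step >= 0,
            cap_fraction > 0, cap_fraction <= 1)
  structure(
    list(
      charge_duration = as.integer(charge_duration),
      production_per_step = production_per_step,
      cap_fraction = cap_fraction,
      growth_resume_step = as.integer(growth_resume_step %||%
                                        charge_duration)
    ),
    class = "consortnet_electrode"
  )
}

#' Attach the electrode source node
#'
#' Appends the single electrode node (no substrate, never divides, zero
#' initial weights, immobile).  At most one electrode may exist.
#'
#' @param network a `consortnet_network` without an electrode.
#' @return The network with the electrode appended.
#' @export
add_electrode <- function(network) {
  if (!is.na(network$electrode_id)) {
    stop("network already has an electrode node", call. = FALSE)
  }
  id <- network$n + 1L
  network$role <- c(network$role, "electrode")
  network$substrate <- c(network$substrate, 0)
  network$h2o2 <- c(network$h2o2, 0)
  network$ai1 <- c(network$ai1, 0)
  network$gfp <- c(network$gfp, 0)
  network$mobile <- c(network$mobile, FALSE)
  network$n <- id
  network$electrode_id <- id
  network
}

#' Electrode production and connectivity for one timestep
#'
#' While `t < charge_duration` the electrode node's hydrogen peroxide is
#' incremented by `production_per_step`.  At every timestep (charged or
#' not) the electrode's links are reset so that
#' `floor(cap_fraction * n_cells)` cell nodes are wired to it: sampled
#' uniformly over all cells in stirred scenarios, or drawn from the
#' designated transmitter pool when transmitters are fixed to the electrode
#' surface.  In unstirred scenarios existing links persist and are only
#' topped up as the population grows.  The deposited peroxide then spreads
#' outward through these links via the ordinary [diffusion_step()].
#'
#' @param network a `consortnet_network` containing the electrode node.
#' @param schedule an [electrode_schedule()].
#' @param t current timestep.
#' @param stirred are edges randomized each step (links resampled) or
#'   persistent (links kept and topped up)?
#' @param link_pool `"all"` or `"transmitters"`: which cells may be wired
#'   to the electrode.
#' @return The updated network.
#' @export
electrode_step <- function(network, schedule, t, stirred = TRUE,
                           link_pool = c("all", "transmitters")) {
  link_pool <- match.arg(link_pool)
  if (is.na(network$electrode_id)) {
    stop("electrical scenario requires an electrode node; see add_electrode()",
         call. = FALSE)
  }
  if (t < schedule$charge_duration) {
    eid <- network$electrode_id
    network$h2o2[eid] <- network$h2o2[eid] + schedule$production_per_step
  }
  cells <- cell_ids(network)
  pool <- if (link_pool == "transmitters") {
    cells[network$role[cells] == "transmitter"]
  } else {
    cells
  }
  target <- min(floor(schedule$cap_fraction * length(cells)), length(pool))
  if (stirred) {
    network$electrode_links <- resample(pool, target)
  } else {
    links <- intersect(network$electrode_links, pool)
    need <- target - length(links)
    if (need > 0) {
      avail <- setdiff(pool, links)
      links <- c(links, resample(avail, min(need, length(avail))))
    }
    network$electrode_links <- links
  }
  network
}

#' Division probability under electrode-driven growth suspension
#'
#' Returns 0 while `t < growth_resume_step`, else the base probability.
#'
#' @param schedule an [electrode_schedule()].
#' @param t current timestep.
#' @param p_div_base the configured division probability.
#' @return A probability.
#' @export
effective_p_div <- function(schedule, t, p_div_base) {
  if (t < schedule$growth_resume_step) 0 else p_div_base
}
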