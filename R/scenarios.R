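SCENARIO_PRESETS <- c("monoculture_chemical", "tr_chemical",
                      "monoculture_electrical", "tr_electrical",
                      "tr_fixed_transmitters", "tr_fully_static")

#' Scenario presets
#'
#' Expands a named scenario preset into a full [sim_config()].  The presets
#' cross the two cellular systems (Monoculture: every cell senses peroxide
#' and makes GFP; Transmitter/Receiver: 10 percent of cells convert
#' peroxide into AI-1 which the remaining 90 percent convert into GFP) with
#' the two induction modes (chemical: a bulk dose of hydrogen peroxide at
#' `t = 0`; electrical: an electrode source node charged for a set number
#' of steps) and the topology variants (stirred edge-randomized culture,
#' transmitters fixed to the electrode with mixed or fixed receivers, or a
#' fully static biofilm-like network).
#'
#' Available presets: `monoculture_chemical`, `tr_chemical`,
#' `monoculture_electrical`, `tr_electrical`, `tr_fixed_transmitters`
#' (transmitters immobile on the electrode, receivers stirred) and
#' `tr_fully_static` (static edges, electrode links persist).
#'
#' @param preset preset name.
#' @param dose uM hydrogen peroxide added at `t = 0` (chemical presets).
#' @param charge_duration electrode on-steps (electrical presets).
#' @param steps_post timesteps simulated after the induction window: the
#'   total horizon is `steps_post` for chemical presets and
#'   `charge_duration + steps_post` for electrical ones, so endpoints are
#'   comparable at 180 steps post-induction.
#' @param ... further overrides passed to [sim_config()].
#' @return A `consortnet_config`.
#' @examples
#' cfg <- scenario_config("tr_chemical", dose = 100)
#' cfg$transmitter_fraction  # 0.1
#' @export
scenario_config <- function(preset = SCENARIO_PRESETS,
                            dose = 100,
                            charge_duration = 30L,
                            steps_post = 180L,
                            ...) {
  preset <- match.arg(preset)
  tr <- preset %in% c("tr_chemical", "tr_electrical",
                      "tr_fixed_transmitters", "tr_fully_static")
  electrical <- preset %in% c("monoculture_electrical", "tr_electrical",
                              "tr_fixed_transmitters", "tr_fully_static")
  base <- list(
    transmitter_fraction = if (tr) 0.10 else 0,
    induction = if (electrical) "electrical" else "chemical",
    h2o2_initial = if (electrical) 0 else dose,
    charge_duration = if (electrical) as.integer(charge_duration) else 0L,
    steps = if (electrical) as.integer(charge_duration) +
              as.integer(steps_post) else as.integer(steps_post)
  )
  if (preset == "tr_fixed_transmitters") {
    base$topology <- "fixed_transmitters_mixed_receivers"
    base$edge_mode <- "partial"
    base$fixed_roles <- "transmitter"
  } else if (preset == "tr_fully_static") {
    base$topology <- "fully_static"
    base$edge_mode <- "static"
  }
  args <- utils::modifyList(base, list(...))
  do.call(sim_config, args)
}

#' Run a scenario preset over several seeds
#'
#' Convenience wrapper: [scenario_config()] then [run_replicates()].
#'
#' @inheritParams scenario_config
#' @param seeds integer vector of seeds.
#' @return A `consortnet_replicates` object.
#' @export
run_scenario <- function(preset, seeds = 1:10, dose = 100,
                         charge_duration = 30L, steps_post = 180L, ...) {
  cfg <- scenario_config(preset, dose = dose,
                         charge_duration = charge_duration,
                         steps_post = steps_post, ...)
  run_replicates(cfg, seeds)
}

#' Dose or charge-duration sweep
#'
#' Runs a preset across a list of induction strengths (initial peroxide
#' doses for chemical presets, charge durations for electrical ones) with
#' the same seeds, and summarizes each condition by its pooled endpoint
#' distribution.
#'
#' @param preset a scenario preset name.
#' @param values numeric doses (chemical) or integer charge durations
#'   (electrical).
#' @param seeds integer vector of seeds per condition.
#' @param steps_post timesteps after the induction window.
#' @param threshold GFP activation threshold for percent-active.
#' @param ... further overrides passed to [scenario_config()].
#' @return A list with `summary` (data.frame: value, pooled median GFP,
#'   pooled percent active, pooled node count) and `replicates` (named list
#'   of `consortnet_replicates`).
#' @export
sweep_scenario <- function(preset, values, seeds = 1:10, steps_post = 180L,
                           threshold = 1000, ...) {
  cfg0 <- scenario_config(preset, ...)
  electrical <- cfg0$induction == "electrical"
  reps <- lapply(values, function(v) {
    if (electrical) {
      run_scenario(preset, seeds = seeds, charge_duration = v,
                   steps_post = steps_post, ...)
    } else {
      run_scenario(preset, seeds = seeds, dose = v,
                   steps_post = steps_post, ...)
    }
  })
  names(reps) <- as.character(values)
  pooled <- lapply(reps, pooled_values, what = "gfp")
  summary <- data.frame(
    value = values,
    median_gfp = vapply(pooled, stats::median, numeric(1)),
    percent_active = vapply(pooled, function(g) mean(g > threshold),
                            numeric(1)),
    pooled_nodes = vapply(pooled, length, numeric(1))
  )
  list(summary = summary, replicates = reps)
}
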