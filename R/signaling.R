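#' Kinetic parameters of gene activation and production
#'
#' Constants of the dose-response curves.  Peroxide-driven activation is a
#' logistic in the local H2O2 concentration with midpoint 8 uM and scale
#' 2 uM; AI-1 driven activation is a much steeper logistic (steepness 50)
#' with midpoint 0.25, reflecting the nanomolar potency of the quorum
#' sensing signal.  Peroxide-driven production saturates at `h2o2_rate_gain`
#' times the local substrate; AI-1 driven production is linear in both AI-1
#' and substrate with gain `ai1_rate_gain`.
#'
#' @param h2o2_prob_midpoint logistic midpoint of peroxide activation (uM).
#' @param h2o2_prob_scale logistic scale of peroxide activation (uM).
#' @param ai1_prob_midpoint activation midpoint for AI-1 (model units).
#' @param ai1_prob_steepness dimensionless steepness of the AI-1 logistic.
#' @param h2o2_rate_gain gain of the saturating peroxide production rate.
#' @param ai1_rate_gain gain of the linear AI-1 production rate.
#' @return A list of class `consortnet_kinetics`.
#' @export
kinetic_params <- function(h2o2_prob_midpoint = 8,
                           h2o2_prob_scale = 2,
                           ai1_prob_midpoint = 0.25,
                           ai1_prob_steepness = 50,
                           h2o2_rate_gain = 2,
                           ai1_rate_gain = 0.2) {
  kin <- list(
    h2o2_prob_midpoint = h2o2_prob_midpoint,
    h2o2_prob_scale = h2o2_prob_scale,
    ai1_prob_midpoint = ai1_prob_midpoint,
    ai1_prob_steepness = ai1_prob_steepness,
    h2o2_rate_gain = h2o2_rate_gain,
    ai1_rate_gain = ai1_rate_gain
  )
  class(kin) <- "consortnet_kinetics"
  validate_kinetics(kin)
  kin
}

validate_kinetics <- function(kin) {
  if (!all(vapply(kin, function(x) is.numeric(x) && x > 0, logical(1)))) {
    stop("all kinetic parameters must be positive numbers", call. = FALSE)
  }
  invisible(kin)
}

#' Gene activation probabilities
#'
#' `prob_h2o2()` is the peroxide-induced activation probability: zero at
#' zero inducer, otherwise the logistic
#' `1 / (1 + exp(-(h - midpoint) / scale))`.  `prob_ai1()` is the AI-1
#' induced activation probability: zero at zero inducer, otherwise the steep
#' logistic `1 / (1 + exp(-steepness * (a - midpoint)))`.  Both are
#' strictly increasing in the inducer and bounded by 1.
#'
#' @param h hydrogen peroxide concentration (uM), nonnegative.
#' @param a AI-1 concentration (model units), nonnegative.
#' @param params a [kinetic_params()] object.
#' @return Probability vector in `[0, 1]`, vectorized over the inducer.
#' @examples
#' prob_h2o2(c(0, 8, 12.5))   # 0, 0.5, ~0.90
#' prob_ai1(c(0, 0.25, 0.5))  # 0, 0.5, ~1
#' @export
prob_h2o2 <- function(h, params = kinetic_params()) {
  if (any(h < 0)) stop("negative H2O2 concentration", call. = FALSE)
  ifelse(h == 0, 0,
         stats::plogis((h - params$h2o2_prob_midpoint) /
                         params$h2o2_prob_scale))
}

#' @rdname prob_h2o2
#' @export
prob_ai1 <- function(a, params = kinetic_params()) {
  if (any(a < 0)) stop("negative AI-1 concentration", call. = FALSE)
  ifelse(a == 0, 0,
         stats::plogis(params$ai1_prob_steepness *
                         (a - params$ai1_prob_midpoint)))
}

#' Molecular production rates
#'
#' `rate_h2o2()` is the peroxide-driven per-step production amount
#' `gain * s / (1 + exp(-h))`: steeply peroxide-dependent at low
#' concentrations and saturating at `gain * s` for large `h`.
#' `rate_ai1()` is the AI-1 driven amount `gain * a * s`, linear in both
#' the signal and the substrate.
#'
#' @param h hydrogen peroxide concentration (uM), nonnegative.
#' @param a AI-1 concentration, nonnegative.
#' @param s substrate, nonnegative.
#' @param params a [kinetic_params()] object.
#' @return Nonnegative production amount per step, vectorized.
#' @examples
#' rate_h2o2(0, 20)      # 20: half the saturated rate
#' rate_ai1(1, 5)        # 1
#' @export
rate_h2o2 <- function(h, s, params = kinetic_params()) {
  if (any(h < 0) || any(s < 0)) stop("negative input", call. = FALSE)
  params$h2o2_rate_gain * s * stats::plogis(h)
}

#' @rdname rate_h2o2
#' @export
rate_ai1 <- function(a, s, params = kinetic_params()) {
  if (any(a < 0) || any(s < 0)) stop("negative input", call. = FALSE)
  params$ai1_rate_gain * a * s
}

#' Gene activation and molecular production for one timestep
#'
#' For every cell node a Bernoulli draw with the role-appropriate activation
#' probability decides whether its circuit fires this step.  Activated
#' Monoculture receivers add `rate_h2o2(h, s)` to GFP; activated
#' transmitters add the same amount to AI-1 (and, by default, to GFP, since
#' they carry the identical peroxide-driven operon); activated AI-1
#' receivers add `rate_ai1(a, s)` to GFP.  All probabilities and rates are
#' evaluated on the state at entry, i.e. on the previous timestep's
#' concentrations; the electrode never produces biologically.
#'
#' @param network a `consortnet_network`.
#' @param params a [kinetic_params()] object.
#' @param transmitter_gfp do transmitters also accumulate GFP?
#' @param deterministic replace the Bernoulli gate by its expectation
#'   (`prob * rate` deterministic increment), consuming no randomness.
#' @return The updated network.
#' @export
production_step <- function(network, params = kinetic_params(),
                            transmitter_gfp = TRUE,
                            deterministic = FALSE) {
  role <- network$role
  h <- network$h2o2
  a <- network$ai1
  s <- network$substrate

  p <- numeric(network$n)
  per <- role == "monoculture_receiver" | role == "transmitter"
  p[per] <- prob_h2o2(h[per], params)
  rec <- role == "ai1_receiver"
  p[rec] <- prob_ai1(a[rec], params)

  gate <- if (deterministic) p else as.numeric(stats::runif(network$n) < p)

  rh <- rate_h2o2(h, s, params)
  mono <- role == "monoculture_receiver"
  network$gfp[mono] <- network$gfp[mono] + gate[mono] * rh[mono]

  tr <- role == "transmitter"
  network$ai1[tr] <- network$ai1[tr] + gate[tr] * rh[tr]
  if (transmitter_gfp) {
    network$gfp[tr] <- network$gfp[tr] + gate[tr] * rh[tr]
  }

  ra <- rate_ai1(a, s, params)
  network$gfp[rec] <- network$gfp[rec] + gate[rec] * ra[rec]
  network
}

#' Discrete diffusion of a signaling species across edges
#'
#' Synchronous discrete graph diffusion: from a frozen copy of the entering
#' state, every node `i` is updated as
#' `c_i(t+1) = c_i(t) + alpha * dt * (sum_{j in N(i)} c_j(t) - c_i(t) * deg(i))`,
#' i.e. a pairwise flux `alpha * dt * (c_j - c_i)` flows along every edge.
#' GFP and substrate never diffuse.  With `alpha * dt * deg` above 1 the
#' explicit scheme can overdraw a node; the default `"limit"` mode scales
#' each node's outgoing fluxes so it never sends more than it holds, which
#' keeps concentrations nonnegative and conserves total mass exactly while
#' reducing to the raw update whenever no node overdraws.  `"clamp"` applies
#' the raw update and clamps negatives to zero (the created mass is
#' accumulated in the network's audit log); `"none"` applies the raw update.
#'
#' @param network a `consortnet_network`.
#' @param species `"h2o2"` or `"ai1"`.
#' @param alpha diffusion coefficient (> 0).
#' @param dt timestep length (> 0).
#' @param mode `"limit"`, `"clamp"` or `"none"`.
#' @return The updated network (audit counters under `$audit`).
#' @export
diffusion_step <- function(network, species = c("h2o2", "ai1"), alpha = 1,
                           dt = 1, mode = c("limit", "clamp", "none")) {
  species <- match.arg(species)
  mode <- match.arg(mode)
  stopifnot(alpha > 0, dt > 0)
  e <- all_edges(network)
  if (nrow(e) == 0) {
    return(network)
  }
  n <- network$n
  cc <- network[[species]]
  eu <- e[, 1L]
  ev <- e[, 2L]

  if (mode == "limit") {
    f <- alpha * dt * (cc[eu] - cc[ev])      # + means flow u -> v
    src <- ifelse(f > 0, eu, ev)
    dst <- ifelse(f > 0, ev, eu)
    mag <- abs(f)
    out <- accumulate_by_id(src, mag, n)
    r <- ifelse(out > 0, pmin(1, cc / out), 1)
    sf <- mag * r[src]
    cn <- cc + accumulate_by_id(dst, sf, n) - accumulate_by_id(src, sf, n)
    network$audit$limited_flux <- network$audit$limited_flux + sum(mag - sf)
    # guard against -0 / rounding dust
    cn[cn < 0 & cn > -1e-12] <- 0
  } else {
    deg <- tabulate(c(eu, ev), nbins = n)
    nsum <- accumulate_by_id(c(eu, ev), c(cc[ev], cc[eu]), n)
    cn <- cc + alpha * dt * (nsum - cc * deg)
    if (mode == "clamp") {
      neg <- cn < 0
      network$audit$clamped_mass <- network$audit$clamped_mass - sum(cn[neg])
      cn[neg] <- 0
    }
  }
  network[[species]] <- cn
  network
}
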