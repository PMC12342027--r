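test_that("activation probabilities follow the dose-response curves", {
  # zero inducer gives exactly zero probability
  expect_identical(prob_h2o2(0), 0)
  expect_identical(prob_ai1(0), 0)
  # logistic symmetry at the midpoint
  expect_equal(prob_h2o2(8), 0.5)
  expect_equal(prob_ai1(0.25), 0.5)
  # frozen values from independent evaluation of the logistics
  expect_equal(prob_h2o2(12.5), 0.9046505351008906, tolerance = 1e-12)
  expect_equal(prob_ai1(0.5), 0.9999962733607158, tolerance = 1e-12)
  expect_error(prob_h2o2(-1), "negative")
  expect_error(prob_ai1(-0.1), "negative")
})

test_that("production rates saturate (peroxide) and stay linear (AI-1)", {
  expect_equal(rate_h2o2(0, 20), 20)        # gain * s / 2 at zero inducer
  expect_equal(rate_h2o2(1e3, 1), 2)        # saturation at gain * s
  expect_equal(rate_h2o2(5, 0), 0)          # proportional to substrate
  expect_equal(rate_ai1(0, 5), 0)
  expect_equal(rate_ai1(1, 5), 1)
  expect_equal(rate_ai1(2, 5), 2 * rate_ai1(1, 5))  # linearity
  expect_error(rate_h2o2(-1, 1), "negative")
  expect_error(rate_ai1(1, -1), "negative")
})

test_that("dose-response functions are monotone nondecreasing", {
  h <- sort(stats::runif(50, 0, 40))
  expect_true(all(diff(prob_h2o2(h)) >= 0))
  a <- sort(stats::runif(50, 0, 2))
  expect_true(all(diff(prob_ai1(a)) >= 0))
  expect_true(all(diff(rate_h2o2(h, 5)) >= 0))
  expect_true(all(diff(rate_ai1(a, 5)) >= 0))
  expect_true(all(prob_h2o2(h) <= 1 & prob_ai1(a) <= 1))
})

test_that("production leaves uninduced nodes untouched", {
  set.seed(5)
  net <- make_net(c("monoculture_receiver", "transmitter", "ai1_receiver"),
                  h2o2 = 0, ai1 = 0, gfp = 100)
  out <- production_step(net)
  expect_equal(out$gfp, net$gfp)
  expect_equal(out$ai1, net$ai1)
})

test_that("Monte-Carlo production increment matches the Bernoulli expectation", {
  # 1e4 independent nodes at h = 8, s = 20: expected GFP gain 0.5 * 20 = 10
  set.seed(7)
  n <- 10000
  net <- make_net(rep("monoculture_receiver", n), substrate = 20, h2o2 = 8)
  out <- production_step(net)
  inc <- out$gfp - net$gfp
  rate <- rate_h2o2(8, 20)
  se <- sqrt(0.25 * rate^2 / n)
  expect_lt(abs(mean(inc) - 0.5 * rate), 3 * se)
  # transmitters route the same expected amount into AI-1
  set.seed(8)
  tr <- make_net(rep("transmitter", n), substrate = 20, h2o2 = 8)
  out_tr <- production_step(tr)
  expect_lt(abs(mean(out_tr$ai1) - 0.5 * rate), 3 * se)
  # and the deterministic-expectation mode gives it exactly
  det <- production_step(net, deterministic = TRUE)
  expect_equal(det$gfp - net$gfp, rep(0.5 * rate, n))
})

test_that("diffusion reproduces hand-applied updates and leaves uniform fields alone", {
  # two connected nodes (1, 0) -> (0, 1) with alpha = dt = 1
  for (mode in c("none", "limit")) {
    net <- make_net(rep("monoculture_receiver", 2), h2o2 = c(1, 0),
                    edges = cbind(1L, 2L))
    out <- diffusion_step(net, "h2o2", alpha = 1, dt = 1, mode = mode)
    expect_equal(out$h2o2, c(0, 1))
  }
  # uniform concentration is a fixed point (zero Laplacian)
  set.seed(9)
  net <- init_network(sim_config(n_initial = 30, mean_degree = 4))
  net$h2o2 <- rep(3.7, 30)
  out <- diffusion_step(net, "h2o2", mode = "none")
  expect_equal(out$h2o2, net$h2o2)
})

test_that("diffusion equals the graph-Laplacian matrix form on random graphs", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    cfg <- sim_config(n_initial = n, mean_degree = 2)
    net <- init_network(cfg)
    net$h2o2 <- stats::runif(n, 0, 10)
    L <- laplacian_matrix_of(net$edges, n)
    a <- 0.05
    expected <- as.vector(net$h2o2 - a * L %*% net$h2o2)
    out_none <- diffusion_step(net, "h2o2", alpha = a, mode = "none")
    expect_equal(out_none$h2o2, expected, tolerance = 1e-12)
    # at this step size no node overdraws, so the limiter is inactive
    out_lim <- diffusion_step(net, "h2o2", alpha = a, mode = "limit")
    expect_equal(out_lim$h2o2, expected, tolerance = 1e-12)
    expect_equal(out_lim$audit$limited_flux, 0)
  }
})

test_that("diffusion conserves mass and the limiter keeps state physical", {
  set.seed(22)
  for (rep in 1:5) {
    net <- init_network(sim_config(n_initial = 40, mean_degree = 6))
    net$ai1 <- stats::rexp(40, 1 / 5)
    tot <- sum(net$ai1)
    out_none <- diffusion_step(net, "ai1", alpha = 1, mode = "none")
    expect_equal(sum(out_none$ai1), tot, tolerance = 1e-9)
    out_lim <- diffusion_step(net, "ai1", alpha = 1, mode = "limit")
    expect_equal(sum(out_lim$ai1), tot, tolerance = 1e-9)
    expect_true(all(out_lim$ai1 >= 0))
    # the raw explicit scheme overdraws at alpha * deg > 1; "clamp" logs it
    out_clamp <- diffusion_step(net, "ai1", alpha = 1, mode = "clamp")
    expect_true(all(out_clamp$ai1 >= 0))
    expect_equal(sum(out_clamp$ai1) - tot, out_clamp$audit$clamped_mass,
                 tolerance = 1e-9)
  }
})

test_that("maximum principle holds on star graphs within the stable regime", {
  set.seed(23)
  net <- make_net(rep("monoculture_receiver", 7), h2o2 = stats::runif(7, 0, 9),
                  edges = star_edges(6))
  # alpha * dt * deg_max = 0.15 * 6 = 0.9 <= 1
  out <- diffusion_step(net, "h2o2", alpha = 0.15, mode = "limit")
  expect_true(all(out$h2o2 >= min(net$h2o2) - 1e-12))
  expect_true(all(out$h2o2 <= max(net$h2o2) + 1e-12))
  expect_equal(out$audit$limited_flux, 0)
})
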