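test_that("a full step matches a hand computation on a 3-node line graph", {
  # deterministic expectation, no growth, static edges; constants below were
  # hand-computed independently from the dose-response definitions
  net <- make_net(c("transmitter", "ai1_receiver", "monoculture_receiver"),
                  substrate = c(10, 5, 20), h2o2 = c(8, 0, 2),
                  ai1 = c(0, 0.5, 0), gfp = c(0, 100, 50),
                  edges = line_edges(3))
  cfg <- sim_config(n_initial = 3, mean_degree = 0.5, p_div = 0,
                    edge_mode = "static", deterministic_expectation = TRUE)
  out <- simulation_step(net, cfg)$network
  expect_equal(out$time, 1L)
  expect_equal(out$gfp,
               c(9.996646498695336, 100.49999813668036, 51.67090282061402),
               tolerance = 1e-12)
  expect_equal(out$h2o2, c(0, 10, 0), tolerance = 1e-12)
  expect_equal(out$ai1, c(0.5, 9.496646498695336, 0.5), tolerance = 1e-12)
  expect_equal(out$substrate, c(10, 5, 20))
})

test_that("a degenerate configuration leaves the state invariant", {
  set.seed(61)
  cfg <- sim_config(n_initial = 20, mean_degree = 2, p_div = 0,
                    h2o2_initial = 0, edge_mode = "static", steps = 5)
  run <- run_simulation(cfg, seed = 4)
  first <- run$metrics[1, -1]
  last <- run$metrics[nrow(run$metrics), -1]
  expect_equal(last, first, ignore_attr = TRUE)
})

test_that("fixed seeds give bit-reproducible trajectories", {
  cfg <- scenario_config("tr_chemical", dose = 25, steps_post = 30)
  a <- run_simulation(cfg, seed = 99)
  b <- run_simulation(cfg, seed = 99)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$network$gfp, b$network$gfp)
  expect_identical(a$network$edges, b$network$edges)
  c <- run_simulation(cfg, seed = 100)
  expect_false(identical(a$network$gfp, c$network$gfp))
})

test_that("zero-dose chemical and zero-charge electrical runs agree", {
  seeds <- 1:6
  chem <- run_replicates(scenario_config("tr_chemical", dose = 0,
                                         steps_post = 60), seeds)
  elec <- run_replicates(scenario_config("tr_electrical", charge_duration = 0,
                                         steps_post = 60), seeds)
  ks <- suppressWarnings(stats::ks.test(pooled_values(chem),
                                        pooled_values(elec)))
  expect_gt(ks$p.value, 0.01)
  # without induction no node ever activates beyond its initial draw
  expect_lt(percent_active(chem), 0.05)
})

test_that("endpoint activation increases with chemical dose", {
  seeds <- 1:3
  pct <- vapply(c(0, 12.5, 100), function(dose) {
    percent_active(run_replicates(
      scenario_config("tr_chemical", dose = dose, steps_post = 60), seeds))
  }, numeric(1))
  expect_true(all(diff(pct) >= 0))
  expect_gt(pct[3], pct[1])
})

test_that("replicate pooling is order-invariant and sums node counts", {
  cfg <- scenario_config("monoculture_chemical", dose = 50, steps_post = 20)
  reps <- run_replicates(cfg, seeds = 1:3)
  pooled <- pooled_values(reps)
  expect_length(pooled, sum(vapply(reps$runs,
                                   function(r) r$network$n, numeric(1))))
  reordered <- reps
  reordered$runs <- rev(reps$runs)
  expect_equal(median_gfp(reordered), median_gfp(reps))
  one <- run_replicates(cfg, seeds = 7)
  expect_equal(pooled_values(one), cell_values(one$runs[[1]]$network, "gfp"))
})
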