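test_that("division halves partitioned weights and copies GFP, role, mobility", {
  set.seed(31)
  net <- make_net("transmitter", substrate = 20, h2o2 = 4, ai1 = 2, gfp = 500)
  out <- growth_step(net, p_div = 1, k = 1)
  expect_equal(out$network$n, 2)
  expect_equal(out$network$substrate, c(10, 10))
  expect_equal(out$network$h2o2, c(2, 2))
  expect_equal(out$network$ai1, c(1, 1))
  expect_equal(out$network$gfp, c(500, 500))
  expect_equal(out$network$role, c("transmitter", "transmitter"))
  expect_equal(out$events$parent, 1L)
  expect_equal(out$events$daughter, 2L)
  # parent and daughter share an edge
  expect_equal(out$network$edges, cbind(1L, 2L), ignore_attr = TRUE)
})

test_that("division requires substrate strictly above the threshold", {
  net <- make_net("monoculture_receiver", substrate = 1)
  out <- growth_step(net, p_div = 1, k = 1)   # s == k: never divides
  expect_equal(out$network$n, 1)
  expect_equal(nrow(out$events), 0)
  out0 <- growth_step(make_net("monoculture_receiver", substrate = 20),
                      p_div = 0, k = 1)
  expect_equal(out0$network$n, 1)
})

test_that("growth conserves substrate, H2O2 and AI-1 totals", {
  set.seed(32)
  net <- init_network(sim_config(n_initial = 60, mean_degree = 4,
                                 transmitter_fraction = 0.1))
  net$h2o2 <- stats::runif(60, 0, 10)
  net$ai1 <- stats::runif(60, 0, 3)
  tots <- c(sum(net$substrate), sum(net$h2o2), sum(net$ai1))
  out <- growth_step(net, p_div = 1, k = 1)
  expect_equal(out$network$n, 120)
  expect_equal(c(sum(out$network$substrate), sum(out$network$h2o2),
                 sum(out$network$ai1)), tots)
  # role counts conserved up to copying
  expect_equal(sum(out$network$role == "transmitter"),
               2 * sum(net$role == "transmitter"))
})

test_that("edge inheritance keeps small neighborhoods and caps large ones", {
  # parent 1 with 3 neighbors, none dividing: both keep all 3 plus the
  # parent-daughter edge
  set.seed(33)
  net <- make_net(rep("monoculture_receiver", 5), edges = star_edges(3))
  net <- growth_step(net, p_div = 0, k = 1)$network   # no-op
  net$substrate <- c(20, 0, 0, 0, 0)                  # only hub eligible
  out <- growth_step(net, p_div = 1, k = 1)
  nn <- out$network
  expect_equal(nn$n, 6)
  d <- nn$n
  expect_setequal(net_neighbors(nn, 1), c(2, 3, 4, d))
  expect_setequal(net_neighbors(nn, d), c(2, 3, 4, 1))

  # parent with 10 neighbors that all divide: 20 candidates, each side
  # samples exactly 10
  set.seed(34)
  hub <- make_net(rep("monoculture_receiver", 21), edges = star_edges(10))
  hub$substrate <- c(20, rep(0, 20))
  daughters <- stats::setNames(11L + 1:10, 2:11)  # pretend neighbors divided
  withr::with_seed(35, {
    inh <- inherit_edges(hub, parent_id = 1L, daughter_id = 12L,
                         max_neighbors = 10,
                         same_step_daughters = daughters)
  })
  nb_parent <- setdiff(net_neighbors(inh, 1), 12L)
  nb_daughter <- setdiff(net_neighbors(inh, 12L), 1L)
  expect_lte(length(nb_parent), 10)
  expect_lte(length(nb_daughter), 10)
  expect_true(all(c(nb_parent, nb_daughter) %in% c(2:11, 13:21)))
  expect_true(12L %in% net_neighbors(inh, 1))

  # isolated parent: only the parent-daughter edge appears
  iso <- make_net(rep("monoculture_receiver", 1), substrate = 20)
  out_iso <- growth_step(iso, p_div = 1, k = 1)
  expect_equal(out_iso$network$edges, cbind(1L, 2L), ignore_attr = TRUE)
})

test_that("same-step daughters can be sampled as neighbors in batch growth", {
  set.seed(36)
  # two connected eligible nodes; both divide, candidate pools include the
  # other's daughter, and every edge endpoint must exist
  net <- make_net(rep("monoculture_receiver", 2), substrate = 20,
                  edges = cbind(1L, 2L))
  out <- growth_step(net, p_div = 1, k = 1)
  nn <- out$network
  expect_equal(nn$n, 4)
  expect_true(all(nn$edges >= 1 & nn$edges <= 4))
  expect_true(2L %in% net_neighbors(nn, 1) || 4L %in% net_neighbors(nn, 1))
})

test_that("max_network_size follows the iterated-halving capacity rule", {
  expect_identical(max_network_size(50, 20, 1), 1600L)
  expect_identical(max_network_size(100, 20, 1), 3200L)
  expect_identical(max_network_size(7, 1, 1), 7L)     # s0 <= k: no division
  expect_identical(max_network_size(1, 4, 1), 4L)     # two halvings
})

test_that("population growth is monotone and bounded by the capacity", {
  set.seed(37)
  bound <- max_network_size(50, 20, 1)
  finals <- numeric(3)
  for (r in 1:3) {
    net <- init_network(sim_config(n_initial = 50, mean_degree = 4))
    counts <- integer(301)
    counts[1] <- net$n
    for (t in 1:300) {
      net <- growth_step(net, p_div = 0.015, k = 1)$network
      counts[t + 1] <- net$n
    }
    expect_true(all(diff(counts) >= 0))
    expect_lte(max(counts), bound)
    finals[r] <- net$n
  }
  # log-phase growth has taken off by 300 steps
  expect_gt(mean(finals), 0.5 * bound)
})
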