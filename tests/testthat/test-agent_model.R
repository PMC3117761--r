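test_that("agent construction enforces its invariants", {
  expect_error(agent("a", "visitor", 0, traits = character(0),
                     trait_sizes = numeric(0), resources = 1),
               "at least one trait")
  expect_error(make_visitor(sizes = c(t1 = -1, t2 = 4)), "0, max_trait_size")
  expect_error(make_visitor(sizes = c(t1 = 2, t2 = 7)), "0, max_trait_size")
  expect_error(make_visitor(resources = -2), "non-negative")
  expect_error(agent("a", "pollinator", 0, "t1", c(t1 = 1), 1))
  a <- make_visitor()
  expect_s3_class(a, "mut_agent")
  expect_identical(a$role, "visitor")
})

test_that("choose_host returns a supplied host, uniformly at random", {
  hosts <- list(make_host("h1"), make_host("h2"), make_host("h3"))
  v <- make_visitor()
  expect_identical(choose_host(v, hosts[1]), hosts[[1]])
  expect_error(choose_host(v, list()), "no available host")

  set.seed(101)
  picks <- replicate(30000, choose_host(v, hosts)$id)
  freq <- table(picks) / length(picks)
  expect_true(all(abs(freq - 1 / 3) < 0.02))
})

test_that("same_habitat is label equality and symmetric", {
  expect_true(same_habitat(1, 1))
  expect_false(same_habitat(0, 1))
  for (a in 0:1) for (b in 0:1) {
    expect_identical(same_habitat(a, b), same_habitat(b, a))
  }
})

test_that("decide_metacommunity gates on resources then on propensity", {
  poor <- make_visitor(resources = 8, metacommunity_prob = 1)
  set.seed(1)
  expect_false(decide_metacommunity(poor, max_resource = 20))

  never <- make_visitor(resources = 20, metacommunity_prob = 0)
  expect_false(decide_metacommunity(never, max_resource = 20))

  sometimes <- make_visitor(resources = 20, metacommunity_prob = 0.1)
  set.seed(202)
  hits <- replicate(100000, decide_metacommunity(sometimes, 20))
  expect_lt(abs(mean(hits) - 0.1), 0.005)
})

test_that("have_trait is set membership, and initialised agents always have one", {
  v <- make_visitor(traits = c("t1", "t2"), sizes = c(t1 = 1, t2 = 2))
  expect_true(have_trait(v, "t1"))
  expect_false(have_trait(v, "t3"))

  set.seed(7)
  community <- init_community(sim_config())
  universe <- paste0("t", seq_len(sim_config()$n_traits_universe))
  for (a in community) {
    expect_true(any(vapply(universe, have_trait, TRUE, visitor = a)))
  }
})

test_that("complementarity_degree matches its normalised-difference form", {
  expect_equal(complementarity_degree(3, 3, 5), 1)
  expect_equal(complementarity_degree(0, 5, 5), 0)
  expect_equal(complementarity_degree(2, 4, 5), 0.6)
  expect_error(complementarity_degree(6, 1, 5), "0, max_trait_size")
  expect_error(complementarity_degree(1, -0.5, 5), "0, max_trait_size")

  # symmetric, and 1 iff the sizes are equal
  grid <- expand.grid(a = seq(0, 5, by = 0.5), b = seq(0, 5, by = 0.5))
  for (i in seq_len(nrow(grid))) {
    d_ab <- complementarity_degree(grid$a[i], grid$b[i], 5)
    d_ba <- complementarity_degree(grid$b[i], grid$a[i], 5)
    expect_identical(d_ab, d_ba)
    expect_identical(d_ab == 1, grid$a[i] == grid$b[i])
  }
})

test_that("is_complementary is a strict threshold", {
  expect_true(is_complementary(0.6, 0))
  expect_false(is_complementary(0, 0))

  # on integer size pairs 1..5 (max 5), exactly degrees 0.6, 0.8, 1 pass 0.5
  degrees <- unique(as.vector(outer(1:5, 1:5, function(a, b) {
    mapply(complementarity_degree, a, b, MoreArgs = list(max_trait_size = 5))
  })))
  passing <- sort(degrees[vapply(degrees, is_complementary, TRUE,
                                 threshold = 0.5)])
  expect_equal(passing, c(0.6, 0.8, 1.0))
})

test_that("compute_demand is linear in complementarity and survival-capped", {
  v <- make_visitor(resources = 15, min_resource = 5)
  expect_equal(compute_demand(v, 0), list(amount = 0, reward = 0))
  expect_equal(compute_demand(v, 1), list(amount = 4, reward = 2))

  # monotone non-decreasing in degree
  degrees <- seq(0, 1, by = 0.05)
  out <- lapply(degrees, compute_demand, visitor = v)
  amounts <- vapply(out, `[[`, 0, "amount")
  rewards <- vapply(out, `[[`, 0, "reward")
  expect_true(all(diff(amounts) >= 0))
  expect_true(all(diff(rewards) >= 0))

  # reward never pushes the visitor below its floor
  tight <- make_visitor(resources = 5.5, min_resource = 5)
  expect_equal(compute_demand(tight, 1)$reward, 0.5)
  broke <- make_visitor(resources = 5, min_resource = 5)
  expect_equal(compute_demand(broke, 1)$reward, 0)
})

test_that("host_has offers the demand capped at the survival floor", {
  h <- make_host(resources = 20, min_resource = 5)
  expect_equal(host_has(h, amount = 4, reward = 2), 4)
  expect_equal(host_has(h, 0, 0), 0)
  floor_host <- make_host(resources = 5, min_resource = 5)
  expect_equal(host_has(floor_host, amount = 3, reward = 0), 0)
  # the incoming reward counts as spendable
  expect_equal(host_has(floor_host, amount = 3, reward = 1), 1)

  # monotone in spare resources
  spares <- seq(5, 12, by = 0.5)
  offers <- vapply(spares, function(r) {
    host_has(make_host(resources = r, min_resource = 5), 4, 0)
  }, 0)
  expect_true(all(diff(offers) >= 0))
})

test_that("settlement moves resources as declared and conserves totals", {
  v <- make_visitor(resources = 10)
  v2 <- settle_visitor(v, offered = 4, reward = 2, is_metacommunity = FALSE,
                       living_cost = 0.1)
  expect_equal(v2$resources - v$resources, 1.9)

  same <- settle_visitor(v, 0, 0, FALSE, living_cost = 0)
  expect_equal(same$resources, v$resources)

  meta <- settle_visitor(v, 4, 2, TRUE, living_cost = 0.1,
                         metacommunity_surcharge = 1)
  expect_lt(meta$resources, v2$resources)

  h <- make_host(resources = 20)
  h2 <- settle_host(h, offered = 4, reward = 2)
  expect_equal(h2$resources, 18)
  expect_equal(settle_host(h, 0, 0)$resources, 20)

  # zero-cost exchange conserves community resources exactly
  v0 <- settle_visitor(v, 4, 2, FALSE, living_cost = 0)
  expect_equal(v0$resources + h2$resources, v$resources + h$resources)
})

test_that("per-interaction conservation holds up to the declared costs", {
  cfg <- ample_config()
  for (meta in c(FALSE, TRUE)) {
    v <- make_visitor(resources = 14, metacommunity_prob = 1,
                      habitat = if (meta) 1 else 0)
    h <- make_host(resources = 18)
    set.seed(5)
    out <- run_interaction(v, h, cfg)
    expect_identical(out$record$outcome, "success")
    gain_v <- out$visitor$resources - v$resources
    gain_h <- out$host$resources - h$resources
    cost <- cfg$living_cost + if (meta) cfg$metacommunity_surcharge else 0
    expect_equal(gain_v + gain_h + cost, 0)
  }
})
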