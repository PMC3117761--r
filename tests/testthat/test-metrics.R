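test_that("connectance is L over S squared", {
  expect_equal(connectance(network_from_matrix(matrix(1, 2, 3))), 6 / 25)
  expect_equal(connectance(network_from_matrix(matrix(1, 1, 1))), 0.25)
  empty <- build_network(data.frame(visitor_id = character(0),
                                    host_id = character(0),
                                    outcome = character(0)))
  expect_error(connectance(empty), "empty network")

  # bipartite upper bound over simulated networks
  for (seed in 1:3) {
    net <- build_network(
      run_simulation(sim_config(target_successes = 50, seed = seed))$records)
    bound <- length(net$host_ids) * length(net$visitor_ids) /
      (length(net$host_ids) + length(net$visitor_ids))^2
    expect_lte(connectance(net), bound)
  }
})

test_that("NODF handles the canonical extremes", {
  expect_equal(nodf(diag(2)), 0)          # equal fills everywhere
  expect_equal(nodf(stepped_matrix(3)), 100)
  expect_equal(nodf(stepped_matrix(6)), 100)
  # counts are binarised before computing
  stepped_counts <- stepped_matrix(4) * sample(1:9, 16, replace = TRUE)
  expect_equal(nodf(stepped_counts), 100)
  expect_error(nodf(matrix(c(1, 0, 0, 0), 2, 2)), "two non-empty")
  expect_error(nodf(matrix(1, 5, 1)), "two non-empty")
})

test_that("NODF equals the brute-force pairwise oracle on random matrices", {
  set.seed(42)
  for (trial in 1:60) {
    m <- random_binary_matrix(6, 8, p = runif(1, 0.2, 0.6))
    expect_equal(nodf(m), nodf_bruteforce(m), tolerance = 1e-12)
  }
})

test_that("NODF is invariant to row and column permutation", {
  set.seed(7)
  m <- random_binary_matrix(10, 15)
  base <- nodf(m)
  for (i in 1:20) {
    shuffled <- m[sample(nrow(m)), sample(ncol(m))]
    expect_lt(abs(nodf(shuffled) - base), 1e-9)
  }
})

test_that("NODF agrees with the vegan reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(99)
  for (trial in 1:20) {
    m <- random_binary_matrix(8, 12, p = runif(1, 0.2, 0.5))
    ref <- unname(vegan::nestednodf(m, order = TRUE)$statistic["NODF"])
    expect_equal(nodf(m), ref, tolerance = 1e-9)
  }
})

test_that("the perfect-nestedness isocline encloses the requested fill", {
  for (fill in c(0.1, 0.3, 0.5, 0.7, 0.999)) {
    curve <- isocline_perfect_nestedness(c(10, 15), fill, n_points = 2000)
    expect_true(all(diff(curve$y) <= 0))
    # trapezoidal area under the sampled curve
    area <- sum(diff(curve$x) * (head(curve$y, -1) + tail(curve$y, -1)) / 2)
    expect_lt(abs(area - fill * 10 * 15) / (10 * 15), 0.01)
  }
  expect_error(isocline_perfect_nestedness(c(5, 5), 0), "strictly between")
  expect_error(isocline_perfect_nestedness(c(5, 5), 1), "strictly between")
})

test_that("interaction frequencies count distinct partners per node", {
  star <- network_from_matrix(matrix(1, 1, 5))
  hist <- interaction_frequency_distribution(star)
  expect_equal(hist[["1"]], 5)
  expect_equal(hist[["5"]], 1)

  single <- network_from_matrix(matrix(1, 1, 1))
  expect_equal(interaction_frequency_distribution(single)[["1"]], 2)

  net <- build_network(
    run_simulation(sim_config(target_successes = 60, seed = 31))$records)
  hist2 <- interaction_frequency_distribution(net)
  expect_equal(sum(hist2),
               length(net$host_ids) + length(net$visitor_ids))
})

test_that("degree distributions follow the host-to-visitor arc convention", {
  star <- network_from_matrix(matrix(1, 1, 5))
  deg <- degree_distributions(star)
  expect_equal(deg$out_degree, stats::setNames(1L, "5"))
  expect_equal(deg$in_degree, stats::setNames(5L, "1"))

  net <- build_network(
    run_simulation(sim_config(target_successes = 60, seed = 32))$records)
  deg2 <- degree_distributions(net)
  in_sum <- sum(as.integer(names(deg2$in_degree)) * deg2$in_degree)
  out_sum <- sum(as.integer(names(deg2$out_degree)) * deg2$out_degree)
  expect_equal(in_sum, nrow(net$edges))
  expect_equal(out_sum, nrow(net$edges))
})

test_that("power_law_fit recovers exact exponents", {
  k <- c(1, 2, 4, 8)
  expect_equal(power_law_fit(stats::setNames(k^-2, k)), -2, tolerance = 1e-9)
  expect_equal(power_law_fit(stats::setNames(rep(3, 4), k)), 0,
               tolerance = 1e-12)
  # frequency rescaling shifts the intercept only
  expect_equal(power_law_fit(stats::setNames(10 * k^-2, k)), -2,
               tolerance = 1e-9)
  expect_error(power_law_fit(stats::setNames(c(1, 2), c(1, 2))),
               "at least three")
})

test_that("dependence distributions are relative frequencies on (0, 1]", {
  star <- network_from_matrix(matrix(1, 1, 5))
  h_on_v <- dependence_distribution(star, "host_on_visitor", bins = 10)
  expect_equal(sum(h_on_v$rel_freq), 1, tolerance = 1e-12)
  expect_equal(h_on_v$rel_freq[h_on_v$lower == 0.1], 1)  # all values at 0.2
  v_on_h <- dependence_distribution(star, "visitor_on_host", bins = 10)
  expect_equal(v_on_h$rel_freq[v_on_h$upper == 1], 1)    # all values at 1.0

  net <- build_network(
    run_simulation(sim_config(target_successes = 60, seed = 33))$records)
  for (dir in c("host_on_visitor", "visitor_on_host")) {
    d <- dependence_distribution(net, dir)
    expect_equal(sum(d$rel_freq), 1, tolerance = 1e-12)
    vals <- dependence_values(net, dir)
    expect_true(all(vals > 0 & vals <= 1))
  }
})

test_that("aggregate_interaction_frequencies averages across networks", {
  nets <- list(network_from_matrix(matrix(1, 1, 5)),
               network_from_matrix(matrix(1, 1, 1)))
  agg <- aggregate_interaction_frequencies(nets)
  expect_identical(agg$partners, c(1L, 5L))
  # degree 1: five nodes in the star, two in the single edge
  expect_equal(agg$mean_freq[1], 3.5)
  expect_equal(agg$sd_freq[1], stats::sd(c(5, 2)))
  expect_equal(agg$mean_freq[2], 0.5)
})

test_that("metrics_report bundles consistent values", {
  net <- build_network(
    run_simulation(sim_config(target_successes = 80, seed = 34))$records)
  rep <- metrics_report(net)
  expect_equal(rep$connectance, rep$L / rep$S^2)
  expect_identical(rep$L, nrow(net$edges))
  expect_identical(rep$n_events, 80L)
  expect_true(rep$nodf >= 0 && rep$nodf <= 100)
  expect_true(all(diff(rep$isocline$y) <= 0))

  js <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(rep, js)
  doc <- jsonlite::read_json(js)
  expect_equal(doc$connectance, rep$connectance)
  expect_equal(doc$nodf, rep$nodf)
})
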