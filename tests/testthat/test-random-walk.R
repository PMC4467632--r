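test_that("transition model matches hand-checked degree arithmetic", {
  net <- build_network(rbind(c("P1", "P2")), list(D1 = "P1", D2 = "P2"))
  tm <- build_transition_model(net)
  expect_equal(unname(tm$s), c(2, 2))
  expect_equal(as.matrix(tm$Q), matrix(c(0, 0.5, 0.5, 0), 2),
               ignore_attr = TRUE)
  expect_equal(unname(tm$a), c(0.5, 0.5))
  expect_equal(as.matrix(tm$S), matrix(c(1, 0, 0, 1), 2),
               ignore_attr = TRUE)

  # isolated attached protein: all absorption, no moves
  iso <- build_network(matrix(character(0), ncol = 2), list(D1 = "P9"))
  tmi <- build_transition_model(iso)
  expect_equal(unname(tmi$a), 1)
  expect_equal(sum(tmi$Q), 0)

  # large-beta limit: absorption dominates at attached proteins
  big <- build_network(rbind(c("P1", "P2")), list(D1 = "P1", D2 = "P2"),
                       beta = 1e9)
  expect_true(all(build_transition_model(big)$a > 1 - 1e-8))

  # row-stochasticity: rowsums of Q plus absorption equal 1
  fx <- generate_fixture(fixture_spec(2, 12, 0.3, 0.02, 3, 2, seed = 3))
  tmf <- build_transition_model(fx$network)
  expect_lt(max(abs(Matrix::rowSums(tmf$Q) + tmf$a - 1)), 1e-12)
})

test_that("unpruned networks with orphan components are rejected", {
  net <- build_network(rbind(c("P1", "P2"), c("P5", "P6")),
                       list(D1 = "P1"))
  expect_error(build_transition_model(net), "prune")
})

test_that("weight vectors solve the absorbing-walk system exactly", {
  tf <- tiny_fixtures()
  for (nm in c("path2", "star")) {
    tm <- build_transition_model(tf[[nm]]$network)
    W <- compute_all_weight_vectors(tm)
    expect_equal(W, tf[[nm]]$expected$W, tolerance = 1e-12)
    # batch equals per-disease solves
    for (d in tm$diseases)
      expect_equal(W[d, ], compute_weight_vector(tm, d), tolerance = 1e-12)
  }
  expect_error(compute_weight_vector(
    build_transition_model(tf$path2$network), "D9"), "unknown disease")

  # single attached protein: one visit then immediate absorption
  iso <- build_network(matrix(character(0), ncol = 2), list(D1 = "P9"))
  expect_equal(unname(compute_weight_vector(build_transition_model(iso), "D1")),
               1)

  # identical gene sets give identical weight vectors
  twin <- build_network(rbind(c("P1", "P2")),
                        list(D1 = "P1", D2 = "P1", D3 = "P2"))
  Wt <- compute_all_weight_vectors(build_transition_model(twin))
  expect_equal(Wt["D1", ], Wt["D2", ])
})

test_that("every walk is absorbed exactly once (conservation)", {
  for (seed in 1:5) {
    fx <- generate_fixture(fixture_spec(3, 10, 0.3, 0.02, 3, 2, seed = seed))
    tm <- build_transition_model(fx$network)
    W <- compute_all_weight_vectors(tm)
    expect_true(all(W >= 0))
    expect_true(all(is.finite(W)))
    expect_lt(max(abs(W %*% tm$a - 1)), 1e-10)
  }
})

test_that("scaling beta and PPI weights together leaves the walk unchanged", {
  fx <- generate_fixture(fixture_spec(2, 10, 0.3, 0.05, 3, 2, seed = 11))
  net1 <- fx$network
  net2 <- build_network(net1$ppi, net1$associations, beta = 7, ppi_weight = 7)
  tm1 <- build_transition_model(net1)
  tm2 <- build_transition_model(net2)
  expect_equal(as.matrix(tm1$Q), as.matrix(tm2$Q), tolerance = 1e-14)
  expect_equal(tm1$a, tm2$a, tolerance = 1e-14)
  expect_equal(compute_all_weight_vectors(tm1), compute_all_weight_vectors(tm2),
               tolerance = 1e-12)
})

test_that("larger beta never increases total expected visits", {
  fx <- generate_fixture(fixture_spec(2, 10, 0.3, 0.05, 3, 2, seed = 5))
  totals <- sapply(c(0.5, 1, 2, 4, 8), function(b) {
    net <- build_network(fx$network$ppi, fx$network$associations, beta = b)
    sum(compute_all_weight_vectors(build_transition_model(net)))
  })
  expect_true(all(diff(totals) <= 1e-12))
})

test_that("Monte-Carlo simulation agrees with the analytic solve", {
  net <- path2_network()
  sim <- simulate_walks(net, "D1", n_walks = 2e4, seed = 42)
  expect_equal(sim$n_truncated, 0L)
  expect_true(all(abs(sim$mean - c(4, 2) / 3) <= 4 * sim$se))

  # a degenerate walk is exact: one visit, zero variance
  iso <- build_network(matrix(character(0), ncol = 2), list(D1 = "P9"))
  simi <- simulate_walks(iso, "D1", n_walks = 500, seed = 1)
  expect_equal(unname(simi$mean), 1)
  expect_equal(unname(simi$se), 0)

  expect_warning(sim0 <- simulate_walks(net, "D1", n_walks = 0), "n_walks")
  expect_equal(unname(sim0$mean), c(0, 0))

  # reproducibility
  s1 <- simulate_walks(net, "D1", n_walks = 1000, seed = 7)
  s2 <- simulate_walks(net, "D1", n_walks = 1000, seed = 7)
  expect_identical(s1, s2)
})

test_that("weight support stays inside the disease's component", {
  tf <- tiny_fixtures()
  tm <- build_transition_model(tf$two_components$network)
  W <- compute_all_weight_vectors(tm)
  expect_equal(unname(W["DA1", c("B1", "B2")]), c(0, 0))
  expect_equal(unname(W["DB1", c("A1", "A2")]), c(0, 0))
})
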