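test_that("farthest-first seeding covers the planted modules", {
  fx <- generate_fixture(fixture_spec(3, 15, 0.3, 0.01, 4, 3, seed = 1))
  W <- compute_all_weight_vectors(build_transition_model(fx$network))

  V0 <- init_clusters(W, K = nrow(W), seed = 1)
  expect_setequal(rownames(V0), rownames(W))

  V1 <- init_clusters(W, K = 1, seed = 1)
  expect_equal(rownames(V1), rownames(W)[which.max(rowSums(W))])

  V3 <- init_clusters(W, K = 3, seed = 1)
  expect_equal(sort(unique(fx$labels[rownames(V3)])), 1:3)

  expect_error(init_clusters(W, 0), "K must")
  expect_error(init_clusters(W, nrow(W) + 1), "K must")
})

test_that("degenerate geometries force the expected memberships", {
  # identical disease vectors: clusters merge to one, all memberships 1
  net <- build_network(rbind(c("P1", "P2")), list(D1 = "P1", D2 = "P1"))
  W <- compute_all_weight_vectors(build_transition_model(net))
  m <- quiet_fit(W, K = 2, seed = 1)
  expect_equal(ncol(m$P), 1L)
  expect_equal(unname(m$P[, 1]), c(1, 1))

  # orthogonal supports force hard assignment
  tf <- tiny_fixtures()
  W2 <- compute_all_weight_vectors(
    build_transition_model(tf$two_components$network))[c("DA1", "DB1"), ]
  m2 <- quiet_fit(W2, K = 2, seed = 1)
  expect_equal(unname(sort(apply(m2$P, 1, max))), c(1, 1))
  expect_equal(unname(sort(apply(m2$P, 1, min))), c(0, 0))
})

test_that("membership rows sum to one at every iteration", {
  fx <- generate_fixture(fixture_spec(3, 12, 0.3, 0.02, 3, 2, seed = 2))
  W <- compute_all_weight_vectors(build_transition_model(fx$network))
  Wn <- W / sqrt(rowSums(W^2))
  V <- init_clusters(W, 3, seed = 2)
  for (it in 1:30) {
    P <- diseaseflow:::e_step(Wn, V, gamma = 5)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
    V <- diseaseflow:::m_step(Wn, P, V)
    expect_lt(max(abs(sqrt(rowSums(V^2)) - 1)), 1e-12)
  }
  m <- quiet_fit(W, K = 3, seed = 2)
  expect_lt(max(abs(rowSums(m$P) - 1)), 1e-9)
  expect_true(all(m$P >= 0 & m$P <= 1))
  # no two fitted cluster vectors exceed the merge threshold
  CC <- m$V %*% t(m$V)
  diag(CC) <- 0
  expect_true(all(CC <= m$merge_threshold))
})

test_that("the soft-assignment objective is non-decreasing at gamma = 1", {
  fx <- generate_fixture(fixture_spec(3, 12, 0.3, 0.02, 3, 2, seed = 3))
  W <- compute_all_weight_vectors(build_transition_model(fx$network))
  Wn <- W / sqrt(rowSums(W^2))
  V <- init_clusters(W, 3, seed = 3)
  obj <- numeric(0)
  for (it in 1:40) {
    P <- diseaseflow:::e_step(Wn, V, gamma = 1)
    obj <- c(obj, sum(P * (Wn %*% t(V))))
    V <- diseaseflow:::m_step(Wn, P, V)
  }
  expect_true(all(diff(obj) >= -1e-10))
})

test_that("permuting the initial centers permutes the clusters", {
  fx <- generate_fixture(fixture_spec(3, 15, 0.3, 0.01, 4, 3, seed = 1))
  W <- compute_all_weight_vectors(build_transition_model(fx$network))
  V0 <- init_clusters(W, 3, seed = 1)
  m1 <- quiet_fit(W, V0 = V0, seed = 1)
  m2 <- quiet_fit(W, V0 = V0[c(3, 1, 2), ], seed = 1)
  expect_equal(m1$P, m2$P[, c(2, 3, 1)], ignore_attr = TRUE,
               tolerance = 1e-6)
})

test_that("planted module structure is recovered", {
  for (seed in 1:2) {
    fx <- generate_fixture(fixture_spec(3, 15, 0.3, 0.01, 4, 3, seed = seed))
    m <- quiet_model(fx$network, K = 3, seed = seed)
    am <- apply(m$clusters$P, 1, which.max)
    expect_gte(perm_accuracy(am, fx$labels[rownames(m$clusters$P)]), 0.9)
  }
})

test_that("membership queries mirror the similarity query semantics", {
  model <- structure(
    list(P = matrix(c(0.7, 0.5, 0.3, 0.5), 2,
                    dimnames = list(c("Dx", "Dy"), c("C1", "C2"))),
         V = matrix(1, 2, 1, dimnames = list(c("C1", "C2"), "P1")),
         gamma = 5, converged = TRUE, n_iter = 1L),
    class = "cluster_model")
  expect_equal(membership_query(model, "Dx", min_prob = 0.5)$cluster_id, "C1")
  # exact tie at rank 1 returns both clusters
  expect_equal(nrow(membership_query(model, "Dy", rank = 1)), 2L)
  expect_equal(nrow(membership_query(model, "Dx", min_prob = 0)), 2L)
  expect_error(membership_query(model, "Dz", rank = 1), "unknown disease")
  expect_error(membership_query(model, "Dx", rank = 1, min_prob = 0.1),
               "exactly one")
})

test_that("cluster listings cover all diseases in descending order", {
  fx <- generate_fixture(fixture_spec(2, 10, 0.3, 0.02, 3, 2, seed = 5))
  m <- quiet_model(fx$network, K = 2, seed = 5)
  for (k in colnames(m$clusters$P)) {
    lst <- cluster_listing(m$clusters, k)
    expect_equal(nrow(lst), nrow(m$clusters$P))
    expect_true(all(diff(lst$probability) <= 0))
  }
  expect_error(cluster_listing(m$clusters, "C99"), "unknown cluster")
})
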