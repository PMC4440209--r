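# Influence metrics: degree, eigendecomposition, betweenness, dynamics,
# ranking. Oracles: closed forms, exhaustive path enumeration, igraph.

test_that("degree counts incident links", {
  expect_equal(node_degree(star_net(12), "n1"), 11L)
  expect_equal(unname(node_degree(star_net(12))[-1]), rep(1L, 11))
  empty <- connection_matrix(matrix(0, 5, 5))
  expect_equal(unname(node_degree(empty)), rep(0L, 5))
  expect_error(node_degree(star_net(4), "nope"), "unknown node")
  set.seed(8)
  for (i in 1:20) {
    net <- random_net(sample(3:8, 1))
    expect_equal(node_degree(net), {
      d <- rowSums(net$weights > 0); storage.mode(d) <- "integer"; d
    })
  }
})

test_that("the triangle has spectrum {2, -1, -1} and eigenpairs satisfy their residual", {
  k3 <- complete_net(3)
  ea <- eigen_analysis(k3)
  expect_equal(ea$values, c(2, -1, -1), tolerance = 1e-12)
  expect_equal(ea$spectral_radius, 2, tolerance = 1e-12)
  expect_equal(unname(ea$influence), c(1, 1, 1), tolerance = 1e-10)
})

test_that("eigen residuals are tiny and the star hub dominates the eigenvector", {
  st <- star_net(9)
  ea <- eigen_analysis(st)
  expect_equal(names(which.max(ea$influence)), "n1")
  expect_equal(max(ea$influence), 1)
  set.seed(21)
  for (i in 1:25) {
    net <- random_net(sample(3:8, 1))
    C <- net$weights
    e <- eigen(C, symmetric = TRUE)
    ea <- eigen_analysis(net)
    normC <- norm(C, "2")
    for (j in seq_along(ea$values)) {
      v <- e$vectors[, j]
      expect_lt(sqrt(sum((C %*% v - ea$values[j] * v)^2)),
                1e-10 * max(normC, 1))
    }
    # eigenvalue sum equals the (zero) trace
    expect_lt(abs(sum(ea$values)), 1e-10 * max(normC, 1))
  }
})

test_that("betweenness matches closed forms on paths and complete graphs", {
  p3 <- path_net(3)
  expect_equal(betweenness(p3, "n2"), 1)
  expect_equal(betweenness(p3, "n1"), 0)
  p5 <- path_net(5)
  expect_equal(unname(betweenness(p5)), c(0, 3, 4, 3, 0))
  expect_equal(unname(betweenness(complete_net(6))), rep(0, 6))
  expect_error(betweenness(p3, "zz"), "unknown node")
})

test_that("betweenness matches exhaustive path enumeration on small random graphs", {
  set.seed(14)
  for (i in 1:40) {
    net <- random_net(sample(3:6, 1), p_edge = runif(1, 0.3, 0.9))
    adj <- net$weights > 0
    expect_equal(unname(betweenness(net)),
                 oracle_betweenness_enum(adj, "fractional"), tolerance = 1e-12)
    expect_equal(unname(betweenness(net, mode = "count")),
                 oracle_betweenness_enum(adj, "count"), tolerance = 1e-12)
  }
})

test_that("total betweenness equals the internal geodesic mass on connected graphs", {
  set.seed(77)
  tried <- 0
  while (tried < 10) {
    net <- random_net(sample(4:7, 1), p_edge = 0.7)
    adj <- net$weights > 0
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (!igraph::is_connected(g)) next
    tried <- tried + 1
    d <- igraph::distances(g)
    # each unordered pair contributes (path length - 1) interior slots,
    # fractionally split; summed over pairs this is the total internal mass
    mass <- sum(d[upper.tri(d)] - 1)
    expect_equal(sum(betweenness(net)), mass, tolerance = 1e-10)
  }
})

test_that("influence propagation is the iterated matrix product", {
  st <- star_net(5, weight = 0.5)
  s0 <- c(1, 2, 3, 4, 5)
  expect_equal(unname(propagate_influence(st, s0, 0)$state), s0)
  set.seed(3)
  for (i in 1:10) {
    net <- random_net(5)
    s0 <- runif(5)
    C <- net$weights
    expect_equal(unname(propagate_influence(net, s0, 4)$state),
                 as.numeric(C %*% C %*% C %*% C %*% s0), tolerance = 1e-12)
    # semigroup property: t1 + t2 steps = t2 steps after t1 steps
    s_a <- propagate_influence(net, s0, 7)$state
    s_b <- propagate_influence(net, propagate_influence(net, s0, 3)$state, 4)$state
    expect_equal(s_a, s_b, tolerance = 1e-12)
  }
  expect_error(propagate_influence(st, 1:3, 2), "one entry per node")
  expect_error(propagate_influence(st, s0, -1), "non-negative")
})

test_that("stability classes follow the spectral radius and the dynamics agree", {
  expect_equal(stability_class(complete_net(3)), "growing")
  expect_equal(stability_class(connection_matrix(matrix(0, 4, 4))), "decaying")
  set.seed(10)
  net <- random_net(8, p_edge = 0.6)
  radius <- eigen_analysis(net)$spectral_radius
  scale_to <- function(net, r_target) {
    connection_matrix(net$weights * (r_target / radius))
  }
  grow <- scale_to(net, 1.8)
  s0 <- runif(8, 0.5, 1)
  s50 <- propagate_influence(grow, s0, 50)$state
  s51 <- propagate_influence(grow, s0, 51)$state
  expect_equal(sqrt(sum(s51^2)) / sqrt(sum(s50^2)), 1.8, tolerance = 0.01)
  decay <- scale_to(net, 0.5)
  sT <- propagate_influence(decay, s0, 50)$state
  expect_lt(sqrt(sum(sT^2)), 1e-6 * sqrt(sum(s0^2)))
})

test_that("node ranking reports maxima with deterministic ties", {
  st <- star_net(7)
  rk <- rank_nodes(node_metrics(st))
  expect_equal(rk$hub, "n1")
  expect_equal(rk$max_eigen, "n1")
  expect_equal(rk$max_betweenness, "n1")
  # two isolated dyads: all degrees tie at 1, all betweenness at 0
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1; w[3, 4] <- w[4, 3] <- 1
  dyads <- connection_matrix(w)
  rk2 <- rank_nodes(node_metrics(dyads))
  expect_equal(rk2$hub, c("n1", "n2", "n3", "n4"))
  expect_equal(rk2$max_betweenness, c("n1", "n2", "n3", "n4"))
  expect_identical(rk2, rank_nodes(node_metrics(dyads)))
})

test_that("metrics permute consistently with node order", {
  set.seed(31)
  net <- random_net(7)
  perm <- sample(7)
  w2 <- net$weights[perm, perm]
  dimnames(w2) <- list(paste0("n", 1:7)[perm], paste0("n", 1:7)[perm])
  net2 <- connection_matrix(w2)
  m1 <- node_metrics(net)
  m2 <- node_metrics(net2)
  m2 <- m2[match(m1$node, m2$node), ]
  expect_equal(m1$degree, m2$degree)
  expect_equal(m1$betweenness, m2$betweenness, tolerance = 1e-10)
  expect_equal(m1$eigen_influence, m2$eigen_influence, tolerance = 1e-8)
  expect_equal(attr(m1, "spectral_radius"), attr(node_metrics(net2), "spectral_radius"),
               tolerance = 1e-12)
})
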