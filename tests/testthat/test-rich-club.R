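test_that("phi reproduces hand-counted subgraph densities", {
  k5 <- net_from(matrix(1, 5, 5) - diag(5))
  for (k in 1:3) expect_equal(phi(k5, k), 1)

  # 4-cycle + diagonal: degrees (3, 2, 3, 2)
  sq <- net_from(adj_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1),
                                        c(1, 3))))
  expect_equal(phi(sq, 2), 1)       # survivors {1, 3}, edge present
  expect_equal(phi(sq, 1), 5 / 6)   # all 4 survive, 5 of 6 possible edges
  expect_true(is.na(phi(sq, 3)))

  star <- net_from(adj_from_edges(5, lapply(2:5, function(j) c(1, j))))
  expect_true(is.na(phi(star, 1)))  # only the center survives
})

test_that("phi agrees with the brute-force subgraph oracle on small graphs", {
  for (s in 1:15) {
    A <- random_graph_adj(7, 0.4, seed = 800 + s)
    net <- net_from(A)
    for (k in 1:6)
      expect_equal(phi(net, k), oracle_phi(A, k))
  }
})

test_that("double-edge-swap rewiring preserves every node's degree", {
  for (s in 1:5) {
    A <- random_graph_adj(20, 0.25, seed = 900 + s)
    net <- net_from(A)
    rn <- randomize_network(net, seed = s, swaps_per_edge = 10)
    expect_equal(rowSums(rn$adjacency), rowSums(A), ignore_attr = TRUE)
    expect_true(all(diag(rn$adjacency) == 0))
    expect_true(all(rn$adjacency %in% c(0, 1)))
    expect_false(identical(rn$adjacency, net$adjacency))  # actually rewired
  }
  # the triangle is the only simple graph on its degree sequence
  tri <- net_from(adj_from_edges(3, list(c(1, 2), c(2, 3), c(1, 3))))
  expect_equal(randomize_network(tri, seed = 1)$adjacency, tri$adjacency)
})

test_that("rewiring is deterministic given the seed", {
  A <- random_graph_adj(15, 0.3, seed = 17)
  net <- net_from(A)
  expect_identical(randomize_network(net, seed = 4)$adjacency,
                   randomize_network(net, seed = 4)$adjacency)
  expect_false(identical(randomize_network(net, seed = 4)$adjacency,
                         randomize_network(net, seed = 5)$adjacency))
})

test_that("the normalised curve is defined where it should be", {
  n <- 20
  kc <- net_from(matrix(1, n, n) - diag(n))
  curve <- phi_norm_curve(kc, n_random = 5, base_seed = 1)
  expect_equal(nrow(curve), n - 1)
  # complete graph: rewiring is the identity, phi_norm = 1 where defined
  defined <- !is.na(curve$phi_norm)
  expect_true(any(defined))
  expect_equal(curve$phi_norm[defined], rep(1, sum(defined)))
  # beyond the maximum degree phi is undefined
  expect_true(all(is.na(curve$phi[curve$k >= n - 1])))
})

test_that("a planted clique yields phi_norm above 1 over a degree range", {
  # 9-clique on 40 nodes over a sparse background
  set.seed(123)
  A <- random_graph_adj(40, 0.12, seed = 321)
  A[1:9, 1:9] <- 1
  diag(A) <- 0
  net <- net_from(A)
  curve <- phi_norm_curve(net, n_random = 30, base_seed = 2)
  win <- curve$phi_norm[curve$k %in% 5:8]
  expect_true(all(is.finite(win)))
  expect_true(all(win > 1))
})

test_that("rich nodes are the top strength decile with stable ties", {
  cfg <- scaled_config(seed = 21)
  panel <- generate_cohort(cfg, qc_check = FALSE)
  pn <- panel_networks(panel)
  mn <- group_mean_network(pn$nets[pn$groups == "HC"])
  rich <- select_rich_nodes(mn, 0.10)
  expect_length(rich$rich, 9)
  expect_length(rich$non_rich, 81)
  expect_setequal(rich$rich, sprintf("R%03d", 1:9))  # the planted rich set

  # all strengths equal: first ceil(0.1 N) labels in order
  flat <- net_from(matrix(1, 20, 20) - diag(20))
  expect_equal(select_rich_nodes(flat, 0.10)$rich, c("R001", "R002"))

  # strictly decreasing strength by label index
  a <- (10:1) / 10
  W <- outer(a, a, `+`) / 9
  diag(W) <- 0
  labs <- sprintf("R%03d", 1:10)
  dimnames(W) <- list(labs, labs)
  mnet <- structure(list(weights = W, n_subjects = 1, region_labels = labs),
                    class = "mean_network")
  expect_true(all(diff(rowSums(W)) < 0))
  expect_equal(select_rich_nodes(mnet, 0.2)$rich, c("R001", "R002"))
})

test_that("connection decomposition partitions the total weight exactly", {
  # worked toy: rich = {1, 2}, edges 12, 13, 24, 34, 45
  toy <- net_from(adj_from_edges(5, list(c(1, 2), c(1, 3), c(2, 4), c(3, 4),
                                         c(4, 5))))
  d <- decompose_connections(toy, c("R001", "R002"))
  expect_equal(d$rich_sum, 1)
  expect_equal(d$feeder_sum, 2)
  expect_equal(d$local_sum, 2)
  expect_equal(d$rich_sum + d$feeder_sum + d$local_sum, d$total)

  # boundary cases
  expect_equal(decompose_connections(toy, character(0))$local_sum, 5)
  all_rich <- decompose_connections(toy, toy$region_labels)
  expect_equal(all_rich$rich_sum, 5)
  expect_equal(all_rich$feeder_sum + all_rich$local_sum, 0)
  expect_error(decompose_connections(toy, "R099"), "unknown rich label")

  # conservation on 100 seeded random networks, binary and weighted
  for (s in 1:100) {
    A <- random_graph_adj(12, 0.3, seed = 1000 + s)
    net <- net_from(A)
    rich <- net$region_labels[1:3]
    d <- decompose_connections(net, rich)
    expect_identical(d$rich_sum + d$feeder_sum + d$local_sum, d$total)
  }
})

test_that("isolating a rich node shifts the decomposition predictably", {
  A <- random_connected_adj(15, 0.35, seed = 31)
  net <- net_from(A)
  rich <- net$region_labels[1:4]
  pre <- decompose_connections(net, rich)
  post <- decompose_connections(post_attack_network(net, "R002"), rich)
  rich_idx <- 1:4
  lost_rich <- sum(A[2, rich_idx])
  lost_feeder <- sum(A[2, -rich_idx])
  expect_equal(pre$rich_sum - post$rich_sum, lost_rich)
  expect_equal(pre$feeder_sum - post$feeder_sum, lost_feeder)
  expect_equal(post$local_sum, pre$local_sum)
})

test_that("the normalised curve is deterministic given its base seed", {
  A <- random_graph_adj(15, 0.35, seed = 77)
  net <- net_from(A)
  c1 <- phi_norm_curve(net, n_random = 8, base_seed = 3)
  c2 <- phi_norm_curve(net, n_random = 8, base_seed = 3)
  expect_identical(c1, c2)
})
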