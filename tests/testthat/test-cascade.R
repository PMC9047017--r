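test_that("initial efficiencies are the edge indicators (or weights)", {
  A <- square_tail()
  g <- init_efficiency_graph(net_from(A))
  expect_equal(g$efficiency, ifelse(A > 0, 1, 0), ignore_attr = TRUE)
  expect_equal(g$efficiency, g$initial_efficiency)

  empty <- init_efficiency_graph(net_from(matrix(0, 3, 3)))
  expect_true(all(empty$efficiency == 0))

  # weighted extension: e = w, i.e. e = 1/d with d = 1/w
  W <- matrix(0, 2, 2); W[1, 2] <- W[2, 1] <- 0.25
  gw <- init_efficiency_graph(net_from(adj_from_edges(2, list(c(1, 2)))),
                              weights = W)
  expect_equal(gw$efficiency[1, 2], 0.25)
})

test_that("node loads count co-optimal shortest paths through a node", {
  path3 <- init_efficiency_graph(net_from(adj_from_edges(3, list(c(1, 2), c(2, 3)))))
  expect_equal(unname(node_loads(path3)), c(0, 2, 0))

  k5 <- init_efficiency_graph(net_from(matrix(1, 5, 5) - diag(5)))
  expect_equal(unname(node_loads(k5)), rep(0, 5))

  # star with 4 leaves: 4 * 3 ordered leaf pairs route through the center
  star <- init_efficiency_graph(net_from(
    adj_from_edges(5, lapply(2:5, function(j) c(1, j)))))
  expect_equal(unname(node_loads(star)), c(12, 0, 0, 0, 0))
})

test_that("node loads match exhaustive path enumeration on small graphs", {
  cases <- c(lapply(1:8, function(s) random_graph_adj(6, 0.45, seed = 200 + s)),
             lapply(1:8, function(s) random_graph_adj(7, 0.35, seed = 300 + s)),
             list(square_tail(), two_triangle_bridge()))
  for (A in cases) {
    g <- init_efficiency_graph(net_from(A))
    expect_equal(unname(node_loads(g)), oracle_loads(g$efficiency))
  }
  # and on a degraded (weighted) efficiency graph
  g <- init_efficiency_graph(net_from(two_triangle_bridge()))
  g$efficiency[1, 2] <- g$efficiency[2, 1] <- 0.5
  g$efficiency[4, 5] <- g$efficiency[5, 4] <- 0.25
  expect_equal(unname(node_loads(g)), oracle_loads(g$efficiency))
})

test_that("capacities scale initial loads by the tolerance", {
  expect_equal(capacities(c(0, 2, 0), a = 1), c(0, 2, 0))
  expect_equal(capacities(c(0, 2, 0), a = 1.5), c(0, 3, 0))
  expect_equal(capacities(c(0, 5), a = 1.2)[1], 0)  # zero load -> zero capacity
  expect_error(capacities(c(1, 2), a = 0.9), ">= 1")
})

test_that("attack zeroes exactly the target's incident efficiencies", {
  star <- net_from(adj_from_edges(5, lapply(2:5, function(j) c(1, j))))
  g <- attack(init_efficiency_graph(star), "R001")
  expect_true(all(g$efficiency == 0))
  g2 <- attack(init_efficiency_graph(star), "R003")
  expect_equal(sum(g2$efficiency) / 2, 3)
  expect_equal(g2$efficiency[1, 3], 0)
  expect_error(attack(init_efficiency_graph(star), "nope"), "unknown region")

  # hub of known degree: exactly that many symmetric pairs zeroed
  A <- random_connected_adj(20, 0.3, seed = 5)
  net <- net_from(A)
  hub <- which.max(rowSums(A))
  ga <- attack(init_efficiency_graph(net), net$region_labels[hub])
  expect_equal((sum(A) - sum(ga$efficiency)) / 2, max(rowSums(A)))
})

test_that("cascade matches the literal update rule step for step", {
  for (case in list(list(A = square_tail(), a = 1.05),
                    list(A = two_triangle_bridge(), a = 1.05),
                    list(A = two_triangle_bridge(), a = 1.0))) {
    A <- case$A
    g0 <- init_efficiency_graph(net_from(A))
    L0 <- oracle_loads(g0$efficiency)
    target_idx <- which.max(L0)
    target <- g0$region_labels[target_idx]
    C <- case$a * L0

    trace <- run_cascade(net_from(A), target, a = case$a, max_iter = 10)

    # oracle simulation of >= 3 iterations
    E0 <- g0$efficiency
    mask <- matrix(FALSE, nrow(A), ncol(A))
    mask[target_idx, E0[target_idx, ] > 0] <- TRUE
    mask[E0[, target_idx] > 0, target_idx] <- TRUE
    E <- E0; E[target_idx, ] <- 0; E[, target_idx] <- 0
    g <- g0; g$efficiency <- E
    for (step in 1:3) {
      E <- oracle_cascade_step(E0, E, C, mask)
      st <- trace$states[[min(step + 1, length(trace$states))]]
      g$efficiency <- E
      expect_equal(st$loads, node_loads(g), tolerance = 1e-12)
    }
  }
})

test_that("a forced reroute at a = 1 degrades a non-attacked edge", {
  A <- two_triangle_bridge()
  net <- net_from(A)
  g0 <- init_efficiency_graph(net)
  L0 <- node_loads(g0)
  target <- net$region_labels[which.max(L0)]
  trace <- run_cascade(net, target, a = 1.0, max_iter = 20)
  Efin <- trace$final_graph$efficiency
  degraded <- A > 0 & !trace$final_graph$attacked & Efin < 1
  expect_true(any(degraded))
})

test_that("efficiency never exceeds its initial value during a cascade", {
  for (s in 1:5) {
    A <- random_connected_adj(12, 0.25, seed = 40 + s)
    net <- net_from(A)
    L0 <- node_loads(init_efficiency_graph(net))
    target <- net$region_labels[which.max(L0)]
    trace <- run_cascade(net, target, a = 1.01, max_iter = 15)
    expect_true(all(trace$final_graph$efficiency <= ifelse(A > 0, 1, 0) + 1e-12))
    effs <- vapply(trace$states, `[[`, 0, "global_efficiency")
    pre <- efficiency_graph_global_efficiency(init_efficiency_graph(net))
    expect_true(all(effs <= pre + 1e-12))
  }
})

test_that("huge capacity tolerance reduces the cascade to pure isolation", {
  A <- random_connected_adj(15, 0.3, seed = 99)
  net <- net_from(A)
  target <- "R004"
  trace <- run_cascade(net, target, a = 1e12, max_iter = 10)
  expect_equal(trace$terminated_reason, "converged")
  expect_lte(length(trace$states), 3)
  iso <- post_attack_network(net, target)
  expect_equal(trace$final_graph$efficiency, iso$adjacency * 1,
               ignore_attr = TRUE)
})

test_that("attacking an isolated node changes nothing", {
  A <- adj_from_edges(4, list(c(1, 2), c(2, 3)))  # node 4 isolated
  net <- net_from(A)
  trace <- run_cascade(net, "R004", a = 1.0, max_iter = 5)
  expect_equal(trace$final_graph$efficiency, ifelse(A > 0, 1, 0),
               ignore_attr = TRUE)
  expect_equal(trace$terminated_reason, "converged")
})

test_that("cascades are deterministic", {
  A <- two_triangle_bridge()
  t1 <- run_cascade(net_from(A), "R001", a = 1.02)
  t2 <- run_cascade(net_from(A), "R001", a = 1.02)
  expect_identical(t1, t2)
})

test_that("isolation fault matrix removes exactly the hub's edges", {
  A <- adj_from_edges(6, list(c(1, 2), c(1, 3), c(1, 4), c(4, 5), c(5, 6)))
  net <- net_from(A)
  post <- post_attack_network(net, "R001")
  expect_equal(sum(post$adjacency[1, ]), 0)
  expect_equal(sum(A) / 2 - sum(post$adjacency) / 2, 3)  # hub degree 3
  others <- 2:6
  expect_equal(post$adjacency[others, others], A[others, others],
               ignore_attr = TRUE)
  expect_error(post_attack_network(net, "zzz"), "unknown region")
})
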