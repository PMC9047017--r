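#' @title CLM load-capacity cascade on an efficiency graph
#'
#' @description
#' The Crucitti-Latora-Marchiori (CLM) model represents each edge by a
#' transmission efficiency `e_ij`, the reciprocal of the link length. A node's
#' load is the number of shortest paths (over ordered node pairs, counting
#' all co-optimal paths) that pass through it; its fixed capacity is a
#' tolerance multiple `a >= 1` of its initial, pre-attack load. An attack
#' does not delete the hub: it removes the efficiencies of the hub's edges,
#' which reroutes traffic, may overload other nodes, and degrades their
#' incident efficiencies in turn -- a cascade of successive failures.
#'
#' @name clm_cascade
NULL

efficiency_graph <- function(efficiency, initial_efficiency, attacked,
                             region_labels) {
  structure(list(efficiency = efficiency,
                 initial_efficiency = initial_efficiency,
                 attacked = attacked, region_labels = region_labels),
            class = "efficiency_graph")
}

#' Initial efficiency graph of a binary network
#'
#' Every existing edge has unit length and therefore efficiency 1; absent
#' edges have efficiency 0. A `weights` matrix may be supplied for the
#' weighted extension, in which case an edge of weight `w` has efficiency
#' `w` (length `1/w`).
#'
#' @param net a `binary_network`.
#' @param weights optional symmetric non-negative matrix of edge weights;
#'   entries on non-edges are ignored.
#' @return an `efficiency_graph` with the t = 0 matrix frozen in
#'   `initial_efficiency`.
#' @export
init_efficiency_graph <- function(net, weights = NULL) {
  stopifnot(inherits(net, "binary_network"))
  E <- net$adjacency * 1
  if (!is.null(weights)) {
    check_square_symmetric(weights, "weights")
    if (any(weights < 0)) stop("edge weights must be non-negative", call. = FALSE)
    E <- net$adjacency * weights
  }
  diag(E) <- 0
  efficiency_graph(E, E, matrix(FALSE, nrow(E), ncol(E)), net$region_labels)
}

# All-pairs shortest distances and co-optimal path counts under lengths
# d_ij = 1/e_ij (Inf where e = 0). Dijkstra per source; a tie in path length
# is declared at relative tolerance `tol`.
shortest_path_counts <- function(E, tol = 1e-9) {
  n <- nrow(E)
  len <- ifelse(E > 0, 1 / E, Inf)
  diag(len) <- Inf
  D <- matrix(Inf, n, n)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    sigma <- rep(0, n); sigma[s] <- 1
    done <- rep(FALSE, n)
    repeat {
      u <- which.min(ifelse(done, Inf, dist))
      if (!is.finite(dist[u])) break
      done[u] <- TRUE
      nb <- which(is.finite(len[u, ]) & !done)
      if (length(nb)) {
        alt <- dist[u] + len[u, nb]
        for (k in seq_along(nb)) {
          v <- nb[k]
          eps <- tol * max(1, abs(alt[k]))
          if (alt[k] < dist[v] - eps) {
            dist[v] <- alt[k]; sigma[v] <- sigma[u]
          } else if (alt[k] <= dist[v] + eps) {
            sigma[v] <- sigma[v] + sigma[u]
          }
        }
      }
      if (all(done | !is.finite(dist))) break
    }
    D[s, ] <- dist
    S[s, ] <- sigma
  }
  diag(S) <- 0
  list(dist = D, sigma = S)
}

#' Node loads of an efficiency graph
#'
#' The load of node `i` is the number of shortest paths between ordered
#' pairs `(s, t)`, `s != t != i`, that pass through `i` as an intermediate
#' node, counting every co-optimal shortest path (an unnormalised
#' betweenness count). Link lengths are `1/e_ij`; pairs with no usable path
#' contribute nothing.
#'
#' @param g an `efficiency_graph`.
#' @param tol relative tolerance for declaring two path lengths equal.
#' @return a named numeric vector of loads.
#' @export
node_loads <- function(g, tol = 1e-9) {
  stopifnot(inherits(g, "efficiency_graph"))
  sp <- shortest_path_counts(g$efficiency, tol)
  D <- sp$dist; S <- sp$sigma
  n <- nrow(D)
  L <- numeric(n)
  for (i in seq_len(n)) {
    via <- outer(D[, i], D[i, ], `+`)
    ok <- is.finite(D) & abs(via - D) <= tol * pmax(1, abs(D))
    ok[i, ] <- FALSE; ok[, i] <- FALSE; diag(ok) <- FALSE
    cnt <- outer(S[, i], S[i, ])
    L[i] <- sum(cnt[ok])
  }
  names(L) <- g$region_labels
  L
}

#' Node capacities from initial loads
#'
#' `C_i = a * L_i(0)` with tolerance parameter `a >= 1`. Capacities are
#' fixed for the whole cascade; a node with zero initial load has zero
#' capacity and overloads under any positive load.
#'
#' @param initial_loads loads of the intact network.
#' @param a capacity tolerance multiplier (`>= 1`).
#' @return numeric vector of capacities.
#' @export
capacities <- function(initial_loads, a = 1.2) {
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || a < 1)
    stop("capacity tolerance 'a' must be a single number >= 1", call. = FALSE)
  a * initial_loads
}

#' Attack a region: zero the efficiencies of its edges
#'
#' All efficiencies incident to `target` are set to 0 and marked as
#' permanently removed: the cascade's restoration branch never revives them,
#' so the attacked hub stays disconnected.
#'
#' @param g an `efficiency_graph`.
#' @param target region label.
#' @return the attacked `efficiency_graph`.
#' @export
attack <- function(g, target) {
  stopifnot(inherits(g, "efficiency_graph"))
  i <- match_labels(g$region_labels, target)
  was_edge <- g$initial_efficiency[i, ] > 0
  g$efficiency[i, ] <- 0
  g$efficiency[, i] <- 0
  g$attacked[i, was_edge] <- TRUE
  g$attacked[was_edge, i] <- TRUE
  g
}

new_cascade_state <- function(t, graph, loads, capacities) {
  structure(list(t = t, graph = graph, loads = loads,
                 capacities = capacities,
                 overloaded = graph$region_labels[loads > capacities]),
            class = "cascade_state")
}

#' One step of the CLM efficiency update
#'
#' For every node `i` with `L_i(t) > C_i`, each incident edge is degraded to
#' `e_ij(0) * C_i / L_i(t)`; edges of nodes at or below capacity return to
#' their initial efficiency. When both endpoints are overloaded the smaller
#' of the two prescribed values is used. Edges removed by the attack stay at
#' zero. Loads are then recomputed on the updated graph.
#'
#' @param state a `cascade_state`.
#' @return the next `cascade_state`.
#' @export
cascade_step <- function(state) {
  stopifnot(inherits(state, "cascade_state"))
  g <- state$graph
  L <- state$loads; C <- state$capacities
  f <- ifelse(L > C, C / pmax(L, .Machine$double.xmin), 1)
  n <- length(f)
  F <- pmin(matrix(f, n, n), matrix(f, n, n, byrow = TRUE))
  Enew <- g$initial_efficiency * F
  Enew[g$attacked] <- 0
  g$efficiency <- Enew
  new_cascade_state(state$t + 1L, g, node_loads(g), C)
}

#' Run the CLM cascade triggered by a hub attack
#'
#' Initialises efficiencies from the binary network, computes initial loads
#' and capacities `C = a * L(0)`, removes the target's edges, then iterates
#' [cascade_step()] until no node is overloaded and the efficiency matrix is
#' stationary (max-norm change below `conv_tol`), or `max_iter` is reached.
#'
#' @param net a `binary_network`.
#' @param target region label to attack.
#' @param a capacity tolerance (default 1.2).
#' @param max_iter iteration cap (default 100).
#' @param conv_tol stationarity tolerance on the efficiency matrix.
#' @return an object of class `cascade_trace`: list with `states` (each a
#'   summary holding `t`, `loads`, `overloaded`, `global_efficiency`),
#'   `final_graph`, `initial_loads`, `capacities`, and
#'   `terminated_reason` (`"converged"` or `"max_iter"`).
#' @export
run_cascade <- function(net, target, a = 1.2, max_iter = 100L,
                        conv_tol = 1e-12) {
  g0 <- init_efficiency_graph(net)
  L0 <- node_loads(g0)
  C <- capacities(L0, a)
  g <- attack(g0, target)
  state <- new_cascade_state(0L, g, node_loads(g), C)
  summarise <- function(st) list(
    t = st$t, loads = st$loads, overloaded = st$overloaded,
    global_efficiency = efficiency_graph_global_efficiency(st$graph))
  states <- list(summarise(state))
  reason <- "max_iter"
  for (it in seq_len(max_iter)) {
    nxt <- cascade_step(state)
    states[[length(states) + 1L]] <- summarise(nxt)
    delta <- max(abs(nxt$graph$efficiency - state$graph$efficiency))
    state <- nxt
    if (length(state$overloaded) == 0 && delta < conv_tol) {
      reason <- "converged"
      break
    }
  }
  structure(list(states = states, final_graph = state$graph,
                 initial_loads = L0, capacities = C,
                 terminated_reason = reason),
            class = "cascade_trace")
}

#' Global efficiency of an efficiency graph
#'
#' Mean of the reciprocal shortest path lengths over ordered node pairs,
#' with link lengths `1/e_ij`; unreachable pairs contribute 0.
#'
#' @param g an `efficiency_graph`.
#' @return a number in `[0, 1]` for graphs whose efficiencies are at most 1.
#' @export
efficiency_graph_global_efficiency <- function(g) {
  D <- shortest_path_counts(g$efficiency)$dist
  n <- nrow(D)
  inv <- ifelse(is.finite(D), 1 / D, 0)
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Post-attack fault network
#'
#' `mode = "isolation"` (the default used by all downstream comparisons)
#' removes every edge incident to the attacked region and leaves all other
#' edges untouched. `mode = "cascade_final"` additionally removes edges
#' whose efficiency is driven to zero by the cascade dynamics.
#'
#' @param net a `binary_network`.
#' @param target region label to attack.
#' @param mode `"isolation"` or `"cascade_final"`.
#' @param a,max_iter cascade parameters (used by `"cascade_final"` only).
#' @return a `binary_network`.
#' @export
post_attack_network <- function(net, target,
                                mode = c("isolation", "cascade_final"),
                                a = 1.2, max_iter = 100L) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "binary_network"))
  i <- match_labels(net$region_labels, target)
  A <- net$adjacency
  A[i, ] <- 0
  A[, i] <- 0
  if (mode == "cascade_final") {
    trace <- run_cascade(net, target, a = a, max_iter = max_iter)
    A[trace$final_graph$efficiency <= 1e-12] <- 0
  }
  binary_network(A, net$region_labels, threshold_used = net$threshold_used)
}
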