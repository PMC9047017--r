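# Brute-force oracles, independent of the package's implementations.

net_from <- function(A, labels = NULL) {
  A <- as.matrix(A)
  binary_network(A, labels)
}

# adjacency from an edge list on n nodes
adj_from_edges <- function(n, edges) {
  A <- matrix(0, n, n)
  for (e in edges) { A[e[1], e[2]] <- 1; A[e[2], e[1]] <- 1 }
  A
}

random_graph_adj <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.numeric(runif(length(up)) < p)
  A + t(A)
}

random_connected_adj <- function(n, p, seed) {
  for (k in 0:200) {
    A <- random_graph_adj(n, p, seed + 1000 * k)
    D <- oracle_distances(A)
    if (all(is.finite(D))) return(A)
  }
  stop("no connected graph found")
}

# Floyd-Warshall hop distances
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_global_efficiency <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j && is.finite(D[i, j]))
    s <- s + 1 / D[i, j]
  s / (n * (n - 1))
}

# triangle-enumeration clustering
oracle_clustering <- function(A) {
  n <- nrow(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) { ci[i] <- 0; next }
    e <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) if (a < b)
      e <- e + A[nb[a], nb[b]]
    ci[i] <- 2 * e / (k * (k - 1))
  }
  list(per_node = ci, mean = mean(ci))
}

# subgraph edge-count rich-club coefficient
oracle_phi <- function(A, k) {
  keep <- which(rowSums(A) > k)
  if (length(keep) < 2) return(NA_real_)
  e <- sum(A[keep, keep]) / 2
  2 * e / (length(keep) * (length(keep) - 1))
}

# Exhaustive simple-path enumeration: for every ordered pair count the
# shortest paths (by total length, lengths = 1/efficiency) through each
# intermediate node. Feasible for n <= 7.
oracle_loads <- function(E, tol = 1e-9) {
  n <- nrow(E)
  len <- ifelse(E > 0, 1 / E, Inf)
  loads <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    paths <- list()
    best <- Inf
    walk <- function(v, visited, d) {
      if (d > best + tol * max(1, best)) return()
      if (v == t) {
        if (d < best - tol * max(1, abs(d))) { best <<- d; paths <<- list() }
        if (d <= best + tol * max(1, abs(d))) paths[[length(paths) + 1]] <<- visited
        return()
      }
      for (w in seq_len(n)) {
        if (is.finite(len[v, w]) && !(w %in% visited))
          walk(w, c(visited, w), d + len[v, w])
      }
    }
    walk(s, s, 0)
    # drop paths that became non-optimal after best tightened
    for (pp in paths) {
      d <- sum(vapply(seq_len(length(pp) - 1),
                      function(i) len[pp[i], pp[i + 1]], 0))
      if (d <= best + tol * max(1, best)) {
        mid <- pp[-c(1, length(pp))]
        loads[mid] <- loads[mid] + 1
      }
    }
  }
  loads
}

# dense eigendecomposition eigenvector-centrality oracle
oracle_ec <- function(A) {
  ev <- eigen(A, symmetric = TRUE)
  v <- ev$vectors[, which.max(ev$values)]
  if (sum(v) < 0) v <- -v
  v / sqrt(sum(v^2))
}

# small cohort config used by simulation-heavy tests
scaled_config <- function(seed, ...) {
  cohort_config(n_subjects_per_group = 10L, n_timepoints = 100L,
                seed = seed, ...)
}

# shared pipeline step: per-subject binary networks + group labels
panel_networks <- function(panel, threshold = 0.3) {
  nets <- lapply(panel$subjects, function(s)
    binarize(pearson_matrix(s$series), threshold = threshold))
  names(nets) <- vapply(panel$subjects, `[[`, "", "subject_id")
  list(nets = nets, groups = vapply(panel$subjects, `[[`, "", "group"))
}

# independent single-step CLM oracle: exhaustive-path loads + the literal
# efficiency update, used to hand-simulate short cascades
oracle_cascade_step <- function(E0, E, C, attacked_mask) {
  L <- oracle_loads(E)
  n <- nrow(E)
  Enew <- E0
  for (i in seq_len(n)) if (L[i] > C[i]) {
    for (j in seq_len(n)) if (E0[i, j] > 0)
      Enew[i, j] <- Enew[j, i] <- min(Enew[i, j], E0[i, j] * C[i] / L[i])
  }
  Enew[attacked_mask] <- 0
  Enew
}

square_tail <- function() {
  adj_from_edges(5, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(4, 5)))
}

two_triangle_bridge <- function() {
  adj_from_edges(6, list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6),
                         c(1, 4), c(2, 5)))
}

# one full pipeline pass on a generated panel: decomposition table +
# contrast battery, shared by replication-style tests
replicate_battery <- function(cfg) {
  panel <- generate_cohort(cfg, qc_check = FALSE)
  pn <- panel_networks(panel)
  hc_mean <- group_mean_network(pn$nets[pn$groups == "HC"])
  cv <- eigenvector_centrality(mean_binary_network(hc_mean))
  target <- select_attack_target(cv)
  rich <- select_rich_nodes(hc_mean)
  decomp <- connection_table(pn$nets, pn$groups, rich, target)
  list(panel = panel, target = target, rich = rich, decomp = decomp,
       battery = run_contrast_battery(decomp))
}
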