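#' Rich-club coefficient at one degree threshold
#'
#' Restricts the network to nodes whose degree in the full network is
#' strictly greater than `k` and returns the edge density of that subgraph,
#' `phi(k) = 2 E_{>k} / (N_{>k} (N_{>k} - 1))`. Undefined (`NA`) when fewer
#' than two nodes survive.
#'
#' @param net a `binary_network`.
#' @param k degree threshold (`>= 1`).
#' @return `phi(k)` in `[0, 1]`, or `NA` where undefined.
#' @export
phi <- function(net, k) {
  stopifnot(inherits(net, "binary_network"))
  stopifnot_scalar(k, "k", 1)
  A <- net$adjacency
  keep <- rowSums(A) > k
  nk <- sum(keep)
  if (nk < 2) return(NA_real_)
  2 * (sum(A[keep, keep]) / 2) / (nk * (nk - 1))
}

#' Degree-preserving randomization by double-edge swaps
#'
#' Maslov-Sneppen rewiring: repeatedly pick two edges `(a, b)` and `(c, d)`
#' and replace them with `(a, d)` and `(c, b)` whenever that creates neither
#' a self-loop nor a duplicate edge. Every node keeps its exact degree. The
#' procedure is deterministic given `seed` and makes
#' `swaps_per_edge * n_edges` attempts.
#'
#' @param net a `binary_network` with at least 2 edges.
#' @param seed integer seed.
#' @param swaps_per_edge attempted swaps per edge (default 10).
#' @return a rewired `binary_network`.
#' @export
randomize_network <- function(net, seed, swaps_per_edge = 10L) {
  stopifnot(inherits(net, "binary_network"))
  A <- net$adjacency
  eidx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  ne <- nrow(eidx)
  if (ne < 2) stop("need at least 2 edges to rewire", call. = FALSE)
  with_seed(seed, {
    attempts <- swaps_per_edge * ne
    for (s in seq_len(attempts)) {
      pick <- sample.int(ne, 2)
      a <- eidx[pick[1], 1]; b <- eidx[pick[1], 2]
      c <- eidx[pick[2], 1]; d <- eidx[pick[2], 2]
      # randomly orient the second edge so both pairings are reachable
      if (stats::runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
      if (a == d || c == b) next
      if (A[a, d] == 1 || A[c, b] == 1) next
      A[a, b] <- A[b, a] <- 0
      A[c, d] <- A[d, c] <- 0
      A[a, d] <- A[d, a] <- 1
      A[c, b] <- A[b, c] <- 1
      eidx[pick[1], ] <- c(min(a, d), max(a, d))
      eidx[pick[2], ] <- c(min(c, b), max(c, b))
    }
    binary_network(A, net$region_labels, threshold_used = net$threshold_used)
  })
}

#' Normalised rich-club curve
#'
#' Evaluates `phi(k)` for `k = 1 .. N-1`, the mean rich-club coefficient of
#' an ensemble of `n_random` degree-preserving rewirings (averaging only
#' ensemble members where `phi` is defined at that `k`), and their ratio
#' `phi_norm(k)`. Replicate seeds are derived as `base_seed + replicate`, so
#' the whole curve is deterministic given `base_seed`.
#'
#' @param net a `binary_network`.
#' @param n_random size of the null ensemble (default 100).
#' @param base_seed integer seed for the ensemble.
#' @param swaps_per_edge rewiring intensity per replicate.
#' @return an object of class `rich_club_curve`: data.frame with columns
#'   `k`, `phi`, `phi_random_mean`, `phi_norm`; attribute `n_random`.
#' @export
phi_norm_curve <- function(net, n_random = 100L, base_seed = 1L,
                           swaps_per_edge = 10L) {
  stopifnot(inherits(net, "binary_network"))
  n <- nrow(net$adjacency)
  ks <- seq_len(n - 1)
  phi_obs <- vapply(ks, function(k) phi(net, k), numeric(1))
  null_phi <- matrix(NA_real_, n_random, length(ks))
  for (r in seq_len(n_random)) {
    rn <- randomize_network(net, seed = base_seed + r,
                            swaps_per_edge = swaps_per_edge)
    null_phi[r, ] <- vapply(ks, function(k) phi(rn, k), numeric(1))
  }
  phi_rand <- colMeans(null_phi, na.rm = TRUE)
  phi_rand[!apply(is.finite(null_phi), 2, any)] <- NA_real_
  phi_norm <- ifelse(is.finite(phi_obs) & is.finite(phi_rand) & phi_rand > 0,
                     phi_obs / phi_rand, NA_real_)
  out <- data.frame(k = ks, phi = phi_obs, phi_random_mean = phi_rand,
                    phi_norm = phi_norm)
  attr(out, "n_random") <- n_random
  class(out) <- c("rich_club_curve", "data.frame")
  out
}

#' Test whether a network shows rich-club organisation
#'
#' One-sample t-test (one-sided, greater) of the defined normalised
#' rich-club coefficients against 1: a significantly positive excess over
#' the degree-preserving null across the degree range is the operational
#' criterion for "the network has a rich club".
#'
#' @param curve a `rich_club_curve`.
#' @return list with `t`, `p`, and `n_defined` (number of usable k values).
#' @export
phi_norm_greater_test <- function(curve) {
  stopifnot(inherits(curve, "rich_club_curve"))
  v <- curve$phi_norm[is.finite(curve$phi_norm)]
  if (length(v) < 2 || stats::var(v) == 0)
    return(list(t = NA_real_, p = NA_real_, n_defined = length(v)))
  res <- one_sample_t(v, mu0 = 1, alternative = "greater")
  list(t = res$t, p = res$p, n_defined = length(v))
}

#' Select rich nodes from a group-mean network
#'
#' Nodes are ranked by strength (weighted row sum of the mean network; plain
#' degree for a binary network) and the top `ceil(fraction * N)` are the
#' rich nodes; ties are broken by label order. By convention the selection
#' is made once, on the healthy-control mean network, and the same set is
#' applied to both groups.
#'
#' @param mean_net a `mean_network` or `binary_network`.
#' @param fraction fraction of nodes selected (default 0.10).
#' @return an object of class `rich_node_set`: list with `rich` (ordered
#'   labels), `non_rich`, and `source`.
#' @export
select_rich_nodes <- function(mean_net, fraction = 0.10) {
  W <- if (inherits(mean_net, "mean_network")) mean_net$weights
       else if (inherits(mean_net, "binary_network")) mean_net$adjacency
       else stop("'mean_net' must be a mean_network or binary_network",
                 call. = FALSE)
  labels <- rownames(W)
  stopifnot_scalar(fraction, "fraction", 1e-12, 1)
  strength <- rowSums(W)
  k <- ceiling(fraction * length(strength))
  ord <- order(-strength, seq_along(strength))
  structure(list(rich = labels[ord[seq_len(k)]],
                 non_rich = labels[sort(ord[-seq_len(k)])],
                 source = class(mean_net)[1]),
            class = "rich_node_set")
}

#' Rich / feeder / local connection decomposition
#'
#' Splits the total edge weight of a network into connections between rich
#' nodes (rich), between a rich and a non-rich node (feeder), and between
#' non-rich nodes (local). The three sums add up exactly to the network's
#' total edge weight.
#'
#' @param net a `binary_network` or `mean_network`.
#' @param rich a `rich_node_set`, or a character vector of rich labels.
#' @return list with `rich_sum`, `feeder_sum`, `local_sum`, and `total`.
#' @export
decompose_connections <- function(net, rich) {
  W <- if (inherits(net, "mean_network")) net$weights
       else if (inherits(net, "binary_network")) net$adjacency
       else stop("'net' must be a mean_network or binary_network", call. = FALSE)
  labels <- rownames(W)
  rich_labels <- if (inherits(rich, "rich_node_set")) rich$rich else rich
  idx <- match_labels(labels, rich_labels, "rich label")
  is_rich <- seq_along(labels) %in% idx
  up <- upper.tri(W)
  rich_mask <- outer(is_rich, is_rich, `&`)
  local_mask <- outer(!is_rich, !is_rich, `&`)
  rich_sum <- sum(W[up & rich_mask])
  local_sum <- sum(W[up & local_mask])
  feeder_sum <- sum(W[up & !rich_mask & !local_mask])
  list(rich_sum = rich_sum, feeder_sum = feeder_sum, local_sum = local_sum,
       total = sum(W[up]))
}
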