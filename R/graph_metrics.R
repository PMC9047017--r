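#' Clustering coefficient, per node and network mean
#'
#' For a node of degree `k_i >= 2`, `c_i = 2 e_i / (k_i (k_i - 1))` where
#' `e_i` counts edges among its neighbours; nodes of degree below 2 are
#' assigned `c_i = 0` and kept in the average, so the network mean stays
#' defined on attacked networks that contain an isolated hub.
#'
#' @param net a `binary_network`.
#' @return list with `per_node` (named vector in `[0, 1]`) and `mean`.
#' @export
clustering_coefficient <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  A <- net$adjacency
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2  # edges among neighbours of each node
  ci <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  names(ci) <- net$region_labels
  list(per_node = ci, mean = mean(ci))
}

#' Global efficiency of a binary network
#'
#' Mean of the reciprocal shortest (hop-count) path lengths over all ordered
#' node pairs; pairs in different components contribute 0, so the measure
#' remains finite on disconnected networks.
#'
#' @param net a `binary_network`.
#' @return a number in `[0, 1]`.
#' @export
global_efficiency <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  n <- nrow(net$adjacency)
  if (n < 2) return(0)
  g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
  D <- igraph::distances(g)
  inv <- ifelse(is.finite(D), 1 / D, 0)
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Pre/post attack metric table for a cohort
#'
#' Convenience wrapper computing mean clustering and global efficiency for
#' each subject's network before and after the isolation attack on `target`.
#'
#' @param nets named list of `binary_network`s (names are subject ids).
#' @param target attacked region label.
#' @return data.frame with columns `subject_id`, `condition` (`pre`/`post`),
#'   `mean_clustering`, `global_efficiency`.
#' @export
metric_table <- function(nets, target) {
  rows <- lapply(names(nets), function(id) {
    pre <- nets[[id]]
    post <- post_attack_network(pre, target)
    data.frame(subject_id = id, condition = c("pre", "post"),
               mean_clustering = c(clustering_coefficient(pre)$mean,
                                   clustering_coefficient(post)$mean),
               global_efficiency = c(global_efficiency(pre),
                                     global_efficiency(post)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
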