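#' Pearson correlation matrix of a regional time-series matrix
#'
#' Computes the region-by-region Pearson correlation of a regions x time
#' matrix. Every region must have nonzero variance over time.
#'
#' @param series numeric matrix, regions in rows, timepoints in columns;
#'   rownames are used as region labels when present.
#' @return an object of class `correlation_matrix`: a list with `values`
#'   (symmetric, unit diagonal) and `region_labels`.
#' @export
pearson_matrix <- function(series) {
  if (!is.matrix(series) || !is.numeric(series))
    stop("'series' must be a numeric matrix (regions x time)", call. = FALSE)
  if (ncol(series) < 3)
    stop("at least 3 timepoints are required", call. = FALSE)
  if (anyNA(series)) stop("'series' contains missing values", call. = FALSE)
  labels <- rownames(series)
  if (is.null(labels)) labels <- default_region_labels(nrow(series))
  v <- apply(series, 1, stats::var)
  if (any(v == 0))
    stop(sprintf("zero-variance region(s): %s",
                 paste(labels[v == 0], collapse = ", ")), call. = FALSE)
  r <- stats::cor(t(series))
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- rep(list(labels), 2)
  structure(list(values = r, region_labels = labels),
            class = "correlation_matrix")
}

#' Fisher z-transform of a correlation matrix
#'
#' Applies `atanh` elementwise off the diagonal; the diagonal is set to 0.
#' Correlations are clipped to `|r| <= 1 - 1e-7` so the transform stays
#' finite.
#'
#' @param r a `correlation_matrix`.
#' @return a symmetric numeric matrix of z values with zero diagonal.
#' @export
fisher_z <- function(r) {
  stopifnot(inherits(r, "correlation_matrix"))
  v <- pmin(pmax(r$values, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(v)
  diag(z) <- 0
  z
}

#' Binarize a correlation matrix into a network
#'
#' An edge is placed between two regions when their raw correlation strictly
#' exceeds `threshold`; a correlation exactly equal to the threshold does not
#' form an edge, and negative correlations never do. The threshold is applied
#' to the correlation scale, not to Fisher z values.
#'
#' @param r a `correlation_matrix`.
#' @param threshold correlation threshold (default 0.3).
#' @return an object of class `binary_network`: a list with `adjacency`
#'   (symmetric 0/1, zero diagonal), `threshold_used`, and `region_labels`.
#' @export
binarize <- function(r, threshold = 0.3) {
  stopifnot(inherits(r, "correlation_matrix"))
  stopifnot_scalar(threshold, "threshold", -1, 1)
  A <- (r$values > threshold) * 1
  diag(A) <- 0
  A <- A * t(A)  # guard symmetry against asymmetric input rounding
  binary_network(A, r$region_labels, threshold_used = threshold)
}

#' Construct a binary network object from an adjacency matrix
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal.
#' @param region_labels optional character labels, one per node.
#' @param threshold_used threshold recorded for provenance (may be `NA`).
#' @return a `binary_network`.
#' @export
binary_network <- function(adjacency, region_labels = NULL,
                           threshold_used = NA_real_) {
  check_square_symmetric(adjacency, "adjacency", tol = 0)
  if (!all(adjacency %in% c(0, 1)))
    stop("'adjacency' must contain only 0/1 entries", call. = FALSE)
  if (any(diag(adjacency) != 0))
    stop("'adjacency' must have a zero diagonal", call. = FALSE)
  if (is.null(region_labels)) {
    region_labels <- rownames(adjacency)
    if (is.null(region_labels))
      region_labels <- default_region_labels(nrow(adjacency))
  }
  if (length(region_labels) != nrow(adjacency))
    stop("label/adjacency size mismatch", call. = FALSE)
  dimnames(adjacency) <- rep(list(region_labels), 2)
  structure(list(adjacency = adjacency, threshold_used = threshold_used,
                 region_labels = region_labels),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  e <- sum(x$adjacency) / 2
  cat(sprintf("binary_network: %d nodes, %d edges (threshold %s)\n",
              nrow(x$adjacency), e, format(x$threshold_used)))
  invisible(x)
}

#' Quality report for a binary brain network
#'
#' Checks the network-construction rules: density between 10 and 50%, mean
#' degree greater than `2 * log(N)`, and no isolated nodes. The report is
#' informational; nothing is modified.
#'
#' @param net a `binary_network`.
#' @return a list with `density`, `mean_degree`, `degree_bound`
#'   (`2 * log(N)`), `isolated` (labels), `connected` flag, per-rule
#'   pass/fail flags, an overall `pass`, and a human-readable `failures`
#'   string.
#' @export
network_checks <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  A <- net$adjacency
  n <- nrow(A)
  deg <- rowSums(A)
  e <- sum(deg) / 2
  density <- 2 * e / (n * (n - 1))
  mean_degree <- 2 * e / n
  bound <- 2 * log(n)
  isolated <- net$region_labels[deg == 0]
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  connected <- igraph::is_connected(g)
  ok_density <- density >= 0.10 && density <= 0.50
  ok_degree <- mean_degree > bound
  ok_isolated <- length(isolated) == 0
  fails <- c(if (!ok_density) sprintf("density %.3f outside [0.10, 0.50]", density),
             if (!ok_degree) sprintf("mean degree %.2f <= 2 ln N = %.2f",
                                     mean_degree, bound),
             if (!ok_isolated) sprintf("%d isolated node(s)", length(isolated)))
  list(density = density, mean_degree = mean_degree, degree_bound = bound,
       isolated = isolated, connected = connected,
       ok_density = ok_density, ok_degree = ok_degree,
       ok_isolated = ok_isolated,
       pass = ok_density && ok_degree && ok_isolated,
       failures = if (length(fails)) paste(fails, collapse = "; ") else "")
}

#' Group-mean network from per-subject binary networks
#'
#' Elementwise mean of the subjects' adjacency matrices; the resulting
#' weights are edge prevalences in `[0, 1]`.
#'
#' @param nets list of `binary_network` objects over identical region labels.
#' @return an object of class `mean_network`: list with `weights`,
#'   `n_subjects`, `region_labels`.
#' @export
group_mean_network <- function(nets) {
  if (!length(nets)) stop("need at least one network", call. = FALSE)
  stopifnot(all(vapply(nets, inherits, logical(1), "binary_network")))
  labels <- nets[[1]]$region_labels
  for (nt in nets)
    if (!identical(nt$region_labels, labels))
      stop("region labels differ between networks", call. = FALSE)
  W <- Reduce(`+`, lapply(nets, `[[`, "adjacency")) / length(nets)
  dimnames(W) <- rep(list(labels), 2)
  structure(list(weights = W, n_subjects = length(nets),
                 region_labels = labels),
            class = "mean_network")
}

#' Binarize a mean network at a prevalence threshold
#'
#' Keeps an edge where the subject-level prevalence strictly exceeds
#' `threshold`. Used to obtain the group-level binary network on which
#' eigenvector centrality and the construction-rule checks operate.
#'
#' @param mean_net a `mean_network`.
#' @param threshold prevalence threshold (default 0.3).
#' @return a `binary_network`.
#' @export
mean_binary_network <- function(mean_net, threshold = 0.3) {
  stopifnot(inherits(mean_net, "mean_network"))
  A <- (mean_net$weights > threshold) * 1
  diag(A) <- 0
  binary_network(A, mean_net$region_labels, threshold_used = threshold)
}
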