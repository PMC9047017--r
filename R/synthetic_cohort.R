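#' Configuration for the synthetic two-group cohort
#'
#' Describes a two-group (healthy control vs patient) cohort of regional
#' time series with a planted rich club and a planted patient deficit in
#' rich-club connectivity. The defaults emulate a resting-state study with
#' 37 subjects per group, 90 regions, and 190 retained timepoints.
#'
#' The ground-truth correlation structure is built from three planted
#' ingredients: a rich block (`rich_set_size` mutually correlated regions at
#' `base_correlation`), a set of background communities covering the non-rich
#' regions (within-community correlation `background_correlation`), and feeder
#' couplings attaching each rich region to one community at
#' `feeder_correlation`. The first rich region is the designated hub: its
#' community is enlarged by `hub_clique_bonus` members so that it carries the
#' highest degree and eigenvector centrality in the control group's mean
#' network.
#'
#' In the patient (JME) arm, rich-block correlations are reduced by
#' `patient_rich_deficit + duration_effect * duration`. With the default
#' `deficit_scope = "hub"` the reduction applies only to rich-block entries
#' incident to the designated hub, so that isolating the hub leaves the two
#' groups with identical residual structure; `deficit_scope = "block"` applies
#' the reduction to the whole rich block.
#'
#' @param n_regions number of regions (network nodes).
#' @param n_subjects_per_group subjects in each of the two groups.
#' @param n_timepoints retained timepoints per subject.
#' @param rich_set_size number of planted rich regions (the first
#'   `rich_set_size` regions).
#' @param base_correlation within-rich-block correlation, in `[0, 1)`.
#' @param background_correlation within-community correlation for non-rich
#'   regions, in `[0, 1)`.
#' @param feeder_correlation correlation between a rich region and the members
#'   of its attached community, in `[0, 1)`.
#' @param patient_rich_deficit constant reduction of the affected rich-block
#'   correlations in patients, in `[0, 1]`.
#' @param duration_effect additional reduction per month of disease duration.
#' @param duration_range_months length-2 interval from which patient disease
#'   durations are drawn uniformly.
#' @param noise_sd standard deviation of the iid observation noise added on
#'   top of the latent signal. The signal covariance is rescaled so that the
#'   observed series still has the designated correlation matrix.
#' @param deficit_scope `"hub"` (default) or `"block"`; see Details.
#' @param hub_clique_bonus extra members moved into the hub's community.
#' @param seed integer RNG seed for [generate_cohort()].
#' @return an object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()], [build_ground_truth_covariance()]
#' @export
cohort_config <- function(n_regions = 90L,
                          n_subjects_per_group = 37L,
                          n_timepoints = 190L,
                          rich_set_size = 9L,
                          base_correlation = 0.45,
                          background_correlation = 0.40,
                          feeder_correlation = 0.35,
                          patient_rich_deficit = 0.15,
                          duration_effect = 0.002,
                          duration_range_months = c(12, 84),
                          noise_sd = 0.25,
                          deficit_scope = c("hub", "block"),
                          hub_clique_bonus = 3L,
                          seed = 1L) {
  deficit_scope <- match.arg(deficit_scope)
  n_regions <- as.integer(stopifnot_scalar(n_regions, "n_regions", 2))
  n_subjects_per_group <- as.integer(
    stopifnot_scalar(n_subjects_per_group, "n_subjects_per_group", 1))
  n_timepoints <- as.integer(stopifnot_scalar(n_timepoints, "n_timepoints", 3))
  rich_set_size <- as.integer(stopifnot_scalar(rich_set_size, "rich_set_size",
                                               1, n_regions))
  stopifnot_scalar(base_correlation, "base_correlation", 0, 1)
  stopifnot_scalar(background_correlation, "background_correlation", 0, 1 - 1e-12)
  stopifnot_scalar(feeder_correlation, "feeder_correlation", 0, 1 - 1e-12)
  stopifnot_scalar(patient_rich_deficit, "patient_rich_deficit", 0, 1)
  stopifnot_scalar(duration_effect, "duration_effect", 0, 1)
  stopifnot_scalar(noise_sd, "noise_sd", 0)
  if (length(duration_range_months) != 2 || duration_range_months[1] < 0 ||
      diff(duration_range_months) < 0)
    stop("'duration_range_months' must be a non-negative, non-decreasing interval",
         call. = FALSE)
  cfg <- list(n_regions = n_regions,
              n_subjects_per_group = n_subjects_per_group,
              n_timepoints = n_timepoints,
              rich_set_size = rich_set_size,
              base_correlation = base_correlation,
              background_correlation = background_correlation,
              feeder_correlation = feeder_correlation,
              patient_rich_deficit = patient_rich_deficit,
              duration_effect = duration_effect,
              duration_range_months = as.numeric(duration_range_months),
              noise_sd = noise_sd,
              deficit_scope = deficit_scope,
              hub_clique_bonus = as.integer(hub_clique_bonus),
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

# Partition the non-rich regions into one community per rich region; the
# hub's community receives `hub_clique_bonus` extra members taken from the
# largest remaining communities.
planted_communities <- function(config) {
  n <- config$n_regions
  m <- config$rich_set_size
  nonrich <- if (m < n) (m + 1L):n else integer(0)
  if (length(nonrich) == 0L) return(rep(list(integer(0)), m))
  sizes <- rep(length(nonrich) %/% m, m)
  rem <- length(nonrich) - sum(sizes)
  if (rem > 0) sizes[m - seq_len(rem) + 1L] <- sizes[m - seq_len(rem) + 1L] + 1L
  bonus <- min(config$hub_clique_bonus, sum(pmax(sizes[-1] - 1L, 0L)))
  taken <- 0L
  while (taken < bonus) {
    k <- which.max(sizes[-1]) + 1L
    sizes[k] <- sizes[k] - 1L
    sizes[1] <- sizes[1] + 1L
    taken <- taken + 1L
  }
  split(nonrich, rep(seq_len(m), times = sizes))
}

#' Ground-truth correlation matrix for one subject
#'
#' Builds the designated correlation matrix for a subject of the given group.
#' Controls carry the full planted structure; patients carry a reduced
#' rich-block correlation, `base - patient_rich_deficit - duration_effect *
#' duration`, floored at zero, over the entries selected by
#' `config$deficit_scope`. If the entrywise construction is not positive
#' semidefinite it is repaired by eigenvalue clipping at zero followed by
#' rescaling to unit diagonal.
#'
#' @param config a [cohort_config()].
#' @param group `"HC"` or `"JME"`.
#' @param duration disease duration in months; forced to 0 for controls.
#' @return a symmetric positive semidefinite correlation matrix with unit
#'   diagonal and `region_labels` as dimnames.
#' @export
build_ground_truth_covariance <- function(config, group = c("HC", "JME"),
                                          duration = 0) {
  group <- match.arg(group)
  if (group == "HC") duration <- 0
  stopifnot_scalar(duration, "duration", 0)
  n <- config$n_regions
  m <- config$rich_set_size
  rich <- seq_len(m)
  C <- diag(n)
  C[rich, rich] <- config$base_correlation
  comm <- planted_communities(config)
  for (c in seq_len(m)) {
    idx <- comm[[c]]
    if (length(idx)) {
      C[idx, idx] <- config$background_correlation
      C[rich[c], idx] <- config$feeder_correlation
      C[idx, rich[c]] <- config$feeder_correlation
    }
  }
  if (group == "JME" && m >= 2) {
    red <- max(config$base_correlation - config$patient_rich_deficit -
                 config$duration_effect * duration, 0)
    if (config$deficit_scope == "hub") {
      C[1, rich[-1]] <- red
      C[rich[-1], 1] <- red
    } else {
      C[rich, rich] <- red
    }
  }
  diag(C) <- 1
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    lam <- pmax(ev$values, 0)
    S <- ev$vectors %*% (lam * t(ev$vectors))
    d <- diag(S)
    if (any(d <= 0))
      stop(sprintf(paste("covariance construction is not repairable:",
                         "base_correlation=%g, background_correlation=%g,",
                         "feeder_correlation=%g give a degenerate structure"),
                   config$base_correlation, config$background_correlation,
                   config$feeder_correlation), call. = FALSE)
    C <- S / sqrt(outer(d, d))
    C <- (C + t(C)) / 2
    diag(C) <- 1
  }
  dimnames(C) <- rep(list(default_region_labels(n)), 2)
  C
}

# Sample `tp` rows from N(0, sigma_signal) + iid noise so that the observed
# series has correlation matrix C exactly in expectation.
sample_subject_series <- function(C, tp, noise_sd) {
  n <- nrow(C)
  sig <- (1 + noise_sd^2) * C - diag(noise_sd^2, n)
  ev <- eigen(sig, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop(sprintf(paste("signal covariance is not positive semidefinite;",
                       "noise_sd=%g is too large for the planted correlations"),
                 noise_sd), call. = FALSE)
  lam <- pmax(ev$values, 0)
  Z <- matrix(stats::rnorm(tp * n), tp, n)
  X <- Z %*% (t(ev$vectors) * sqrt(lam))
  if (noise_sd > 0) X <- X + matrix(stats::rnorm(tp * n, 0, noise_sd), tp, n)
  t(X)  # regions x time
}

#' Generate a synthetic two-group cohort of regional time series
#'
#' Draws one region-by-time matrix per subject: controls share the planted
#' ground-truth correlation structure; each patient receives a disease
#' duration (uniform over `duration_range_months`) and a correspondingly
#' reduced rich-block correlation. Sampling is fully deterministic given
#' `config$seed`.
#'
#' After generation the control group's mean binary network (threshold 0.3)
#' is checked against the network-construction rules (density within
#' 10--50%, mean degree above `2 * log(n_regions)`, no isolated nodes); a
#' violation is an error instructing a parameter change rather than a silent
#' degradation, because every downstream stage assumes those rules.
#'
#' @param config a [cohort_config()].
#' @param qc_check run the mean-network quality gate (default `TRUE`).
#' @return an object of class `timeseries_panel`: a list with `subjects`
#'   (each a list of `subject_id`, `group`, `duration_months`, `series`),
#'   `region_labels`, and the generating `config`.
#' @export
generate_cohort <- function(config, qc_check = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n_sub <- config$n_subjects_per_group
  labels <- default_region_labels(config$n_regions)
  panel <- with_seed(config$seed, {
    durations <- stats::runif(n_sub, config$duration_range_months[1],
                              config$duration_range_months[2])
    C_hc <- build_ground_truth_covariance(config, "HC")
    subjects <- vector("list", 2L * n_sub)
    for (s in seq_len(n_sub)) {
      series <- sample_subject_series(C_hc, config$n_timepoints, config$noise_sd)
      rownames(series) <- labels
      subjects[[s]] <- list(subject_id = sprintf("HC%02d", s), group = "HC",
                            duration_months = 0, series = series)
    }
    for (s in seq_len(n_sub)) {
      C_jme <- build_ground_truth_covariance(config, "JME", durations[s])
      series <- sample_subject_series(C_jme, config$n_timepoints, config$noise_sd)
      rownames(series) <- labels
      subjects[[n_sub + s]] <- list(subject_id = sprintf("JME%02d", s),
                                    group = "JME",
                                    duration_months = durations[s],
                                    series = series)
    }
    structure(list(subjects = subjects, region_labels = labels,
                   config = config),
              class = "timeseries_panel")
  })
  if (qc_check) {
    hc_nets <- lapply(panel$subjects[seq_len(n_sub)], function(s)
      binarize(pearson_matrix(s$series), threshold = 0.3))
    mean_net <- group_mean_network(hc_nets)
    qc <- network_checks(mean_binary_network(mean_net, threshold = 0.3))
    if (!qc$pass)
      stop(paste("generated control mean network violates the construction",
                 "rules (", qc$failures, "); adjust the planted correlations",
                 "or cohort size in cohort_config()"), call. = FALSE)
  }
  panel
}

#' @export
print.timeseries_panel <- function(x, ...) {
  n <- length(x$subjects)
  cat(sprintf("timeseries_panel: %d subjects (%s), %d regions x %d timepoints\n",
              n, paste(names(table(vapply(x$subjects, `[[`, "", "group"))),
                       table(vapply(x$subjects, `[[`, "", "group")),
                       sep = "=", collapse = ", "),
              length(x$region_labels), ncol(x$subjects[[1]]$series)))
  invisible(x)
}

#' Subjects of one group
#'
#' @param panel a `timeseries_panel`.
#' @param group group label to keep.
#' @return the subject sublist.
#' @export
panel_subjects <- function(panel, group = NULL) {
  if (is.null(group)) return(panel$subjects)
  keep <- vapply(panel$subjects, function(s) s$group == group, logical(1))
  panel$subjects[keep]
}
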