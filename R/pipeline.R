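#' Pipeline configuration
#'
#' Collects and validates every stage parameter before anything runs:
#' correlation threshold, hub fraction, CLM capacity tolerance, null-model
#' ensemble size, attack mode, FDR family, and seeds.
#'
#' @param cohort a [cohort_config()] for synthetic mode, or `NULL` when
#'   `input_dir` points at an existing cohort written by [write_cohort()].
#' @param input_dir directory with a cohort on disk (ignored in synthetic
#'   mode).
#' @param threshold correlation threshold for binarisation (default 0.3).
#' @param top_fraction hub/rich-node fraction (default 0.10).
#' @param a CLM capacity tolerance (default 1.2).
#' @param n_random rich-club null ensemble size (default 100).
#' @param attack_mode `"isolation"` (default) or `"cascade_final"`.
#' @param fdr_family `"contrast"` (default) or `"global"`.
#' @param selection_group group whose mean network selects the hub and the
#'   rich nodes (default `"HC"`).
#' @param base_seed seed for the rich-club null ensemble.
#' @param output_dir where result tables are written (`NULL`: nothing is
#'   written).
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            input_dir = NULL,
                            threshold = 0.3,
                            top_fraction = 0.10,
                            a = 1.2,
                            n_random = 100L,
                            attack_mode = c("isolation", "cascade_final"),
                            fdr_family = c("contrast", "global"),
                            selection_group = "HC",
                            base_seed = 1L,
                            output_dir = NULL) {
  attack_mode <- match.arg(attack_mode)
  fdr_family <- match.arg(fdr_family)
  if (is.null(cohort) && is.null(input_dir))
    stop("either a cohort config (synthetic mode) or an input_dir is required",
         call. = FALSE)
  if (!is.null(cohort)) stopifnot(inherits(cohort, "cohort_config"))
  stopifnot_scalar(threshold, "threshold", -1, 1)
  stopifnot_scalar(top_fraction, "top_fraction", 1e-12, 1)
  stopifnot_scalar(a, "a", 1)
  stopifnot_scalar(n_random, "n_random", 1)
  structure(list(cohort = cohort, input_dir = input_dir,
                 threshold = threshold, top_fraction = top_fraction,
                 a = a, n_random = as.integer(n_random),
                 attack_mode = attack_mode, fdr_family = fdr_family,
                 selection_group = selection_group,
                 base_seed = as.integer(base_seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Per-subject pre/post connection table
#'
#' Decomposes every subject's binary network into rich / feeder / local
#' connection sums before and after the attack on `target`.
#'
#' @param nets named list of `binary_network`s.
#' @param groups character vector of group labels, parallel to `nets`.
#' @param rich a `rich_node_set` (or character labels).
#' @param target attacked region.
#' @param mode attack mode passed to [post_attack_network()].
#' @param a capacity tolerance (used by `"cascade_final"`).
#' @return data.frame with columns `subject_id`, `group`, `condition`,
#'   `rich_sum`, `feeder_sum`, `local_sum`.
#' @export
connection_table <- function(nets, groups, rich, target,
                             mode = "isolation", a = 1.2) {
  stopifnot(length(nets) == length(groups))
  ids <- names(nets)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(nets))
  rows <- lapply(seq_along(nets), function(i) {
    pre <- decompose_connections(nets[[i]], rich)
    post_net <- post_attack_network(nets[[i]], target, mode = mode, a = a)
    post <- decompose_connections(post_net, rich)
    data.frame(subject_id = ids[i], group = groups[i],
               condition = c("pre", "post"),
               rich_sum = c(pre$rich_sum, post$rich_sum),
               feeder_sum = c(pre$feeder_sum, post$feeder_sum),
               local_sum = c(pre$local_sum, post$local_sum),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full hub-attack analysis
#'
#' Executes the whole sequence: obtain the cohort (generate or read), build
#' per-subject correlation and binary networks, form the group-mean
#' networks, select the hub by eigenvector centrality on the selection
#' group's mean network, run the CLM cascade against it, decompose every
#' subject's network into rich / feeder / local connections before and
#' after the attack, run the contrast battery with FDR correction, the
#' duration correlation, the normalised rich-club curves of both group-mean
#' networks, and the clustering / global-efficiency metric table. Identical
#' configuration and seeds give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param verbose print one progress line per stage.
#' @return a list of results: `panel` summary, `qc`, `centrality`,
#'   `target`, `cascade`, `decompositions`, `battery`, `duration`,
#'   `rich_nodes`, `curves`, `club_tests` (one-sided tests of
#'   `phi_norm > 1` per group), `metrics`, and (when `output_dir` is set)
#'   `manifest` describing the written files.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  panel <- if (!is.null(config$cohort)) {
    say("stage generate: synthetic cohort (seed %d)", config$cohort$seed)
    generate_cohort(config$cohort)
  } else {
    say("stage load: cohort from %s", config$input_dir)
    read_cohort(config$input_dir)
  }

  say("stage build: correlation + binary networks (threshold %g)",
      config$threshold)
  groups <- vapply(panel$subjects, `[[`, "", "group")
  nets <- lapply(panel$subjects, function(s)
    binarize(pearson_matrix(s$series), threshold = config$threshold))
  names(nets) <- vapply(panel$subjects, `[[`, "", "subject_id")

  sel <- groups == config$selection_group
  if (!any(sel)) stop("selection_group has no subjects", call. = FALSE)
  mean_sel <- group_mean_network(nets[sel])
  sel_bin <- mean_binary_network(mean_sel, threshold = config$threshold)
  qc <- network_checks(sel_bin)

  say("stage centrality: hub selection on the %s mean network",
      config$selection_group)
  cv <- eigenvector_centrality(sel_bin)
  hubs <- rank_hubs(cv, config$top_fraction)
  target <- select_attack_target(cv)

  say("stage attack: CLM cascade against %s (a = %g)", target, config$a)
  cascade <- run_cascade(sel_bin, target, a = config$a)

  say("stage richclub: node selection, curves, decompositions")
  rich <- select_rich_nodes(mean_sel, fraction = config$top_fraction)
  decomp <- connection_table(nets, groups, rich, target,
                             mode = config$attack_mode, a = config$a)
  curves <- list()
  club_tests <- list()
  for (g in unique(groups)) {
    gb <- mean_binary_network(group_mean_network(nets[groups == g]),
                              threshold = config$threshold)
    curves[[g]] <- phi_norm_curve(gb, n_random = config$n_random,
                                  base_seed = config$base_seed)
    club_tests[[g]] <- phi_norm_greater_test(curves[[g]])
  }

  say("stage stats: contrast battery + duration correlation")
  battery <- run_contrast_battery(decomp, fdr_family = config$fdr_family)
  jme <- groups == "JME"
  duration <- if (any(jme)) {
    durs <- vapply(panel$subjects[jme], `[[`, 0, "duration_months")
    rs <- decomp$rich_sum[decomp$condition == "pre" & decomp$group == "JME"]
    duration_correlation(durs, rs)
  } else NULL

  metrics <- metric_table(nets, target)

  out <- list(panel = panel, qc = qc, centrality = cv, hubs = hubs,
              target = target, cascade = cascade, rich_nodes = rich,
              decompositions = decomp, battery = battery,
              duration = duration, curves = curves, club_tests = club_tests,
              metrics = metrics,
              config = config)
  if (!is.null(config$output_dir))
    out$manifest <- write_pipeline_outputs(out, config$output_dir)
  invisible(out)
}

# Writes the declared result tables and returns a manifest with file hashes.
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cv_tab <- data.frame(region = res$centrality$region_labels,
                       ec = unname(res$centrality$scores))
  cv_tab <- cv_tab[order(-cv_tab$ec, cv_tab$region), ]
  files <- list(
    centrality = write_tsv(cv_tab, file.path(dir, "centrality.tsv")),
    hubs = write_tsv(res$hubs, file.path(dir, "hubs.tsv")),
    decompositions = write_tsv(res$decompositions,
                               file.path(dir, "connection_decomposition.tsv")),
    battery = write_tsv(res$battery, file.path(dir, "contrast_battery.tsv")),
    metrics = write_tsv(res$metrics, file.path(dir, "graph_metrics.tsv")))
  for (g in names(res$curves))
    files[[paste0("curve_", g)]] <-
      write_tsv(res$curves[[g]], file.path(dir, sprintf("rich_club_%s.tsv", g)))
  trace_rows <- do.call(rbind, lapply(res$cascade$states, function(st)
    data.frame(t = st$t,
               n_overloaded = length(st$overloaded),
               global_efficiency = st$global_efficiency)))
  files$cascade <- write_tsv(trace_rows, file.path(dir, "cascade_trace.tsv"))
  summary <- list(
    target = res$target,
    terminated = res$cascade$terminated_reason,
    qc = res$qc[c("density", "mean_degree", "pass")],
    duration = res$duration,
    significant = res$battery[res$battery$significant,
                              c("contrast", "connection_class")])
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files$summary <- file.path(dir, "summary.json")
  paths <- unlist(files, use.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("hubfail")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = list(threshold = res$config$threshold,
                  top_fraction = res$config$top_fraction,
                  a = res$config$a, n_random = res$config$n_random,
                  attack_mode = res$config$attack_mode,
                  fdr_family = res$config$fdr_family,
                  base_seed = res$config$base_seed,
                  cohort = if (!is.null(res$config$cohort))
                    unclass(res$config$cohort)),
    files = lapply(paths, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
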