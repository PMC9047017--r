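#' Two-sample t-test
#'
#' Independent-samples two-sided t-test, pooled variance by default
#' (Welch by `var_equal = FALSE`).
#'
#' @param x,y numeric samples, each of size at least 2.
#' @param var_equal pool the variances (default `TRUE`).
#' @return list with `t` and `p`.
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs at least 2 observations", call. = FALSE)
  if (stats::var(x) + stats::var(y) == 0)
    stop("degenerate samples: pooled variance is zero", call. = FALSE)
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' One-sample t-test
#'
#' Two-sided by default; `alternative = "greater"` supports the directional
#' rich-club question of whether the normalised coefficient exceeds 1.
#'
#' @param x numeric sample of size at least 2 with nonzero variance.
#' @param mu0 null value.
#' @param alternative `"two.sided"`, `"greater"`, or `"less"`.
#' @return list with `t` and `p`.
#' @export
one_sample_t <- function(x, mu0 = 0, alternative = "two.sided") {
  if (length(x) < 2) stop("sample needs at least 2 observations", call. = FALSE)
  if (stats::var(x) == 0)
    stop("degenerate sample: variance is zero", call. = FALSE)
  ht <- stats::t.test(x, mu = mu0, alternative = alternative)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' One-way ANOVA
#'
#' Classic (equal-variance) one-way analysis of variance across two or more
#' groups. For two groups the F statistic equals the square of the pooled
#' two-sample t statistic.
#'
#' @param groups list of numeric samples, each of size at least 2.
#' @return list with `F` and `p`.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 0L) < 2))
    stop("each group needs at least 2 observations", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), times = vapply(groups, length, 0L)))
  if (stats::var(y) == 0) return(list(F = 0, p = 1))
  ht <- stats::oneway.test(y ~ g, var.equal = TRUE)
  f <- unname(ht$statistic)
  if (is.na(f)) f <- 0  # all within-group variance zero but groups equal
  list(F = f, p = if (is.na(ht$p.value)) 1 else ht$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, mapped back to the input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values.
#' @export
fdr_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Correlation between disease duration and rich-connection weight
#'
#' Pearson correlation with a two-sided p-value, quantifying whether
#' patients with longer disease duration have weaker rich-club connectivity.
#'
#' @param durations months of disease per patient.
#' @param rich_sums per-patient rich connection sums.
#' @return list with `r` and `p`.
#' @export
duration_correlation <- function(durations, rich_sums) {
  if (length(durations) != length(rich_sums) || length(durations) < 3)
    stop("need at least 3 paired observations", call. = FALSE)
  if (stats::var(durations) == 0 || stats::var(rich_sums) == 0)
    stop("degenerate input: a variable is constant", call. = FALSE)
  ht <- stats::cor.test(durations, rich_sums)
  list(r = unname(ht$estimate), p = ht$p.value)
}

#' The four group contrasts on rich / feeder / local connections
#'
#' Runs the study's inferential battery on a per-subject connection table:
#' healthy-vs-patient before the attack, healthy before-vs-after, patient
#' before-vs-after, and healthy-vs-patient after the attack, each for the
#' rich, feeder, and local connection sums (12 t-tests), plus the matching
#' one-way ANOVAs. FDR correction is applied within each contrast's family
#' of three connection classes by default, or across all 12 tests with
#' `fdr_family = "global"`.
#'
#' @param decomp data.frame with columns `subject_id`, `group`
#'   (`HC`/`JME`), `condition` (`pre`/`post`), `rich_sum`, `feeder_sum`,
#'   `local_sum` (see [connection_table()]).
#' @param fdr_family `"contrast"` (default) or `"global"`.
#' @param q_threshold significance threshold on the q-value (default 0.05).
#' @param var_equal pooled-variance t-tests (default `TRUE`).
#' @return data.frame with one row per contrast x class: `contrast`,
#'   `connection_class`, `statistic` (t), `F`, `p_value`, `q_value`,
#'   `significant`, `significant_01`.
#' @export
run_contrast_battery <- function(decomp, fdr_family = c("contrast", "global"),
                                 q_threshold = 0.05, var_equal = TRUE) {
  fdr_family <- match.arg(fdr_family)
  need <- c("subject_id", "group", "condition",
            "rich_sum", "feeder_sum", "local_sum")
  if (!all(need %in% names(decomp)))
    stop("decomposition table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  cells <- expand.grid(group = c("HC", "JME"), condition = c("pre", "post"),
                       stringsAsFactors = FALSE)
  have <- with(decomp, paste(group, condition))
  missing <- with(cells, paste(group, condition))
  missing <- missing[!missing %in% have]
  if (length(missing))
    stop("missing design cells: ", paste(missing, collapse = ", "),
         call. = FALSE)
  pull <- function(grp, cond, cls)
    decomp[[cls]][decomp$group == grp & decomp$condition == cond]
  contrasts <- list(
    HCpre_vs_JMEpre  = function(cls) list(pull("HC", "pre", cls),
                                          pull("JME", "pre", cls)),
    HCpre_vs_HCpost  = function(cls) list(pull("HC", "pre", cls),
                                          pull("HC", "post", cls)),
    JMEpre_vs_JMEpost = function(cls) list(pull("JME", "pre", cls),
                                           pull("JME", "post", cls)),
    HCpost_vs_JMEpost = function(cls) list(pull("HC", "post", cls),
                                           pull("JME", "post", cls)))
  classes <- c(rich = "rich_sum", feeder = "feeder_sum", local = "local_sum")
  rows <- list()
  for (cn in names(contrasts)) for (cl in names(classes)) {
    xy <- contrasts[[cn]](classes[[cl]])
    # a contrast with no variation anywhere carries no evidence: t = 0, p = 1
    if (stats::var(xy[[1]]) + stats::var(xy[[2]]) == 0) {
      tt <- list(t = 0, p = 1); av <- list(F = 0, p = 1)
    } else {
      tt <- two_sample_t(xy[[1]], xy[[2]], var_equal = var_equal)
      av <- anova_oneway(xy)
    }
    rows[[paste(cn, cl)]] <- data.frame(
      contrast = cn, connection_class = cl,
      statistic = tt$t, F = av$F, p_value = tt$p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (fdr_family == "global") {
    out$q_value <- fdr_adjust(out$p_value)
  } else {
    out$q_value <- NA_real_
    for (cn in unique(out$contrast)) {
      sel <- out$contrast == cn
      out$q_value[sel] <- fdr_adjust(out$p_value[sel])
    }
  }
  out$significant <- out$q_value < q_threshold
  out$significant_01 <- out$q_value < 0.01
  out
}
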