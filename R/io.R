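# Delimited-text I/O. One dialect everywhere: tab separator, full square
# matrices with a label header and a leading label column, full double
# precision so binary matrices round-trip bit-exactly and real matrices to
# 1e-15.

fmt_num <- function(x) {
  out <- vapply(x, function(v) format(v, digits = 17, scientific = FALSE,
                                      trim = TRUE), character(1))
  out
}

write_square_matrix <- function(m, path) {
  labels <- rownames(m)
  if (is.null(labels)) labels <- default_region_labels(nrow(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("region", labels), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(labels[i], fmt_num(m[i, ])), collapse = "\t"), con)
  invisible(path)
}

read_square_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("matrix file is empty: ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  labels <- header[-1]
  n <- length(labels)
  if (length(lines) - 1L != n)
    stop(sprintf("expected %d data rows, found %d in %s", n,
                 length(lines) - 1L, path), call. = FALSE)
  m <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    parts <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
    if (length(parts) != n + 1L)
      stop(sprintf("ragged row %d in %s: %d fields, expected %d",
                   i, path, length(parts), n + 1L), call. = FALSE)
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(vals))
      stop(sprintf("non-numeric cell at (row %d, col %d) in %s",
                   i, which(is.na(vals))[1], path), call. = FALSE)
    m[i, ] <- vals
  }
  m
}

#' Write / read an adjacency matrix
#'
#' Tab-separated square matrix with a label header row and label column.
#' `read_adjacency` symmetrises silently when the asymmetry is at floating
#' rounding level (max difference below 1e-8) and fails with the offending
#' row/column otherwise.
#'
#' @param net a `binary_network`.
#' @param path file path.
#' @return `write_adjacency` returns the path invisibly; `read_adjacency`
#'   returns a `binary_network`.
#' @export
write_adjacency <- function(net, path) {
  stopifnot(inherits(net, "binary_network"))
  write_square_matrix(net$adjacency, path)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  m <- read_square_matrix(path)
  asym <- abs(m - t(m))
  if (max(asym) > 1e-8) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("adjacency in %s is asymmetric beyond tolerance at (%d, %d)",
                 path, ij[1], ij[2]), call. = FALSE)
  }
  m <- (m + t(m)) / 2
  m <- round(m)
  diag(m) <- 0
  binary_network(m, rownames(m))
}

#' Write / read a subject's region-by-time series
#'
#' Tab-separated, one row per region with its label in the first column and
#' timepoints `t1 .. tT` as the header.
#'
#' @param series regions x time numeric matrix with region rownames.
#' @param path file path.
#' @return `write_subject_matrix` returns the path invisibly;
#'   `read_subject_matrix` returns the matrix.
#' @export
write_subject_matrix <- function(series, path) {
  labels <- rownames(series)
  if (is.null(labels)) labels <- default_region_labels(nrow(series))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("region", sprintf("t%d", seq_len(ncol(series)))),
                   collapse = "\t"), con)
  for (i in seq_len(nrow(series)))
    writeLines(paste(c(labels[i], fmt_num(series[i, ])), collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_subject_matrix
#' @export
read_subject_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("series file is empty: ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  tp <- length(header) - 1L
  rows <- lapply(seq_along(lines)[-1], function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != tp + 1L)
      stop(sprintf("ragged row %d in %s: %d fields, expected %d",
                   i - 1L, path, length(parts), tp + 1L), call. = FALSE)
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(vals))
      stop(sprintf("non-numeric cell at (row %d, col %d) in %s",
                   i - 1L, which(is.na(vals))[1], path), call. = FALSE)
    list(label = parts[1], vals = vals)
  })
  m <- do.call(rbind, lapply(rows, `[[`, "vals"))
  rownames(m) <- vapply(rows, `[[`, "", "label")
  m
}

#' Write a generated cohort to a directory
#'
#' One series file per subject, a tab-separated cohort manifest
#' (`subject_id`, `group`, `duration_months`, `file`), and the generating
#' configuration as YAML.
#'
#' @param panel a `timeseries_panel`.
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort <- function(panel, dir) {
  stopifnot(inherits(panel, "timeseries_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(panel$subjects, function(s) {
    f <- paste0(s$subject_id, ".tsv")
    write_subject_matrix(s$series, file.path(dir, f))
    data.frame(subject_id = s$subject_id, group = s$group,
               duration_months = s$duration_months, file = f,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "cohort.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(panel$config))
    yaml::write_yaml(unclass(panel$config), file.path(dir, "config.yaml"))
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `cohort.tsv` and the subject files.
#' @return a `timeseries_panel` (without a generator config unless
#'   `config.yaml` is present).
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "cohort.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    series <- read_subject_matrix(file.path(dir, manifest$file[i]))
    list(subject_id = manifest$subject_id[i], group = manifest$group[i],
         duration_months = manifest$duration_months[i], series = series)
  })
  cfg_path <- file.path(dir, "config.yaml")
  cfg <- if (file.exists(cfg_path)) {
    raw <- yaml::read_yaml(cfg_path)
    do.call(cohort_config, raw)
  } else NULL
  structure(list(subjects = subjects,
                 region_labels = rownames(subjects[[1]]$series),
                 config = cfg),
            class = "timeseries_panel")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
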