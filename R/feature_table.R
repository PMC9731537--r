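#' Feature table with block and kind tags
#'
#' A `feature_table` is the package's container for a sample-by-feature
#' clinical table: a purely numeric data frame (categorical features are
#' integer-coded), unique sample identifiers, and two per-column tags:
#'
#' * `block`: `"sociodemo"`, `"cfa"` (cognitive/functional assessment) or
#'   `"imaging"` (regional tau-PET/MRI values);
#' * `kind`: `"numeric"` or `"categorical"` — decides mean- vs mode-based
#'   imputation and the per-feature similarity used by
#'   [impute_similarity()].
#'
#' Missing entries are `NA`. After [run_preprocess()] a feature table
#' contains no missing entries and every value lies in `[0, 1]`.
#'
#' @param data Data frame (or matrix) of feature values, all columns numeric.
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   row. Defaults to `S001, S002, ...`.
#' @param block Character vector of block tags, one per column (recycled if
#'   length 1).
#' @param kind Character vector of kind tags, one per column (recycled if
#'   length 1).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(data,
                          sample_ids = NULL,
                          block = "imaging",
                          kind = "numeric") {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  rownames(data) <- NULL
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(nrow(data)))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stopf("sample_ids must be unique")
  if (length(sample_ids) != nrow(data)) {
    stopf("sample_ids length (%d) != number of rows (%d)",
          length(sample_ids), nrow(data))
  }
  nc <- ncol(data)
  block <- rep_len(block, nc)
  kind <- rep_len(kind, nc)
  bad_block <- setdiff(unique(block), c("sociodemo", "cfa", "imaging"))
  if (length(bad_block)) stopf("unknown block tag: %s", bad_block[1])
  bad_kind <- setdiff(unique(kind), c("numeric", "categorical"))
  if (length(bad_kind)) stopf("unknown kind tag: %s", bad_kind[1])
  not_num <- names(data)[!vapply(data, is.numeric, logical(1))]
  if (length(not_num)) {
    stopf("all feature columns must be numeric; offending column: %s",
          not_num[1])
  }
  names(block) <- names(data)
  names(kind) <- names(data)
  structure(
    list(data = data, sample_ids = sample_ids, block = block, kind = kind),
    class = "feature_table"
  )
}

#' @export
dim.feature_table <- function(x) dim(x$data)

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(factor(x$block, levels = c("sociodemo", "cfa", "imaging")))
  cat(sprintf(
    "<feature_table> %d samples x %d features (sociodemo %d, cfa %d, imaging %d)\n",
    nrow(x$data), ncol(x$data), tab[["sociodemo"]], tab[["cfa"]],
    tab[["imaging"]]
  ))
  n_na <- sum(is.na(as.matrix(x$data)))
  cat(sprintf("  missing cells: %d (%.2f%%)\n", n_na,
              100 * n_na / max(1, prod(dim(x$data)))))
  invisible(x)
}

#' @export
as.data.frame.feature_table <- function(x, ...) {
  cbind(data.frame(sample_id = x$sample_ids, stringsAsFactors = FALSE),
        x$data)
}

ft_matrix <- function(x) as.matrix(x$data)

ft_replace_data <- function(x, data) {
  stopifnot(nrow(data) == length(x$sample_ids))
  x$data <- as.data.frame(data, stringsAsFactors = FALSE)
  x
}

# Subset rows of a feature table.
ft_rows <- function(x, idx) {
  feature_table(x$data[idx, , drop = FALSE],
                sample_ids = x$sample_ids[idx],
                block = x$block, kind = x$kind)
}

#' Write / read a feature table as CSV with a metadata sidecar
#'
#' The CSV has one header row, a leading `sample_id` column and empty cells
#' for missing values. Column block/kind tags go to a YAML sidecar
#' (`<path>.meta.yaml`) so the table round-trips exactly.
#'
#' @param x A [feature_table()].
#' @param path CSV file path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a `feature_table`.
#' @export
write_feature_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  meta <- list(block = as.list(x$block), kind = as.list(x$kind))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  meta_path <- paste0(path, ".meta.yaml")
  ids <- as.character(df$sample_id)
  df$sample_id <- NULL
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    block <- unlist(meta$block)[names(df)]
    kind <- unlist(meta$kind)[names(df)]
  } else {
    block <- "imaging"
    kind <- "numeric"
  }
  feature_table(df, sample_ids = ids, block = block, kind = kind)
}

#' Diagnostic label sets
#'
#' A `label_set` stores a per-sample diagnosis in `{CN, MCI, AD}` together
#' with a provenance flag (`"original"` for clinician labels, `"relabelled"`
#' after cluster-based revision) and a per-sample mask marking changed
#' labels. Only CN-to-AD and MCI-to-AD changes are representable downstream:
#' [relabel_ad_cluster()] never touches AD-labelled samples.
#'
#' @param diagnosis Character or factor vector with values in
#'   `c("CN", "MCI", "AD")`.
#' @param provenance `"original"` or `"relabelled"`.
#' @param relabel_mask Logical vector marking changed labels; must be
#'   all-`FALSE` when `provenance = "original"`.
#' @return An object of class `label_set`.
#' @export
label_set <- function(diagnosis,
                      provenance = c("original", "relabelled"),
                      relabel_mask = NULL) {
  provenance <- match.arg(provenance)
  diagnosis <- factor(as.character(diagnosis), levels = diagnosis_levels())
  if (anyNA(diagnosis)) stopf("diagnosis values must be in CN/MCI/AD")
  if (is.null(relabel_mask)) relabel_mask <- rep(FALSE, length(diagnosis))
  if (length(relabel_mask) != length(diagnosis)) {
    stopf("relabel_mask length mismatch")
  }
  if (provenance == "original" && any(relabel_mask)) {
    stopf("relabel_mask must be all-FALSE for original labels")
  }
  structure(
    list(diagnosis = diagnosis, provenance = provenance,
         relabel_mask = relabel_mask),
    class = "label_set"
  )
}

#' @export
length.label_set <- function(x) length(x$diagnosis)

#' @export
print.label_set <- function(x, ...) {
  cts <- table(x$diagnosis)
  cat(sprintf("<label_set> %d samples (%s), CN %d / MCI %d / AD %d",
              length(x), x$provenance, cts[["CN"]], cts[["MCI"]],
              cts[["AD"]]))
  if (any(x$relabel_mask)) cat(sprintf(", %d relabelled", sum(x$relabel_mask)))
  cat("\n")
  invisible(x)
}

#' Cluster assignments
#'
#' Hard per-sample cluster memberships plus optional human-readable cluster
#' names. Cluster indices are 1-based (`1..k`, the R convention); every index
#' in `1..k` must be occupied.
#'
#' @param assignment Integer vector of cluster indices in `1..k`.
#' @param k Number of clusters (defaults to `max(assignment)`).
#' @param names Optional character vector of length `k` naming each cluster.
#' @return An object of class `cluster_assignment`.
#' @export
cluster_assignment <- function(assignment, k = max(assignment), names = NULL) {
  assignment <- as.integer(assignment)
  if (!is_count(k) || k < 1) stopf("k must be a positive integer")
  if (any(assignment < 1L | assignment > k)) {
    stopf("cluster indices must lie in 1..k")
  }
  if (length(assignment) > 0 && !all(seq_len(k) %in% assignment)) {
    stopf("every cluster index in 1..k must appear at least once")
  }
  if (!is.null(names) && length(names) != k) {
    stopf("names must have length k")
  }
  structure(list(assignment = assignment, k = as.integer(k), names = names),
            class = "cluster_assignment")
}

#' @export
length.cluster_assignment <- function(x) length(x$assignment)

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d samples in %d clusters\n",
              length(x$assignment), x$k))
  sizes <- tabulate(x$assignment, nbins = x$k)
  lab <- if (is.null(x$names)) as.character(seq_len(x$k)) else x$names
  for (i in seq_len(x$k)) cat(sprintf("  %s: %d\n", lab[i], sizes[i]))
  invisible(x)
}
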