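#' UMAP manifold embedding
#'
#' Embeds a fully preprocessed (complete, numeric) feature table into a
#' low-dimensional manifold with UMAP. Defaults follow the analysis this
#' package implements: a large neighbourhood (30 neighbours) to avoid very
#' local structure, minimum distance 0 to densify clusters, and 5 output
#' dimensions. The embedding is computed by the `umap-learn` Python library
#' (invoked in a subprocess, seeded and single-threaded), so identical
#' inputs and seed give identical coordinates.
#'
#' @param table A [feature_table()] (or numeric matrix/data frame) with no
#'   missing values.
#' @param neighbours Nearest-neighbour count (default 30).
#' @param min_dist Minimum embedding distance (default 0).
#' @param dims Number of embedding dimensions (default 5).
#' @param seed Integer RNG seed.
#' @param python Python executable used to run `umap-learn`.
#' @return An object of class `umap_embedding`: a list with `coords`
#'   (n x dims matrix) and `params`.
#' @export
embed_umap <- function(table, neighbours = 30L, min_dist = 0, dims = 5L,
                       seed = 1L, python = Sys.which("python")) {
  m <- if (inherits(table, "feature_table")) ft_matrix(table) else as.matrix(table)
  if (anyNA(m)) stopf("embed_umap requires a table with no missing values")
  n <- nrow(m)
  if (dims >= n) stopf("dims (%d) must be smaller than the sample count (%d)", dims, n)
  if (neighbours >= n) {
    stopf("neighbours (%d) must be smaller than the sample count (%d)",
          neighbours, n)
  }
  if (!nzchar(python)) stopf("no python executable found for umap-learn")
  script <- system.file("python", "run_umap.py", package = "adrelabel")
  if (!nzchar(script)) stopf("bundled run_umap.py not found")
  in_csv <- tempfile(fileext = ".csv")
  out_csv <- tempfile(fileext = ".csv")
  on.exit(unlink(c(in_csv, out_csv)), add = TRUE)
  utils::write.csv(as.data.frame(m), in_csv, row.names = FALSE)
  res <- suppressWarnings(system2(
    python,
    c(shQuote(script), shQuote(in_csv), shQuote(out_csv),
      as.integer(neighbours), format(min_dist), as.integer(dims),
      as.integer(seed)),
    stdout = TRUE, stderr = TRUE
  ))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    stopf("umap-learn subprocess failed (exit %d):\n%s", status,
          paste(utils::tail(res, 15), collapse = "\n"))
  }
  coords <- as.matrix(utils::read.csv(out_csv, header = FALSE))
  dimnames(coords) <- list(NULL, paste0("umap_", seq_len(ncol(coords))))
  if (nrow(coords) != n || ncol(coords) != dims || anyNA(coords)) {
    stopf("unexpected embedding shape from umap-learn")
  }
  structure(
    list(coords = coords,
         params = list(neighbours = as.integer(neighbours),
                       min_dist = min_dist, dims = as.integer(dims),
                       seed = as.integer(seed))),
    class = "umap_embedding"
  )
}

#' @export
print.umap_embedding <- function(x, ...) {
  cat(sprintf("<umap_embedding> %d samples x %d dims (neighbours %d, min_dist %g, seed %d)\n",
              nrow(x$coords), ncol(x$coords), x$params$neighbours,
              x$params$min_dist, x$params$seed))
  invisible(x)
}

#' Write an embedding as CSV
#'
#' @param embedding A `umap_embedding`.
#' @param sample_ids Sample identifiers for the leading column.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, sample_ids, path) {
  df <- data.frame(sample_id = sample_ids, embedding$coords)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' k-means clustering of an embedding
#'
#' Partitions the embedded samples into `k` clusters with [stats::kmeans()]
#' (k-means++-like greedy behaviour via multiple restarts; the run with the
#' lowest within-cluster sum of squares wins, first on ties). Seeded, so
#' repeated identical calls agree.
#'
#' @param embedding A `umap_embedding` (or numeric matrix).
#' @param k Number of clusters (default 5).
#' @param seed Integer RNG seed.
#' @param n_init Number of random restarts (default 50; the embedding's
#'   tight, unequal-size blobs make k-means prone to local optima at few
#'   restarts).
#' @return A [cluster_assignment()].
#' @export
kmeans_cluster <- function(embedding, k = 5L, seed = 1L, n_init = 50L) {
  coords <- if (inherits(embedding, "umap_embedding")) embedding$coords else as.matrix(embedding)
  n <- nrow(coords)
  if (!is_count(k) || k < 1) stopf("k must be a positive integer")
  if (k > n) stopf("k (%d) exceeds the sample count (%d)", k, n)
  fit <- with_seed(seed, {
    stats::kmeans(coords, centers = k, nstart = n_init, iter.max = 100L)
  })
  out <- cluster_assignment(fit$cluster, k = k)
  attr(out, "inertia") <- fit$tot.withinss
  out
}

plugin_entropy <- function(x) {
  p <- table(x)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Equal-frequency discretisation into at most n_bins bins; duplicate
# quantile breaks are collapsed so heavily tied features get fewer bins.
equal_freq_bins <- function(x, n_bins) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2) return(rep(1L, length(x)))
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
}

#' Rank features by information gain against cluster membership
#'
#' For each feature, computes the information gain
#' `IG = H(cluster) - H(cluster | feature)` in bits, with continuous
#' features discretised into equal-frequency bins and categorical features
#' used as-is, and returns the `top_n` highest-scoring features in
#' non-increasing order.
#'
#' @param table A [feature_table()] with no missing values.
#' @param clusters A [cluster_assignment()] (or integer vector).
#' @param top_n Number of features to return (default 10).
#' @param n_bins Number of equal-frequency bins for continuous features
#'   (default 5).
#' @return An object of class `feature_ranking`: a data frame with columns
#'   `feature` and `info_gain` (bits), sorted by decreasing gain.
#' @export
rank_features_infogain <- function(table, clusters, top_n = 10L,
                                   n_bins = 5L) {
  cl <- if (inherits(clusters, "cluster_assignment")) clusters$assignment else as.integer(clusters)
  if (length(cl) != nrow(table$data)) stopf("cluster/table length mismatch")
  if (top_n > ncol(table$data)) stopf("top_n exceeds the feature count")
  if (length(unique(cl)) == 1) {
    warnf("single-cluster assignment: all information-gain scores are 0")
  }
  h_cl <- plugin_entropy(cl)
  ig <- vapply(seq_along(table$data), function(j) {
    x <- table$data[[j]]
    if (anyNA(x)) stopf("rank_features_infogain requires complete data (column '%s')",
                        names(table$data)[j])
    b <- if (table$kind[[j]] == "categorical") x else equal_freq_bins(x, n_bins)
    cond <- 0
    for (v in unique(b)) {
      sel <- b == v
      cond <- cond + mean(sel) * plugin_entropy(cl[sel])
    }
    max(0, h_cl - cond)
  }, numeric(1))
  ord <- order(-ig, names(table$data))
  out <- data.frame(feature = names(table$data)[ord],
                    info_gain = ig[ord],
                    stringsAsFactors = FALSE)[seq_len(top_n), ]
  rownames(out) <- NULL
  class(out) <- c("feature_ranking", "data.frame")
  out
}

#' Name discovered clusters by their characteristics
#'
#' Applies a fixed naming rule mirroring how the discovered clusters are
#' interpreted: single-gender clusters become `"Male"` / `"Female"`; the
#' youngest remaining cluster becomes `"Young-FH"` provided its family
#' history rate exceeds the cohort average and it is strictly youngest; the
#' remaining cluster with the highest AD proportion (if any AD cases exist)
#' becomes `"AD"`; everything else is `"Catchall-NRF"`. Duplicate names are
#' suffixed with the cluster index.
#'
#' @param clusters A [cluster_assignment()].
#' @param table The corresponding [feature_table()] (needs `gender`,
#'   `age` and `mother_ad` columns, pre- or post-normalisation).
#' @param labels A [label_set()] with the original diagnoses.
#' @return The cluster assignment with its `names` field filled.
#' @export
name_clusters <- function(clusters, table, labels) {
  need <- c("gender", "age", "mother_ad")
  if (!all(need %in% names(table$data))) {
    stopf("name_clusters needs columns: %s", paste(need, collapse = ", "))
  }
  k <- clusters$k
  asg <- clusters$assignment
  nm <- rep(NA_character_, k)
  gender <- table$data$gender
  age <- table$data$age
  fh <- table$data$mother_ad
  diag <- labels$diagnosis
  for (i in seq_len(k)) {
    g <- gender[asg == i]
    if (length(unique(g)) == 1) {
      nm[i] <- if (unique(g) == max(gender)) "Male" else "Female"
    }
  }
  remaining <- which(is.na(nm))
  if (length(remaining)) {
    mean_age <- vapply(remaining, function(i) mean(age[asg == i]), numeric(1))
    fh_rate <- vapply(remaining, function(i) mean(fh[asg == i]), numeric(1))
    youngest <- remaining[which.min(mean_age)]
    strictly_youngest <- sum(mean_age == min(mean_age)) == 1
    if (strictly_youngest && fh_rate[which.min(mean_age)] > mean(fh)) {
      nm[youngest] <- "Young-FH"
    }
  }
  remaining <- which(is.na(nm))
  if (length(remaining)) {
    ad_prop <- vapply(remaining, function(i) mean(diag[asg == i] == "AD"),
                      numeric(1))
    if (max(ad_prop) > 0) nm[remaining[which.max(ad_prop)]] <- "AD"
  }
  nm[is.na(nm)] <- "Catchall-NRF"
  dup <- nm %in% nm[duplicated(nm)]
  if (any(dup)) {
    warnf("duplicate cluster names disambiguated by index")
    nm[dup] <- paste0(nm[dup], "-", which(dup))
  }
  cluster_assignment(asg, k = k, names = nm)
}

#' Write a cluster assignment as CSV
#'
#' @param clusters A [cluster_assignment()].
#' @param sample_ids Sample identifiers.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, sample_ids, path) {
  nm <- if (is.null(clusters$names)) {
    as.character(clusters$assignment)
  } else {
    clusters$names[clusters$assignment]
  }
  utils::write.csv(
    data.frame(sample_id = sample_ids, cluster = clusters$assignment,
               cluster_name = nm),
    path, row.names = FALSE)
  invisible(path)
}

#' Write a feature ranking as TSV
#'
#' @param ranking A `feature_ranking`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  df <- data.frame(rank = seq_len(nrow(ranking)), feature = ranking$feature,
                   info_gain_bits = ranking$info_gain)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
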