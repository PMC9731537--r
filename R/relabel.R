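#' Identify the AD-dominated cluster
#'
#' Returns the index of the cluster with the highest within-cluster
#' proportion of clinically diagnosed AD cases. Ties are broken by the
#' lowest cluster index (with a message); if no AD case exists anywhere,
#' this is an error — there is no AD-enriched cluster to find.
#'
#' @param clusters A [cluster_assignment()].
#' @param labels A [label_set()] with `provenance = "original"`.
#' @return Integer cluster index.
#' @export
identify_ad_cluster <- function(clusters, labels) {
  if (labels$provenance != "original") {
    stopf("identify_ad_cluster expects original (clinician) labels")
  }
  if (length(labels) != length(clusters)) stopf("label/cluster length mismatch")
  prop <- vapply(seq_len(clusters$k), function(i) {
    mean(labels$diagnosis[clusters$assignment == i] == "AD")
  }, numeric(1))
  if (max(prop) == 0) stopf("no AD-enriched cluster: no AD cases in any cluster")
  hits <- which(prop == max(prop))
  if (length(hits) > 1) {
    message(sprintf("AD-proportion tie between clusters %s; taking the lowest index",
                    paste(hits, collapse = ", ")))
  }
  hits[1]
}

#' Re-label CN/MCI cases inside the AD cluster
#'
#' Every sample in the AD cluster whose original diagnosis is CN or MCI is
#' re-labelled AD, with its `relabel_mask` flag set. AD-labelled samples
#' and samples outside the cluster are never changed (in particular, AD
#' cases outside the AD cluster keep their AD label).
#'
#' @param labels A [label_set()] with `provenance = "original"`.
#' @param clusters A [cluster_assignment()] of the same length.
#' @param ad_cluster Cluster index, typically from [identify_ad_cluster()].
#' @return A [label_set()] with `provenance = "relabelled"`.
#' @export
relabel_ad_cluster <- function(labels, clusters, ad_cluster) {
  if (labels$provenance != "original") {
    stopf("relabel_ad_cluster expects original labels")
  }
  if (length(labels) != length(clusters)) stopf("label/cluster length mismatch")
  if (!is_count(ad_cluster) || ad_cluster < 1 || ad_cluster > clusters$k) {
    stopf("ad_cluster index out of range 1..%d", clusters$k)
  }
  diag <- as.character(labels$diagnosis)
  mask <- clusters$assignment == ad_cluster & diag != "AD"
  diag[mask] <- "AD"
  label_set(diag, provenance = "relabelled", relabel_mask = mask)
}

#' Cohen's kappa between two labelings
#'
#' Unweighted chance-corrected agreement
#' `kappa = (p_o - p_e) / (1 - p_e)`, with the expected agreement `p_e`
#' computed from the two marginal class distributions. Ranges over
#' `[-1, 1]`; 1 means perfect agreement. If both labelings are the same
#' constant (`p_e = 1`), 1 is returned by convention with a message.
#'
#' @param a,b [label_set()]s (or vectors) of equal length over the same
#'   label alphabet.
#' @return Kappa as a single number.
#' @export
cohen_kappa <- function(a, b) {
  av <- if (inherits(a, "label_set")) as.character(a$diagnosis) else as.character(a)
  bv <- if (inherits(b, "label_set")) as.character(b$diagnosis) else as.character(b)
  if (length(av) != length(bv)) stopf("label vectors differ in length")
  if (length(av) == 0) stopf("empty label vectors")
  lev <- union(av, bv)
  ta <- table(factor(av, levels = lev))
  tb <- table(factor(bv, levels = lev))
  n <- length(av)
  p_o <- mean(av == bv)
  p_e <- sum((ta / n) * (tb / n))
  if (p_e >= 1) {
    message("both labelings constant and equal: kappa = 1 by convention")
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Per-group feature summaries
#'
#' For each named group of samples and each requested feature, reports the
#' group size, mean and standard deviation (n-1 denominator) in the
#' feature's units. Used for the post-hoc validation of re-labelled cases:
#' groups such as non-AD, CN/MCI-to-AD, remained AD, and AD outside the AD
#' cluster. Groups of size < 2 report an `NA` standard deviation.
#'
#' @param table A [feature_table()].
#' @param groups Named list of integer row-index vectors; must be pairwise
#'   disjoint.
#' @param features Character vector of feature names present in `table`
#'   (values outside the table, e.g. a held-out biomarker, can be summarised
#'   by passing them via `extra`).
#' @param extra Optional named list of numeric vectors (length = number of
#'   samples) summarised alongside the table's features.
#' @return A data frame with columns `group`, `feature`, `n`, `mean`, `sd`,
#'   of class `group_summary`.
#' @export
posthoc_group_summary <- function(table, groups, features,
                                  extra = list()) {
  idx_all <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(idx_all)) stopf("groups must be disjoint")
  missing_feat <- setdiff(features, c(names(table$data), names(extra)))
  if (length(missing_feat)) {
    stopf("unknown feature(s): %s", paste(missing_feat, collapse = ", "))
  }
  rows <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    for (f in features) {
      v <- if (f %in% names(table$data)) table$data[[f]][idx] else extra[[f]][idx]
      v <- v[!is.na(v)]
      rows[[length(rows) + 1]] <- data.frame(
        group = g, feature = f, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Standard post-hoc validation groups
#'
#' Builds the four disjoint case sets used to validate a re-labelling:
#' `non_AD` (never AD under either labeling), `CN_MCI_to_AD` (re-labelled
#' cases), `remained_AD` (clinician AD inside the AD cluster) and
#' `AD_outside_AD_cluster` (clinician AD outside it, deliberately not
#' re-labelled).
#'
#' @param labels Original [label_set()].
#' @param relabelled Relabelled [label_set()] from [relabel_ad_cluster()].
#' @param clusters A [cluster_assignment()].
#' @param ad_cluster AD-cluster index.
#' @return Named list of row-index vectors.
#' @export
relabel_groups <- function(labels, relabelled, clusters, ad_cluster) {
  orig <- as.character(labels$diagnosis)
  in_ad <- clusters$assignment == ad_cluster
  list(
    non_AD = which(orig != "AD" & !relabelled$relabel_mask),
    CN_MCI_to_AD = which(relabelled$relabel_mask),
    remained_AD = which(orig == "AD" & in_ad),
    AD_outside_AD_cluster = which(orig == "AD" & !in_ad)
  )
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value (thin wrapper over [stats::t.test()]). If both
#' samples have zero variance and equal means, `p = 1` is returned with a
#' message.
#'
#' @param x,y Numeric vectors of length >= 2 with finite values.
#' @return List with `t`, `df` and `p`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stopf("both samples need length >= 2")
  if (!all(is.finite(x)) || !all(is.finite(y))) stopf("samples must be finite")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      message("both samples constant and equal: p = 1")
      return(list(t = 0, df = NA_real_, p = 1))
    }
    return(list(t = if (mean(x) > mean(y)) Inf else -Inf, df = NA_real_,
                p = 0))
  }
  fit <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value))
}

#' Write relabelled labels as CSV
#'
#' @param labels Original [label_set()].
#' @param relabelled Relabelled [label_set()].
#' @param sample_ids Sample identifiers.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_relabelled <- function(labels, relabelled, sample_ids, path) {
  utils::write.csv(
    data.frame(sample_id = sample_ids,
               original = as.character(labels$diagnosis),
               relabelled = as.character(relabelled$diagnosis),
               changed = relabelled$relabel_mask),
    path, row.names = FALSE)
  invisible(path)
}
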