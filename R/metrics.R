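#' One-vs-all AUC
#'
#' Probability that a randomly chosen positive sample receives a higher
#' score than a randomly chosen negative one, with ties credited 1/2 (the
#' Mann-Whitney formulation, computed from ranks).
#'
#' @param scores Numeric score for the positive class, one per sample.
#' @param labels Vector of class labels.
#' @param positive The label treated as positive.
#' @return AUC in `[0, 1]`, or `NA` (with a warning) when either class is
#'   absent.
#' @export
one_vs_all_auc <- function(scores, labels, positive) {
  pos <- labels == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    warnf("AUC undefined: class '%s' has no %s samples", positive,
          if (n_pos == 0) "positive" else "negative")
    return(NA_real_)
  }
  r <- rank(scores)  # average ranks give the 1/2 tie credit
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Macro one-vs-all AUC
#'
#' Averages [one_vs_all_auc()] over the classes present in `labels`; each
#' class uses its own score column.
#'
#' @param score_matrix Numeric matrix, one column per class (named).
#' @param labels Vector of true class labels.
#' @param classes Classes to average over (default: column names).
#' @return List with `macro` and named `per_class` AUCs.
#' @export
macro_auc <- function(score_matrix, labels, classes = colnames(score_matrix)) {
  per <- vapply(classes, function(cl) {
    if (!cl %in% labels) return(NA_real_)
    one_vs_all_auc(score_matrix[, cl], labels, cl)
  }, numeric(1))
  list(macro = mean(per, na.rm = TRUE), per_class = per)
}

#' Balanced accuracy
#'
#' Unweighted mean of per-class recall over classes with at least one true
#' sample; classes absent from `labels` are excluded with a warning.
#'
#' @param predictions Vector of predicted class labels.
#' @param labels Vector of true class labels.
#' @param classes Classes considered (default: those in `labels`).
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(predictions, labels,
                              classes = sort(unique(as.character(labels)))) {
  if (length(predictions) != length(labels)) stopf("length mismatch")
  absent <- setdiff(classes, as.character(labels))
  if (length(absent)) {
    warnf("class(es) with zero true samples excluded: %s",
          paste(absent, collapse = ", "))
    classes <- setdiff(classes, absent)
  }
  rec <- vapply(classes, function(cl) {
    sel <- labels == cl
    mean(predictions[sel] == cl)
  }, numeric(1))
  mean(rec)
}

#' Aggregate metrics over repeated runs
#'
#' Summarises per-repeat macro AUC and balanced accuracy with means and
#' standard deviations; when two paired series are supplied (e.g. original
#' vs re-labelled training targets evaluated on identical splits), adds a
#' paired comparison block with the mean difference and a two-sided paired
#' t-test.
#'
#' @param repeats Data frame with columns `repeat_id`, `macro_auc`,
#'   `balanced_accuracy`, and optionally `arm` naming two paired series.
#' @return An object of class `metrics_report`.
#' @export
aggregate_repeats <- function(repeats) {
  if (nrow(repeats) < 1) stopf("need at least one repeat")
  sd_or_na <- function(x) if (length(x) >= 2) stats::sd(x) else NA_real_
  report <- list(per_repeat = repeats)
  if (!is.null(repeats$arm)) {
    arms <- unique(repeats$arm)
    report$summary <- do.call(rbind, lapply(arms, function(a) {
      sub <- repeats[repeats$arm == a, ]
      data.frame(arm = a, n_repeats = nrow(sub),
                 mean_macro_auc = mean(sub$macro_auc),
                 sd_macro_auc = sd_or_na(sub$macro_auc),
                 mean_balanced_accuracy = mean(sub$balanced_accuracy),
                 sd_balanced_accuracy = sd_or_na(sub$balanced_accuracy),
                 stringsAsFactors = FALSE)
    }))
    if (length(arms) == 2) {
      a1 <- repeats[repeats$arm == arms[1], ]
      a2 <- repeats[repeats$arm == arms[2], ]
      if (nrow(a1) != nrow(a2)) stopf("paired series differ in length")
      a1 <- a1[order(a1$repeat_id), ]
      a2 <- a2[order(a2$repeat_id), ]
      d <- a2$macro_auc - a1$macro_auc
      comparison <- list(arms = as.character(arms),
                         mean_difference = mean(d))
      if (nrow(a1) >= 2 && stats::sd(d) > 0) {
        tt <- stats::t.test(d)
        comparison$t <- unname(tt$statistic)
        comparison$p <- unname(tt$p.value)
      } else {
        comparison$t <- NA_real_
        comparison$p <- if (nrow(a1) >= 2 && all(d == 0)) 1 else NA_real_
      }
      report$comparison <- comparison
    }
  } else {
    report$summary <- data.frame(
      arm = "all", n_repeats = nrow(repeats),
      mean_macro_auc = mean(repeats$macro_auc),
      sd_macro_auc = sd_or_na(repeats$macro_auc),
      mean_balanced_accuracy = mean(repeats$balanced_accuracy),
      sd_balanced_accuracy = sd_or_na(repeats$balanced_accuracy),
      stringsAsFactors = FALSE)
  }
  class(report) <- "metrics_report"
  report
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$comparison)) {
    cat(sprintf("  paired difference (%s - %s): %+0.4f macro AUC",
                x$comparison$arms[2], x$comparison$arms[1],
                x$comparison$mean_difference))
    if (!is.na(x$comparison$p)) cat(sprintf(" (t = %0.3f, p = %0.4f)",
                                            x$comparison$t, x$comparison$p))
    cat("\n")
  }
  invisible(x)
}

#' Serialise a metrics report
#'
#' Writes the report as JSON plus a flat one-row-per-arm TSV summary.
#'
#' @param report A `metrics_report`.
#' @param json_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisible list of paths written.
#' @export
write_metrics_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  if (!is.null(tsv_path)) {
    utils::write.table(report$summary, tsv_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(list(json = json_path, tsv = tsv_path))
}
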