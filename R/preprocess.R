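#' Mean / mode imputation
#'
#' Replaces each missing numeric cell by its column mean over observed
#' values and each missing categorical cell by its column mode (ties broken
#' by the smallest value, for determinism). Observed cells are never
#' altered.
#'
#' @param table A [feature_table()].
#' @return The imputed table.
#' @export
impute_simple <- function(table) {
  df <- table$data
  for (j in seq_along(df)) {
    x <- df[[j]]
    miss <- is.na(x)
    if (!any(miss)) next
    obs <- x[!miss]
    if (length(obs) == 0) {
      stopf("cannot impute column '%s': no observed values", names(df)[j])
    }
    fill <- if (table$kind[[j]] == "numeric") {
      mean(obs)
    } else {
      tab <- table(obs)
      as.numeric(names(tab)[which.max(tab)])  # max count, lowest value on tie
    }
    x[miss] <- fill
    df[[j]] <- x
  }
  ft_replace_data(table, df)
}

# Gower-style similarity between one target row and candidate rows, averaged
# over the features observed in both. Numeric features contribute
# 1 - |xi - xj| / range (range over observed column values); categorical
# features contribute 1 on equality, 0 otherwise. `rng` is the precomputed
# per-column range. Vectorised over candidates; returns NA where no feature
# is shared.
gower_similarity <- function(m, kinds, rng, target, candidates) {
  tgt <- m[target, ]
  cand <- m[candidates, , drop = FALSE]
  s <- matrix(NA_real_, nrow = nrow(cand), ncol = ncol(cand))
  num <- which(kinds == "numeric")
  cat_ <- which(kinds == "categorical")
  if (length(num)) {
    s[, num] <- 1 - abs(sweep(cand[, num, drop = FALSE], 2, tgt[num])) /
      rep(rng[num], each = nrow(cand))
  }
  if (length(cat_)) {
    s[, cat_] <- (cand[, cat_, drop = FALSE] ==
                    rep(tgt[cat_], each = nrow(cand))) * 1
  }
  out <- rowMeans(s, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Similarity-matrix imputation
#'
#' For each row with a missing cell in the target block, computes a
#' Gower-style similarity to all rows that are complete in that block,
#' shortlists the `n_neighbours` most similar, and copies the missing value
#' from the single most similar reference row. Ties in similarity are broken
#' by the lowest sample identifier. When no complete reference rows exist
#' the function falls back to modal/mean imputation with a warning.
#'
#' @param table A [feature_table()].
#' @param target_block Block tag whose missing cells to impute
#'   (default `"sociodemo"`).
#' @param n_neighbours Size of the similarity shortlist (default 10).
#' @return The table with the target block's missing cells filled.
#' @export
impute_similarity <- function(table, target_block = "sociodemo",
                              n_neighbours = 10L) {
  cols <- which(table$block == target_block)
  if (length(cols) == 0) return(table)
  df <- table$data
  block_m <- as.matrix(df[, cols, drop = FALSE])
  incomplete <- which(rowSums(is.na(block_m)) > 0)
  if (length(incomplete) == 0) return(table)
  complete <- which(rowSums(is.na(block_m)) == 0)
  if (length(complete) == 0) {
    warnf("no complete reference rows in block '%s'; falling back to mean/mode imputation",
          target_block)
    sub <- feature_table(df[, cols, drop = FALSE],
                         sample_ids = table$sample_ids,
                         block = table$block[cols], kind = table$kind[cols])
    filled <- impute_simple(sub)
    df[, cols] <- filled$data
    return(ft_replace_data(table, df))
  }
  m <- ft_matrix(table)
  rng <- vapply(seq_len(ncol(m)), function(j) {
    r <- suppressWarnings(diff(range(m[, j], na.rm = TRUE)))
    if (!is.finite(r) || r == 0) 1 else r
  }, numeric(1))
  for (i in incomplete) {
    sims <- gower_similarity(m, table$kind, rng, i, complete)
    ok <- which(!is.na(sims))
    if (length(ok) == 0) next
    cand <- complete[ok]
    s <- sims[ok]
    # shortlist ~n_neighbours most similar, then the single best reference;
    # ties resolved by lowest sample ID
    ord <- order(-s, table$sample_ids[cand])
    short <- ord[seq_len(min(n_neighbours, length(ord)))]
    ref <- cand[short[1]]
    for (j in cols) {
      if (is.na(df[i, j])) df[i, j] <- df[ref, j]
    }
  }
  ft_replace_data(table, df)
}

#' Shift columns to be non-negative
#'
#' Any column containing a negative value is increased by the absolute value
#' of its minimum, so its new minimum is exactly 0; columns already
#' non-negative are left unchanged.
#'
#' @param table A [feature_table()] with no missing entries.
#' @return The shifted table.
#' @export
shift_nonnegative <- function(table) {
  df <- table$data
  for (j in seq_along(df)) {
    mn <- min(df[[j]])
    if (is.na(mn)) stopf("shift_nonnegative requires complete data (column '%s')",
                         names(df)[j])
    if (mn < 0) df[[j]] <- df[[j]] + abs(mn)
  }
  ft_replace_data(table, df)
}

#' Min-max normalisation
#'
#' Maps each column to `(x - min) / (max - min)` so all values lie in
#' `[0, 1]`. Constant columns are mapped to all-0 with a warning (they carry
#' no information but column count is preserved).
#'
#' @param table A [feature_table()] with no missing entries.
#' @return The normalised table.
#' @export
minmax_normalize <- function(table) {
  df <- table$data
  constant <- character(0)
  for (j in seq_along(df)) {
    x <- df[[j]]
    if (anyNA(x)) stopf("minmax_normalize requires complete data (column '%s')",
                        names(df)[j])
    rng <- range(x)
    if (rng[1] == rng[2]) {
      df[[j]] <- rep(0, length(x))
      constant <- c(constant, names(df)[j])
    } else {
      df[[j]] <- (x - rng[1]) / (rng[2] - rng[1])
    }
  }
  if (length(constant)) {
    warnf("constant column(s) normalised to 0: %s",
          paste(constant, collapse = ", "))
  }
  ft_replace_data(table, df)
}

#' One-hot encode the APoE4 allele count
#'
#' Expands an ordinal 0/1/2 allele-count vector into three indicator
#' columns; exactly one indicator is 1 per sample.
#'
#' @param values Numeric vector with values in `{0, 1, 2}`.
#' @return A data frame with columns `apoe4_0`, `apoe4_1`, `apoe4_2`.
#' @export
onehot_apoe4 <- function(values) {
  if (anyNA(values) || !all(values %in% 0:2)) {
    stopf("APoE4 values must all be 0, 1 or 2")
  }
  out <- data.frame(apoe4_0 = as.numeric(values == 0),
                    apoe4_1 = as.numeric(values == 1),
                    apoe4_2 = as.numeric(values == 2))
  out
}

# Replace the ordinal apoe4 column by its three indicators, in place.
expand_apoe4 <- function(table) {
  j <- match("apoe4", names(table$data))
  if (is.na(j)) return(table)  # already expanded (or never present)
  oh <- onehot_apoe4(table$data[[j]])
  before <- table$data[, seq_len(j - 1), drop = FALSE]
  after <- if (j < ncol(table$data)) {
    table$data[, (j + 1):ncol(table$data), drop = FALSE]
  } else {
    NULL
  }
  df <- cbind(before, oh, after)
  block <- append(table$block[-j], rep(table$block[[j]], 3), after = j - 1)
  kind <- append(table$kind[-j], rep("categorical", 3), after = j - 1)
  names(block) <- names(df)
  names(kind) <- names(df)
  feature_table(df, sample_ids = table$sample_ids, block = block,
                kind = kind)
}

#' Full preprocessing chain
#'
#' Applies, in order: similarity imputation of the sociodemographic block,
#' mean/mode imputation of remaining missing cells, one-hot expansion of the
#' APoE4 allele count, non-negative shifting, and min-max normalisation.
#' The result has no missing entries and every value in `[0, 1]`; the chain
#' is idempotent on its own output.
#'
#' @param table A raw [feature_table()].
#' @param verbose Print one line per stage with the number of cells changed.
#' @return The preprocessed table.
#' @export
run_preprocess <- function(table, verbose = FALSE) {
  if (nrow(table$data) == 0) return(table)
  stages <- list(
    impute_similarity = function(t) impute_similarity(t),
    impute_simple = impute_simple,
    onehot_apoe4 = expand_apoe4,
    shift_nonnegative = shift_nonnegative,
    minmax_normalize = minmax_normalize
  )
  for (nm in names(stages)) {
    before <- table
    table <- tryCatch(stages[[nm]](table), error = function(e) {
      stopf("preprocessing stage '%s' failed: %s", nm, conditionMessage(e))
    })
    if (verbose) {
      changed <- if (identical(dim(before$data), dim(table$data))) {
        bm <- ft_matrix(before)
        am <- ft_matrix(table)
        sum(is.na(bm) != is.na(am) |
              (!is.na(bm) & !is.na(am) & bm != am))
      } else {
        NA_integer_
      }
      message(sprintf("[preprocess] %-18s cells changed: %s", nm,
                      ifelse(is.na(changed), "(columns expanded)", changed)))
    }
  }
  table
}
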