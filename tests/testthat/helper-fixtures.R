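# Shared fixtures, memoised so expensive objects are built once per test run.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

default_dataset <- function() {
  memo("ds", generate_dataset(synthetic_config(seed = 7)))
}

default_prep <- function() {
  memo("prep", suppressWarnings(run_preprocess(default_dataset()$table)))
}

# A small raw table with known structure for preprocessing tests.
toy_table <- function(n = 12, seed = 99) {
  withr::with_seed(seed, {
    feature_table(
      data.frame(
        age = rnorm(n, 75, 6),
        gender = rbinom(n, 1, 0.5),
        score_a = rnorm(n),
        score_b = rnorm(n, -2, 1),
        tau_a = rnorm(n, 1.5, 0.4)
      ),
      block = c("sociodemo", "sociodemo", "cfa", "cfa", "imaging"),
      kind = c("numeric", "categorical", "numeric", "numeric", "numeric")
    )
  })
}

# The reference cohort's per-cluster clinician-diagnosis composition:
# five clusters, counts CN/MCI/AD per cluster, summing to 363/137/59.
cohort_composition <- function() {
  data.frame(
    cluster = 1:5,
    name = c("AD", "Catchall", "Female", "Male", "Young-FH"),
    cn = c(6L, 114L, 96L, 82L, 65L),
    mci = c(18L, 32L, 28L, 44L, 15L),
    ad = c(26L, 20L, 7L, 5L, 1L)
  )
}

# Labels + cluster assignment realising that composition.
cohort_fixture <- function() {
  comp <- cohort_composition()
  diag <- unlist(lapply(seq_len(nrow(comp)), function(i) {
    rep(c("CN", "MCI", "AD"), times = c(comp$cn[i], comp$mci[i], comp$ad[i]))
  }))
  cl <- rep(comp$cluster, times = comp$cn + comp$mci + comp$ad)
  list(labels = label_set(diag),
       clusters = cluster_assignment(cl, k = 5, names = comp$name))
}

# Independent information-gain oracle: mutual information from the joint
# contingency table, I(V; C) = sum p(v,c) log2(p(v,c) / (p(v) p(c))).
mi_oracle <- function(v, cl) {
  joint <- table(v, cl) / length(v)
  pv <- rowSums(joint)
  pc <- colSums(joint)
  s <- 0
  for (i in seq_along(pv)) {
    for (j in seq_along(pc)) {
      if (joint[i, j] > 0) {
        s <- s + joint[i, j] * log2(joint[i, j] / (pv[i] * pc[j]))
      }
    }
  }
  unname(s)
}

# Brute-force pairwise-counting AUC oracle, O(n^2), ties credited 1/2.
auc_oracle <- function(scores, labels, positive) {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  total <- 0
  for (i in pos) {
    for (j in neg) {
      total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  total / (length(pos) * length(neg))
}

# Exhaustive minimum within-cluster sum of squares over all 2-partitions.
best_two_partition_wss <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- as.integer(intToBits(code))[seq_len(n)]
    wss <- 0
    for (g in 0:1) {
      sub <- x[grp == g, , drop = FALSE]
      if (nrow(sub) == 0) next
      ctr <- colMeans(sub)
      wss <- wss + sum(sweep(sub, 2, ctr)^2)
    }
    if (wss < best) best <- wss
  }
  best
}

# Down-scaled synthetic cohort (~quarter size) for pipeline tests.
small_cluster_spec <- function() {
  spec <- default_cluster_spec()
  spec$n_cn <- c(2L, 28L, 24L, 20L, 16L)
  spec$n_mci <- c(5L, 8L, 7L, 11L, 4L)
  spec$n_ad <- c(7L, 5L, 2L, 1L, 1L)
  spec
}
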