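test_that("mean/mode imputation fills missing cells and nothing else", {
  tab <- feature_table(
    data.frame(x = c(1, 2, NA, 3), g = c(0, 0, 1, NA)),
    block = "cfa", kind = c("numeric", "categorical"))
  out <- impute_simple(tab)
  expect_equal(out$data$x, c(1, 2, 2, 3))     # mean of 1, 2, 3
  expect_equal(out$data$g, c(0, 0, 1, 0))     # mode is 0
  # observed cells untouched, and a complete table is returned unchanged
  expect_identical(impute_simple(out)$data, out$data)

  empty_col <- feature_table(data.frame(x = c(NA_real_, NA_real_)),
                             block = "cfa", kind = "numeric")
  expect_error(impute_simple(empty_col), "x")
})

test_that("imputation never alters observed cells", {
  tab <- inject_missingness(toy_table(n = 30), 0.2, seed = 8)
  m0 <- as.matrix(tab$data)
  obs <- !is.na(m0)
  for (out in list(impute_simple(tab),
                   impute_similarity(tab, "sociodemo"))) {
    m1 <- as.matrix(out$data)
    expect_equal(m1[obs], m0[obs])
  }
})

test_that("similarity imputation copies from the closest reference row", {
  df <- data.frame(
    g = c(0, 0, 1, NA),
    age = c(70, 70, 85, 70),
    s1 = c(1.0, 1.1, 3.0, 1.05),
    s2 = c(2.0, 2.1, 5.0, 2.05))
  tab <- feature_table(df, sample_ids = c("A", "B", "C", "D"),
                       block = c("sociodemo", "sociodemo", "cfa", "cfa"),
                       kind = c("categorical", "numeric", "numeric",
                                "numeric"))
  out <- impute_similarity(tab, "sociodemo")
  expect_equal(out$data$g[4], 0)  # rows A/B are near-duplicates of D

  # two exactly equidistant references with different values:
  # deterministic tie-break by lowest sample ID
  df2 <- data.frame(g = c(0, 1, NA), age = c(70, 70, 70))
  tab2 <- feature_table(df2, sample_ids = c("S2", "S1", "S3"),
                        block = "sociodemo",
                        kind = c("categorical", "numeric"))
  out2 <- impute_similarity(tab2, "sociodemo")
  expect_equal(out2$data$g[3], 1)  # S1 < S2 lexicographically

  # no complete reference rows: falls back to mean/mode with a warning
  df3 <- data.frame(g = c(NA, NA, 0), age = c(NA, 70, NA))
  tab3 <- feature_table(df3, block = "sociodemo",
                        kind = c("categorical", "numeric"))
  expect_warning(out3 <- impute_similarity(tab3, "sociodemo"),
                 "falling back")
  expect_false(anyNA(out3$data))
})

test_that("similarity imputation beats mode imputation on correlated data", {
  # two latent groups; a categorical sociodemographic flag tracks the group
  # and the remaining features are strongly group-shifted, so neighbours
  # carry the missing value while the global mode does not
  n <- 60
  truth <- withr::with_seed(11, {
    grp <- rep(c(0, 1), times = c(40, 20))
    feature_table(
      data.frame(flag = grp,
                 f1 = rnorm(n, 5 * grp), f2 = rnorm(n, -5 * grp),
                 f3 = rnorm(n, 3 * grp)),
      block = c("sociodemo", "cfa", "cfa", "cfa"),
      kind = c("categorical", "numeric", "numeric", "numeric"))
  })
  masked <- truth
  hide <- withr::with_seed(12, sample(n, 15))
  masked$data$flag[hide] <- NA
  sim <- impute_similarity(masked, "sociodemo")
  mode_imp <- impute_simple(masked)
  err_sim <- mean(abs(sim$data$flag[hide] - truth$data$flag[hide]))
  err_mode <- mean(abs(mode_imp$data$flag[hide] - truth$data$flag[hide]))
  expect_lt(err_sim, err_mode)
})

test_that("negative columns are shifted so their minimum is zero", {
  tab <- feature_table(data.frame(a = c(-2, 0, 3), b = c(0, 1, 2),
                                  c = c(-5, -1, -1)))
  out <- shift_nonnegative(tab)
  expect_equal(out$data$a, c(0, 2, 5))
  expect_equal(out$data$b, c(0, 1, 2))     # untouched
  expect_equal(out$data$c, c(0, 4, 4))
  expect_equal(min(out$data$a), 0)
})

test_that("min-max normalisation maps every column to [0, 1]", {
  tab <- feature_table(data.frame(a = c(0, 5, 10), b = c(0, 0.5, 1),
                                  k = c(7, 7, 7)))
  expect_warning(out <- minmax_normalize(tab), "constant")
  expect_equal(out$data$a, c(0, 0.5, 1))
  expect_equal(out$data$b, c(0, 0.5, 1))   # idempotent on [0,1] columns
  expect_equal(out$data$k, c(0, 0, 0))     # constant maps to 0
})

test_that("APoE4 one-hot encoding produces exactly one indicator per row", {
  oh <- onehot_apoe4(c(1, 0, 2, 0))
  expect_equal(oh$apoe4_0, c(0, 1, 0, 1))
  expect_equal(oh$apoe4_1, c(1, 0, 0, 0))
  expect_equal(oh$apoe4_2, c(0, 0, 1, 0))
  expect_true(all(rowSums(oh) == 1))
  expect_error(onehot_apoe4(c(0, 3)), "APoE4")
  expect_error(onehot_apoe4(c(0, NA)), "APoE4")
})

test_that("shift-then-normalise equals normalise alone", {
  tab <- withr::with_seed(21, {
    feature_table(data.frame(a = rnorm(50, -3), b = runif(50, -1, 1),
                             c = rnorm(50, 10)))
  })
  via_shift <- minmax_normalize(shift_nonnegative(tab))
  direct <- minmax_normalize(tab)
  expect_equal(via_shift$data, direct$data, tolerance = 1e-12)
})

test_that("the full chain removes missingness and lands in [0, 1]", {
  prep <- default_prep()
  m <- as.matrix(prep$data)
  expect_equal(sum(is.na(m)), 0L)
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(ncol(m), 226L)  # APoE4 expands one column into three
  expect_true(all(c("apoe4_0", "apoe4_1", "apoe4_2") %in% colnames(m)))
  expect_false("apoe4" %in% colnames(m))
})

test_that("preprocessing is idempotent on its own output", {
  prep <- default_prep()
  again <- suppressWarnings(run_preprocess(prep))
  expect_equal(again$data, prep$data, tolerance = 1e-12)
})

test_that("degenerate tables pass through the chain", {
  empty <- feature_table(data.frame(x = numeric(0)))
  expect_equal(nrow(run_preprocess(empty)$data), 0L)

  clean <- feature_table(data.frame(a = c(1, 2, 4), b = c(0.1, 0.5, 0.2)))
  out <- run_preprocess(clean)
  expect_equal(out$data$a, c(0, 1 / 3, 1))  # only normalisation acts
})
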