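#' Default latent cluster specification
#'
#' Five latent clusters emulating the structure reported for an ADNI-like
#' baseline cohort: an AD-dominated cluster with elevated tau-region values,
#' a mixed "catchall" cluster with intermediate pathology, single-gender
#' male and female clusters, and a younger cluster with frequent parental
#' family history of AD. Per-cluster observed diagnosis counts sum to the
#' cohort composition 363 CN / 137 MCI / 59 AD over 559 samples.
#'
#' Columns:
#' * `name`: cluster label.
#' * `n_cn`, `n_mci`, `n_ad`: observed (clinician) diagnosis counts.
#' * `gender`: `"male"`, `"female"` or `"mixed"`; `prop_male` applies to
#'   mixed clusters.
#' * `age_mean`, `age_sd`: age distribution in years.
#' * `tau_effect`: upward shift (in feature SD units) of tau-sensitive
#'   imaging regions for cluster members.
#' * `cfa_effect`: downward shift of memory-loaded cognitive scores.
#' * `fh_rate`: probability of maternal family history of AD.
#' * `severity`: cluster-level disease severity driving the exogenous
#'   CSF amyloid-beta biomarker (higher severity, lower biomarker).
#' * `abeta_na_rate`: per-cluster missingness of the biomarker.
#' * `ad_latent`: whether non-AD observed labels inside this cluster are
#'   planted label noise (their latent diagnosis is AD).
#'
#' @return A data frame with one row per latent cluster.
#' @export
default_cluster_spec <- function() {
  data.frame(
    name = c("AD", "Catchall", "Female", "Male", "Young-FH"),
    n_cn = c(6L, 114L, 96L, 82L, 65L),
    n_mci = c(18L, 32L, 28L, 44L, 15L),
    n_ad = c(26L, 20L, 7L, 5L, 1L),
    gender = c("mixed", "mixed", "female", "male", "mixed"),
    prop_male = c(0.60, 0.42, 0, 1, 0.43),
    age_mean = c(75.1, 74.6, 75.9, 78.8, 71.3),
    age_sd = c(9.8, 7.2, 8.2, 6.9, 6.4),
    tau_effect = c(1.2, 0.4, 0, 0, 0),
    cfa_effect = c(1.0, 0.3, 0, 0, 0),
    fh_rate = c(0.2, 0.2, 0.2, 0.2, 0.8),
    severity = c(1.75, 1.0, 0, 0.3, 0),
    abeta_na_rate = c(0, 0, 0, 0, 0.7),
    ad_latent = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Synthetic cohort configuration
#'
#' Parameters for [generate_dataset()]. Defaults emulate the reference
#' cohort: 559 participants, 224 features (7 sociodemographic/medical
#' history, 40 cognitive/functional assessment, 177 tau-PET/MRI regional
#' values), observed class counts 363/137/59, five latent clusters, ~6%
#' missingness, and an amyloid-beta-like exogenous biomarker that decreases
#' with disease severity.
#'
#' @param cluster_spec Data frame as returned by [default_cluster_spec()].
#' @param n_sociodemo,n_cfa,n_imaging Feature-block sizes.
#' @param label_noise Optional fraction in `[0, 1)`: proportion of AD-like
#'   cluster members given a non-AD observed label. `NULL` (default) keeps
#'   the counts in `cluster_spec` as-is; otherwise the AD-like cluster's
#'   composition is re-derived from its total size.
#' @param missing_rate MCAR missingness fraction over the feature table.
#' @param abeta_params List with `baseline`, `sd`, `slope` (biomarker units;
#'   mean = baseline - slope * cluster severity) and `relabel_shift`, an
#'   additional shift applied to AD-like-cluster members whose observed
#'   label is not AD (the biomarker is more advanced in those cases).
#' @param effects List with `cluster_sep` (SD of per-cluster centroid
#'   offsets over cfa+imaging features), `tau_sev` and `cfa_sev` (per-unit
#'   latent-severity shifts of tau-sensitive and memory-loaded features) and
#'   `noise_sd` (residual feature noise).
#' @param n_tau_sensitive,n_memory Numbers of imaging features that respond
#'   to tau elevation and of CFA features that respond to memory decline.
#' @param seed Integer RNG seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(cluster_spec = default_cluster_spec(),
                             n_sociodemo = 7L,
                             n_cfa = 40L,
                             n_imaging = 177L,
                             label_noise = NULL,
                             missing_rate = 0.06,
                             abeta_params = list(baseline = 1340, sd = 380,
                                                 slope = 280,
                                                 relabel_shift = -230),
                             effects = list(cluster_sep = 1.5, tau_sev = 0.5,
                                            cfa_sev = 0.8, noise_sd = 1),
                             n_tau_sensitive = 40L,
                             n_memory = 10L,
                             seed = 1L) {
  need <- c("name", "n_cn", "n_mci", "n_ad", "gender", "prop_male",
            "age_mean", "age_sd", "tau_effect", "cfa_effect", "fh_rate",
            "severity", "abeta_na_rate", "ad_latent")
  missing_cols <- setdiff(need, names(cluster_spec))
  if (length(missing_cols)) {
    stopf("cluster_spec is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  counts <- as.matrix(cluster_spec[, c("n_cn", "n_mci", "n_ad")])
  if (any(counts < 0) || any(counts != floor(counts))) {
    stopf("cluster diagnosis counts must be non-negative integers")
  }
  if (!is.null(label_noise)) {
    if (!is.numeric(label_noise) || label_noise < 0 || label_noise >= 1) {
      stopf("label_noise must lie in [0, 1)")
    }
    i <- which(cluster_spec$ad_latent)
    for (ci in i) {
      n_c <- sum(counts[ci, ])
      n_noise <- round(label_noise * n_c)
      n_cn <- round(n_noise * 0.25)
      cluster_spec$n_cn[ci] <- n_cn
      cluster_spec$n_mci[ci] <- n_noise - n_cn
      cluster_spec$n_ad[ci] <- n_c - n_noise
    }
    counts <- as.matrix(cluster_spec[, c("n_cn", "n_mci", "n_ad")])
  }
  if (missing_rate < 0 || missing_rate > 1) {
    stopf("missing_rate must lie in [0, 1]")
  }
  if (n_sociodemo != 7L) {
    stopf("n_sociodemo is fixed at 7 (age, gender, education, mother/father family history, APoE4, hypertension)")
  }
  if (n_cfa < n_memory || n_imaging < n_tau_sensitive) {
    stopf("feature block sizes smaller than their sensitive subsets")
  }
  cfg <- structure(
    list(cluster_spec = cluster_spec,
         n_samples = sum(counts),
         class_counts = c(CN = sum(counts[, 1]), MCI = sum(counts[, 2]),
                          AD = sum(counts[, 3])),
         n_sociodemo = as.integer(n_sociodemo),
         n_cfa = as.integer(n_cfa),
         n_imaging = as.integer(n_imaging),
         missing_rate = missing_rate,
         abeta_params = abeta_params,
         effects = effects,
         n_tau_sensitive = as.integer(n_tau_sensitive),
         n_memory = as.integer(n_memory),
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> %d samples, %d features, CN/MCI/AD %d/%d/%d, %d clusters, %.0f%% missing\n",
    x$n_samples, x$n_sociodemo + x$n_cfa + x$n_imaging,
    x$class_counts[["CN"]], x$class_counts[["MCI"]], x$class_counts[["AD"]],
    nrow(x$cluster_spec), 100 * x$missing_rate))
  invisible(x)
}

cfa_feature_names <- function(n) {
  fixed <- c("phc_mem", "adas_total", "mmse_total", "cdr_global",
             "lm_immediate", "lm_delayed", "npi_total", "gds_total",
             "hachinski", "cog_battery")
  c(fixed, sprintf("cfa_%02d", seq_len(max(0, n - length(fixed)))))[seq_len(n)]
}

imaging_feature_names <- function(n) {
  fixed <- c("lh_amygdala", "wm_lh_entorhinal", "ctx_lh_inferiorparietal",
             "ctx_rh_inferiorparietal", "ctx_lh_middletemporal",
             "ctx_lh_lateraloccipital", "wm_lh_inferiortemporal",
             "rh_amygdala", "ctx_lh_entorhinal", "ctx_rh_middletemporal")
  c(fixed, sprintf("tau_region_%03d", seq_len(max(0, n - length(fixed)))))[seq_len(n)]
}

#' Generate a synthetic ADNI-like dataset
#'
#' Draws a complete cohort under a [synthetic_config()]: per-cluster
#' sociodemographics, cluster-offset Gaussian CFA and imaging features with
#' tau elevation for AD-like cluster members and severity-driven memory
#' decline, planted label noise (non-AD observed labels inside the AD-like
#' cluster whose latent diagnosis is AD), an exogenous amyloid-beta-like
#' biomarker inversely related to severity, and MCAR missingness.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `synthetic_dataset`: a list with elements
#'   `table` ([feature_table()]), `labels` (observed [label_set()]),
#'   `latent_labels` (ground-truth diagnoses), `latent_clusters`
#'   ([cluster_assignment()] of the generating clusters) and `abeta`
#'   (numeric biomarker with possible `NA`s, never part of the feature
#'   table).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    stopf("config must be a synthetic_config")
  }
  spec <- config$cluster_spec
  k <- nrow(spec)
  n <- config$n_samples
  eff <- config$effects
  with_seed(config$seed, {
    cluster <- rep(seq_len(k), times = spec$n_cn + spec$n_mci + spec$n_ad)
    observed <- unlist(lapply(seq_len(k), function(i) {
      rep(c("CN", "MCI", "AD"),
          times = c(spec$n_cn[i], spec$n_mci[i], spec$n_ad[i]))
    }))
    latent <- observed
    latent[spec$ad_latent[cluster]] <- "AD"
    severity <- c(CN = 0, MCI = 1, AD = 2)[latent]
    # Planted-noise cases are latent AD at a slightly earlier disease stage
    # than clinically diagnosed AD (their biomarkers are intermediate).
    noise_case <- spec$ad_latent[cluster] & observed != "AD"
    severity[noise_case] <- 1.5

    gender <- numeric(n)  # 1 = male, 0 = female
    for (i in seq_len(k)) {
      idx <- which(cluster == i)
      gender[idx] <- switch(spec$gender[i],
        male = 1,
        female = 0,
        mixed = stats::rbinom(length(idx), 1, spec$prop_male[i]))
    }
    age <- stats::rnorm(n, spec$age_mean[cluster], spec$age_sd[cluster])
    education <- pmax(8, stats::rnorm(n, 16.5, 2.5))
    mother_ad <- stats::rbinom(n, 1, spec$fh_rate[cluster])
    father_ad <- stats::rbinom(n, 1, spec$fh_rate[cluster] * 0.6)
    apoe_probs <- rbind(CN = c(0.65, 0.30, 0.05),
                        MCI = c(0.50, 0.40, 0.10),
                        AD = c(0.30, 0.50, 0.20))
    apoe4 <- vapply(latent, function(l) {
      sample(0:2, 1, prob = apoe_probs[l, ])
    }, numeric(1))
    hypertension <- stats::rbinom(n, 1, 0.3)

    sociodemo <- data.frame(age = age, gender = gender,
                            education = education, mother_ad = mother_ad,
                            father_ad = father_ad, apoe4 = apoe4,
                            hypertension = hypertension)

    n_quant <- config$n_cfa + config$n_imaging
    # One centroid offset vector per latent cluster over the quantitative
    # features; this carries the cluster separation the embedding recovers.
    centroids <- matrix(stats::rnorm(k * n_quant, 0, eff$cluster_sep),
                        nrow = k)
    quant <- centroids[cluster, , drop = FALSE] +
      matrix(stats::rnorm(n * n_quant, 0, eff$noise_sd), nrow = n)

    mem_cols <- seq_len(config$n_memory)
    quant[, mem_cols] <- quant[, mem_cols] -
      outer(eff$cfa_sev * severity + spec$cfa_effect[cluster],
            rep(1, length(mem_cols)))
    tau_cols <- config$n_cfa + seq_len(config$n_tau_sensitive)
    quant[, tau_cols] <- quant[, tau_cols] +
      outer(eff$tau_sev * severity + spec$tau_effect[cluster],
            rep(1, length(tau_cols)))

    cfa <- as.data.frame(quant[, seq_len(config$n_cfa), drop = FALSE])
    names(cfa) <- cfa_feature_names(config$n_cfa)
    imaging <- as.data.frame(
      quant[, config$n_cfa + seq_len(config$n_imaging), drop = FALSE])
    names(imaging) <- imaging_feature_names(config$n_imaging)

    ab <- config$abeta_params
    abeta <- stats::rnorm(n, ab$baseline - ab$slope * spec$severity[cluster],
                          ab$sd)
    abeta[noise_case] <- abeta[noise_case] + ab$relabel_shift
    ab_na <- stats::runif(n) < spec$abeta_na_rate[cluster]
    abeta[ab_na] <- NA_real_

    ord <- sample.int(n)
    tab <- feature_table(
      cbind(sociodemo, cfa, imaging)[ord, , drop = FALSE],
      sample_ids = sprintf("S%04d", seq_len(n)),
      block = rep(c("sociodemo", "cfa", "imaging"),
                  times = c(config$n_sociodemo, config$n_cfa,
                            config$n_imaging)),
      kind = c("numeric", "categorical", "numeric", "categorical",
               "categorical", "categorical", "categorical",
               rep("numeric", config$n_cfa + config$n_imaging))
    )
    tab <- inject_missingness(tab, config$missing_rate,
                              seed = stage_seed(config$seed, "missingness"))
    structure(
      list(table = tab,
           labels = label_set(observed[ord], provenance = "original"),
           latent_labels = label_set(latent[ord], provenance = "original"),
           latent_clusters = cluster_assignment(cluster[ord], k = k,
                                                names = spec$name),
           abeta = abeta[ord],
           config = config),
      class = "synthetic_dataset"
    )
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>\n")
  print(x$table)
  print(x$labels)
  invisible(x)
}

#' Insert missing values completely at random
#'
#' Masks feature cells of a [feature_table()] independently with the given
#' probability. Sample identifiers are never masked (labels live outside the
#' table and are untouched by construction).
#'
#' @param table A [feature_table()].
#' @param rate Missingness probability in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @return The table with masked cells set to `NA`.
#' @export
inject_missingness <- function(table, rate, seed = 1L) {
  if (!is.numeric(rate) || length(rate) != 1 || is.na(rate) ||
      rate < 0 || rate > 1) {
    stopf("rate must be a single value in [0, 1]")
  }
  if (rate == 0) return(table)
  m <- ft_matrix(table)
  with_seed(seed, {
    mask <- matrix(stats::runif(length(m)) < rate, nrow = nrow(m))
    m[mask] <- NA_real_
  })
  ft_replace_data(table, as.data.frame(m))
}

#' Write / read a synthetic dataset
#'
#' Persists the feature table (CSV + metadata sidecar), observed and latent
#' labels with latent cluster and biomarker columns (CSV), and a YAML echo
#' of the generating configuration.
#'
#' @param dataset A `synthetic_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisible character vector of the files written.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data_path <- file.path(dir, "dataset.csv")
  write_feature_table(dataset$table, data_path)
  truth <- data.frame(
    sample_id = dataset$table$sample_ids,
    diagnosis = as.character(dataset$labels$diagnosis),
    latent_diagnosis = as.character(dataset$latent_labels$diagnosis),
    latent_cluster = dataset$latent_clusters$assignment,
    latent_cluster_name =
      dataset$latent_clusters$names[dataset$latent_clusters$assignment],
    abeta = dataset$abeta,
    stringsAsFactors = FALSE
  )
  truth_path <- file.path(dir, "truth.csv")
  utils::write.csv(truth, truth_path, row.names = FALSE, na = "")
  cfg <- dataset$config
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(
    n_samples = cfg$n_samples,
    class_counts = as.list(cfg$class_counts),
    n_sociodemo = cfg$n_sociodemo, n_cfa = cfg$n_cfa,
    n_imaging = cfg$n_imaging,
    missing_rate = cfg$missing_rate,
    abeta_params = cfg$abeta_params,
    effects = cfg$effects,
    n_tau_sensitive = cfg$n_tau_sensitive, n_memory = cfg$n_memory,
    seed = cfg$seed,
    cluster_spec = lapply(seq_len(nrow(cfg$cluster_spec)), function(i) {
      as.list(cfg$cluster_spec[i, ])
    })
  ), cfg_path)
  invisible(c(data_path, truth_path, cfg_path))
}

#' @rdname write_synthetic_dataset
#' @param path Path to a `config.yaml` written by
#'   [write_synthetic_dataset()].
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- do.call(rbind, lapply(y$cluster_spec, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  synthetic_config(cluster_spec = spec,
                   n_sociodemo = y$n_sociodemo, n_cfa = y$n_cfa,
                   n_imaging = y$n_imaging,
                   missing_rate = y$missing_rate,
                   abeta_params = y$abeta_params,
                   effects = y$effects,
                   n_tau_sensitive = y$n_tau_sensitive,
                   n_memory = y$n_memory,
                   seed = y$seed)
}
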