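#' Auto-metric GNN configuration
#'
#' Hyper-parameters for the auto-metric graph neural network classifier: a
#' node-classification network whose adjacency is produced by a trainable
#' similarity function over a handful of "graph features", trained with
#' episodic meta-tasks and evaluated one-shot.
#'
#' @param graph_features Feature names used for edge construction (default:
#'   gender, age, education and parental family history).
#' @param n_classes Number of diagnostic classes (3: CN/MCI/AD).
#' @param iterations Training iterations, one episode each (default 300).
#' @param batch_size Nodes per episode (default 64).
#' @param train_fraction Fraction of samples used for training (default
#'   0.8).
#' @param gnn_layers Number of graph-convolution rounds (default 2). Each
#'   round owns a similarity network with two trainable transforms, so the
#'   default stack has four convolutional transforms in total.
#' @param hidden_dim Width of the node representations (default 32).
#' @param sim_hidden Hidden width of each similarity network (default 8).
#' @param support_per_class Labelled support nodes per class in a training
#'   episode (default 5).
#' @param test_support_per_class Supports per class at test time (default
#'   1: one-shot evaluation).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param eval_passes Number of full covering passes over the test set
#'   during evaluation; per-sample scores are averaged across passes
#'   (default 5).
#' @param seed Integer RNG seed.
#' @return An object of class `amgnn_config`.
#' @export
amgnn_config <- function(graph_features = c("gender", "age", "education",
                                            "mother_ad", "father_ad"),
                         n_classes = 3L,
                         iterations = 300L,
                         batch_size = 64L,
                         train_fraction = 0.8,
                         gnn_layers = 2L,
                         hidden_dim = 32L,
                         sim_hidden = 8L,
                         support_per_class = 5L,
                         test_support_per_class = 1L,
                         learning_rate = 1e-3,
                         eval_passes = 5L,
                         seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stopf("train_fraction must lie strictly between 0 and 1")
  }
  if (batch_size < n_classes * support_per_class + 1) {
    stopf("batch_size must be at least n_classes * support_per_class + 1")
  }
  structure(
    list(graph_features = graph_features, n_classes = as.integer(n_classes),
         iterations = as.integer(iterations),
         batch_size = as.integer(batch_size),
         train_fraction = train_fraction,
         gnn_layers = as.integer(gnn_layers),
         hidden_dim = as.integer(hidden_dim),
         sim_hidden = as.integer(sim_hidden),
         support_per_class = as.integer(support_per_class),
         test_support_per_class = as.integer(test_support_per_class),
         learning_rate = learning_rate,
         eval_passes = as.integer(eval_passes),
         seed = as.integer(seed)),
    class = "amgnn_config"
  )
}

#' Stratified train/test split
#'
#' Splits sample indices into train and test sets, stratified by class so
#' each class keeps (up to rounding) the requested training fraction.
#' Deterministic for a fixed seed.
#'
#' @param labels A [label_set()] (or vector of class labels).
#' @param train_fraction Training fraction in (0, 1).
#' @param seed Integer RNG seed.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   union = all samples).
#' @export
split_train_test <- function(labels, train_fraction = 0.8, seed = 1L) {
  y <- if (inherits(labels, "label_set")) as.character(labels$diagnosis) else as.character(labels)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stopf("train_fraction must lie strictly between 0 and 1")
  }
  counts <- table(y)
  if (any(counts < 2)) {
    stopf("class '%s' has fewer than 2 samples; cannot stratify",
          names(counts)[which.min(counts)])
  }
  with_seed(seed, {
    train <- integer(0)
    for (cl in names(counts)) {
      idx <- which(y == cl)
      n_tr <- max(1L, min(length(idx) - 1L, round(train_fraction * length(idx))))
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(y), train))
  })
}

# ---- parameters ------------------------------------------------------------

init_amgnn_params <- function(d_in, config) {
  g <- length(config$graph_features)
  h <- config$hidden_dim
  sh <- config$sim_hidden
  C <- config$n_classes
  L <- config$gnn_layers
  rnorm_m <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
  params <- list()
  dims_in <- c(d_in, rep(h, L - 1))
  for (l in seq_len(L)) {
    params[[paste0("sim", l, "_W1")]] <- rnorm_m(g, sh, 0.3)
    params[[paste0("sim", l, "_b1")]] <- matrix(0, 1, sh)
    params[[paste0("sim", l, "_w2")]] <- rnorm_m(sh, 1, 0.3)
    params[[paste0("sim", l, "_b2")]] <- matrix(0, 1, 1)
    params[[paste0("gnn", l, "_W")]] <- rnorm_m(dims_in[l], h, sqrt(1 / dims_in[l]))
    params[[paste0("gnn", l, "_Wself")]] <- rnorm_m(dims_in[l], h, sqrt(1 / dims_in[l]))
    params[[paste0("gnn", l, "_b")]] <- matrix(0, 1, h)
  }
  params[["out_W"]] <- rnorm_m(h, C, sqrt(1 / h))
  params[["out_b"]] <- matrix(0, 1, C)
  params
}

# Pairwise absolute graph-feature differences for an episode, as an
# (n^2 x g) matrix in column-major (i, j) order.
pairwise_absdiff <- function(G) {
  n <- nrow(G)
  P <- matrix(0, n * n, ncol(G))
  for (k in seq_len(ncol(G))) {
    P[, k] <- as.vector(abs(outer(G[, k], G[, k], "-")))
  }
  P
}

# Learned adjacency for one GNN layer: a two-transform similarity network
# maps each pairwise absolute-difference vector to a non-negative raw
# weight exp(-z^2) (maximal, 1, at zero difference when biases are zero);
# rows are normalised to sum to 1. Returns the cache needed for backprop.
adjacency_layer <- function(params, l, P, n) {
  W1 <- params[[paste0("sim", l, "_W1")]]
  b1 <- params[[paste0("sim", l, "_b1")]]
  w2 <- params[[paste0("sim", l, "_w2")]]
  b2 <- params[[paste0("sim", l, "_b2")]]
  H <- tanh(sweep(P %*% W1, 2, -b1[1, ]))
  z <- as.vector(H %*% w2) + b2[1, 1]
  R <- matrix(exp(-z^2), n, n)
  s <- rowSums(R)
  list(A = R / s, H = H, z = z, R = R, s = s)
}

adjacency_backward <- function(cache, dA) {
  n <- nrow(dA)
  rs <- rowSums(dA * cache$A)
  dR <- sweep(sweep(dA, 1, rs), 1, cache$s, "/")
  dz <- as.vector(dR) * (-2 * cache$z * as.vector(cache$R))
  dz
}

#' Build the learned similarity graph for an episode
#'
#' Computes the first-layer adjacency matrix of the auto-metric GNN: edge
#' weight `w(i, j)` is a trainable scalar function of the elementwise
#' absolute difference of the two nodes' graph-feature vectors (gender,
#' age, education, family history by default), including self-edges, with
#' each row normalised to sum to 1. All weights are non-negative.
#'
#' @param graph_features Numeric matrix (nodes x graph features).
#' @param params Model parameter list (e.g. from a trained model); if
#'   `NULL`, freshly initialised parameters are used.
#' @param config An [amgnn_config()].
#' @param seed Seed for fresh parameter initialisation.
#' @return Row-normalised edge-weight matrix.
#' @export
build_graph <- function(graph_features, params = NULL,
                        config = amgnn_config(), seed = 1L) {
  G <- as.matrix(graph_features)
  if (!all(is.finite(G))) stopf("graph features must be finite")
  if (is.null(params)) {
    params <- with_seed(seed, init_amgnn_params(d_in = 1L, config))
  }
  P <- pairwise_absdiff(G)
  adjacency_layer(params, 1L, P, nrow(G))$A
}

# Forward pass over one episode. X: node features (n x d_feat); G: graph
# features; y: integer class labels (1..C), NA for queries. Query label
# channels are a uniform placeholder. Returns per-node class probabilities
# and, optionally, all intermediates.
amgnn_forward <- function(params, X, G, y, config, keep_cache = FALSE) {
  n <- nrow(X)
  C <- config$n_classes
  L <- config$gnn_layers
  labch <- matrix(1 / C, n, C)
  sup <- which(!is.na(y))
  labch[sup, ] <- 0
  labch[cbind(sup, y[sup])] <- 1
  Xin <- cbind(X, labch)
  P <- pairwise_absdiff(G)
  caches <- vector("list", L)
  Xl <- Xin
  layer_in <- vector("list", L)
  for (l in seq_len(L)) {
    adj <- adjacency_layer(params, l, P, n)
    M <- adj$A %*% Xl
    # neighbourhood aggregation plus an explicit self term, so a node's own
    # features survive even when the learned adjacency is near-uniform
    S <- sweep(M %*% params[[paste0("gnn", l, "_W")]] +
                 Xl %*% params[[paste0("gnn", l, "_Wself")]], 2,
               -params[[paste0("gnn", l, "_b")]][1, ])
    layer_in[[l]] <- Xl
    Xl_next <- tanh(S)
    caches[[l]] <- list(adj = adj, M = M, X_out = Xl_next)
    Xl <- Xl_next
  }
  O <- sweep(Xl %*% params$out_W, 2, -params$out_b[1, ])
  O <- O - apply(O, 1, max)
  E <- exp(O)
  probs <- E / rowSums(E)
  out <- list(probs = probs)
  if (keep_cache) {
    out$cache <- list(P = P, Xin = Xin, layer_in = layer_in,
                      caches = caches, X_top = Xl, n = n)
  }
  out
}

# Cross-entropy loss on query nodes plus gradients for every parameter.
amgnn_loss_grads <- function(params, X, G, y, y_query, config) {
  fw <- amgnn_forward(params, X, G, y, config, keep_cache = TRUE)
  cache <- fw$cache
  probs <- fw$probs
  n <- cache$n
  C <- config$n_classes
  L <- config$gnn_layers
  query <- which(is.na(y))
  nq <- length(query)
  loss <- -mean(log(pmax(probs[cbind(query, y_query[query])], 1e-12)))
  dO <- matrix(0, n, C)
  Yq <- matrix(0, nq, C)
  Yq[cbind(seq_len(nq), y_query[query])] <- 1
  dO[query, ] <- (probs[query, , drop = FALSE] - Yq) / nq
  grads <- list()
  grads$out_W <- t(cache$X_top) %*% dO
  grads$out_b <- matrix(colSums(dO), 1)
  dX <- dO %*% t(params$out_W)
  for (l in rev(seq_len(L))) {
    cl <- cache$caches[[l]]
    dS <- dX * (1 - cl$X_out^2)
    grads[[paste0("gnn", l, "_W")]] <- t(cl$M) %*% dS
    grads[[paste0("gnn", l, "_Wself")]] <- t(cache$layer_in[[l]]) %*% dS
    grads[[paste0("gnn", l, "_b")]] <- matrix(colSums(dS), 1)
    dM <- dS %*% t(params[[paste0("gnn", l, "_W")]])
    dA <- dM %*% t(cache$layer_in[[l]])
    dX <- t(cl$adj$A) %*% dM + dS %*% t(params[[paste0("gnn", l, "_Wself")]])
    dz <- adjacency_backward(cl$adj, dA)
    H <- cl$adj$H
    w2 <- params[[paste0("sim", l, "_w2")]]
    grads[[paste0("sim", l, "_w2")]] <- t(H) %*% matrix(dz, ncol = 1)
    grads[[paste0("sim", l, "_b2")]] <- matrix(sum(dz), 1, 1)
    dH <- matrix(dz, ncol = 1) %*% t(w2)
    dpre <- dH * (1 - H^2)
    grads[[paste0("sim", l, "_W1")]] <- t(cache$P) %*% dpre
    grads[[paste0("sim", l, "_b1")]] <- matrix(colSums(dpre), 1)
  }
  list(loss = loss, grads = grads, probs = probs)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Sample a meta-task episode
#'
#' Training mode draws `support_per_class` labelled supports per class and
#' fills the rest of the batch with query nodes, all from the training
#' pool. Test mode draws one-shot supports (`test_support_per_class` per
#' class) from the training pool and takes its queries from the test pool,
#' so no test sample ever appears as a support.
#'
#' @param pool Integer indices of the training pool.
#' @param labels A [label_set()] (or label vector) for all samples.
#' @param config An [amgnn_config()].
#' @param mode `"train"` or `"test"`.
#' @param test_pool Integer indices of test queries (test mode only).
#' @param seed Optional seed; by default the caller's RNG stream is used.
#' @return List with `idx` (global node indices), `y_input` (labels with
#'   `NA` for queries), `y_true` (labels for all nodes) and `is_support`.
#' @export
sample_episode <- function(pool, labels, config, mode = c("train", "test"),
                           test_pool = NULL, seed = NULL) {
  mode <- match.arg(mode)
  y_all <- if (inherits(labels, "label_set")) as.integer(labels$diagnosis) else as.integer(factor(labels))
  draw <- function() {
    C <- config$n_classes
    spc <- if (mode == "train") config$support_per_class else config$test_support_per_class
    support <- integer(0)
    for (cl in seq_len(C)) {
      cand <- pool[y_all[pool] == cl]
      if (length(cand) < spc) {
        stopf("training pool has only %d sample(s) of class %d (need %d)",
              length(cand), cl, spc)
      }
      support <- c(support, sample(cand, spc))
    }
    if (mode == "train") {
      rest <- setdiff(pool, support)
      n_query <- min(config$batch_size - length(support), length(rest))
      if (n_query < 1) stopf("no query nodes available in the training pool")
      query <- sample(rest, n_query)
    } else {
      if (is.null(test_pool) || length(test_pool) < 1) {
        stopf("test mode needs a non-empty test_pool")
      }
      # queries keep the supplied order so callers can align scores
      n_query <- min(config$batch_size - length(support), length(test_pool))
      query <- test_pool[seq_len(n_query)]
    }
    idx <- c(support, query)
    y_input <- y_all[idx]
    y_input[(length(support) + 1):length(idx)] <- NA_integer_
    list(idx = idx, y_input = y_input, y_true = y_all[idx],
         is_support = c(rep(TRUE, length(support)),
                        rep(FALSE, length(query))))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Train the auto-metric GNN
#'
#' Runs episodic meta-task training: at each iteration an episode is
#' sampled from the training pool, a forward/backward pass computes the
#' cross-entropy loss on the episode's query nodes, and one Adam step
#' updates all parameters (the similarity networks and graph-convolution
#' weights jointly). Deterministic given the config seed.
#'
#' @param table A preprocessed [feature_table()].
#' @param labels A [label_set()] (training targets).
#' @param config An [amgnn_config()].
#' @param train_idx Integer indices forming the training pool (default: all
#'   samples).
#' @return An object of class `amgnn_model`: parameters, config, the
#'   training pool, and a per-iteration log (`iteration`, `loss`,
#'   `macro_auc`, `balanced_accuracy` over each episode's queries).
#' @export
train_amgnn <- function(table, labels, config = amgnn_config(),
                        train_idx = seq_len(nrow(table$data))) {
  gf <- config$graph_features
  missing_gf <- setdiff(gf, names(table$data))
  if (length(missing_gf)) {
    stopf("graph feature(s) not in table: %s",
          paste(missing_gf, collapse = ", "))
  }
  Xall <- ft_matrix(table)
  if (anyNA(Xall)) stopf("train_amgnn requires a fully preprocessed table")
  Gall <- Xall[, gf, drop = FALSE]
  y_all <- as.integer(labels$diagnosis)
  d_in <- ncol(Xall) + config$n_classes
  with_seed(config$seed, {
    params <- init_amgnn_params(d_in, config)
    state <- adam_init(params)
    log <- data.frame(iteration = integer(0), loss = numeric(0),
                      macro_auc = numeric(0), balanced_accuracy = numeric(0))
    if (config$iterations > 0) {
      log <- data.frame(iteration = seq_len(config$iterations),
                        loss = NA_real_, macro_auc = NA_real_,
                        balanced_accuracy = NA_real_)
      for (it in seq_len(config$iterations)) {
        ep <- sample_episode(train_idx, labels, config, mode = "train")
        res <- amgnn_loss_grads(params, Xall[ep$idx, , drop = FALSE],
                                Gall[ep$idx, , drop = FALSE],
                                ep$y_input, ep$y_true, config)
        if (!is.finite(res$loss)) {
          stopf("training diverged (non-finite loss) at iteration %d", it)
        }
        upd <- adam_step(params, res$grads, state, config$learning_rate)
        params <- upd$params
        state <- upd$state
        q <- which(!ep$is_support)
        qy <- levels(labels$diagnosis)[ep$y_true[q]]
        sc <- res$probs[q, , drop = FALSE]
        colnames(sc) <- levels(labels$diagnosis)
        pred <- colnames(sc)[max.col(sc, ties.method = "first")]
        log$loss[it] <- res$loss
        log$macro_auc[it] <- suppressWarnings(macro_auc(sc, qy)$macro)
        log$balanced_accuracy[it] <- suppressWarnings(
          balanced_accuracy(pred, qy))
      }
    }
    structure(list(params = params, config = config, train_idx = train_idx,
                   d_in = d_in, log = log,
                   class_levels = levels(labels$diagnosis)),
              class = "amgnn_model")
  })
}

#' @export
print.amgnn_model <- function(x, ...) {
  cat(sprintf("<amgnn_model> %d GNN layer(s), hidden %d, %d iterations trained\n",
              x$config$gnn_layers, x$config$hidden_dim, nrow(x$log)))
  if (nrow(x$log) > 0) {
    cat(sprintf("  final loss %.4f (first %.4f)\n",
                x$log$loss[nrow(x$log)], x$log$loss[1]))
  }
  invisible(x)
}

#' Evaluate a trained model one-shot on a test set
#'
#' Collects class scores for every test sample over one-shot episodes:
#' each covering pass shuffles the test set, chunks it into query groups
#' that fit the batch alongside one support per class drawn from the
#' training pool, and runs a forward pass. Scores are averaged over
#' `eval_passes` covering passes, then summarised as per-class one-vs-all
#' AUC, macro AUC and balanced accuracy.
#'
#' @param model An `amgnn_model`.
#' @param table The preprocessed [feature_table()].
#' @param labels A [label_set()] providing the evaluation ground truth for
#'   test samples (and support labels for the training pool).
#' @param test_idx Integer indices of the test set.
#' @param train_idx Integer indices of the training pool (defaults to the
#'   model's).
#' @param support_labels Optional [label_set()] used for support labelling
#'   if it should differ from `labels` (e.g. evaluate against latent truth
#'   while supports carry training labels). Defaults to `labels`.
#' @param seed Seed for episode sampling (default: model seed + 1).
#' @return A list with `macro_auc`, `per_class_auc`, `balanced_accuracy`,
#'   `scores` (test x class matrix) and `predictions`.
#' @export
evaluate_amgnn <- function(model, table, labels, test_idx,
                           train_idx = model$train_idx,
                           support_labels = labels,
                           seed = model$config$seed + 1L) {
  config <- model$config
  Xall <- ft_matrix(table)
  Gall <- Xall[, config$graph_features, drop = FALSE]
  lev <- model$class_levels
  scores <- matrix(0, length(test_idx), config$n_classes,
                   dimnames = list(NULL, lev))
  counts <- numeric(length(test_idx))
  with_seed(seed, {
    spc <- config$test_support_per_class
    chunk_size <- config$batch_size - config$n_classes * spc
    for (pass in seq_len(config$eval_passes)) {
      ord <- sample(seq_along(test_idx))
      chunks <- split(ord, ceiling(seq_along(ord) / chunk_size))
      for (ch in chunks) {
        ep <- sample_episode(train_idx, support_labels, config,
                             mode = "test", test_pool = test_idx[ch])
        fw <- amgnn_forward(model$params, Xall[ep$idx, , drop = FALSE],
                            Gall[ep$idx, , drop = FALSE], ep$y_input,
                            config)
        q <- which(!ep$is_support)
        scores[ch, ] <- scores[ch, , drop = FALSE] +
          fw$probs[q, , drop = FALSE]
        counts[ch] <- counts[ch] + 1
      }
    }
  })
  scores <- scores / counts
  y_eval <- as.character(labels$diagnosis)[test_idx]
  ma <- macro_auc(scores, y_eval)
  pred <- lev[max.col(scores, ties.method = "first")]
  list(macro_auc = ma$macro, per_class_auc = ma$per_class,
       balanced_accuracy = balanced_accuracy(pred, y_eval,
                                             classes = lev),
       scores = scores, predictions = pred)
}

#' Paired label-arm experiment
#'
#' Repeats, `n_repeats` times: draw a fresh stratified train/test split,
#' train one model per label arm (e.g. original clinician labels vs
#' cluster-based re-labelled targets) on the identical split, and evaluate
#' both one-shot on the test set. Repeat `r` uses seed `base + r` for
#' every source of randomness. Returns per-repeat paired metrics and a
#' paired t-test on the macro AUC difference (when `n_repeats >= 2`).
#'
#' @param table A preprocessed [feature_table()].
#' @param labels_a,labels_b The two [label_set()] arms; splits are
#'   stratified on `labels_a`.
#' @param config An [amgnn_config()]; its `seed` is the base seed.
#' @param n_repeats Number of repetitions (default 30).
#' @param eval_labels Optional [label_set()] with the evaluation ground
#'   truth (e.g. latent diagnoses for synthetic data). By default each arm
#'   is evaluated against its own labels.
#' @param arm_names Names of the two arms in the report.
#' @return A `metrics_report` (see [aggregate_repeats()]).
#' @export
run_experiment <- function(table, labels_a, labels_b,
                           config = amgnn_config(), n_repeats = 30L,
                           eval_labels = NULL,
                           arm_names = c("original", "relabelled")) {
  if (length(labels_a) != length(labels_b)) {
    stopf("the two label arms differ in length")
  }
  rows <- list()
  for (r in seq_len(n_repeats)) {
    seed_r <- config$seed + r
    split <- split_train_test(labels_a, config$train_fraction, seed = seed_r)
    for (ai in 1:2) {
      arm_labels <- if (ai == 1) labels_a else labels_b
      cfg_r <- config
      cfg_r$seed <- seed_r
      model <- tryCatch(
        train_amgnn(table, arm_labels, cfg_r, train_idx = split$train),
        error = function(e) stopf("repeat %d, arm '%s': %s", r,
                                  arm_names[ai], conditionMessage(e)))
      ev_labels <- if (is.null(eval_labels)) arm_labels else eval_labels
      ev <- evaluate_amgnn(model, table, ev_labels, split$test,
                           train_idx = split$train,
                           support_labels = arm_labels,
                           seed = seed_r + 10000L)
      rows[[length(rows) + 1]] <- data.frame(
        repeat_id = r, arm = arm_names[ai], macro_auc = ev$macro_auc,
        balanced_accuracy = ev$balanced_accuracy, stringsAsFactors = FALSE)
    }
  }
  aggregate_repeats(do.call(rbind, rows))
}
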