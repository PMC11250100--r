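# Certainty-weighted random-forest classifier. The ensemble is fitted by
# `ranger` (single-threaded, seeded, probability trees) behind this
# module's surface; every observation is weighted by the certainty of the
# group assessment (fraction of raters agreeing with the majority), and
# model selection uses grouped leave-one-subject-out cross-validation
# with an exhaustive grid scored by class-support-weighted F1.

#' Random-forest hyperparameter configuration
#'
#' @param n_trees Number of trees (default 300).
#' @param max_depth Maximum tree depth; `NA` = unlimited.
#' @param min_samples_leaf Minimum observations per leaf (default 5) —
#'   the hyperparameter whose tuning matters most for this problem.
#' @param max_features_rule `"sqrt"` (default) or `"all"` features tried
#'   per split.
#' @param seed Integer RNG seed, recorded in every trained model.
#' @return A `forest_config` object.
#' @export
forest_config <- function(n_trees = 300L, max_depth = NA_integer_,
                          min_samples_leaf = 5L,
                          max_features_rule = c("sqrt", "all"),
                          seed = 1L) {
  max_features_rule <- match.arg(max_features_rule)
  stopifnot(n_trees >= 1L, is.na(max_depth) || max_depth >= 1L,
            min_samples_leaf >= 1L)
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = if (is.na(max_depth)) NA_integer_ else as.integer(max_depth),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 max_features_rule = max_features_rule,
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Leave-one-subject-out folds
#'
#' One fold per infant: that infant's epochs form the validation set and
#' every other epoch the training set, so no infant ever appears on both
#' sides of a fold.
#'
#' @param registry data.frame with an `infant_id` column (row order =
#'   epoch order), e.g. from [epoch_registry()].
#' @return List of `list(train, validation)` integer index vectors.
#' @export
loso_folds <- function(registry) {
  ids <- unique(registry$infant_id)
  if (length(ids) < 2L) stop("loso_folds: need at least 2 infants")
  lapply(ids, function(id) {
    val <- which(registry$infant_id == id)
    list(train = setdiff(seq_len(nrow(registry)), val), validation = val)
  })
}

#' Grouped, stratified train/test split
#'
#' Whole infants are assigned to the test side (no infant straddles the
#' split) by a seeded greedy pass that fills per-(age_group, stimulus)
#' quotas of `test_fraction`. When exact stratification is impossible the
#' split is best-effort and the attained per-stratum deviation is
#' attached as attribute `"deviation"`.
#'
#' @param registry data.frame with `infant_id`, `age_group`, `stimulus`.
#' @param test_fraction Fraction of epochs for the test side, in (0, 1).
#' @param seed Integer seed (same seed, same split).
#' @return List of `train` and `test` integer index vectors.
#' @export
grouped_stratified_split <- function(registry, test_fraction, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  strata <- paste(registry$age_group, registry$stimulus, sep = "\r")
  target <- c(table(strata)) * test_fraction
  ids <- unique(registry$infant_id)
  ids <- ids[with_seed_(seed, sample(length(ids)))]
  contribs <- lapply(ids, function(id) {
    tab <- table(strata[registry$infant_id == id])
    v <- stats::setNames(rep(0, length(target)), names(target))
    v[names(tab)] <- tab
    v
  })
  # best-fit greedy: repeatedly move the whole infant whose transfer most
  # reduces the total absolute deviation from the per-stratum quotas
  got <- stats::setNames(rep(0, length(target)), names(target))
  free <- rep(TRUE, length(ids))
  test_ids <- character(0)
  repeat {
    cur <- sum(abs(got - target))
    gains <- vapply(seq_along(ids), function(i) {
      if (!free[i]) return(Inf)
      sum(abs(got + contribs[[i]] - target))
    }, numeric(1))
    best <- which.min(gains)
    if (!is.finite(gains[best]) || gains[best] >= cur) break
    got <- got + contribs[[best]]
    free[best] <- FALSE
    test_ids <- c(test_ids, ids[best])
  }
  test <- which(registry$infant_id %in% test_ids)
  dev <- max(abs(got - target))
  if (dev > 1)
    warning(sprintf("grouped_stratified_split: best-effort split, max stratum deviation %.1f epochs", dev))
  structure(list(train = setdiff(seq_len(nrow(registry)), test), test = test),
            deviation = dev)
}

as_feature_matrix <- function(features) {
  m <- as.matrix(features)
  storage.mode(m) <- "double"
  m
}

training_fingerprint <- function(x, y) {
  # lightweight content fingerprint; detects accidental data swaps
  v <- c(dim(x), sum(x), sum(x^2), range(x), sum(y), length(y))
  paste(sprintf("%.10e", v), collapse = "|")
}

#' Train the certainty-weighted random forest
#'
#' @param features data.frame/matrix of feature values, columns in the
#'   canonical manifest order.
#' @param labels Binary consensus labels (1 = artefact), no `NA`s (drop
#'   tied epochs first).
#' @param weights Per-observation certainty weights, e.g.
#'   `majority_vote(m)$weight`; default all-1.
#' @param config A [forest_config()].
#' @return A `trained_forest`: fitted ensemble, feature manifest, config,
#'   decision threshold (0.5) and a training-set fingerprint.
#' @export
rf_train <- function(features, labels, weights = NULL,
                     config = forest_config()) {
  x <- as_feature_matrix(features)
  y <- as.integer(labels)
  stopifnot(nrow(x) == length(y), !anyNA(y))
  if (length(unique(y)) < 2L)
    stop("rf_train: training set contains a single class")
  if (is.null(weights)) weights <- rep(1, length(y))
  stopifnot(length(weights) == length(y), all(weights > 0))
  p <- ncol(x)
  mtry <- if (config$max_features_rule == "sqrt") max(1L, floor(sqrt(p))) else p
  dat <- data.frame(x, .label = factor(y, levels = c(0L, 1L)),
                    check.names = FALSE)
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = dat,
    num.trees = config$n_trees, mtry = mtry,
    min.node.size = config$min_samples_leaf,
    max.depth = if (is.na(config$max_depth)) 0L else config$max_depth,
    case.weights = weights / mean(weights),
    probability = TRUE, seed = config$seed, num.threads = 1L,
    verbose = FALSE)
  structure(list(forest = fit, manifest = colnames(x), config = config,
                 threshold = 0.5,
                 fingerprint = training_fingerprint(x, y)),
            class = "trained_forest")
}

#' @export
print.trained_forest <- function(x, ...) {
  cat(sprintf("<trained_forest> %d trees, %d features, threshold %.2f, seed %d\n",
              x$config$n_trees, length(x$manifest), x$threshold,
              x$config$seed))
  invisible(x)
}

check_manifest <- function(model, features) {
  got <- colnames(features)
  want <- model$manifest
  if (!identical(got, want)) {
    bad <- c(setdiff(want, got), setdiff(got, want),
             got[got != want[seq_along(got)]])[1L]
    stop("feature manifest mismatch at feature '", bad,
         "': model expects exactly (", paste(want, collapse = ", "), ")")
  }
}

#' Posterior artefact probability
#'
#' Mean over trees of the per-tree class probability: the probability
#' that the rater group would reject the epoch.
#'
#' @param model A `trained_forest`.
#' @param features Feature rows matching the model's manifest (columns
#'   must match by name and order; mismatches error naming the offending
#'   feature).
#' @return Numeric vector of posteriors in `[0, 1]`.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "trained_forest"))
  check_manifest(model, features)
  x <- as.data.frame(as_feature_matrix(features), check.names = FALSE)
  pr <- stats::predict(model$forest, data = x, num.threads = 1L)$predictions
  unname(pr[, "1"])
}

#' Classify epochs at a probability threshold
#'
#' An epoch is called artefact iff its posterior is at or above the
#' threshold (>=, favouring sensitivity at the boundary). The
#' artefact set therefore shrinks monotonically as the threshold rises.
#'
#' @param model A `trained_forest`.
#' @param features Feature rows matching the manifest.
#' @param threshold Decision threshold in `[0, 1]`; defaults to the
#'   model's stored threshold (0.5).
#' @return Integer vector, 1 = artefact.
#' @export
rf_classify <- function(model, features, threshold = NULL) {
  if (is.null(threshold)) threshold <- model$threshold
  stopifnot(threshold >= 0, threshold <= 1)
  as.integer(predict_proba(model, features) >= threshold)
}

#' Class-support-weighted F1 score
#'
#' @param pred,truth Binary vectors.
#' @return F1 of each class weighted by its support in `truth`.
#' @export
weighted_f1 <- function(pred, truth) {
  f1_one <- function(cls) {
    tp <- sum(pred == cls & truth == cls)
    fp <- sum(pred == cls & truth != cls)
    fn <- sum(pred != cls & truth == cls)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }
  support <- c(mean(truth == 0), mean(truth == 1))
  sum(support * c(f1_one(0), f1_one(1)))
}

#' Default hyperparameter grid
#'
#' `min_samples_leaf` gets the widest range: it is the hyperparameter
#' whose tuning visibly moves performance on this problem.
#'
#' @return data.frame of configurations (one row each).
#' @export
default_grid <- function() {
  expand.grid(n_trees = c(100L, 300L), max_depth = c(NA, 5L, 10L),
              min_samples_leaf = c(1L, 5L, 10L, 20L),
              max_features_rule = c("sqrt", "all"),
              stringsAsFactors = FALSE)
}

#' Exhaustive grid search over grouped folds
#'
#' Every grid point is evaluated on every fold; the score is the
#' class-support-weighted F1 averaged over folds. Ties are broken by
#' fewer trees, then shallower depth (unlimited counts as deepest), then
#' larger leaf, then lexicographically — so the winner is deterministic
#' and independent of grid enumeration order.
#'
#' @param features,labels,weights Training data as in [rf_train()].
#' @param grid data.frame of configurations, e.g. [default_grid()].
#' @param folds Folds from [loso_folds()].
#' @param seed Seed passed to each fitted configuration.
#' @return List: `best` ([forest_config()]), `scores` (grid with a
#'   `score` column).
#' @export
grid_search <- function(features, labels, weights = NULL, grid = default_grid(),
                        folds, seed = 1L) {
  stopifnot(nrow(grid) >= 1L)
  x <- as_feature_matrix(features)
  if (is.null(weights)) weights <- rep(1, length(labels))
  score_one <- function(row) {
    cfg <- forest_config(row$n_trees, row$max_depth, row$min_samples_leaf,
                         row$max_features_rule, seed = seed)
    f1s <- vapply(folds, function(fold) {
      tr <- fold$train; va <- fold$validation
      if (length(unique(labels[tr])) < 2L) return(NA_real_)
      m <- rf_train(x[tr, , drop = FALSE], labels[tr], weights[tr], cfg)
      weighted_f1(rf_classify(m, x[va, , drop = FALSE]), labels[va])
    }, numeric(1))
    mean(f1s, na.rm = TRUE)
  }
  scores <- vapply(seq_len(nrow(grid)), function(i) score_one(grid[i, ]),
                   numeric(1))
  depth_key <- ifelse(is.na(grid$max_depth), Inf, grid$max_depth)
  ord <- order(-scores, grid$n_trees, depth_key, -grid$min_samples_leaf,
               grid$max_features_rule)
  best_row <- grid[ord[1L], ]
  list(best = forest_config(best_row$n_trees, best_row$max_depth,
                            best_row$min_samples_leaf,
                            best_row$max_features_rule, seed = seed),
       scores = cbind(grid, score = scores))
}

#' McNemar's test for paired classifier comparison
#'
#' Discordant pairs are epochs one classifier gets right and the other
#' wrong. With fewer than 25 discordant pairs the exact two-sided
#' binomial p is used; otherwise the continuity-corrected chi-square.
#'
#' @param pred_a,pred_b Predictions of the two classifiers.
#' @param truth Reference labels.
#' @return List with `p_value`, `n_discordant`, `method`.
#' @export
mcnemar_test <- function(pred_a, pred_b, truth) {
  stopifnot(length(pred_a) == length(truth), length(pred_b) == length(truth))
  a_ok <- pred_a == truth
  b_ok <- pred_b == truth
  n1 <- sum(a_ok & !b_ok)
  n2 <- sum(!a_ok & b_ok)
  nd <- n1 + n2
  if (nd == 0L)
    return(list(p_value = 1, n_discordant = 0L, method = "exact"))
  if (nd < 25L) {
    p <- min(1, 2 * stats::pbinom(min(n1, n2), nd, 0.5))
    method <- "exact"
  } else {
    chi <- (abs(n1 - n2) - 1)^2 / nd
    p <- stats::pchisq(chi, df = 1L, lower.tail = FALSE)
    method <- "chisq"
  }
  list(p_value = p, n_discordant = as.integer(nd), method = method)
}

#' Serialize / restore a trained model
#'
#' The container embeds the feature manifest, configuration, seed and
#' training fingerprint; predictions after a round trip are
#' bit-identical.
#'
#' @param model A `trained_forest`.
#' @param path File path.
#' @return `path` / the restored model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_forest"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "trained_forest"))
    stop("load_model: not a trained_forest container")
  model
}
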