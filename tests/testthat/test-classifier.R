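# Small separable feature problem used throughout: class 1 sits 6 sd away
# on two of four features.
toy_problem <- function(n = 120, seed = 10) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- cbind(f1 = rnorm(n) + 6 * y, f2 = rnorm(n) - 6 * y,
             f3 = rnorm(n), f4 = rnorm(n))
  list(x = as.data.frame(x), y = y,
       registry = data.frame(infant_id = paste0("i", rep(1:(n / 4), each = 4))))
}

test_that("LOSO folds never split an infant and cover every epoch", {
  reg <- data.frame(infant_id = c("a", "a", "b", "c", "c"))
  folds <- loso_folds(reg)
  expect_length(folds, 3L)
  expect_setequal(unlist(lapply(folds, `[[`, "validation")), 1:5)
  for (f in folds) {
    expect_length(intersect(f$train, f$validation), 0L)
    expect_length(intersect(reg$infant_id[f$train],
                            reg$infant_id[f$validation]), 0L)
    expect_setequal(c(f$train, f$validation), 1:5)
  }
  expect_equal(folds[[1L]]$validation, c(1L, 2L))   # both epochs of infant a
  expect_error(loso_folds(data.frame(infant_id = rep("a", 3))), "2 infants")
})

test_that("grouped stratified split hits the study's 340/70 shape", {
  spec <- sim_spec(seed = 7)
  ds <- gen_dataset(spec, grid = default_registry_grid())
  reg <- ds$registry
  sp <- grouped_stratified_split(reg, test_fraction = 70 / 410, seed = 3)
  expect_length(sp$test, nrow(reg) - length(sp$train))
  expect_lte(abs(length(sp$test) - 70), 2)
  expect_lte(abs(length(sp$train) - 340), 2)
  expect_length(intersect(reg$infant_id[sp$train], reg$infant_id[sp$test]), 0L)
  sp2 <- grouped_stratified_split(reg, test_fraction = 70 / 410, seed = 3)
  expect_identical(sp, sp2)
  # per-stratum proportions near target
  strata <- paste(reg$age_group, reg$stimulus)
  dev <- attr(sp, "deviation")
  expect_lte(dev, 1 + 1e-9)
})

test_that("training is deterministic, weight-scale invariant, and separable", {
  tp <- toy_problem()
  cfg <- forest_config(n_trees = 100L, seed = 5L)
  m1 <- rf_train(tp$x, tp$y, config = cfg)
  m2 <- rf_train(tp$x, tp$y, config = cfg)
  expect_identical(predict_proba(m1, tp$x), predict_proba(m2, tp$x))
  tr_pred <- rf_classify(m1, tp$x)
  expect_equal(confusion_metrics(tr_pred, tp$y)$balanced_accuracy, 1)
  # doubling all weights changes nothing
  w <- runif(length(tp$y), 0.5, 1)
  ma <- rf_train(tp$x, tp$y, weights = w, config = cfg)
  mb <- rf_train(tp$x, tp$y, weights = 2 * w, config = cfg)
  expect_identical(predict_proba(ma, tp$x), predict_proba(mb, tp$x))
  expect_error(rf_train(tp$x, rep(1L, nrow(tp$x))), "single class")
})

test_that("posterior is the mean of per-tree probabilities", {
  tp <- toy_problem(60)
  m <- rf_train(tp$x, tp$y, config = forest_config(n_trees = 3L, seed = 2L))
  post <- predict_proba(m, tp$x)
  per_tree <- stats::predict(m$forest,
                             data = tp$x, predict.all = TRUE,
                             num.threads = 1L)$predictions
  expect_equal(post, rowMeans(per_tree[, 2L, ]), tolerance = 1e-12)
  expect_true(all(post >= 0 & post <= 1))
  # complement sums to one
  expect_equal(post + rowMeans(per_tree[, 1L, ]), rep(1, 60),
               tolerance = 1e-12)
})

test_that("prediction refuses a mismatched feature manifest by name", {
  tp <- toy_problem(40)
  m <- rf_train(tp$x, tp$y)
  bad <- tp$x
  names(bad)[2L] <- "f2_renamed"
  expect_error(predict_proba(m, bad), "f2")
  expect_error(predict_proba(m, tp$x[, c(2, 1, 3, 4)]), "manifest")
})

test_that("threshold semantics are >= with a monotone artefact set", {
  tp <- toy_problem(80)
  m <- rf_train(tp$x, tp$y, config = forest_config(n_trees = 50L, seed = 1L))
  post <- predict_proba(m, tp$x)
  expect_equal(rf_classify(m, tp$x, threshold = 0), rep(1L, 80))
  at1 <- rf_classify(m, tp$x, threshold = 1)
  expect_equal(at1, as.integer(post >= 1))
  prev <- NULL
  for (th in seq(0, 1, by = 0.1)) {
    cur <- which(rf_classify(m, tp$x, threshold = th) == 1L)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("grid search is exhaustive, deterministic and order-invariant", {
  tp <- toy_problem(64, seed = 3)
  folds <- loso_folds(tp$registry)[1:6]
  grid <- expand.grid(n_trees = c(20L, 50L), max_depth = c(NA, 4L),
                      min_samples_leaf = c(1L, 5L),
                      max_features_rule = "sqrt", stringsAsFactors = FALSE)
  gs <- grid_search(tp$x, tp$y, grid = grid, folds = folds, seed = 9L)
  expect_equal(nrow(gs$scores), nrow(grid))
  # same grid in reverse order: same winner, same per-point scores
  gs_rev <- grid_search(tp$x, tp$y, grid = grid[nrow(grid):1, ],
                        folds = folds, seed = 9L)
  expect_equal(gs$best, gs_rev$best)
  merged <- merge(gs$scores, gs_rev$scores,
                  by = c("n_trees", "max_depth", "min_samples_leaf",
                         "max_features_rule"))
  expect_equal(merged$score.x, merged$score.y)
  # single-point grid returns that point
  one <- grid_search(tp$x, tp$y, grid = grid[3, ], folds = folds, seed = 9L)
  expect_equal(one$best$n_trees, grid$n_trees[3])
  expect_equal(one$best$min_samples_leaf, grid$min_samples_leaf[3])
})

test_that("grid search finds a planted depth-dependent optimum", {
  # XOR-style interaction: depth-1 stumps cannot represent it
  set.seed(12)
  n <- 240
  a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
  y <- as.integer(xor(a, b))
  x <- data.frame(f1 = a + rnorm(n, sd = 0.05), f2 = b + rnorm(n, sd = 0.05))
  reg <- data.frame(infant_id = paste0("i", rep(1:40, each = 6)))
  grid <- expand.grid(n_trees = 60L, max_depth = c(1L, 6L),
                      min_samples_leaf = 1L, max_features_rule = "all",
                      stringsAsFactors = FALSE)
  gs <- grid_search(x, y, grid = grid, folds = loso_folds(reg)[1:8], seed = 2L)
  expect_equal(gs$best$max_depth, 6L)
  sc <- gs$scores
  expect_gt(sc$score[sc$max_depth == 6L], sc$score[sc$max_depth == 1L])
})

test_that("McNemar handles exact, chi-square and degenerate regimes", {
  truth <- rep(c(0L, 1L), 50)
  pred <- truth
  expect_equal(mcnemar_test(pred, pred, truth)$p_value, 1)
  # discordant (15, 5): exact two-sided binomial = 2 * P(X <= 5 | 20, .5)
  a_ok <- c(rep(TRUE, 80), rep(TRUE, 15), rep(FALSE, 5))
  b_ok <- c(rep(TRUE, 80), rep(FALSE, 15), rep(TRUE, 5))
  truth2 <- rep(0L, 100)
  pa <- ifelse(a_ok, 0L, 1L)
  pb <- ifelse(b_ok, 0L, 1L)
  r <- mcnemar_test(pa, pb, truth2)
  expect_equal(r$n_discordant, 20L)
  expect_equal(r$p_value, 2 * pbinom(5, 20, 0.5), tolerance = 1e-12)
  expect_equal(r$p_value, 0.0414, tolerance = 1e-3)
  expect_equal(mcnemar_test(pb, pa, truth2)$p_value, r$p_value)
  # large discordant count: continuity-corrected chi-square, cross-checked
  a_ok3 <- c(rep(TRUE, 30), rep(FALSE, 12))
  b_ok3 <- c(rep(FALSE, 30), rep(TRUE, 12))
  truth3 <- rep(0L, 42)
  r3 <- mcnemar_test(ifelse(a_ok3, 0L, 1L), ifelse(b_ok3, 0L, 1L), truth3)
  expect_equal(r3$method, "chisq")
  ref <- stats::mcnemar.test(matrix(c(0, 30, 12, 0), 2), correct = TRUE)
  expect_equal(r3$p_value, unname(ref$p.value), tolerance = 1e-12)
})

test_that("serialization round-trips to bit-identical predictions", {
  tp <- toy_problem(50, seed = 6)
  m <- rf_train(tp$x, tp$y, config = forest_config(n_trees = 40L, seed = 3L))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict_proba(m2, tp$x), predict_proba(m, tp$x))
  expect_identical(m2$fingerprint, m$fingerprint)
  expect_identical(m2$manifest, m$manifest)
})
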