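test_that("confusion metrics reproduce the balanced-accuracy identity", {
  # a panel giving sensitivity 0.76 and specificity 0.95
  truth <- c(rep(1L, 100), rep(0L, 100))
  pred <- c(rep(1L, 76), rep(0L, 24), rep(0L, 95), rep(1L, 5))
  cm <- confusion_metrics(pred, truth)
  expect_equal(cm$sensitivity, 0.76)
  expect_equal(cm$specificity, 0.95)
  expect_equal(cm$balanced_accuracy, 0.855)
  expect_equal(cm$balanced_accuracy, (cm$sensitivity + cm$specificity) / 2)
  expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 200)
  expect_equal(confusion_metrics(truth, truth)$balanced_accuracy, 1)
  expect_equal(confusion_metrics(1L - truth, truth)$balanced_accuracy, 0)
  expect_error(confusion_metrics(pred, rep(1L, 200)), "single class")
})

test_that("AUC equals the pair-counting concordance oracle", {
  set.seed(5)
  for (rep_i in 1:5) {
    n <- 150
    truth <- rbinom(n, 1, 0.35)
    post <- round(runif(n), 2)                     # ties on purpose
    post[truth == 1] <- post[truth == 1] + rnorm(sum(truth), 0.2, 0.3)
    post <- pmin(pmax(post, 0), 1)
    r <- roc_curve(post, truth)
    pairs <- expand.grid(i = which(truth == 1), j = which(truth == 0))
    conc <- mean(ifelse(post[pairs$i] > post[pairs$j], 1,
                        ifelse(post[pairs$i] == post[pairs$j], 0.5, 0)))
    expect_equal(r$auc, conc, tolerance = 1e-12)
  }
})

test_that("ROC endpoints and reference cases behave", {
  truth <- c(rep(1L, 20), rep(0L, 20))
  sep <- c(runif(20, 0.8, 1), runif(20, 0, 0.2))
  expect_equal(roc_curve(sep, truth)$auc, 1)
  set.seed(6)
  big_truth <- rbinom(4000, 1, 0.5)
  expect_equal(roc_curve(runif(4000), big_truth)$auc, 0.5, tolerance = 0.05)
  r <- roc_curve(sep, truth)
  expect_equal(r$curve$fpr[1], 0); expect_equal(r$curve$tpr[1], 0)
  expect_equal(utils::tail(r$curve$fpr, 1), 1)
  expect_equal(utils::tail(r$curve$tpr, 1), 1)
  # independent implementation agrees
  pr <- suppressMessages(pROC::roc(truth, sep, quiet = TRUE))
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("threshold sweep of the classifier lands on the ROC curve", {
  tp_truth <- rep(c(0L, 1L), 40)
  set.seed(7)
  x <- data.frame(f1 = rnorm(80) + 2.5 * tp_truth, f2 = rnorm(80))
  m <- rf_train(x, tp_truth, config = forest_config(n_trees = 60L, seed = 2L))
  post <- predict_proba(m, x)
  r <- roc_curve(post, tp_truth)
  for (th in unique(post)) {
    cm <- confusion_metrics(as.integer(post >= th), tp_truth)
    hit <- any(abs(r$curve$fpr - (1 - cm$specificity)) < 1e-12 &
               abs(r$curve$tpr - cm$sensitivity) < 1e-12)
    expect_true(hit)
  }
})

test_that("permutation importance isolates informative features", {
  set.seed(8)
  n <- 200
  truth <- rbinom(n, 1, 0.5)
  x <- data.frame(signal = rnorm(n) + 3 * truth, noise = rnorm(n))
  m <- rf_train(x, truth, config = forest_config(n_trees = 100L, seed = 4L))
  # importance scored on held-out data, where memorised noise splits
  # carry no information
  truth_new <- rbinom(n, 1, 0.5)
  x_new <- data.frame(signal = rnorm(n) + 3 * truth_new, noise = rnorm(n))
  imp <- permutation_importance(m, x_new, truth_new, n_perm = 30L, seed = 11L)
  sig <- imp[imp$feature == "signal", ]
  noi <- imp[imp$feature == "noise", ]
  # permuting the lone informative feature collapses towards chance
  expect_gt(sig$mean_drop, 0.3)
  # a pure-noise feature moves nothing beyond its own interval width
  expect_lt(abs(noi$mean_drop), 2 * (noi$ci_hi - noi$ci_lo) + 1e-3)
  expect_true(all(imp$ci_lo <= imp$mean_drop & imp$mean_drop <= imp$ci_hi))
  # duplicated informative feature masks itself
  x2 <- data.frame(signal = x$signal, twin = x$signal + rnorm(n, sd = 1e-3),
                   noise = x$noise)
  x2_new <- data.frame(signal = x_new$signal,
                       twin = x_new$signal + rnorm(n, sd = 1e-3),
                       noise = x_new$noise)
  m2 <- rf_train(x2, truth, config = forest_config(n_trees = 100L, seed = 4L))
  imp2 <- permutation_importance(m2, x2_new, truth_new, n_perm = 30L,
                                 seed = 11L)
  expect_lt(imp2$mean_drop[imp2$feature == "signal"], sig$mean_drop)
})

test_that("univariate logit screening is calibrated and powered", {
  set.seed(9)
  labels <- rep(c(0L, 1L), 100)
  same <- rnorm(200)
  r0 <- feature_univariate_p(same, labels)
  expect_gt(r0$p_value, 0.05)
  shifted <- rnorm(200) + 3 * labels                 # d = 3
  expect_lt(feature_univariate_p(shifted, labels)$p_value, 1e-6)
  # perfect separation flagged, not Wald-ed
  sep <- c(rnorm(100, 0), rnorm(100, 50))[order(labels)]
  sep <- ifelse(labels == 1, abs(rnorm(200)) + 10, -abs(rnorm(200)))
  rs <- feature_univariate_p(sep, labels)
  expect_true(rs$separation)
  expect_equal(rs$p_value, 0)
  # null calibration: permuted labels give uniform p-values
  ps <- vapply(1:120, function(i) {
    feature_univariate_p(same, sample(labels))$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("SNR divides the evoked peak by the baseline spread", {
  fs <- 1000
  baseline <- rep(c(-2, 2), 250)                     # sd ~ 2
  post <- c(rep(0, 400), 1, rep(0, 599))             # peak 1 uV
  ep <- eeg_epoch(c(baseline, post), fs = fs, event_offset = 0.5)
  expect_equal(snr(ep), 1 / stats::sd(baseline), tolerance = 1e-12)
  sc <- ep; sc$samples <- 3.7 * ep$samples
  expect_equal(snr(sc), snr(ep), tolerance = 1e-12)
  flat <- eeg_epoch(c(rep(1, 500), post), fs = fs, event_offset = 0.5)
  expect_error(snr(flat), "zero-variance")
  # parameter recovery on generated epochs: strong deflection, weak noise
  spec <- generator_spec(seed = 1, background_rms = 4, erp_amplitude = 120)
  vals <- vapply(1:20, function(s)
    snr(gen_clean_epoch(spec, seed = s)), numeric(1))
  expect_equal(median(vals), 120 / 4, tolerance = 0.25)
})

test_that("subgroup accuracy is bootstrapped per stratum", {
  set.seed(10)
  truth <- rbinom(300, 1, 0.3)
  pred <- ifelse(runif(300) < 0.15, 1L - truth, truth)
  groups <- rep(c("g1", "g2"), 150)
  res <- accuracy_by_subgroup(pred, truth, groups, n_boot = 200L, seed = 2L)
  expect_equal(nrow(res), 2L)
  expect_true(all(res$ci_lo <= res$balanced_accuracy &
                  res$balanced_accuracy <= res$ci_hi))
  # single group equals the global metric
  one <- accuracy_by_subgroup(pred, truth, rep("all", 300), n_boot = 50L)
  expect_equal(one$balanced_accuracy,
               confusion_metrics(pred, truth)$balanced_accuracy)
  # a one-class group is skipped with a warning
  g3 <- c(rep("solo", 5), rep("rest", 295))
  truth3 <- c(rep(1L, 5), truth[6:300])
  expect_warning(accuracy_by_subgroup(pred, truth3, g3, n_boot = 50L),
                 "skipped")
})

test_that("evaluation reports write JSON, Markdown and ROC CSV", {
  set.seed(11)
  truth <- rbinom(120, 1, 0.4)
  post <- pmin(pmax(truth * 0.6 + runif(120, 0, 0.4), 0), 1)
  rep_ <- eval_report(post, truth)
  expect_equal(rep_$balanced_accuracy,
               (rep_$sensitivity + rep_$specificity) / 2)
  stem <- file.path(withr::local_tempdir(), "report")
  write_eval_report(rep_, stem)
  expect_true(file.exists(paste0(stem, ".json")))
  expect_true(file.exists(paste0(stem, ".md")))
  roc_back <- utils::read.csv(paste0(stem, "_roc.csv"))
  expect_equal(nrow(roc_back), nrow(rep_$roc))
})
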