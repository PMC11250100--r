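# Evaluation battery: confusion metrics (artefact = positive class),
# ROC/AUC, permutation feature importance, univariate binomial-logit
# feature screening, evoked-response SNR, and bootstrap subgroup
# accuracy.

#' Confusion-matrix metrics
#'
#' Sensitivity = tp/(tp+fn) with artefact (1) as the positive class,
#' specificity = tn/(tn+fp), balanced accuracy = their mean.
#'
#' @param pred,truth Binary vectors (1 = artefact); `truth` must contain
#'   both classes.
#' @return List: `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `balanced_accuracy`.
#' @export
confusion_metrics <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  if (length(unique(truth)) < 2L)
    stop("confusion_metrics: truth contains a single class")
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  tn <- sum(pred == 0 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = sens, specificity = spec,
       balanced_accuracy = (sens + spec) / 2)
}

#' ROC curve and AUC
#'
#' Operating points at every unique posterior value (plus the extremes),
#' with the artefact call made at posterior >= threshold. The AUC is the
#' trapezoidal area, which equals the concordance probability (ties
#' counted half).
#'
#' @param posteriors Numeric scores in `[0, 1]`.
#' @param truth Binary vector containing both classes.
#' @return List: `curve` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_curve <- function(posteriors, truth) {
  stopifnot(length(posteriors) == length(truth))
  if (length(unique(truth)) < 2L)
    stop("roc_curve: truth contains a single class")
  thr <- c(sort(unique(posteriors), decreasing = TRUE), -Inf)
  thr <- c(Inf, thr)
  P <- sum(truth == 1); N <- sum(truth == 0)
  tpr <- vapply(thr, function(t) sum(posteriors >= t & truth == 1) / P,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(posteriors >= t & truth == 0) / N,
                numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Permutation feature importance
#'
#' Each feature column is shuffled `n_perm` times; the importance is the
#' mean drop in balanced accuracy (the headline metric here, rather than
#' raw accuracy) with a 95% normal interval over the permutations.
#' Correlated features can mask one another: permuting one leaves its
#' information available through the others, deflating both importances.
#'
#' @param model A `trained_forest`.
#' @param features Feature rows matching the model manifest.
#' @param truth Binary reference labels.
#' @param n_perm Number of permutations per feature (default 100).
#' @param seed Integer seed (reproducible shuffles).
#' @param threshold Decision threshold (default the model's).
#' @return data.frame: `feature`, `mean_drop`, `ci_lo`, `ci_hi`.
#' @export
permutation_importance <- function(model, features, truth, n_perm = 100L,
                                   seed = 1L, threshold = NULL) {
  x <- as_feature_matrix(features)
  check_manifest(model, x)
  base <- confusion_metrics(rf_classify(model, x, threshold), truth)$balanced_accuracy
  p <- ncol(x)
  res <- with_seed_(seed, {
    out <- matrix(NA_real_, n_perm, p)
    for (j in seq_len(p)) {
      for (r in seq_len(n_perm)) {
        xp <- x
        xp[, j] <- x[sample(nrow(x)), j]
        out[r, j] <- base -
          confusion_metrics(rf_classify(model, xp, threshold), truth)$balanced_accuracy
      }
    }
    out
  })
  mu <- colMeans(res)
  se <- apply(res, 2L, stats::sd) / sqrt(n_perm)
  data.frame(feature = colnames(x), mean_drop = mu,
             ci_lo = mu - 1.96 * se, ci_hi = mu + 1.96 * se,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Univariate binomial-logit screening p-value
#'
#' Single-predictor logistic regression of the label on one feature;
#' two-sided Wald p for the slope. Perfect separation is reported as
#' p = 0 with a `separation` flag rather than a fragile Wald statistic.
#'
#' @param values Feature values.
#' @param labels Binary labels with at least 2 observations per class.
#' @return List: `p_value`, `slope`, `separation`.
#' @export
feature_univariate_p <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  if (min(table(labels)) < 2L)
    stop("feature_univariate_p: need >=2 observations per class")
  sep <- max(values[labels == 0]) < min(values[labels == 1]) ||
    max(values[labels == 1]) < min(values[labels == 0])
  if (sep) return(list(p_value = 0, slope = NA_real_, separation = TRUE))
  fit <- suppressWarnings(
    stats::glm(labels ~ values, family = stats::binomial()))
  co <- summary(fit)$coefficients
  list(p_value = co["values", "Pr(>|z|)"], slope = co["values", "Estimate"],
       separation = FALSE)
}

#' Evoked-response signal-to-noise ratio of an epoch
#'
#' `max |post-stimulus amplitude| / sd(pre-stimulus baseline)` (the
#' peak-to-peak ERP magnitude is available via `erp_mag = "p2p"`).
#'
#' @param epoch An `eeg_epoch` with a non-empty baseline
#'   (`event_offset > 0`).
#' @param erp_mag `"absmax"` (default) or `"p2p"`.
#' @return Dimensionless SNR.
#' @export
snr <- function(epoch, erp_mag = c("absmax", "p2p")) {
  erp_mag <- match.arg(erp_mag)
  if (epoch$event_offset <= 0) stop("snr: empty pre-stimulus baseline")
  split_at <- round(epoch$event_offset * epoch$fs)
  baseline <- epoch$samples[seq_len(split_at)]
  post <- epoch$samples[(split_at + 1L):length(epoch$samples)]
  s <- stats::sd(baseline)
  if (!is.finite(s) || s <= 0) stop("snr: zero-variance baseline")
  mag <- if (erp_mag == "absmax") max(abs(post)) else diff(range(post))
  mag / s
}

#' Balanced accuracy by subgroup with bootstrap confidence intervals
#'
#' Splits the scored epochs by stimulus, age group or rater-agreement
#' count and reports per-group balanced accuracy with a seeded
#' percentile bootstrap (1000 resamples). Groups missing a class are
#' skipped with a warning.
#'
#' @param pred,truth Binary vectors.
#' @param groups Grouping vector (same length).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return data.frame: `group`, `n`, `balanced_accuracy`, `ci_lo`,
#'   `ci_hi`.
#' @export
accuracy_by_subgroup <- function(pred, truth, groups, n_boot = 1000L,
                                 seed = 1L) {
  stopifnot(length(pred) == length(truth), length(groups) == length(truth))
  out <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(unique(truth[idx])) < 2L) {
      warning("accuracy_by_subgroup: group '", g,
              "' lacks a class; skipped")
      next
    }
    ba <- confusion_metrics(pred[idx], truth[idx])$balanced_accuracy
    boots <- with_seed_(seed, vapply(seq_len(n_boot), function(b) {
      i <- sample(idx, length(idx), replace = TRUE)
      if (length(unique(truth[i])) < 2L) return(NA_real_)
      confusion_metrics(pred[i], truth[i])$balanced_accuracy
    }, numeric(1)))
    ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      group = as.character(g), n = length(idx), balanced_accuracy = ba,
      ci_lo = ci[1L], ci_hi = ci[2L], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Full evaluation report
#'
#' Confusion metrics, kappa against the consensus, ROC and AUC in one
#' container; [write_eval_report()] emits it as JSON plus a Markdown
#' summary and the ROC points as CSV.
#'
#' @param posteriors Model posteriors.
#' @param truth Binary consensus labels.
#' @param threshold Decision threshold (default 0.5).
#' @return List of class `eval_report`.
#' @export
eval_report <- function(posteriors, truth, threshold = 0.5) {
  pred <- as.integer(posteriors >= threshold)
  cm <- confusion_metrics(pred, truth)
  roc <- roc_curve(posteriors, truth)
  structure(c(cm, list(kappa_vs_consensus = cohens_kappa(pred, truth),
                       auc = roc$auc, roc = roc$curve,
                       threshold = threshold, n = length(truth))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> n=%d  sens=%.3f  spec=%.3f  ",
                     "balanced acc=%.3f  kappa=%.3f  AUC=%.3f\n"),
              x$n, x$sensitivity, x$specificity, x$balanced_accuracy,
              x$kappa_vs_consensus, x$auc))
  invisible(x)
}

#' @rdname eval_report
#' @param report An `eval_report`.
#' @param stem Output path stem; writes `<stem>.json`, `<stem>.md`,
#'   `<stem>_roc.csv`.
#' @export
write_eval_report <- function(report, stem) {
  stopifnot(inherits(report, "eval_report"))
  scalar <- report[c("tp", "fp", "tn", "fn", "sensitivity", "specificity",
                     "balanced_accuracy", "kappa_vs_consensus", "auc",
                     "threshold", "n")]
  json <- paste0("{", paste(sprintf('"%s": %.10g', names(scalar),
                                    as.numeric(scalar)), collapse = ", "),
                 "}")
  writeLines(json, paste0(stem, ".json"))
  md <- c("# Artefact-detector evaluation", "",
          sprintf("- epochs scored: %d", report$n),
          sprintf("- sensitivity: %.3f", report$sensitivity),
          sprintf("- specificity: %.3f", report$specificity),
          sprintf("- balanced accuracy: %.3f", report$balanced_accuracy),
          sprintf("- Cohen's kappa vs consensus: %.3f",
                  report$kappa_vs_consensus),
          sprintf("- ROC AUC: %.3f", report$auc),
          sprintf("- decision threshold: %.2f", report$threshold))
  writeLines(md, paste0(stem, ".md"))
  utils::write.csv(report$roc, paste0(stem, "_roc.csv"), row.names = FALSE)
  invisible(stem)
}
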