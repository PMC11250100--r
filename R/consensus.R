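# Ground truth from multi-rater panels: majority vote with a certainty
# weight (fraction of raters agreeing with the majority), pairwise
# Cohen's kappa, and leave-one-rater-out consensus so that no rater —
# nor the classifier, scored as an eighth rater — is judged against a
# truth that includes their own votes.

#' Construct a rater-label matrix
#'
#' @param labels epochs x raters matrix with cells in \{0, 1\}
#'   (1 = artefact). Row names are epoch ids, column names rater ids
#'   (generated when absent).
#' @param rater_tier Optional character vector per rater,
#'   `"experienced"` or `"expert"`.
#' @return A `rater_matrix` object.
#' @export
rater_matrix <- function(labels, rater_tier = NULL) {
  m <- as.matrix(labels)
  storage.mode(m) <- "integer"
  if (ncol(m) < 2L) stop("rater_matrix: need at least 2 raters")
  if (anyNA(m)) stop("rater_matrix: missing cells are not allowed")
  if (!all(m %in% c(0L, 1L))) stop("rater_matrix: cells must be 0 or 1")
  if (is.null(colnames(m))) colnames(m) <- paste0("R", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("e", seq_len(nrow(m)))
  if (!is.null(rater_tier)) {
    stopifnot(length(rater_tier) == ncol(m),
              all(rater_tier %in% c("experienced", "expert")))
  }
  structure(m, class = c("rater_matrix", "matrix"), rater_tier = rater_tier)
}

#' Majority-vote consensus labels with certainty weights
#'
#' Per epoch: the modal rating, the number of raters agreeing with it,
#' and the certainty weight `n_agree / n_raters`. With an even panel an
#' exact split is flagged `tied` (label `NA`); the caller's policy
#' decides (see [loro_truth()]).
#'
#' @param m A `rater_matrix`.
#' @return data.frame with columns `epoch_id`, `label`, `n_agree`,
#'   `weight`, `tied`.
#' @export
majority_vote <- function(m) {
  stopifnot(inherits(m, "rater_matrix"))
  R <- ncol(m)
  votes <- rowSums(m)
  tied <- votes * 2L == R
  label <- ifelse(tied, NA_integer_, as.integer(votes > R / 2))
  n_agree <- ifelse(label == 1L, votes, R - votes)
  n_agree[tied] <- NA_integer_
  data.frame(epoch_id = rownames(m), label = label,
             n_agree = as.integer(n_agree), weight = n_agree / R,
             tied = tied, row.names = NULL, stringsAsFactors = FALSE)
}

#' Cohen's kappa between two binary label vectors
#'
#' Chance-corrected agreement, `(p_o - p_e) / (1 - p_e)` with the chance
#' term from the marginals. Degenerate case `p_e = 1` (both raters
#' constant): defined as 1 when they agree everywhere, else 0.
#'
#' @param a,b Equal-length binary vectors.
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 1L)
  n <- length(a)
  po <- mean(a == b)
  pa1 <- mean(a == 1); pb1 <- mean(b == 1)
  pe <- pa1 * pb1 + (1 - pa1) * (1 - pb1)
  if (abs(1 - pe) < .Machine$double.eps^0.5)
    return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Pairwise Cohen's kappa table and per-rater means
#'
#' A rater's mean kappa against all other raters indicates how well their
#' decisions align with the group; the diagonal is excluded from means.
#'
#' @param m A `rater_matrix`.
#' @return List with `kappa` (symmetric raters x raters matrix, `NA`
#'   diagonal), `rater_mean` (named vector), and `tier_mean` (mean of
#'   within-tier pairs, when tiers are attached).
#' @export
pairwise_kappa <- function(m) {
  stopifnot(inherits(m, "rater_matrix"))
  R <- ncol(m)
  K <- matrix(NA_real_, R, R, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(R - 1L)) {
    for (j in (i + 1L):R) {
      K[i, j] <- K[j, i] <- cohens_kappa(m[, i], m[, j])
    }
  }
  rater_mean <- rowMeans(K, na.rm = TRUE)
  tier_mean <- NULL
  tiers <- attr(m, "rater_tier")
  if (!is.null(tiers)) {
    tier_mean <- vapply(unique(tiers), function(tr) {
      idx <- which(tiers == tr)
      if (length(idx) < 2L) return(NA_real_)
      mean(K[idx, idx], na.rm = TRUE)
    }, numeric(1))
  }
  list(kappa = K, rater_mean = rater_mean, tier_mean = tier_mean)
}

#' Leave-one-rater-out consensus truth
#'
#' Majority vote among all raters except `held_out`; with an even number
#' of remaining raters an exact split marks the epoch `NA` (excluded from
#' that rater's accuracy computation rather than given a fabricated
#' label). Model predictions are scored the same way, treating the
#' classifier as one more rater.
#'
#' @param m A `rater_matrix`.
#' @param held_out Rater id or column index to hold out.
#' @return Integer vector of labels (`NA` = tied, excluded), one per
#'   epoch.
#' @export
loro_truth <- function(m, held_out) {
  stopifnot(inherits(m, "rater_matrix"), ncol(m) >= 3L)
  if (is.character(held_out)) held_out <- match(held_out, colnames(m))
  if (is.na(held_out) || held_out < 1L || held_out > ncol(m))
    stop("loro_truth: unknown rater")
  rest <- m[, -held_out, drop = FALSE]
  R <- ncol(rest)
  votes <- rowSums(rest)
  out <- as.integer(votes > R / 2)
  out[votes * 2L == R] <- NA_integer_
  out
}

#' Score a prediction vector as an additional rater
#'
#' Balanced accuracy and kappa of `pred` against the panel's full
#' consensus, with tied consensus epochs excluded — the scheme used for
#' every human rater via [loro_truth()].
#'
#' @param pred Binary predictions, one per epoch of `m`.
#' @param m A `rater_matrix`.
#' @return List with `balanced_accuracy`, `kappa`, `n_scored`.
#' @export
score_as_rater <- function(pred, m) {
  stopifnot(length(pred) == nrow(m))
  truth <- majority_vote(m)$label
  keep <- !is.na(truth)
  cm <- confusion_metrics(pred[keep], truth[keep])
  list(balanced_accuracy = cm$balanced_accuracy,
       kappa = cohens_kappa(pred[keep], truth[keep]),
       n_scored = sum(keep))
}
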