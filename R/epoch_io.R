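# Tabular dialects
#
# Epoch table: one row per epoch. Header is
#   infant_id, age_group, stimulus, fs, event_offset, s0001 ... sNNNN
# with voltages in microvolts, UTF-8, "." decimal separator, header
# mandatory. Numbers are written with 17 significant digits so the
# round trip is exact at double precision.
#
# Feature table: header = feature names in the canonical manifest order
# (see `feature_manifest()`), optionally followed by a `label` column.
#
# Rater matrix: rows = epoch ids, columns = rater ids, cells in {0,1}.

fmt_num <- function(x) sprintf("%.17g", x)

sample_col_names <- function(n) sprintf("s%04d", seq_len(n))

#' Write a list of epochs as a CSV epoch table
#'
#' @param epochs List of `eeg_epoch` objects, all with the same length and
#'   sampling rate.
#' @param path Output file path.
#' @param sep Field separator, `","` (CSV) or `"\t"` (TSV).
#' @return `path`, invisibly.
#' @export
write_epoch_table <- function(epochs, path, sep = ",") {
  stopifnot(length(epochs) >= 1L)
  lapply(epochs, validate_epoch)
  n <- length(epochs[[1L]]$samples)
  if (!all(vapply(epochs, function(e) length(e$samples), integer(1)) == n))
    stop("write_epoch_table: epochs differ in length")
  header <- c("infant_id", "age_group", "stimulus", "fs", "event_offset",
              sample_col_names(n))
  rows <- vapply(epochs, function(e) {
    paste(c(e$infant_id, e$age_group, e$stimulus, fmt_num(e$fs),
            fmt_num(e$event_offset), fmt_num(e$samples)), collapse = sep)
  }, character(1))
  writeLines(c(paste(header, collapse = sep), rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read an epoch table
#'
#' Dialect violations (wrong column count, non-numeric sample, unknown
#' stimulus or age-group label) raise an error naming the offending data
#' row. Epoch order in the returned list equals row order in the file.
#'
#' @param path CSV/TSV file in the epoch-table dialect.
#' @param sep Field separator; guessed from the header when `NULL`.
#' @return List of `eeg_epoch` objects.
#' @export
read_epoch_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("read_epoch_table: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("read_epoch_table: empty file: ", path)
  if (is.null(sep)) sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  header <- strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]]
  meta_cols <- c("infant_id", "age_group", "stimulus", "fs", "event_offset")
  if (length(header) < 6L || !identical(header[1:5], meta_cols))
    stop("read_epoch_table: header must start with ",
         paste(meta_cols, collapse = ", "))
  n <- length(header) - 5L
  body <- lines[-1L]
  body <- body[nzchar(body)]
  out <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[[i]], sep, fixed = TRUE)[[1L]]
    if (length(f) != n + 5L)
      stop(sprintf("read_epoch_table: row %d has %d fields, expected %d",
                   i, length(f), n + 5L))
    nums <- suppressWarnings(as.numeric(f[4:(n + 5L)]))
    if (anyNA(nums)) {
      bad <- which(is.na(nums))[1L]
      stop(sprintf("read_epoch_table: row %d: non-numeric value '%s' in column %s",
                   i, f[3L + bad], header[3L + bad]))
    }
    ep <- tryCatch(
      eeg_epoch(samples = nums[-(1:2)], fs = nums[1L], event_offset = nums[2L],
                stimulus = f[3L], infant_id = f[1L], age_group = f[2L]),
      error = function(e)
        stop(sprintf("read_epoch_table: row %d: %s", i, conditionMessage(e)),
             call. = FALSE))
    out[[i]] <- ep
  }
  out
}

#' Write a feature table
#'
#' @param features A data.frame or matrix of feature values, one row per
#'   epoch, columns in the canonical manifest order; or a list of named
#'   numeric vectors sharing one ordering (inconsistent orderings error).
#' @param path Output CSV path.
#' @param labels Optional vector of binary labels (1 = artefact), appended
#'   as a final `label` column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, labels = NULL) {
  if (is.list(features) && !is.data.frame(features)) {
    if (length(features)) {
      ord <- names(features[[1L]])
      ok <- vapply(features, function(v) identical(names(v), ord), logical(1))
      if (!all(ok))
        stop("write_feature_table: inconsistent feature orderings across vectors")
      features <- do.call(rbind, lapply(features, function(v)
        as.data.frame(as.list(v), check.names = FALSE)))
    } else {
      features <- as.data.frame(
        matrix(numeric(0), nrow = 0, ncol = length(feature_manifest()),
               dimnames = list(NULL, feature_manifest())))
    }
  }
  features <- as.data.frame(features, check.names = FALSE)
  header <- names(features)
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(features))
    header <- c(header, "label")
  }
  rows <- character(nrow(features))
  for (i in seq_len(nrow(features))) {
    vals <- fmt_num(as.numeric(features[i, ]))
    if (!is.null(labels)) vals <- c(vals, as.character(labels[i]))
    rows[i] <- paste(vals, collapse = ",")
  }
  writeLines(c(paste(header, collapse = ","), rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return data.frame of features (and `label` column when present).
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Write / read a rater-label matrix
#'
#' The CSV carries rows = epoch ids, columns = rater ids, cells in
#' \{0, 1\} (1 = artefact). Rater experience tiers travel in an optional
#' sidecar file of `rater_id,tier` pairs.
#'
#' @param m A `rater_matrix` (see [rater_matrix()]).
#' @param path Output CSV path.
#' @param tier_path Optional sidecar path for the tier map.
#' @return `path`, invisibly.
#' @export
write_rater_matrix <- function(m, path, tier_path = NULL) {
  stopifnot(inherits(m, "rater_matrix"))
  df <- as.data.frame(unclass(m))
  utils::write.csv(cbind(epoch_id = rownames(m), df), path,
                   row.names = FALSE, quote = FALSE)
  if (!is.null(tier_path)) {
    tiers <- attr(m, "rater_tier")
    utils::write.csv(data.frame(rater_id = colnames(m), tier = tiers),
                     tier_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_rater_matrix
#' @export
read_rater_matrix <- function(path, tier_path = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  tiers <- NULL
  if (!is.null(tier_path)) {
    td <- utils::read.csv(tier_path)
    tiers <- stats::setNames(td$tier, td$rater_id)[colnames(m)]
  }
  rater_matrix(m, rater_tier = tiers)
}
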