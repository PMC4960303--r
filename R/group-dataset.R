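#' Multi-subject region-by-time dataset
#'
#' Container for `k` subjects' recordings of the same `p` regions over the
#' same `n` timepoints, sampled every `tr` seconds. All subjects must share
#' region order and series length; analyses assume the rows have been
#' z-scored with [zscore_subjects()] (Pearson correlation is invariant to
#' the scaling, so raw data give identical ISFC/FC values, but stored
#' intermediates are only comparable after standardization).
#'
#' @param subjects list of `p x n` numeric matrices, one per subject.
#' @param tr sampling interval in seconds (the repetition time).
#' @param region_labels character vector of length `p`; defaults to the
#'   rownames of the first subject or `R1..Rp`.
#' @param condition free-form condition tag (e.g. `"intact"`, `"rest"`).
#' @return An object of class `group_dataset` with elements `subjects`,
#'   `tr`, `region_labels`, `condition` and the dimensions `k`, `p`, `n`.
#' @examples
#' xs <- replicate(3, matrix(rnorm(40), 4, 10), simplify = FALSE)
#' ds <- group_dataset(xs, tr = 1.5)
#' ds$k; ds$p; ds$n
#' @export
group_dataset <- function(subjects, tr, region_labels = NULL,
                          condition = "unspecified") {
  if (!is.list(subjects) || length(subjects) == 0L)
    stop("no subjects: 'subjects' must be a non-empty list of matrices")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("'tr' must be a single positive number of seconds")
  subjects <- lapply(subjects, function(x) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  })
  p <- nrow(subjects[[1L]])
  n <- ncol(subjects[[1L]])
  for (i in seq_along(subjects)) {
    if (nrow(subjects[[i]]) != p)
      stop(sprintf("region mismatch: subject %d has %d regions, expected %d",
                   i, nrow(subjects[[i]]), p))
    if (ncol(subjects[[i]]) != n)
      stop(sprintf("timepoint mismatch: subject %d has %d timepoints, expected %d",
                   i, ncol(subjects[[i]]), n))
    if (!all(is.finite(subjects[[i]])))
      stop(sprintf("subject %d contains non-finite values", i))
  }
  if (is.null(region_labels)) {
    region_labels <- rownames(subjects[[1L]])
    if (is.null(region_labels)) region_labels <- paste0("R", seq_len(p))
  }
  if (length(region_labels) != p)
    stop("'region_labels' must have one entry per region")
  subjects <- lapply(subjects, function(x) {
    dimnames(x) <- list(region_labels, NULL)
    x
  })
  structure(
    list(subjects = subjects, tr = tr, region_labels = region_labels,
         condition = condition, k = length(subjects), p = p, n = n),
    class = "group_dataset"
  )
}

#' @export
print.group_dataset <- function(x, ...) {
  cat(sprintf("group_dataset: %d subjects x %d regions x %d timepoints (TR %.3g s, condition '%s')\n",
              x$k, x$p, x$n, x$tr, x$condition))
  invisible(x)
}

#' Read parcellated time-series tables into a group dataset
#'
#' One tab-separated table per subject: regions as rows, a leading label
#' column named `region`, remaining columns the timepoints. All files must
#' agree in region set/order and series length.
#'
#' @param paths character vector of TSV file paths, one per subject.
#' @param tr sampling interval in seconds.
#' @param condition condition tag stored on the dataset.
#' @return A [group_dataset()]; no z-scoring is applied.
#' @seealso [write_parcellated()]
#' @export
load_parcellated <- function(paths, tr, condition = "unspecified") {
  if (length(paths) == 0L) stop("no subjects: empty file list")
  subjects <- vector("list", length(paths))
  labels <- NULL
  for (i in seq_along(paths)) {
    tab <- utils::read.delim(paths[i], check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (!"region" %in% names(tab))
      stop(sprintf("file '%s' lacks a 'region' column", paths[i]))
    lab <- as.character(tab$region)
    x <- as.matrix(tab[, setdiff(names(tab), "region"), drop = FALSE])
    rownames(x) <- lab
    if (is.null(labels)) labels <- lab
    else if (!identical(lab, labels))
      stop(sprintf("region mismatch: file '%s' disagrees with '%s'",
                   paths[i], paths[1L]))
    subjects[[i]] <- x
  }
  n1 <- ncol(subjects[[1L]])
  for (i in seq_along(subjects))
    if (ncol(subjects[[i]]) != n1)
      stop(sprintf("timepoint mismatch: file '%s' has %d timepoints, expected %d",
                   paths[i], ncol(subjects[[i]]), n1))
  group_dataset(subjects, tr = tr, region_labels = labels,
                condition = condition)
}

#' Write a group dataset as per-subject TSV tables plus a JSON sidecar
#'
#' @param ds a [group_dataset()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; subject `i` goes to `<prefix>_sub<i>.tsv`.
#' @return Invisibly, the vector of written table paths.
#' @export
write_parcellated <- function(ds, dir, prefix = "ts") {
  stopifnot(inherits(ds, "group_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(ds$k)
  for (i in seq_len(ds$k)) {
    tab <- data.frame(region = ds$region_labels, ds$subjects[[i]],
                      check.names = FALSE)
    names(tab) <- c("region", paste0("t", seq_len(ds$n)))
    paths[i] <- file.path(dir, sprintf("%s_sub%02d.tsv", prefix, i))
    utils::write.table(tab, paths[i], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  meta <- list(tr = ds$tr, condition = ds$condition, k = ds$k, p = ds$p,
               n = ds$n, region_labels = ds$region_labels)
  jsonlite::write_json(meta, file.path(dir, paste0(prefix, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# sample-sd z-score of one matrix's rows; zero-variance rows are zeroed and
# flagged in the "degenerate" attribute
.zscore_rows <- function(x) {
  mu <- rowMeans(x)
  xc <- x - mu
  sdv <- sqrt(rowSums(xc^2) / (ncol(x) - 1L))
  degen <- sdv < .Machine$double.eps^0.5 * (abs(mu) + 1)
  sdv[degen] <- 1
  out <- xc / sdv
  out[degen, ] <- 0
  attr(out, "degenerate") <- degen
  out
}

#' Z-score every region time course within each subject
#'
#' Each row is centred and scaled to unit sample standard deviation
#' (denominator `n - 1`). Rows with zero variance cannot be standardized;
#' they are set to zero and flagged, and downstream correlation code
#' excludes them rather than treating them as data.
#'
#' @param ds a [group_dataset()].
#' @return The dataset with standardized rows; each subject matrix carries a
#'   logical `"degenerate"` attribute marking zero-variance regions.
#' @export
zscore_subjects <- function(ds) {
  stopifnot(inherits(ds, "group_dataset"))
  for (i in seq_len(ds$k)) {
    z <- .zscore_rows(ds$subjects[[i]])
    if (any(attr(z, "degenerate")))
      warning(sprintf("subject %d: degenerate (zero-variance) regions: %s",
                      i, paste(ds$region_labels[attr(z, "degenerate")],
                               collapse = ", ")))
    dimnames(z) <- list(ds$region_labels, NULL)
    ds$subjects[[i]] <- z
  }
  ds
}

# logical p-vector of degenerate rows for one subject matrix (flag if
# present, else recomputed)
.degenerate_rows <- function(x) {
  d <- attr(x, "degenerate")
  if (is.null(d)) {
    v <- rowSums((x - rowMeans(x))^2) / (ncol(x) - 1L)
    d <- !is.finite(v) | v < .Machine$double.eps
  }
  d
}
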