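#' Chance classification accuracy
#'
#' @param n_classes number of equiprobable classes (`>= 2`).
#' @return Chance accuracy in percent, `100 / n_classes` (25 for four
#'   conditions; 7.14... for 14 story intervals).
#' @export
chance_level <- function(n_classes) {
  if (!is.numeric(n_classes) || n_classes < 2L)
    stop("need at least 2 classes")
  100 / n_classes
}

# Fisher-z edges of the symmetrized subject-level matrix for one held-out
# subject, and the group template from the remaining subjects
.trial_fingerprint <- function(xs, i, method) {
  if (method == "isfc") {
    loo <- Reduce(`+`, xs[-i]) / (length(xs) - 1L)
    m <- subject_isfc(xs[[i]], loo)
    m <- (m + t(m)) / 2
  } else {
    d <- .degenerate_rows(xs[[i]])
    m <- .row_cor(xs[[i]], xs[[i]], d, d)
  }
  m[.edge_index(nrow(m))]
}

.template_fingerprint <- function(xs, exclude, method) {
  xs <- xs[-exclude]
  if (method == "isfc") avg <- .fisher_mean_mats(.subject_isfc_list(xs))
  else avg <- .fisher_mean_mats(lapply(xs, function(x) {
    d <- .degenerate_rows(x)
    .row_cor(x, x, d, d)
  }))
  avg[.edge_index(nrow(avg))]
}

# nearest-template prediction: Pearson similarity of Fisher-z fingerprints
# (feature "full") or closest mean edge (feature "mean"); ties -> lowest
# class index (which.max convention)
.nearest_template <- function(test_edges, templates, feature) {
  if (feature == "full") {
    sims <- vapply(templates, function(tp)
      stats::cor(atanh(.fisher_clip(test_edges)), atanh(.fisher_clip(tp))),
      numeric(1L))
  } else {
    sims <- -vapply(templates, function(tp)
      abs(mean(test_edges, na.rm = TRUE) - mean(tp, na.rm = TRUE)),
      numeric(1L))
  }
  which.max(sims)
}

#' Leave-one-subject-out decoding of experimental condition
#'
#' Quantifies how much information about the stimulus condition is carried
#' by a connectivity estimate. For each held-out subject and each
#' condition, the subject's connectivity fingerprint (its subject-level
#' ISFC against the remaining group of that condition, or its own FC) is
#' matched to per-condition group templates built from the remaining
#' subjects; the predicted condition is the nearest template. With
#' `feature = "full"` the whole Fisher-z fingerprint is compared by Pearson
#' similarity; with `feature = "mean"` only the scalar mean edge is used.
#'
#' @param condition_data named list of [group_dataset()]s, one per
#'   condition, with subjects aligned across conditions (same `k >= 2`).
#' @param method `"isfc"` or `"fc"`.
#' @param feature `"full"` or `"mean"`.
#' @return List: `accuracy` (percent), `chance` (percent), `confusion`
#'   (true x predicted counts), `method`, `feature`.
#' @export
classify_conditions <- function(condition_data, method = c("isfc", "fc"),
                                feature = c("full", "mean")) {
  method <- match.arg(method); feature <- match.arg(feature)
  nc <- length(condition_data)
  if (nc < 2L) stop("need at least 2 conditions")
  ks <- vapply(condition_data, `[[`, integer(1L), "k")
  if (length(unique(ks)) != 1L)
    stop("all conditions must hold the same subjects")
  k <- ks[1L]
  if (k < 2L) stop("leave-one-subject-out needs at least 2 subjects")
  labs <- names(condition_data)
  if (is.null(labs)) labs <- paste0("cond", seq_len(nc))
  confusion <- matrix(0L, nc, nc, dimnames = list(true = labs, pred = labs))
  for (i in seq_len(k)) {
    templates <- lapply(condition_data, function(ds)
      .template_fingerprint(ds$subjects, i, method))
    for (ci in seq_len(nc)) {
      test <- .trial_fingerprint(condition_data[[ci]]$subjects, i, method)
      pred <- .nearest_template(test, templates, feature)
      confusion[ci, pred] <- confusion[ci, pred] + 1L
    }
  }
  list(accuracy = 100 * sum(diag(confusion)) / sum(confusion),
       chance = chance_level(nc), confusion = confusion,
       method = method, feature = feature)
}

#' Leave-one-subject-out decoding of story intervals
#'
#' Splits the series into `n_intervals` consecutive non-overlapping
#' intervals of `interval_tr` TRs (the reference analysis uses 14 intervals
#' of 20 TRs = 30 s) and asks whether a held-out subject's momentary
#' connectivity fingerprint identifies which interval it came from. Per
#' interval, a group template fingerprint is built from the remaining
#' subjects; the test subject's interval fingerprint is assigned to the
#' most-correlated template.
#'
#' @param ds a z-scored [group_dataset()] with `n >= n_intervals *
#'   interval_tr` and `k >= 2`.
#' @param n_intervals,interval_tr number and length (TRs) of intervals.
#' @param method `"isfc"` or `"fc"`.
#' @return List: `subject_accuracy` (percent, per subject), `accuracy`
#'   (group mean, percent), `chance` (percent), `confusion`.
#' @export
classify_intervals <- function(ds, n_intervals = 14L, interval_tr = 20L,
                               method = c("isfc", "fc")) {
  stopifnot(inherits(ds, "group_dataset"))
  method <- match.arg(method)
  if (n_intervals < 1L) stop("need at least 1 interval")
  if (ds$n < n_intervals * interval_tr)
    stop("series too short for the requested intervals")
  if (ds$k < 2L) stop("leave-one-subject-out needs at least 2 subjects")
  slices <- lapply(seq_len(n_intervals), function(t)
    ((t - 1L) * interval_tr + 1L):(t * interval_tr))
  interval_data <- lapply(slices, function(ii)
    lapply(ds$subjects, function(x) x[, ii, drop = FALSE]))
  confusion <- matrix(0L, n_intervals, n_intervals)
  subject_acc <- numeric(ds$k)
  for (i in seq_len(ds$k)) {
    templates <- lapply(interval_data, function(xs)
      .template_fingerprint(xs, i, method))
    hits <- 0L
    for (t in seq_len(n_intervals)) {
      test <- .trial_fingerprint(interval_data[[t]], i, method)
      pred <- .nearest_template(test, templates, "full")
      confusion[t, pred] <- confusion[t, pred] + 1L
      if (pred == t) hits <- hits + 1L
    }
    subject_acc[i] <- 100 * hits / n_intervals
  }
  list(subject_accuracy = subject_acc, accuracy = mean(subject_acc),
       chance = if (n_intervals >= 2L) chance_level(n_intervals) else 100,
       confusion = confusion, method = method)
}
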