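#' Correlation-matrix container
#'
#' Result type shared by [group_isfc()] and [group_fc()]: a symmetric
#' `p x p` matrix plus the bookkeeping needed to interpret its diagonal.
#' For ISFC the diagonal is the inter-subject correlation (ISC) of each
#' region; for FC it is identically 1.
#'
#' @param values symmetric numeric matrix with entries in `[-1, 1]` (NA
#'   allowed for entries involving degenerate regions).
#' @param kind `"ISFC"` or `"FC"`.
#' @param k_subjects number of subjects averaged.
#' @param fisher_averaged whether entries are Fisher r-to-z averages.
#' @return An object of class `corr_matrix`.
#' @export
corr_matrix <- function(values, kind = c("ISFC", "FC"), k_subjects,
                        fisher_averaged = TRUE) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("'values' must be square")
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-12)
    stop("'values' must be symmetric")
  fin <- values[is.finite(values)]
  if (length(fin) && max(abs(fin)) > 1 + 1e-12)
    stop("correlation entries must lie in [-1, 1]")
  structure(
    list(values = values,
         kind = kind,
         diagonal_meaning = if (kind == "ISFC") "ISC" else "unity",
         k_subjects = as.integer(k_subjects),
         fisher_averaged = isTRUE(fisher_averaged)),
    class = "corr_matrix"
  )
}

#' @export
print.corr_matrix <- function(x, ...) {
  off <- x$values[lower.tri(x$values)]
  cat(sprintf("corr_matrix [%s]: %d regions, %d subjects; mean edge %.3f, diagonal = %s\n",
              x$kind, nrow(x$values), x$k_subjects,
              mean(off, na.rm = TRUE), x$diagonal_meaning))
  invisible(x)
}

#' @export
as.matrix.corr_matrix <- function(x, ...) x$values

# clip to the open interval so atanh stays finite
.fisher_clip <- function(r, eps = 1e-7) pmin(pmax(r, -1 + eps), 1 - eps)

#' Fisher r-to-z average of correlation coefficients
#'
#' Averages correlations on the variance-stabilized z scale:
#' `tanh(mean(atanh(r)))`. Values are clipped to within `1e-7` of the unit
#' bounds before `atanh`, so `r = 1` averages to a finite value instead of
#' infinity. NA entries are dropped.
#'
#' @param r numeric vector of correlations in `[-1, 1]`.
#' @return A single averaged correlation.
#' @examples
#' fisher_average(c(0.8, 0.2))   # 0.5716..., not the arithmetic 0.5
#' @export
fisher_average <- function(r) {
  r <- r[!is.na(r)]
  if (length(r) == 0L) stop("no valid correlations to average")
  tanh(mean(atanh(.fisher_clip(r))))
}

# correlation between rows of a (p x n) and rows of b (p x n); entries
# touching degenerate rows are NA. No validation: internal hot path.
.row_cor <- function(a, b, degen_a, degen_b) {
  cc <- suppressWarnings(stats::cor(t(a), t(b)))
  if (any(degen_a)) cc[degen_a, ] <- NA_real_
  if (any(degen_b)) cc[, degen_b] <- NA_real_
  cc
}

#' Subject-level ISFC matrix
#'
#' The correlation between each region's time course in one subject and
#' each region's time course in the average of the remaining subjects:
#' entry `(a, b)` is `cor(x_i[a, ], others_mean[b, ])`. The matrix is not
#' generally symmetric; symmetrization happens once at the group stage.
#'
#' @param x_i `p x n` matrix for the held-out subject.
#' @param others_mean `p x n` mean of all other subjects' matrices.
#' @return `p x p` matrix; rows index the subject's regions, columns the
#'   group-average regions. Entries involving zero-variance rows are NA.
#' @export
subject_isfc <- function(x_i, others_mean) {
  x_i <- as.matrix(x_i); others_mean <- as.matrix(others_mean)
  if (!identical(dim(x_i), dim(others_mean)))
    stop("subject and group-average matrices must share dimensions")
  .row_cor(x_i, others_mean, .degenerate_rows(x_i),
           .degenerate_rows(others_mean))
}

# list of k subject-level ISFC matrices via the leave-one-out total trick
.subject_isfc_list <- function(xs) {
  k <- length(xs)
  total <- Reduce(`+`, xs)
  degen <- lapply(xs, .degenerate_rows)
  lapply(seq_len(k), function(i) {
    loo <- (total - xs[[i]]) / (k - 1)
    .row_cor(xs[[i]], loo, degen[[i]], Reduce(`|`, degen[-i]))
  })
}

# Fisher-average a list of matrices entrywise (NA dropped), then symmetrize
.fisher_mean_mats <- function(mats) {
  zs <- lapply(mats, function(m) atanh(.fisher_clip(m)))
  zsum <- Reduce(`+`, lapply(zs, function(z) ifelse(is.na(z), 0, z)))
  zn <- Reduce(`+`, lapply(zs, function(z) !is.na(z)))
  avg <- tanh(zsum / zn)        # NaN where zn == 0 (all-missing entry)
  avg[zn == 0] <- NA_real_
  (avg + t(avg)) / 2
}

#' Group inter-subject functional correlation matrix
#'
#' For each subject `i`, correlates that subject's region time courses with
#' the arithmetic mean of all other subjects' time courses
#' ([subject_isfc()]); the `k` subject matrices are then averaged entrywise
#' on the Fisher z scale and the result symmetrized as `(C + t(C)) / 2`,
#' treating the coupling between two regions as undirected. The diagonal is
#' the inter-subject correlation (ISC) of each region. Because intrinsic
#' fluctuations and subject-specific noise are uncorrelated across
#' subjects, only stimulus-locked covariance survives in this matrix.
#'
#' @param ds a [group_dataset()] with at least 2 subjects (z-scored rows
#'   recommended; values are unaffected by row scaling).
#' @return A [corr_matrix()] with `kind = "ISFC"`.
#' @export
group_isfc <- function(ds) {
  stopifnot(inherits(ds, "group_dataset"))
  if (ds$k < 2L) stop("ISFC requires at least 2 subjects")
  usable <- !vapply(ds$subjects, function(x) all(.degenerate_rows(x)),
                    logical(1L))
  if (!all(usable)) {
    warning(sprintf("excluding %d entirely degenerate subject(s)",
                    sum(!usable)))
    if (sum(usable) < 2L) stop("fewer than 2 usable subjects")
  }
  xs <- ds$subjects[usable]
  avg <- .fisher_mean_mats(.subject_isfc_list(xs))
  if (anyNA(avg))
    warning("entries involving degenerate regions are NA in all subjects")
  dimnames(avg) <- list(ds$region_labels, ds$region_labels)
  corr_matrix(avg, kind = "ISFC", k_subjects = length(xs))
}

#' Inter-subject correlation of each region
#'
#' The correlation of the same region's time course across subjects,
#' obtained as the diagonal of the group ISFC matrix.
#'
#' @param ds a [group_dataset()] with at least 2 subjects.
#' @return Named numeric vector of length `p`.
#' @export
isc <- function(ds) {
  diag(group_isfc(ds)$values)
}

#' Seed-based ISFC map
#'
#' The row of the symmetrized group ISFC matrix for one seed region: the
#' stimulus-locked correlation between the seed and every region (its own
#' entry being the seed's ISC).
#'
#' @param ds a [group_dataset()].
#' @param seed region index or label.
#' @return Named numeric vector of length `p`.
#' @export
seed_isfc <- function(ds, seed) {
  C <- group_isfc(ds)
  if (is.character(seed)) seed <- match(seed, ds$region_labels)
  if (is.na(seed) || seed < 1L || seed > ds$p)
    stop("invalid seed region")
  C$values[seed, ]
}

#' Group within-subject functional connectivity matrix
#'
#' The conventional FC estimate: each subject's `p x p` Pearson correlation
#' matrix of its own region time courses, Fisher-averaged entrywise across
#' subjects, with the diagonal forced to 1. Unlike ISFC this mixes
#' stimulus-locked, intrinsic and non-neuronal covariance.
#'
#' @param ds a [group_dataset()] with at least 1 subject.
#' @return A [corr_matrix()] with `kind = "FC"`.
#' @export
group_fc <- function(ds) {
  stopifnot(inherits(ds, "group_dataset"))
  mats <- lapply(ds$subjects, function(x) {
    d <- .degenerate_rows(x)
    .row_cor(x, x, d, d)
  })
  avg <- .fisher_mean_mats(mats)
  diag(avg) <- 1
  dimnames(avg) <- list(ds$region_labels, ds$region_labels)
  corr_matrix(avg, kind = "FC", k_subjects = ds$k)
}
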