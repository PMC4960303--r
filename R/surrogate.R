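#' Phase-randomized surrogate of a time series
#'
#' Generates a surrogate with the same amplitude spectrum (hence the same
#' mean, variance and autocorrelation) as the input but randomized phases:
#' each complex Fourier amplitude is rotated by an independent
#' Uniform(0, 2*pi) phase, mirrored conjugate-symmetrically
#' (`phi(f) = -phi(-f)`) so the inverse transform is real. The DC bin is
#' untouched (mean preserved); for even-length series the Nyquist bin is
#' also untouched, since its phase is constrained to 0 or pi for a real
#' signal. This is the appropriate null for correlations between
#' autocorrelated series such as BOLD signals.
#'
#' @param x numeric series of length at least 2 (or a matrix: each row is
#'   randomized independently).
#' @return Surrogate of the same shape as `x`.
#' @export
phase_randomize <- function(x) {
  if (is.matrix(x)) return(.phase_randomize_rows(x))
  if (length(x) < 2L) stop("series must have at least 2 points")
  if (!all(is.finite(x))) stop("series must be finite")
  drop(.phase_randomize_rows(matrix(x, nrow = 1L)))
}

# independent surrogate per row; one mvfft round-trip for the whole matrix
.phase_randomize_rows <- function(x) {
  n <- ncol(x)
  p <- nrow(x)
  f <- stats::mvfft(t(x))                       # n x p spectra
  half <- if (n %% 2L == 0L) n %/% 2L else (n + 1L) %/% 2L
  nfree <- half - 1L                            # bins 2..half get free phases
  phi <- matrix(0, n, p)
  if (nfree > 0L) {
    ph <- matrix(stats::runif(nfree * p, 0, 2 * pi), nfree, p)
    phi[2L:half, ] <- ph
    mirror_rows <- n + 2L - (2L:half)           # conjugate bins, reversed
    phi[mirror_rows, ] <- -ph
  }
  out <- t(Re(stats::mvfft(f * exp(1i * phi), inverse = TRUE)) / n)
  dimnames(out) <- dimnames(x)
  out
}

#' Null distribution of map-wise maximum correlations
#'
#' Builds the resampling null used for family-wise error control: on each
#' iteration every region time course of every subject is replaced by an
#' independent phase-randomized surrogate (destroying all cross-region and
#' cross-subject dependence while preserving each series' autocorrelation),
#' the full ISFC or FC map is recomputed, and its maximum entry recorded.
#' For ISFC the maximum is over all matrix entries including the ISC
#' diagonal; for FC the structural unit diagonal is excluded.
#'
#' @param ds a z-scored [group_dataset()].
#' @param statistic `"isfc"` or `"fc"`.
#' @param n_iter number of surrogate iterations (10,000 for publication
#'   thresholds; hundreds suffice for exploration).
#' @param seed optional integer seed for reproducible surrogates.
#' @return Object of class `null_distribution`: sorted `samples`, `n_iter`,
#'   `metric`, `seed`.
#' @export
max_null <- function(ds, statistic = c("isfc", "fc"), n_iter = 1000L,
                     seed = NULL) {
  stopifnot(inherits(ds, "group_dataset"))
  statistic <- match.arg(statistic)
  if (n_iter < 1L) stop("'n_iter' must be positive")
  if (!is.null(seed)) set.seed(seed)
  k <- ds$k; p <- ds$p; n <- ds$n
  # spectra are fixed across iterations: transform every series once and
  # only redraw phases + one stacked inverse FFT per iteration
  stacked <- t(do.call(rbind, ds$subjects))            # n x (k p)
  f0 <- stats::mvfft(stacked)
  half <- if (n %% 2L == 0L) n %/% 2L else (n + 1L) %/% 2L
  nfree <- half - 1L
  mirror_rows <- n + 2L - (2L:half)
  cols <- lapply(seq_len(k), function(i) ((i - 1L) * p + 1L):(i * p))
  off_diag <- which(row(diag(p)) != col(diag(p)))
  samples <- vapply(seq_len(n_iter), function(it) {
    rot <- matrix(1 + 0i, n, k * p)
    if (nfree > 0L) {
      ph <- stats::runif(nfree * k * p, 0, 2 * pi)
      z <- matrix(complex(real = cos(ph), imaginary = sin(ph)), nfree, k * p)
      rot[2L:half, ] <- z
      rot[mirror_rows, ] <- Conj(z)
    }
    surro <- Re(stats::mvfft(f0 * rot, inverse = TRUE)) / n
    if (statistic == "isfc") {
      total <- Reduce(`+`, lapply(cols, function(cc) surro[, cc]))
      zsum <- 0
      for (i in seq_len(k)) {
        si <- surro[, cols[[i]]]
        cc <- stats::cor(si, (total - si) / (k - 1))
        zsum <- zsum + atanh(.fisher_clip(cc))
      }
      avg <- tanh(zsum / k)
      max((avg + t(avg)) / 2)       # same symmetrization as group_isfc
    } else {
      zsum <- 0
      for (i in seq_len(k))
        zsum <- zsum + atanh(.fisher_clip(stats::cor(surro[, cols[[i]]])))
      max(tanh(zsum / k)[off_diag])
    }
  }, numeric(1L))
  structure(list(samples = sort(samples), n_iter = as.integer(n_iter),
                 metric = statistic, seed = seed),
            class = "null_distribution")
}

#' Family-wise error correlation threshold from a max-statistic null
#'
#' Returns `R*`, the `(1 - q) * 100`th percentile (linear interpolation
#' between order statistics) of the null distribution of map-wise maxima.
#' Declaring significant only entries above `R*` controls the probability
#' of any false positive across the whole map at level `q`.
#'
#' @param null a `null_distribution` from [max_null()].
#' @param q family-wise error rate in (0, 1), e.g. 0.01.
#' @return The threshold `R*`.
#' @export
fwer_threshold <- function(null, q) {
  stopifnot(inherits(null, "null_distribution"))
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("'q' must lie strictly between 0 and 1")
  unname(stats::quantile(null$samples, probs = 1 - q, type = 7))
}

#' Threshold a statistic map at a correlation cutoff
#'
#' @param stat_map numeric vector or matrix of observed correlations.
#' @param r_star threshold, typically from [fwer_threshold()].
#' @param q the error level the threshold was built for (bookkeeping only).
#' @return Object of class `significance_result`: `threshold`, `q`, logical
#'   `mask` (TRUE strictly above threshold) and the surviving `values`.
#' @export
threshold_map <- function(stat_map, r_star, q = NA_real_) {
  if (!all(is.finite(stat_map) | is.na(stat_map)))
    stop("statistic map must be finite (NA allowed)")
  mask <- !is.na(stat_map) & stat_map > r_star
  structure(list(threshold = r_star, q = q, mask = mask,
                 values = stat_map[mask]),
            class = "significance_result")
}

#' Correlation with a phase-randomization permutation p-value
#'
#' Pearson correlation of two equal-length series, with a two-sided p-value
#' from phase-randomized surrogates of `x`: the fraction of surrogates whose
#' absolute correlation with `y` reaches the observed one, using the
#' `(b + 1) / (m + 1)` estimator so p is never exactly zero. Appropriate
#' when both series are autocorrelated, which invalidates the parametric
#' t-test for Pearson's r.
#'
#' @param x,y numeric series of equal length `>= 3`; surrogates are drawn
#'   for `x`.
#' @param n_perm number of surrogates.
#' @param seed optional integer seed.
#' @return List with elements `r` and `p`.
#' @export
perm_corr_pvalue <- function(x, y, n_perm = 1000L, seed = NULL) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate (constant) series")
  if (!is.null(seed)) set.seed(seed)
  r_obs <- stats::cor(x, y)
  b <- 0L
  for (i in seq_len(n_perm)) {
    r_null <- stats::cor(phase_randomize(x), y)
    if (abs(r_null) >= abs(r_obs)) b <- b + 1L
  }
  list(r = r_obs, p = (b + 1) / (n_perm + 1))
}
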