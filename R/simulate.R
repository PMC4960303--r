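# symmetric square root of a covariance via its eigendecomposition;
# meaningfully negative eigenvalues are rejected, tiny ones clamped to 0
.cov_factor <- function(C, label) {
  C <- as.matrix(C)
  if (max(abs(C - t(C))) > 1e-10)
    stop(sprintf("%s covariance must be symmetric", label))
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values)))
    stop(sprintf("%s covariance is not positive semi-definite", label))
  ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
}

# p x n matrix of correlated Gaussian rows with correlation C
.draw_mvn_rows <- function(C_factor, n) {
  p <- nrow(C_factor)
  C_factor %*% matrix(stats::rnorm(p * n), p, n)
}

#' Simulation configuration for the three-component signal model
#'
#' Defines a synthetic multi-subject experiment under the decomposition
#' `X_i = sqrt(s) S + sqrt(1 - s - eta) I_i + sqrt(eta) N_i` per region:
#' a stimulus-locked component `S` shared by all subjects (inter-regional
#' correlation `C_S`, optionally a different correlation state per
#' segment), an intrinsic component `I_i` drawn independently per subject
#' with correlation `C_I`, and white noise `N_i`. Optionally a per-subject
#' scalar confound series (respiration/motion-like) is added to every
#' region with a region-specific gain — shared within a subject, hence
#' visible to FC but not to ISFC. Regions may integrate the stimulus over
#' a timescale `memory_tau` (leaky accumulation), making their responses
#' depend on stimulus history.
#'
#' @param k,p,n subjects, regions, timepoints.
#' @param tr sampling interval in seconds (default 1.5).
#' @param C_S stimulus inter-regional correlation matrix, or a list of such
#'   matrices (one state per entry) used with `states`.
#' @param stimulus_share scalar or per-region share `s` in `[0, 1]` of
#'   signal variance that is stimulus-locked.
#' @param C_I intrinsic inter-regional correlation matrix, or a list of
#'   `k` matrices giving each subject an idiosyncratic intrinsic network
#'   (the realistic case: intrinsic dynamics differ across individuals).
#' @param noise_share scalar or per-region white-noise variance share
#'   `eta`, with `s + eta <= 1` (the intrinsic share is the remainder).
#' @param confound_sd amplitude of the per-subject global confound series
#'   (0 disables it).
#' @param memory_tau per-region context-integration timescale in TRs
#'   (0 = instantaneous response).
#' @param segments data frame with columns `start`, `length` tiling
#'   `1..n`; defaults to one segment. Used for piecewise states and
#'   scrambling.
#' @param states integer vector, one `C_S` state index per segment, when
#'   `C_S` is a list.
#' @param seed RNG seed making the draw fully reproducible.
#' @return A `sim_config` object.
#' @export
sim_config <- function(k, p, n, tr = 1.5,
                       C_S = diag(p), stimulus_share = 0.5,
                       C_I = diag(p), noise_share = 0,
                       confound_sd = 0, memory_tau = 0,
                       segments = NULL, states = NULL, seed = 1L) {
  stimulus_share <- rep_len(stimulus_share, p)
  noise_share <- rep_len(noise_share, p)
  memory_tau <- rep_len(memory_tau, p)
  if (any(stimulus_share < 0 | stimulus_share > 1))
    stop("stimulus shares must lie in [0, 1]")
  if (any(noise_share < 0) || any(stimulus_share + noise_share > 1 + 1e-12))
    stop("per-region shares must satisfy s + eta <= 1")
  if (any(memory_tau < 0)) stop("memory timescales must be >= 0")
  if (confound_sd < 0) stop("'confound_sd' must be >= 0")
  if (is.null(segments))
    segments <- data.frame(start = 1L, length = as.integer(n))
  segments <- .check_segments(segments, n)
  if (is.list(C_I) && !is.matrix(C_I)) {
    if (length(C_I) != k)
      stop("per-subject 'C_I' must supply one matrix per subject")
  } else C_I <- list(C_I)
  if (is.list(C_S) && !is.matrix(C_S)) {
    if (is.null(states)) stop("piecewise 'C_S' needs a 'states' vector")
    if (length(states) != nrow(segments))
      stop("'states' must give one state per segment")
    if (any(states < 1L | states > length(C_S)))
      stop("'states' indexes outside the C_S list")
  } else {
    C_S <- list(C_S)
    states <- rep(1L, nrow(segments))
  }
  structure(list(k = as.integer(k), p = as.integer(p), n = as.integer(n),
                 tr = tr, C_S = C_S, stimulus_share = stimulus_share,
                 C_I = C_I, noise_share = noise_share,
                 confound_sd = confound_sd, memory_tau = memory_tau,
                 segments = segments, states = as.integer(states),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Leaky context integration of stimulus rows
#'
#' Replaces each row with timescale `tau > 0` by a leaky accumulation
#' `y_t = exp(-1/tau) y_(t-1) + x_t`, re-standardized to zero mean and
#' unit sample variance; rows with `tau = 0` pass through unchanged. This
#' realizes history-dependent ("integrator") regions: once `tau` exceeds
#' the segment length, responses depend on which segments preceded the
#' current one, so scrambling segments before integration is not undone by
#' reordering the output.
#'
#' @param S `p x n` stimulus matrix.
#' @param tau scalar or per-region timescale in TRs.
#' @return Matrix of the same shape.
#' @export
apply_memory <- function(S, tau) {
  S <- as.matrix(S)
  tau <- rep_len(tau, nrow(S))
  if (any(tau < 0)) stop("'tau' must be >= 0")
  for (r in which(tau > 0)) {
    a <- exp(-1 / tau[r])
    y <- stats::filter(S[r, ], filter = a, method = "recursive")
    y <- as.numeric(y) - mean(y)
    sdy <- stats::sd(y)
    S[r, ] <- if (sdy > 0) y / sdy else 0
  }
  S
}

#' Uniformly permute the segment order of a stimulus matrix
#'
#' Emulates the construction of scrambled stimuli: the series is cut at
#' the segment boundaries (words or paragraphs) and the segments are
#' re-concatenated in uniformly random order. The permutation is returned
#' so [reorder_segments()] can restore the original order downstream.
#'
#' @param S `p x n` matrix.
#' @param segments data frame (`start`, `length`) tiling the series.
#' @param seed optional integer seed.
#' @return List: `S` (scrambled matrix), `order` (position `i` of the
#'   output holds original segment `order[i]`), `inverse` (permutation
#'   restoring the original order).
#' @export
scramble_segments <- function(S, segments, seed = NULL) {
  S <- as.matrix(S)
  segments <- .check_segments(segments, ncol(S))
  if (!is.null(seed)) set.seed(seed)
  ord <- sample.int(nrow(segments))
  idx <- unlist(lapply(ord, function(s)
    seq.int(segments$start[s], length.out = segments$length[s])))
  # the scrambled series has its own boundary table (segment lengths move
  # with the permutation); reorder_segments(out, segments_out, inverse)
  # restores the original order
  len_out <- segments$length[ord]
  segments_out <- data.frame(start = cumsum(c(1L, len_out[-length(len_out)])),
                             length = len_out)
  list(S = S[, idx, drop = FALSE], order = ord, inverse = order(ord),
       segments_out = segments_out)
}

#' Simulate a multi-subject group under the three-component model
#'
#' Draws one shared stimulus component `S` (piecewise by segment state if
#' configured), independent per-subject intrinsic components `I_i` and
#' white noise `N_i`, and mixes them per region as
#' `sqrt(s) S + sqrt(1 - s - eta) I_i + sqrt(eta) N_i`, plus an optional
#' per-subject global confound. The draw is deterministic under
#' `cfg$seed`.
#'
#' When `scramble = TRUE` the stimulus segments are scrambled *before*
#' memory integration — the subjects "hear" the scrambled story — and the
#' permutation is returned so measured responses can be reordered to the
#' intact timeline with [reorder_segments()].
#'
#' Regions with `memory_tau > 0` respond with a leaky integral of their
#' stimulus row. In an intact presentation the context flows continuously,
#' so the integrated response is still fully shared across subjects. In a
#' scrambled presentation the narrative context breaks at every segment
#' boundary: the integrator state carried into each segment is modelled as
#' an idiosyncratic per-subject draw from the stationary state
#' distribution (each brain fills the incoherent junction with its own
#' context). Short segments therefore leave integrator regions with little
#' shared variance, long segments with more — the coherence gradient —
#' while instantaneous regions are unaffected by scrambling.
#'
#' @param cfg a [sim_config()].
#' @param scramble scramble the stimulus segment order before integration.
#' @return List: `dataset` (the raw, un-z-scored [group_dataset()]) and
#'   `truth` (list with `S`, `I`, `N`, `confound`, `gains`, segment
#'   `states`, and `order`/`inverse` when scrambled).
#' @export
simulate_group <- function(cfg, scramble = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  p <- cfg$p; n <- cfg$n; k <- cfg$k
  facs <- lapply(cfg$C_S, .cov_factor, label = "stimulus")
  fac_i <- lapply(cfg$C_I, .cov_factor, label = "intrinsic")
  if (length(fac_i) == 1L) fac_i <- rep(fac_i, k)

  # stimulus: per-segment draw with that segment's state covariance
  S <- matrix(0, p, n)
  for (q in seq_len(nrow(cfg$segments))) {
    idx <- seq.int(cfg$segments$start[q], length.out = cfg$segments$length[q])
    S[, idx] <- .draw_mvn_rows(facs[[cfg$states[q]]], length(idx))
  }
  scr <- NULL
  if (scramble) {
    scr <- scramble_segments(S, cfg$segments)
    S <- scr$S
  }
  # context blocks over which integration runs uninterrupted: the whole
  # series when the presentation is coherent, single segments when not
  blocks <- if (scramble) scr$segments_out
            else data.frame(start = 1L, length = n)
  taus <- cfg$memory_tau
  integ <- which(taus > 0)
  ctx_sd <- matrix(0, 0, 0)
  if (length(integ)) {
    a <- exp(-1 / taus[integ])
    sd_stat <- sqrt(1 / (1 - a^2))    # stationary sd of the leaky integral
    for (q in seq_len(nrow(blocks))) {
      idx <- seq.int(blocks$start[q], length.out = blocks$length[q])
      for (w in seq_along(integ)) {
        r <- integ[w]
        S[r, idx] <- stats::filter(S[r, idx], exp(-1 / taus[r]),
                                   method = "recursive")
      }
    }
    # shared part standardized by the stationary sd; the per-subject
    # context state entering each block (same scale) is added below
    S[integ, ] <- S[integ, , drop = FALSE] / sd_stat
    ctx_sd <- sd_stat
  }

  ws <- sqrt(cfg$stimulus_share)
  wi <- sqrt(pmax(1 - cfg$stimulus_share - cfg$noise_share, 0))
  wn <- sqrt(cfg$noise_share)
  I_list <- vector("list", k); N_list <- vector("list", k)
  confounds <- matrix(0, k, n); gains <- matrix(0, k, p)
  subjects <- vector("list", k)
  for (i in seq_len(k)) {
    I_list[[i]] <- .draw_mvn_rows(fac_i[[i]], n)
    N_list[[i]] <- matrix(stats::rnorm(p * n), p, n)
    # subject's stimulus-locked component: the shared integral plus this
    # subject's idiosyncratic context state entering each block
    z_i <- S
    if (length(integ)) {
      for (q in seq_len(nrow(blocks))) {
        t0 <- blocks$start[q]; L <- blocks$length[q]
        for (w in seq_along(integ)) {
          r <- integ[w]
          a_r <- exp(-1 / taus[r])
          c0 <- stats::rnorm(1, sd = ctx_sd[w])
          z_i[r, t0:(t0 + L - 1L)] <- z_i[r, t0:(t0 + L - 1L)] +
            c0 * a_r^(seq_len(L)) / ctx_sd[w]
        }
      }
    }
    # confound always drawn so paired runs differing only in confound_sd
    # share the identical S, I and N realizations
    confounds[i, ] <- stats::rnorm(n)
    gains[i, ] <- stats::runif(p, 0.5, 1.5)
    subjects[[i]] <- ws * z_i + wi * I_list[[i]] + wn * N_list[[i]] +
      cfg$confound_sd * outer(gains[i, ], confounds[i, ])
  }
  ds <- group_dataset(subjects, tr = cfg$tr,
                      condition = if (scramble) "scrambled" else "intact")
  truth <- list(S = S, I = I_list, N = N_list,
                confound = confounds, gains = gains,
                states = cfg$states, segments = cfg$segments,
                order = scr$order, inverse = scr$inverse,
                segments_out = scr$segments_out)
  list(dataset = ds, truth = truth)
}

#' Analytic group-ISFC expectation under the simulator's model
#'
#' For instantaneous (no-memory) regions with a common stimulus share `s`
#' and stimulus edge correlation `rho`, the population value of a single
#' subject-vs-rest ISFC entry is `s * rho / sqrt(s + (1 - s) / (k - 1))`:
#' the numerator is the shared stimulus covariance, the denominator the
#' standard deviation of the leave-one-out average, whose unshared
#' components shrink by `1 / (k - 1)` but do not vanish. The diagonal
#' (ISC) expectation is the same expression with `rho = 1`.
#'
#' @param s stimulus variance share in `[0, 1]`.
#' @param rho stimulus inter-regional correlation of the edge.
#' @param k number of subjects.
#' @return The expected correlation.
#' @export
isfc_expected <- function(s, rho = 1, k) {
  if (k < 2L) stop("'k' must be at least 2")
  s * rho / sqrt(s + (1 - s) / (k - 1))
}

#' Simulate sparse behavioural scores coupled to a network time course
#'
#' Draws `n_blanks` rating timestamps evenly over the series and scores
#' `coupling * series(t) + noise`, affinely mapped into the 0-4 rating
#' scale — a fixture for [behavior_coupling()].
#'
#' @param series numeric network time course (e.g. windowed mean ISFC).
#' @param at TR positions of `series` (default `1..length`).
#' @param coupling linear coupling strength (0 = independent behaviour).
#' @param noise_sd rating noise, in units of the series' SD.
#' @param n_blanks number of rated blanks (`>= 3`).
#' @param seed optional integer seed.
#' @return A [behavior_series()].
#' @export
simulate_behavior <- function(series, at = seq_along(series), coupling,
                              noise_sd, n_blanks, seed = NULL) {
  if (n_blanks < 3L) stop("need at least 3 blanks")
  if (!is.null(seed)) set.seed(seed)
  t_blank <- round(seq(min(at), max(at), length.out = n_blanks))
  t_blank <- unique(pmax(1L, as.integer(t_blank)))
  base <- stats::approx(at, series, xout = t_blank, rule = 2)$y
  z <- (base - mean(base)) / max(stats::sd(base), 1e-12)
  raw <- coupling * z + stats::rnorm(length(z), sd = noise_sd)
  rng <- range(raw)
  scaled <- if (diff(rng) > 0) 4 * (raw - rng[1L]) / diff(rng) else rep(2, length(raw))
  behavior_series(t_blank, scaled, span_tr = max(at))
}

#' Equicorrelation matrix
#'
#' @param p dimension.
#' @param rho common off-diagonal correlation (must keep the matrix PSD,
#'   i.e. `rho >= -1 / (p - 1)`).
#' @return `p x p` correlation matrix.
#' @export
cor_constant <- function(p, rho) {
  if (p > 1 && (rho < -1 / (p - 1) - 1e-12 || rho > 1))
    stop("'rho' outside the positive semi-definite range")
  C <- matrix(rho, p, p)
  diag(C) <- 1
  C
}

#' Random well-conditioned correlation matrix
#'
#' Builds `cov2cor(W W' + d I)` from a Gaussian factor matrix `W`; larger
#' `strength` gives stronger (and more structured) off-diagonal
#' correlations. Used to plant distinct covariance states in simulations.
#'
#' @param p dimension.
#' @param strength ratio of factor to idiosyncratic variance (default 1).
#' @param n_factors number of latent factors (default 2).
#' @param seed optional integer seed.
#' @return `p x p` correlation matrix.
#' @export
random_cor <- function(p, strength = 1, n_factors = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(stats::rnorm(p * n_factors), p, n_factors)
  stats::cov2cor(strength * tcrossprod(W) + diag(p))
}
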