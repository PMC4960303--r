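# edge (region-pair) index table in fixed row-major lower-triangle order:
# (2,1), (3,1), (3,2), (4,1), ... so fingerprints are comparable across runs
.edge_index <- function(p) {
  i <- rep(2:p, times = (2:p) - 1L)
  j <- unlist(lapply(2:p, function(r) seq_len(r - 1L)))
  cbind(row = i, col = j)
}

#' Mean correlation across all network edges
#'
#' The arithmetic mean of the `p(p-1)/2` lower off-diagonal entries of a
#' correlation matrix — the scalar summary of network coupling strength
#' used for sliding-window time courses. The diagonal is excluded.
#'
#' @param C a [corr_matrix()] or plain symmetric matrix with `p >= 2`.
#' @return A single number.
#' @export
mean_edges <- function(C) {
  v <- if (inherits(C, "corr_matrix")) C$values else as.matrix(C)
  if (nrow(v) < 2L) stop("need at least 2 regions to have edges")
  mean(v[lower.tri(v)], na.rm = TRUE)
}

#' Connectivity fingerprint of a correlation matrix
#'
#' Flattens the `p(p-1)/2` lower off-diagonal entries into a fixed-order
#' edge vector (row-major over the lower triangle), labelled
#' `"regionA-regionB"`. The fingerprint is the network-state descriptor
#' used for reliability and decoding analyses; together with the diagonal
#' it reconstructs the matrix exactly ([fingerprint_matrix()]).
#'
#' @param C a [corr_matrix()] or symmetric matrix.
#' @return Object of class `fingerprint`: `edges`, `labels`, `p`,
#'   `diagonal`.
#' @export
fingerprint <- function(C) {
  v <- if (inherits(C, "corr_matrix")) C$values else as.matrix(C)
  p <- nrow(v)
  if (p < 2L) stop("need at least 2 regions")
  labs <- rownames(v)
  if (is.null(labs)) labs <- paste0("R", seq_len(p))
  ei <- .edge_index(p)
  structure(list(edges = v[ei],
                 labels = paste0(labs[ei[, 1L]], "-", labs[ei[, 2L]]),
                 p = p, diagonal = diag(v)),
            class = "fingerprint")
}

#' Rebuild a symmetric matrix from a fingerprint
#'
#' @param fp a [fingerprint()].
#' @param diagonal diagonal values; defaults to those stored on `fp`.
#' @return Symmetric `p x p` matrix.
#' @export
fingerprint_matrix <- function(fp, diagonal = fp$diagonal) {
  p <- fp$p
  v <- matrix(0, p, p)
  ei <- .edge_index(p)
  v[ei] <- fp$edges
  v <- v + t(v)
  diag(v) <- diagonal
  v
}

#' Sliding-window ISFC or FC
#'
#' Recomputes the group correlation matrix within a window of `window_tr`
#' samples slid along the series: the window starting at TR `t` covers
#' samples `t .. t + window_tr - 1` (half-open `[t, t + w)` convention,
#' labelled by start TR). A 60-TR window at TR 1.5 s is the 90-s window of
#' the dynamic analyses; 30 TRs gives the 45-s variant.
#'
#' @param ds a z-scored [group_dataset()].
#' @param window_tr window length in TRs (`<= n`).
#' @param step_tr shift between consecutive windows in TRs (default 1).
#' @param statistic `"isfc"` or `"fc"`.
#' @return Object of class `window_series`: `start_trs`, `window_tr`,
#'   `step_tr`, `statistic` and the list `matrices` of [corr_matrix()].
#' @export
sliding_isfc <- function(ds, window_tr, step_tr = 1L,
                         statistic = c("isfc", "fc")) {
  stopifnot(inherits(ds, "group_dataset"))
  statistic <- match.arg(statistic)
  if (window_tr > ds$n) stop("window longer than the series")
  if (window_tr < 2L) stop("window must span at least 2 TRs")
  starts <- seq.int(1L, ds$n - window_tr + 1L, by = step_tr)
  fun <- if (statistic == "isfc") group_isfc else group_fc
  mats <- lapply(starts, function(t0) {
    sub <- ds
    sub$subjects <- lapply(ds$subjects, function(x)
      x[, t0:(t0 + window_tr - 1L), drop = FALSE])
    sub$n <- window_tr
    fun(sub)
  })
  structure(list(start_trs = starts, window_tr = as.integer(window_tr),
                 step_tr = as.integer(step_tr), statistic = statistic,
                 matrices = mats),
            class = "window_series")
}

#' @export
print.window_series <- function(x, ...) {
  cat(sprintf("window_series [%s]: %d windows of %d TRs, step %d\n",
              x$statistic, length(x$start_trs), x$window_tr, x$step_tr))
  invisible(x)
}

#' Mean-edge time course of a window series
#'
#' @param ws a `window_series` from [sliding_isfc()].
#' @return Numeric vector, one [mean_edges()] value per window.
#' @export
mean_edge_series <- function(ws) {
  stopifnot(inherits(ws, "window_series"))
  vapply(ws$matrices, mean_edges, numeric(1L))
}

#' Fingerprints of a window series as an edge-by-window matrix
#'
#' @param ws a `window_series`.
#' @return Matrix with one column per window, rows in fixed edge order.
#' @export
fingerprint_series <- function(ws) {
  stopifnot(inherits(ws, "window_series"))
  fps <- lapply(ws$matrices, fingerprint)
  out <- vapply(fps, `[[`, numeric(length(fps[[1L]]$edges)), "edges")
  rownames(out) <- fps[[1L]]$labels
  colnames(out) <- ws$start_trs
  out
}

#' Split-half reliability of windowed connectivity fingerprints
#'
#' Repeatedly partitions the subjects into two random halves, computes each
#' half's sliding-window ISFC fingerprints, and correlates the two halves'
#' fingerprints within each window. High values mean the momentary network
#' configuration is reproduced in independent subjects — i.e. it is
#' stimulus-locked rather than idiosyncratic.
#'
#' @param ds a z-scored [group_dataset()] with an even number (`>= 4`) of
#'   subjects; with `drop_odd = TRUE` an odd dataset drops its last subject.
#' @param window_tr,step_tr window length and shift in TRs.
#' @param n_iter number of random partitions (100 in the reference
#'   analysis).
#' @param seed optional integer seed.
#' @param drop_odd drop the last subject instead of erroring on odd `k`.
#' @return List: `start_trs`, per-window `mean_r` and `sd_r` across
#'   iterations, `n_iter`.
#' @export
split_half_reliability <- function(ds, window_tr, step_tr = 1L,
                                   n_iter = 100L, seed = NULL,
                                   drop_odd = FALSE) {
  stopifnot(inherits(ds, "group_dataset"))
  if (ds$k %% 2L == 1L) {
    if (!drop_odd) stop("odd number of subjects; set drop_odd = TRUE to drop one")
    warning("dropping the last subject to obtain even halves")
    ds$subjects <- ds$subjects[-ds$k]
    ds$k <- ds$k - 1L
  }
  if (ds$k < 4L) stop("need at least 4 subjects for split-half analysis")
  if (!is.null(seed)) set.seed(seed)
  half <- ds$k %/% 2L
  rs <- NULL
  for (it in seq_len(n_iter)) {
    pick <- sample.int(ds$k, half)
    d1 <- ds; d1$subjects <- ds$subjects[pick]; d1$k <- half
    d2 <- ds; d2$subjects <- ds$subjects[-pick]; d2$k <- ds$k - half
    f1 <- fingerprint_series(sliding_isfc(d1, window_tr, step_tr))
    f2 <- fingerprint_series(sliding_isfc(d2, window_tr, step_tr))
    r_it <- vapply(seq_len(ncol(f1)),
                   function(w) stats::cor(f1[, w], f2[, w]), numeric(1L))
    rs <- cbind(rs, r_it)
  }
  starts <- seq.int(1L, ds$n - window_tr + 1L, by = step_tr)
  list(start_trs = starts,
       mean_r = rowMeans(rs),
       sd_r = apply(rs, 1L, stats::sd),
       n_iter = as.integer(n_iter))
}

# validate that segments (start, length) tile 1..n; returns ordered table
.check_segments <- function(segments, n) {
  segments <- as.data.frame(segments)
  if (!all(c("start", "length") %in% names(segments)))
    stop("'segments' needs columns 'start' and 'length'")
  segments <- segments[order(segments$start), , drop = FALSE]
  ends <- segments$start + segments$length - 1L
  if (segments$start[1L] != 1L || ends[nrow(segments)] != n ||
      (nrow(segments) > 1L &&
       any(segments$start[-1L] != ends[-nrow(segments)] + 1L)))
    stop("segments must tile the series exactly, without gaps or overlap")
  segments
}

#' Reorder time-course segments of every subject
#'
#' Re-concatenates the series segment-wise in a new order — used to put
#' responses to a paragraph-scrambled stimulus back into the intact story's
#' order, so that history (context) effects can be read off by comparing
#' against the intact run.
#'
#' @param ds a [group_dataset()].
#' @param segments data frame with columns `start`, `length` (1-based TRs)
#'   tiling the series exactly.
#' @param order integer permutation of the segments: position `i` of the
#'   output carries segment `order[i]`.
#' @return The reordered [group_dataset()].
#' @export
reorder_segments <- function(ds, segments, order) {
  stopifnot(inherits(ds, "group_dataset"))
  segments <- .check_segments(segments, ds$n)
  if (!setequal(order, seq_len(nrow(segments))) ||
      length(order) != nrow(segments))
    stop("'order' must be a permutation of the segment indices")
  idx <- unlist(lapply(order, function(s)
    seq.int(segments$start[s], length.out = segments$length[s])))
  ds$subjects <- lapply(ds$subjects, function(x) {
    out <- x[, idx, drop = FALSE]
    attr(out, "degenerate") <- attr(x, "degenerate")
    out
  })
  ds
}

#' Behavioural score series
#'
#' Sparse ratings (e.g. recall accuracy for story segments, scored 0-4)
#' attached to story timestamps in TR units.
#'
#' @param t integer TR timestamps, strictly increasing.
#' @param value scores in `[0, 4]`.
#' @param span_tr total series span in TRs (must cover all timestamps).
#' @return Object of class `behavior_series` (a data frame with metadata).
#' @export
behavior_series <- function(t, value, span_tr) {
  if (length(t) != length(value)) stop("timestamps and values differ in length")
  if (is.unsorted(t, strictly = TRUE)) stop("timestamps must be strictly increasing")
  if (any(value < 0 | value > 4)) stop("scores must lie in [0, 4]")
  if (max(t) > span_tr || min(t) < 1) stop("timestamps outside the series span")
  structure(data.frame(t = t, value = value),
            span_tr = as.integer(span_tr), class = c("behavior_series", "data.frame"))
}

# local linear regression with tricube weights, bandwidth span_tr/2,
# evaluated at eval_t; the window widens to the nearest 3 points if needed
.loess_tricube <- function(t, v, span_tr, eval_t) {
  h0 <- span_tr / 2
  vapply(eval_t, function(t0) {
    d <- abs(t - t0)
    h <- max(h0, sort(d)[min(3L, length(d))] + 1e-9)
    w <- (1 - pmin(d / h, 1)^3)^3
    use <- w > 0
    dt <- t[use] - t0
    W <- w[use]
    # weighted straight-line fit; intercept at t0 is the smoothed value
    sw <- sum(W); swx <- sum(W * dt); swx2 <- sum(W * dt^2)
    swy <- sum(W * v[use]); swxy <- sum(W * dt * v[use])
    det <- sw * swx2 - swx^2
    if (abs(det) < 1e-12) swy / sw
    else (swx2 * swy - swx * swxy) / det
  }, numeric(1L))
}

#' Coupling between a windowed ISFC time course and behaviour
#'
#' Smooths sparse behavioural scores with local linear (tricube-weighted)
#' regression over a `span_tr`-TR span, evaluates the smooth at the window
#' start TRs of the ISFC series, and tests the Pearson correlation between
#' the two series with a phase-randomization permutation p-value
#' ([perm_corr_pvalue()]; the behavioural series is the one randomized).
#'
#' @param isfc_series a `window_series` from [sliding_isfc()], or a numeric
#'   series with TR positions in `at`.
#' @param behavior a [behavior_series()] with at least 3 scores.
#' @param span_tr smoothing span in TRs (30 TRs = 45 s at TR 1.5 s).
#' @param n_perm number of surrogates for the p-value.
#' @param seed optional integer seed.
#' @param at TR positions when `isfc_series` is a plain vector.
#' @return List: `r`, `p`, and the `smoothed` behaviour on the window grid.
#' @export
behavior_coupling <- function(isfc_series, behavior, span_tr = 30L,
                              n_perm = 1000L, seed = NULL, at = NULL) {
  if (inherits(isfc_series, "window_series")) {
    at <- isfc_series$start_trs
    isfc_series <- mean_edge_series(isfc_series)
  }
  if (is.null(at)) at <- seq_along(isfc_series)
  stopifnot(inherits(behavior, "behavior_series"))
  if (nrow(behavior) < 3L) stop("need at least 3 behavioural scores")
  if (stats::sd(behavior$value) == 0) stop("degenerate (constant) behaviour")
  sm <- .loess_tricube(behavior$t, behavior$value, span_tr, at)
  res <- perm_corr_pvalue(sm, isfc_series, n_perm = n_perm, seed = seed)
  list(r = res$r, p = res$p, smoothed = sm, at = at)
}

#' Windowed mean ISFC between and within networks
#'
#' For each pair of networks (A, B), the mean over all ISFC entries with
#' one region in A and one in B, per sliding window; a network paired with
#' itself is summarized by [mean_edges()] of its sub-block. Transient
#' anti-correlations between networks appear as sign flips of these
#' series.
#'
#' @param ds a z-scored [group_dataset()].
#' @param membership character/factor of length `p` assigning each region
#'   to a network (at least 2 networks, none empty).
#' @param window_tr,step_tr window length and shift in TRs.
#' @return List: `start_trs`, `pairs` (two-column matrix of network
#'   names), and `series` (windows x pairs matrix).
#' @export
cross_network_isfc <- function(ds, membership, window_tr, step_tr = 1L) {
  stopifnot(inherits(ds, "group_dataset"))
  membership <- as.character(membership)
  if (length(membership) != ds$p)
    stop("'membership' must assign every region")
  nets <- unique(membership)
  if (length(nets) < 2L) stop("need at least 2 networks")
  ws <- sliding_isfc(ds, window_tr, step_tr)
  pairs <- t(utils::combn(nets, 2L))
  pairs <- rbind(pairs, cbind(nets, nets))    # within-network blocks too
  series <- sapply(seq_len(nrow(pairs)), function(q) {
    a <- membership == pairs[q, 1L]
    b <- membership == pairs[q, 2L]
    vapply(ws$matrices, function(C) {
      blk <- C$values[a, b, drop = FALSE]
      if (pairs[q, 1L] == pairs[q, 2L]) {
        if (nrow(blk) < 2L) NA_real_      # one-region network: no edges
        else mean_edges(blk)
      } else mean(blk, na.rm = TRUE)
    }, numeric(1L))
  })
  series <- matrix(series, nrow = length(ws$start_trs))
  colnames(series) <- paste(pairs[, 1L], pairs[, 2L], sep = ":")
  list(start_trs = ws$start_trs, pairs = pairs, series = series)
}

#' Export a correlation matrix as a drawable graph
#'
#' Converts a `p x p` correlation matrix to node and edge tables using the
#' standard drawing conventions: node diameter proportional to the
#' region's ISC, edge line width `60 * r`, small negative edges
#' (`-0.1 < r < 0`) zeroed out, and edges at or below `-0.1` styled as
#' negative with width `60 * |r|`.
#'
#' @param C a [corr_matrix()]; for ISFC the diagonal supplies the ISC.
#' @param isc optional explicit ISC vector (required for FC matrices whose
#'   diagonal is structurally 1).
#' @param node_scale multiplier from ISC to node diameter.
#' @return List of data frames `nodes` (label, isc, diameter) and `edges`
#'   (from, to, r, width, style).
#' @export
export_graph <- function(C, isc = NULL, node_scale = 1) {
  stopifnot(inherits(C, "corr_matrix"))
  v <- C$values
  p <- nrow(v)
  labs <- rownames(v); if (is.null(labs)) labs <- paste0("R", seq_len(p))
  if (is.null(isc)) {
    if (C$kind != "ISFC")
      stop("supply 'isc' explicitly for FC matrices (their diagonal is 1 by construction)")
    isc <- diag(v)
  }
  ei <- .edge_index(p)
  r <- v[ei]
  width <- ifelse(r >= 0, 60 * r, ifelse(r > -0.1, 0, 60 * abs(r)))
  style <- ifelse(r >= 0, "positive", ifelse(r > -0.1, "zeroed", "negative"))
  list(nodes = data.frame(label = labs, isc = isc,
                          diameter = node_scale * isc),
       edges = data.frame(from = labs[ei[, 1L]], to = labs[ei[, 2L]],
                          r = r, width = width, style = style))
}

#' Write a graph export as edge-list and node TSV files
#'
#' @param g result of [export_graph()].
#' @param prefix output path prefix; writes `<prefix>_nodes.tsv` and
#'   `<prefix>_edges.tsv` (Cytoscape-importable).
#' @return Invisibly, the two paths.
#' @export
write_graph_tsv <- function(g, prefix) {
  np <- paste0(prefix, "_nodes.tsv"); ep <- paste0(prefix, "_edges.tsv")
  utils::write.table(g$nodes, np, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(g$edges, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(np, ep))
}
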