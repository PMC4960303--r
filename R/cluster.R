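#' K-means partition of connectivity feature rows
#'
#' Partitions elements (rows of a correlation/feature matrix) into `K`
#' mutually exclusive clusters minimizing the summed squared Euclidean
#' distance to cluster centroids, taking the best of `n_restarts` random
#' starts. Deterministic under a fixed seed.
#'
#' @param x numeric matrix, one element (e.g. voxel or region correlation
#'   map) per row.
#' @param K number of clusters (`< nrow(x)`).
#' @param n_restarts random restarts (default 10).
#' @param seed optional integer seed.
#' @return Object of class `cluster_solution`: `K`, `labels` (named by
#'   rownames), `centroids`, `inertia` (total within-cluster sum of
#'   squares), `seed`.
#' @export
kmeans_networks <- function(x, K, n_restarts = 10L, seed = NULL) {
  x <- as.matrix(x)
  if (K >= nrow(x)) stop("'K' must be smaller than the number of elements")
  if (K < 1L) stop("'K' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  km <- stats::kmeans(x, centers = K, nstart = n_restarts, iter.max = 200L)
  labels <- km$cluster
  names(labels) <- rownames(x)
  structure(list(K = as.integer(K), labels = labels,
                 centroids = km$centers, inertia = km$tot.withinss,
                 seed = seed),
            class = "cluster_solution")
}

#' Sorensen-Dice overlap matrix between two cluster solutions
#'
#' `D[i, j] = 2 |X_i intersect Y_j| / (|X_i| + |Y_j|)` for cluster `i` of
#' the first solution and cluster `j` of the second, computed over a shared
#' element universe. Identical partitions give a (row-permuted) identity
#' matrix; disjoint clusters give 0.
#'
#' @param sol1,sol2 `cluster_solution`s over the same elements (matched by
#'   name when available, else by position).
#' @return `K1 x K2` matrix of Dice indices in `[0, 1]`.
#' @export
dice_matrix <- function(sol1, sol2) {
  l1 <- sol1$labels; l2 <- sol2$labels
  if (length(l1) != length(l2))
    stop("solutions cover different element universes")
  if (!is.null(names(l1)) && !is.null(names(l2))) {
    if (!setequal(names(l1), names(l2)))
      stop("solutions cover different element universes")
    l2 <- l2[names(l1)]
  }
  ct <- table(factor(l1, levels = seq_len(sol1$K)),
              factor(l2, levels = seq_len(sol2$K)))
  sz1 <- rowSums(ct); sz2 <- colSums(ct)
  d <- 2 * ct / outer(sz1, sz2, `+`)
  matrix(as.numeric(d), sol1$K, sol2$K)
}

#' Choose the number of clusters by split-half Dice reproducibility
#'
#' For each candidate `K`, clusters two independent group-halves' feature
#' matrices (same elements, features from disjoint subject halves),
#' computes the Dice matrix between the two solutions, and scores `K` by
#' the worst row: `min_i max_j D[i, j]`. The chosen `K` maximizes this
#' score (every cluster of half 1 must find a good match in half 2); ties
#' go to the smaller `K`. Uniformly low scores across `K` indicate no
#' reproducible structure, which the returned score table makes visible.
#'
#' @param x1,x2 feature matrices for the two group-halves (same rows).
#' @param k_range candidate cluster counts.
#' @param n_restarts,seed passed to [kmeans_networks()].
#' @return List: chosen `K`, named `scores`, and the per-K solutions.
#' @export
select_k <- function(x1, x2, k_range, n_restarts = 10L, seed = NULL) {
  if (length(k_range) == 0L) stop("empty candidate range")
  if (!is.null(seed)) set.seed(seed)
  k_range <- sort(unique(as.integer(k_range)))
  scores <- numeric(length(k_range))
  sols <- vector("list", length(k_range))
  for (q in seq_along(k_range)) {
    s1 <- kmeans_networks(x1, k_range[q], n_restarts)
    s2 <- kmeans_networks(x2, k_range[q], n_restarts)
    d <- dice_matrix(s1, s2)
    scores[q] <- min(apply(d, 1L, max))
    sols[[q]] <- list(half1 = s1, half2 = s2, dice = d)
  }
  names(scores) <- k_range
  list(K = k_range[which.max(scores)], scores = scores, solutions = sols)
}

#' Agglomerate elements into contiguous ROIs by neighbourhood correlation
#'
#' Greedy spatially constrained agglomeration: repeatedly find the
#' adjacent pair of clusters whose (average) time series are most
#' similar (Pearson), merge them, replace their series by the average of
#' the two, and recompute similarities with the merged cluster's
#' neighbours — stopping when no merge can be made without exceeding
#' `target_size` elements. Ties are broken deterministically in favour of
#' the lowest-index pair. Elements with no neighbours remain singletons
#' (with a warning).
#'
#' @param series matrix, one element time series per row.
#' @param adjacency symmetric logical/0-1 matrix or list of neighbour index
#'   vectors.
#' @param target_size maximum number of elements per output ROI.
#' @return List: `membership` (element to ROI id, 1..n_rois), `sizes`,
#'   `n_rois`, `roi_series` (averaged series per ROI).
#' @export
decluster <- function(series, adjacency, target_size) {
  series <- as.matrix(series)
  ne <- nrow(series)
  if (target_size < 1L) stop("'target_size' must be at least 1")
  if (is.list(adjacency)) {
    adj <- matrix(FALSE, ne, ne)
    for (i in seq_along(adjacency)) adj[i, adjacency[[i]]] <- TRUE
  } else adj <- adjacency != 0
  if (!isTRUE(all.equal(adj, t(adj)))) stop("adjacency must be symmetric")
  diag(adj) <- FALSE
  if (any(rowSums(adj) == 0L))
    warning("element(s) with no neighbours kept as singleton ROIs")

  cl_series <- series                 # current cluster-average series
  size <- rep(1L, ne)
  alive <- rep(TRUE, ne)
  member <- seq_len(ne)               # element -> cluster id (a live row)
  # pairwise similarity among adjacent live clusters; NA when not adjacent
  sim <- suppressWarnings(stats::cor(t(series)))
  sim[!adj] <- NA_real_
  sim[is.na(sim) & adj] <- -Inf       # constant series: least preferred
  sim[!adj] <- NA_real_

  repeat {
    cand <- which(!is.na(sim) & upper.tri(sim), arr.ind = TRUE)
    if (nrow(cand) == 0L) break
    ok <- size[cand[, 1L]] + size[cand[, 2L]] <= target_size
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0L) break
    s <- sim[cand]
    best <- max(s)
    hit <- cand[s == best, , drop = FALSE]
    # deterministic tie-break: lowest first index, then lowest second
    hit <- hit[order(hit[, 1L], hit[, 2L])[1L], ]
    i <- hit[1L]; j <- hit[2L]
    cl_series[i, ] <- (cl_series[i, ] + cl_series[j, ]) / 2
    size[i] <- size[i] + size[j]
    member[member == j] <- i
    alive[j] <- FALSE
    adj[i, ] <- adj[i, ] | adj[j, ]
    adj[, i] <- adj[, i] | adj[, j]
    adj[i, i] <- FALSE
    adj[j, ] <- FALSE; adj[, j] <- FALSE
    sim[j, ] <- NA_real_; sim[, j] <- NA_real_
    nb <- which(adj[i, ] & alive)
    sim[i, ] <- NA_real_; sim[, i] <- NA_real_
    for (m in nb) {
      r <- suppressWarnings(stats::cor(cl_series[i, ], cl_series[m, ]))
      if (is.na(r)) r <- -Inf
      sim[min(i, m), max(i, m)] <- r
      sim[max(i, m), min(i, m)] <- r
    }
  }
  ids <- sort(unique(member))
  membership <- match(member, ids)
  list(membership = membership,
       sizes = as.integer(table(membership)),
       n_rois = length(ids),
       roi_series = cl_series[ids, , drop = FALSE])
}
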