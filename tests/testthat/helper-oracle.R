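# Independent direct-summation oracles for the group correlation methods.
# These deliberately avoid the package's vectorized code paths: explicit
# Pearson sums per entry, explicit atanh/tanh averaging, loops throughout.

clip_r <- function(r) pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)

pearson_hand <- function(x, y) {
  xc <- x - sum(x) / length(x)
  yc <- y - sum(y) / length(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

oracle_group_isfc <- function(xs) {
  k <- length(xs)
  p <- nrow(xs[[1L]])
  zsum <- matrix(0, p, p)
  for (i in seq_len(k)) {
    others <- matrix(0, p, ncol(xs[[1L]]))
    for (j in setdiff(seq_len(k), i)) others <- others + xs[[j]]
    others <- others / (k - 1)
    for (a in seq_len(p)) for (b in seq_len(p))
      zsum[a, b] <- zsum[a, b] + atanh(clip_r(pearson_hand(xs[[i]][a, ],
                                                           others[b, ])))
  }
  avg <- tanh(zsum / k)
  (avg + t(avg)) / 2
}

oracle_group_fc <- function(xs) {
  k <- length(xs)
  p <- nrow(xs[[1L]])
  zsum <- matrix(0, p, p)
  for (i in seq_len(k))
    for (a in seq_len(p)) for (b in seq_len(p))
      zsum[a, b] <- zsum[a, b] + atanh(clip_r(pearson_hand(xs[[i]][a, ],
                                                           xs[[i]][b, ])))
  avg <- tanh(zsum / k)
  avg <- (avg + t(avg)) / 2
  diag(avg) <- 1
  avg
}

# small z-scored random dataset
toy_dataset <- function(k = 3, p = 4, n = 8, seed = 42, tr = 1.5) {
  set.seed(seed)
  xs <- replicate(k, matrix(rnorm(p * n), p, n), simplify = FALSE)
  zscore_subjects(group_dataset(xs, tr = tr))
}

# z-scored simulated dataset in one call
sim_ds <- function(...) zscore_subjects(simulate_group(sim_config(...))$dataset)

# restrict a dataset to a subset of regions
subset_regions <- function(ds, idx) {
  ds$subjects <- lapply(ds$subjects, function(x) x[idx, , drop = FALSE])
  ds$region_labels <- ds$region_labels[idx]
  ds$p <- length(idx)
  ds
}
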