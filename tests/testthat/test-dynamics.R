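test_that("window bookkeeping: counts, labels, and full-length consistency", {
  ds <- toy_dataset(k = 2, p = 3, n = 300, seed = 1)
  ws <- sliding_isfc(ds, 60)
  expect_length(ws$start_trs, 241)               # n - w + 1 at step 1
  expect_equal(ws$start_trs[1], 1)
  # a window as long as the series reproduces the full-series matrix exactly
  ws_full <- sliding_isfc(ds, ds$n)
  expect_length(ws_full$matrices, 1)
  expect_equal(ws_full$matrices[[1]]$values, group_isfc(ds)$values)
  expect_error(sliding_isfc(ds, 301), "longer than")
})

test_that("mean_edges averages exactly the lower off-diagonal entries", {
  m <- matrix(0.3, 2, 2); diag(m) <- 1
  expect_equal(mean_edges(m), 0.3)
  expect_equal(mean_edges(diag(5)), 0)
  set.seed(2)
  a <- matrix(rnorm(25), 5); a <- (a + t(a)) / 2
  acc <- 0; cnt <- 0
  for (i in 2:5) for (j in 1:(i - 1)) { acc <- acc + a[i, j]; cnt <- cnt + 1 }
  expect_equal(mean_edges(a), acc / cnt, tolerance = 1e-12)
  expect_error(mean_edges(matrix(1, 1, 1)), "at least 2")
})

test_that("fingerprints have p(p-1)/2 edges in fixed order and invert exactly", {
  set.seed(3)
  a <- matrix(rnorm(100), 10); a <- (a + t(a)) / 2; diag(a) <- 1
  fp <- fingerprint(a)
  expect_length(fp$edges, 45)
  expect_length(fingerprint(matrix(c(1, .2, .2, 1), 2))$edges, 1)
  expect_equal(fp$edges[1:3], c(a[2, 1], a[3, 1], a[3, 2]))  # row-major order
  expect_equal(fingerprint_matrix(fp), a, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a planted covariance switch shows up in the windowed mean edge", {
  cfg <- sim_config(k = 8, p = 6, n = 240,
                    C_S = list(cor_constant(6, 0), cor_constant(6, 0.8)),
                    states = c(1, 2),
                    segments = data.frame(start = c(1, 121), length = 120),
                    stimulus_share = 0.7, noise_share = 0.3, seed = 77)
  ds <- zscore_subjects(simulate_group(cfg)$dataset)
  ws <- sliding_isfc(ds, 40, step_tr = 10)
  ser <- mean_edge_series(ws)
  early <- ser[ws$start_trs <= 60]
  late <- ser[ws$start_trs >= 160]
  expect_lt(mean(early), 0.15)                  # state with rho = 0
  expect_gt(mean(late), 0.4)                    # state with rho = 0.8
  # stationary control: flat series
  cfg0 <- sim_config(k = 8, p = 6, n = 240, C_S = cor_constant(6, 0.5),
                     stimulus_share = 0.7, noise_share = 0.3, seed = 78)
  ser0 <- mean_edge_series(sliding_isfc(zscore_subjects(simulate_group(cfg0)$dataset),
                                        40, step_tr = 10))
  expect_lt(diff(range(ser0)), 0.35)
})

test_that("segment reordering is exact, involutive, and validated", {
  ds <- toy_dataset(k = 2, p = 3, n = 30, seed = 4)
  segs <- data.frame(start = c(1, 11, 21), length = 10)
  expect_equal(reorder_segments(ds, segs, 1:3)$subjects, ds$subjects)
  swapped <- reorder_segments(ds, segs, c(2, 1, 3))
  expect_false(identical(swapped$subjects, ds$subjects))
  expect_equal(reorder_segments(swapped, segs, c(2, 1, 3))$subjects,
               ds$subjects)
  expect_error(reorder_segments(ds, data.frame(start = c(1, 10), length = 10),
                                1:2), "tile")
  expect_error(reorder_segments(ds, segs, c(1, 1, 2)), "permutation")
})

test_that("split-half reliability is seed-deterministic and null-centred on noise", {
  ds <- sim_ds(k = 8, p = 6, n = 80, stimulus_share = 0, seed = 5)
  r1 <- split_half_reliability(ds, 40, step_tr = 20, n_iter = 10, seed = 2)
  r2 <- split_half_reliability(ds, 40, step_tr = 20, n_iter = 10, seed = 2)
  expect_identical(r1$mean_r, r2$mean_r)
  expect_lt(max(abs(r1$mean_r)), 2 / sqrt(15))   # 15 edges at p = 6
  expect_error(split_half_reliability(subset_regions(ds, 1:6), 40),
               NA)                                # p subset fine, k even
  ds_odd <- ds; ds_odd$subjects <- ds$subjects[1:7]; ds_odd$k <- 7L
  expect_error(split_half_reliability(ds_odd, 40), "odd")

  # strong shared stimulus: reliable fingerprints
  ds_sig <- sim_ds(k = 8, p = 6, n = 80, C_S = random_cor(6, 2, seed = 9),
                   stimulus_share = 0.8, noise_share = 0.2, seed = 6)
  rel <- split_half_reliability(ds_sig, 40, step_tr = 20, n_iter = 10, seed = 3)
  expect_gt(mean(rel$mean_r), 0.6)
})

test_that("behaviour coupling recovers a planted affine relation", {
  t <- 1:200
  ser <- sin(t / 15) + 0.2 * cos(t / 40)
  ts_b <- seq(5, 195, by = 5)
  beh <- behavior_series(ts_b, pmin(4, pmax(0, 2 + ser[ts_b])), 200)
  bc <- behavior_coupling(ser, beh, span_tr = 15, n_perm = 199, seed = 3, at = t)
  expect_gt(bc$r, 0.95)
  expect_lt(bc$p, 0.02)
  expect_error(behavior_coupling(ser, behavior_series(c(10, 20, 30),
               rep(2, 3), 200), n_perm = 10), "constant")
})

test_that("cross-network series reduce to single entries and ignore label order", {
  ds <- toy_dataset(k = 3, p = 2, n = 60, seed = 8)
  cn <- cross_network_isfc(ds, c("A", "B"), window_tr = 30, step_tr = 10)
  ws <- sliding_isfc(ds, 30, step_tr = 10)
  entry <- vapply(ws$matrices, function(C) C$values[1, 2], numeric(1))
  expect_equal(cn$series[, "A:B"], entry, tolerance = 1e-12,
               ignore_attr = TRUE)

  ds4 <- toy_dataset(k = 3, p = 4, n = 60, seed = 9)
  c1 <- cross_network_isfc(ds4, c("A", "A", "B", "B"), 30, 10)
  perm <- c(3, 4, 1, 2)
  c2 <- cross_network_isfc(subset_regions(ds4, perm),
                           c("B", "B", "A", "A"), 30, 10)
  expect_equal(c1$series[, "A:B"], c2$series[, "B:A"], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(cross_network_isfc(ds4, rep("A", 4), 30), "at least 2")
})

test_that("graph export follows the width and small-negative conventions", {
  v <- matrix(c(1, 0.5, -0.05, 0.5, 1, -0.2, -0.05, -0.2, 1), 3, 3)
  C <- corr_matrix(v, kind = "ISFC", k_subjects = 5)
  g <- export_graph(C)
  e <- g$edges
  expect_equal(e$width[e$r == 0.5], 30)                  # 60 x r
  expect_equal(e$width[e$r == -0.05], 0)                 # small negative zeroed
  expect_equal(e$width[e$r == -0.2], 12)                 # negative-styled
  expect_equal(e$style, c("positive", "zeroed", "negative"))
  expect_equal(g$nodes$diameter, diag(v))
  C_fc <- corr_matrix(v, kind = "FC", k_subjects = 5)
  expect_error(export_graph(C_fc), "isc")
  g2 <- export_graph(C_fc, isc = c(0.2, 0.3, 0.4))
  expect_equal(g2$nodes$isc, c(0.2, 0.3, 0.4))
})
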