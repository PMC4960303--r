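test_that("Fisher averaging is exact on constants and bounded at r = 1", {
  expect_equal(fisher_average(c(0.5, 0.5)), 0.5, tolerance = 1e-12)
  expect_equal(fisher_average(c(0.8, 0.2)),
               tanh(mean(atanh(c(0.8, 0.2)))), tolerance = 1e-12)
  one <- fisher_average(1.0)
  expect_true(is.finite(one) && one >= 0.999)
  expect_error(fisher_average(c(NA_real_)), "no valid")
})

test_that("subject-level ISFC entries are plain Pearson correlations", {
  # orthonormal z-scored rows against themselves: identity structure
  x <- rbind(c(1, -1, 1, -1), c(1, 1, -1, -1)) / sqrt(4 / 3)
  s <- subject_isfc(x, x)
  expect_equal(diag(s), c(1, 1), tolerance = 1e-12)
  expect_lt(max(abs(s[row(s) != col(s)])), 1e-12)

  a <- c(0, 1, 0, 1); b <- c(0, 1, 1, 0)
  s2 <- subject_isfc(rbind(a, a), rbind(b, -a))
  expect_equal(s2[1, 1], 0, tolerance = 1e-12)       # hand Pearson: r = 0
  expect_equal(s2[1, 2], -1, tolerance = 1e-12)      # anticorrelation
})

test_that("group ISFC and FC match the direct-summation oracle to 1e-12", {
  ds <- toy_dataset(k = 3, p = 4, n = 8, seed = 42)
  expect_equal(group_isfc(ds)$values, oracle_group_isfc(ds$subjects),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(group_fc(ds)$values, oracle_group_fc(ds$subjects),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(isc(ds), diag(oracle_group_isfc(ds$subjects)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(seed_isfc(ds, 2), oracle_group_isfc(ds$subjects)[2, ],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("shared signal drives the diagonal, unshared noise stays near zero", {
  set.seed(11)
  # identical subjects, independent white-noise region courses
  x <- matrix(rnorm(2 * 2000), 2, 2000)
  ds <- zscore_subjects(group_dataset(list(x, x, x), tr = 1.5))
  C <- group_isfc(ds)$values
  expect_true(all(diag(C) > 0.999))
  expect_lt(max(abs(C[row(C) != col(C)])), 0.05)

  # mutually independent subjects: everything near zero
  ds0 <- toy_dataset(k = 6, p = 4, n = 500, seed = 13)
  expect_lt(max(abs(group_isfc(ds0)$values)), 3 / sqrt(500))
})

test_that("seed map and k = 1 FC behave as special cases", {
  ds <- toy_dataset(k = 3, p = 5, n = 30, seed = 5)
  C <- group_isfc(ds)
  expect_equal(seed_isfc(ds, 3)[3], isc(ds)[3], tolerance = 1e-12)
  expect_error(seed_isfc(ds, 9), "invalid seed")

  d1 <- ds; d1$subjects <- d1$subjects[1]; d1$k <- 1L
  expect_equal(group_fc(d1)$values, cor(t(d1$subjects[[1]])),
               tolerance = 1e-6, ignore_attr = TRUE)   # Fisher clip at diag
  expect_error(group_isfc(d1), "at least 2")
})

test_that("region permutation is equivariant and subject order irrelevant", {
  ds <- toy_dataset(k = 4, p = 5, n = 40, seed = 21)
  C <- group_isfc(ds)$values
  perm <- c(3, 1, 5, 2, 4)
  dsp <- subset_regions(ds, perm)
  expect_equal(group_isfc(dsp)$values, C[perm, perm], tolerance = 1e-12,
               ignore_attr = TRUE)
  dss <- ds; dss$subjects <- ds$subjects[c(4, 2, 1, 3)]
  expect_equal(group_isfc(dss)$values, C, tolerance = 1e-12)
})

test_that("ISFC grows with stimulus share while FC tracks intrinsic structure", {
  shares <- c(0, 0.25, 0.5, 0.75, 1)
  m <- vapply(shares, function(s) {
    mean(vapply(1:5, function(r) {
      ds <- sim_ds(k = 10, p = 6, n = 500, C_S = cor_constant(6, 0.6),
                   stimulus_share = s, C_I = cor_constant(6, 0.3),
                   seed = 100 * r + round(100 * s))
      mean_edges(group_isfc(ds))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(m) > 0))
  expect_lt(abs(m[1]), 0.05)
  # analytic attenuation of the top cell
  expect_equal(m[5], isfc_expected(1, 0.6, 10), tolerance = 0.05)
})

test_that("a per-subject global confound inflates FC but barely moves ISFC", {
  mk <- function(conf) sim_ds(k = 10, p = 6, n = 2000,
                              C_S = cor_constant(6, 0.6), stimulus_share = 0.05,
                              C_I = cor_constant(6, 0.2), noise_share = 0.2,
                              confound_sd = conf, seed = 31)
  d0 <- mk(0); d1 <- mk(0.5)      # same S, I, N realizations by construction
  expect_gt(mean_edges(group_fc(d1)) - mean_edges(group_fc(d0)), 0.1)
  expect_lt(abs(mean_edges(group_isfc(d1)) - mean_edges(group_isfc(d0))), 0.02)
})

test_that("degenerate regions propagate as missing, not as zeros", {
  set.seed(8)
  xs <- replicate(3, matrix(rnorm(80), 4, 20), simplify = FALSE)
  xs <- lapply(xs, function(x) { x[2, ] <- 7; x })    # region 2 flat everywhere
  ds <- suppressWarnings(zscore_subjects(group_dataset(xs, tr = 1)))
  C <- suppressWarnings(group_isfc(ds))$values
  expect_true(all(is.na(C[2, ])))
  expect_true(all(is.na(C[, 2])))
  expect_true(all(is.finite(C[-2, -2])))
})
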