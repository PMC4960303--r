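test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(k = 4, p = 5, n = 60, C_S = cor_constant(5, 0.4),
                    stimulus_share = 0.5, noise_share = 0.2,
                    confound_sd = 0.3, memory_tau = c(0, 0, 5, 5, 0),
                    seed = 123)
  s1 <- simulate_group(cfg)
  s2 <- simulate_group(cfg)
  expect_identical(s1$dataset$subjects, s2$dataset$subjects)
  expect_identical(s1$truth$S, s2$truth$S)
})

test_that("component variances follow the configured budget", {
  cfg <- sim_config(k = 3, p = 4, n = 4000, C_S = cor_constant(4, 0.5),
                    stimulus_share = 0.6, noise_share = 0.1, seed = 17)
  sim <- simulate_group(cfg)
  x <- sim$dataset$subjects[[1]]
  tr3 <- 3 * sqrt(2 / 3999)                      # 3 SE of a unit variance
  expect_lt(max(abs(apply(x, 1, var) - 1)), tr3)
  expect_lt(max(abs(apply(sqrt(0.6) * sim$truth$S, 1, var) - 0.6)), 0.6 * tr3)
  expect_lt(max(abs(apply(sqrt(0.3) * sim$truth$I[[1]], 1, var) - 0.3)),
            0.3 * tr3)
  expect_error(sim_config(k = 2, p = 2, n = 10, stimulus_share = 0.8,
                          noise_share = 0.5), "s \\+ eta")
  expect_error(simulate_group(sim_config(k = 2, p = 2, n = 10,
    C_S = matrix(c(1, 2, 2, 1), 2))), "positive semi-definite")
})

test_that("limiting shares reproduce the rest/task dissociation", {
  # s = 1, no noise: all subjects identical, ISC saturates
  ds1 <- sim_ds(k = 3, p = 3, n = 300, C_S = cor_constant(3, 0.3),
                stimulus_share = 1, seed = 4)
  expect_identical(ds1$subjects[[1]], ds1$subjects[[2]])
  expect_true(all(isc(ds1) > 0.999))
  # s = 0: ISFC empty while FC shows the intrinsic network
  ds0 <- sim_ds(k = 10, p = 6, n = 2000, stimulus_share = 0,
                C_I = cor_constant(6, 0.6), seed = 3)
  expect_lt(max(abs(group_isfc(ds0)$values)), 0.08)
  expect_equal(mean_edges(group_fc(ds0)), 0.6, tolerance = 0.05)
})

test_that("measured ISFC matches the analytic leave-one-out expectation", {
  reps <- vapply(1:10, function(r) {
    ds <- sim_ds(k = 18, p = 4, n = 2000, C_S = cor_constant(4, 0.6),
                 stimulus_share = 0.5, seed = 900 + r)
    c(mean_edges(group_isfc(ds)), mean(isc(ds)))
  }, numeric(2))
  expect_equal(mean(reps[1, ]), isfc_expected(0.5, 0.6, 18), tolerance = 0.02)
  expect_equal(mean(reps[2, ]), isfc_expected(0.5, 1, 18), tolerance = 0.02)
})

test_that("leaky integration is the identity at tau 0 and saturates at large tau", {
  set.seed(6)
  S <- matrix(rnorm(3000), 3, 1000)
  expect_identical(apply_memory(S, 0), S)
  y <- apply_memory(S, c(0, 0, 1e6))[3, ]
  expect_gt(cor(y[-1], y[-1000]), 0.97)           # near-unit autocorrelation
  expect_equal(sd(y), 1, tolerance = 1e-8)
})

test_that("scrambling commutes with integration only for memoryless regions", {
  set.seed(8)
  n <- 120
  segs <- data.frame(start = seq(1, n, by = 20), length = 20)
  S <- matrix(rnorm(2 * n), 2, n)
  scr <- scramble_segments(S, segs, seed = 31)
  # single segment: identity permutation
  one <- scramble_segments(S, data.frame(start = 1, length = n), seed = 1)
  expect_identical(one$S, S)
  # scramble then restore the original order
  restore <- function(m) {
    idx <- unlist(lapply(scr$inverse, function(s)
      seq.int(scr$segments_out$start[s],
              length.out = scr$segments_out$length[s])))
    m[, idx, drop = FALSE]
  }
  expect_identical(restore(scr$S), S)
  # tau = 0: integrate-after-restore equals intact (trivially: no memory)
  expect_equal(restore(apply_memory(scr$S, 0)), apply_memory(S, 0))
  # tau > segment length: history leaks across boundaries, orders differ
  intact40 <- apply_memory(S, 40)
  scram40 <- restore(apply_memory(scr$S, 40))
  expect_gt(max(abs(intact40 - scram40)), 0.5)
  expect_error(scramble_segments(S, data.frame(start = 1, length = 50)),
               "tile")
})

test_that("short-segment scrambling degrades integrator ISFC more than long", {
  n <- 240
  word_segs <- data.frame(start = seq(1, n, by = 6), length = 6)
  para_segs <- data.frame(start = seq(1, n, by = 60), length = 60)
  gap <- vapply(1:8, function(r) {
    vapply(list(para_segs, word_segs), function(sg) {
      cfg <- sim_config(k = 8, p = 4, n = n, C_S = cor_constant(4, 0.7),
                        stimulus_share = 0.8, noise_share = 0.2,
                        memory_tau = 30, segments = sg, seed = 6000 + r)
      mean_edges(group_isfc(zscore_subjects(simulate_group(cfg,
                                            scramble = TRUE)$dataset)))
    }, numeric(1))
  }, numeric(2))
  # graded coherence: word-scale scrambling hurts integrators more
  expect_gt(mean(gap[1, ]), mean(gap[2, ]))
})

test_that("simulated behaviour couples to the series as configured", {
  t <- 1:200
  ser <- sin(t / 20)
  b0 <- simulate_behavior(ser, t, coupling = 0, noise_sd = 1, n_blanks = 40,
                          seed = 2)
  expect_s3_class(b0, "behavior_series")
  expect_true(all(b0$value >= 0 & b0$value <= 4))
  b1 <- simulate_behavior(ser, t, coupling = 1, noise_sd = 0, n_blanks = 40,
                          seed = 2)
  bc <- behavior_coupling(ser, b1, span_tr = 10, n_perm = 99, seed = 3, at = t)
  expect_gt(bc$r, 0.95)
  # coupling 1 with unit noise targets r near 1/sqrt(2): moderate coupling
  rs <- vapply(1:50, function(r) {
    b <- simulate_behavior(ser, t, coupling = 1, noise_sd = 1, n_blanks = 40,
                           seed = 100 + r)
    cor(b$value, ser[b$t])
  }, numeric(1))
  expect_gt(mean(rs), 0.4)
  expect_lt(mean(rs), 0.8)
})

test_that("ISFC estimates the stimulus correlation better than FC when intrinsic structure is strong", {
  rho_s <- 0.6
  cells <- expand.grid(s = c(0.2, 0.4), rho_i = c(0.3, 0.6))
  wins <- unlist(lapply(seq_len(nrow(cells)), function(ci) {
    vapply(1:10, function(r) {
      ds <- sim_ds(k = 18, p = 6, n = 1000,
                   C_S = cor_constant(6, rho_s),
                   stimulus_share = cells$s[ci],
                   C_I = cor_constant(6, cells$rho_i[ci]),
                   seed = 7000 + 100 * ci + r)
      target <- cells$s[ci] * rho_s
      abs(mean_edges(group_isfc(ds)) - target) <
        abs(mean_edges(group_fc(ds)) - target)
    }, logical(1))
  }))
  expect_gte(mean(wins), 0.9)
})
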