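test_that("prediction error vanishes when the truth is plugged back in", {
  ts <- generate_test_set(0.25, 0.5, cn_default)
  pe <- prediction_error(0.25, 0.5, ts, cn_default)
  expect_lt(pe$mean_dpao2_mmhg, 1e-6)
  expect_lt(pe$mean_dpaco2_mmhg, 1e-6)
  # generic properties of the absolute-mean summaries
  pe2 <- prediction_error(0.30, 0.45, ts, cn_default)
  expect_gte(pe2$mean_dpao2_mmhg, 0)
  expect_lte(pe2$mean_dpao2_mmhg, max(pe2$dpao2))
  expect_equal(pe2$mean_dpao2_mmhg, mean(pe2$dpao2))
  expect_length(pe2$dpao2, 17)
})

test_that("FiO2 clusters partition 1000 equidistant identification points", {
  idx <- gasx:::.cluster_index(seq(0.21, 1, length.out = 1000))
  # the first cluster spans 9 percentage points, the others 10, so the
  # counts of an equidistant grid are uneven but partition the run exactly
  expect_equal(as.vector(table(idx)),
               c(114L, 127L, 126L, 127L, 126L, 127L, 126L, 127L))
  expect_equal(sum(table(idx)), 1000L)
  # edges: half-open to the right except the last cluster
  expect_equal(gasx:::.cluster_index(c(0.21, 0.2999, 0.30, 0.8999, 0.90, 1.0)),
               c(1L, 1L, 2L, 7L, 8L, 8L))
})

test_that("a noise-free study recovers every class with near-zero deviation", {
  st <- run_study(t1[c(2, 8), ], n = 8, noise = 0, seed = 1,
                  constants = cn_default)
  expect_equal(nrow(st$raw), 16)
  expect_lt(max(st$raw$mean_dpao2_pct), 1e-3)
  expect_lt(max(st$raw$mean_dpaco2_pct), 1e-3)
  cd <- cluster_deviations(st)
  expect_equal(sum(cd$n), 16)
  expect_true(all(cd$mean_dpao2_pct < 1e-3))
})

test_that("study aggregates are pure functions of the raw table", {
  st <- run_study(t1[c(1, 12), ], n = 24, noise = 0.05, seed = 42,
                  constants = cn_default)
  expect_equal(sum(cluster_deviations(st)$n), nrow(st$raw))
  cd1 <- cluster_deviations(st)
  cd2 <- cluster_deviations(st$raw)
  expect_identical(cd1, cd2)
  opt <- optimal_clusters(st)
  expect_equal(nrow(opt), 2)
  for (j in opt$class) {
    g <- cd1[cd1$class == j, ]
    expect_equal(opt$mean_dpao2_pct[opt$class == j], min(g$mean_dpao2_pct))
  }
  b <- pao2_binned_errors(st)
  expect_true(all(b$mean_dpao2_pct >= 0))
  expect_equal(sum(b$n), nrow(st$raw))
  expect_equal(sum(b$optimal), 1)
  # bins cannot extend beyond the achieved oxygenation range
  expect_lte(max(b$pao2_lo), max(st$raw$pao2_meas))
  expect_error(pao2_binned_errors(st, classes = 99), "no identifications")
})

test_that("leave-none-out verification is exact on noise-free records", {
  fio2 <- c(0.3, 0.5, 0.8, 1.0)
  cur <- simulate_curve(0.17, 0.6, fio2, cn_default)
  meas <- lapply(seq_along(fio2), function(i)
    gx_measurement(fio2[i], cur$pao2[i], cur$paco2[i], cn_default))
  v <- verify_on_measurements(meas)
  expect_equal(dim(v$dpao2), c(4, 4))
  expect_lt(max(v$dpao2), 1e-4)
  expect_lt(max(v$dpaco2), 1e-4)
})

test_that("verification on a noisy severe-class record favours higher-FiO2 identification", {
  fio2 <- c(0.21, 0.5, 0.75, 1.0)
  cur <- simulate_curve(0.30, 0.30, fio2, cn_default)
  set.seed(42)
  meas <- lapply(seq_along(fio2), function(i)
    gx_measurement(fio2[i], cur$pao2[i] * (1 + runif(1, -0.05, 0.05)),
                   cur$paco2[i] * (1 + runif(1, -0.05, 0.05)), cn_default))
  v <- verify_on_measurements(meas)
  expect_equal(dim(v$dpao2), c(4, 4))
  expect_true(all(is.finite(v$summary$mean_dpao2_mmhg)))
  # identification at room air is the most noise-sensitive for an impaired
  # lung: its mean deviation exceeds the best mid/high-FiO2 row
  expect_gt(v$summary$mean_dpao2_mmhg[1], min(v$summary$mean_dpao2_mmhg[-1]))
})

test_that("PaCO2 prediction error is insensitive to the identification FiO2", {
  st <- run_study(t1[c(3, 10), ], n = 48, noise = 0.05, seed = 42,
                  constants = cn_default)
  cd <- cluster_deviations(st)
  for (j in unique(cd$class)) {
    g <- cd[cd$class == j, ]
    expect_lt(diff(range(g$mean_dpaco2_pct)), diff(range(g$mean_dpao2_pct)))
  }
})
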