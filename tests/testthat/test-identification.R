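test_that("the SSE objective weights CO2 deviations threefold", {
  sim <- gx_simulate(0.15, 0.6, 0.5, cn_default)
  m0 <- gx_measurement(0.5, sim$pao2, sim$paco2, cn_default)
  expect_equal(sse_objective(0.15, 0.6, m0), 0, tolerance = 1e-12)
  m1 <- gx_measurement(0.5, sim$pao2 + 1, sim$paco2 + 1, cn_default)
  expect_equal(sse_objective(0.15, 0.6, m1), 4, tolerance = 1e-6)
  m2 <- gx_measurement(0.5, sim$pao2 + 2, sim$paco2, cn_default)
  expect_equal(sse_objective(0.15, 0.6, m2), 4, tolerance = 1e-6)
  # infeasible parameters return the finite penalty, keeping a simplex alive
  expect_equal(sse_objective(0.2, 0, m0), 1e12)
})

test_that("noise-free single-point identification recovers the generating parameters", {
  fit <- gx_fit(measurement = clean_measurement(0.2, 0.5, 0.5))
  expect_lt(fit$sse, 1e-10)
  expect_equal(unname(coef(fit)), c(0.2, 0.5), tolerance = 1e-4)
  expect_true(fit$converged)
  expect_equal(unname(residuals(fit)), c(0, 0), tolerance = 1e-6)
})

test_that("identified models reproduce the generating prediction curve", {
  # prediction equivalence at FiO2 0.6 for a healthy, a moderate and the
  # severest class; f_A recovery may be loose inside the flat valley but
  # the curve must match
  for (j in c(1, 6, 12)) {
    fit <- gx_fit(measurement = clean_measurement(t1$fs[j], t1$fa[j], 0.6))
    ts <- generate_test_set(t1$fs[j], t1$fa[j], cn_default)
    pred <- predict(fit)
    expect_lt(max(abs(pred$pao2 - ts$pao2_sim)), 0.1)
    expect_lt(max(abs(pred$paco2 - ts$paco2_sim)), 0.1)
  }
})

test_that("identified parameters respect the bounds for noisy data", {
  set.seed(3)
  for (k in 1:5) {
    sim <- gx_simulate(0.35, 0.3, 0.4, cn_default)
    fit <- gx_fit(sim$pao2 * (1 + runif(1, -0.05, 0.05)),
                  sim$paco2 * (1 + runif(1, -0.05, 0.05)), 0.4, cn_default)
    expect_gte(coef(fit)[["fs"]], 0); expect_lte(coef(fit)[["fs"]], 0.5)
    expect_gte(coef(fit)[["fa"]], 0); expect_lte(coef(fit)[["fa"]], 0.9)
  }
})

test_that("the minimiser beats the truth on a perturbed objective", {
  sim <- gx_simulate(0.25, 0.5, 0.5, cn_default)
  m <- gx_measurement(0.5, sim$pao2 * 1.05, sim$paco2, cn_default)
  fit <- gx_fit(measurement = m)
  expect_false(isTRUE(all.equal(coef(fit)[["fs"]], 0.25, tolerance = 1e-4)))
  expect_lte(fit$sse, sse_objective(0.25, 0.5, m))
})

test_that("error surface is non-negative with its minimum at the truth cell", {
  # 45-node axes keep the generating pair {0.1, 0.7} exactly on the grid
  m <- clean_measurement(0.1, 0.7, 0.5)
  es <- error_surface(m, resolution = 45)
  expect_identical(dim(es$sse), c(45L, 45L))
  expect_true(all(es$sse >= 0))
  expect_equal(unname(es$argmin), c(0.1, 0.7), tolerance = 1e-9)
  # the continuous optimiser is at least as good as the grid
  fit <- gx_fit(measurement = m)
  expect_gte(min(es$sse), fit$sse - 1e-10)
  expect_error(error_surface(m, resolution = 1), "at least 2")
})

test_that("the objective valley is flat along fa and steep along fs", {
  m <- clean_measurement(0.1, 0.7, 0.5)
  es <- error_surface(m, resolution = 45)
  i0 <- which.min(abs(es$fs - 0.1)); j0 <- which.min(abs(es$fa - 0.7))
  w <- 4
  along_fs <- diff(range(es$sse[(i0 - w):(i0 + w), j0]))
  along_fa <- diff(range(es$sse[i0, (j0 - w):(j0 + w)]))
  expect_gt(along_fs / along_fa, 10)
})

test_that("fit methods expose the model sensibly", {
  fit <- gx_fit(measurement = clean_measurement(0.2, 0.5, 0.5))
  expect_named(coef(fit), c("fs", "fa"))
  pr <- predict(fit, fio2 = c(0.3, 0.6))
  expect_equal(nrow(pr), 2)
  expect_true(all(pr$pao2 > 0))
  s <- summary(fit)
  expect_equal(unname(round(s$vq, 2)), c(6.82, 0.76))
  expect_output(print(fit), "single-point identification")
  sims <- simulate(fit, nsim = 2, seed = 9, noise = 0.05)
  expect_length(sims, 2)
  expect_true(all(abs(sims[[1]]$pao2 / predict(fit)$pao2 - 1) <= 0.05))
  sims2 <- simulate(fit, nsim = 2, seed = 9, noise = 0.05)
  expect_identical(sims, sims2)
})
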