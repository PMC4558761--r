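test_that("the twelve patient classes carry the published parameters and labels", {
  expect_equal(nrow(t1), 12)
  expect_equal(t1$fs[1], 0.05); expect_equal(t1$fa[1], 0.90)
  expect_equal(t1$severity[1], "Healthy")
  expect_equal(t1$fs[8], 0.30); expect_equal(t1$fa[8], 0.50)
  expect_equal(t1$severity[8], "Severe")
  expect_equal(sum(t1$severity == "Severe"), 5)
  expect_equal(round(t1$vq_high, 2), vq_printed$high)
  expect_equal(round(t1$vq_low, 2), vq_printed$low)
})

test_that("P/F severity index decreases strictly with class number", {
  cls <- patient_classes(cn_default, pf = TRUE)
  expect_true(all(diff(cls$pf_ratio) < 0))
  expect_gt(cls$pf_ratio[1], 400)   # healthy class: normal oxygenation index
  expect_lt(cls$pf_ratio[12], 200)  # severest class: ARDS-range index
})

test_that("end-tidal O2 closure follows the respiratory quotient relation", {
  expect_equal(fet_o2_from(0.21, 0.056, 0.8), 0.14)
  expect_equal(fet_o2_from(0.5, 0, 0.8), 0.5)
  expect_error(fet_o2_from(0.21, 0.20, 0.8), "infeasible")
  expect_error(fet_o2_from(0.21, 0.056, 0), "RQ")
})

test_that("measurement sets span the FiO2 range with bounded uniform noise", {
  ms <- generate_measurement_set(0.1, 0.7, n = 1000, noise = 0.05, seed = 7,
                                 constants = cn_default)
  d <- ms$data
  expect_equal(nrow(d), 1000)
  expect_equal(d$fio2[1], 0.21)
  expect_equal(d$fio2[1000], 1.00)
  expect_equal(diff(range(diff(d$fio2))), 0, tolerance = 1e-12) # equidistant
  expect_true(all(abs(d$pao2_meas / d$pao2_sim - 1) <= 0.05))
  expect_true(all(abs(d$paco2_meas / d$paco2_sim - 1) <= 0.05))
  expect_true(all(diff(d$pao2_sim) > 0))
})

test_that("zero noise reproduces the clean curve and seeds are bitwise reproducible", {
  ms0 <- generate_measurement_set(0.2, 0.5, n = 10, noise = 0, seed = 1,
                                  constants = cn_default)
  expect_identical(ms0$data$pao2_meas, ms0$data$pao2_sim)
  a <- generate_measurement_set(0.2, 0.5, n = 25, seed = 123,
                                constants = cn_default)
  b <- generate_measurement_set(0.2, 0.5, n = 25, seed = 123,
                                constants = cn_default)
  expect_identical(a$data, b$data)
  # the generator must not disturb the global RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99)
  invisible(generate_measurement_set(0.2, 0.5, n = 5, seed = 1,
                                     constants = cn_default))
  expect_identical(runif(1), x1)
})

test_that("the 17-point test set sits on the 5%-step grid and matches the generator", {
  ts <- generate_test_set(0.3, 0.5, cn_default)
  expect_equal(nrow(ts), 17)
  expect_equal(ts$fio2, c(0.21, seq(0.25, 1, by = 0.05)))
  # consistency with the measurement-set generator where the grids meet
  ms <- generate_measurement_set(0.3, 0.5, n = 80, noise = 0, seed = 1,
                                 constants = cn_default)
  expect_equal(ts$pao2_sim[1], ms$data$pao2_sim[1], tolerance = 1e-8)
  expect_equal(ts$pao2_sim[17], ms$data$pao2_sim[80], tolerance = 1e-8)
})

test_that("extra classes are reproducible and stay inside the bounds", {
  ex <- extra_classes(32, seed = 5, constants = cn_default, pf = FALSE)
  expect_equal(nrow(ex), 32)
  expect_true(all(ex$fs >= 0 & ex$fs <= 0.5))
  expect_true(all(ex$fa >= 0 & ex$fa <= 0.9))
  ex2 <- extra_classes(32, seed = 5, constants = cn_default, pf = FALSE)
  expect_identical(ex, ex2)
})
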