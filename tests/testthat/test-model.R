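test_that("alveolar ventilation follows tidal volume minus dead space", {
  expect_equal(alveolar_ventilation(cn_default), 4.2)
  cn2 <- patient_constants(V_ds = 1e-9)
  expect_equal(alveolar_ventilation(cn2), cn2$MV, tolerance = 1e-6)
  expect_error(patient_constants(V_tid = 0.5, V_ds = 0.5), "V_tid")
})

test_that("minute ventilation identity and Table-2 defaults hold", {
  expect_equal(cn_default$MV, cn_default$V_tid * cn_default$f_R)
  expect_equal(cn_default$MV, 6)
  expect_equal(cn_default$Q, 5.5)
  expect_equal(cn_default$cHb, 140)
  expect_equal(cn_default$f_Q, 0.9)
})

test_that("V/Q ratios reproduce the published values for representative classes", {
  expect_equal(unname(round(vq_ratios(0.05, 0.90, cn_default), 2)),
               c(1.15, 1.15))
  expect_equal(unname(round(vq_ratios(0.10, 0.70, cn_default), 2)),
               c(3.64, 0.94))
  expect_equal(unname(round(vq_ratios(0.35, 0.15, cn_default), 2)),
               c(14.27, 0.28))
  expect_error(vq_ratios(1, 0.5), "fs")
})

test_that("compartment flux and venous concentration follow the Fick relations", {
  expect_equal(compartment_flux(0.21, 0.21, 2), 0)
  expect_equal(compartment_flux(0.21, 0.15, 0), 0)
  expect_equal(compartment_flux(0.21, 0.15, 0.42), 0.0252)
  expect_error(compartment_flux(1.2, 0.1, 1), "\\[0, 1\\]")
  expect_equal(venous_concentration(200, 0, 5), 200)
  expect_equal(venous_concentration(200, 0.25, 5), 150)
  expect_lt(venous_concentration(180, 0.1, 4), 180)
  expect_error(venous_concentration(200, 0.1, 0), "perfusion")
})

test_that("alveolar solve satisfies the end-tidal mixing constraint and venous equality", {
  for (p in list(c(0.05, 0.9, 0.21), c(0.2, 0.5, 0.5), c(0.35, 0.15, 0.7),
                 c(0.3, 0.3, 1.0))) {
    st <- solve_alveolar_state(p[1], p[2], p[3], cn_default)
    fet_o2 <- st$feto2; fet_co2 <- st$fetco2
    expect_equal((1 - p[2]) * st$FA_O2[["high"]] + p[2] * st$FA_O2[["low"]],
                 fet_o2, tolerance = 1e-9)
    expect_equal((1 - p[2]) * st$FA_CO2[["high"]] + p[2] * st$FA_CO2[["low"]],
                 fet_co2, tolerance = 1e-9)
    expect_lt(abs(st$Cv_O2[["high"]] - st$Cv_O2[["low"]]), 1e-8)
    expect_lt(abs(st$Cv_CO2[["high"]] - st$Cv_CO2[["low"]]), 1e-8)
    expect_true(all(st$FA_O2 >= 0 & st$FA_O2 <= 1))
    expect_true(all(st$FA_CO2 >= 0 & st$FA_CO2 <= 1))
  }
})

test_that("equal V/Q compartments collapse to the end-tidal fractions", {
  # fa = 0.9 gives both compartments the same V/Q ratio, so each equals the
  # end-tidal mixture
  st <- solve_alveolar_state(0.1, 0.9, 0.4, cn_default)
  expect_equal(st$FA_O2[["high"]], st$FA_O2[["low"]], tolerance = 1e-7)
  expect_equal(st$FA_O2[["high"]], st$feto2, tolerance = 1e-7)
  expect_equal(st$FA_CO2[["low"]], st$fetco2, tolerance = 1e-7)
})

test_that("brute-force grid refinement agrees with the Newton solve", {
  # independent oracle: minimise the summed squared venous-equality
  # residuals over a refined grid of the two low-V/Q fractions, using only
  # the public curve functions
  fs <- 0.2; fa <- 0.5; fio2 <- 0.4
  cn <- cn_default
  feto2 <- fet_o2_from(fio2, cn$FetCO2, cn$RQ)
  ctx <- blood_context()
  va <- alveolar_ventilation(cn)
  vent <- c(1 - fa, fa) * va
  perf <- c(1 - cn$f_Q, cn$f_Q) * (1 - fs) * cn$Q
  obj <- function(u1, u2) {
    f1o <- (feto2 - fa * u1) / (1 - fa)
    f1c <- (cn$FetCO2 - fa * u2) / (1 - fa)
    fo <- c(f1o, u1); fc <- c(f1c, u2)
    po2 <- fraction_to_pressure(fo, ctx); pco2 <- fraction_to_pressure(fc, ctx)
    so2 <- o2_saturation(po2, pco2)
    cco <- o2_content(po2[1], pco2[1], ctx)
    cco <- c(cco, o2_content(po2[2], pco2[2], ctx))
    ccc <- co2_content(pco2, so2, ctx)
    cvo <- venous_concentration(cco, compartment_flux(fio2, fo, vent), perf)
    cvc <- venous_concentration(ccc, compartment_flux(0, fc, vent), perf)
    (cvo[1] - cvo[2])^2 + (cvc[1] - cvc[2])^2
  }
  ctr <- c(feto2, cn$FetCO2); half <- c(0.2, 0.03)
  for (lev in 1:6) {
    u1g <- seq(max(0, ctr[1] - half[1]), min(1, ctr[1] + half[1]),
               length.out = 21)
    u2g <- seq(max(0, ctr[2] - half[2]), min(1, ctr[2] + half[2]),
               length.out = 21)
    val <- outer(u1g, u2g, Vectorize(obj))
    idx <- arrayInd(which.min(val), dim(val))
    ctr <- c(u1g[idx[1]], u2g[idx[2]])
    half <- half / 8
  }
  st <- solve_alveolar_state(fs, fa, fio2, cn)
  expect_equal(ctr[1], st$FA_O2[["low"]], tolerance = 1e-4)
  expect_equal(ctr[2], st$FA_CO2[["low"]], tolerance = 1e-4)
})

test_that("mass balance: total gas flux equals the arteriovenous content difference", {
  for (p in list(c(0, 0.5, 0.3), c(0.2, 0.5, 0.5), c(0.35, 0.15, 0.8))) {
    sim <- gx_simulate(p[1], p[2], p[3], cn_default)
    st <- sim$state
    total_o2 <- sum(st$flux_O2) * 1000          # ml/min
    fick_o2 <- cn_default$Q * (sim$cao2 - st$Cv_O2[["high"]])
    expect_equal(total_o2, fick_o2, tolerance = 1e-6)
    total_co2 <- sum(st$flux_CO2) * 1000
    fick_co2 <- cn_default$Q * (sim$caco2 - st$Cv_CO2[["high"]])
    expect_equal(total_co2, fick_co2, tolerance = 1e-6)
  }
})

test_that("arterial mixing follows the shunt-weighted content equation", {
  # no shunt: arterial content is the perfusion-weighted capillary mixture
  sim <- gx_simulate(0, 0.5, 0.5, cn_default)
  st <- sim$state
  expect_equal(sim$cao2,
               0.1 * st$Cc_O2[["high"]] + 0.9 * st$Cc_O2[["low"]],
               tolerance = 1e-9)
  # with shunt, venous admixture pulls arterial O2 content down
  sim2 <- gx_simulate(0.3, 0.5, 0.5, cn_default)
  expect_lt(sim2$cao2, sim$cao2)
})

test_that("arterial pressures are consistent with the inverted curves", {
  sim <- gx_simulate(0.2, 0.5, 0.6, cn_default)
  ctx <- blood_context()
  expect_equal(o2_content(sim$pao2, sim$paco2, ctx), sim$cao2,
               tolerance = 1e-7)
  so2a <- o2_saturation(sim$pao2, sim$paco2)
  expect_equal(co2_content(sim$paco2, so2a, ctx), sim$caco2,
               tolerance = 1e-7)
})

test_that("PaO2 rises with FiO2 and falls with shunt", {
  for (j in c(1, 5, 12)) {
    cur <- simulate_curve(t1$fs[j], t1$fa[j],
                          seq(0.21, 1, length.out = 30), cn_default)
    expect_true(all(diff(cur$pao2) > 0))
  }
  pao2 <- vapply(c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                 function(fs) gx_simulate(fs, 0.5, 0.5, cn_default)$pao2,
                 numeric(1))
  expect_true(all(diff(pao2) < 0))
})

test_that("simulation is deterministic", {
  a <- gx_simulate(0.17, 0.42, 0.37, cn_default)
  b <- gx_simulate(0.17, 0.42, 0.37, cn_default)
  expect_identical(a$pao2, b$pao2)
  expect_identical(a$paco2, b$paco2)
})

test_that("compiled forward core agrees with the R reference implementation", {
  set.seed(11)
  for (k in 1:25) {
    fs <- runif(1, 0, 0.45); fa <- runif(1, 0.12, 0.9)
    fio2 <- runif(1, 0.25, 1)
    a <- gasx:::.gx_forward(fs, fa, fio2, cn_default)
    b <- gasx:::.gx_forward_r(fs, fa, fio2, cn_default)
    expect_lt(abs(a$pao2 - b$pao2), 1e-6)
    expect_lt(abs(a$paco2 - b$paco2), 1e-6)
  }
})

test_that("physically impossible demands fail loudly", {
  # an unventilated compartment receiving 90% of perfusion cannot carry the
  # fixed metabolic O2 uptake: no steady state exists
  expect_error(solve_alveolar_state(0.2, 0, 0.5, cn_default))
  # end-tidal closure breaks down when FetO2 would be negative
  cnx <- patient_constants(FetCO2 = 0.2)
  expect_error(gx_simulate(0.1, 0.7, 0.21, cnx), "FetO2|end-tidal")
})
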