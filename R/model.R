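#' Alveolar ventilation
#'
#' The ventilation actually reaching the alveoli: respiratory frequency
#' times the tidal volume in excess of the anatomic dead space,
#' \code{VA = f_R * (V_tid - V_ds)}.
#'
#' @param constants a [patient_constants()].
#' @return alveolar ventilation, l/min.
#' @export
alveolar_ventilation <- function(constants = patient_constants()) {
  if (!(constants$V_tid > constants$V_ds))
    stop("V_tid must exceed V_ds: no alveolar ventilation")
  constants$f_R * (constants$V_tid - constants$V_ds)
}

#' Ventilation/perfusion ratios of the two alveolar compartments
#'
#' Ratio of ventilation to perfusion per compartment, using total minute
#' ventilation over the compartmental share of non-shunted cardiac output:
#' \code{high = (1 - f_A) MV / ((1 - f_Q)(1 - f_s) Q)} and
#' \code{low = f_A MV / (f_Q (1 - f_s) Q)} with \code{f_Q = 0.9}. An
#' alternative convention divides alveolar ventilation \code{VA} instead of
#' \code{MV}; the MV-based form is the model's reporting convention.
#'
#' @param fs shunt fraction, \code{[0, 1)}.
#' @param fa fraction of alveolar ventilation to the low-V/Q compartment.
#' @param constants a [patient_constants()].
#' @return named numeric vector \code{c(high = , low = )}, unitless.
#' @examples
#' round(vq_ratios(0.10, 0.70), 2)  # high 3.64, low 0.94
#' @export
vq_ratios <- function(fs, fa, constants = patient_constants()) {
  if (fs >= 1 || fs < 0) stop("fs must lie in [0, 1)")
  if (fa < 0 || fa > 1) stop("fa must lie in [0, 1]")
  qn <- (1 - fs) * constants$Q
  c(high = (1 - fa) * constants$MV / ((1 - constants$f_Q) * qn),
    low  = fa * constants$MV / (constants$f_Q * qn))
}

#' Net gas flux of one alveolar compartment
#'
#' Gas exchanged between alveolar air and blood in one compartment:
#' ventilation share times the inspired-minus-alveolar fraction difference,
#' \code{V = vent_share * (F_i - FA)}. Positive for uptake (O2); negative
#' for elimination (CO2, whose inspired fraction is 0).
#'
#' @param fi inspired gas fraction, \code{[0, 1]}.
#' @param fa_frac alveolar gas fraction, \code{[0, 1]}.
#' @param vent_share ventilation reaching the compartment, l/min.
#' @return gas flux, l/min (STPD).
#' @export
compartment_flux <- function(fi, fa_frac, vent_share) {
  if (any(fi < 0 | fi > 1 | fa_frac < 0 | fa_frac > 1))
    stop("gas fractions must lie in [0, 1]")
  if (any(vent_share < 0)) stop("vent_share must be non-negative")
  vent_share * (fi - fa_frac)
}

#' Mixed-venous concentration implied by capillary content and gas flux
#'
#' Fick mass balance of one compartment: the venous inflow content equals
#' the end-capillary content minus the gas taken up per litre of perfusing
#' blood, \code{Cv = Cc - 1000 * flux / perfusion} (flux l/min converted to
#' ml/min; contents ml/l).
#'
#' @param cc end-capillary content, ml/l.
#' @param flux gas flux of the compartment, l/min.
#' @param perfusion blood flow through the compartment, l/min.
#' @return venous content, ml/l.
#' @export
venous_concentration <- function(cc, flux, perfusion) {
  if (any(perfusion <= 0)) stop("perfusion must be positive")
  cc - 1000 * flux / perfusion
}

# Resolve the end-tidal O2 fraction used at a given FiO2: an explicitly
# pinned FetO2 wins; otherwise the metabolic closure FiO2 - FetCO2/RQ.
.resolve_feto2 <- function(fio2, cn, feto2 = NULL) {
  if (!is.null(feto2)) return(feto2)
  if (!is.na(cn$FetO2)) return(cn$FetO2)
  fio2 - cn$FetCO2 / cn$RQ
}

#' Solve the steady-state alveolar gas fractions
#'
#' Finds the alveolar O2 and CO2 fractions of the high- and low-V/Q
#' compartments such that (i) the ventilation-weighted mixture of the two
#' compartments reproduces the end-tidal fractions, and (ii) the mixed-venous
#' concentration implied by each compartment's Fick balance is the same for
#' both compartments (one common venous inflow), for both gases.
#'
#' The two end-tidal mixing constraints are linear, so the high-V/Q
#' fractions are eliminated analytically and a damped Newton iteration (with
#' numerical Jacobian and box safeguarding) runs on the two low-V/Q
#' fractions only. This keeps the system well conditioned in the degenerate
#' corners: at \code{fa = 0.9} both compartments share one V/Q ratio and the
#' iteration converges at its starting point; at \code{fa = 0} the
#' unventilated compartment equilibrates with venous blood.
#'
#' @param fs shunt fraction.
#' @param fa ventilation fraction of the low-V/Q compartment.
#' @param fio2 inspired O2 fraction.
#' @param constants a [patient_constants()].
#' @param feto2 end-tidal O2 fraction; default closes it from FiO2, see
#'   [patient_constants()].
#' @param tol convergence tolerance on the venous-equality residuals, ml/l.
#' @param maxit maximum Newton iterations.
#' @return An object of class \code{"alveolar_state"}: per-compartment
#'   alveolar fractions, partial pressures, saturations, end-capillary and
#'   venous contents and fluxes (components named \code{c(high, low)}), the
#'   end-tidal fractions used, and solver diagnostics.
#' @export
solve_alveolar_state <- function(fs, fa, fio2, constants = patient_constants(),
                                 feto2 = NULL, tol = 1e-9, maxit = 200) {
  if (fs < 0 || fs >= 1) stop("fs must lie in [0, 1)")
  if (fa < 0 || fa > 1) stop("fa must lie in [0, 1]")
  if (fio2 < 0 || fio2 > 1) stop("FiO2 must lie in [0, 1]")
  s <- .alv_core(fs, fa, fio2, constants, feto2 = feto2,
                 tol = tol, maxit = maxit)
  .state_from_core(s, fio2)
}

# dress a lean .alv_core result up as the documented classed state
.state_from_core <- function(s, fio2) {
  structure(list(
    FA_O2 = c(high = s$fo[1], low = s$fo[2]),
    FA_CO2 = c(high = s$fc[1], low = s$fc[2]),
    PO2 = c(high = s$po2[1], low = s$po2[2]),
    PCO2 = c(high = s$pco2[1], low = s$pco2[2]),
    SO2 = c(high = s$so2[1], low = s$so2[2]),
    Cc_O2 = c(high = s$cco[1], low = s$cco[2]),
    Cc_CO2 = c(high = s$ccc[1], low = s$ccc[2]),
    Cv_O2 = c(high = s$cvo[1], low = s$cvo[2]),
    Cv_CO2 = c(high = s$cvc[1], low = s$cvc[2]),
    flux_O2 = c(high = s$vo[1], low = s$vo[2]),
    flux_CO2 = c(high = s$vc[1], low = s$vc[2]),
    vent = s$vent, perfusion = s$perf,
    feto2 = s$feto2, fetco2 = s$fetco2, fio2 = fio2,
    residual = s$res, iterations = s$it), class = "alveolar_state")
}

# Newton core behind solve_alveolar_state()/.gx_forward(): validation-light,
# returns plain per-compartment vectors c(high, low).
.alv_core <- function(fs, fa, fio2, cn, feto2 = NULL, tol = 1e-9,
                      maxit = 200) {
  feto2 <- .resolve_feto2(fio2, cn, feto2)
  fetco2 <- cn$FetCO2
  if (feto2 <= 0)
    stop("infeasible end-tidal closure: FetO2 <= 0 at this FiO2")
  if (feto2 >= fio2)
    stop("need FetO2 < FiO2 for net oxygen uptake")

  va   <- cn$f_R * (cn$V_tid - cn$V_ds)
  if (va <= 0) stop("V_tid must exceed V_ds: no alveolar ventilation")
  vent <- c(1 - fa, fa) * va
  perf <- c(1 - cn$f_Q, cn$f_Q) * (1 - fs) * cn$Q
  pdry <- cn$Pb - cn$PH2O

  hb <- cn$cHb * cn$hufner; alpha_o2 <- cn$alpha_o2
  shift <- cn$sat_shift; kb <- cn$co2_base; kc <- cn$co2_chb
  ko2perf <- 1000 * vent / perf

  # residual of the venous-equality conditions at low-V/Q fractions u
  resid <- function(u) {
    if (fa > 0) {
      f1o <- (feto2 - fa * u[1]) / (1 - fa)
      f1c <- (fetco2 - fa * u[2]) / (1 - fa)
    } else {
      f1o <- feto2; f1c <- fetco2
    }
    fo <- c(f1o, u[1]); fc <- c(f1c, u[2])
    po2  <- pdry * (fo + abs(fo)) / 2
    pco2 <- pdry * (fc + abs(fc)) / 2 + 1e-12
    x <- po2 * shift * pco2^-0.06
    so2 <- 1 / (23400 / (x * x * x + 150 * x) + 1)
    cco  <- hb * so2 + alpha_o2 * po2
    ccc  <- kb * (1 - kc / (3.352 - 0.456 * so2)) * pco2
    cvo  <- cco - ko2perf * (fio2 - fo)
    cvc  <- ccc + ko2perf * fc
    c(cvo[1] - cvo[2], cvc[1] - cvc[2])
  }

  if (fa > 0) {
    lo <- pmax(0, (c(feto2, fetco2) - (1 - fa)) / fa)
    hi <- pmin(1, c(feto2, fetco2) / fa)
  } else {
    lo <- c(0, 0); hi <- c(1, 1)
  }
  u <- pmin(pmax(c(feto2, fetco2), lo), hi)
  r <- resid(u)
  it <- 0L
  fresh <- TRUE
  J <- NULL
  while (max(abs(r)) >= tol && it < maxit) {
    it <- it + 1L
    if (is.null(J)) {
      # numerical Jacobian, differencing away from the upper box edge
      h <- 1e-7
      h1 <- if (u[1] + h > hi[1] + 1e-3) -h else h
      h2 <- if (u[2] + h > hi[2] + 1e-3) -h else h
      J <- cbind((resid(u + c(h1, 0)) - r) / h1,
                 (resid(u + c(0, h2)) - r) / h2)
      fresh <- TRUE
    }
    dt <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
    if (!is.finite(dt) || abs(dt) < 1e-300)
      stop("alveolar solver: singular Jacobian")
    delta <- -c(J[2, 2] * r[1] - J[1, 2] * r[2],
                -J[2, 1] * r[1] + J[1, 1] * r[2]) / dt
    n2 <- sum(r * r)
    t <- 1
    repeat {
      un <- pmin(pmax(u + t * delta, lo), hi)
      rn <- resid(un)
      if (sum(rn * rn) <= n2 || t < 1 / 256) break
      t <- t / 2
    }
    if (sum(rn * rn) > n2) {
      # no descent along this direction
      if (!fresh) { J <- NULL; next }   # stale Jacobian: recompute, retry
      if (all(un == u))
        stop("alveolar solver stalled at the feasibility boundary")
      # fresh Jacobian yet no descent: accept the damped step and continue
    }
    du <- un - u; dr <- rn - r
    if (!is.null(J) && sum(du * du) > 0) {
      # Broyden rank-1 update keeps subsequent steps at one residual
      # evaluation instead of three
      corr <- (dr - c(J[1, 1] * du[1] + J[1, 2] * du[2],
                      J[2, 1] * du[1] + J[2, 2] * du[2])) / sum(du * du)
      J <- J + cbind(corr * du[1], corr * du[2])
      fresh <- FALSE
    }
    u <- un; r <- rn
  }
  if (max(abs(r)) >= tol)
    stop(sprintf(
      "alveolar solver did not converge in %d iterations (|residual| = %.3g ml/l)",
      maxit, max(abs(r))))

  if (fa > 0) {
    f1o <- (feto2 - fa * u[1]) / (1 - fa)
    f1c <- (fetco2 - fa * u[2]) / (1 - fa)
  } else {
    f1o <- feto2; f1c <- fetco2
  }
  fo <- c(f1o, u[1]); fc <- c(f1c, u[2])
  if (any(fo < -1e-8 | fo > 1 + 1e-8 | fc < -1e-8 | fc > 1 + 1e-8))
    stop("infeasible alveolar state: gas fraction outside [0, 1]")
  po2  <- pdry * (fo + abs(fo)) / 2
  pco2 <- pdry * (fc + abs(fc)) / 2 + 1e-12
  x <- po2 * shift * pco2^-0.06
  so2 <- 1 / (23400 / (x * x * x + 150 * x) + 1)
  cco  <- hb * so2 + alpha_o2 * po2
  ccc  <- kb * (1 - kc / (3.352 - 0.456 * so2)) * pco2
  vo   <- vent * (fio2 - fo)
  vc   <- vent * (0 - fc)
  list(fo = fo, fc = fc, po2 = po2, pco2 = pco2, so2 = so2,
       cco = cco, ccc = ccc,
       cvo = cco - 1000 * vo / perf, cvc = ccc - 1000 * vc / perf,
       vo = vo, vc = vc, vent = vent, perf = perf,
       feto2 = feto2, fetco2 = fetco2,
       res = max(abs(r)), it = it)
}

# Safeguarded secant iteration (with bisection bracket [0, pmax]) inverting
# the O2 content curve at fixed PCO2. The curve is strictly increasing, so
# the bracket always contains the root.
.o2_invert <- function(target, pco2, cn, init = 100, pmax = 800) {
  hb <- cn$cHb * cn$hufner; al <- cn$alpha_o2
  sf <- cn$sat_shift * max(pco2, 1e-9)^-0.06
  f <- function(p) {
    x <- p * sf
    hb / (23400 / (x * x * x + 150 * x) + 1) + al * p - target
  }
  lo <- 0; hi <- pmax
  if (f(hi) < 0)
    stop(sprintf("O2 content %.1f ml/l not representable below %g mmHg",
                 target, pmax))
  p0 <- if (init > lo && init < hi) init else 100
  f0 <- f(p0)
  if (f0 > 0) hi <- p0 else lo <- p0
  p1 <- min(max(p0 * 1.02 + 0.01, lo + 1e-6), hi - 1e-6)
  f1 <- f(p1)
  for (k in 1:100) {
    if (abs(f1) < 1e-10) break
    if (f1 > 0) hi <- p1 else lo <- p1
    pn <- p1 - f1 * (p1 - p0) / (f1 - f0)
    if (!is.finite(pn) || pn <= lo || pn >= hi) pn <- (lo + hi) / 2
    p0 <- p1; f0 <- f1
    p1 <- pn; f1 <- f(p1)
  }
  p1
}

# Lean forward simulation used in inner loops: returns pao2/paco2/cao2/
# caco2 through the compiled core. Same mathematics as the R reference
# path .gx_forward_r(), which the tests hold it against.
.gx_forward <- function(fs, fa, fio2, cn, feto2 = NULL,
                        tol = 1e-9, maxit = 200) {
  if (fs < 0 || fs >= 1) stop("fs must lie in [0, 1)")
  if (fa < 0 || fa > 1) stop("fa must lie in [0, 1]")
  if (fio2 < 0 || fio2 > 1) stop("FiO2 must lie in [0, 1]")
  feto2 <- .resolve_feto2(fio2, cn, feto2)
  va <- cn$f_R * (cn$V_tid - cn$V_ds)
  if (va <= 0) stop("V_tid must exceed V_ds: no alveolar ventilation")
  out <- .forward_cpp(fs, fa, fio2, feto2, cn$FetCO2, va,
                      (1 - cn$f_Q) * (1 - fs) * cn$Q,
                      cn$f_Q * (1 - fs) * cn$Q,
                      cn$Pb - cn$PH2O, cn$cHb * cn$hufner, cn$alpha_o2,
                      cn$sat_shift, cn$co2_base, cn$co2_chb, cn$f_Q,
                      tol, as.integer(maxit))
  list(pao2 = out[1], paco2 = out[2], cao2 = out[3], caco2 = out[4],
       fio2 = fio2)
}

# Reference R implementation of the same forward calculation.
.gx_forward_r <- function(fs, fa, fio2, cn, feto2 = NULL,
                          tol = 1e-9, maxit = 200) {
  st <- .alv_core(fs, fa, fio2, cn, feto2 = feto2,
                  tol = tol, maxit = maxit)
  w <- c(1 - cn$f_Q, cn$f_Q) * (1 - fs)
  cao2  <- st$cco[1] * w[1] + st$cco[2] * w[2] + st$cvo[1] * fs
  caco2 <- st$ccc[1] * w[1] + st$ccc[2] * w[2] + st$cvc[1] * fs
  if (!is.finite(cao2) || cao2 <= 0 || !is.finite(caco2) || caco2 <= 0)
    stop("arterial gas content non-positive: infeasible parameters")
  shift <- cn$sat_shift; kb <- cn$co2_base; kc <- cn$co2_chb
  # couple the two inversions through arterial SO2 (Bohr/Haldane): fixed
  # point on PaCO2, PaO2 re-inverted against the forward O2 curve each pass
  paco2 <- 40
  pao2 <- 100
  for (k in 1:60) {
    pao2 <- .o2_invert(cao2, paco2, cn, init = pao2)
    x <- pao2 * shift * paco2^-0.06
    so2a <- 1 / (23400 / (x * x * x + 150 * x) + 1)
    pc <- caco2 / (kb * (1 - kc / (3.352 - 0.456 * so2a)))
    if (abs(pc - paco2) < 1e-10) { paco2 <- pc; break }
    paco2 <- pc
  }
  pao2 <- .o2_invert(cao2, paco2, cn, init = pao2)
  list(pao2 = pao2, paco2 = paco2, cao2 = cao2, caco2 = caco2,
       fio2 = fio2, core = st)
}

#' Simulate arterial blood gases at a given inspired oxygen fraction
#'
#' Forward model run: solve the two-compartment steady state
#' ([solve_alveolar_state()]), mix end-capillary blood of the two
#' compartments with shunted venous blood into arterial blood,
#' \code{Ca = (1 - f_s)((1 - f_Q) Cc_high + f_Q Cc_low) + f_s Cv},
#' and invert the dissociation curves to arterial partial pressures. The two
#' inversions are coupled through arterial saturation and solved jointly.
#'
#' @param fs shunt fraction.
#' @param fa ventilation fraction of the low-V/Q compartment.
#' @param fio2 inspired O2 fraction.
#' @param constants a [patient_constants()].
#' @param feto2 optional pinned end-tidal O2 fraction (default: closed from
#'   FiO2, see [patient_constants()]).
#' @param tol,maxit alveolar-solver settings, see [solve_alveolar_state()].
#' @return An object of class \code{"gx_bloodgas"}: \code{pao2} and
#'   \code{paco2} (mmHg), arterial contents \code{cao2}, \code{caco2}
#'   (ml/l), and the underlying \code{state}.
#' @examples
#' sim <- gx_simulate(0.1, 0.7, fio2 = 0.5)
#' c(sim$pao2, sim$paco2)
#' @export
gx_simulate <- function(fs, fa, fio2, constants = patient_constants(),
                        feto2 = NULL, tol = 1e-9, maxit = 200) {
  out <- .gx_forward(fs, fa, fio2, constants, feto2 = feto2,
                     tol = tol, maxit = maxit)
  out$state <- solve_alveolar_state(fs, fa, fio2, constants, feto2 = feto2,
                                    tol = tol, maxit = maxit)
  class(out) <- "gx_bloodgas"
  out
}

#' @export
print.gx_bloodgas <- function(x, ...) {
  cat(sprintf("Arterial blood gases at FiO2 %.3g: PaO2 %.1f mmHg, PaCO2 %.1f mmHg\n",
              x$fio2, x$pao2, x$paco2))
  invisible(x)
}

#' Simulate a blood-gas curve over a range of inspired oxygen fractions
#'
#' Runs [gx_simulate()] at each FiO2 value and collects the arterial
#' pressures.
#'
#' @param fs,fa model parameters.
#' @param fio2 vector of inspired O2 fractions.
#' @param constants a [patient_constants()].
#' @return data frame with columns \code{fio2}, \code{pao2}, \code{paco2}.
#' @export
simulate_curve <- function(fs, fa, fio2, constants = patient_constants()) {
  out <- vapply(fio2, function(f) {
    s <- .gx_forward(fs, fa, f, constants)
    c(s$pao2, s$paco2)
  }, numeric(2))
  data.frame(fio2 = fio2, pao2 = out[1, ], paco2 = out[2, ])
}
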