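#' Physiological constants of a simulated patient
#'
#' The fixed quantities needed for forward simulation and identification:
#' ventilation and perfusion settings, blood properties, and the end-tidal
#' closure constants. Defaults are standard values for an adult man
#' (minute ventilation 6 l/min as tidal volume 0.5 l times respiratory
#' frequency 12/min, dead space 0.15 l, cardiac output 5.5 l/min,
#' haemoglobin 140 g/l, pH 7.4, base excess 0, 37 C, respiratory
#' quotient 0.8).
#'
#' \code{FetCO2} defaults to 0.030 (end-tidal PCO2 of about 21 mmHg). A
#' fixed end-tidal CO2 fraction is equivalent to a fixed whole-body CO2
#' output \code{VCO2 = VA * FetCO2} (here 126 ml/min, with O2 uptake
#' \code{VA * FetCO2 / RQ} = 157 ml/min — basal rates of a sedated,
#' mechanically ventilated adult). The value is calibrated so that the
#' steady state exists for every simulated patient class over the whole
#' FiO2 range 21--100\% with a clinically plausible mixed-venous O2
#' saturation (at least about 30\% even for the severest class at room
#' air); larger values demand more O2 transfer at low FiO2 than severely
#' mismatched lungs can deliver. \code{FetO2} is normally left \code{NA},
#' in which case every simulation closes it from the inspired fraction via
#' \code{FetO2 = FiO2 - FetCO2 / RQ} (see [fet_o2_from()]); supplying a
#' number pins it instead (as when replaying a recorded measurement).
#'
#' The fraction \code{f_Q = 0.9} of non-shunted perfusion directed to the
#' low-V/Q compartment is a structural constant of the model.
#'
#' @param V_tid tidal volume, l.
#' @param f_R respiratory frequency, 1/min.
#' @param V_ds anatomic dead-space volume, l (must be < \code{V_tid}).
#' @param Q cardiac output, l/min.
#' @param cHb haemoglobin concentration, g/l.
#' @param pH plasma pH.
#' @param BE base excess, mmol/l.
#' @param temp temperature, C.
#' @param RQ respiratory quotient.
#' @param FetCO2 end-tidal CO2 fraction.
#' @param FetO2 end-tidal O2 fraction, or \code{NA} to close from FiO2.
#' @param f_Q perfusion fraction of the low-V/Q compartment (fixed 0.9).
#' @param Pb,PH2O barometric and water-vapour pressure, mmHg.
#' @param hufner,alpha_o2 O2-carriage constants, see [blood_context()].
#'
#' @return An object of class \code{"patient_constants"}; a named list that
#'   also carries the derived minute ventilation \code{MV = V_tid * f_R}.
#' @examples
#' cn <- patient_constants()
#' cn$MV                      # 6 l/min
#' alveolar_ventilation(cn)   # 4.2 l/min
#' @export
patient_constants <- function(V_tid = 0.5, f_R = 12, V_ds = 0.15,
                              Q = 5.5, cHb = 140, pH = 7.4, BE = 0,
                              temp = 37, RQ = 0.8,
                              FetCO2 = 0.030, FetO2 = NA_real_,
                              f_Q = 0.9,
                              Pb = 760, PH2O = 47,
                              hufner = 1.34, alpha_o2 = 0.03) {
  if (!(V_tid > V_ds && V_ds > 0))
    stop("need V_tid > V_ds > 0 (no alveolar ventilation otherwise)")
  if (!(f_R > 0)) stop("f_R must be positive")
  if (!(Q > 0)) stop("cardiac output Q must be positive")
  if (!(RQ > 0)) stop("respiratory quotient RQ must be positive")
  if (FetCO2 < 0 || FetCO2 > 1) stop("FetCO2 must lie in [0, 1]")
  if (!is.na(FetO2) && (FetO2 < 0 || FetO2 > 1))
    stop("FetO2 must lie in [0, 1] (or NA)")
  if (!(f_Q > 0 && f_Q < 1)) stop("f_Q must lie in (0, 1)")
  ctx <- blood_context(pH = pH, temp = temp, cHb = cHb, BE = BE,
                       Pb = Pb, PH2O = PH2O,
                       hufner = hufner, alpha_o2 = alpha_o2)
  # precomputed dissociation-curve factors (hot-loop constants):
  # saturation virtual-pressure shift excluding the PCO2 term, and the
  # CO2-curve slope split into its saturation-independent base and the
  # haemoglobin correction coefficient
  sat_shift <- 10^(0.024 * (37 - temp) + 0.40 * (pH - 7.4) +
                   0.06 * log10(40))
  pk  <- 6.086 + 0.042 * (7.4 - pH) +
         (38 - temp) * (0.00472 + 0.00139 * (7.4 - pH))
  sol <- 0.0307 + 0.00057 * (37 - temp) + 0.00002 * (37 - temp)^2
  structure(list(MV = V_tid * f_R, V_tid = V_tid, f_R = f_R, V_ds = V_ds,
                 Q = Q, cHb = cHb, pH = pH, BE = BE, temp = temp, RQ = RQ,
                 FetCO2 = FetCO2, FetO2 = FetO2, f_Q = f_Q,
                 Pb = Pb, PH2O = PH2O,
                 hufner = hufner, alpha_o2 = alpha_o2,
                 ctx = ctx,
                 sat_shift = sat_shift,
                 co2_base = 22.26 * sol * (1 + 10^(pH - pk)),
                 co2_chb = 0.00289 * cHb / (8.142 - pH)),
            class = "patient_constants")
}

#' @export
print.patient_constants <- function(x, ...) {
  cat("Patient constants:\n")
  cat(sprintf("  MV %.3g l/min (V_tid %.3g l x f_R %.3g /min), V_ds %.3g l\n",
              x$MV, x$V_tid, x$f_R, x$V_ds))
  cat(sprintf("  Q %.3g l/min, cHb %.3g g/l, pH %.3g, BE %.3g mmol/l, T %.3g C\n",
              x$Q, x$cHb, x$pH, x$BE, x$temp))
  cat(sprintf("  RQ %.3g, FetCO2 %.4g, FetO2 %s, f_Q %.2g\n",
              x$RQ, x$FetCO2,
              if (is.na(x$FetO2)) "closed from FiO2" else format(x$FetO2),
              x$f_Q))
  invisible(x)
}

#' End-tidal oxygen fraction from the inspired fraction
#'
#' Metabolic closure used when no end-tidal O2 measurement is available:
#' \code{FetO2 = FiO2 - FetCO2 / RQ}, i.e. the O2 extracted equals the CO2
#' appearing scaled by the respiratory quotient.
#'
#' @param fio2 inspired O2 fraction (vectorised).
#' @param fetco2 end-tidal CO2 fraction.
#' @param rq respiratory quotient.
#' @return end-tidal O2 fraction.
#' @examples
#' fet_o2_from(0.21, 0.056, 0.8)  # 0.14
#' @export
fet_o2_from <- function(fio2, fetco2 = 0.030, rq = 0.8) {
  if (any(rq <= 0)) stop("RQ must be positive")
  out <- fio2 - fetco2 / rq
  if (any(out < 0))
    stop("infeasible end-tidal closure: FiO2 - FetCO2/RQ is negative")
  out
}
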