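#' Blood context: acid-base and physical constants for the dissociation curves
#'
#' Bundles the quantities the O2 and CO2 dissociation curves depend on:
#' plasma pH, blood temperature, haemoglobin concentration, base excess, and
#' the ambient-pressure constants used to convert dry gas fractions to
#' partial pressures.
#'
#' @param pH plasma pH (unitless), default 7.4.
#' @param temp blood temperature in degrees Celsius, default 37.
#' @param cHb haemoglobin concentration in g/l, default 140.
#' @param BE base excess in mmol/l, default 0 (carried for completeness; the
#'   implemented CO2 curve is parameterised directly by pH).
#' @param Pb barometric pressure in mmHg, default 760 (sea level).
#' @param PH2O saturated water-vapour pressure in mmHg, default 47 (37 C).
#' @param hufner oxygen-binding capacity of haemoglobin in ml O2 per g Hb
#'   (Huefner constant), default 1.34.
#' @param alpha_o2 solubility of O2 in blood, ml O2 per (l blood * mmHg),
#'   default 0.03.
#'
#' @return An object of class \code{"blood_context"}: a named list of the
#'   validated constants.
#' @examples
#' ctx <- blood_context()
#' o2_content(100, 40, ctx)
#' @export
blood_context <- function(pH = 7.4, temp = 37, cHb = 140, BE = 0,
                          Pb = 760, PH2O = 47,
                          hufner = 1.34, alpha_o2 = 0.03) {
  if (!(pH > 6.5 && pH < 8.0)) stop("pH must lie in (6.5, 8.0)")
  if (!(temp > 30 && temp < 43)) stop("temperature must lie in (30, 43) C")
  if (!(cHb > 0)) stop("cHb must be positive")
  if (!(Pb > PH2O && PH2O >= 0)) stop("need Pb > PH2O >= 0")
  structure(list(pH = pH, temp = temp, cHb = cHb, BE = BE,
                 Pb = Pb, PH2O = PH2O,
                 hufner = hufner, alpha_o2 = alpha_o2),
            class = "blood_context")
}

#' Convert a dry gas fraction to a partial pressure
#'
#' Partial pressure of a gas in humidified alveolar air:
#' \code{P = F * (Pb - PH2O)}.
#'
#' @param frac dry gas fraction in \code{[0, 1]} (vectorised).
#' @param ctx a [blood_context()].
#' @return partial pressure in mmHg.
#' @export
fraction_to_pressure <- function(frac, ctx = blood_context()) {
  if (any(frac < 0 | frac > 1)) stop("gas fraction must lie in [0, 1]")
  frac * (ctx$Pb - ctx$PH2O)
}

#' Haemoglobin oxygen saturation
#'
#' Severinghaus' equation for the adult oxyhaemoglobin dissociation curve,
#' \code{SO2 = 1 / (23400 / (x^3 + 150 x) + 1)}, evaluated at a virtual
#' oxygen pressure \code{x} that applies Kelman's corrections shifting the
#' curve for pH, PCO2 (Bohr effect) and temperature away from the standard
#' state (pH 7.4, PCO2 40 mmHg, 37 C).
#'
#' @param po2 oxygen partial pressure, mmHg (vectorised).
#' @param pco2 carbon dioxide partial pressure, mmHg; default 40.
#' @param pH plasma pH; default 7.4.
#' @param temp temperature, C; default 37.
#' @return saturation in \code{[0, 1]}.
#' @references Severinghaus JW (1979) J Appl Physiol 46:599-602.
#'   Kelman GR (1966) J Appl Physiol 21:1375-1376.
#' @export
o2_saturation <- function(po2, pco2 = 40, pH = 7.4, temp = 37) {
  if (any(po2 < 0)) stop("PO2 must be non-negative")
  x <- po2 * 10^(0.024 * (37 - temp) + 0.40 * (pH - 7.4) +
                 0.06 * (log10(40) - log10(pmax(pco2, 1e-6))))
  s <- 1 / (23400 / (x^3 + 150 * x) + 1)
  s[po2 <= 0] <- 0
  pmin(pmax(s, 0), 1)
}

# Lean unvalidated saturation kernel for inner loops (inputs >= 0).
.sat <- function(po2, pco2, pH, temp) {
  pco2 <- (pco2 + abs(pco2)) / 2 + 1e-9
  x <- po2 * 10^(0.024 * (37 - temp) + 0.40 * (pH - 7.4) +
                 0.06 * (log10(40) - log10(pco2)))
  1 / (23400 / (x * x * x + 150 * x) + 1)
}

#' Oxygen content of blood
#'
#' Haemoglobin-bound plus physically dissolved oxygen:
#' \code{cHb * hufner * SO2(PO2) + alpha_o2 * PO2}, in ml O2 (STPD) per litre
#' of blood.
#'
#' @param po2,pco2 partial pressures, mmHg (vectorised over \code{po2}).
#' @param ctx a [blood_context()].
#' @return O2 content, ml/l.
#' @export
o2_content <- function(po2, pco2 = 40, ctx = blood_context()) {
  if (any(po2 < 0)) stop("PO2 must be non-negative")
  s <- o2_saturation(po2, pco2, ctx$pH, ctx$temp)
  ctx$cHb * ctx$hufner * s + ctx$alpha_o2 * po2
}

# Lean CO2-curve slope for inner loops; see co2_k().
.co2k <- function(so2, pH, temp, cHb) {
  pk  <- 6.086 + 0.042 * (7.4 - pH) +
         (38 - temp) * (0.00472 + 0.00139 * (7.4 - pH))
  sol <- 0.0307 + 0.00057 * (37 - temp) + 0.00002 * (37 - temp)^2
  rb  <- 1 - (0.00289 * cHb) / ((3.352 - 0.456 * so2) * (8.142 - pH))
  22.26 * sol * (1 + 10^(pH - pk)) * rb
}

# Proportionality constant of the CO2 content curve: content = k(SO2) * PCO2.
# Douglas et al. (1988) whole-blood CO2 curve: plasma content from CO2
# solubility and the Henderson-Hasselbalch bicarbonate term, scaled to whole
# blood by a haemoglobin- and saturation-dependent factor (Haldane effect).
# Units: ml CO2 (STPD) per l blood per mmHg (22.26 ml per mmol CO2).
co2_k <- function(so2, ctx) .co2k(so2, ctx$pH, ctx$temp, ctx$cHb)

#' Carbon dioxide content of blood
#'
#' Whole-blood CO2 content (dissolved + bicarbonate/carbamino) after Douglas
#' et al. (1988): the plasma curve from CO2 solubility and the
#' Henderson-Hasselbalch relation, corrected to whole blood with a
#' haemoglobin- and oxygen-saturation-dependent factor, which carries the
#' Haldane effect (deoxygenated blood holds more CO2).
#'
#' @param pco2 CO2 partial pressure, mmHg (vectorised).
#' @param so2 oxygen saturation of the same blood, \code{[0, 1]}.
#' @param ctx a [blood_context()].
#' @return CO2 content, ml/l.
#' @references Douglas AR, Jones NL, Reed JW (1988) J Appl Physiol
#'   64:473-477.
#' @export
co2_content <- function(pco2, so2 = 0.97, ctx = blood_context()) {
  if (any(pco2 < 0)) stop("PCO2 must be non-negative")
  if (any(so2 < 0 | so2 > 1)) stop("SO2 must lie in [0, 1]")
  co2_k(so2, ctx) * pco2
}

#' Invert the oxygen dissociation curve
#'
#' Oxygen partial pressure at which [o2_content()] equals \code{content},
#' found by safeguarded 1-D root bracketing on the (strictly increasing)
#' forward curve over \code{[0, 800]} mmHg.
#'
#' @param content O2 content, ml/l.
#' @param pco2 CO2 partial pressure of the same blood, mmHg.
#' @param ctx a [blood_context()].
#' @param pmax upper end of the bracketing interval, mmHg.
#' @return PO2, mmHg.
#' @export
o2_pressure <- function(content, pco2 = 40, ctx = blood_context(),
                        pmax = 800) {
  if (length(content) > 1)
    return(vapply(content, o2_pressure, numeric(1), pco2 = pco2, ctx = ctx,
                  pmax = pmax))
  if (content < 0) stop("O2 content must be non-negative")
  if (content == 0) return(0)
  top <- o2_content(pmax, pco2, ctx)
  if (content > top)
    stop(sprintf("O2 content %.1f ml/l exceeds maximum %.1f ml/l at %g mmHg",
                 content, top, pmax))
  stats::uniroot(function(p) o2_content(p, pco2, ctx) - content,
                 lower = 0, upper = pmax, tol = 1e-10)$root
}

#' Invert the carbon dioxide dissociation curve
#'
#' CO2 partial pressure at which [co2_content()] equals \code{content}. At
#' fixed saturation, pH and temperature the implemented curve is
#' proportional to PCO2, so the inverse is analytic.
#'
#' @param content CO2 content, ml/l (vectorised).
#' @param so2 oxygen saturation of the same blood, \code{[0, 1]}.
#' @param ctx a [blood_context()].
#' @return PCO2, mmHg.
#' @export
co2_pressure <- function(content, so2 = 0.97, ctx = blood_context()) {
  if (any(content < 0)) stop("CO2 content must be non-negative")
  content / co2_k(so2, ctx)
}
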