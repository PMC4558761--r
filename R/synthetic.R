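#' The 17-point inspired-oxygen evaluation grid
#'
#' FiO2 values 21\% and 25\% to 100\% in 5\% steps, the fixed grid on which
#' prediction accuracy is scored.
#'
#' @return numeric vector of length 17.
#' @export
test_fio2_grid <- function() c(0.21, seq(0.25, 1, by = 0.05))

#' The twelve simulated patient classes
#'
#' Parameter pairs \code{(f_s, f_A)} spanning pulmonary impairment from
#' healthy to severe, with the V/Q ratios of both compartments
#' ([vq_ratios()]), an impairment label, and (optionally) a simulated
#' severity index \code{pf_ratio}: the minimum of PaO2/FiO2 over the
#' 17-point grid, which decreases strictly from class 1 to class 12.
#'
#' @param constants a [patient_constants()].
#' @param pf if \code{TRUE} (default) simulate the P/F severity index per
#'   class (runs 17 forward simulations per class).
#' @return data frame with one row per class: \code{j}, \code{fs},
#'   \code{fa}, \code{vq_high}, \code{vq_low}, \code{severity}, and
#'   \code{pf_ratio} when \code{pf = TRUE}.
#' @export
patient_classes <- function(constants = patient_constants(), pf = FALSE) {
  fs <- c(0.05, 0.10, 0.15, 0.20, 0.20, 0.25, 0.25, 0.30, 0.30, 0.35, 0.35, 0.35)
  fa <- c(0.90, 0.70, 0.70, 0.70, 0.50, 0.50, 0.30, 0.50, 0.30, 0.50, 0.30, 0.15)
  severity <- c("Healthy", "Mild", "Mild", "Moderate", "Moderate", "Moderate",
                "Moderate", "Severe", "Severe", "Severe", "Severe", "Severe")
  vq <- t(mapply(vq_ratios, fs, fa, MoreArgs = list(constants = constants)))
  out <- data.frame(j = 1:12, fs = fs, fa = fa,
                    vq_high = vq[, "high"], vq_low = vq[, "low"],
                    severity = severity)
  if (pf) out$pf_ratio <- vapply(1:12, function(j)
    pf_ratio(fs[j], fa[j], constants), numeric(1))
  out
}

#' Simulated P/F severity index
#'
#' Minimum of PaO2/FiO2 over the 17-point FiO2 grid for a given parameter
#' pair — a single oxygenation-impairment number per simulated patient
#' (lower is more severe).
#'
#' @param fs,fa model parameters.
#' @param constants a [patient_constants()].
#' @return P/F ratio, mmHg.
#' @export
pf_ratio <- function(fs, fa, constants = patient_constants()) {
  cur <- simulate_curve(fs, fa, test_fio2_grid(), constants)
  min(cur$pao2 / cur$fio2)
}

#' Generate a noisy synthetic measurement set for one patient class
#'
#' Forward-simulates \code{n} noise-free blood-gas pairs at equidistant FiO2
#' values between 21\% and 100\% and corrupts both gases with independent
#' uniformly distributed multiplicative noise of half-width \code{noise}
#' (default \eqn{\pm}5\%), emulating blood-gas measurement error.
#'
#' @param fs,fa generating model parameters (a row of [patient_classes()]).
#' @param n number of measurements, default 1000.
#' @param noise relative noise half-width, default 0.05; \code{0} gives
#'   clean data.
#' @param seed RNG seed; the global RNG state is restored afterwards, so a
#'   stored seed regenerates the set bit-for-bit.
#' @param constants a [patient_constants()].
#' @return object of class \code{"gx_measurement_set"}: a list with
#'   \code{data} (data frame \code{fio2}, \code{pao2_sim},
#'   \code{paco2_sim}, \code{pao2_meas}, \code{paco2_meas}), the generating
#'   parameters, \code{noise} and \code{seed}.
#' @export
generate_measurement_set <- function(fs, fa, n = 1000, noise = 0.05,
                                     seed = 1L,
                                     constants = patient_constants()) {
  if (n < 2) stop("need at least 2 measurements")
  if (noise < 0) stop("noise must be non-negative")
  fio2 <- seq(0.21, 1, length.out = n)
  clean <- simulate_curve(fs, fa, fio2, constants)
  rng <- .with_seed(seed)
  on.exit(rng())
  eps_o2 <- stats::runif(n, -noise, noise)
  eps_co2 <- stats::runif(n, -noise, noise)
  structure(list(
    data = data.frame(fio2 = fio2,
                      pao2_sim = clean$pao2, paco2_sim = clean$paco2,
                      pao2_meas = clean$pao2 * (1 + eps_o2),
                      paco2_meas = clean$paco2 * (1 + eps_co2)),
    fs = fs, fa = fa, noise = noise, seed = seed,
    constants = constants), class = "gx_measurement_set")
}

#' @export
print.gx_measurement_set <- function(x, ...) {
  cat(sprintf(
    "Synthetic measurement set: fs = %.3g, fa = %.3g, %d points, noise +/-%g%%, seed %s\n",
    x$fs, x$fa, nrow(x$data), 100 * x$noise, format(x$seed)))
  invisible(x)
}

#' Generate the noise-free 17-point test set for one patient class
#'
#' The reference curve on which prediction accuracy is evaluated: exact
#' model output at the 17 FiO2 values of [test_fio2_grid()].
#'
#' @param fs,fa generating model parameters.
#' @param constants a [patient_constants()].
#' @return data frame \code{fio2}, \code{pao2_sim}, \code{paco2_sim}
#'   (17 rows).
#' @export
generate_test_set <- function(fs, fa, constants = patient_constants()) {
  cur <- simulate_curve(fs, fa, test_fio2_grid(), constants)
  data.frame(fio2 = cur$fio2, pao2_sim = cur$pao2, paco2_sim = cur$paco2)
}

#' Sample additional simulated patient classes
#'
#' Draws parameter pairs uniformly over \code{fs} in \code{[0.03, 0.38]}
#' and \code{fa} in \code{[0.15, 0.90]} — the steady-state-feasible region
#' under the end-tidal closure, spanning roughly the P/F range of the
#' twelve named classes — to densify the severity-versus-optimal-FiO2
#' relation.
#'
#' @param n number of classes.
#' @param seed RNG seed (state restored afterwards).
#' @param constants a [patient_constants()].
#' @param pf simulate the per-class P/F severity index (default TRUE).
#' @return data frame \code{j}, \code{fs}, \code{fa} and, when
#'   \code{pf = TRUE}, \code{pf_ratio}.
#' @export
extra_classes <- function(n = 32, seed = 1L,
                          constants = patient_constants(), pf = TRUE) {
  if (n < 1) stop("need n >= 1")
  rng <- .with_seed(seed)
  fs <- stats::runif(n, 0.03, 0.38)
  fa <- stats::runif(n, 0.15, 0.90)
  rng()
  out <- data.frame(j = seq_len(n), fs = fs, fa = fa)
  if (pf) out$pf_ratio <- vapply(seq_len(n), function(i)
    pf_ratio(fs[i], fa[i], constants), numeric(1))
  out
}
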