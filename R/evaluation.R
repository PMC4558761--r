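#' Prediction error of an identified parameter pair against a test set
#'
#' Forward-simulates the identified model over the 17-point FiO2 grid and
#' scores it against the noise-free reference curve of the generating
#' class: mean absolute deviation per gas, in mmHg and as percent of the
#' true value.
#'
#' @param fs_star,fa_star identified parameters.
#' @param test_set reference curve from [generate_test_set()] (columns
#'   \code{fio2}, \code{pao2_sim}, \code{paco2_sim}).
#' @param constants a [patient_constants()].
#' @return list with \code{mean_dpao2_mmhg}, \code{mean_dpao2_pct},
#'   \code{mean_dpaco2_mmhg}, \code{mean_dpaco2_pct} and the per-point
#'   absolute deviations \code{dpao2}, \code{dpaco2} (mmHg).
#' @export
prediction_error <- function(fs_star, fa_star, test_set,
                             constants = patient_constants()) {
  pred <- simulate_curve(fs_star, fa_star, test_set$fio2, constants)
  dpao2 <- abs(pred$pao2 - test_set$pao2_sim)
  dpaco2 <- abs(pred$paco2 - test_set$paco2_sim)
  list(mean_dpao2_mmhg = mean(dpao2),
       mean_dpao2_pct = mean(dpao2 / test_set$pao2_sim) * 100,
       mean_dpaco2_mmhg = mean(dpaco2),
       mean_dpaco2_pct = mean(dpaco2 / test_set$paco2_sim) * 100,
       dpao2 = dpao2, dpaco2 = dpaco2)
}

# FiO2 cluster edges: 21-30, 30-40, ..., 90-100 % (integer-derived so the
# edges are the exact doubles nearest each decimal)
.cluster_breaks <- function() c(0.21, seq(30L, 100L, by = 10L) / 100)

# cluster index 1..8 for identification FiO2 values (half-open on the
# right except the last cluster, closed at 100 %)
.cluster_index <- function(fio2) {
  findInterval(fio2, .cluster_breaks(), rightmost.closed = TRUE)
}

#' Run the practical-identifiability study over simulated patient classes
#'
#' For every class, generates \code{n} noisy single measurements across
#' FiO2 21--100\% ([generate_measurement_set()]), identifies \code{{f_s,
#' f_A}} from each measurement alone ([gx_fit()]), predicts the 17-point
#' noise-free test curve, and records the prediction error
#' ([prediction_error()]). Aggregates (clusters, optima, pooled CO2
#' statistics) are pure functions of the returned raw table and can be
#' recomputed from it at any time.
#'
#' @param classes data frame with columns \code{j}, \code{fs}, \code{fa}
#'   (e.g. [patient_classes()], [extra_classes()]).
#' @param n noisy measurements (hence identifications) per class.
#' @param noise relative measurement-noise half-width.
#' @param seed master seed; per-class streams are derived from it, so the
#'   whole study is reproducible.
#' @param constants a [patient_constants()].
#' @param control,restarts simplex settings forwarded to [gx_fit()]; the
#'   defaults are slightly looser than [gx_fit()]'s own because parameter
#'   precision far below the measurement noise does not change the error
#'   statistics.
#' @param verbose print one progress line per class.
#' @return An object of class \code{"gx_study"}: \code{raw} (one row per
#'   identification: class, generating parameters, identification FiO2 and
#'   measured gases, identified parameters, SSE, convergence flag and the
#'   four error summaries), \code{classes}, \code{n}, \code{noise},
#'   \code{seed}, and \code{failed} (count of identifications whose
#'   forward prediction failed; excluded from \code{raw}).
#' @seealso [cluster_deviations()], [optimal_clusters()],
#'   [pao2_binned_errors()], [paco2_summary()]
#' @export
run_study <- function(classes = patient_classes(), n = 200, noise = 0.05,
                      seed = 1L, constants = patient_constants(),
                      control = list(reltol = 1e-10, maxit = 1000),
                      restarts = 1, verbose = FALSE) {
  rows <- vector("list", nrow(classes))
  failed <- 0L
  for (ci in seq_len(nrow(classes))) {
    j <- classes$j[ci]; fs <- classes$fs[ci]; fa <- classes$fa[ci]
    ms <- generate_measurement_set(fs, fa, n = n, noise = noise,
                                   seed = seed + 7919L * as.integer(j),
                                   constants = constants)
    ts <- generate_test_set(fs, fa, constants)
    d <- ms$data
    res <- matrix(NA_real_, n, 9)
    for (i in seq_len(n)) {
      fit <- gx_fit(d$pao2_meas[i], d$paco2_meas[i], d$fio2[i], constants,
                    control = control, restarts = restarts)
      pe <- tryCatch(prediction_error(coef(fit)[[1]], coef(fit)[[2]], ts,
                                      constants),
                     error = function(e) NULL)
      if (is.null(pe)) { failed <- failed + 1L; next }
      res[i, ] <- c(coef(fit), fit$sse, as.numeric(fit$converged),
                    pe$mean_dpao2_mmhg, pe$mean_dpao2_pct,
                    pe$mean_dpaco2_mmhg, pe$mean_dpaco2_pct,
                    fit$n_evals)
    }
    ok <- !is.na(res[, 1])
    rows[[ci]] <- data.frame(
      class = j, fs_true = fs, fa_true = fa,
      fio2_ident = d$fio2[ok],
      pao2_meas = d$pao2_meas[ok], paco2_meas = d$paco2_meas[ok],
      fs_star = res[ok, 1], fa_star = res[ok, 2],
      sse = res[ok, 3], converged = res[ok, 4] > 0,
      mean_dpao2_mmhg = res[ok, 5], mean_dpao2_pct = res[ok, 6],
      mean_dpaco2_mmhg = res[ok, 7], mean_dpaco2_pct = res[ok, 8],
      n_evals = res[ok, 9])
    if (verbose)
      message(sprintf("class %s: %d/%d identifications, median dPaO2 %.2f%%",
                      format(j), sum(ok), n,
                      stats::median(res[ok, 6])))
  }
  structure(list(raw = do.call(rbind, rows), classes = classes,
                 n = n, noise = noise, seed = seed, failed = failed,
                 constants = constants),
            class = "gx_study")
}

#' @export
print.gx_study <- function(x, ...) {
  cat(sprintf(
    "Identifiability study: %d classes x %d noisy single-point identifications (noise +/-%g%%, seed %s)\n",
    nrow(x$classes), x$n, 100 * x$noise, format(x$seed)))
  pc <- paco2_summary(x)
  cat(sprintf("  pooled mean |dPaCO2|: %.2f%% (%.2f mmHg) of the true value\n",
              pc$mean_pct, pc$mean_mmhg))
  opt <- optimal_clusters(x)
  cat("  per-class optimal identification-FiO2 cluster:\n")
  print(opt[, c("class", "cluster", "fio2_lo", "fio2_hi", "mean_dpao2_pct")],
        row.names = FALSE)
  invisible(x)
}

#' Cluster the prediction errors by identification FiO2
#'
#' Partitions each class's identifications into the eight FiO2 clusters
#' 21--30, 30--40, ..., 90--100\% and summarises the mean PaO2 test-curve
#' deviation per cluster (mean and SD, in \% of true value and mmHg), plus
#' the same for PaCO2.
#'
#' @param study a [run_study()] result (or its \code{raw} data frame).
#' @return data frame, one row per class and cluster: \code{class},
#'   \code{cluster}, \code{fio2_lo}, \code{fio2_hi}, \code{n},
#'   \code{mean_dpao2_pct}, \code{sd_dpao2_pct}, \code{mean_dpao2_mmhg},
#'   \code{mean_dpaco2_pct}, \code{sd_dpaco2_pct}.
#' @export
cluster_deviations <- function(study) {
  raw <- if (is.data.frame(study)) study else study$raw
  br <- .cluster_breaks()
  cl <- .cluster_index(raw$fio2_ident)
  out <- do.call(rbind, lapply(split(raw, list(raw$class, cl), drop = TRUE,
                                     sep = "\r"), function(g) {
    k <- .cluster_index(g$fio2_ident[1])
    data.frame(class = g$class[1], cluster = k,
               fio2_lo = br[k], fio2_hi = br[k + 1], n = nrow(g),
               mean_dpao2_pct = mean(g$mean_dpao2_pct),
               sd_dpao2_pct = stats::sd(g$mean_dpao2_pct),
               mean_dpao2_mmhg = mean(g$mean_dpao2_mmhg),
               mean_dpaco2_pct = mean(g$mean_dpaco2_pct),
               sd_dpaco2_pct = stats::sd(g$mean_dpaco2_pct))
  }))
  out <- out[order(out$class, out$cluster), ]
  rownames(out) <- NULL
  out
}

#' Optimal identification cluster per class
#'
#' For each class, the FiO2 cluster whose identifications give the smallest
#' mean PaO2 prediction deviation.
#'
#' @param study a [run_study()] result or a [cluster_deviations()] table.
#' @return data frame, one row per class, with the winning cluster's index,
#'   bounds, midpoint and mean deviation.
#' @export
optimal_clusters <- function(study) {
  cd <- if (is.data.frame(study) && "cluster" %in% names(study)) study
        else cluster_deviations(study)
  out <- do.call(rbind, lapply(split(cd, cd$class), function(g) {
    w <- g[which.min(g$mean_dpao2_pct), ]
    w$fio2_mid <- (w$fio2_lo + w$fio2_hi) / 2
    w
  }))
  out <- out[order(out$class), ]
  rownames(out) <- NULL
  out
}

#' Pooled PaCO2 prediction-error statistics
#'
#' Mean and SD, over all identifications of all classes, of the mean
#' absolute PaCO2 test-curve deviation.
#'
#' @param study a [run_study()] result or its raw table.
#' @return list \code{mean_pct}, \code{sd_pct}, \code{mean_mmhg},
#'   \code{sd_mmhg}.
#' @export
paco2_summary <- function(study) {
  raw <- if (is.data.frame(study)) study else study$raw
  list(mean_pct = mean(raw$mean_dpaco2_pct),
       sd_pct = stats::sd(raw$mean_dpaco2_pct),
       mean_mmhg = mean(raw$mean_dpaco2_mmhg),
       sd_mmhg = stats::sd(raw$mean_dpaco2_mmhg))
}

#' Prediction error as a function of the measured PaO2
#'
#' Bins identifications by the measured PaO2 of the identification point
#' and summarises the mean PaO2 test-curve deviation per bin, pooled over
#' the requested classes.
#'
#' @param study a [run_study()] result or its raw table.
#' @param classes class labels to pool (default: all present).
#' @param width bin width, mmHg.
#' @return data frame, one row per non-empty bin: \code{pao2_lo},
#'   \code{pao2_hi}, \code{n}, \code{mean_dpao2_pct}, \code{sd_dpao2_pct};
#'   the bin minimising the mean deviation is marked in column
#'   \code{optimal}.
#' @export
pao2_binned_errors <- function(study, classes = NULL, width = 50) {
  raw <- if (is.data.frame(study)) study else study$raw
  if (!is.null(classes)) raw <- raw[raw$class %in% classes, ]
  if (nrow(raw) == 0) stop("no identifications in the requested classes")
  bin <- floor(raw$pao2_meas / width)
  out <- do.call(rbind, lapply(split(raw, bin), function(g) {
    b <- floor(g$pao2_meas[1] / width)
    data.frame(pao2_lo = b * width, pao2_hi = (b + 1) * width, n = nrow(g),
               mean_dpao2_pct = mean(g$mean_dpao2_pct),
               sd_dpao2_pct = stats::sd(g$mean_dpao2_pct))
  }))
  out <- out[order(out$pao2_lo), ]
  out$optimal <- seq_len(nrow(out)) == which.min(out$mean_dpao2_pct)
  rownames(out) <- NULL
  out
}

#' Cross-validated identification over a set of recorded measurements
#'
#' Emulates the bedside verification workflow: identify the model at each
#' recorded measurement in turn, predict the blood gases at the FiO2 of
#' every recorded measurement, and tabulate the absolute deviations from
#' the measured values.
#'
#' @param measurements a list of [gx_measurement()] (each may carry its own
#'   constants), or a data frame as returned by
#'   [read_measurements_csv()]'s \code{$data}.
#' @param ... forwarded to [gx_fit()].
#' @return An object of class \code{"gx_verification"}: square matrices
#'   \code{dpao2} and \code{dpaco2} (row = identification point, column =
#'   evaluated point, mmHg), a per-identification-point summary data frame
#'   \code{summary} (mean deviations in mmHg and \% of the measured value),
#'   and \code{skipped} (indices of measurements where identification
#'   failed).
#' @export
verify_on_measurements <- function(measurements, ...) {
  if (is.data.frame(measurements))
    measurements <- .measurements_from_df(measurements)
  nm <- length(measurements)
  if (nm < 2) stop("need at least 2 measurements")
  dpao2 <- matrix(NA_real_, nm, nm)
  dpaco2 <- matrix(NA_real_, nm, nm)
  skipped <- integer(0)
  pao2_meas <- vapply(measurements, `[[`, numeric(1), "pao2")
  paco2_meas <- vapply(measurements, `[[`, numeric(1), "paco2")
  for (i in seq_len(nm)) {
    m <- measurements[[i]]
    fit <- tryCatch(gx_fit(measurement = m, ...), error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$sse)) {
      warning(sprintf("identification failed at measurement %d; skipped", i))
      skipped <- c(skipped, i)
      next
    }
    for (k in seq_len(nm)) {
      pred <- tryCatch(
        .gx_forward(coef(fit)[[1]], coef(fit)[[2]],
                    measurements[[k]]$fio2, measurements[[k]]$constants),
        error = function(e) NULL)
      if (is.null(pred)) next
      dpao2[i, k] <- abs(pred$pao2 - pao2_meas[k])
      dpaco2[i, k] <- abs(pred$paco2 - paco2_meas[k])
    }
  }
  fio2 <- vapply(measurements, `[[`, numeric(1), "fio2")
  summ <- data.frame(
    fio2_ident = fio2, pao2_meas = pao2_meas,
    mean_dpao2_mmhg = rowMeans(dpao2, na.rm = TRUE),
    mean_dpao2_pct = rowMeans(sweep(dpao2, 2, pao2_meas, "/"),
                              na.rm = TRUE) * 100,
    mean_dpaco2_mmhg = rowMeans(dpaco2, na.rm = TRUE),
    mean_dpaco2_pct = rowMeans(sweep(dpaco2, 2, paco2_meas, "/"),
                               na.rm = TRUE) * 100)
  structure(list(dpao2 = dpao2, dpaco2 = dpaco2, summary = summ,
                 skipped = skipped), class = "gx_verification")
}

#' @export
print.gx_verification <- function(x, ...) {
  cat(sprintf("Leave-none-out verification over %d recorded measurements\n",
              nrow(x$summary)))
  print(round(x$summary, 2), row.names = FALSE)
  if (length(x$skipped))
    cat("  skipped identification points:",
        paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
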