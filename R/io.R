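#' Default study configuration
#'
#' The full set of tunable quantities with their defaults: the
#' physiological constants of [patient_constants()] and the study settings
#' (number of noisy measurements per class, noise level, master seed,
#' error-surface resolution, PaO2 bin width).
#'
#' @return nested list with elements \code{constants} and \code{study}.
#' @export
gx_config <- function() {
  list(constants = list(V_tid = 0.5, f_R = 12, V_ds = 0.15, Q = 5.5,
                        cHb = 140, pH = 7.4, BE = 0, temp = 37, RQ = 0.8,
                        FetCO2 = 0.030, FetO2 = NA_real_, f_Q = 0.9,
                        Pb = 760, PH2O = 47,
                        hufner = 1.34, alpha_o2 = 0.03),
       study = list(n = 200, noise = 0.05, seed = 1,
                    resolution = 90, bin_width = 50))
}

#' Read a study configuration from YAML
#'
#' Unspecified fields keep their defaults ([gx_config()]); unknown keys are
#' an error so that typos cannot silently fall back to defaults.
#'
#' @param path YAML file.
#' @return list as [gx_config()], with \code{constants} additionally
#'   instantiated as a [patient_constants()] under
#'   \code{$patient_constants}.
#' @export
load_config <- function(path) {
  cfg <- gx_config()
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  bad <- setdiff(names(user), names(cfg))
  if (length(bad))
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "))
  for (sec in names(user)) {
    bad <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
    if (length(bad))
      stop(sprintf("unknown key(s) in '%s': %s", sec,
                   paste(bad, collapse = ", ")))
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  cfg$patient_constants <- do.call(patient_constants, cfg$constants)
  cfg
}

#' Write a study configuration to YAML
#'
#' @param cfg a configuration list as returned by [gx_config()] or
#'   [load_config()].
#' @param path output file.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg[c("constants", "study")], path)
  invisible(path)
}

# canonical lower-case column names accepted in measurement tables
.meas_cols <- c(fio2 = "fio2", pao2 = "pao2", paco2 = "paco2",
                f_r = "f_R", q = "Q", v_tid = "V_tid", v_ds = "V_ds",
                chb = "cHb", ph = "pH", t = "temp", be = "BE", rq = "RQ",
                fetco2 = "FetCO2", feto2 = "FetO2")

.measurements_from_df <- function(df, defaults = patient_constants()) {
  names(df) <- tolower(names(df))
  need <- c("fio2", "pao2", "paco2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  known <- intersect(names(df), names(.meas_cols))
  for (col in known)
    if (!is.numeric(df[[col]]))
      stop(sprintf("column '%s' is not numeric", col))
  def_args <- formals(patient_constants)
  lapply(seq_len(nrow(df)), function(i) {
    args <- list()
    for (col in setdiff(known, need)) {
      v <- df[[col]][i]
      if (!is.na(v)) args[[.meas_cols[[col]]]] <- v
    }
    # inherit non-default fields of the supplied constants object
    for (nm in names(def_args))
      if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
    args$MV <- NULL
    cn <- do.call(patient_constants, args)
    # a row without a FetO2 measurement gets the metabolic closure at its
    # own FiO2 (and keeps it fixed, as a recorded value would be)
    if (is.na(cn$FetO2))
      cn$FetO2 <- fet_o2_from(df$fio2[i], cn$FetCO2, cn$RQ)
    gx_measurement(df$fio2[i], df$pao2[i], df$paco2[i], cn)
  })
}

#' Read recorded blood-gas measurements from CSV
#'
#' Reads a measurement table in the bedside format: one row per blood-gas
#' analysis with columns \code{fio2}, \code{pao2}, \code{paco2}
#' (mandatory), and optionally the per-row physiological constants
#' \code{f_r}, \code{q}, \code{v_tid}, \code{v_ds}, \code{chb}, \code{ph},
#' \code{t}, \code{be}, \code{rq}, \code{fetco2}, \code{feto2} (column
#' names case-insensitive; fractions as decimals in \code{[0, 1]},
#' pressures in mmHg). Rows lacking a measured \code{feto2} get it from
#' the metabolic closure \code{FiO2 - FetCO2/RQ}.
#'
#' @param path CSV file (header row mandatory).
#' @param defaults a [patient_constants()] supplying any constant not
#'   present as a column.
#' @return list of [gx_measurement()], one per row, each carrying its own
#'   constants; the parsed table is attached as attribute \code{"data"}.
#' @export
read_measurements_csv <- function(path, defaults = patient_constants()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- .measurements_from_df(df, defaults)
  attr(out, "data") <- df
  out
}

#' Write a study report to JSON (and the raw table to CSV)
#'
#' Persists the aggregate statistics (cluster summaries, per-class optima,
#' pooled PaCO2 statistics) together with the study settings, and the raw
#' per-identification table as CSV next to it. All aggregates are pure
#' functions of the raw table, so re-reading the CSV and re-aggregating
#' reproduces the JSON content exactly.
#'
#' @param study a [run_study()] result.
#' @param path output JSON file; the raw table goes to the same name with
#'   extension \code{.csv} unless \code{csv_path} is given.
#' @param csv_path optional explicit CSV path.
#' @return invisibly, the JSON path.
#' @export
write_report <- function(study, path, csv_path = NULL) {
  if (is.null(csv_path)) csv_path <- sub("\\.json$", ".csv", path)
  if (identical(csv_path, path)) csv_path <- paste0(path, ".csv")
  report <- list(
    settings = list(n = study$n, noise = study$noise, seed = study$seed,
                    classes = study$classes[, c("j", "fs", "fa")],
                    failed = study$failed),
    paco2 = paco2_summary(study),
    clusters = cluster_deviations(study),
    optimal_clusters = optimal_clusters(study))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null", pretty = TRUE)
  utils::write.csv(study$raw, csv_path, row.names = FALSE)
  invisible(path)
}
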