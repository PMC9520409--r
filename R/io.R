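# Readers/writers for the package's plain-text formats.  All times are
# serialized in ms except trend timestamps, which are in seconds; units are
# embedded in column names.  Files written here re-read and re-write
# byte-stably.

read_csv_checked <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path)
  for (cl in cols) {
    if (!cl %in% names(dt))
      stop("parse error in ", path, ": missing column '", cl, "'")
    v <- dt[[cl]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      stop("parse error in ", path, ": non-numeric value in column '", cl,
           "' at data row ", if (length(bad)) bad[1] else "?")
    }
  }
  dt
}

#' Read / write an atrial or ventricular impulse series CSV
#'
#' Single column `time_ms` of strictly increasing impulse times.
#'
#' @param path file path.
#' @param x numeric vector of times (ms).
#' @return `read_aa_csv` returns the numeric vector; `write_aa_csv` returns
#'   `path` invisibly.
#' @export
read_aa_csv <- function(path) {
  dt <- read_csv_checked(path, "time_ms")
  x <- as.numeric(dt$time_ms)
  if (is.unsorted(x, strictly = TRUE))
    stop("parse error in ", path, ": time_ms must be strictly increasing")
  x
}

#' @rdname read_aa_csv
#' @export
write_aa_csv <- function(x, path) {
  data.table::fwrite(data.table::data.table(time_ms = as.numeric(x)), path)
  invisible(path)
}

#' Read / write an RR series CSV
#'
#' Columns `rr_ms` (positive intervals) and `valid` (0/1 exclusion mask).
#'
#' @param path file path.
#' @param rr an `rr_series`.
#' @return `read_rr_csv` returns an `rr_series`.
#' @export
read_rr_csv <- function(path) {
  dt <- read_csv_checked(path, c("rr_ms", "valid"))
  rr_series(as.numeric(dt$rr_ms), as.numeric(dt$valid) != 0)
}

#' @rdname read_rr_csv
#' @export
write_rr_csv <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  data.table::fwrite(data.table::data.table(
    rr_ms = rr$intervals, valid = as.integer(rr$valid)), path)
  invisible(path)
}

#' Read / write an AA parameter trend CSV
#'
#' Columns `time_s`, `mu_ms`, `sigma_ms`.
#'
#' @param path file path.
#' @param trend an `aa_param_trend`.
#' @return `read_trend_csv` returns an `aa_param_trend`.
#' @export
read_trend_csv <- function(path) {
  dt <- read_csv_checked(path, c("time_s", "mu_ms", "sigma_ms"))
  aa_param_trend(as.numeric(dt$time_s), as.numeric(dt$mu_ms),
                 as.numeric(dt$sigma_ms))
}

#' @rdname read_trend_csv
#' @export
write_trend_csv <- function(trend, path) {
  data.table::fwrite(data.table::data.table(
    time_s = trend$time_s, mu_ms = trend$mu_ms, sigma_ms = trend$sigma_ms),
    path)
  invisible(path)
}

#' Read / write an AFR trend CSV
#'
#' Columns `time_s`, `afr_hz` at uniform (0.02 s) resolution.
#'
#' @param path file path.
#' @param afr an `afr_trend`.
#' @return `read_afr_csv` returns an `afr_trend`.
#' @export
read_afr_csv <- function(path) {
  dt <- read_csv_checked(path, c("time_s", "afr_hz"))
  if (any(dt$afr_hz <= 0))
    stop("parse error in ", path, ": afr_hz must be positive")
  structure(data.frame(time_s = as.numeric(dt$time_s),
                       afr_hz = as.numeric(dt$afr_hz)),
            class = c("afr_trend", "data.frame"))
}

#' @rdname read_afr_csv
#' @export
write_afr_csv <- function(afr, path) {
  data.table::fwrite(data.table::data.table(
    time_s = afr$time_s, afr_hz = afr$afr_hz), path)
  invisible(path)
}

#' Read / write model parameters as JSON
#'
#' JSON object with keys `sp`, `fp`, `cn` (each holding the six pathway
#' parameters in ms) and scalar `a_r`, `a_d`.
#'
#' @param path file path.
#' @param mp a `model_params` (with scalar scales).
#' @return `read_params_json` returns a `model_params`.
#' @export
read_params_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in c("sp", "fp", "cn"))
    if (is.null(j[[k]])) stop("parse error in ", path, ": missing key '", k, "'")
  pp <- function(l) do.call(pathway_params, as.list(l)[c(
    "r_min", "delta_r", "tau_r", "d_min", "delta_d", "tau_d")])
  model_params(sp = pp(j$sp), fp = pp(j$fp), cn = pp(j$cn),
               a_r = if (is.null(j$a_r)) 1 else j$a_r,
               a_d = if (is.null(j$a_d)) 1 else j$a_d)
}

#' @rdname read_params_json
#' @export
write_params_json <- function(mp, path) {
  stopifnot(inherits(mp, "model_params"),
            is.numeric(mp$a_r), is.numeric(mp$a_d))
  jsonlite::write_json(list(sp = unclass(mp$sp), fp = unclass(mp$fp),
                            cn = unclass(mp$cn), a_r = mp$a_r, a_d = mp$a_d),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read / write a parameter-set ensemble as JSON
#'
#' A JSON array of model-parameter objects (see [read_params_json()]).
#'
#' @param path file path.
#' @param ensemble list of `model_params`.
#' @return `read_ensemble_json` returns a list of `model_params`.
#' @export
read_ensemble_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(j, function(e) {
    pp <- function(l) do.call(pathway_params, l[c(
      "r_min", "delta_r", "tau_r", "d_min", "delta_d", "tau_d")])
    model_params(sp = pp(e$sp), fp = pp(e$fp),
                 cn = if (is.null(e$cn)) cn_default() else pp(e$cn),
                 a_r = if (is.null(e$a_r)) 1 else e$a_r,
                 a_d = if (is.null(e$a_d)) 1 else e$a_d)
  })
}

#' @rdname read_ensemble_json
#' @export
write_ensemble_json <- function(ensemble, path) {
  jsonlite::write_json(lapply(ensemble, function(mp) list(
    sp = unclass(mp$sp), fp = unclass(mp$fp), cn = unclass(mp$cn),
    a_r = mp$a_r, a_d = mp$a_d)), path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}

#' Read a tilt protocol file (YAML or JSON)
#'
#' Expects a `segments` list of three entries with `label`, `duration_s`,
#' `a_r`, `a_d` (supine, HDT, HUT order).
#'
#' @param path file path (`.yaml`, `.yml` or `.json`).
#' @return A `tilt_protocol`.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = FALSE)
       else yaml::read_yaml(path)
  if (is.null(j$segments) || length(j$segments) != 3)
    stop("parse error in ", path, ": need a 'segments' list of 3 entries")
  g <- function(field) vapply(j$segments, function(s) as.numeric(s[[field]]),
                              numeric(1))
  tilt_protocol(durations_s = g("duration_s"), a_r = g("a_r"), a_d = g("a_d"))
}

#' Write a tilt protocol YAML file
#' @param protocol a `tilt_protocol`.
#' @param path file path.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "tilt_protocol"))
  yaml::write_yaml(list(segments = lapply(1:3, function(k) list(
    label = protocol$labels[k], duration_s = protocol$durations_s[k],
    a_r = protocol$a_r[k], a_d = protocol$a_d[k]))), path)
  invisible(path)
}

#' Write a sensitivity result CSV
#'
#' One row per parameter: coefficients, dummy thresholds (repeated per row)
#' and influential flags.
#'
#' @param res a `sensitivity_result`.
#' @param path file path.
#' @export
write_sensitivity_csv <- function(res, path) {
  stopifnot(inherits(res, "sensitivity_result"))
  df <- res$coefficients[, c("parameter", "s_mean", "s_rmssd", "s_sampen",
                             "influential_mean", "influential_rmssd",
                             "influential_sampen")]
  df$dummy_mean <- res$dummy[["dummy_mean"]]
  df$dummy_rmssd <- res$dummy[["dummy_rmssd"]]
  df$dummy_sampen <- res$dummy[["dummy_sampen"]]
  data.table::fwrite(df, path)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON manifest recording the configuration (which must include the master
#' seed), derived seeds, package version, and acceptance-relevant summary
#' numbers.  Identical configuration and seed reproduce identical summaries.
#'
#' @param config named list; must contain `seed`.
#' @param results named list of summary numbers.
#' @param path output path.
#' @return The manifest list, invisibly.
#' @export
run_manifest <- function(config, results, path) {
  if (is.null(config$seed)) stop("manifest requires config$seed")
  manifest <- list(package = "avnodenet",
                   version = as.character(packageVersion("avnodenet")),
                   config = config,
                   seeds = list(master = config$seed),
                   summary = results)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
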