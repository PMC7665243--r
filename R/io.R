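# File formats
#
# Trace CSV: comment header lines "# channel=", "# sample_rate_hz=",
# "# start_time_s=" followed by "time_s,pressure_mmhg" and one row per
# sample. Pressures are written with 17 significant digits so a write/read
# cycle round-trips doubles exactly. ".gz" paths are transparently
# compressed. Cuff CSV: "time_s,systolic,diastolic,map". Session manifest:
# YAML naming the component files plus needle gauges and pump geometry.

open_conn <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

abort_format <- function(path, msg) {
  abort_linebp("format", sprintf("%s: %s", path, msg))
}

#' Read and write pressure-trace CSV files
#'
#' @param trace A [pressure_trace()].
#' @param path CSV path; a `.gz` suffix enables compression.
#' @return `read_trace_csv()` returns a [pressure_trace()];
#'   `write_trace_csv()` returns `path` invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(is_pressure_trace(trace))
  con <- open_conn(path, "wb")
  on.exit(close(con))
  writeLines(c(
    sprintf("# channel=%s", trace_channel(trace)),
    sprintf("# sample_rate_hz=%.17g", trace_sample_rate(trace)),
    sprintf("# start_time_s=%.17g", trace_start_time(trace)),
    "time_s,pressure_mmhg",
    sprintf("%.6f,%.17g", trace$time_s, trace$pressure_mmhg)
  ), con)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) abort_format(path, "file not found")
  con <- open_conn(path, "rt")
  head_lines <- readLines(con, n = 20)
  close(con)
  meta_lines <- grep("^#", head_lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  if (is.null(meta$channel) || is.null(meta$sample_rate_hz)) {
    abort_format(path, "missing '# channel=' or '# sample_rate_hz=' metadata")
  }
  fs <- as.numeric(meta$sample_rate_hz)
  if (!is.finite(fs) || fs <= 0) abort_format(path, "invalid sample_rate_hz")
  # base read.csv parses doubles via strtod, which round-trips the %.17g
  # representation exactly (readr's fast parser can be off by one ULP)
  dat <- utils::read.csv(path, comment.char = "#")
  if (!identical(names(dat), c("time_s", "pressure_mmhg"))) {
    abort_format(path, "header must be exactly 'time_s,pressure_mmhg'")
  }
  if (nrow(dat) < 1 || anyNA(dat$pressure_mmhg) || anyNA(dat$time_s)) {
    abort_format(path, "empty or truncated trace data")
  }
  if (nrow(dat) > 1) {
    jitter <- abs(diff(dat$time_s) - 1 / fs)
    if (max(jitter) > 1e-9 + 1e-6 / fs) {
      abort_format(path, sprintf(
        "non-uniform timestamps (max deviation %.3g s from the %.3g ms grid)",
        max(jitter), 1000 / fs
      ))
    }
  }
  start <- if (!is.null(meta$start_time_s)) as.numeric(meta$start_time_s) else dat$time_s[1]
  pressure_trace(dat$pressure_mmhg, fs, meta$channel, start)
}

#' Read and write cuff-measurement CSV files
#'
#' @param cuffs A [cuff_measurements()] tibble.
#' @param path CSV path with header `time_s,systolic,diastolic,map`.
#' @return `read_cuff_csv()` returns a validated cuff tibble.
#' @export
write_cuff_csv <- function(cuffs, path) {
  con <- open_conn(path, "wb")
  on.exit(close(con))
  writeLines(c(
    "time_s,systolic,diastolic,map",
    sprintf("%.17g,%.17g,%.17g,%.17g", cuffs$time_s, cuffs$systolic_mmhg,
            cuffs$diastolic_mmhg, cuffs$map_mmhg)
  ), con)
  invisible(path)
}

#' @rdname write_cuff_csv
#' @export
read_cuff_csv <- function(path) {
  if (!file.exists(path)) abort_format(path, "file not found")
  dat <- utils::read.csv(path)
  need <- c("time_s", "systolic", "diastolic", "map")
  if (!all(need %in% names(dat))) {
    abort_format(path, "header must contain time_s,systolic,diastolic,map")
  }
  cuff_measurements(dat$time_s, dat$systolic, dat$diastolic, dat$map)
}

needle_to_manifest <- function(ns) {
  list(gauge = ns$gauge, inner_diameter_mm = ns$inner_diameter_mm)
}

needle_from_manifest <- function(x, path) {
  if (is.null(x$gauge)) abort_format(path, "needle entry missing 'gauge'")
  needle_spec(x$gauge, inner_diameter_mm = x$inner_diameter_mm)
}

#' Write a session to a directory
#'
#' Writes `arterial.csv`, `venous.csv`, `cuffs.csv` and a `session.yaml`
#' manifest naming them along with needle and pump configuration.
#'
#' @param session A [session_record()].
#' @param dir Output directory (created if needed).
#' @param compress If `TRUE`, trace CSVs are gzipped.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, compress = FALSE) {
  stopifnot(inherits(session, "session_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (compress) ".csv.gz" else ".csv"
  write_trace_csv(session$arterial, file.path(dir, paste0("arterial", ext)))
  write_trace_csv(session$venous, file.path(dir, paste0("venous", ext)))
  write_cuff_csv(session$cuffs, file.path(dir, "cuffs.csv"))
  manifest <- list(
    session_id = session$session_id,
    arterial_trace = paste0("arterial", ext),
    venous_trace = paste0("venous", ext),
    cuffs = "cuffs.csv",
    arterial_needle = needle_to_manifest(session$arterial_needle),
    venous_needle = needle_to_manifest(session$venous_needle),
    pump = list(
      line_radius_mm = session$pump$line_radius_mm,
      effective_length_mm = session$pump$effective_length_mm,
      lobe_count = session$pump$lobe_count
    ),
    gauge_set = session$gauge_set
  )
  if (!is.null(session$set_flow_ml_min)) {
    manifest$set_flow_ml_min <- session$set_flow_ml_min
  }
  yaml::write_yaml(manifest, file.path(dir, "session.yaml"))
  invisible(dir)
}

#' Read a session from a directory or manifest
#'
#' Accepts either a directory containing `session.yaml` or the manifest path
#' itself. Component files are resolved relative to the manifest. The
#' assembled record is validated with [validate_session()]; findings are
#' emitted as warnings (warning-severity) or reported in the returned
#' attribute `validation`.
#'
#' @param path Directory or manifest file path.
#' @return A [session_record()] with attribute `validation`.
#' @export
read_session <- function(path) {
  manifest_path <- if (dir.exists(path)) file.path(path, "session.yaml") else path
  if (!file.exists(manifest_path)) abort_format(manifest_path, "manifest not found")
  man <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  need <- c("arterial_trace", "venous_trace", "cuffs")
  for (k in need) {
    if (is.null(man[[k]])) abort_format(manifest_path, paste0("manifest missing '", k, "'"))
    if (!file.exists(file.path(base, man[[k]]))) {
      abort_format(file.path(base, man[[k]]), "component file missing")
    }
  }
  session <- session_record(
    arterial = read_trace_csv(file.path(base, man$arterial_trace)),
    venous = read_trace_csv(file.path(base, man$venous_trace)),
    cuffs = read_cuff_csv(file.path(base, man$cuffs)),
    arterial_needle = needle_from_manifest(man$arterial_needle, manifest_path),
    venous_needle = needle_from_manifest(man$venous_needle, manifest_path),
    pump = pump_geometry(
      line_radius_mm = man$pump$line_radius_mm %||% 4,
      effective_length_mm = man$pump$effective_length_mm %||% 107.8,
      lobe_count = man$pump$lobe_count %||% 2L
    ),
    set_flow_ml_min = man$set_flow_ml_min,
    session_id = man$session_id %||% basename(base),
    gauge_set = man$gauge_set
  )
  findings <- validate_session(session)
  for (msg in findings$message[findings$severity == "warning"]) warn(msg)
  attr(session, "validation") <- findings
  session
}

#' Write and read the ground truth of a simulated session
#'
#' Ground truth is stored in a separate `ground_truth.csv` so that
#' estimation commands operating on a session directory cannot consume it by
#' accident.
#'
#' @param sim A `sim_session` from [simulate_session()].
#' @param dir Session directory.
#' @return The truth tibble (for `read_ground_truth_csv`).
#' @export
write_ground_truth_csv <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_session"))
  readr::write_csv(sim$truth, file.path(dir, "ground_truth.csv"),
                   progress = FALSE)
  invisible(dir)
}

#' @rdname write_ground_truth_csv
#' @param path Path of a `ground_truth.csv`.
#' @export
read_ground_truth_csv <- function(path) {
  if (!file.exists(path)) abort_format(path, "file not found")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
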