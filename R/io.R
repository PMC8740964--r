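#' Export and re-import run results as tidy CSV
#'
#' A `pod_run` exports rows `replicate,t,belief_level,count,fraction`
#' (replicate 1); a `pod_batch` exports the same schema over all its
#' replicates, so the row count is `replicates * (T + 1) * R`. Re-importing
#' reproduces the timeseries exactly.
#'
#' @param x A `pod_run` or `pod_batch`.
#' @param path Output CSV path.
#' @return `export_run()` returns `x` invisibly; `read_run_csv()` returns a
#'   tibble `replicate, t, belief_level, count, fraction`.
#' @export
export_run <- function(x, path) {
  ts <- if (inherits(x, "pod_batch")) {
    x$timeseries
  } else if (inherits(x, "pod_run")) {
    dplyr::mutate(x$timeseries, replicate = 1L, .before = 1)
  } else {
    abort("`x` must be a pod_run or pod_batch.")
  }
  out <- ts |>
    dplyr::select(replicate = "replicate", t = "t", belief_level = "level",
                  count = "count", fraction = "fraction")
  readr::write_csv(out, path)
  invisible(x)
}

#' @rdname export_run
#' @export
read_run_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    replicate = readr::col_integer(), t = readr::col_integer(),
    belief_level = readr::col_integer(), count = readr::col_double(),
    fraction = readr::col_double()))
}

#' Export a cascade event log as CSV
#'
#' Columns `t,message_uid,sender,receiver,outcome`; sender 0 denotes the
#' institution.
#'
#' @param run A `pod_run` created with `record_events = TRUE`.
#' @param path Output CSV path.
#' @export
export_events <- function(run, path) {
  if (is.null(run$events)) abort("run has no event log; set `record_events = TRUE`.")
  out <- dplyr::select(run$events, t = "t", message_uid = "uid",
                       sender = "sender", receiver = "receiver",
                       outcome = "outcome")
  readr::write_csv(out, path)
  invisible(run)
}

#' Write an experiment manifest
#'
#' Records, before any simulation output, everything needed to re-run an
#' experiment bit-identically: the configuration, the resolved seed list,
#' the output paths and the package version.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if missing).
#' @param name Experiment name.
#' @param outputs Character vector of planned output file names.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(config, out_dir, name = "experiment",
                           outputs = character(0)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, paste0(name, "-config.yaml"))
  write_config(config, cfg_path)
  manifest <- list(
    name = name,
    config = basename(cfg_path),
    seeds = config$seed + seq_len(config$replicates),
    outputs = as.list(outputs),
    package_version = as.character(utils::packageVersion("cogcascade")))
  path <- file.path(out_dir, paste0(name, "-manifest.yaml"))
  yaml::write_yaml(manifest, path)
  invisible(path)
}
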