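# Delimited-text interchange: one CSV per sensor plus a YAML manifest per
# session, and a flat CSV for gait-variable tables.

#' Write a session to delimited text files
#'
#' Writes one CSV per sensor (`<horse>_<surface>_<placement>.csv` with
#' header `time_s,gx_dps,gy_dps,gz_dps,ax_g,ay_g,az_g`) and a YAML
#' manifest mapping placements to files and recording the horse id,
#' surface, sample rate and standstill window.
#'
#' @param session An `imu_session`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "imu_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  placements <- unique(session$streams$placement)
  files <- stats::setNames(
    sprintf("%s_%s_%s.csv", session$horse_id, session$surface, placements),
    placements
  )
  for (p in placements) {
    readr::write_csv(
      dplyr::select(session_stream(session, p), -"placement"),
      file.path(dir, files[[p]])
    )
  }
  manifest <- list(
    horse_id = session$horse_id,
    surface = session$surface,
    sample_rate = session$sample_rate,
    standstill = as.integer(session$standstill),
    streams = as.list(files)
  )
  path <- file.path(dir, sprintf("%s_%s_manifest.yaml",
                                 session$horse_id, session$surface))
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a session from its manifest
#'
#' @param manifest Path to a manifest written by [write_session()].
#' @return An `imu_session` (without a ground-truth payload).
#' @export
read_session <- function(manifest) {
  m <- yaml::read_yaml(manifest)
  dir <- dirname(manifest)
  streams <- purrr::imap(m$streams, function(f, placement) {
    dplyr::mutate(
      readr::read_csv(file.path(dir, f), show_col_types = FALSE),
      placement = placement, .before = 1
    )
  })
  structure(
    list(
      horse_id = m$horse_id,
      surface = m$surface,
      sample_rate = m$sample_rate,
      standstill = if (length(m$standstill)) as.integer(m$standstill) else NULL,
      streams = dplyr::bind_rows(streams),
      truth = NULL,
      protocol = NULL
    ),
    class = "imu_session"
  )
}

#' Write / read a gait-variable table
#'
#' Flat CSV with the metadata columns (`horse_id`, `surface`,
#' `evaluator_id`, `evaluator_type`, `repetition`, and
#' `n_strides_evaluated` when present) followed by the variable columns.
#'
#' @param table Gait-variable tibble.
#' @param path CSV path.
#' @return `write_gait_table()` returns the path invisibly;
#'   `read_gait_table()` the tibble.
#' @export
write_gait_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_gait_table
#' @export
read_gait_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
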