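#' Configuration of a full simulated reliability study
#'
#' Bundles everything [run_study()] needs: the blinded study design, the
#' population kinematics and between-horse variability, the recording
#' protocol settings, and the extraction/analysis parameters.
#'
#' @param design A [study_design()].
#' @param population Population-mean [horse_profile()].
#' @param between_horse_sd Between-horse variability (see
#'   [simulate_horse_profile()]).
#' @param protocol_args Named list of [session_protocol()] arguments
#'   shared by all recordings (surface and seed are filled in per
#'   session). The defaults include moderate sensor noise and a small
#'   gyroscope bias so that evaluator window choices genuinely matter.
#' @param min_strides,cv_threshold Window-selection settings (see
#'   [select_window()]).
#' @param mode Variance-component mode for the reliability report.
#' @param n_grid Cycle grid resolution.
#' @return An object of class `study_config`.
#' @export
study_config <- function(design = study_design(),
                         population = horse_profile(),
                         between_horse_sd = default_between_horse_sd(),
                         protocol_args = list(
                           n_trot_strides = 25,
                           noise_sd_gyro = 2,
                           noise_sd_accel = 0.02,
                           gyro_bias = 0.2
                         ),
                         min_strides = 5,
                         cv_threshold = 0.05,
                         mode = c("paper", "balanced"),
                         n_grid = 100) {
  structure(
    list(
      design = design,
      population = population,
      between_horse_sd = between_horse_sd,
      protocol_args = protocol_args,
      min_strides = min_strides,
      cv_threshold = cv_threshold,
      mode = match.arg(mode),
      n_grid = n_grid
    ),
    class = "study_config"
  )
}

# Evaluator window habit: a per-evaluator preferred window length fraction
# and start position within the steady run, plus per-dataset jitter. This
# emulates evaluators choosing different data windows within the same
# preselected trot segment, without claiming anything about how the human
# choices actually differed.
evaluator_window <- function(run, pref, min_strides, seed, counter) {
  run_len <- length(run)
  with_substream(seed, counter, {
    len <- round(run_len * pref$frac_len + rnorm(1, 0, 0.5))
    len <- max(min(len, run_len), min(min_strides, run_len))
    start_max <- run_len - len + 1L
    pos <- 1L + round(pref$frac_start * (start_max - 1L) + rnorm(1, 0, 0.7))
    pos <- max(min(pos, start_max), 1L)
    c(run[pos], run[pos + len - 1L])
  })
}

#' Run a complete simulated blinded reliability study
#'
#' End-to-end orchestration of the study: draw one kinematic profile per
#' horse, simulate an IMU session per horse and surface, blind and copy
#' the recordings, let every evaluator extract the gait variables from
#' every blinded dataset (each evaluator applies their own habitual
#' window choice, jittered per dataset), unblind, and compute the full
#' per-surface reliability report. Every random step draws from a
#' sub-stream of the design seed, so the same configuration reproduces
#' identical results and identical report files.
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given the report files are
#'   written there via [write_study_report()].
#' @return An object of class `study_report`: list with `table` (the
#'   unblinded gait-variable table, `I * J * K` rows per surface),
#'   `reliability` (a [reliability_report()] result), `profiles` (tibble
#'   of true per-horse variable values), `keys` (blinding keys), `config`
#'   and `seed`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  design <- config$design
  seed <- design$seed
  eval_ids <- names(design$evaluators)

  profiles <- purrr::map(seq_len(design$n_horses), function(j) {
    simulate_horse_profile(
      population = config$population,
      between_horse_sd = config$between_horse_sd,
      seed = if (is.null(seed)) NULL else substream_seed(seed, 200L + j),
      horse_id = sprintf("H%02d", j)
    )
  })
  prefs <- purrr::map(stats::setNames(seq_along(eval_ids), eval_ids), function(i) {
    with_substream(seed, 300L + i,
                   list(frac_len = stats::runif(1, 0.6, 1),
                        frac_start = stats::runif(1)))
  })

  all_rows <- list()
  keys <- list()
  for (si in seq_along(design$surfaces)) {
    surf <- design$surfaces[si]
    sessions <- purrr::map(profiles, function(p) {
      proto <- do.call(session_protocol, c(
        list(surface = surf,
             seed = if (is.null(seed)) NULL
                    else substream_seed(seed, 400L + si * 32L +
                                          match(p$horse_id, sprintf("H%02d", seq_len(design$n_horses))))),
        config$protocol_args
      ))
      simulate_session(p, proto)
    })
    names(sessions) <- vapply(sessions, `[[`, character(1), "horse_id")
    bl <- blind_copies(sessions, design, surface = surf)
    keys[[surf]] <- bl$key
    preps <- purrr::map(sessions, prepare_session, n_grid = config$n_grid)
    rows <- purrr::map(seq_len(nrow(bl$key)), function(bi) {
      true_horse <- bl$key$horse_id[bi]
      prep <- preps[[true_horse]]
      run <- select_window(prep$strides, config$min_strides,
                           config$cv_threshold)
      purrr::map(seq_along(eval_ids), function(ei) {
        w <- evaluator_window(
          run, prefs[[ei]], config$min_strides, seed,
          1000L + (si * 64L + bi) * 8L + ei
        )
        rec <- extract_record(
          prep, evaluator_id = eval_ids[ei],
          min_strides = config$min_strides,
          cv_threshold = config$cv_threshold, window = w
        )
        rec$horse_id <- bl$key$blinded_id[bi]
        rec
      }) %>% dplyr::bind_rows()
    }) %>% dplyr::bind_rows()
    rows <- unblind_table(rows, bl$key)
    all_rows[[surf]] <- rows
  }

  table <- dplyr::bind_rows(all_rows) %>%
    dplyr::mutate(
      evaluator_type = unname(design$evaluators[.data$evaluator_id]),
      .after = "evaluator_id"
    ) %>%
    dplyr::arrange(.data$surface, .data$horse_id, .data$evaluator_id,
                   .data$repetition)

  rel <- reliability_report(table, mode = config$mode)
  truth <- purrr::map_dfr(profiles, function(p) {
    dplyr::bind_cols(tibble::tibble(horse_id = p$horse_id), profile_truth(p))
  })
  report <- structure(
    list(table = table, reliability = rel, profiles = truth,
         keys = keys, config = config, seed = seed),
    class = "study_report"
  )
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> ", nrow(x$table), " extracted records over ",
      length(unique(x$table$surface)), " surface(s); seed ", x$seed,
      "\n", sep = "")
  print(x$reliability$summary)
  invisible(x)
}

#' Write the report files of a study run
#'
#' Writes `gait_table.csv`, `reliability_variables.csv`,
#' `reliability_summary.csv`, `blinding_key.csv`, `horse_truth.csv` and a
#' `study_log.yaml` header with the seed and design provenance. Re-running
#' the same configuration reproduces the files byte for byte.
#'
#' @param report A [run_study()] result.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the output directory.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$table, file.path(out_dir, "gait_table.csv"))
  readr::write_csv(report$reliability$variables,
                   file.path(out_dir, "reliability_variables.csv"))
  readr::write_csv(report$reliability$summary,
                   file.path(out_dir, "reliability_summary.csv"))
  readr::write_csv(dplyr::bind_rows(report$keys),
                   file.path(out_dir, "blinding_key.csv"))
  readr::write_csv(report$profiles, file.path(out_dir, "horse_truth.csv"))
  design <- report$config$design
  yaml::write_yaml(list(
    seed = report$seed,
    surfaces = design$surfaces,
    n_horses = design$n_horses,
    copies_per_horse = design$copies_per_horse,
    evaluators = as.list(design$evaluators),
    mode = report$config$mode,
    min_strides = report$config$min_strides,
    cv_threshold = report$config$cv_threshold
  ), file.path(out_dir, "study_log.yaml"))
  invisible(out_dir)
}
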