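#' Study design for a blinded reliability experiment
#'
#' @param surfaces Surfaces to record on.
#' @param n_horses Horses per surface.
#' @param copies_per_horse How many blinded copies of each horse's
#'   processed recording the evaluators receive (the "repetitions" of the
#'   reliability model).
#' @param evaluators Named character vector mapping evaluator ids to
#'   `"experienced"` / `"inexperienced"`.
#' @param seed Integer seed driving profile draws, sensor noise, blinding
#'   shuffles and evaluator window jitter (expanded into sub-streams).
#' @return An object of class `study_design`.
#' @export
study_design <- function(surfaces = c("treadmill", "soft", "hard"),
                         n_horses = 10,
                         copies_per_horse = 3,
                         evaluators = c(
                           E1 = "experienced", E2 = "experienced",
                           E3 = "experienced", E4 = "inexperienced",
                           E5 = "inexperienced", E6 = "inexperienced"
                         ),
                         seed = 1) {
  if (n_horses < 1 || copies_per_horse < 1 || length(evaluators) < 1) {
    abort_eg("All design counts must be at least 1.", "equigait_error_parameter")
  }
  structure(
    list(
      surfaces = surfaces,
      n_horses = as.integer(n_horses),
      copies_per_horse = as.integer(copies_per_horse),
      evaluators = evaluators,
      seed = seed
    ),
    class = "study_design"
  )
}

#' Blind and copy the sessions of one surface
#'
#' Duplicates each horse's processed recording `copies_per_horse` times
#' and hides the identities behind shuffled opaque ids (zero-padded
#' sequential labels after a seeded permutation), exactly as evaluators
#' would receive them. The blinding key — the bijection from blinded id to
#' (horse, copy) — is returned separately and is inverted with
#' [unblind_table()] before any statistical analysis.
#'
#' @param sessions List of sessions (or any objects carrying a `horse_id`
#'   field), one per horse.
#' @param design A [study_design()]; its `copies_per_horse` and `seed`
#'   are used.
#' @param surface Surface label recorded in the key.
#' @return List with `blinded` (named list of sessions keyed by blinded
#'   id, `horse_id` replaced by the blinded id) and `key` (tibble
#'   `blinded_id`, `horse_id`, `copy`, `surface`).
#' @export
blind_copies <- function(sessions, design = study_design(), surface = NULL) {
  ids <- vapply(sessions, function(s) s$horse_id, character(1))
  if (anyDuplicated(ids)) {
    abort_eg("Duplicate horse ids: one session per horse required.",
             "equigait_error_input")
  }
  surface <- surface %||%
    (if (!is.null(sessions[[1]]$surface)) sessions[[1]]$surface else "unspecified")
  n_total <- length(sessions) * design$copies_per_horse
  key <- tidyr::expand_grid(
    horse_id = ids,
    copy = seq_len(design$copies_per_horse)
  )
  counter <- match(surface, design$surfaces)
  if (is.na(counter)) counter <- 0L
  perm <- with_substream(design$seed, 100L + counter, sample.int(n_total))
  key$blinded_id <- sprintf("B%03d", perm)
  key$surface <- surface
  key <- dplyr::arrange(key, .data$blinded_id)
  blinded <- purrr::map(seq_len(nrow(key)), function(r) {
    s <- sessions[[match(key$horse_id[r], ids)]]
    s$horse_id <- key$blinded_id[r]
    s
  })
  names(blinded) <- key$blinded_id
  list(blinded = blinded,
       key = key[, c("blinded_id", "horse_id", "copy", "surface")])
}

#' Invert the blinding of an extracted gait-variable table
#'
#' Replaces the blinded ids in the `horse_id` column by the true horse
#' identities and fills `repetition` with the copy index, using the
#' blinding key.
#'
#' @param table Table whose `horse_id` column holds blinded ids.
#' @param key Blinding key from [blind_copies()].
#' @return The unblinded table.
#' @export
unblind_table <- function(table, key) {
  m <- match(table$horse_id, key$blinded_id)
  if (anyNA(m)) {
    abort_eg("Table contains ids absent from the blinding key.",
             "equigait_error_input")
  }
  table$horse_id <- key$horse_id[m]
  table$repetition <- as.integer(key$copy[m])
  table
}
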