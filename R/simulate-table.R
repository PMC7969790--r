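#' Specification for simulating a gait-variable table
#'
#' Defines the crossed reliability design and the additive variance model
#' under which response values are drawn: for each variable,
#' `Y_ijk = mu + a_i + b_j + e_ijk` with evaluator effects
#' `a_i ~ N(0, sigma2_evaluator)`, horse effects `b_j ~ N(0, sigma2_horse)`
#' and residuals `e_ijk ~ N(0, sigma2_repetition)`, plus an optional
#' additive `type_effect` for evaluators of the experienced group.
#'
#' @param n_horses Number of horses J per surface (default 10).
#' @param n_evaluators Number of evaluators I (default 6).
#' @param n_repetitions Number of repetitions K per horse and evaluator
#'   (default 3); the default design yields `I * J * K = 180` rows per
#'   surface.
#' @param surfaces Character vector of surfaces to simulate.
#' @param evaluator_types Named character vector mapping evaluator ids to
#'   `"experienced"`/`"inexperienced"`; default splits the evaluators half
#'   and half (first half experienced).
#' @param variables Character vector of response-variable names.
#' @param means Named numeric vector of grand means per variable (recycled
#'   if scalar).
#' @param sigma2_horse,sigma2_evaluator,sigma2_repetition Variance
#'   components per variable (scalar or named vector, all `>= 0`).
#' @param type_effect Additive shift applied to experienced evaluators.
#' @param seed Integer seed; identical spec and seed give a bit-identical
#'   table.
#' @return An object of class `table_sim_spec`.
#' @seealso [simulate_gait_table()]
#' @export
table_sim_spec <- function(n_horses = 10,
                           n_evaluators = 6,
                           n_repetitions = 3,
                           surfaces = "treadmill",
                           evaluator_types = NULL,
                           variables = gait_variable_names(),
                           means = default_variable_means(),
                           sigma2_horse = default_table_sigma2()$horse,
                           sigma2_evaluator = default_table_sigma2()$evaluator,
                           sigma2_repetition = default_table_sigma2()$repetition,
                           type_effect = 0,
                           seed = NULL) {
  if (n_horses < 1 || n_evaluators < 1 || n_repetitions < 1) {
    abort_eg("Design counts must all be at least 1.", "equigait_error_parameter")
  }
  expand <- function(x, what) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- rep(x, length(variables))
      names(x) <- variables
    }
    if (!all(variables %in% names(x))) {
      abort_eg(paste0("`", what, "` must cover all simulated variables."),
               "equigait_error_parameter")
    }
    x[variables]
  }
  means <- expand(means, "means")
  s2h <- expand(sigma2_horse, "sigma2_horse")
  s2e <- expand(sigma2_evaluator, "sigma2_evaluator")
  s2r <- expand(sigma2_repetition, "sigma2_repetition")
  if (any(c(s2h, s2e, s2r) < 0)) {
    abort_eg("Variance components must be non-negative.",
             "equigait_error_parameter")
  }
  eval_ids <- sprintf("E%d", seq_len(n_evaluators))
  if (is.null(evaluator_types)) {
    evaluator_types <- ifelse(seq_len(n_evaluators) <= n_evaluators / 2,
                              "experienced", "inexperienced")
    names(evaluator_types) <- eval_ids
  }
  if (!all(eval_ids %in% names(evaluator_types))) {
    abort_eg("`evaluator_types` must name every evaluator id E1..EI.",
             "equigait_error_parameter")
  }
  structure(
    list(
      n_horses = as.integer(n_horses),
      n_evaluators = as.integer(n_evaluators),
      n_repetitions = as.integer(n_repetitions),
      surfaces = surfaces,
      evaluator_types = evaluator_types[eval_ids],
      variables = variables,
      means = means,
      sigma2_horse = s2h,
      sigma2_evaluator = s2e,
      sigma2_repetition = s2r,
      type_effect = type_effect,
      seed = seed
    ),
    class = "table_sim_spec"
  )
}

#' Default variance components for the gait-variable table simulator
#'
#' Partitions each variable's total variance so that the horse dominates
#' (variance-partitioning shares of roughly 0.92 horse, 0.02 evaluator,
#' 0.06 repetition) with the horse component anchored to the squared
#' between-horse spread of [default_variable_sds()]. This mirrors a highly
#' reliable measurement system where virtually all variation is biological.
#'
#' @return List with named vectors `horse`, `evaluator`, `repetition`.
#' @export
default_table_sigma2 <- function() {
  s2h <- default_variable_sds()^2
  list(
    horse = s2h,
    evaluator = s2h * (0.02 / 0.92),
    repetition = s2h * (0.06 / 0.92)
  )
}

#' Simulate a gait-variable table under the additive reliability model
#'
#' Draws one balanced horse x evaluator x repetition table per surface
#' under the model described in [table_sim_spec()]. Rows are ordered by
#' surface, horse, evaluator, repetition.
#'
#' @param spec A [table_sim_spec()].
#' @return Tibble with columns `horse_id`, `surface`, `evaluator_id`,
#'   `evaluator_type`, `repetition` and one column per response variable.
#' @export
#' @examples
#' tab <- simulate_gait_table(table_sim_spec(variables = "y", means = 0,
#'   sigma2_horse = 1, sigma2_evaluator = 0.1, sigma2_repetition = 0.1,
#'   seed = 1))
#' nrow(tab) # 6 * 10 * 3
simulate_gait_table <- function(spec = table_sim_spec()) {
  stopifnot(inherits(spec, "table_sim_spec"))
  I <- spec$n_evaluators
  J <- spec$n_horses
  K <- spec$n_repetitions
  eval_ids <- names(spec$evaluator_types)
  horse_ids <- sprintf("H%02d", seq_len(J))
  out <- purrr::imap(
    stats::setNames(spec$surfaces, spec$surfaces),
    function(surface, .y) {
      s_idx <- match(surface, spec$surfaces)
      grid <- tidyr::expand_grid(
        horse_id = horse_ids,
        evaluator_id = eval_ids,
        repetition = seq_len(K)
      )
      vals <- purrr::imap(
        stats::setNames(spec$variables, spec$variables),
        function(v, .vy) {
          counter <- (s_idx - 1L) * length(spec$variables) +
            match(v, spec$variables)
          with_substream(spec$seed, counter, {
            a <- rnorm(I, 0, sqrt(spec$sigma2_evaluator[[v]]))
            b <- rnorm(J, 0, sqrt(spec$sigma2_horse[[v]]))
            e <- rnorm(I * J * K, 0, sqrt(spec$sigma2_repetition[[v]]))
            shift <- ifelse(
              spec$evaluator_types[grid$evaluator_id] == "experienced",
              spec$type_effect, 0
            )
            spec$means[[v]] + a[match(grid$evaluator_id, eval_ids)] +
              b[match(grid$horse_id, horse_ids)] + e + shift
          })
        }
      )
      dplyr::bind_cols(
        tibble::tibble(
          horse_id = grid$horse_id,
          surface = surface,
          evaluator_id = grid$evaluator_id,
          evaluator_type = unname(spec$evaluator_types[grid$evaluator_id]),
          repetition = grid$repetition
        ),
        tibble::as_tibble(vals)
      )
    }
  )
  dplyr::bind_rows(out)
}
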