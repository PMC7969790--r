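#' Repeated-measures ANOVA mean squares of a gait-variable table
#'
#' Fits the additive reliability model `Y_ijk = mu + a_i + b_j + e_ijk`
#' (evaluator `i` as within-subject factor, horse `j` as subject,
#' repetition and any interaction pooled into the error term) on one
#' balanced surface table, and returns the sums of squares, degrees of
#' freedom and mean squares that the variance-component, ICC and VPC
#' computations consume.
#'
#' For a balanced crossed design the decomposition is closed-form:
#' `SS_Horse = I*K * sum_j (mean_j - mean)^2`,
#' `SS_Evaluator = J*K * sum_i (mean_i - mean)^2`, and
#' `SS_Error = SS_Total - SS_Horse - SS_Evaluator` with error degrees of
#' freedom `n - 1 - (I-1) - (J-1)`.
#'
#' @param table Data frame with `horse_id`, `evaluator_id`, `repetition`
#'   columns and the response variable; must contain a single surface and
#'   exactly one row per evaluator x horse x repetition cell.
#' @param variable Name of the response column.
#' @return An object of class `mean_squares`: a list with `ms_horse`,
#'   `ms_evaluator`, `ms_error`, the corresponding `ss_*` and `df_*`
#'   entries and the design sizes `I`, `J`, `K`, `n`.
#' @export
#' @examples
#' tab <- simulate_gait_table(table_sim_spec(variables = "y", means = 0,
#'   sigma2_horse = 1, sigma2_evaluator = 0.1, sigma2_repetition = 0.1,
#'   seed = 42))
#' anova_mean_squares(tab, "y")
anova_mean_squares <- function(table, variable) {
  if (!variable %in% names(table)) {
    abort_eg(paste0("No column `", variable, "` in the table."),
             "equigait_error_input")
  }
  if ("surface" %in% names(table) && length(unique(table$surface)) > 1L) {
    abort_eg("Analyse each surface separately: more than one surface present.",
             "equigait_error_design")
  }
  I <- length(unique(table$evaluator_id))
  J <- length(unique(table$horse_id))
  n <- nrow(table)
  K <- n / (I * J)
  cells <- dplyr::count(table, .data$evaluator_id, .data$horse_id)
  if (K != round(K) || nrow(cells) != I * J || any(cells$n != K)) {
    abort_eg("Unbalanced design: need exactly K rows per evaluator x horse cell.",
             "equigait_error_design")
  }
  K <- as.integer(K)
  y <- table[[variable]]
  g <- mean(y)
  mh <- tapply(y, table$horse_id, mean)
  me <- tapply(y, table$evaluator_id, mean)
  ss_h <- I * K * sum((mh - g)^2)
  ss_e <- J * K * sum((me - g)^2)
  ss_t <- sum((y - g)^2)
  ss_err <- max(ss_t - ss_h - ss_e, 0)
  df_h <- J - 1L
  df_e <- I - 1L
  df_err <- n - 1L - df_h - df_e
  structure(
    list(
      ms_horse = ss_h / df_h,
      ms_evaluator = ss_e / df_e,
      ms_error = ss_err / df_err,
      ss_horse = ss_h, ss_evaluator = ss_e, ss_error = ss_err,
      df_horse = df_h, df_evaluator = df_e, df_error = df_err,
      I = I, J = J, K = K, n = n,
      variable = variable
    ),
    class = "mean_squares"
  )
}

#' @export
print.mean_squares <- function(x, ...) {
  cat("<mean_squares>", x$variable %||% "", "\n")
  print(tibble::tibble(
    term = c("horse", "evaluator", "error"),
    df = c(x$df_horse, x$df_evaluator, x$df_error),
    ss = c(x$ss_horse, x$ss_evaluator, x$ss_error),
    ms = c(x$ms_horse, x$ms_evaluator, x$ms_error)
  ))
  invisible(x)
}

#' Variance components from ANOVA mean squares
#'
#' Converts mean squares into the horse, evaluator and repetition variance
#' components. Two conversion modes are provided:
#' \describe{
#'   \item{`"paper"`}{the literal divisors 10 and 6:
#'     `sigma2_horse = (MS_Horse - MS_Error) / 10`,
#'     `sigma2_evaluator = (MS_Evaluator - MS_Error) / 6`,
#'     `sigma2_repetition = MS_Error`.}
#'   \item{`"balanced"`}{the expected-mean-square divisors of the balanced
#'     crossed design, `I*K` and `J*K` respectively (18 and 30 for the
#'     default 6 x 10 x 3 design), which make the estimators consistent
#'     for the simulated variance components.}
#' }
#' Negative estimates are truncated to zero before any ICC/VPC use.
#'
#' @param ms A [anova_mean_squares()] result.
#' @param mode `"paper"` (default) or `"balanced"`.
#' @return An object of class `variance_components`: list with
#'   `sigma2_horse`, `sigma2_evaluator`, `sigma2_repetition` and `mode`.
#' @export
variance_components <- function(ms, mode = c("paper", "balanced")) {
  mode <- match.arg(mode)
  div <- switch(mode,
    paper = c(horse = 10, evaluator = 6),
    balanced = c(horse = ms$I * ms$K, evaluator = ms$J * ms$K)
  )
  structure(
    list(
      sigma2_horse = max((ms$ms_horse - ms$ms_error) / div[["horse"]], 0),
      sigma2_evaluator = max((ms$ms_evaluator - ms$ms_error) / div[["evaluator"]], 0),
      sigma2_repetition = max(ms$ms_error, 0),
      mode = mode
    ),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components> (mode: ", x$mode, ") horse ",
      format(x$sigma2_horse, digits = 4), ", evaluator ",
      format(x$sigma2_evaluator, digits = 4), ", repetition ",
      format(x$sigma2_repetition, digits = 4), "\n", sep = "")
  invisible(x)
}

total_variance <- function(components) {
  components$sigma2_horse + components$sigma2_evaluator +
    components$sigma2_repetition
}

#' Interclass and intraclass correlation coefficients
#'
#' From the variance components:
#' `ICC_inter = sigma2_horse / total` (between-evaluator reliability: the
#' fraction of variance attributable to genuine horse differences when
#' evaluator and repetition variation count as error) and
#' `ICC_intra = (sigma2_horse + sigma2_evaluator) / total`
#' (within-evaluator reliability). Both lie in `[0, 1]` and
#' `ICC_intra >= ICC_inter` always.
#'
#' @param components A [variance_components()] result (or any list with
#'   the three `sigma2_*` fields, after zero-truncation).
#' @return One-row tibble with `icc_inter` and `icc_intra`.
#' @export
#' @examples
#' icc(list(sigma2_horse = 3, sigma2_evaluator = 1, sigma2_repetition = 1))
icc <- function(components) {
  tot <- total_variance(components)
  if (tot <= 0) {
    abort_eg("Total variance is zero; ICC undefined.",
             "equigait_error_undefined")
  }
  tibble::tibble(
    icc_inter = components$sigma2_horse / tot,
    icc_intra = (components$sigma2_horse + components$sigma2_evaluator) / tot
  )
}

#' Variance partitioning coefficients
#'
#' Each factor's variance component divided by the total variance. The
#' three coefficients are non-negative and sum to one; `vpc_horse` is
#' identical to the interclass ICC.
#'
#' @inheritParams icc
#' @return One-row tibble with `vpc_horse`, `vpc_evaluator`,
#'   `vpc_repetition`.
#' @export
vpc <- function(components) {
  tot <- total_variance(components)
  if (tot <= 0) {
    abort_eg("Total variance is zero; VPC undefined.",
             "equigait_error_undefined")
  }
  tibble::tibble(
    vpc_horse = components$sigma2_horse / tot,
    vpc_evaluator = components$sigma2_evaluator / tot,
    vpc_repetition = components$sigma2_repetition / tot
  )
}

#' Test for an effect of evaluator experience
#'
#' Repeated-measures test of the experienced-versus-inexperienced contrast
#' with evaluator nested in experience type and horse as the (crossed)
#' subject: the type mean square is tested against the between-evaluator
#' within-type mean square, both computed from the per-evaluator means
#' (the shared horse contributions cancel in every evaluator contrast),
#' giving `F = MS_Type / MS_Evaluator(Type)` on `(T - 1, I - T)` degrees
#' of freedom for `T` types.
#'
#' @param table Gait-variable table for one surface with an
#'   `evaluator_type` column; every type needs at least two evaluators.
#' @param variable Response column name.
#' @return One-row tibble with `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
experience_effect <- function(table, variable) {
  if (!"evaluator_type" %in% names(table)) {
    abort_eg("`evaluator_type` column required.", "equigait_error_design")
  }
  ev <- dplyr::distinct(table, .data$evaluator_id, .data$evaluator_type)
  counts <- table(ev$evaluator_type)
  if (length(counts) < 2L || any(counts < 2L)) {
    abort_eg("Each evaluator type needs at least two evaluators.",
             "equigait_error_design")
  }
  per_obs <- nrow(table) / nrow(ev)
  m <- tapply(table[[variable]], table$evaluator_id, mean)
  type_of <- stats::setNames(ev$evaluator_type, ev$evaluator_id)[names(m)]
  grand <- mean(m)
  tmeans <- tapply(m, type_of, mean)
  ss_type <- per_obs * sum(as.numeric(counts[names(tmeans)]) * (tmeans - grand)^2)
  ss_within <- per_obs * sum((m - tmeans[type_of])^2)
  df1 <- length(counts) - 1L
  df2 <- length(m) - length(counts)
  ms_type <- ss_type / df1
  ms_within <- ss_within / df2
  f <- if (ms_within > 0) ms_type / ms_within else if (ms_type > 0) Inf else 0
  tibble::tibble(
    statistic = f,
    df1 = df1,
    df2 = df2,
    p_value = stats::pf(f, df1, df2, lower.tail = FALSE)
  )
}

#' Descriptive summary of one variable
#'
#' Mean, sample standard deviation (`n - 1` denominator), median and
#' interquartile range (third minus first quartile, linear-interpolation
#' quantiles).
#'
#' @param table Data frame.
#' @param variable Response column name.
#' @param quantile_type Quantile algorithm passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return One-row tibble with `mean`, `sd`, `median`, `iqr`, `n`.
#' @export
describe_variable <- function(table, variable, quantile_type = 7) {
  y <- table[[variable]]
  if (length(y) < 2L) {
    abort_eg("At least two values required.", "equigait_error_input")
  }
  q <- stats::quantile(y, c(0.25, 0.75), type = quantile_type, names = FALSE)
  tibble::tibble(
    mean = mean(y),
    sd = stats::sd(y),
    median = stats::median(y),
    iqr = q[2] - q[1],
    n = length(y)
  )
}
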