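#' Full per-surface reliability report
#'
#' For every surface and every analysed variable in the table, computes
#' the descriptive summary, the repeated-measures ANOVA mean squares, the
#' variance components (in the requested mode), the interclass and
#' intraclass correlation coefficients, the three variance partitioning
#' coefficients and (when evaluator types are present) the
#' evaluator-experience p-value. Variables whose total variance is zero
#' are reported with `NA` reliability values and a note; the run always
#' completes.
#'
#' @param table Gait-variable table (e.g. from [simulate_gait_table()],
#'   [run_study()] or [read_gait_table()]) with `horse_id`,
#'   `evaluator_id`, `repetition`, optionally `surface` and
#'   `evaluator_type`, and the response columns.
#' @param mode Variance-component mode, `"paper"` or `"balanced"` (see
#'   [variance_components()]).
#' @param variables Response columns to analyse; defaults to whichever of
#'   [gait_variable_names()] are present.
#' @return An object of class `reliability_result`: list with
#'   `variables` (tibble: one row per surface x variable with
#'   descriptives, mean squares, components, ICCs, VPCs, experience
#'   p-value), `summary` (tibble: mean ICCs over temporal, spatial and all
#'   variables per surface) and `mode`. Use [tidy()]/[glance()] to pull
#'   the tibbles.
#' @export
#' @examples
#' tab <- simulate_gait_table(table_sim_spec(seed = 1))
#' rel <- reliability_report(tab)
#' glance(rel)
reliability_report <- function(table, mode = c("paper", "balanced"),
                               variables = NULL) {
  mode <- match.arg(mode)
  if (is.null(variables)) {
    variables <- intersect(gait_variable_names(), names(table))
  }
  if (!length(variables)) {
    abort_eg("No analysable gait-variable columns in the table.",
             "equigait_error_input")
  }
  if (!"surface" %in% names(table)) table$surface <- "unspecified"
  has_types <- "evaluator_type" %in% names(table)

  rows <- purrr::map_dfr(unique(table$surface), function(surf) {
    sub <- dplyr::filter(table, .data$surface == surf)
    purrr::map_dfr(variables, function(v) {
      desc <- describe_variable(sub, v)
      ms <- anova_mean_squares(sub, v)
      comp <- variance_components(ms, mode)
      base <- tibble::tibble(
        surface = surf,
        variable = v,
        class = ifelse(v %in% gait_variable_names("temporal"),
                       "temporal", "spatial"),
        mean = desc$mean, sd = desc$sd, median = desc$median, iqr = desc$iqr,
        ms_horse = ms$ms_horse, ms_evaluator = ms$ms_evaluator,
        ms_error = ms$ms_error,
        sigma2_horse = comp$sigma2_horse,
        sigma2_evaluator = comp$sigma2_evaluator,
        sigma2_repetition = comp$sigma2_repetition
      )
      if (total_variance(comp) > 0) {
        ic <- icc(comp)
        vp <- vpc(comp)
        base <- dplyr::bind_cols(base, ic, vp)
        base$note <- NA_character_
      } else {
        base$icc_inter <- NA_real_
        base$icc_intra <- NA_real_
        base$vpc_horse <- NA_real_
        base$vpc_evaluator <- NA_real_
        base$vpc_repetition <- NA_real_
        base$note <- "total variance zero; ICC/VPC undefined"
      }
      base$experience_p <- if (has_types) {
        tryCatch(experience_effect(sub, v)$p_value,
                 equigait_error = function(e) NA_real_)
      } else {
        NA_real_
      }
      base
    })
  })

  summary <- rows %>%
    dplyr::group_by(.data$surface) %>%
    dplyr::summarise(
      mean_icc_inter_temporal = mean(.data$icc_inter[.data$class == "temporal"], na.rm = TRUE),
      mean_icc_inter_spatial = mean(.data$icc_inter[.data$class == "spatial"], na.rm = TRUE),
      mean_icc_inter_total = mean(.data$icc_inter, na.rm = TRUE),
      mean_icc_intra_temporal = mean(.data$icc_intra[.data$class == "temporal"], na.rm = TRUE),
      mean_icc_intra_spatial = mean(.data$icc_intra[.data$class == "spatial"], na.rm = TRUE),
      mean_icc_intra_total = mean(.data$icc_intra, na.rm = TRUE),
      .groups = "drop"
    )

  structure(
    list(variables = rows, summary = summary, mode = mode),
    class = "reliability_result"
  )
}

#' @export
print.reliability_result <- function(x, ...) {
  cat("<reliability_result> mode:", x$mode, "\n")
  print(x$summary)
  cat("Per-variable detail in $variables (", nrow(x$variables),
      " rows); tidy() / glance() supported.\n", sep = "")
  invisible(x)
}

#' @rdname reliability_report
#' @param x A `reliability_result`.
#' @param ... Unused.
#' @export
tidy.reliability_result <- function(x, ...) {
  x$variables
}

#' @rdname reliability_report
#' @export
glance.reliability_result <- function(x, ...) {
  x$summary
}

#' Plot reliability coefficients per variable
#'
#' Dot plot of the interclass and intraclass correlation coefficients for
#' every variable, faceted by surface.
#'
#' @param object A `reliability_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reliability_result <- function(object, ...) {
  df <- object$variables %>%
    tidyr::pivot_longer(c("icc_inter", "icc_intra"),
                        names_to = "coefficient", values_to = "icc")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$icc, y = .data$variable, colour = .data$coefficient
  )) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$surface)) +
    ggplot2::labs(
      x = "intraclass correlation coefficient", y = NULL,
      colour = NULL,
      title = "Inter- and intra-evaluator reliability per gait variable"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the variance partition per variable
#'
#' Stacked bars of the horse, evaluator and repetition variance
#' partitioning coefficients, faceted by surface.
#'
#' @param result A `reliability_result`.
#' @return A ggplot object.
#' @export
plot_vpc <- function(result) {
  stopifnot(inherits(result, "reliability_result"))
  df <- result$variables %>%
    tidyr::pivot_longer(c("vpc_horse", "vpc_evaluator", "vpc_repetition"),
                        names_to = "factor", values_to = "vpc") %>%
    dplyr::mutate(factor = sub("^vpc_", "", .data$factor))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$vpc, y = .data$variable, fill = .data$factor
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$surface)) +
    ggplot2::labs(
      x = "variance partitioning coefficient", y = NULL, fill = NULL,
      title = "Sources of measurement variance"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the gyroscope traces of a session
#'
#' Lateromedial rotation velocity of each sensor over time — the channel
#' that drives stride segmentation and limb phasing.
#'
#' @param object An `imu_session`.
#' @param channel Stream column to plot (default `"gx_dps"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.imu_session <- function(object, channel = "gx_dps", ...) {
  ggplot2::ggplot(object$streams, ggplot2::aes(
    x = .data$time_s, y = .data[[channel]]
  )) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$placement), ncol = 1) +
    ggplot2::labs(
      x = "time [s]", y = channel,
      title = paste("IMU session", object$horse_id, "on", object$surface)
    ) +
    ggplot2::theme_minimal()
}
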