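test_that("mean squares match the hand-computed 2x2 example", {
  tab <- tibble::tibble(
    horse_id = c("H1", "H1", "H2", "H2"),
    evaluator_id = c("E1", "E2", "E1", "E2"),
    repetition = 1L,
    y = c(1, 2, 3, 4)
  )
  ms <- anova_mean_squares(tab, "y")
  expect_equal(ms$ms_horse, 4)
  expect_equal(ms$ms_evaluator, 1)
  expect_equal(ms$ms_error, 0)
  expect_equal(c(ms$df_horse, ms$df_evaluator, ms$df_error), c(1, 1, 1))
})

test_that("mean squares equal the explicit-loop oracle on random tables", {
  for (s in 1:50) {
    tab <- random_balanced_table(seed = s)
    got <- anova_mean_squares(tab, "y")
    want <- oracle_mean_squares(tab, "y")
    expect_equal(got$ms_horse, want$ms_horse, tolerance = 1e-10)
    expect_equal(got$ms_evaluator, want$ms_evaluator, tolerance = 1e-10)
    expect_equal(got$ms_error, want$ms_error, tolerance = 1e-10)
  }
})

test_that("mean squares agree with the additive stats::aov fit", {
  tab <- random_balanced_table(seed = 99)
  fit <- stats::aov(y ~ evaluator_id + horse_id, data = tab)
  sm <- summary(fit)[[1]]
  ms <- anova_mean_squares(tab, "y")
  expect_equal(ms$ms_evaluator, sm["evaluator_id", "Mean Sq"],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(ms$ms_horse, sm["horse_id", "Mean Sq"],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(ms$ms_error, sm["Residuals", "Mean Sq"],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("degenerate and malformed tables are handled", {
  const <- random_balanced_table(seed = 1)
  const$y <- 3
  ms <- anova_mean_squares(const, "y")
  expect_equal(c(ms$ms_horse, ms$ms_evaluator, ms$ms_error), c(0, 0, 0))

  unbal <- random_balanced_table(seed = 2)[-1, ]
  expect_error(anova_mean_squares(unbal, "y"),
               class = "equigait_error_design")
  expect_error(anova_mean_squares(const, "nope"),
               class = "equigait_error_input")
})

test_that("variance components follow the printed divisors in paper mode", {
  ms <- structure(list(ms_horse = 10, ms_evaluator = 4, ms_error = 1,
                       I = 6, J = 10, K = 3), class = "mean_squares")
  comp <- variance_components(ms, "paper")
  expect_equal(comp$sigma2_horse, 0.9)
  expect_equal(comp$sigma2_evaluator, 0.5)
  expect_equal(comp$sigma2_repetition, 1)

  bal <- variance_components(ms, "balanced")
  expect_equal(bal$sigma2_horse, 9 / 18)
  expect_equal(bal$sigma2_evaluator, 3 / 30)

  same <- structure(list(ms_horse = 1, ms_evaluator = 0.5, ms_error = 1,
                         I = 6, J = 10, K = 3), class = "mean_squares")
  trunc <- variance_components(same, "paper")
  expect_equal(trunc$sigma2_horse, 0)
  expect_equal(trunc$sigma2_evaluator, 0)
})

test_that("balanced-mode estimates recover simulated components", {
  est <- vapply(1:500, function(s) {
    tab <- simulate_gait_table(table_sim_spec(
      variables = "y", means = 0,
      sigma2_horse = 2, sigma2_evaluator = 0.5, sigma2_repetition = 0.25,
      seed = s
    ))
    comp <- variance_components(anova_mean_squares(tab, "y"), "balanced")
    c(comp$sigma2_horse, comp$sigma2_evaluator, comp$sigma2_repetition)
  }, numeric(3))
  means <- rowMeans(est)
  expect_lt(abs(means[1] / 2 - 1), 0.05)
  expect_lt(abs(means[2] / 0.5 - 1), 0.05)
  expect_lt(abs(means[3] / 0.25 - 1), 0.05)
})

test_that("ICC and VPC evaluate their closed forms", {
  comp <- list(sigma2_horse = 1, sigma2_evaluator = 0, sigma2_repetition = 0)
  expect_equal(unlist(icc(comp)), c(icc_inter = 1, icc_intra = 1))
  expect_equal(unlist(vpc(comp)),
               c(vpc_horse = 1, vpc_evaluator = 0, vpc_repetition = 0))

  comp <- list(sigma2_horse = 3, sigma2_evaluator = 1, sigma2_repetition = 1)
  expect_equal(unlist(icc(comp)), c(icc_inter = 0.6, icc_intra = 0.8))

  comp <- list(sigma2_horse = 0, sigma2_evaluator = 0, sigma2_repetition = 1)
  expect_equal(unlist(icc(comp)), c(icc_inter = 0, icc_intra = 0))

  comp <- list(sigma2_horse = 2, sigma2_evaluator = 1, sigma2_repetition = 1)
  expect_equal(unlist(vpc(comp)),
               c(vpc_horse = 0.5, vpc_evaluator = 0.25, vpc_repetition = 0.25))

  zero <- list(sigma2_horse = 0, sigma2_evaluator = 0, sigma2_repetition = 0)
  expect_error(icc(zero), class = "equigait_error_undefined")
  expect_error(vpc(zero), class = "equigait_error_undefined")
})

test_that("experience effect is null when type means coincide", {
  # identical evaluator-effect patterns (+1, -1, 0) in both type groups:
  # within-type variance is positive, the type contrast is exactly zero
  tab <- random_balanced_table(seed = 5)
  tab$evaluator_type <- ifelse(tab$evaluator_id %in% c("E1", "E2", "E3"),
                               "experienced", "inexperienced")
  delta <- c(E1 = 1, E2 = -1, E3 = 0, E4 = 1, E5 = -1, E6 = 0)
  b <- stats::setNames(sin(1:10) * 3, sprintf("H%02d", 1:10))
  tab$y <- b[tab$horse_id] + delta[tab$evaluator_id]
  res <- experience_effect(tab, "y")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("a strong experience effect is detected", {
  for (s in 1:5) {
    tab <- simulate_gait_table(table_sim_spec(
      variables = "y", means = 0,
      sigma2_horse = 0.9, sigma2_evaluator = 0.05, sigma2_repetition = 0.05,
      type_effect = 5, seed = s
    ))
    expect_lt(experience_effect(tab, "y")$p_value, 0.001)
  }
})

test_that("experience effect needs two evaluators per type", {
  tab <- random_balanced_table(seed = 6)
  tab$evaluator_type <- ifelse(tab$evaluator_id == "E1",
                               "experienced", "inexperienced")
  expect_error(experience_effect(tab, "y"),
               class = "equigait_error_design")
  expect_error(experience_effect(dplyr::select(tab, -evaluator_type), "y"),
               class = "equigait_error_design")
})

test_that("descriptives use sample sd and interpolated quantiles", {
  tab <- tibble::tibble(y = c(1, 2, 3, 4))
  d <- describe_variable(tab, "y")
  expect_equal(d$mean, 2.5)
  expect_equal(d$median, 2.5)
  expect_equal(d$sd, sd(c(1, 2, 3, 4)))

  const <- tibble::tibble(y = rep(7, 10))
  dc <- describe_variable(const, "y")
  expect_equal(dc$sd, 0)
  expect_equal(dc$iqr, 0)

  withr::with_seed(8, {
    y <- rnorm(101)
    d <- describe_variable(tibble::tibble(y = y), "y")
    expect_equal(d$iqr, oracle_quantile(y, 0.75) - oracle_quantile(y, 0.25),
                 tolerance = 1e-12)
    expect_equal(d$median, oracle_quantile(y, 0.5), tolerance = 1e-12)
  })
  expect_error(describe_variable(tibble::tibble(y = 1), "y"),
               class = "equigait_error_input")
})

test_that("the report analyses each surface independently and survives
           zero-variance variables", {
  spec <- table_sim_spec(surfaces = c("treadmill", "soft", "hard"), seed = 2)
  rel <- reliability_report(simulate_gait_table(spec))
  expect_equal(nrow(rel$summary), 3)
  expect_equal(nrow(rel$variables), 3 * 19)
  expect_true(all(rel$variables$vpc_horse + rel$variables$vpc_evaluator +
                    rel$variables$vpc_repetition - 1 < 1e-9, na.rm = TRUE))
  expect_true(all(rel$variables$icc_intra >= rel$variables$icc_inter,
                  na.rm = TRUE))

  const <- simulate_gait_table(table_sim_spec(
    variables = "y", means = 1,
    sigma2_horse = 0, sigma2_evaluator = 0, sigma2_repetition = 0, seed = 1
  ))
  rel0 <- reliability_report(const, variables = "y")
  expect_true(is.na(rel0$variables$icc_inter))
  expect_match(rel0$variables$note, "undefined")

  expect_identical(tidy(rel), rel$variables)
  expect_identical(glance(rel), rel$summary)
})

test_that("raising the horse component raises interclass ICC in both modes", {
  base <- list(ms_evaluator = 3, ms_error = 1, I = 6, J = 10, K = 3)
  iccs <- vapply(c(2, 5, 10, 50), function(msh) {
    ms <- structure(c(list(ms_horse = msh), base), class = "mean_squares")
    c(
      icc(variance_components(ms, "paper"))$icc_inter,
      icc(variance_components(ms, "balanced"))$icc_inter
    )
  }, numeric(2))
  expect_true(all(diff(iccs[1, ]) > 0))
  expect_true(all(diff(iccs[2, ]) > 0))
})
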