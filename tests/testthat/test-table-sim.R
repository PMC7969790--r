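test_that("default design yields 180 rows per surface, balanced", {
  tab <- simulate_gait_table(table_sim_spec(seed = 3))
  expect_equal(nrow(tab), 180)
  expect_equal(length(unique(tab$horse_id)), 10)
  expect_equal(length(unique(tab$evaluator_id)), 6)
  counts <- dplyr::count(tab, horse_id, evaluator_id)
  expect_true(all(counts$n == 3))

  two <- simulate_gait_table(table_sim_spec(surfaces = c("soft", "hard"),
                                            seed = 3))
  expect_equal(nrow(two), 360)
  expect_equal(as.integer(table(two$surface)), c(180L, 180L))
})

test_that("degenerate variances collapse the table onto the horse means", {
  spec <- table_sim_spec(
    variables = "y", means = c(y = 10),
    sigma2_horse = 1, sigma2_evaluator = 0, sigma2_repetition = 0,
    seed = 4
  )
  tab <- simulate_gait_table(spec)
  per_horse <- tapply(tab$y, tab$horse_id, function(v) length(unique(v)))
  expect_true(all(per_horse == 1))

  const <- simulate_gait_table(table_sim_spec(
    variables = "y", means = c(y = 5),
    sigma2_horse = 0, sigma2_evaluator = 0, sigma2_repetition = 0, seed = 1
  ))
  expect_true(all(const$y == 5))
})

test_that("tables are seed-deterministic and reject invalid variances", {
  spec <- table_sim_spec(seed = 9)
  expect_identical(simulate_gait_table(spec), simulate_gait_table(spec))
  expect_error(
    table_sim_spec(variables = "y", means = 0, sigma2_horse = -1,
                   sigma2_evaluator = 0, sigma2_repetition = 0),
    class = "equigait_error_parameter"
  )
  expect_error(table_sim_spec(n_horses = 0),
               class = "equigait_error_parameter")
})

test_that("simulated variance decomposes into the programmed components", {
  truth <- c(horse = 0.9, evaluator = 0.05, repetition = 0.05)
  est <- t(vapply(1:200, function(s) {
    tab <- simulate_gait_table(table_sim_spec(
      variables = "y", means = 0,
      sigma2_horse = truth[["horse"]],
      sigma2_evaluator = truth[["evaluator"]],
      sigma2_repetition = truth[["repetition"]],
      seed = s
    ))
    comp <- variance_components(anova_mean_squares(tab, "y"), "balanced")
    c(comp$sigma2_horse, comp$sigma2_evaluator, comp$sigma2_repetition)
  }, numeric(3)))
  means <- colMeans(est)
  # Monte-Carlo error of the mean over 200 replicates
  expect_lt(abs(means[1] - 0.9), 0.1)
  expect_lt(abs(means[2] - 0.05), 0.02)
  expect_lt(abs(means[3] - 0.05), 0.005)
})

test_that("the experienced-group shift lands on the right evaluators", {
  spec <- table_sim_spec(
    variables = "y", means = c(y = 0),
    sigma2_horse = 0, sigma2_evaluator = 0, sigma2_repetition = 0,
    type_effect = 2, seed = 1
  )
  tab <- simulate_gait_table(spec)
  expect_true(all(tab$y[tab$evaluator_type == "experienced"] == 2))
  expect_true(all(tab$y[tab$evaluator_type == "inexperienced"] == 0))
})
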