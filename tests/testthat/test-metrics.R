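test_that("concordance agrees with the defining formula", {
  withr::with_seed(2, {
    for (rep in 1:10) {
      x <- rnorm(7 + rep)
      y <- 0.6 * x + rnorm(length(x), sd = 0.4) + 0.3
      got <- ccc(x, y)
      expect_equal(got$est, ccc_oracle(x, y), tolerance = 1e-10)
      expect_true(got$lo <= got$est && got$est <= got$hi)
    }
  })
})

test_that("concordance penalizes agreement failures that correlation ignores", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(ccc(x, x)$est, 1)
  shifted <- ccc(x, x + 2)
  expect_lt(shifted$est, 1)
  expect_equal(cor(x, x + 2), 1) # Pearson blind to the shift
  scaled <- ccc(x, 2 * x)
  expect_lt(scaled$est, 1)
  # anti-agreement
  expect_equal(ccc(x, rev(x))$est, -1, tolerance = 1e-10)
})

test_that("concordance never exceeds the absolute Pearson correlation", {
  withr::with_seed(31, {
    for (rep in 1:200) {
      n <- sample(5:40, 1)
      x <- rnorm(n)
      y <- rnorm(n, mean = runif(1, -2, 2), sd = runif(1, 0.2, 3)) +
        runif(1, -1, 1) * x
      expect_lte(abs(ccc(x, y)$est), abs(cor(x, y)) + 1e-12)
    }
  })
})

test_that("concordance input validation", {
  expect_error(ccc(1:5, 1:4))
  expect_error(ccc(1:2, 1:2))
  expect_error(ccc(rep(1, 5), rep(1, 5)))
})

test_that("cumulative reliability is 1 for identical trajectories and errors when undefined", {
  traj <- tidyr::expand_grid(agent_id = 1:5, trial = 1:6) |>
    dplyr::mutate(estimate = agent_id * 1.0 + trial * 0.01)
  curve <- cumulative_trr(traj, traj)
  expect_s3_class(curve, "trr_curve")
  expect_equal(curve$ccc, rep(1, 6))
  expect_equal(curve$n, rep(5, 6))
  expect_error(cumulative_trr(traj[traj$agent_id < 3, ],
                              traj[traj$agent_id < 3, ]))
  expect_error(cumulative_trr(traj, traj[traj$agent_id < 5, ]))
})

test_that("the curve endpoint equals the concordance of final estimates", {
  withr::with_seed(9, {
    traj_a <- tidyr::expand_grid(agent_id = 1:8, trial = 1:5) |>
      dplyr::mutate(estimate = rnorm(40))
    traj_b <- tidyr::expand_grid(agent_id = 1:8, trial = 1:5) |>
      dplyr::mutate(estimate = traj_a$estimate + rnorm(40, sd = 0.3))
  })
  curve <- cumulative_trr(traj_a, traj_b)
  final <- ccc(traj_a$estimate[traj_a$trial == 5],
               traj_b$estimate[traj_b$trial == 5])
  expect_equal(curve$ccc[curve$trial == 5], final$est)
})

test_that("efficiency reports the first threshold crossing or not-reached", {
  curve <- tibble::tibble(trial = 1:10, ccc = rep(1, 10))
  expect_equal(trials_to_threshold(curve), 1L)
  flat <- tibble::tibble(trial = 1:10, ccc = rep(0.5, 10))
  expect_true(is.na(trials_to_threshold(flat, 0.9)))
  rising <- tibble::tibble(trial = 1:10,
                           ccc = c(0.2, 0.4, 0.5, 0.6, 0.7, 0.8, 0.92, 0.95,
                                   0.96, 0.97))
  expect_equal(trials_to_threshold(rising, 0.9), 7L)
  expect_error(trials_to_threshold(rising, 1.2))
})

test_that("the outlier rule removes exactly the planted extreme, once", {
  results <- tibble::tibble(agent_id = 1:20,
                            post_sd_logk = rep(c(0.09, 0.1, 0.11, 0.1), 5))
  expect_equal(nrow(exclude_outliers(results)), 20) # homogeneous cohort
  planted <- results
  base_mean <- mean(planted$post_sd_logk)
  base_sd <- sd(planted$post_sd_logk)
  planted$post_sd_logk[13] <- base_mean + 5 * base_sd
  kept <- exclude_outliers(planted)
  expect_equal(setdiff(planted$agent_id, kept$agent_id), 13)
  # single pass: applying the rule to its own output changes nothing more
  expect_equal(exclude_outliers(kept), kept)
  # zero-variance cohort excludes nobody
  flat <- tibble::tibble(agent_id = 1:5, post_sd_logk = rep(0.2, 5))
  expect_equal(nrow(exclude_outliers(flat)), 5)
})

test_that("parameter correlation matches a direct computation", {
  toy <- tibble::tibble(
    mean_log_k = c(-6, -5, -4.2, -3, -2.5),
    mean_beta = c(2, 1.5, 3, 0.8, 1.1)
  )
  got <- param_correlation(toy)
  ref <- cor.test(toy$mean_log_k, 1 / toy$mean_beta)
  expect_equal(got$estimate, unname(ref$estimate))
  expect_equal(got$p.value, ref$p.value)
  # perfect linear relation
  lin <- tibble::tibble(mean_log_k = 1 / c(2, 1.5, 3, 0.8), mean_beta = c(2, 1.5, 3, 0.8))
  expect_equal(param_correlation(lin)$estimate, 1)
  expect_error(param_correlation(toy[1:2, ]))
  expect_error(param_correlation(dplyr::mutate(toy, mean_beta = 0)))
})

test_that("independent parameters show weak correlation at cohort scale", {
  withr::with_seed(40, {
    sim <- tibble::tibble(mean_log_k = runif(100, -9, -1),
                          mean_beta = rlnorm(100, 0, 0.5))
  })
  got <- param_correlation(sim)
  expect_lt(abs(got$estimate), 0.25)
})
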