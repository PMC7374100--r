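test_that("engine initialization produces a normalized uniform prior", {
  eng <- toy_engine()
  expect_equal(sum(eng$mass), 1, tolerance = 1e-12)
  expect_equal(unique(eng$mass), 1 / (12 * 6))
  # bounds respected: no grid point above the configured ceiling
  eng2 <- ado_engine(k_bounds = c(1e-5, 0.1), n_k = 20, n_beta = 4,
                     design_space = ado_design_space(r_ss = c(200, 400),
                                                    t_ll = c(30, 365)))
  expect_true(all(exp(eng2$log_k) <= 0.1 + 1e-12))
  # determinism: same config, same state
  expect_identical(toy_engine()[c("mass", "log_k", "beta")],
                   toy_engine()[c("mass", "log_k", "beta")])
  expect_error(ado_engine(k_bounds = c(0.1, 0.1)))
  expect_error(ado_engine(beta_bounds = c(2, 1)))
  expect_error(ado_engine(n_k = 1))
})

test_that("posterior updates match brute-force normalization and commute", {
  eng <- toy_engine()
  withr::with_seed(3, {
    s <- dd_design(
      r_ss = sample(seq(100, 700, 100), 5, replace = TRUE), t_ss = 0,
      r_ll = 800, t_ll = sample(c(30, 365, 3650), 5, replace = TRUE)
    )
    s$choice <- rbinom(5, 1, 0.5)
  })
  live <- eng
  for (i in 1:5) {
    live <- update_posterior(live, s[i, ], s$choice[i])
    expect_equal(sum(live$mass), 1, tolerance = 1e-12) # conservation
  }
  expect_equal(live$mass, posterior_oracle(eng, s), tolerance = 1e-12)
  # exchangeability: reversed order, same posterior
  rev_eng <- eng
  for (i in 5:1) rev_eng <- update_posterior(rev_eng, s[i, ], s$choice[i])
  expect_equal(rev_eng$mass, live$mass, tolerance = 1e-12)
  expect_error(update_posterior(eng, s[1, ], 2))
})

test_that("a zero-inverse-temperature row is untouched by updates", {
  eng <- ado_engine(beta_bounds = c(0, 1), n_k = 8, n_beta = 2,
                    design_space = ado_design_space(r_ss = c(200, 400),
                                                    t_ll = c(30, 365)))
  d <- dd_design(r_ss = 400, t_ss = 0, r_ll = 800, t_ll = 365)
  upd <- update_posterior(eng, d, 1)
  # likelihood is exactly 0.5 everywhere on the beta = 0 row, so relative
  # mass within that row is unchanged
  row0 <- which(upd$th_beta == 0)
  expect_equal(upd$mass[row0] / sum(upd$mass[row0]),
               eng$mass[row0] / sum(eng$mass[row0]))
})

test_that("replay from history reproduces the live posterior bit-for-bit", {
  eng <- toy_engine()
  live <- eng
  withr::with_seed(5, {
    for (t in 1:12) {
      d <- next_trial(live)
      ch <- rbinom(1, 1, 0.6)
      live <- update_posterior(live, d[, c("r_ss", "t_ss", "r_ll", "t_ll")], ch)
    }
  })
  expect_identical(replay_engine(live)$mass, live$mass)
})

test_that("predictive probability is the posterior mixture of choice probabilities", {
  # degenerate prior: predictive equals the single theta's probability
  prior <- rep(0, 12 * 6)
  prior[40] <- 1
  eng <- toy_engine(prior = prior)
  d <- dd_design(r_ss = 300, t_ss = 0, r_ll = 800, t_ll = 365)
  expect_equal(predictive_prob(eng, d),
               p_choose_ll(d, eng$th_logk[40], eng$th_beta[40]))
  # three-point toy mixture against an explicit sum
  prior3 <- rep(0, 12 * 6)
  prior3[c(2, 30, 60)] <- c(0.2, 0.5, 0.3)
  eng3 <- toy_engine(prior = prior3)
  hand <- 0.2 * p_choose_ll(d, eng3$th_logk[2], eng3$th_beta[2]) +
    0.5 * p_choose_ll(d, eng3$th_logk[30], eng3$th_beta[30]) +
    0.3 * p_choose_ll(d, eng3$th_logk[60], eng3$th_beta[60])
  expect_equal(predictive_prob(eng3, d), hand, tolerance = 1e-12)
  expect_true(predictive_prob(toy_engine(), d) > 0 &&
                predictive_prob(toy_engine(), d) < 1)
})

test_that("expected information gain matches the double-sum oracle", {
  # hand-set 2x2 grid
  eng <- ado_engine(
    k_bounds = c(1e-4, 0.1), beta_bounds = c(0.5, 2), n_k = 2, n_beta = 2,
    prior = c(0.1, 0.4, 0.3, 0.2),
    design_space = ado_design_space(r_ss = c(200, 400, 600),
                                    t_ll = c(30, 365))
  )
  u <- design_utility(eng)
  for (i in seq_len(nrow(u))) {
    expect_equal(u$utility[i], utility_oracle(eng, u[i, ]), tolerance = 1e-12)
  }
  # larger random states
  withr::with_seed(8, {
    for (rep in 1:5) {
      pr <- runif(12 * 6)
      e <- toy_engine(prior = pr)
      d <- dd_design(r_ss = sample(seq(100, 700, 100), 1), t_ss = 0,
                     r_ll = 800, t_ll = sample(c(30, 365, 3650), 1))
      got <- design_utility(e, d)
      expect_equal(got$utility, utility_oracle(e, d), tolerance = 1e-12)
      expect_true(got$utility >= 0)
      # entropy identity: H(predictive) - E[H(conditional)]
      p1 <- p_choose_ll(d, e$th_logk, e$th_beta)
      h <- function(p) -(p * log(p) + (1 - p) * log1p(-p))
      ident <- h(sum(e$mass * p1)) - sum(e$mass * h(p1))
      expect_equal(got$utility, ident, tolerance = 1e-10)
    }
  })
})

test_that("utility vanishes when parameters cannot affect the outcome", {
  # all mass on one cell: no residual uncertainty
  prior <- rep(0, 12 * 6); prior[17] <- 1
  eng <- toy_engine(prior = prior)
  expect_equal(max(design_utility(eng)$utility), 0)
  # beta pinned to 0: every theta predicts 0.5 regardless of design
  eng0 <- ado_engine(beta_bounds = c(0, 1e-9), n_k = 8, n_beta = 2,
                     design_space = ado_design_space(r_ss = c(200, 400),
                                                    t_ll = c(30, 365)))
  expect_equal(max(design_utility(eng0)$utility), 0, tolerance = 1e-12)
})

test_that("design selection is the exhaustive argmax with canonical tie-break", {
  eng <- toy_engine(prior = {
    withr::with_seed(13, runif(12 * 6))
  })
  space <- eng$design_space[withr::with_seed(14, sample(nrow(eng$design_space), 20)), ]
  per_candidate <- vapply(
    seq_len(nrow(space)),
    function(i) design_utility(eng, space[i, ])$utility,
    numeric(1)
  )
  picked <- select_design(eng, space = space)
  expect_equal(picked$utility, max(per_candidate), tolerance = 1e-12)
  expect_equal(picked[, c("r_ss", "t_ll")],
               space[which.max(per_candidate), c("r_ss", "t_ll")])
  # single-candidate space
  one <- select_design(eng, space = space[7, ])
  expect_equal(one$r_ss, space$r_ss[7])
  # degenerate posterior: utilities all zero, first candidate in canonical
  # order (ascending t_ll then r_ss) wins
  point <- rep(0, 12 * 6); point[5] <- 1
  degen <- toy_engine(prior = point)
  first <- select_design(degen)
  expect_equal(first[, c("t_ll", "r_ss")], degen$design_space[1, c("t_ll", "r_ss")])
  expect_error(select_design(eng, space = eng$design_space[0, ]))
})

test_that("next_trial applies the easy-trial policy without changing trial counts", {
  eng <- toy_engine()
  # policy off: identical to select_design on a non-degenerate state
  d <- update_posterior(eng, dd_design(400, 0, 800, 365), 1)
  expect_equal(next_trial(d)[, c("r_ss", "t_ll")],
               select_design(d)[, c("r_ss", "t_ll")], ignore_attr = TRUE)
  # policy about to trigger: streak at threshold inserts the easiest trial
  pol <- toy_engine(policy = easy_trial_policy(streak = 3))
  pol <- update_posterior(pol, dd_design(400, 0, 800, 365), 1)
  u <- design_utility(pol)
  pol$top_design <- which.max(u$utility)
  pol$top_streak <- 2L
  easy <- next_trial(pol)
  expect_equal(easy[, c("r_ss", "t_ll")],
               u[which.max(abs(u$pred_p - 0.5)), c("r_ss", "t_ll")],
               ignore_attr = TRUE)
  # triggered policy with a single candidate still returns that candidate
  single <- next_trial(pol, space = pol$design_space[4, ])
  expect_equal(single$r_ss, pol$design_space$r_ss[4])
})

test_that("marginal point estimates equal direct weighted moments", {
  eng <- toy_engine()
  withr::with_seed(21, {
    agent <- make_cohort(1, seed = 2)
    s <- run_ado_session(agent, eng, n_trials = 20, seed = 4)
  })
  fitted <- attr(s, "engine")
  est <- point_estimates(fitted)
  grid <- tidy(fitted)
  mu_k <- sum(grid$mass * grid$log_k)
  sd_k <- sqrt(sum(grid$mass * (grid$log_k - mu_k)^2))
  mu_b <- sum(grid$mass * grid$beta)
  sd_b <- sqrt(sum(grid$mass * (grid$beta - mu_b)^2))
  expect_equal(est$mean, c(mu_k, mu_b), tolerance = 1e-12)
  expect_equal(est$sd, c(sd_k, sd_b), tolerance = 1e-12)
  # point mass: zero SD; uniform prior: midpoint mean
  point <- rep(0, 12 * 6); point[29] <- 1
  pe <- point_estimates(toy_engine(prior = point))
  expect_equal(pe$sd, c(0, 0))
  unif <- point_estimates(toy_engine())
  expect_equal(unif$mean[1], mean(range(toy_engine()$log_k)))
})

test_that("credible interval covers the central mass of a uniform posterior", {
  eng <- toy_engine()
  ci <- credible_interval_logk(eng, level = 0.95)
  h <- eng$log_k[2] - eng$log_k[1]
  lo_edge <- eng$log_k[1] - h / 2
  hi_edge <- eng$log_k[12] + h / 2
  expect_equal(ci$lo, lo_edge + 0.025 * (hi_edge - lo_edge), tolerance = 1e-9)
  expect_equal(ci$hi, lo_edge + 0.975 * (hi_edge - lo_edge), tolerance = 1e-9)
})

test_that("glance and tidy expose the fit in broom style", {
  eng <- toy_engine()
  g <- glance(eng)
  expect_named(g, c("mean_log_k", "sd_log_k", "mean_beta", "sd_beta", "n_trials"))
  expect_equal(g$n_trials, 0L)
  td <- tidy(eng)
  expect_equal(nrow(td), 12 * 6)
  expect_equal(sum(td$mass), 1, tolerance = 1e-12)
})
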