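test_that("value update follows the constant step-size rule", {
  expect_equal(update_q(c(0.5, 0), 1, 1.0, beta = 0.2)[1], 0.6)
  expect_equal(update_q(c(0.5, 0.3), 1, 0.5, beta = 0.2), c(0.5, 0.3))
  expect_equal(update_q(c(0.5, 0), 2, 0.9, beta = 1)[2], 0.9)
  # other arms untouched
  expect_equal(update_q(c(0.5, 0.3), 1, 1.0)[2], 0.3)
})

test_that("value update contracts toward the reward at rate 1 - beta", {
  set.seed(3)
  for (i in 1:20) {
    q <- runif(2, -1, 2); r <- runif(1, -1, 2); b <- runif(1, 0.05, 1)
    q2 <- update_q(q, 1, r, beta = b)
    expect_equal(abs(q2[1] - r), (1 - b) * abs(q[1] - r))
  }
})

test_that("epsilon-greedy is greedy at eps 0 and uniform at eps 1", {
  expect_equal(egreedy_action(c(0.2, 0.9, 0.1), epsilon = 0), 2)
  # ties break toward the lowest index
  expect_equal(egreedy_action(c(0.5, 0.5), epsilon = 0), 1)
  set.seed(1)
  draws <- replicate(1e5, egreedy_action(c(1, 0), epsilon = 1))
  expect_lt(abs(mean(draws == 1) - 0.5), 0.01)
})

test_that("with eps = 0 and zero noise the learner locks onto the best arm", {
  env <- bandit_env(2, 30, list(list(start = 1, arms = list(
    arm_spec("gaussian", 0.4, 0), arm_spec("gaussian", 1.0, 0)))))
  q <- c(0, 0)
  set.seed(1)
  for (t in 1:30) {
    # force one exploratory look at each arm first
    a <- if (t <= 2) t else egreedy_action(q, epsilon = 0)
    q <- update_q(q, a, sample_reward(env, a, t))
  }
  expect_equal(egreedy_action(q, epsilon = 0), 2)
})

test_that("success-based copying picks the best individual's arm", {
  hist <- info_hist_from(
    list(actions = c(1, 1, 2, 2), rewards = c(0.9, 0.2, 0.7, 0.1)))
  expect_equal(success_based_action(hist, t = 2, tau = 1), 1)
  # single individual recorded
  hist1 <- info_hist_from(list(actions = 2, rewards = 0.3))
  expect_equal(success_based_action(hist1, t = 2, tau = 1), 2)
  # exact reward tie across arms: lowest arm index wins
  tie <- info_hist_from(list(actions = c(2, 1), rewards = c(0.8, 0.8)))
  expect_equal(success_based_action(tie, t = 2, tau = 1), 1)
})

test_that("conformist copying picks the majority arm with low-index ties", {
  hist <- info_hist_from(
    list(actions = c(1, 2, 2, 2, 1, 2, 2, 2, 2, 2),
         rewards = rep(0.5, 10)))
  expect_equal(conformist_action(hist, t = 2, tau = 1), 2)
  tie <- info_hist_from(list(actions = c(1, 2), rewards = c(0, 0)))
  expect_equal(conformist_action(tie, t = 2, tau = 1), 1)
})

test_that("social learning before t - tau > 0 is a latency error", {
  hist <- info_hist_from(list(actions = c(1, 2), rewards = c(0, 1)))
  expect_error(success_based_action(hist, t = 1, tau = 1), "t - tau")
  expect_error(conformist_action(hist, t = 1, tau = 1), "t - tau")
})

test_that("social actions depend only on the record at t - tau", {
  h1 <- info_hist_from(
    list(actions = c(1, 2), rewards = c(0.9, 0.1)),
    list(actions = c(2, 2), rewards = c(0.5, 0.6)))
  h2 <- info_hist_from(
    list(actions = c(1, 2), rewards = c(0.9, 0.1)),
    list(actions = c(1, 1), rewards = c(0.8, 0.2)))
  expect_equal(success_based_action(h1, 2, 1), success_based_action(h2, 2, 1))
  expect_equal(conformist_action(h1, 2, 1), conformist_action(h2, 2, 1))
})

test_that("social_info summarises frequencies, counts and moments", {
  info <- social_info(c(1, 1, 2), c(0.4, 0.6, 1.0), k = 3)
  expect_equal(info$h, c(2 / 3, 1 / 3, 0))
  expect_equal(sum(info$h), 1)
  expect_equal(info$counts, c(2, 1, 0))
  expect_equal(info$mu, c(0.5, 1.0, NA))
  expect_equal(info$sd[1], sd(c(0.4, 0.6)))
  expect_equal(info$sd[2], 0)  # single chooser: sd defined as 0
  expect_equal(info$best_arm, 2)
  expect_equal(info$best_reward, 1.0)
})

test_that("perfect copy takes the true best arm; random copy follows h", {
  env <- make_environment("reversal", horizon = 100)
  expect_equal(copy_variant_action("perfect", env = env, t = 10), 1)
  expect_equal(copy_variant_action("perfect", env = env, t = 90), 2)
  hist <- info_hist_from(
    list(actions = rep(c(1, 2), c(25, 75)), rewards = runif(100)))
  set.seed(2)
  draws <- replicate(1e4, copy_variant_action("random", hist, t = 2))
  expect_lt(abs(mean(draws == 2) - 0.75), 4 * sqrt(0.75 * 0.25 / 1e4))
  # all individuals on one arm: that arm always
  one <- info_hist_from(list(actions = rep(2, 5), rewards = rep(0, 5)))
  expect_equal(copy_variant_action("random", one, t = 2), 2)
})
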