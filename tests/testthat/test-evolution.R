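test_that("roulette selection follows fitness-proportionate probabilities", {
  set.seed(1)
  # total dominance
  expect_true(all(roulette_select(c(1, 0), 100) == 1))
  # equal fitness: uniform within 1%
  draws <- roulette_select(rep(2, 4), 1e5)
  expect_true(all(abs(tabulate(draws, 4) / 1e5 - 0.25) < 0.01))
  # hand-computed two-point case: p = (0.75, 0.25)
  draws <- roulette_select(c(3, 1), 2e4)
  expect_lt(abs(mean(draws == 1) - 0.75), 0.02)
  # s -> 0 washes out fitness differences
  draws <- roulette_select(c(5, 1), 2e4, s = 1e-9)
  expect_lt(abs(mean(draws == 1) - 0.5), 0.02)
  # selection-strength exponent sharpens: f^2 gives p = (0.9, 0.1)
  draws <- roulette_select(c(3, 1), 2e4, s = 2)
  expect_lt(abs(mean(draws == 1) - 0.9), 0.02)
  # all-equal after flooring (negative rewards): uniform, no error
  draws <- roulette_select(c(-1, -1, -1), 3e3)
  expect_true(all(abs(tabulate(draws, 3) / 3e3 - 1 / 3) < 0.05))
})

test_that("fitness flooring preserves the order of non-negative fitnesses", {
  set.seed(2)
  f <- c(0, 0.2, 1.5, 0.7)
  draws <- roulette_select(f, 4e4)
  freq <- tabulate(draws, 4) / 4e4
  expect_true(all(order(freq) == order(f)))
})

test_that("type mutation hits at the configured rate", {
  set.seed(3)
  expect_identical(mutate_types(rep("IL", 50), 0, c("IL", "SL"))$types,
                   rep("IL", 50))
  res <- mutate_types(rep("IL", 5000), 1, "SL")
  expect_true(all(res$types == "SL"))
  expect_true(all(res$mutated))
  # mr = 0.005 with m = 5000: ~25 events, binomial 3 sigma band
  res <- mutate_types(rep("IL", 5000), 0.005, c("IL", "SL"))
  expect_lt(abs(sum(res$mutated) - 25), 3 * sqrt(5000 * 0.005 * 0.995))
})

test_that("age bookkeeping: first copy inherits, others reset, then +1", {
  expect_equal(update_ages(c(7, 2), parents = c(1, 1, 1),
                           mutated = rep(FALSE, 3)), c(8, 1, 1))
  expect_equal(update_ages(c(4, 9), parents = c(2, 1)), c(10, 5))
  expect_equal(update_ages(c(4, 9), parents = c(1, 2),
                           mutated = c(TRUE, FALSE)), c(1, 10))
})

test_that("the first generation acts by individual learning", {
  env <- tiny_reversal()
  set.seed(4)
  pop <- init_population(env, tiny_cfg(), "conformist")
  pop <- run_generation(pop, env, tiny_cfg())
  expect_equal(pop$last_log$il_steps, length(pop$types))
})

test_that("an all-conformist cohort copies the same arm after the latency", {
  env <- tiny_reversal()
  cfg <- tiny_cfg(m = 30, mr = 0, init_sl = 1)
  set.seed(5)
  pop <- init_population(env, cfg, "conformist")
  pop$types <- rep("SL", 30)
  pop <- run_generation(pop, env, cfg)  # t = 1: IL fallback
  pop$types <- rep("SL", 30)
  pop <- run_generation(pop, env, cfg)
  info <- pop$info_hist[[2]]
  expect_equal(max(info$h), 1)  # everyone on one arm
  expect_equal(pop$last_log$il_steps, 0)
})

test_that("noise-free IL-only psi approaches the eps-greedy asymptote", {
  env <- make_environment("reversal", horizon = 200, sigma = c(0, 0))
  cfg <- evo_config(m = 200, generations = 200)
  set.seed(6)
  run <- evolve_population(env, cfg, sls = "none")
  # (1 - eps) mu_best + eps * mean(mu): random arm includes the best
  asymptote <- 0.9 * 1.0 + 0.1 * 0.75
  expect_lt(abs(mean(run$log$psi[150:199]) - asymptote), 0.02)
})

test_that("population size and ratio bookkeeping stay consistent", {
  env <- tiny_reversal()
  cfg <- tiny_cfg(m = 25)
  set.seed(7)
  run <- evolve_population(env, cfg, sls = "success")
  expect_length(run$population$types, 25)
  expect_true(all(run$log$sl_ratio >= 0 & run$log$sl_ratio <= 1))
  expect_true(all(run$log$il_steps >= 0 & run$log$il_steps <= 25))
  expect_true(all(run$population$ages >= 1))
})

test_that("runs are exactly reproducible from their seed", {
  env <- tiny_reversal()
  r1 <- evolve_population(env, tiny_cfg(), "success", seed = 99)
  r2 <- evolve_population(env, tiny_cfg(), "success", seed = 99)
  expect_identical(r1$log, r2$log)
  m1 <- evolve_meta(env, tiny_cfg(), pool = c("IL-Only", "SL-Conf"),
                    seed = 42)
  m2 <- evolve_meta(env, tiny_cfg(), pool = c("IL-Only", "SL-Conf"),
                    seed = 42)
  expect_identical(m1$log, m2$log)
})

test_that("meta run with a single-strategy pool keeps ratio 1", {
  env <- tiny_reversal()
  set.seed(8)
  run <- evolve_meta(env, tiny_cfg(m = 20), pool = "SL-Conf")
  expect_true(all(run$log[["SL-Conf"]] == 1))
  expect_true(all(rowSums(run$log[, run$pool, drop = FALSE]) == 1))
})

test_that("meta competition: ratios sum to one and mutation floors survival", {
  env <- tiny_reversal(horizon = 80)
  cfg <- tiny_cfg(m = 60, generations = 80, mr = 0.02)
  set.seed(9)
  run <- evolve_meta(env, cfg, pool = c("IL-Only", "SL-Conf", "SL-Succ"))
  rs <- rowSums(run$log[, run$pool])
  expect_true(all(abs(rs - 1) < 1e-12))
  # with mr > 0 no strategy is permanently eliminated: it reappears
  final <- unlist(run$log[nrow(run$log), run$pool])
  expect_true(all(colMeans(run$log[40:80, run$pool] > 0) > 0))
})

test_that("a strictly dominant strategy does not decline in expectation", {
  # stationary noise-free task: SL-Conf pays no exploration cost while
  # IL-Only does, so the conformist meta-strategy should gain ground
  env <- bandit_env(2, 30, list(list(start = 1, arms = list(
    arm_spec("gaussian", 1.0, 0), arm_spec("gaussian", 0.5, 0)))))
  cfg <- evo_config(m = 40, generations = 30, mr = 0)
  set.seed(10)
  gains <- vapply(1:30, function(i) {
    run <- evolve_meta(env, cfg, pool = c("IL-Only", "SL-Conf"),
                       seed = 1000 + i)
    run$log[["SL-Conf"]][30] - run$log[["SL-Conf"]][1]
  }, numeric(1))
  expect_lt(binom.test(sum(gains > 0), sum(gains != 0),
                       alternative = "greater")$p.value, 0.05)
  expect_gt(mean(gains), 0)
})

test_that("meta run accepts trained artifacts", {
  env <- tiny_reversal()
  pol <- discrete_policy("IIIIIIII")
  set.seed(11)
  run <- evolve_meta(env, tiny_cfg(m = 20), pool = "SL-GA",
                     trained = list(policy = pol))
  # an all-IL policy never performs social learning
  expect_true(all(run$log$il_steps == 20))
})
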