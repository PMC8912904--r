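# training runs here use deliberately tiny populations/horizons: the
# point is the optimiser mechanics, not the quality of the optimum

tiny_train_env <- function() tiny_reversal(horizon = 30)
tiny_train_cfg <- function() tiny_cfg(m = 20, generations = 30)

test_that("the policy genotype has 10 genes: 8 discrete + 2 thresholds", {
  g <- c(sample(1:3, 8, replace = TRUE), 0.3, 0.1)
  expect_length(g, 10)
  pol <- metasl:::.policy_from_genotype(g)
  expect_s3_class(pol, "discrete_policy")
  expect_length(pol$table, 8)
  expect_equal(pol$th_ec, 0.3)
  # thresholds are clipped to [0, 1]
  pol2 <- metasl:::.policy_from_genotype(c(rep(1, 8), -0.5, 1.7))
  expect_equal(c(pol2$th_ec, pol2$th_u), c(0, 1))
})

test_that("candidate fitness is deterministic given seeds and scales", {
  env <- tiny_train_env()
  pol <- policy_ec_conf_unc()
  f1 <- policy_fitness(pol, env, tiny_train_cfg(), seeds = c(3, 5))
  f2 <- policy_fitness(pol, env, tiny_train_cfg(), seeds = c(3, 5))
  expect_identical(f1, f2)
  # identical seeds: median equals the single-run value
  f3 <- policy_fitness(pol, env, tiny_train_cfg(), seeds = c(7, 7, 7))
  f4 <- policy_fitness(pol, env, tiny_train_cfg(), seeds = 7)
  expect_identical(f3, f4)
  # a one-generation run reduces to psi(1)
  cfg1 <- tiny_cfg(m = 20, generations = 1)
  set.seed(7)
  expect_identical(policy_fitness(pol, env, cfg1, seeds = 7),
                   sum(evolve_meta(env, cfg1, pool = "SL-GA",
                                   trained = list(policy = pol),
                                   seed = 7)$log$psi))
})

test_that("one-point crossover cuts between genes and preserves length", {
  set.seed(1)
  for (i in 1:20) {
    cs <- metasl:::.one_point_crossover(rep(1, 10), rep(2, 10))
    a <- cs[[1]]
    expect_length(a, 10)
    # a prefix of parent 1 followed by a suffix of parent 2
    cut <- max(which(a == 1))
    expect_true(all(a[seq_len(cut)] == 1) && all(a[-seq_len(cut)] == 2))
  }
})

test_that("policy GA improves monotonically under elitism and returns a policy", {
  env <- tiny_train_env()
  res <- ga_optimize_policy(
    env, ga = ga_config(pop_size = 6, elites = 2, stagnation = 3,
                        max_generations = 6, restarts = 1),
    cfg = tiny_train_cfg(), eval_runs = 2, seed = 2)
  expect_s3_class(res$policy, "discrete_policy")
  expect_true(all(diff(res$history[[1]]) >= 0))
})

test_that("informed policies beat the all-IL policy on a benign task", {
  # exploration costs make pure individual learning strictly worse when
  # rewards are noise-free and copying is reliable
  env <- make_environment("reversal", horizon = 40, sigma = c(0, 0))
  cfg <- evo_config(m = 30, generations = 40)
  seeds <- 1:20
  f_il <- policy_fitness(discrete_policy("IIIIIIII"), env, cfg, seeds)
  f_rule <- policy_fitness(policy_ec_conf_unc(), env, cfg, seeds)
  expect_gt(f_rule, f_il)
  # paired per-seed comparison: sign test
  per_seed <- vapply(seeds, function(s)
    policy_fitness(policy_ec_conf_unc(), env, cfg, s) -
      policy_fitness(discrete_policy("IIIIIIII"), env, cfg, s), numeric(1))
  expect_lt(binom.test(sum(per_seed > 0), length(per_seed),
                       alternative = "greater")$p.value, 0.01)
})

test_that("neuroevolution genome has 123 dimensions and optimises", {
  env <- tiny_train_env()
  res <- ne_optimize_fcn(
    env, method = "GA",
    ctrl = ga_config(pop_size = 6, elites = 2, stagnation = 2,
                     max_generations = 4, restarts = 1),
    cfg = tiny_train_cfg(), eval_runs = 2, seed = 3)
  expect_equal(fcn_n_params(res$fcn), 123)
  expect_true(all(diff(res$history[[1]]) >= 0))
})

test_that("differential evolution mechanics and parameter limits", {
  set.seed(4)
  res <- metasl:::.run_de(5, function(w) -sum((w - 0.2)^2),
                          de_config(pop_size = 6, F = 0.5, CR = 1,
                                    stagnation = 3, max_generations = 10,
                                    restarts = 1))
  expect_length(res$best, 5)
  expect_true(all(diff(res$history) >= 0))
  expect_equal(de_config(CR = 1)$CR, 1)  # CR = 1: trial equals the mutant
  expect_error(de_config(F = 0), "F")
})

test_that("DE improves on a smooth objective", {
  set.seed(5)
  res <- metasl:::.run_de(4, function(w) -sum((w - 0.5)^2),
                          de_config(pop_size = 10, stagnation = 5,
                                    max_generations = 30))
  expect_lt(sum((res$best - 0.5)^2), 0.05)
})

test_that("Q-learning training shapes the table toward observed rewards", {
  env <- make_environment("reversal", horizon = 60, sigma = c(0, 0))
  qt <- train_qlearning(env, evo_config(m = 30, generations = 60),
                        alpha = 0.1, seed = 6)
  expect_equal(dim(qt), c(8, 3))
  # values stay within the observed reward range
  expect_true(all(qt >= 0 & qt <= 1.05))
  # the visited cells moved away from the zero initialisation
  expect_gt(max(qt), 0.5)
})

test_that("gamma = 0 reduces the Bellman update to a running average", {
  st <- bandit_controller("QL", alpha = 0.25, gamma = 0)
  s <- list(ec = 0, conf = 0, unc = 0)
  q <- 0
  for (r in c(1, 1, 0.5)) {
    st <- update_value_controller(st, "IL", r, ctx = s)
    q <- q + 0.25 * (r - q)
  }
  expect_equal(st$q_table[1, 1], q)
})
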