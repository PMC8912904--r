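ctx <- function(ec = 0, conf = 0, unc = 0) list(ec = ec, conf = conf,
                                                unc = unc)

test_that("rule-based controllers implement the arbitration table", {
  # conformity wins regardless of uncertainty
  expect_equal(select_observation_based("EC_CONF_UNC", ctx(0, 1, 1)), "CONFORMIST")
  expect_equal(select_observation_based("EC_CONF_UNC", ctx(0, 1, 0)), "CONFORMIST")
  # non-conformity: low uncertainty -> success-based, high -> IL
  expect_equal(select_observation_based("EC_CONF_UNC", ctx(0, 0, 0)), "SUCCESS")
  expect_equal(select_observation_based("EC_CONF_UNC", ctx(0, 0, 1)), "IL")
  # environment change or the first step reverts to IL
  expect_equal(select_observation_based("EC_CONF_UNC", ctx(1, 1, 0)), "IL")
  expect_equal(select_observation_based("EC_CONF_UNC", ctx(0, 1, 0), t = 1), "IL")
  expect_equal(select_observation_based("EC_CONF", ctx(0, 1, 1)), "CONFORMIST")
  expect_equal(select_observation_based("EC_CONF", ctx(0, 0, 0)), "IL")
  expect_equal(select_observation_based("EC_SUCC", ctx(0, 0, 0)), "SUCCESS")
  expect_equal(select_observation_based("EC_SUCC", ctx(0, 1, 1)), "IL")
})

test_that("the EC-Conf-Unc rule equals its discrete-policy encoding on all 8 states", {
  pol <- policy_ec_conf_unc()
  for (ec in 0:1) for (cf in 0:1) for (u in 0:1) {
    s <- ctx(ec, cf, u)
    expect_equal(select_from_policy(pol, s),
                 select_observation_based("EC_CONF_UNC", s, t = 2),
                 info = sprintf("state (%d,%d,%d)", ec, cf, u))
  }
})

test_that("the discrete policy space holds exactly 3^8 distinct tables", {
  all_pol <- enumerate_policies()
  expect_length(all_pol, 6561)
  expect_length(unique(all_pol), 6561)
  # an all-IL policy returns IL in every state
  pol <- discrete_policy("IIIIIIII")
  for (ec in 0:1) for (cf in 0:1) for (u in 0:1)
    expect_equal(select_from_policy(pol, ctx(ec, cf, u)), "IL")
})

test_that("policies serialize to JSON and back", {
  pol <- discrete_policy("SICCIISC", th_ec = 0.2, th_u = 0.07)
  path <- withr::local_tempfile(fileext = ".json")
  write_controller(pol, path)
  pol2 <- read_controller(path)
  expect_equal(pol2$table, pol$table)
  expect_equal(pol2$th_u, 0.07)
})

test_that("network controller has the stated architecture and size", {
  fcn <- fcn_controller(k = 2, hidden = 12)
  expect_equal(fcn_n_params(fcn), 123)   # 12*(6+1) + 3*(12+1)
  expect_equal(dim(fcn$w1), c(12, 7))
  expect_equal(dim(fcn$w2), c(3, 13))
  expect_error(fcn_controller(rep(0, 100)), "123")
  # round trip through the flat weight vector and JSON
  set.seed(1)
  w <- runif(123, -1, 1)
  fcn2 <- fcn_controller(w)
  expect_equal(fcn_weights(fcn2), w)
  path <- withr::local_tempfile(fileext = ".json")
  write_controller(fcn2, path)
  expect_equal(fcn_weights(read_controller(path)), w)
})

test_that("network forward pass: ties fall to IL, crafted weights route", {
  zero <- fcn_controller(k = 2)
  expect_equal(select_from_fcn(zero, c(1, 0.5), c(0.1, 0.1), c(0.6, 0.4)),
               "IL")
  expect_equal(select_from_fcn(zero, c(NA, NA), c(0, 0), c(0, 0)), "IL")
  # route input h(a_1) (input 5) through hidden unit 1 to output 3 with
  # large gain: h = (1, 0) must select CONFORMIST
  w1 <- matrix(0, 12, 7); w1[1, 5] <- 10
  w2 <- matrix(0, 3, 13); w2[3, 1] <- 10
  fcn <- fcn_controller(c(t(w1), t(w2)))
  expect_equal(select_from_fcn(fcn, c(0, 0), c(0, 0), c(1, 0)), "CONFORMIST")
  # hand-check the forward pass value
  hid <- tanh(10 * 1); out3 <- 10 * hid
  expect_gt(out3, 0)
  expect_equal(select_from_fcn(fcn, c(0, 0), c(0, 0), c(0, 1)), "IL")
})

test_that("network output is arm-permutation consistent", {
  set.seed(9)
  w <- runif(123, -1, 1)
  fcn <- fcn_controller(w)
  # swap arms in the inputs AND the corresponding first-layer columns
  perm <- c(2, 1, 4, 3, 6, 5, 7)
  w1s <- fcn$w1[, perm]
  fcn_s <- fcn_controller(c(t(w1s), t(fcn$w2)))
  mu <- c(0.9, 0.4); sg <- c(0.2, 0.3); h <- c(0.7, 0.3)
  expect_equal(select_from_fcn(fcn, mu, sg, h),
               select_from_fcn(fcn_s, mu[2:1], sg[2:1], h[2:1]))
})

test_that("value-based controllers select and update correctly", {
  st <- bandit_controller("RL", epsilon = 0)
  st$q <- c(1, 0, 0)
  expect_equal(select_value_based(st), "IL")
  st <- update_value_controller(st, "IL", reward = 0.5)
  expect_equal(st$q[1], 1 + 0.2 * (0.5 - 1))
  expect_equal(st$n[1], 1L)

  # UCB: untried strategies first
  st <- bandit_controller("UCB")
  expect_equal(select_value_based(st), "IL")
  st <- update_value_controller(st, "IL", 1)
  expect_equal(select_value_based(st), "SUCCESS")
  st <- update_value_controller(st, "SUCCESS", 0)
  expect_equal(select_value_based(st), "CONFORMIST")

  # QL with gamma = 0 reduces to a running average toward r
  st <- bandit_controller("QL", alpha = 0.5)
  s <- ctx(0, 1, 0)
  st <- update_value_controller(st, "CONFORMIST", 1, ctx = s)
  st <- update_value_controller(st, "CONFORMIST", 1, ctx = s)
  expect_equal(st$q_table[context_state_index(0, 1, 0), 3], 0.75)
  st$epsilon_ql <- 0
  expect_equal(select_value_based(st, ctx = s), "CONFORMIST")
})

test_that("fixed-probability baselines hit their stated frequencies", {
  expect_equal(select_baseline("IL_ONLY"), "IL")
  set.seed(6)
  draws <- replicate(3e4, select_baseline("RAND"))
  expect_true(all(abs(table(draws) / 3e4 - 1 / 3) < 0.01))
  draws <- replicate(1e4, select_baseline("CONF"))
  expect_lt(abs(mean(draws == "CONFORMIST") - 0.95), 0.01)
  expect_false(any(draws == "SUCCESS"))
  draws <- replicate(1e4, select_baseline("PROP"))
  expect_lt(abs(mean(draws == "SUCCESS") - 0.45), 0.02)
  expect_lt(abs(mean(draws == "IL") - 0.10), 0.01)
})

test_that("every controller is total over reachable inputs", {
  set.seed(10)
  states <- expand.grid(ec = 0:1, conf = 0:1, unc = 0:1)
  pol <- discrete_policy(sample(c("I", "S", "C"), 8, replace = TRUE) |>
                           paste(collapse = ""))
  fcn <- fcn_controller(runif(123, -1, 1))
  for (i in seq_len(nrow(states))) {
    s <- ctx(states$ec[i], states$conf[i], states$unc[i])
    for (v in c("EC_CONF", "EC_SUCC", "EC_CONF_UNC"))
      expect_true(select_observation_based(v, s) %in% strategies())
    expect_true(select_from_policy(pol, s) %in% strategies())
    expect_true(select_value_based(bandit_controller("QL"), s) %in%
                  strategies())
  }
  expect_true(select_from_fcn(fcn, runif(2), runif(2), c(0.5, 0.5)) %in%
                strategies())
})
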