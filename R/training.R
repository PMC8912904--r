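# Offline optimisation of meta-controllers: a genetic algorithm over the
# 10-gene discrete policies (SL-GA), neuroevolution of the network
# controller by GA or differential evolution (SL-NE), and Q-learning
# (SL-QL). Trained controllers are meant to be evaluated on environments
# different from the training environment.

#' Genetic-algorithm settings
#'
#' @param pop_size Population size (default 50).
#' @param elites Elite count carried unchanged (4 for the policy GA, 5
#'   for neuroevolution).
#' @param crossover_prob 1-point crossover probability (default 0.8).
#' @param mut_sd Gaussian perturbation sd for continuous genes (default
#'   0.1).
#' @param stagnation Stop after this many generations without improvement
#'   (default 20).
#' @param max_generations Hard cap on generations per restart (default
#'   200).
#' @param restarts Independent restarts; the best-of-restarts is returned
#'   (default 10).
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 50, elites = 4, crossover_prob = 0.8,
                      mut_sd = 0.1, stagnation = 20, max_generations = 200,
                      restarts = 10) {
  stopifnot(elites < pop_size, crossover_prob >= 0, crossover_prob <= 1)
  structure(list(pop_size = pop_size, elites = elites,
                 crossover_prob = crossover_prob, mut_sd = mut_sd,
                 stagnation = stagnation, max_generations = max_generations,
                 restarts = restarts),
            class = "ga_config")
}

#' Differential-evolution settings
#'
#' rand/1 mutation with uniform (binomial) crossover.
#'
#' @param pop_size Population size (default 50).
#' @param F Differential weight (default 0.5).
#' @param CR Crossover rate (default 0.1).
#' @param init_range Uniform initialisation range (default \[-1, 1\]).
#' @param stagnation,max_generations,restarts As in [ga_config()].
#' @return A list of class `de_config`.
#' @export
de_config <- function(pop_size = 50, F = 0.5, CR = 0.1,
                      init_range = c(-1, 1), stagnation = 20,
                      max_generations = 200, restarts = 10) {
  stopifnot(F > 0, F <= 2, CR >= 0, CR <= 1, pop_size >= 4)
  structure(list(pop_size = pop_size, F = F, CR = CR,
                 init_range = init_range, stagnation = stagnation,
                 max_generations = max_generations, restarts = restarts),
            class = "de_config")
}

#' Fitness of a candidate meta-controller
#'
#' Runs full evolutionary simulations in which every agent uses the
#' candidate controller (a [discrete_policy()] or [fcn_controller()]) and
#' returns the median over runs of the cumulative sum of the average
#' population reward, `median_i sum_t psi_i(t)`. Evaluations are seeded:
#' the same candidate with the same `seeds` gives identical fitness.
#'
#' @param candidate A [discrete_policy()] or [fcn_controller()].
#' @param env Training [bandit_env()].
#' @param cfg An [evo_config()] for the inner simulations.
#' @param seeds Integer seeds, one per evaluation run.
#' @return Numeric fitness (median cumulative average reward).
#' @export
policy_fitness <- function(candidate, env, cfg = evo_config(), seeds = 1:16) {
  stopifnot(length(seeds) >= 1)
  if (inherits(candidate, "discrete_policy")) {
    pool <- "SL-GA"; trained <- list(policy = candidate)
  } else if (inherits(candidate, "fcn_controller")) {
    pool <- "SL-NE"; trained <- list(fcn = candidate)
  } else stop("candidate must be a discrete_policy or fcn_controller")
  tot <- vapply(seeds, function(sd) {
    r <- evolve_meta(env, cfg, pool = pool, trained = trained, seed = sd)
    sum(r$log$psi)
  }, numeric(1))
  stats::median(tot)
}

.policy_from_genotype <- function(g) {
  discrete_policy(strategies()[g[1:8]],
                  th_ec = min(max(g[9], 0), 1), th_u = min(max(g[10], 0), 1))
}

.one_point_crossover <- function(a, b) {
  L <- length(a)
  cut <- sample.int(L - 1L, 1)   # cut point between genes
  list(c(a[1:cut], b[(cut + 1):L]), c(b[1:cut], a[(cut + 1):L]))
}

# generic generational GA with elitism over a list of genotypes
.run_ga <- function(init_fun, eval_fun, mutate_fun, ga) {
  pop <- lapply(seq_len(ga$pop_size), function(i) init_fun())
  fit <- vapply(pop, eval_fun, numeric(1))
  best_fit <- -Inf; best <- NULL; stale <- 0L
  history <- numeric(0)
  for (gen in seq_len(ga$max_generations)) {
    ord <- order(fit, decreasing = TRUE)
    if (fit[ord[1]] > best_fit) {
      best_fit <- fit[ord[1]]; best <- pop[[ord[1]]]; stale <- 0L
    } else stale <- stale + 1L
    history <- c(history, best_fit)
    if (stale >= ga$stagnation) break
    elite <- pop[ord[seq_len(ga$elites)]]
    n_child <- ga$pop_size - ga$elites
    parents <- roulette_select(fit, 2L * n_child)
    children <- vector("list", n_child)
    i <- 1L
    while (i <= n_child) {
      a <- pop[[parents[2L * i - 1L]]]; b <- pop[[parents[2L * i]]]
      if (stats::runif(1) < ga$crossover_prob) {
        cs <- .one_point_crossover(a, b)
        a <- cs[[1]]; b <- cs[[2]]
      }
      children[[i]] <- mutate_fun(a)
      if (i + 1L <= n_child) children[[i + 1L]] <- mutate_fun(b)
      i <- i + 2L
    }
    pop <- c(elite, children)
    fit <- c(fit[ord[seq_len(ga$elites)]],
             vapply(children, eval_fun, numeric(1)))
  }
  list(best = best, fitness = best_fit, history = history)
}

#' Optimise a discrete meta-control policy by a genetic algorithm
#'
#' The genotype has 10 genes: 8 discrete strategy genes (one per context
#' state) and the two continuous detection thresholds. Discrete genes
#' mutate with probability `1 / (L - 2) = 1/8` each, replacing the gene
#' by one of the other two strategies; continuous genes receive Gaussian
#' perturbation with sd `mut_sd` and are clipped to \[0, 1\]. A standard
#' generational GA with roulette selection, elitism and 1-point crossover
#' runs until the stagnation rule fires; the best candidate over
#' `restarts` independent restarts is returned. Candidate evaluations
#' within a restart share the same seed list (common random numbers).
#'
#' @param env Training [bandit_env()].
#' @param ga A [ga_config()] (default: 50 individuals, 4 elites).
#' @param cfg An [evo_config()] for the inner simulations.
#' @param eval_runs Simulation runs per fitness evaluation.
#' @param seed Base RNG seed.
#' @return A list of class `ga_result`: `policy` (the best
#'   [discrete_policy()]), `fitness`, `history` (per-restart best-fitness
#'   traces).
#' @export
ga_optimize_policy <- function(env, ga = ga_config(), cfg = evo_config(),
                               eval_runs = 16, seed = 1) {
  set.seed(seed)
  best <- NULL; best_fit <- -Inf; histories <- list()
  for (r in seq_len(ga$restarts)) {
    eval_seeds <- sample.int(.Machine$integer.max %/% 2, eval_runs)
    init_fun <- function()
      c(sample.int(3, 8, replace = TRUE), stats::runif(2))
    mutate_fun <- function(g) {
      flip <- stats::runif(8) < 1 / 8
      if (any(flip))
        g[1:8][flip] <- vapply(g[1:8][flip], function(cur)
          sample(setdiff(1:3, cur), 1), numeric(1))
      g[9:10] <- pmin(pmax(g[9:10] + stats::rnorm(2, 0, ga$mut_sd), 0), 1)
      g
    }
    eval_fun <- function(g)
      policy_fitness(.policy_from_genotype(g), env, cfg, seeds = eval_seeds)
    res <- .run_ga(init_fun, eval_fun, mutate_fun, ga)
    histories[[r]] <- res$history
    if (res$fitness > best_fit) {
      best_fit <- res$fitness; best <- res$best
    }
  }
  structure(list(policy = .policy_from_genotype(best), fitness = best_fit,
                 history = histories),
            class = "ga_result")
}

#' Optimise the network meta-controller by neuroevolution
#'
#' Evolves the flat 123-weight genome of the [fcn_controller()] with
#' either a GA (roulette selection, 5 elites, 1-point crossover with
#' probability 0.8, independent Gaussian perturbation `N(0, 0.1)` per
#' dimension) or differential evolution (rand/1 mutation, uniform
#' crossover, `F = 0.5`, `CR = 0.1`). Weights initialise uniformly in
#' \[-1, 1\] and are unbounded afterwards.
#'
#' @param env Training [bandit_env()].
#' @param method `"GA"` or `"DE"`.
#' @param ctrl A [ga_config()] (GA; default 5 elites) or [de_config()]
#'   (DE).
#' @param cfg An [evo_config()] for the inner simulations.
#' @param eval_runs Simulation runs per fitness evaluation.
#' @param seed Base RNG seed.
#' @param k,hidden Network architecture (defaults 2 arms, 12 hidden).
#' @return A list of class `ne_result`: `fcn` (best [fcn_controller()]),
#'   `fitness`, `history`.
#' @export
ne_optimize_fcn <- function(env, method = c("GA", "DE"), ctrl = NULL,
                            cfg = evo_config(), eval_runs = 16, seed = 1,
                            k = 2, hidden = 12) {
  method <- match.arg(method)
  if (is.null(ctrl))
    ctrl <- if (method == "GA") ga_config(elites = 5) else de_config()
  set.seed(seed)
  n_par <- hidden * (3 * k + 1) + 3 * (hidden + 1)
  best <- NULL; best_fit <- -Inf; histories <- list()
  for (r in seq_len(ctrl$restarts)) {
    eval_seeds <- sample.int(.Machine$integer.max %/% 2, eval_runs)
    eval_fun <- function(w)
      policy_fitness(fcn_controller(w, k = k, hidden = hidden), env, cfg,
                     seeds = eval_seeds)
    if (method == "GA") {
      res <- .run_ga(
        init_fun = function() stats::runif(n_par, -1, 1),
        eval_fun = eval_fun,
        mutate_fun = function(w) w + stats::rnorm(n_par, 0, ctrl$mut_sd),
        ga = ctrl)
    } else {
      res <- .run_de(n_par, eval_fun, ctrl)
    }
    histories[[r]] <- res$history
    if (res$fitness > best_fit) {
      best_fit <- res$fitness; best <- res$best
    }
  }
  structure(list(fcn = fcn_controller(best, k = k, hidden = hidden),
                 fitness = best_fit, history = histories),
            class = "ne_result")
}

# differential evolution, rand/1/bin
.run_de <- function(n_par, eval_fun, de) {
  pop <- lapply(seq_len(de$pop_size), function(i)
    stats::runif(n_par, de$init_range[1], de$init_range[2]))
  fit <- vapply(pop, eval_fun, numeric(1))
  best_fit <- -Inf; best <- NULL; stale <- 0L; history <- numeric(0)
  for (gen in seq_len(de$max_generations)) {
    if (max(fit) > best_fit) {
      best_fit <- max(fit); best <- pop[[which.max(fit)]]; stale <- 0L
    } else stale <- stale + 1L
    history <- c(history, best_fit)
    if (stale >= de$stagnation) break
    for (i in seq_len(de$pop_size)) {
      rs <- sample(setdiff(seq_len(de$pop_size), i), 3)
      mutant <- pop[[rs[1]]] + de$F * (pop[[rs[2]]] - pop[[rs[3]]])
      cross <- stats::runif(n_par) < de$CR
      cross[sample.int(n_par, 1)] <- TRUE   # guaranteed dimension
      trial <- pop[[i]]
      trial[cross] <- mutant[cross]
      f_trial <- eval_fun(trial)
      if (f_trial >= fit[i]) {
        pop[[i]] <- trial; fit[i] <- f_trial
      }
    }
  }
  list(best = best, fitness = best_fit, history = history)
}

#' Train the Q-learning meta-controller
#'
#' Online training inside an evolutionary simulation: a population of
#' agents all select strategies epsilon_QL-greedily on a shared 8 x 3
#' Q-table over the context states, and every agent's
#' (state, strategy, reward) experience updates the table with the
#' Bellman rule — with the default discount `gamma = 0` this reduces to
#' `Q <- Q + alpha * (r - Q)`.
#'
#' @param env Training [bandit_env()].
#' @param cfg An [evo_config()].
#' @param epsilon_ql Exploration rate (default 0.2).
#' @param alpha Learning rate (default 0.01).
#' @param gamma Discount factor (default 0).
#' @param episodes Number of passes over the environment horizon.
#' @param ctx_params A [context_params()].
#' @param seed RNG seed.
#' @return The trained 8 x 3 Q-table (states x strategies).
#' @export
train_qlearning <- function(env, cfg = evo_config(), epsilon_ql = 0.2,
                            alpha = 0.01, gamma = 0, episodes = 1,
                            ctx_params = context_params(), seed = 1) {
  set.seed(seed)
  qt <- matrix(0, 8, 3, dimnames = list(NULL, strategies()))
  m <- cfg$m; k <- env$k
  for (ep in seq_len(episodes)) {
    Q <- matrix(0, m, k)
    info_hist <- vector("list", env$horizon)
    T_run <- min(cfg$generations, env$horizon)
    prev <- NULL   # (state, strategy, per-agent flags) awaiting reward
    for (t in seq_len(T_run)) {
      raw <- .context_raw(info_hist, t - 1L, ctx_params$delta,
                          ctx_params$sigma_floor)
      ctx <- .ctx_from_raw(raw, ctx_params$th_ec, ctx_params$th_u)
      s <- context_state_index(ctx$ec, ctx$conf, ctx$unc)
      sel <- max.col(matrix(qt[s, ], m, 3, byrow = TRUE),
                     ties.method = "first")
      expl <- stats::runif(m) < epsilon_ql
      sel[expl] <- sample.int(3, sum(expl), replace = TRUE)
      exec <- sel
      if (t - cfg$tau <= 0) exec[exec != 1L] <- 1L
      actions <- .egreedy_actions(Q, cfg$epsilon)
      if (any(exec == 2L))
        actions[exec == 2L] <- success_based_action(info_hist, t, cfg$tau)
      if (any(exec == 3L))
        actions[exec == 3L] <- conformist_action(info_hist, t, cfg$tau)
      rewards <- sample_reward(env, actions, t)
      idx <- cbind(seq_len(m), actions)
      Q[idx] <- Q[idx] + cfg$beta * (rewards - Q[idx])
      info_hist[[t]] <- social_info(actions, rewards, k)
      # table update; gamma > 0 would need the successor state, which is
      # this step's context re-encoded after acting
      boot <- if (gamma > 0) {
        raw2 <- .context_raw(info_hist, t, ctx_params$delta,
                             ctx_params$sigma_floor)
        ctx2 <- .ctx_from_raw(raw2, ctx_params$th_ec, ctx_params$th_u)
        gamma * max(qt[context_state_index(ctx2$ec, ctx2$conf, ctx2$unc), ])
      } else 0
      for (a in 1:3) {
        hit <- sel == a
        if (any(hit))
          for (r in rewards[hit])
            qt[s, a] <- qt[s, a] + alpha * (r + boot - qt[s, a])
      }
      parents <- roulette_select(rewards, m, cfg$s)
      Q <- Q[parents, , drop = FALSE]
    }
  }
  qt
}
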