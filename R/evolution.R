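#' Configuration of the agent-based evolutionary simulation
#'
#' @param m Population size (constant across generations; default 100).
#' @param generations Number of generations `T` (default 400).
#' @param mr Type/strategy mutation rate per agent per generation
#'   (default 0.005).
#' @param s Selection-strength exponent: selection probability is
#'   proportional to `fitness^s`. Named presets `"low"`, `"moderate"`,
#'   `"high"` map to 0.5, 1, 2.
#' @param epsilon Individual learners' exploration rate (default 0.1).
#' @param beta Value-update step size (default 0.2).
#' @param tau Social observation latency in generations (default 1).
#' @param init_sl Initial social-learner fraction for two-type runs
#'   (default 0.5; agents are assigned types at random).
#' @return A list of class `evo_config`.
#' @export
evo_config <- function(m = 100, generations = 400, mr = 0.005, s = 1,
                       epsilon = 0.1, beta = 0.2, tau = 1, init_sl = 0.5) {
  if (is.character(s))
    s <- c(low = 0.5, moderate = 1, high = 2)[[match.arg(s, c("low",
                                                              "moderate",
                                                              "high"))]]
  stopifnot(m >= 2, generations >= 1, mr >= 0, mr <= 1, s > 0,
            epsilon >= 0, epsilon <= 1, beta > 0, beta <= 1, tau >= 1,
            init_sl >= 0, init_sl <= 1)
  structure(list(m = as.integer(m), generations = as.integer(generations),
                 mr = mr, s = s, epsilon = epsilon, beta = beta,
                 tau = as.integer(tau), init_sl = init_sl),
            class = "evo_config")
}

#' Fitness-proportionate (roulette wheel) selection
#'
#' Samples `m` parent indices with replacement with probability
#' `p_i = f_i^s / sum_j f_j^s`. Fitnesses are first shifted by
#' `min(0, min(f))` and floored at 1e-9 so that negative rewards (possible
#' under wide Gaussian reward noise) yield valid selection masses; if all
#' fitnesses coincide after flooring, selection is uniform.
#'
#' @param fitness Numeric fitness vector.
#' @param m Number of parents to draw.
#' @param s Selection-strength exponent (default 1).
#' @return Integer vector of `m` parent indices.
#' @export
roulette_select <- function(fitness, m, s = 1) {
  stopifnot(m >= 1, s > 0, length(fitness) >= 1)
  f <- fitness - min(0, min(fitness))
  f <- pmax(f, 1e-9)
  sample.int(length(fitness), m, replace = TRUE, prob = f^s)
}

#' Mutate agent types / strategies
#'
#' Each agent's type is independently resampled from `pool` with
#' probability `mr`. For a two-entry pool of the agent's own type plus
#' one alternative this flips IL and SL; for the meta-competition the
#' pool is the full strategy set (resampling may draw the same type).
#'
#' @param types Character vector of current types.
#' @param mr Mutation rate in \[0, 1\].
#' @param pool Candidate types to resample from.
#' @return A list with `types` (updated vector) and `mutated` (logical
#'   flags; a flag is set whenever the resampling event occurred).
#' @export
mutate_types <- function(types, mr, pool) {
  stopifnot(mr >= 0, mr <= 1, length(pool) >= 1)
  hit <- stats::runif(length(types)) < mr
  n_hit <- sum(hit)
  if (n_hit > 0)
    types[hit] <- pool[sample.int(length(pool), n_hit, replace = TRUE)]
  list(types = types, mutated = hit)
}

#' Age bookkeeping across a selection step
#'
#' When a parent is selected multiple times the copies are treated as
#' offspring: only the first copy inherits the parent's age, the others
#' start at zero; mutated agents also restart at zero. All ages are then
#' incremented by one for the new generation.
#'
#' @param ages Integer ages of the parent generation.
#' @param parents Parent indices from [roulette_select()].
#' @param mutated Logical mutation flags for the offspring.
#' @return Integer ages of the offspring generation.
#' @examples
#' update_ages(c(7, 2), parents = c(1, 1, 1), mutated = rep(FALSE, 3))
#' # 8 1 1
#' @export
update_ages <- function(ages, parents, mutated = logical(length(parents))) {
  new <- ages[parents]
  new[duplicated(parents)] <- 0L
  new[mutated] <- 0L
  new + 1L
}

#' Initialise a two-type population of individual and social learners
#'
#' @param env A [bandit_env()].
#' @param cfg An [evo_config()].
#' @param sls Social learning strategy of the SL type: `"success"`,
#'   `"conformist"`, `"perfect"`, `"random"`, or `"none"` for an IL-only
#'   population.
#' @return An object of class `sl_population`.
#' @export
init_population <- function(env, cfg, sls = c("success", "conformist",
                                              "perfect", "random", "none")) {
  sls <- match.arg(sls)
  m <- cfg$m
  frac <- if (sls == "none") 0 else cfg$init_sl
  is_sl <- stats::runif(m) < frac
  structure(list(
    types = ifelse(is_sl, "SL", "IL"),
    Q = matrix(0, nrow = m, ncol = env$k),
    ages = rep(0L, m),
    sls = sls, t = 0L, info_hist = vector("list", env$horizon)),
    class = "sl_population")
}

#' @export
print.sl_population <- function(x, ...) {
  cat(sprintf("<sl_population> %d agents (%.0f%% SL, strategy %s), generation %d\n",
              length(x$types), 100 * mean(x$types == "SL"), x$sls, x$t))
  invisible(x)
}

#' Advance a two-type population by one generation
#'
#' Each agent acts (individual learners by epsilon-greedy choice on their
#' own value estimates; social learners by their strategy with latency
#' `tau`, falling back to individual learning while no social records
#' exist), receives a reward, updates its decision model and takes the
#' reward as its fitness. The shared social information is recorded, then
#' fitness-proportionate selection and type mutation produce the next
#' generation (offspring carry their parent's decision model).
#'
#' @param pop An [init_population()] object.
#' @param env A [bandit_env()].
#' @param cfg An [evo_config()].
#' @return The updated population, with a `last_log` entry (list with
#'   `psi`, `sl_ratio`, `il_steps`, `mean_age_il`, `mean_age_sl`).
#' @export
run_generation <- function(pop, env, cfg) {
  stopifnot(inherits(pop, "sl_population"))
  t <- pop$t + 1L
  if (t > env$horizon) stop("environment horizon exhausted")
  m <- length(pop$types)
  is_sl <- pop$types == "SL"
  social_ok <- pop$sls != "none" && (t - cfg$tau > 0 || pop$sls == "perfect")

  actions <- .egreedy_actions(pop$Q, cfg$epsilon)
  il_exec <- rep(TRUE, m)
  if (social_ok && any(is_sl)) {
    if (pop$sls == "random") {
      info <- pop$info_hist[[t - cfg$tau]]
      actions[is_sl] <- sample.int(env$k, sum(is_sl), replace = TRUE,
                                   prob = info$h)
    } else {
      a_sl <- switch(pop$sls,
        success = success_based_action(pop$info_hist, t, cfg$tau),
        conformist = conformist_action(pop$info_hist, t, cfg$tau),
        perfect = copy_variant_action("perfect", env = env, t = t))
      actions[is_sl] <- a_sl
    }
    il_exec[is_sl] <- FALSE
  }

  rewards <- sample_reward(env, actions, t)
  idx <- cbind(seq_len(m), actions)
  pop$Q[idx] <- pop$Q[idx] + cfg$beta * (rewards - pop$Q[idx])
  pop$info_hist[[t]] <- social_info(actions, rewards, env$k)

  parents <- roulette_select(rewards, m, cfg$s)
  mut <- mutate_types(pop$types[parents], cfg$mr,
                      pool = if (pop$sls == "none") "IL" else c("IL", "SL"))
  ages <- update_ages(pop$ages, parents, mut$mutated)

  pop$last_log <- list(
    psi = mean(rewards), sl_ratio = mean(is_sl), il_steps = sum(il_exec),
    mean_age_il = if (any(!is_sl)) mean(pop$ages[!is_sl]) else NA_real_,
    mean_age_sl = if (any(is_sl)) mean(pop$ages[is_sl]) else NA_real_)
  pop$types <- mut$types
  pop$Q <- pop$Q[parents, , drop = FALSE]
  pop$ages <- ages
  pop$t <- t
  pop
}

#' Evolve a two-type population over the full horizon
#'
#' Convenience wrapper running [run_generation()] for every step of the
#' environment.
#'
#' @inheritParams init_population
#' @param seed Optional RNG seed (the whole run is reproducible from it).
#' @return An object of class `evo_run`: list with `log` (data frame of
#'   per-generation `psi`, `sl_ratio`, `il_steps`, mean ages), the final
#'   population, `cfg` and `sls`.
#' @examples
#' env <- make_environment("reversal", horizon = 50)
#' run <- evolve_population(env, evo_config(m = 50, generations = 50),
#'                          sls = "conformist", seed = 1)
#' mean(run$log$psi[40:50])
#' @export
evolve_population <- function(env, cfg = evo_config(),
                              sls = c("success", "conformist", "perfect",
                                      "random", "none"),
                              seed = NULL) {
  sls <- match.arg(sls)
  if (!is.null(seed)) set.seed(seed)
  T_run <- min(cfg$generations, env$horizon)
  pop <- init_population(env, cfg, sls)
  log <- matrix(NA_real_, nrow = T_run, ncol = 5,
                dimnames = list(NULL, c("psi", "sl_ratio", "il_steps",
                                        "mean_age_il", "mean_age_sl")))
  for (t in seq_len(T_run)) {
    pop <- run_generation(pop, env, cfg)
    log[t, ] <- unlist(pop$last_log)
  }
  structure(list(log = as.data.frame(cbind(generation = seq_len(T_run), log)),
                 population = pop, cfg = cfg, sls = sls, seed = seed),
            class = "evo_run")
}

#' @export
print.evo_run <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf("<evo_run> %s strategy, %d generations, m=%d\n",
              x$sls, n, x$cfg$m))
  last <- max(1L, n - 49L):n
  cat(sprintf("  mean psi over final 50 generations: %.4f (SL ratio %.2f)\n",
              mean(x$log$psi[last]), x$log$sl_ratio[n]))
  invisible(x)
}

#' @export
plot.evo_run <- function(x, ...) {
  graphics::plot(x$log$generation, x$log$psi, type = "l", col = "grey40",
                 xlab = "generation", ylab = expression(psi(t)), ...)
  graphics::lines(x$log$generation, x$log$sl_ratio, col = "steelblue")
  graphics::legend("bottomright", c("avg reward", "SL ratio"), lty = 1,
                   col = c("grey40", "steelblue"), bty = "n")
  invisible(x)
}
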