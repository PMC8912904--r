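# Meta-strategy populations: every agent carries its own meta-controller
# that picks IL / success-based / conformist each generation.

#' The full set of meta-social learning strategy names
#'
#' @return Character vector of the 13 meta-strategy names.
#' @export
meta_strategy_pool <- function() {
  c("IL-Only", "SL-Rand", "SL-Prop", "SL-Conf", "SL-Succ",
    "SL-EC-Conf", "SL-EC-Succ", "SL-EC-Conf-Unc",
    "SL-GA", "SL-NE", "SL-RL", "SL-UCB", "SL-QL")
}

.baseline_of <- c("IL-Only" = "IL_ONLY", "SL-Rand" = "RAND",
                  "SL-Prop" = "PROP", "SL-Conf" = "CONF",
                  "SL-Succ" = "SUCC")
.obs_of <- c("SL-EC-Conf" = "EC_CONF", "SL-EC-Succ" = "EC_SUCC",
             "SL-EC-Unc" = "EC_SUCC", "SL-EC-Conf-Unc" = "EC_CONF_UNC")

# threshold-free context summary for one observation step; thresholds are
# applied afterwards so several threshold settings can share one ODPU call
.context_raw <- function(info_hist, t_obs, delta = 1, sigma_floor = 1e-6) {
  if (t_obs < 1 || is.null(info_hist[[t_obs]]))
    return(list(dmu = NA_real_, agree = NA, odpu = NA_real_))
  info <- info_hist[[t_obs]]
  mu_now <- if (all(is.na(info$mu))) NA_real_ else max(info$mu, na.rm = TRUE)
  mu_lag <- NA_real_
  if (t_obs - delta >= 1 && !is.null(info_hist[[t_obs - delta]])) {
    lag <- info_hist[[t_obs - delta]]
    if (!all(is.na(lag$mu))) mu_lag <- max(lag$mu, na.rm = TRUE)
  }
  dmu <- if (is.na(mu_now) || is.na(mu_lag)) NA_real_ else
    abs(mu_now - mu_lag)
  agree <- if (all(is.na(info$mu))) NA else
    which.max(info$mu) == which.max(info$h)
  ok <- !is.na(info$mu) & info$counts >= 1
  od <- if (sum(ok) >= 2)
    odpu(info$mu[ok], pmax(info$sd[ok], sigma_floor), pmax(info$counts[ok], 1))
  else NA_real_
  list(dmu = dmu, agree = agree, odpu = od)
}

.ctx_from_raw <- function(raw, th_ec, th_u) {
  ec <- if (!is.na(raw$dmu) && raw$dmu > th_ec) 1L else 0L
  conf <- if (ec == 0L && isTRUE(raw$agree)) 1L else 0L
  unc <- if (!is.na(raw$odpu) && raw$odpu > th_u) 1L else 0L
  list(ec = ec, conf = conf, unc = unc)
}

#' Evolve a population of meta-social learners
#'
#' Every agent carries one of the meta-strategies in `pool` and uses it
#' each generation to pick individual learning, success-based or
#' conformist copying; the picked strategy is executed against the shared
#' social records (with latency `tau`; success/conformist selections fall
#' back to individual learning while no records exist). Fitness is the
#' received reward; fitness-proportionate selection and strategy-resample
#' mutation produce the next generation, with age bookkeeping as in
#' [update_ages()].
#'
#' @param env A [bandit_env()].
#' @param cfg An [evo_config()].
#' @param pool Meta-strategy names (subset of [meta_strategy_pool()]).
#' @param assignment Optional initial strategy per agent; default uniform
#'   random over `pool`.
#' @param trained Optional trained artifacts: list with `policy` (a
#'   [discrete_policy()] for SL-GA; defaults to [policy_ec_conf_unc()],
#'   the table the genetic optimisation converges to), `fcn` (an
#'   [fcn_controller()] for SL-NE; defaults to zero weights) and
#'   `q_table` (8 x 3 initial table for SL-QL; defaults to zeros).
#' @param ctx_params A [context_params()] used by the rule-based and QL
#'   controllers.
#' @param seed Optional RNG seed.
#' @return An object of class `meta_run`: list with `log` (data frame:
#'   generation, psi, il_steps, per-strategy ratios), `ages` (data frame
#'   of per-strategy mean ages), final `strategies`, `cfg`, `pool`.
#' @export
evolve_meta <- function(env, cfg = evo_config(), pool = meta_strategy_pool(),
                        assignment = NULL, trained = list(),
                        ctx_params = context_params(), seed = NULL) {
  stopifnot(all(pool %in% c(meta_strategy_pool(), "SL-EC-Unc")))
  if (!is.null(seed)) set.seed(seed)
  m <- cfg$m; k <- env$k
  T_run <- min(cfg$generations, env$horizon)
  policy <- trained$policy
  if (is.null(policy)) policy <- policy_ec_conf_unc(ctx_params$th_ec,
                                                    ctx_params$th_u)
  fcn <- trained$fcn
  if (is.null(fcn)) fcn <- fcn_controller(k = k)
  ql0 <- trained$q_table
  if (is.null(ql0)) ql0 <- matrix(0, 8, 3)
  ql0_row <- as.vector(t(ql0))

  meta <- if (is.null(assignment))
    pool[sample.int(length(pool), m, replace = TRUE)] else assignment
  stopifnot(length(meta) == m)
  Q <- matrix(0, m, k)
  ages <- rep(0L, m)
  vq <- matrix(0, m, 3)      # per-agent strategy values (SL-RL / SL-UCB)
  vn <- matrix(0L, m, 3)
  qtab <- matrix(ql0_row, m, 24, byrow = TRUE)  # per-agent 8x3 table, row-major
  info_hist <- vector("list", T_run)

  n_pool <- length(pool)
  ratio <- matrix(NA_real_, T_run, n_pool, dimnames = list(NULL, pool))
  age_log <- matrix(NA_real_, T_run, n_pool, dimnames = list(NULL, pool))
  psi <- il_steps <- numeric(T_run)

  pol_code <- .strategy_code(policy$table)

  for (t in seq_len(T_run)) {
    raw <- .context_raw(info_hist, t - 1L, ctx_params$delta,
                        ctx_params$sigma_floor)
    ctx <- .ctx_from_raw(raw, ctx_params$th_ec, ctx_params$th_u)
    ctx_ga <- .ctx_from_raw(raw, policy$th_ec, policy$th_u)
    state_idx <- context_state_index(ctx$ec, ctx$conf, ctx$unc)

    sel <- integer(m)  # chosen strategy code per agent (1 IL, 2 SUCC, 3 CONF)
    for (nm in unique(meta)) {
      grp <- which(meta == nm)
      sel[grp] <- if (nm %in% names(.baseline_of)) {
        p <- .baseline_probs[[.baseline_of[[nm]]]]
        sample.int(3, length(grp), replace = TRUE, prob = p)
      } else if (nm %in% names(.obs_of)) {
        rep(.strategy_code(select_observation_based(.obs_of[[nm]], ctx, t)),
            length(grp))
      } else if (nm == "SL-GA") {
        if (t == 1) 1L    # no records yet; the table covers all 8 states
        else rep(pol_code[context_state_index(ctx_ga$ec, ctx_ga$conf,
                                              ctx_ga$unc)], length(grp))
      } else if (nm == "SL-NE") {
        obs <- if (t - cfg$tau >= 1) info_hist[[t - cfg$tau]] else NULL
        s <- if (is.null(obs)) "IL" else
          select_from_fcn(fcn, obs$mu, obs$sd, obs$h)
        rep(.strategy_code(s), length(grp))
      } else if (nm == "SL-RL") {
        .egreedy_actions(vq[grp, , drop = FALSE], cfg$epsilon)
      } else if (nm == "SL-UCB") {
        nmat <- vn[grp, , drop = FALSE]
        bonus <- sqrt(log(max(t, 2)) / nmat)   # n = 0 gives Inf: untried first
        max.col(vq[grp, , drop = FALSE] + bonus, ties.method = "first")
      } else if (nm == "SL-QL") {
        cols <- (state_idx - 1L) * 3L + 1:3
        qrows <- qtab[grp, cols, drop = FALSE]
        pick <- max.col(qrows, ties.method = "first")
        expl <- stats::runif(length(grp)) < 0.2
        pick[expl] <- sample.int(3, sum(expl), replace = TRUE)
        pick
      } else stop("unhandled meta strategy: ", nm)
    }

    # execute the selected strategies (social choices need t - tau > 0)
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

    # controller feedback (value-based controllers learn on every step)
    vb <- meta %in% c("SL-RL", "SL-UCB")
    if (any(vb)) {
      i2 <- cbind(which(vb), sel[vb])
      vq[i2] <- vq[i2] + cfg$beta * (rewards[vb] - vq[i2])
      vn[i2] <- vn[i2] + 1L
    }
    qlr <- meta == "SL-QL"
    if (any(qlr)) {    # gamma = 0 Bellman update on the visited cell
      i3 <- cbind(which(qlr), (state_idx - 1L) * 3L + sel[qlr])
      qtab[i3] <- qtab[i3] + 0.01 * (rewards[qlr] - qtab[i3])
    }

    psi[t] <- mean(rewards)
    il_steps[t] <- sum(exec == 1L)
    for (j in seq_len(n_pool)) {
      in_j <- meta == pool[j]
      ratio[t, j] <- mean(in_j)
      age_log[t, j] <- if (any(in_j)) mean(ages[in_j]) else NA_real_
    }

    parents <- roulette_select(rewards, m, cfg$s)
    mut <- mutate_types(meta[parents], cfg$mr, pool)
    ages <- update_ages(ages, parents, mut$mutated)
    meta <- mut$types
    Q <- Q[parents, , drop = FALSE]
    vq <- vq[parents, , drop = FALSE]
    vn <- vn[parents, , drop = FALSE]
    qtab <- qtab[parents, , drop = FALSE]
    if (any(mut$mutated)) {  # mutated agents start with a fresh controller
      vq[mut$mutated, ] <- 0
      vn[mut$mutated, ] <- 0L
      qtab[mut$mutated, ] <- matrix(ql0_row, sum(mut$mutated), 24,
                                    byrow = TRUE)
    }
  }

  structure(list(
    log = data.frame(generation = seq_len(T_run), psi = psi,
                     il_steps = il_steps, ratio, check.names = FALSE),
    ages = data.frame(generation = seq_len(T_run), age_log,
                      check.names = FALSE),
    strategies = meta, cfg = cfg, pool = pool, seed = seed),
    class = "meta_run")
}

#' @export
print.meta_run <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf("<meta_run> %d generations, m=%d, %d strategies\n",
              n, x$cfg$m, length(x$pool)))
  fin <- sort(unlist(x$log[n, x$pool]), decreasing = TRUE)
  cat("  final ratios:", paste(sprintf("%s=%.2f", names(fin), fin),
                               collapse = " "), "\n")
  invisible(x)
}

#' Run the meta-strategy evolutionary competition
#'
#' Repeats [evolve_meta()] over independent seeded runs with a uniform
#' random initial strategy assignment, as in the competition experiments.
#'
#' @inheritParams evolve_meta
#' @param runs Number of independent runs.
#' @param seed Base seed; run `i` uses `seed + i - 1`.
#' @return A list of class `meta_competition` with `runs` (list of
#'   [evolve_meta()] results), `final_ratios` (runs x strategies matrix)
#'   and `pool`.
#' @export
run_meta_competition <- function(env, cfg = evo_config(),
                                 pool = meta_strategy_pool(), runs = 16,
                                 trained = list(),
                                 ctx_params = context_params(), seed = 1) {
  stopifnot(runs >= 1)
  res <- lapply(seq_len(runs), function(i)
    evolve_meta(env, cfg, pool, trained = trained, ctx_params = ctx_params,
                seed = seed + i - 1L))
  fr <- matrix(unlist(lapply(res, function(r)
    unlist(r$log[nrow(r$log), r$pool]))),
    nrow = length(res), ncol = length(pool), byrow = TRUE,
    dimnames = list(NULL, pool))
  structure(list(runs = res, final_ratios = fr, pool = pool),
            class = "meta_competition")
}

#' @export
print.meta_competition <- function(x, ...) {
  cat(sprintf("<meta_competition> %d runs, %d strategies\n",
              nrow(x$final_ratios), length(x$pool)))
  mu <- sort(colMeans(x$final_ratios), decreasing = TRUE)
  cat("  mean final ratios:\n")
  for (nm in names(mu)) cat(sprintf("    %-16s %.3f\n", nm, mu[[nm]]))
  invisible(x)
}
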