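# Experiment runners and the statistical machinery used to compare
# strategies (Wilcoxon rank-sum, Friedman average ranks, Nemenyi critical
# difference), plus the exploration-cost metric.

#' Exploration cost of a run
#'
#' Exploration enters only through individual learning, so the cost of a
#' run is the number of agent-steps executed as individual learning,
#' multiplied by the exploration rate epsilon.
#'
#' @param log An [evolve_population()] / [evolve_meta()] result, or a data
#'   frame with an `il_steps` column.
#' @param epsilon Exploration rate; defaults to the run's configured value.
#' @return Numeric cost (dimensionless).
#' @examples
#' # an all-IL population of 100 agents over 400 generations at eps = 0.1
#' # has cost 0.1 * 100 * 400 = 4000
#' @export
exploration_cost <- function(log, epsilon = NULL) {
  if (inherits(log, c("evo_run", "meta_run"))) {
    if (is.null(epsilon)) epsilon <- log$cfg$epsilon
    log <- log$log
  }
  if (is.null(epsilon)) stop("epsilon must be supplied for a bare log")
  stopifnot("il_steps" %in% names(log))
  epsilon * sum(log$il_steps)
}

#' Mean average-population-reward over an analysis window
#'
#' @param run An [evolve_population()] / [evolve_meta()] result.
#' @param window Length-2 inclusive generation range, e.g. `c(350, 400)`.
#' @return Mean of `psi(t)` over the window.
#' @export
window_mean <- function(run, window) {
  log <- if (inherits(run, c("evo_run", "meta_run"))) run$log else run
  stopifnot(length(window) == 2, window[1] >= 1,
            window[2] <= max(log$generation))
  sel <- log$generation >= window[1] & log$generation <= window[2]
  mean(log$psi[sel])
}

#' Pairwise Wilcoxon rank-sum comparison of strategies
#'
#' Takes per-run summary values (e.g. window means of the average
#' population reward) for two or more strategies and runs two-sided
#' Wilcoxon rank-sum tests between every pair (normal approximation with
#' tie correction for n >= 20, exact enumeration below, as implemented by
#' [stats::wilcox.test()]).
#'
#' @param values Named list of numeric vectors, one per strategy, each
#'   with one value per run (>= 2 runs each).
#' @return A list with `summary` (data frame of per-strategy mean/sd/n)
#'   and `p` (symmetric matrix of p-values).
#' @export
compare_strategies <- function(values) {
  stopifnot(is.list(values), length(values) >= 2,
            !is.null(names(values)))
  if (any(vapply(values, length, integer(1)) < 2))
    stop("statistics unavailable: each strategy needs at least 2 runs")
  nm <- names(values)
  p <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  diag(p) <- 1
  for (i in seq_along(nm)) for (j in seq_along(nm)) if (i < j) {
    pv <- suppressWarnings(
      stats::wilcox.test(values[[i]], values[[j]],
                         exact = length(values[[i]]) < 20 &&
                           length(values[[j]]) < 20)$p.value)
    p[i, j] <- p[j, i] <- pv
  }
  summary <- data.frame(
    strategy = nm,
    mean = vapply(values, mean, numeric(1)),
    sd = vapply(values, stats::sd, numeric(1)),
    n = vapply(values, length, integer(1)), row.names = NULL)
  list(summary = summary, p = p)
}

#' Friedman average ranks with the Nemenyi critical difference
#'
#' Ranks the strategies within each run (rank 1 = best, i.e. highest
#' performance; midranks on ties), averages the ranks across runs and
#' computes the Nemenyi critical difference
#' `CD = q_alpha * sqrt(k * (k + 1) / (6 * N))`, where `q_alpha` is the
#' studentized-range quantile divided by sqrt(2). Two strategies are
#' linked (not significantly different) when their average ranks differ
#' by less than the CD.
#'
#' @param performance Numeric runs x strategies matrix (higher is
#'   better); no missing cells.
#' @param alpha Significance level (default 0.05).
#' @return A list of class `rank_cd`: `avg_rank` (named vector), `cd`
#'   (critical difference), `linked` (logical strategy x strategy
#'   matrix), `friedman_p` (Friedman test p-value), `alpha`.
#' @export
rank_and_cd <- function(performance, alpha = 0.05) {
  performance <- as.matrix(performance)
  k <- ncol(performance); n <- nrow(performance)
  if (k < 2) stop("need at least 2 strategies to rank")
  if (anyNA(performance)) stop("performance matrix has missing cells")
  if (is.null(colnames(performance)))
    colnames(performance) <- paste0("S", seq_len(k))
  ranks <- t(apply(performance, 1, function(r) rank(-r)))
  avg <- colMeans(ranks)
  q_alpha <- stats::qtukey(1 - alpha, k, df = Inf) / sqrt(2)
  cd <- q_alpha * sqrt(k * (k + 1) / (6 * n))
  diff <- abs(outer(avg, avg, "-"))
  linked <- diff < cd
  fr_p <- if (n >= 2) stats::friedman.test(performance)$p.value else NA_real_
  structure(list(avg_rank = avg, cd = cd, linked = linked,
                 friedman_p = fr_p, alpha = alpha, n = n, k = k),
            class = "rank_cd")
}

#' @export
print.rank_cd <- function(x, ...) {
  cat(sprintf("<rank_cd> %d strategies over %d runs; CD=%.3f at alpha=%g\n",
              x$k, x$n, x$cd, x$alpha))
  ord <- order(x$avg_rank)
  for (i in ord)
    cat(sprintf("  %5.2f  %s\n", x$avg_rank[i], names(x$avg_rank)[i]))
  invisible(x)
}

# shared runner: per-composition seeded two-type runs on one environment
.composition_runs <- function(env, cfg, compositions, runs, seed) {
  out <- lapply(compositions, function(sls)
    lapply(seq_len(runs), function(i)
      evolve_population(env, cfg, sls = sls, seed = seed + i - 1L)))
  names(out) <- compositions
  out
}

#' Strategy-composition comparison on reversal environments
#'
#' Runs the three population compositions (individual learners only,
#' success-based + IL, conformist + IL) on low- and high-uncertainty
#' reversal environments, summarises the post-change window and the
#' end-of-process window, and computes pairwise Wilcoxon rank-sum tests
#' and Friedman/Nemenyi ranks.
#'
#' @param m,horizon Population size and number of generations.
#' @param runs Independent seeded runs per composition.
#' @param seed Base RNG seed.
#' @param windows Named list of analysis windows (defaults: after-change
#'   `[200, 250]` and end `[350, 400]`, scaled proportionally when
#'   `horizon != 400`).
#' @param cfg An [evo_config()]; `m` and `horizon` override its size
#'   fields.
#' @return A list of class `fig2_result`: per environment, per window:
#'   per-run window means, [compare_strategies()] output and
#'   [rank_and_cd()] ranks; plus mean psi trajectories.
#' @export
run_fig2 <- function(m = 100, horizon = 400, runs = 30, seed = 1,
                     windows = NULL, cfg = evo_config()) {
  cfg$m <- as.integer(m); cfg$generations <- as.integer(horizon)
  if (is.null(windows)) {
    sc <- horizon / 400
    windows <- list(after_change = round(c(200, 250) * sc),
                    end = round(c(350, 400) * sc))
  }
  compositions <- c("none", "success", "conformist")
  out <- list()
  for (unc in c("low", "high")) {
    env <- make_environment("reversal", horizon = horizon, uncertainty = unc)
    sims <- .composition_runs(env, cfg, compositions, runs, seed)
    traj <- sapply(sims, function(rs)
      rowMeans(sapply(rs, function(r) r$log$psi)))
    res_w <- list()
    for (wn in names(windows)) {
      vals <- lapply(sims, function(rs)
        vapply(rs, window_mean, numeric(1), window = windows[[wn]]))
      perf <- do.call(cbind, vals)
      res_w[[wn]] <- list(values = vals,
                          tests = compare_strategies(vals),
                          ranks = rank_and_cd(perf))
    }
    out[[unc]] <- list(windows = res_w, mean_psi = traj)
  }
  structure(c(out, list(window_defs = windows, runs = runs, m = m,
                        horizon = horizon)),
            class = "fig2_result")
}

#' ODPU versus performance-difference correlation
#'
#' Sweeps a grid of (sigma1, sigma2) reward noise levels at fixed arm
#' means; for each cell runs paired seeded two-type simulations of the
#' conformist + IL and success-based + IL compositions on the reversal
#' task, records the end-window difference in average population reward
#' (conformist minus success; per-cell values aggregate across seeds by
#' the median, which is robust to rare finite-population lock-in runs)
#' and the cell's ODPU computed from the true specs with configured group
#' sizes, and reports the Pearson correlation across cells.
#'
#' @param sigma_grid Noise levels for each arm's sweep (the grid is the
#'   Cartesian product).
#' @param mu Fixed arm means.
#' @param counts Group sizes (optimal, sub-optimal) fed to the ODPU.
#'   `NULL` (default) measures them per cell from the success-composition
#'   runs as the mean end-window per-arm chooser counts, so the ODPU is
#'   evaluated at the same occupancy whose performance it predicts (the
#'   resulting value is the per-generation probability that the best
#'   observed reward comes from the sub-optimal arm). A fixed pair such
#'   as `c(5, 95)` (the post-change occupancy) can be supplied instead.
#' @param m,horizon,runs,seed,cfg As in [run_fig2()].
#' @param window End-of-process window (default scaled `[350, 400]`).
#' @return A list of class `fig3_result`: `grid` (data frame with
#'   sigma1, sigma2, odpu, dpsi), `r` (Pearson correlation).
#' @export
run_fig3 <- function(sigma_grid = c(0.1, 0.2, 0.3, 0.4), mu = c(1.0, 0.5),
                     counts = NULL, m = 100, horizon = 400, runs = 10,
                     seed = 1, window = NULL, cfg = evo_config()) {
  cfg$m <- as.integer(m); cfg$generations <- as.integer(horizon)
  if (is.null(window)) window <- round(c(350, 400) * horizon / 400)
  cells <- expand.grid(sigma1 = sigma_grid, sigma2 = sigma_grid)
  if (nrow(cells) < 2) stop("correlation undefined on a single-cell grid")
  res <- lapply(seq_len(nrow(cells)), function(i) {
    s1 <- cells$sigma1[i]; s2 <- cells$sigma2[i]
    env <- make_environment("reversal", horizon = horizon, mu = mu,
                            sigma = c(s1, s2))
    gens <- window[1]:window[2]
    opt_arm <- which.max(expected_reward(env, t = window[2]))
    n_opt <- n_sub <- numeric(0)
    wm <- function(sls) vapply(seq_len(runs), function(j) {
      run <- evolve_population(env, cfg, sls = sls,
                               seed = seed + (i - 1L) * runs + j - 1L)
      if (sls == "success") {   # record end-window occupancy per arm
        cnt <- rowMeans(sapply(run$population$info_hist[gens],
                               `[[`, "counts"))
        n_opt <<- c(n_opt, cnt[opt_arm])
        n_sub <<- c(n_sub, sum(cnt[-opt_arm]))
      }
      window_mean(run, window)
    }, numeric(1))
    dpsi <- stats::median(wm("conformist")) - stats::median(wm("success"))
    n_cell <- if (is.null(counts))
      pmax(c(mean(n_opt), mean(n_sub)), 1) else counts
    od <- odpu(mean = mu, sd = c(s1, s2), n = n_cell)
    c(odpu = od, dpsi = dpsi, n_opt = n_cell[1], n_sub = n_cell[2])
  })
  grid <- cbind(cells, do.call(rbind, res))
  r <- if (stats::sd(grid$odpu) > 0 && stats::sd(grid$dpsi) > 0)
    stats::cor(grid$odpu, grid$dpsi) else NA_real_
  structure(list(grid = grid, r = r,
                 counts = counts, runs = runs, window = window),
            class = "fig3_result")
}

#' @export
print.fig3_result <- function(x, ...) {
  cat(sprintf("<fig3_result> %d grid cells, %d runs per composition per cell\n",
              nrow(x$grid), x$runs))
  cat(sprintf("  Pearson r(ODPU, conformist - success) = %.4f\n", x$r))
  invisible(x)
}

#' Performance versus exploration cost of all meta-strategies
#'
#' Runs each meta-strategy as a homogeneous population on each test
#' environment (stable and volatile crossed with low and high
#' uncertainty, a random-volatile environment, and a gradual-change
#' environment), recording mean reward, exploration cost and the
#' Friedman/Nemenyi ranks per environment.
#'
#' @param pool Meta-strategies to evaluate.
#' @param environments Named list of [bandit_env()] objects; defaults to
#'   the six test environments at the configured scale.
#' @param m,horizon,runs,seed,cfg Simulation scale controls.
#' @param trained Trained artifacts for SL-GA / SL-NE / SL-QL (see
#'   [evolve_meta()]).
#' @return A list of class `fig4_result`: per environment a data frame of
#'   per-strategy mean reward and exploration cost, the runs x strategies
#'   reward matrix and its [rank_and_cd()].
#' @export
run_fig4 <- function(pool = meta_strategy_pool(), environments = NULL,
                     m = 100, horizon = 400, runs = 10, seed = 1,
                     trained = list(), cfg = evo_config()) {
  cfg$m <- as.integer(m); cfg$generations <- as.integer(horizon)
  if (is.null(environments))
    environments <- list(
      stable_low = make_environment("stable", horizon = horizon,
                                    uncertainty = "low"),
      stable_high = make_environment("stable", horizon = horizon,
                                     uncertainty = "high"),
      volatile_low = make_environment("volatile", horizon = horizon,
                                      uncertainty = "low"),
      volatile_high = make_environment("volatile", horizon = horizon,
                                       uncertainty = "high"),
      random_volatile = make_environment("random_volatile",
                                         horizon = horizon, seed = seed),
      gradual = make_environment("gradual", horizon = horizon,
                                 uncertainty = "high"))
  out <- list()
  for (en in names(environments)) {
    env <- environments[[en]]
    perf <- matrix(NA_real_, runs, length(pool),
                   dimnames = list(NULL, pool))
    cost <- matrix(NA_real_, runs, length(pool),
                   dimnames = list(NULL, pool))
    for (j in seq_along(pool)) {
      for (i in seq_len(runs)) {
        r <- evolve_meta(env, cfg, pool = pool[j], trained = trained,
                         seed = seed + (i - 1L))
        perf[i, j] <- mean(r$log$psi)
        cost[i, j] <- exploration_cost(r)
      }
    }
    out[[en]] <- list(
      summary = data.frame(strategy = pool, mean_reward = colMeans(perf),
                           mean_cost = colMeans(cost), row.names = NULL),
      performance = perf, cost = cost,
      ranks = if (length(pool) >= 2) rank_and_cd(perf) else NULL)
  }
  structure(list(environments = out, pool = pool, runs = runs),
            class = "fig4_result")
}

#' Meta-strategy evolutionary competition across environments
#'
#' Runs [run_meta_competition()] on each supplied environment, ranks the
#' strategies by their final population ratios and links ratio
#' differences that a Wilcoxon rank-sum test cannot distinguish.
#' Optionally sweeps selection strength and mutation rate.
#'
#' @inheritParams run_fig4
#' @param s_levels Optional named selection-strength values to sweep
#'   (e.g. `c(low = 0.5, moderate = 1, high = 2)`).
#' @param mr_levels Optional mutation rates to sweep.
#' @param alpha Significance level for the rank-sum links.
#' @return A list of class `fig5_result`: per environment the
#'   [run_meta_competition()] result, mean final ratios, and the
#'   rank-sum link matrix; sweep results when requested.
#' @export
run_fig5 <- function(pool = meta_strategy_pool(), environments = NULL,
                     m = 100, horizon = 400, runs = 16, seed = 1,
                     trained = list(), cfg = evo_config(),
                     s_levels = NULL, mr_levels = NULL, alpha = 0.05) {
  cfg$m <- as.integer(m); cfg$generations <- as.integer(horizon)
  if (is.null(environments))
    environments <- list(
      volatile_low = make_environment("volatile", horizon = horizon,
                                      uncertainty = "low"),
      volatile_high = make_environment("volatile", horizon = horizon,
                                       uncertainty = "high"))
  one <- function(env, cfg) {
    comp <- run_meta_competition(env, cfg, pool, runs = runs,
                                 trained = trained, seed = seed)
    vals <- lapply(seq_along(pool), function(j) comp$final_ratios[, j])
    names(vals) <- pool
    tests <- if (runs >= 2 && length(pool) >= 2)
      compare_strategies(vals) else NULL
    list(competition = comp, mean_final = colMeans(comp$final_ratios),
         links = if (!is.null(tests)) tests$p > alpha else NULL)
  }
  out <- lapply(environments, one, cfg = cfg)
  sweeps <- NULL
  if (!is.null(s_levels) || !is.null(mr_levels)) {
    sweeps <- list()
    for (s in if (is.null(s_levels)) cfg$s else s_levels)
      for (mr in if (is.null(mr_levels)) cfg$mr else mr_levels) {
        cfg2 <- cfg; cfg2$s <- s; cfg2$mr <- mr
        sweeps[[sprintf("s=%g_mr=%g", s, mr)]] <-
          lapply(environments, one, cfg = cfg2)
      }
  }
  structure(list(environments = out, sweeps = sweeps, pool = pool,
                 runs = runs),
            class = "fig5_result")
}
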