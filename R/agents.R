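#' Incremental action-value update
#'
#' `Q(a) <- Q(a) + beta * (r - Q(a))`: a constant step-size running
#' estimate of the chosen arm's reward; other arms are unchanged.
#'
#' @param q Numeric vector of per-arm value estimates.
#' @param arm Chosen arm index.
#' @param reward Received reward.
#' @param beta Step size in (0, 1\] (default 0.2).
#' @return Updated value-estimate vector.
#' @examples
#' update_q(c(0.5, 0), arm = 1, reward = 1)  # 0.6 on arm 1
#' @export
update_q <- function(q, arm, reward, beta = 0.2) {
  stopifnot(beta > 0, beta <= 1, arm >= 1, arm <= length(q))
  q[arm] <- q[arm] + beta * (reward - q[arm])
  q
}

#' Epsilon-greedy action selection
#'
#' With probability `1 - epsilon` the arm with the highest value estimate
#' is chosen (ties broken toward the lowest index); with probability
#' `epsilon` a uniformly random arm.
#'
#' @param q Numeric vector of per-arm value estimates.
#' @param epsilon Exploration probability in \[0, 1\] (default 0.1).
#' @return Chosen arm index.
#' @export
egreedy_action <- function(q, epsilon = 0.1) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  if (stats::runif(1) < epsilon) sample.int(length(q), 1)
  else which.max(q)
}

# vectorised epsilon-greedy over the rows of a value matrix
.egreedy_actions <- function(Q, epsilon) {
  greedy <- max.col(Q, ties.method = "first")
  explore <- stats::runif(nrow(Q)) < epsilon
  n_ex <- sum(explore)
  if (n_ex > 0)
    greedy[explore] <- sample.int(ncol(Q), n_ex, replace = TRUE)
  greedy
}

#' Cross-sectional social information for one step
#'
#' Summarises one generation's public record: action frequencies, per-arm
#' chooser counts, per-arm running reward estimates (cross-sectional mean
#' and sd of the rewards observed this step; sd is 0 for arms with fewer
#' than two choosers), and the single best individual reward with its arm
#' (reward ties broken toward the lowest arm index).
#'
#' @param actions Integer vector of chosen arms (one per individual).
#' @param rewards Numeric vector of received rewards.
#' @param k Number of arms.
#' @return A list with elements `h` (frequencies summing to 1), `counts`,
#'   `mu` (per-arm mean, `NA` where unsampled), `sd`, `best_arm`,
#'   `best_reward`, and `n` (population size).
#' @export
social_info <- function(actions, rewards, k) {
  stopifnot(length(actions) == length(rewards), length(actions) >= 1)
  counts <- tabulate(actions, nbins = k)
  h <- counts / length(actions)
  mu <- rep(NA_real_, k)
  sdv <- rep(0, k)
  sums <- vapply(seq_len(k), function(j) sum(rewards[actions == j]),
                 numeric(1))
  mu[counts > 0] <- sums[counts > 0] / counts[counts > 0]
  multi <- which(counts >= 2)
  for (j in multi) sdv[j] <- stats::sd(rewards[actions == j])
  best_reward <- max(rewards)
  # lowest arm index among the tied best rewards
  best_arm <- min(actions[rewards == best_reward])
  list(h = h, counts = counts, mu = mu, sd = sdv,
       best_arm = best_arm, best_reward = best_reward,
       n = length(actions))
}

.get_lagged <- function(info_hist, t, tau) {
  if (t - tau <= 0)
    stop("social learning requires t - tau > 0 (no records yet); ",
         "fall back to individual learning", call. = FALSE)
  info <- info_hist[[t - tau]]
  if (is.null(info)) stop("no social information recorded at step t - tau")
  info
}

#' Success-based social learning action
#'
#' Copies the arm chosen by the individual with the single best recorded
#' reward at step `t - tau` (reward ties toward the lowest arm index).
#'
#' @param info_hist List of [social_info()] records indexed by step.
#' @param t Current step; requires `t - tau > 0`.
#' @param tau Observation latency in steps (default 1).
#' @return Arm index.
#' @export
success_based_action <- function(info_hist, t, tau = 1) {
  .get_lagged(info_hist, t, tau)$best_arm
}

#' Conformist social learning action
#'
#' Copies the most frequent action in the population at step `t - tau`
#' (frequency ties toward the lowest arm index).
#'
#' @inheritParams success_based_action
#' @return Arm index.
#' @export
conformist_action <- function(info_hist, t, tau = 1) {
  which.max(.get_lagged(info_hist, t, tau)$h)
}

#' Perfect- and random-copy baseline actions
#'
#' `perfect` copies the arm with the highest true expected reward at `t`
#' (an omniscient model); `random` copies the arm of a uniformly sampled
#' individual at `t - tau`.
#'
#' @param mode `"perfect"` or `"random"`.
#' @param info_hist List of [social_info()] records (random mode).
#' @param env A [bandit_env()] (perfect mode).
#' @param t Current step.
#' @param tau Observation latency (random mode).
#' @return Arm index.
#' @export
copy_variant_action <- function(mode = c("perfect", "random"),
                                info_hist = NULL, env = NULL, t, tau = 1) {
  mode <- match.arg(mode)
  if (mode == "perfect") {
    stopifnot(inherits(env, "bandit_env"))
    return(which.max(expected_reward(env, t = t)))
  }
  info <- .get_lagged(info_hist, t, tau)
  sample.int(length(info$h), 1, prob = info$h)
}
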