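#' Reward distribution of a single bandit arm
#'
#' An arm pays out either Gaussian rewards `N(mean, sd)` or Bernoulli
#' rewards (1 with probability `mean`, 0 otherwise).
#'
#' @param kind `"gaussian"` or `"bernoulli"`.
#' @param mean Mean reward; for Bernoulli arms the success probability,
#'   which must lie in \[0, 1\].
#' @param sd Standard deviation (Gaussian arms only); must be >= 0.
#' @return An object of class `arm_spec`.
#' @examples
#' arm_spec("gaussian", mean = 1.0, sd = 0.4)
#' arm_spec("bernoulli", mean = 0.7)
#' @export
arm_spec <- function(kind = c("gaussian", "bernoulli"), mean, sd = 0) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean))
  if (kind == "bernoulli") {
    if (mean < 0 || mean > 1)
      stop("bernoulli arm mean (success probability) must be in [0, 1]")
    sd <- sqrt(mean * (1 - mean))
  } else {
    stopifnot(is.numeric(sd), length(sd) == 1L, sd >= 0)
  }
  structure(list(kind = kind, mean = mean, sd = sd), class = "arm_spec")
}

#' Non-stationary bandit environment schedule
#'
#' A schedule partitions the horizon `1..T` into contiguous periods; each
#' period assigns one [arm_spec()] per arm. Reward distributions change at
#' period boundaries, either abruptly or by linear interpolation of
#' (mean, sd) over a transition window starting at the change step.
#'
#' @param k Number of arms.
#' @param horizon Number of steps `T`.
#' @param periods List of periods; each a list with `start` (step, the first
#'   period must start at 1) and `arms` (list of `k` [arm_spec()] objects).
#' @param transition `"abrupt"` or `"gradual"`.
#' @param window Transition window length in steps (gradual only).
#' @return An object of class `bandit_env`.
#' @export
bandit_env <- function(k, horizon, periods, transition = c("abrupt", "gradual"),
                       window = NULL) {
  transition <- match.arg(transition)
  stopifnot(k >= 1, horizon >= 1, length(periods) >= 1)
  periods <- lapply(periods, function(p) {
    p$start <- as.integer(p$start)
    p
  })
  starts <- vapply(periods, `[[`, integer(1), "start")
  if (starts[1] != 1L)
    stop("first period must start at step 1")
  if (is.unsorted(starts, strictly = TRUE))
    stop("period starts must be strictly increasing")
  if (any(starts > horizon))
    stop("period start beyond horizon")
  for (p in periods) {
    if (length(p$arms) != k)
      stop("each period must supply exactly k arm specs")
    ok <- vapply(p$arms, inherits, logical(1), what = "arm_spec")
    if (!all(ok)) stop("period arms must be arm_spec objects")
  }
  if (transition == "gradual") {
    if (is.null(window)) window <- floor(horizon / 2)
    stopifnot(window >= 1)
  }
  env <- structure(
    list(k = k, horizon = as.integer(horizon), periods = periods,
         transition = transition, window = window),
    class = "bandit_env")
  # precomputed per-step (mean, sd) matrices make the simulation loops cheap
  env$mu <- .env_param_matrix(env, "mean")
  env$sd <- .env_param_matrix(env, "sd")
  env$kind <- periods[[1]]$arms[[1]]$kind
  env
}

# step x arm matrix of the named parameter, with gradual interpolation applied
.env_param_matrix <- function(env, what) {
  starts <- vapply(env$periods, function(p) as.integer(p$start), integer(1))
  out <- matrix(NA_real_, nrow = env$horizon, ncol = env$k)
  n_per <- length(env$periods)
  for (i in seq_len(n_per)) {
    from <- starts[i]
    to <- if (i < n_per) starts[i + 1] - 1L else env$horizon
    vals <- vapply(env$periods[[i]]$arms, function(a) a[[what]], numeric(1))
    out[from:to, ] <- matrix(vals, nrow = to - from + 1L, ncol = env$k,
                             byrow = TRUE)
    if (env$transition == "gradual" && i > 1L) {
      w <- env$window
      prev <- vapply(env$periods[[i - 1]]$arms, function(a) a[[what]],
                     numeric(1))
      ramp_to <- min(to, from + w - 1L)
      steps <- from:ramp_to
      frac <- (steps - from) / w
      out[steps, ] <- outer(1 - frac, prev) + outer(frac, vals)
    }
  }
  out
}

#' @export
print.bandit_env <- function(x, ...) {
  cat(sprintf("<bandit_env> %d arms, horizon %d, %d period(s), %s changes\n",
              x$k, x$horizon, length(x$periods), x$transition))
  cat(sprintf("  reward kind: %s\n", x$kind))
  for (i in seq_along(x$periods)) {
    a <- x$periods[[i]]$arms
    cat(sprintf("  period %d (from t=%d): %s\n", i, x$periods[[i]]$start,
                paste(vapply(a, function(s)
                  sprintf("(%.3g, %.3g)", s$mean, s$sd), character(1)),
                  collapse = " ")))
  }
  invisible(x)
}

.check_arm_t <- function(env, arm, t) {
  if (any(t < 1) || any(t > env$horizon))
    stop("step t out of range [1, horizon]")
  if (any(arm < 1) || any(arm > env$k))
    stop("arm index out of range [1, k]")
}

#' Expected reward of an arm at a step
#'
#' Returns the mean of the distribution active at step `t` (linearly
#' interpolated inside a gradual transition window).
#'
#' @param env A [bandit_env()].
#' @param arm Arm index in `1..k`, or `NULL` for all arms.
#' @param t Step in `1..horizon`.
#' @return Numeric mean reward(s).
#' @export
expected_reward <- function(env, arm = NULL, t) {
  stopifnot(inherits(env, "bandit_env"), length(t) == 1L)
  if (is.null(arm)) return(env$mu[t, ])
  .check_arm_t(env, arm, t)
  env$mu[t, arm]
}

#' Active standard deviation of an arm at a step
#'
#' @inheritParams expected_reward
#' @return Numeric standard deviation(s).
#' @export
reward_sd <- function(env, arm = NULL, t) {
  stopifnot(inherits(env, "bandit_env"), length(t) == 1L)
  if (is.null(arm)) return(env$sd[t, ])
  .check_arm_t(env, arm, t)
  env$sd[t, arm]
}

#' Sample rewards from the environment
#'
#' Draws one reward per element of `arm` from the distributions active at
#' step `t`, using the current RNG state.
#'
#' @param env A [bandit_env()].
#' @param arm Vector of arm indices in `1..k` (one draw each).
#' @param t Step in `1..horizon`.
#' @return Numeric vector of rewards, one per element of `arm`.
#' @examples
#' env <- make_environment("reversal", horizon = 10)
#' set.seed(1)
#' sample_reward(env, arm = c(1, 2), t = 1)
#' @export
sample_reward <- function(env, arm, t) {
  stopifnot(inherits(env, "bandit_env"), length(t) == 1L)
  .check_arm_t(env, arm, t)
  mu <- env$mu[t, arm]
  if (env$kind == "bernoulli") {
    as.numeric(stats::runif(length(arm)) < mu)
  } else {
    sd <- env$sd[t, arm]
    stats::rnorm(length(arm), mean = mu, sd = sd)
  }
}

#' Construct one of the canonical environment schedules
#'
#' Builders for the study's environment families on `k = 2` arms:
#' \describe{
#'   \item{reversal}{two equal periods; the arm specs are swapped at the
#'     midpoint of the horizon (one change).}
#'   \item{stable}{3 periods (2 changes) alternating the arm assignment.}
#'   \item{volatile}{6 periods (5 changes) alternating the arm assignment.}
#'   \item{random_volatile}{change count drawn uniformly from
#'     `change_pool` and per-period specs drawn from `sigma_pool`, using
#'     `seed`.}
#'   \item{gradual}{a reversal with a linear transition window.}
#'   \item{binary}{Bernoulli arms with success probabilities `mu`, reversed
#'     at the midpoint.}
#' }
#' The default Gaussian specs put means at 1.0 and 0.5; `uncertainty`
#' selects the standard deviations. `"low"` gives sd 0.05 on both arms
#' (nearly disjoint distributions). `"high"` gives sd 0.1 on the optimal
#' arm and 0.4 on the sub-optimal arm: uncertainty here means a high
#' probability that the best *observed* reward comes from the sub-optimal
#' distribution (high ODPU, see [odpu()]), which requires the optimum to
#' be concentrated while the sub-optimal tail overlaps it. (Inflating
#' both sds equally does not raise the ODPU, because the optimum group's
#' maximum grows with its own sd.) The sd assignment follows the means
#' through reversals, so the optimal arm keeps its sd.
#'
#' @param name Environment family (see Details).
#' @param k Number of arms (2 for the canonical tasks).
#' @param horizon Steps `T` (default 400).
#' @param mu Length-`k` base means (Bernoulli: success probabilities).
#' @param sigma Length-`k` base standard deviations, or `NULL` to use
#'   `uncertainty`.
#' @param uncertainty `"low"` (sd 0.05) or `"high"` (sd 0.4).
#' @param window Gradual transition window (default `horizon / 2`).
#' @param n_changes Override for the number of changes (stable/volatile).
#' @param change_pool Candidate change counts for `random_volatile`.
#' @param sigma_pool Candidate sd values for `random_volatile` periods.
#' @param seed RNG seed for `random_volatile`.
#' @return A [bandit_env()].
#' @examples
#' make_environment("reversal", uncertainty = "high")
#' make_environment("volatile", uncertainty = "low")
#' @export
make_environment <- function(name = c("reversal", "stable", "volatile",
                                      "random_volatile", "gradual", "binary"),
                             k = 2, horizon = 400, mu = c(1.0, 0.5),
                             sigma = NULL,
                             uncertainty = c("low", "high"),
                             window = NULL,
                             n_changes = NULL,
                             change_pool = 3:8,
                             sigma_pool = c(0.05, 0.1, 0.2, 0.3, 0.4),
                             seed = NULL) {
  name <- match.arg(name)
  uncertainty <- match.arg(uncertainty)
  stopifnot(length(mu) == k)
  if (is.null(sigma)) {
    sigma <- if (uncertainty == "low") rep(0.05, k) else {
      # high ODPU: concentrated optimum, heavy-tailed sub-optimal arms
      s <- rep(0.4, k)
      s[which.max(mu)] <- 0.1
      s
    }
  }
  stopifnot(length(sigma) == k)

  gauss_period <- function(start, mu, sigma)
    list(start = start,
         arms = Map(function(m, s) arm_spec("gaussian", m, s), mu, sigma))
  # alternate by rotating the mean/sd assignment one arm to the right
  rotate <- function(x, j) x[((seq_along(x) - 1 + j) %% length(x)) + 1]

  if (name == "binary") {
    mid <- floor(horizon / 2) + 1L
    periods <- list(
      list(start = 1L, arms = lapply(mu, function(m) arm_spec("bernoulli", m))),
      list(start = mid,
           arms = lapply(rev(mu), function(m) arm_spec("bernoulli", m))))
    return(bandit_env(k, horizon, periods))
  }

  if (name %in% c("reversal", "gradual")) {
    mid <- floor(horizon / 2) + 1L
    periods <- list(gauss_period(1L, mu, sigma),
                    gauss_period(mid, rotate(mu, 1), rotate(sigma, 1)))
    return(bandit_env(k, horizon, periods,
                      transition = if (name == "gradual") "gradual" else "abrupt",
                      window = window))
  }

  if (name %in% c("stable", "volatile")) {
    nc <- if (!is.null(n_changes)) n_changes else if (name == "stable") 2L else 5L
    if (nc + 1L > horizon) stop("more changes than steps in the horizon")
    starts <- 1L + floor(horizon * (0:nc) / (nc + 1L))
    periods <- lapply(seq_along(starts), function(i)
      gauss_period(starts[i], rotate(mu, i - 1L), rotate(sigma, i - 1L)))
    return(bandit_env(k, horizon, periods))
  }

  # random_volatile: draw the change count, change points and per-period sds
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  nc <- if (!is.null(n_changes)) n_changes else sample(change_pool, 1)
  if (nc + 1L > horizon) stop("more changes than steps in the horizon")
  cuts <- sort(sample(2:horizon, nc))
  starts <- c(1L, cuts)
  periods <- lapply(seq_along(starts), function(i) {
    s <- sample(sigma_pool, k, replace = TRUE)
    gauss_period(starts[i], rotate(mu, i - 1L), s)
  })
  bandit_env(k, horizon, periods)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write / read an environment schedule as JSON (or YAML)
#'
#' The document has keys `k`, `T`, `periods` (each with `start` and `arms`,
#' each arm with `kind`, `mean`, `sd`) and `transition` (`mode`, `window`).
#' Files ending in `.yaml`/`.yml` use YAML (requires the `yaml` package);
#' anything else is JSON.
#'
#' @param env A [bandit_env()].
#' @param path File path.
#' @return `write_environment` returns `path` invisibly; `read_environment`
#'   returns a [bandit_env()].
#' @export
write_environment <- function(env, path) {
  stopifnot(inherits(env, "bandit_env"))
  doc <- list(
    k = env$k, T = env$horizon,
    periods = lapply(env$periods, function(p) list(
      start = p$start,
      arms = lapply(p$arms, function(a)
        list(kind = a$kind, mean = a$mean, sd = a$sd)))),
    transition = list(mode = env$transition,
                      window = if (is.null(env$window)) NA else env$window))
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML output")
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_environment
#' @export
read_environment <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML input")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path)
  }
  periods <- lapply(doc$periods, function(p) list(
    start = as.integer(p$start),
    arms = lapply(p$arms, function(a)
      arm_spec(a$kind, a$mean, if (is.null(a$sd)) 0 else a$sd))))
  w <- doc$transition$window
  if (is.null(w) || (length(w) == 1L && is.na(w))) w <- NULL
  bandit_env(doc$k, doc$T, periods, transition = doc$transition$mode,
             window = w)
}
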