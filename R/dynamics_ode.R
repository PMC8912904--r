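#' Default replicator-mutator mutation matrix
#'
#' Row-stochastic 3 x 3 matrix over the types (A1, A2, SL): individual
#' learners of either action mutate into social learners at rate `mr`
#' and vice versa (split evenly over the two IL actions).
#'
#' @param mr Mutation rate (default 0.005).
#' @return A 3 x 3 row-stochastic matrix.
#' @export
default_mutation_matrix <- function(mr = 0.005) {
  stopifnot(mr >= 0, mr <= 1)
  matrix(c(1 - mr, 0,      mr,
           0,      1 - mr, mr,
           mr / 2, mr / 2, 1 - mr),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("A1", "A2", "SL"), c("A1", "A2", "SL")))
}

#' Configuration of the replicator-mutator model
#'
#' Mean-field dynamics of two individual-learner action types (A1, A2)
#' and one social-learner type (SL) on a 2-armed task. Payoffs enter as
#' functions of time; by default they are taken from a [bandit_env()]'s
#' expected rewards (the model is mean-field, so distribution means stand
#' in for sampled rewards).
#'
#' @param epsilon Individual learners' exploration rate: their fitness is
#'   the epsilon-weighted mixture of the two actions' payoffs (this also
#'   carries the implicit exploration cost).
#' @param tau Observation delay of the social learners in time units
#'   (default one integration step).
#' @param sls Social learning closure: `"success"` (copy the optimum
#'   action; fitness is the optimal payoff) or `"conformist"` (copy the
#'   delayed majority action).
#' @param dt Euler step size in time units (default 0.01).
#' @param horizon Integration end time.
#' @return A list of class `ode_config`.
#' @export
ode_config <- function(epsilon = 0.1, tau = NULL,
                       sls = c("success", "conformist"),
                       dt = 0.01, horizon = 40) {
  sls <- match.arg(sls)
  stopifnot(dt > 0, horizon > 0, epsilon >= 0, epsilon <= 1)
  if (is.null(tau)) tau <- dt
  stopifnot(tau >= 0)
  structure(list(epsilon = epsilon, tau = tau, sls = sls, dt = dt,
                 horizon = horizon),
            class = "ode_config")
}

#' Fitness closure of the replicator-mutator model
#'
#' Individual-learner types earn the epsilon-weighted mixture of the two
#' payoffs, `f_Ai = (1 - eps) r(a_i) + eps r(a_j)`. Success-based social
#' learners earn the optimal payoff `r(a*)`. Conformist social learners
#' concentrate on the majority action of the delayed frequency vector
#' `h_lag` and earn its payoff; before any history exists
#' (`h_lag = NULL`) their fitness is 0.
#'
#' @param r Length-2 payoff vector at the current time.
#' @param cfg An [ode_config()].
#' @param h_lag Delayed action-frequency vector (conformist), or `NULL`.
#' @return A list with `f` (fitness vector over A1, A2, SL) and `h_sl`
#'   (the social learners' action distribution, zeros when inactive).
#' @export
fitness_vector <- function(r, cfg, h_lag = NULL) {
  stopifnot(length(r) == 2, inherits(cfg, "ode_config"))
  eps <- cfg$epsilon
  f_a <- c((1 - eps) * r[1] + eps * r[2],
           (1 - eps) * r[2] + eps * r[1])
  h_sl <- c(0, 0)
  if (cfg$sls == "success") {
    star <- which.max(r)
    h_sl[star] <- 1
    f_sl <- r[star]
  } else {
    if (is.null(h_lag)) {
      f_sl <- 0
    } else {
      maj <- which.max(h_lag)
      h_sl[maj] <- 1
      f_sl <- r[maj]
    }
  }
  list(f = c(f_a, f_sl), h_sl = h_sl)
}

#' Replicator-mutator time derivative
#'
#' For state `x` on the 3-simplex, fitness row vector `F` and
#' row-stochastic mutation matrix `M`:
#' `dx_k/dt = F . (x * M[, k]) - x_k * psi` with the average fitness
#' `psi = F . x`. Because `M` is row-stochastic the components of the
#' derivative sum to zero, so the simplex is conserved.
#'
#' @param state Length-3 frequency vector (A1, A2, SL) on the simplex.
#' @param fitness Length-3 fitness vector.
#' @param M 3 x 3 row-stochastic mutation matrix.
#' @param tol Simplex tolerance for the input state.
#' @return Length-3 derivative (components sum to 0).
#' @export
replicator_derivative <- function(state, fitness, M = default_mutation_matrix(),
                                  tol = 1e-6) {
  stopifnot(length(state) == 3, length(fitness) == 3, all(dim(M) == c(3, 3)))
  if (abs(sum(state) - 1) > tol || any(state < -tol))
    stop("state is off the simplex beyond tolerance")
  psi <- sum(fitness * state)
  drop(crossprod(M, fitness * state)) - state * psi
}

#' Integrate the replicator-mutator dynamics
#'
#' Fixed-step explicit Euler integration with a stored history of the
#' population action frequencies `h(a_i, t) = A_i + SL * H_SL(a_i, t)`
#' implementing the conformists' observation delay (delayed values are
#' looked up at the nearest stored step). The state is renormalised
#' whenever numerical drift from the simplex exceeds 1e-9.
#'
#' @param state0 Initial frequencies (A1, A2, SL) on the simplex.
#' @param cfg An [ode_config()].
#' @param payoff Either a [bandit_env()] (payoffs are its expected
#'   rewards; ODE time is mapped to steps 1..horizon) or a function
#'   `function(t)` returning the length-2 payoff vector.
#' @param M 3 x 3 row-stochastic mutation matrix.
#' @return An object of class `replicator_traj`: a data frame with
#'   columns `t`, `a1`, `a2`, `sl`, `h1`, `h2`, `psi`.
#' @examples
#' env <- make_environment("reversal", horizon = 400)
#' cfg <- ode_config(sls = "success", dt = 0.05, horizon = 400)
#' traj <- replicator_integrate(c(0.45, 0.45, 0.1), cfg, env)
#' tail(as.data.frame(traj), 2)
#' @export
replicator_integrate <- function(state0, cfg, payoff,
                                 M = default_mutation_matrix()) {
  stopifnot(inherits(cfg, "ode_config"), length(state0) == 3)
  if (abs(sum(state0) - 1) > 1e-9 || any(state0 < 0))
    stop("initial state must lie on the simplex")
  r_fun <- if (inherits(payoff, "bandit_env")) {
    function(t) expected_reward(payoff, t = max(1L, min(payoff$horizon,
                                                        as.integer(ceiling(t)))))
  } else {
    stopifnot(is.function(payoff))
    payoff
  }
  n_steps <- floor(cfg$horizon / cfg$dt)
  lag_steps <- max(1L, as.integer(round(cfg$tau / cfg$dt)))
  out <- matrix(NA_real_, nrow = n_steps + 1L, ncol = 7,
                dimnames = list(NULL, c("t", "a1", "a2", "sl", "h1", "h2",
                                        "psi")))
  x <- state0
  h_hist <- matrix(NA_real_, nrow = n_steps + 1L, ncol = 2)
  for (i in 0:n_steps) {
    t <- i * cfg$dt
    r <- r_fun(if (t == 0) cfg$dt else t)
    h_lag <- if (i - lag_steps >= 0) h_hist[i - lag_steps + 1L, ] else NULL
    active <- t > cfg$tau   # social learners need observable history
    fv <- fitness_vector(r, cfg, h_lag)
    if (!active && cfg$sls == "success") {
      # no records to copy yet: social learners are inactive
      fv$f[3] <- 0
      fv$h_sl <- c(0, 0)
    }
    h <- x[1:2] + x[3] * fv$h_sl
    if (!active) h <- x[1:2] + x[3] * 0    # h reflects IL actions only
    h_hist[i + 1L, ] <- h
    psi <- sum(fv$f * x)
    out[i + 1L, ] <- c(t, x, h, psi)
    if (i == n_steps) break
    x <- x + cfg$dt * replicator_derivative(x, fv$f, M)
    x[x < 0] <- 0
    if (abs(sum(x) - 1) > 1e-9) x <- x / sum(x)
  }
  structure(as.data.frame(out), class = c("replicator_traj", "data.frame"),
            config = cfg)
}

#' @export
print.replicator_traj <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<replicator_traj> %d steps, dt=%g, sls=%s\n",
              nrow(x) - 1L, cfg$dt, cfg$sls))
  last <- x[nrow(x), ]
  cat(sprintf("  final state: A1=%.4f A2=%.4f SL=%.4f (psi=%.4f)\n",
              last$a1, last$a2, last$sl, last$psi))
  invisible(x)
}

#' @export
plot.replicator_traj <- function(x, ...) {
  graphics::matplot(x$t, cbind(x$a1, x$a2, x$sl), type = "l", lty = 1,
                    col = c("steelblue", "tomato", "darkgreen"),
                    xlab = "time", ylab = "frequency", ...)
  graphics::legend("topright", c("A1", "A2", "SL"), lty = 1,
                   col = c("steelblue", "tomato", "darkgreen"), bty = "n")
  invisible(x)
}
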