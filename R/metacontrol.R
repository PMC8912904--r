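#' The three base learning strategies
#'
#' Every meta-controller maps its inputs to one of `"IL"` (individual
#' learning), `"SUCCESS"` (success-based copying) or `"CONFORMIST"`
#' (conformist copying). Internally strategies are the integer codes
#' 1, 2, 3 in that order.
#'
#' @return Character vector of the three strategy labels.
#' @export
strategies <- function() c("IL", "SUCCESS", "CONFORMIST")

.strategy_code <- function(s) {
  i <- match(s, strategies())
  if (any(is.na(i))) stop("unknown strategy label: ", paste(s[is.na(i)],
                                                            collapse = ", "))
  i
}

#' Joint-state index of the binary context triple
#'
#' States enumerate (EC, C, U) as binary counting with EC the most
#' significant bit: state 1 is (0,0,0), state 2 is (0,0,1), ..., state 8
#' is (1,1,1).
#'
#' @param ec,conf,unc Context bits.
#' @return Integer state index in 1..8.
#' @export
context_state_index <- function(ec, conf, unc) {
  stopifnot(ec %in% 0:1, conf %in% 0:1, unc %in% 0:1)
  4L * as.integer(ec) + 2L * as.integer(conf) + as.integer(unc) + 1L
}

#' Rule-based (observation-based) meta-control
#'
#' All variants start with individual learning (`t == 1`) and switch back
#' to it after a detected environment change (`ec == 1`). Otherwise:
#' \describe{
#'   \item{EC_CONF}{conformist when conformity holds, else IL.}
#'   \item{EC_SUCC}{success-based under low uncertainty, else IL (also
#'     known as the uncertainty-only variant, EC-Unc).}
#'   \item{EC_CONF_UNC}{conformist when conformity holds (any
#'     uncertainty); success-based when non-conformity and low
#'     uncertainty; IL when non-conformity and high uncertainty.}
#' }
#'
#' @param variant One of `"EC_CONF"`, `"EC_SUCC"`, `"EC_CONF_UNC"`.
#' @param ctx A [encode_context()] state (or any list with `ec`, `conf`,
#'   `unc`).
#' @param t Current step (strategy is IL at `t == 1`).
#' @return A strategy label (see [strategies()]).
#' @export
select_observation_based <- function(variant = c("EC_CONF", "EC_SUCC",
                                                 "EC_CONF_UNC"),
                                     ctx, t = 2) {
  variant <- match.arg(variant)
  if (t == 1 || ctx$ec == 1L) return("IL")
  switch(variant,
    EC_CONF = if (ctx$conf == 1L) "CONFORMIST" else "IL",
    EC_SUCC = if (ctx$unc == 0L) "SUCCESS" else "IL",
    EC_CONF_UNC =
      if (ctx$conf == 1L) "CONFORMIST"
      else if (ctx$unc == 0L) "SUCCESS"
      else "IL")
}

# ---------------------------------------------------------------------------
# Discrete table policies (the 10-gene genotype: 8 strategy genes + 2
# thresholds)

#' Discrete meta-control policy over the 8 context states
#'
#' Maps each joint state of (EC, C, U) — see [context_state_index()] —
#' to a strategy, together with the two detection thresholds. The
#' genotype therefore has 10 genes: 8 discrete strategy genes and the 2
#' continuous thresholds.
#'
#' @param table Length-8 character vector of strategy labels, or a
#'   compact 8-character string over `I`, `S`, `C` in state order.
#' @param th_ec Environment-change threshold (default 0.15).
#' @param th_u Uncertainty threshold (default 0.1).
#' @return An object of class `discrete_policy`.
#' @examples
#' discrete_policy("SICCIIII")  # the rule table of the EC-Conf-Unc controller
#' @export
discrete_policy <- function(table, th_ec = 0.15, th_u = 0.1) {
  if (is.character(table) && length(table) == 1L && nchar(table) == 8L) {
    code <- strsplit(table, "")[[1]]
    table <- c(I = "IL", S = "SUCCESS", C = "CONFORMIST")[code]
    if (any(is.na(table))) stop("policy string must use only I, S, C")
    names(table) <- NULL
  }
  stopifnot(length(table) == 8L, all(table %in% strategies()),
            th_ec >= 0, th_u >= 0)
  structure(list(table = table, th_ec = th_ec, th_u = th_u),
            class = "discrete_policy")
}

#' @export
print.discrete_policy <- function(x, ...) {
  cat(sprintf("<discrete_policy> %s  th_ec=%g th_u=%g\n",
              policy_string(x), x$th_ec, x$th_u))
  invisible(x)
}

#' Compact 8-character encoding of a policy table
#'
#' @param policy A [discrete_policy()].
#' @return A string over `I`, `S`, `C` in state order.
#' @export
policy_string <- function(policy) {
  paste(c(IL = "I", SUCCESS = "S", CONFORMIST = "C")[policy$table],
        collapse = "")
}

#' Look up a policy's strategy for a context state
#'
#' @param policy A [discrete_policy()].
#' @param ctx A context state (list with bits `ec`, `conf`, `unc`).
#' @return A strategy label.
#' @export
select_from_policy <- function(policy, ctx) {
  stopifnot(inherits(policy, "discrete_policy"))
  policy$table[context_state_index(ctx$ec, ctx$conf, ctx$unc)]
}

#' Enumerate the discrete policy space
#'
#' All distinct strategy tables over the 8 context states: `3^8 = 6561`
#' policies.
#'
#' @return Character vector of all 8-character policy strings.
#' @export
enumerate_policies <- function() {
  grids <- rep(list(c("I", "S", "C")), 8)
  tab <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  apply(as.matrix(tab), 1, paste, collapse = "")
}

#' The hand-derived EC-Conf-Unc policy as a discrete table
#'
#' Environment change maps every `ec = 1` state to IL; with `ec = 0`,
#' conformity selects conformist copying, and otherwise low uncertainty
#' selects success-based copying, else IL.
#'
#' @param th_ec,th_u Detection thresholds.
#' @return A [discrete_policy()].
#' @export
policy_ec_conf_unc <- function(th_ec = 0.15, th_u = 0.1) {
  discrete_policy("SICCIIII", th_ec = th_ec, th_u = th_u)
}

# ---------------------------------------------------------------------------
# Fully connected feedforward controller (neuroevolution substrate)

#' Small feedforward network meta-controller
#'
#' A one-hidden-layer fully connected network mapping the population
#' observables (per-arm running means, sds and action frequencies) to the
#' three strategies. For `k` arms the input has `3k` units plus a bias
#' unit (constant +1); the hidden layer has `hidden` tanh units plus a
#' bias unit; the output layer is linear and the strategy is the argmax
#' of the three outputs (ties toward the lowest index, i.e. IL). For the
#' default 2-arm, 12-hidden architecture the parameter count is
#' `12 * (6 + 1) + 3 * (12 + 1) = 123`.
#'
#' @param weights Numeric vector of all weights in row-major order
#'   (hidden-layer rows first, then output rows), or `NULL` for zeros.
#' @param k Number of arms (default 2).
#' @param hidden Hidden layer width (default 12).
#' @return An object of class `fcn_controller`.
#' @export
fcn_controller <- function(weights = NULL, k = 2, hidden = 12) {
  k <- as.integer(k); hidden <- as.integer(hidden)
  n_in <- 3L * k
  n_par <- hidden * (n_in + 1L) + 3L * (hidden + 1L)
  if (is.null(weights)) weights <- numeric(n_par)
  if (length(weights) != n_par)
    stop(sprintf("expected %d weights, got %d", n_par, length(weights)))
  w1 <- matrix(weights[seq_len(hidden * (n_in + 1L))], nrow = hidden,
               byrow = TRUE)
  w2 <- matrix(weights[-seq_len(hidden * (n_in + 1L))], nrow = 3L,
               byrow = TRUE)
  structure(list(w1 = w1, w2 = w2, k = k, hidden = hidden, n_par = n_par),
            class = "fcn_controller")
}

#' @export
print.fcn_controller <- function(x, ...) {
  cat(sprintf("<fcn_controller> %d-%d-3 with bias units, %d parameters\n",
              3 * x$k, x$hidden, x$n_par))
  invisible(x)
}

#' Number of parameters of a network controller
#'
#' @param fcn An [fcn_controller()].
#' @return Integer parameter count.
#' @export
fcn_n_params <- function(fcn) fcn$n_par

#' Flatten a network controller to its weight vector
#'
#' Inverse of the `weights` argument of [fcn_controller()].
#'
#' @param fcn An [fcn_controller()].
#' @return Numeric vector (row-major, hidden layer first).
#' @export
fcn_weights <- function(fcn) c(t(fcn$w1), t(fcn$w2))

#' Strategy selection by the network controller
#'
#' Forward pass on inputs `(mu'_1..k, sigma'_1..k, h_1..k)`; undefined
#' inputs (no social records yet) fall back to IL.
#'
#' @param fcn An [fcn_controller()].
#' @param mu,sigma,h Per-arm running means, sds and action frequencies.
#' @return A strategy label.
#' @export
select_from_fcn <- function(fcn, mu, sigma, h) {
  stopifnot(inherits(fcn, "fcn_controller"))
  x <- c(mu, sigma, h)
  if (length(x) != 3 * fcn$k) stop("expected 3k input values")
  if (any(is.na(x))) return("IL")
  hid <- tanh(drop(fcn$w1 %*% c(x, 1)))
  out <- drop(fcn$w2 %*% c(hid, 1))
  strategies()[which.max(out)]
}

# ---------------------------------------------------------------------------
# Value-based controllers (strategy-level bandit / Q-learning)

#' State of a value-based strategy controller
#'
#' `RL` and `UCB` keep per-strategy value estimates `Q` and pull counts
#' `N` over the three strategies; `QL` keeps an 8 x 3 Q-table over
#' context states.
#'
#' @param variant `"RL"`, `"UCB"` or `"QL"`.
#' @param epsilon Exploration rate (RL; default 0.1).
#' @param beta Value-update step size (RL/UCB; default 0.2).
#' @param c Exploration constant (UCB; default 1).
#' @param epsilon_ql,alpha,gamma Q-learning exploration rate, learning
#'   rate and discount (defaults 0.2, 0.01, 0).
#' @param q_table Optional initial 8 x 3 Q-table (QL), e.g. from
#'   [train_qlearning()].
#' @return An object of class `bandit_controller`.
#' @export
bandit_controller <- function(variant = c("RL", "UCB", "QL"),
                              epsilon = 0.1, beta = 0.2, c = 1,
                              epsilon_ql = 0.2, alpha = 0.01, gamma = 0,
                              q_table = NULL) {
  variant <- match.arg(variant)
  st <- list(variant = variant, epsilon = epsilon, beta = beta, c = c,
             epsilon_ql = epsilon_ql, alpha = alpha, gamma = gamma)
  if (variant == "QL") {
    if (is.null(q_table)) q_table <- matrix(0, 8, 3)
    stopifnot(all(dim(q_table) == c(8, 3)))
    st$q_table <- q_table
  } else {
    st$q <- numeric(3)
    st$n <- integer(3)
    st$t <- 0L
  }
  structure(st, class = "bandit_controller")
}

#' Strategy selection by a value-based controller
#'
#' RL is epsilon-greedy over the three strategy values; UCB maximises
#' `Q + c * sqrt(log(t) / N)` with untried strategies chosen first (the
#' infinite-bonus convention); QL is epsilon_QL-greedy on the Q-table row
#' of the current context state.
#'
#' @param state A [bandit_controller()].
#' @param ctx Context state (required for QL).
#' @return A strategy label.
#' @export
select_value_based <- function(state, ctx = NULL) {
  stopifnot(inherits(state, "bandit_controller"))
  if (state$variant == "QL") {
    if (is.null(ctx)) stop("QL controller requires a context state")
    row <- state$q_table[context_state_index(ctx$ec, ctx$conf, ctx$unc), ]
    if (stats::runif(1) < state$epsilon_ql)
      return(strategies()[sample.int(3, 1)])
    return(strategies()[which.max(row)])
  }
  if (state$variant == "UCB") {
    untried <- which(state$n == 0L)
    if (length(untried) > 0) return(strategies()[untried[1]])
    bonus <- state$c * sqrt(log(state$t) / state$n)
    return(strategies()[which.max(state$q + bonus)])
  }
  if (stats::runif(1) < state$epsilon)
    return(strategies()[sample.int(3, 1)])
  strategies()[which.max(state$q)]
}

#' Reward feedback to a value-based controller
#'
#' RL/UCB apply the constant step-size value update to the chosen
#' strategy's estimate; QL applies the Bellman update on the visited
#' (state, strategy) cell — with the default discount `gamma = 0` this
#' reduces to `Q <- Q + alpha * (r - Q)`.
#'
#' @param state A [bandit_controller()].
#' @param strategy The strategy that was executed (label).
#' @param reward Received reward.
#' @param ctx Context state at selection time (QL).
#' @param ctx_next Context state after the step (QL; optional, used when
#'   `gamma > 0`).
#' @return The updated controller state.
#' @export
update_value_controller <- function(state, strategy, reward, ctx = NULL,
                                    ctx_next = NULL) {
  stopifnot(inherits(state, "bandit_controller"))
  a <- .strategy_code(strategy)
  if (state$variant == "QL") {
    s <- context_state_index(ctx$ec, ctx$conf, ctx$unc)
    target <- reward
    if (state$gamma > 0 && !is.null(ctx_next)) {
      s2 <- context_state_index(ctx_next$ec, ctx_next$conf, ctx_next$unc)
      target <- reward + state$gamma * max(state$q_table[s2, ])
    }
    state$q_table[s, a] <- state$q_table[s, a] +
      state$alpha * (target - state$q_table[s, a])
  } else {
    state$q[a] <- state$q[a] + state$beta * (reward - state$q[a])
    state$n[a] <- state$n[a] + 1L
    state$t <- state$t + 1L
  }
  state
}

# ---------------------------------------------------------------------------
# Fixed-probability baselines

.baseline_probs <- list(
  IL_ONLY = c(IL = 1, SUCCESS = 0, CONFORMIST = 0),
  RAND = c(IL = 1, SUCCESS = 1, CONFORMIST = 1) / 3,
  PROP = c(IL = 0.10, SUCCESS = 0.45, CONFORMIST = 0.45),
  CONF = c(IL = 0.05, SUCCESS = 0, CONFORMIST = 0.95),
  SUCC = c(IL = 0.05, SUCCESS = 0.95, CONFORMIST = 0))

#' Fixed-probability baseline strategy selection
#'
#' \describe{
#'   \item{IL_ONLY}{always individual learning.}
#'   \item{RAND}{uniform over the three strategies.}
#'   \item{PROP}{success-based 0.45, conformist 0.45, IL 0.10.}
#'   \item{CONF}{conformist 0.95, IL 0.05.}
#'   \item{SUCC}{success-based 0.95, IL 0.05.}
#' }
#'
#' @param variant Baseline name.
#' @return A strategy label drawn with the variant's probabilities.
#' @export
select_baseline <- function(variant = c("IL_ONLY", "RAND", "PROP", "CONF",
                                        "SUCC")) {
  variant <- match.arg(variant)
  p <- .baseline_probs[[variant]]
  strategies()[sample.int(3, 1, prob = p)]
}

# ---------------------------------------------------------------------------
# Serialization of trained controllers

#' Write / read controllers as JSON
#'
#' Discrete policies serialize as the 8-character table string plus the
#' two thresholds; network controllers as the flat weight vector
#' (row-major) plus the architecture; Q-tables as the 8 x 3 matrix.
#'
#' @param x A [discrete_policy()], [fcn_controller()] or 8 x 3 Q-table
#'   matrix.
#' @param path File path.
#' @return `write_controller` returns `path` invisibly; `read_controller`
#'   returns the reconstructed object.
#' @export
write_controller <- function(x, path) {
  doc <- if (inherits(x, "discrete_policy")) {
    list(type = "discrete_policy", table = policy_string(x),
         th_ec = x$th_ec, th_u = x$th_u)
  } else if (inherits(x, "fcn_controller")) {
    list(type = "fcn_controller", k = x$k, hidden = x$hidden,
         weights = fcn_weights(x))
  } else if (is.matrix(x) && all(dim(x) == c(8, 3))) {
    list(type = "q_table", q = as.vector(t(x)))
  } else stop("unsupported controller object")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_controller
#' @export
read_controller <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(doc$type,
    discrete_policy = discrete_policy(doc$table, doc$th_ec, doc$th_u),
    fcn_controller = fcn_controller(doc$weights, k = doc$k,
                                    hidden = doc$hidden),
    q_table = matrix(doc$q, nrow = 8, byrow = TRUE),
    stop("unknown controller type: ", doc$type))
}
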