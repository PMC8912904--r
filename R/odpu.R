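#' Density and distribution function of the maximum of Gaussian draws
#'
#' For `n` independent draws from `N(mean, sd)`, the maximum (the `n`-th
#' order statistic) has density
#' `(n / sd) * phi(z) * Phi(z)^(n - 1)` and distribution function
#' `Phi(z)^n`, with `z = (x - mean) / sd`. The power is evaluated in
#' log-space so that large `n` does not underflow.
#'
#' @param x Evaluation points.
#' @param mean,sd Parameters of the underlying Gaussian; `sd` must be > 0.
#' @param n Number of independent draws (>= 1).
#' @param log Return the log-density / log-probability?
#' @return Numeric vector of densities (`max_order_stat_pdf`) or
#'   probabilities (`max_order_stat_cdf`).
#' @examples
#' max_order_stat_pdf(0, mean = 0, sd = 1, n = 2)  # 2 * phi(0) * Phi(0)
#' @export
max_order_stat_pdf <- function(x, mean = 0, sd = 1, n = 1, log = FALSE) {
  stopifnot(sd > 0, n >= 1)
  z <- (x - mean) / sd
  lf <- log(n) - log(sd) + stats::dnorm(z, log = TRUE) +
    (n - 1) * stats::pnorm(z, log.p = TRUE)
  if (log) lf else exp(lf)
}

#' @rdname max_order_stat_pdf
#' @export
max_order_stat_cdf <- function(x, mean = 0, sd = 1, n = 1, log = FALSE) {
  stopifnot(sd > 0, n >= 1)
  lF <- n * stats::pnorm((x - mean) / sd, log.p = TRUE)
  if (log) lF else exp(lF)
}

.odpu_check <- function(mean, sd, n) {
  if (length(mean) < 2) stop("ODPU needs at least 2 distribution summaries")
  stopifnot(length(sd) == length(mean), length(n) == length(mean),
            all(n >= 1))
  if (any(sd <= 0)) stop("ODPU integral form requires all sd > 0")
  best <- which(mean == max(mean))
  if (length(best) > 1)
    warning("exact tie in means; treating the lowest index as the optimum")
  best[1]
}

#' Optimum distribution prediction uncertainty (ODPU)
#'
#' The probability that the maximum of draws from the sub-optimal reward
#' distributions exceeds the maximum of draws from the optimal one (the
#' distribution with the largest mean). With `f` and `F` the density and
#' distribution function of each group's maximum ([max_order_stat_pdf()]),
#' `ODPU = 1 - integral of f_opt(y) * prod_i F_subopt_i(y) dy`.
#' High ODPU means a sub-optimal arm is likely to produce the single best
#' observed reward, which misleads success-based copying.
#'
#' @param mean,sd Per-group Gaussian parameters (length >= 2; all `sd > 0`).
#' @param n Per-group number of independent draws (e.g. individuals
#'   choosing each arm).
#' @param rel.tol Quadrature relative tolerance.
#' @details The integral is evaluated after the change of variables
#' `u = F_opt(y)` (the quantile space of the optimal group's maximum),
#' giving `1 - integral over (0,1) of prod_i F_i(F_opt^{-1}(u)) du` with
#' `F_opt^{-1}(u) = mean + sd * qnorm(u^(1/n))`. The transformed
#' integrand is bounded and smooth, so the quadrature stays accurate even
#' when a standard deviation is nearly zero and the original integrand
#' degenerates into a spike (estimates with a tiny sd floor are exactly
#' what the context encoding feeds in).
#' @return A probability in \[0, 1\].
#' @examples
#' odpu(mean = c(1, 0.5), sd = c(0.4, 0.4), n = c(50, 50))
#' odpu(mean = c(1, 0.5), sd = c(0.05, 0.05), n = c(50, 50))  # ~0
#' @export
odpu <- function(mean, sd, n, rel.tol = 1e-9) {
  best <- .odpu_check(mean, sd, n)
  others <- setdiff(seq_along(mean), best)
  integrand <- function(u) {
    y <- mean[best] + sd[best] * stats::qnorm(u^(1 / n[best]))
    lg <- 0
    for (i in others)
      lg <- lg + max_order_stat_cdf(y, mean[i], sd[i], n[i], log = TRUE)
    exp(lg)
  }
  p_opt <- stats::integrate(integrand, 0, 1, rel.tol = rel.tol,
                            subdivisions = 400L)$value
  min(max(1 - p_opt, 0), 1)
}

#' Monte-Carlo estimate of the ODPU
#'
#' Simulation oracle for [odpu()]: the empirical fraction of replicates in
#' which some sub-optimal group's maximum exceeds the optimal group's
#' maximum.
#'
#' @inheritParams odpu
#' @param reps Number of replicates (>= 1).
#' @return A probability in \[0, 1\].
#' @export
odpu_monte_carlo <- function(mean, sd, n, reps = 1e5) {
  stopifnot(reps >= 1)
  best <- .odpu_check(mean, sd, n)
  others <- setdiff(seq_along(mean), best)
  # max of n iid N(mu, sd) via inverse cdf of the maximum: mu + sd * qnorm(u^(1/n))
  rmax <- function(i) mean[i] + sd[i] *
    stats::qnorm(stats::runif(reps)^(1 / n[i]))
  m_opt <- rmax(best)
  exceeded <- rep(FALSE, reps)
  for (i in others) exceeded <- exceeded | (rmax(i) > m_opt)
  mean(exceeded)
}

#' ODPU for Bernoulli rewards (exact)
#'
#' With two-point rewards the maximum of each group is 0 or 1 and the ODPU
#' has a closed form: the optimal group's maximum fails to reach 1 while
#' some sub-optimal group's maximum does.
#'
#' @param prob Per-group success probabilities (the group with the largest
#'   probability is the optimum).
#' @param n Per-group number of draws.
#' @return A probability in \[0, 1\].
#' @examples
#' odpu_bernoulli(prob = c(0.9, 0.5), n = c(50, 50))
#' @export
odpu_bernoulli <- function(prob, n) {
  if (length(prob) < 2) stop("ODPU needs at least 2 distribution summaries")
  stopifnot(length(n) == length(prob), all(n >= 1),
            all(prob >= 0), all(prob <= 1))
  best <- which(prob == max(prob))
  if (length(best) > 1)
    warning("exact tie in probabilities; treating the lowest index as the optimum")
  best <- best[1]
  others <- setdiff(seq_along(prob), best)
  p_opt_zero <- (1 - prob[best])^n[best]
  p_sub_all_zero <- prod((1 - prob[others])^n[others])
  p_opt_zero * (1 - p_sub_all_zero)
}
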