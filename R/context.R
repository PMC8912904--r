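#' Context-encoding parameters
#'
#' Thresholds and lags for the binary context encoding.
#'
#' @param th_ec Environment-change threshold on the shift of the estimated
#'   optimum arm's mean reward (default 0.15).
#' @param th_u Uncertainty threshold on the ODPU (default 0.1).
#' @param delta Step lag for the environment-change comparison (default 1).
#' @param sigma_floor Lower bound applied to running sd estimates so the
#'   ODPU is defined when estimates collapse (default 1e-6).
#' @return A list of class `context_params`.
#' @export
context_params <- function(th_ec = 0.15, th_u = 0.1, delta = 1,
                           sigma_floor = 1e-6) {
  stopifnot(th_ec >= 0, th_u >= 0, delta >= 1, sigma_floor > 0)
  structure(list(th_ec = th_ec, th_u = th_u, delta = as.integer(delta),
                 sigma_floor = sigma_floor),
            class = "context_params")
}

#' Environment-change detection
#'
#' Fires (returns 1) when the estimated mean reward of the currently
#' estimated optimum action moved by more than `th_ec` (strict) relative
#' to `delta` steps ago. The optimum is re-evaluated at each step as the
#' arm with the highest running mean. Returns 0 when either estimate is
#' unavailable (e.g. no history yet).
#'
#' @param mu_star_now,mu_star_lagged Estimated optimum-arm mean reward now
#'   and `delta` steps ago (`NA` when undefined).
#' @param th_ec Detection threshold (default 0.15).
#' @return 0 or 1.
#' @examples
#' detect_environment_change(1.0, 0.8, th_ec = 0.15)  # 1
#' detect_environment_change(1.0, 0.85, th_ec = 0.15) # 0 (strict)
#' @export
detect_environment_change <- function(mu_star_now, mu_star_lagged,
                                      th_ec = 0.15) {
  if (is.na(mu_star_now) || is.na(mu_star_lagged)) return(0L)
  as.integer(abs(mu_star_now - mu_star_lagged) > th_ec)
}

#' Conformity detection
#'
#' Returns 1 when the majority of individuals perform the behaviour with
#' the highest average reward, i.e. the arm with the highest running mean
#' coincides with the most frequent arm — unless an environment change was
#' detected, which resets conformity to 0.
#'
#' @param mu_prime Per-arm running mean rewards (`NA` where unsampled).
#' @param h Per-arm action frequencies.
#' @param ec Environment-change bit.
#' @return 0 or 1.
#' @export
detect_conformity <- function(mu_prime, h, ec = 0L) {
  if (ec == 1L) return(0L)
  if (all(is.na(mu_prime))) return(0L)
  as.integer(which.max(mu_prime) == which.max(h))
}

#' Uncertainty detection
#'
#' Returns 1 when the ODPU computed from the running per-arm estimates
#' exceeds `th_u`. Degenerate inputs (fewer than two sampled arms) return
#' 0 with a warning.
#'
#' @param mu_prime,sigma_prime Per-arm running mean and sd estimates.
#' @param counts Per-arm chooser counts fed to the ODPU (floored at 1 for
#'   sampled arms).
#' @param th_u Uncertainty threshold (default 0.1).
#' @param sigma_floor Lower bound on sd estimates (default 1e-6).
#' @return 0 or 1.
#' @export
detect_uncertainty <- function(mu_prime, sigma_prime, counts, th_u = 0.1,
                               sigma_floor = 1e-6) {
  ok <- !is.na(mu_prime) & counts >= 1
  if (sum(ok) < 2) {
    warning("fewer than two sampled arms; uncertainty undefined, returning 0")
    return(0L)
  }
  val <- odpu(mean = mu_prime[ok],
              sd = pmax(sigma_prime[ok], sigma_floor),
              n = pmax(counts[ok], 1))
  as.integer(val > th_u)
}

#' Encode the environment context from social information
#'
#' Computes the binary triple (environment change, conformity,
#' uncertainty) at step `t` from the recorded social information, using
#' the thresholds in `params`. A pure function of its inputs.
#'
#' @param info_hist List of [social_info()] records indexed by step
#'   (`1..t`, with the record at `t` present).
#' @param t Current step.
#' @param params A [context_params()].
#' @return A list with integer elements `ec`, `conf`, `unc` plus the
#'   thresholds used, of class `context_state`.
#' @export
encode_context <- function(info_hist, t, params = context_params()) {
  stopifnot(inherits(params, "context_params"), t >= 1)
  info <- info_hist[[t]]
  if (is.null(info)) stop("no social information recorded at step t")
  mu_star_now <- if (all(is.na(info$mu))) NA_real_ else max(info$mu, na.rm = TRUE)
  mu_star_lag <- NA_real_
  if (t - params$delta >= 1) {
    lag <- info_hist[[t - params$delta]]
    if (!is.null(lag) && !all(is.na(lag$mu)))
      mu_star_lag <- max(lag$mu, na.rm = TRUE)
  }
  ec <- detect_environment_change(mu_star_now, mu_star_lag, params$th_ec)
  conf <- detect_conformity(info$mu, info$h, ec)
  unc <- suppressWarnings(
    detect_uncertainty(info$mu, info$sd, info$counts, params$th_u,
                       params$sigma_floor))
  structure(list(ec = ec, conf = conf, unc = unc,
                 th_ec = params$th_ec, th_u = params$th_u,
                 delta = params$delta),
            class = "context_state")
}

#' @export
print.context_state <- function(x, ...) {
  cat(sprintf("<context_state> EC=%d C=%d U=%d (th_ec=%g, th_u=%g, delta=%d)\n",
              x$ec, x$conf, x$unc, x$th_ec, x$th_u, x$delta))
  invisible(x)
}
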