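#' Kaplan-Meier product-limit estimate
#'
#' Estimates the event-free probability over time from right-censored
#' follow-up. At tied times events are handled before censorings (censored
#' subjects remain in the risk set at their own time), the standard
#' convention. Pairs with a missing time or status are dropped.
#'
#' @param times non-negative follow-up times (months).
#' @param events event indicators (1 = event, 0 = censored).
#' @return an object of class `"survival_curve"`: list with `times`
#'   (starting at 0), `survival` (starting at 1), `at_risk`, `n_events`,
#'   `n_censored`, `n`.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))
#' @export
km_estimate <- function(times, events) {
  if (length(times) != length(events)) {
    stop("times and events must have equal length", call. = FALSE)
  }
  keep <- !is.na(times) & !is.na(events)
  times <- times[keep]; events <- events[keep]
  if (length(times) == 0L) stop("no complete observations", call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("times must be finite and non-negative", call. = FALSE)
  }
  if (!all(events %in% c(0, 1))) {
    stop("events must be 0/1", call. = FALSE)
  }
  n <- length(times)
  ut <- sort(unique(times))
  at_risk <- vapply(ut, function(t) sum(times >= t), integer(1))
  d <- vapply(ut, function(t) sum(times == t & events == 1), integer(1))
  surv <- cumprod(1 - d / at_risk)
  # anchor the curve at (0, 1) unless events occur at time 0 itself
  if (length(ut) == 0L || ut[1] > 0) {
    ut <- c(0, ut); surv <- c(1, surv); at_risk <- c(n, at_risk)
  }
  structure(list(times = ut, survival = surv,
                 at_risk = at_risk,
                 n_events = sum(events == 1), n_censored = sum(events == 0),
                 n = n),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d events, %d censored\n",
              x$n, x$n_events, x$n_censored))
  print(data.frame(time = x$times, at_risk = x$at_risk,
                   survival = round(x$survival, 4)), row.names = FALSE)
  invisible(x)
}

#' Event-free proportion at a horizon
#'
#' The Kaplan-Meier estimate evaluated at `horizon` months (step function,
#' right-continuous). With no censoring before the horizon this equals the
#' empirical proportion still event-free.
#'
#' @inheritParams km_estimate
#' @param horizon non-negative time (months) at which to read the curve.
#' @return scalar event-free probability.
#' @export
event_free_proportion <- function(times, events, horizon) {
  if (!is.finite(horizon) || horizon < 0) {
    stop("horizon must be finite and non-negative", call. = FALSE)
  }
  km <- km_estimate(times, events)
  km$survival[max(which(km$times <= horizon))]
}

#' Log-rank test across K groups
#'
#' Mantel-Haenszel log-rank test comparing event-time distributions between
#' two or more groups. At each distinct event time the observed events per
#' group are compared with their hypergeometric expectation given the risk
#' sets; the quadratic form of the summed differences against the summed
#' hypergeometric covariance gives a chi-squared statistic with K - 1
#' degrees of freedom. A generalized inverse is used for the covariance so
#' that degenerate configurations (e.g. identical groups) return 0 rather
#' than failing.
#'
#' @param groups list of K >= 2 groups, each a list with elements `times`
#'   and `events` as in [km_estimate()].
#' @return list with `chi2`, `df`, and `p`.
#' @export
logrank_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least two groups", call. = FALSE)
  }
  k <- length(groups)
  tt <- ev <- gg <- numeric(0)
  for (g in seq_len(k)) {
    ti <- groups[[g]]$times; e <- groups[[g]]$events
    keep <- !is.na(ti) & !is.na(e)
    ti <- ti[keep]; e <- e[keep]
    if (length(ti) == 0L) stop("group ", g, " has no subjects", call. = FALSE)
    if (any(ti < 0)) stop("times must be non-negative", call. = FALSE)
    if (!all(e %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)
    tt <- c(tt, ti); ev <- c(ev, e); gg <- c(gg, rep(g, length(ti)))
  }
  ut <- sort(unique(tt[ev == 1]))
  obs <- exp_ <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ut) {
    at <- tt >= t
    n_t <- sum(at)
    if (n_t == 0) next
    d_t <- sum(tt == t & ev == 1)
    n_g <- vapply(seq_len(k), function(g) sum(at & gg == g), numeric(1))
    d_g <- vapply(seq_len(k), function(g) sum(tt == t & ev == 1 & gg == g),
                  numeric(1))
    obs <- obs + d_g
    exp_ <- exp_ + d_t * n_g / n_t
    if (n_t > 1) {
      w <- d_t * (n_t - d_t) / (n_t - 1)
      V <- V + w * (diag(n_g / n_t) - tcrossprod(n_g / n_t))
    }
  }
  z <- (obs - exp_)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  chi2 <- drop(t(z) %*% MASS::ginv(Vk) %*% z)
  chi2 <- max(chi2, 0)
  list(chi2 = chi2, df = k - 1L,
       p = stats::pchisq(chi2, df = k - 1, lower.tail = FALSE))
}
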