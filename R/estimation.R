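#' Per-ego maximum-likelihood estimation of the scale parameter eta
#'
#' @description
#' Given one ego's positive grooming weights `s_1, ..., s_L`, the continuum
#' model describes the normalized costs `t_i = (s_max - s_i)/(s_max - s_min)`
#' as draws from the truncated-exponential density `p(t) = eta * exp(eta*t) /
#' (exp(eta) - 1)` on `[0, 1]`. This is a one-parameter exponential family
#' in `t`, so the maximum-likelihood estimate of `eta` is the moment
#' condition `E[t; eta] = t_bar`: a single monotone implicit equation,
#' solved here by bracketing root finding. Confidence intervals are Wald
#' intervals on `t_bar` with the model variance `Var[t; eta_hat]/L`,
#' propagated through the strictly increasing inverse map `eta(t_bar)`.
#'
#' @name estimation
NULL

#' Normalized relationship costs of an ego-network
#'
#' Maps the ego's weights to `t_i = (s_max - s_i)/(s_max - s_min)` using the
#' ego's own observed extremes, so the most-groomed alter gets `t = 0` and
#' the least-groomed `t = 1` (both extremes are attained by construction and
#' are included in the mean). The mean cost `sigma` is the arithmetic mean
#' of the `L` positive weights; the normalized mean is
#' `t_bar = (s_max - sigma)/(s_max - s_min)`.
#'
#' @param network an [ego_network()].
#' @return object of class `normalized_costs`: list with `ego_id`,
#'   `t_values` (named by alter), `t_bar`, `sigma`, `s_max`, `s_min`, `L`.
#' @export
normalize_costs <- function(network) {
  stopifnot(inherits(network, "ego_network"))
  if (network$L < 2)
    stop(sprintf("ego '%s': need at least 2 alters to normalize costs (L = %d)",
                 network$ego_id, network$L))
  if (network$s_max == network$s_min)
    stop(sprintf("ego '%s': degenerate network, all %d weights equal (%g)",
                 network$ego_id, network$L, network$s_max))
  s <- network$weights
  t_values <- (network$s_max - s) / (network$s_max - network$s_min)
  structure(list(ego_id = network$ego_id,
                 t_values = t_values,
                 t_bar = mean(t_values),
                 sigma = mean(s),
                 s_max = network$s_max, s_min = network$s_min,
                 L = network$L),
            class = "normalized_costs")
}

#' Invert the mean-cost equation for eta
#'
#' Solves `mean_normalized_cost(eta) = t_bar` for the unique root. The mean
#' is strictly increasing in `eta`, so a bracketing search is guaranteed;
#' the initial bracket `[-50, 50]` is doubled outward as needed (a `t_bar`
#' at the domain boundary corresponds to infinite `eta` and is rejected).
#' `t_bar` within solver resolution of 1/2 returns exactly 0, the regime
#' boundary.
#'
#' @param t_bar mean normalized cost, strictly inside (0, 1).
#' @param tol absolute tolerance on the root (default 1e-10).
#' @return the scalar maximum-likelihood `eta`.
#' @examples
#' solve_eta(mean_normalized_cost(6))  # 6
#' @export
solve_eta <- function(t_bar, tol = 1e-10) {
  stopifnot(is.numeric(t_bar), length(t_bar) == 1L, is.finite(t_bar))
  if (t_bar <= 0 || t_bar >= 1)
    stop("`t_bar` must lie strictly inside (0, 1); a boundary mean implies infinite eta")
  if (abs(t_bar - 0.5) < tol / 12) return(0)
  f <- function(eta) mean_normalized_cost(eta) - t_bar
  lo <- -50; hi <- 50
  while (f(hi) < 0 && hi < 1e9) hi <- hi * 2
  while (f(lo) > 0 && lo > -1e9) lo <- lo * 2
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' Wald confidence interval for eta
#'
#' A `1 - 2*delta` interval: `t_bar +/- z_{1-delta} * sqrt(Var[t; eta_hat]/L)`
#' on the mean-cost scale, mapped through the strictly increasing inverse
#' `eta(t_bar)` (so the interval always contains `eta_hat`). Endpoints
#' falling outside (0, 1) are clipped just inside the domain, which caps the
#' bounds at the solver bracket.
#'
#' @param t_values numeric vector of normalized costs (length `L >= 2`).
#' @param eta_hat fitted eta.
#' @param delta half-tail probability; `delta = 0.025` gives a nominal 95%
#'   interval.
#' @return numeric vector `c(lower, upper)`.
#' @export
eta_confint <- function(t_values, eta_hat, delta = 0.025) {
  stopifnot(length(t_values) >= 2, is.finite(eta_hat))
  if (!(delta > 0 && delta < 0.5))
    stop("`delta` must lie in (0, 0.5)")
  L <- length(t_values)
  se <- sqrt(cost_variance(eta_hat) / L)
  z <- stats::qnorm(1 - delta)
  t_bar <- mean(t_values)
  eps <- 1e-12
  lower <- solve_eta(min(max(t_bar - z * se, eps), 1 - eps))
  upper <- solve_eta(min(max(t_bar + z * se, eps), 1 - eps))
  c(lower = lower, upper = upper)
}

#' Bootstrap confidence interval for eta
#'
#' Nonparametric percentile bootstrap resampling alters with replacement;
#' a cross-check for the Wald interval of [eta_confint()]. Degenerate
#' resamples (all costs equal) are redrawn.
#'
#' @inheritParams eta_confint
#' @param n_boot number of bootstrap resamples.
#' @return numeric vector `c(lower, upper)`.
#' @export
eta_confint_boot <- function(t_values, delta = 0.025, n_boot = 999) {
  stopifnot(length(t_values) >= 2)
  eta_b <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    tb <- 0.5
    for (tries in 1:100) {
      ts <- sample(t_values, replace = TRUE)
      tb <- mean(ts)
      if (tb > 0 && tb < 1 && stats::var(ts) > 0) break
    }
    eta_b[b] <- solve_eta(tb)
  }
  stats::quantile(eta_b, c(delta, 1 - delta), names = FALSE) ->
    q
  c(lower = q[1], upper = q[2])
}

.regime_label <- function(eta_hat, ci) {
  if (ci[1] < 0 && ci[2] > 0) return("boundary")
  if (eta_hat > 0) "normal" else if (eta_hat < 0) "inverted" else "boundary"
}

new_continuum_fit <- function(ego_id, group_id, eta_hat, t_bar, sigma, L,
                              ci, delta, degenerate = FALSE,
                              reason = NA_character_, t_values = NULL) {
  structure(list(ego_id = ego_id, group_id = group_id,
                 eta_hat = eta_hat, t_bar = t_bar, sigma = sigma, L = L,
                 ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 delta = delta,
                 regime = if (degenerate) NA_character_
                          else .regime_label(eta_hat, ci),
                 degenerate = degenerate, reason = reason,
                 t_values = t_values),
            class = "continuum_fit")
}

#' @export
print.continuum_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<continuum_fit> %s: degenerate (%s)\n", x$ego_id, x$reason))
  } else {
    cat(sprintf("<continuum_fit> %s: eta = %.3f [%.3f, %.3f] (%d%% CI), L = %d, regime %s\n",
                x$ego_id, x$eta_hat, x$ci_low, x$ci_high,
                round(100 * (1 - 2 * x$delta)), x$L, x$regime))
  }
  invisible(x)
}

#' Fit the continuum model to a sample of normalized costs
#'
#' The estimation core, shared by [fit_ego()] and by noise-free recovery
#' experiments that draw `t` directly from the model density.
#'
#' @param t_values numeric vector of normalized costs in `[0, 1]`, length
#'   `>= 2`.
#' @param delta half-tail probability of the confidence interval.
#' @param ego_id,group_id optional identifiers carried into the fit.
#' @return a `continuum_fit`.
#' @export
fit_costs <- function(t_values, delta = 0.025, ego_id = NA_character_,
                      group_id = NA_character_) {
  stopifnot(is.numeric(t_values), length(t_values) >= 2)
  t_bar <- mean(t_values)
  if (t_bar <= 0 || t_bar >= 1 || stats::var(t_values) == 0)
    return(new_continuum_fit(ego_id, group_id, NA_real_, t_bar,
                             NA_real_, length(t_values),
                             c(NA_real_, NA_real_), delta,
                             degenerate = TRUE, reason = "degenerate costs",
                             t_values = t_values))
  eta_hat <- solve_eta(t_bar)
  ci <- eta_confint(t_values, eta_hat, delta)
  new_continuum_fit(ego_id, group_id, eta_hat, t_bar, NA_real_,
                    length(t_values), ci, delta, t_values = t_values)
}

#' Fit the continuum model to one ego-network
#'
#' Composes [normalize_costs()], [solve_eta()] and [eta_confint()].
#' Networks below the partner threshold are refused (they should have been
#' removed by [filter_egos()]); degenerate networks (all weights equal) are
#' returned as flagged, non-fatal records with no fitted `eta`. The regime
#' label is `"normal"` (`eta > 0`) or `"inverted"` (`eta < 0`), or
#' `"boundary"` when the confidence interval straddles 0.
#'
#' @param network an [ego_network()].
#' @param delta half-tail probability; default 0.025 (95% interval).
#' @param min_partners minimum number of alters (default 5).
#' @return a `continuum_fit`.
#' @export
fit_ego <- function(network, delta = 0.025, min_partners = 5) {
  stopifnot(inherits(network, "ego_network"))
  if (network$L < min_partners)
    stop(sprintf("ego '%s' has L = %d < %d grooming partners; excluded from fitting",
                 network$ego_id, network$L, min_partners))
  costs <- tryCatch(normalize_costs(network), error = identity)
  if (inherits(costs, "error"))
    return(new_continuum_fit(network$ego_id, network$group_id, NA_real_,
                             NA_real_, mean(network$weights), network$L,
                             c(NA_real_, NA_real_), delta, degenerate = TRUE,
                             reason = conditionMessage(costs)))
  fit <- fit_costs(costs$t_values, delta, ego_id = network$ego_id,
                   group_id = network$group_id)
  fit$sigma <- costs$sigma
  fit
}

#' Fit every retained ego-network
#'
#' @param networks named list of `ego_network` objects (the `retained`
#'   component of [filter_egos()]).
#' @inheritParams fit_ego
#' @return data frame with one row per ego: `ego_id`, `group_id`, `L`,
#'   `sigma`, `t_bar`, `eta_hat`, `ci_low`, `ci_high`, `regime`,
#'   `degenerate`. The list of `continuum_fit` objects is attached as
#'   attribute `"fits"`.
#' @export
fit_egos <- function(networks, delta = 0.025, min_partners = 5) {
  fits <- lapply(networks, fit_ego, delta = delta,
                 min_partners = min_partners)
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(ego_id = f$ego_id, group_id = as.character(f$group_id),
               L = f$L, sigma = f$sigma, t_bar = f$t_bar,
               eta_hat = f$eta_hat, ci_low = f$ci_low, ci_high = f$ci_high,
               regime = f$regime, degenerate = f$degenerate,
               stringsAsFactors = FALSE, row.names = NULL)))
  if (is.null(tab))
    tab <- data.frame(ego_id = character(), group_id = character(),
                      L = integer(), sigma = numeric(), t_bar = numeric(),
                      eta_hat = numeric(), ci_low = numeric(),
                      ci_high = numeric(), regime = character(),
                      degenerate = logical(), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' Empirical cumulative distribution of normalized costs
#'
#' Right-continuous step points of the empirical cdf of `t`: at each
#' distinct `t_i`, the fraction of costs `<= t_i`. Ties are grouped into a
#' single step; the final point is `(max t, 1)`. These are the "data dots"
#' overlaid on the fitted `chi(t)` curve.
#'
#' @param costs a `normalized_costs` object or a numeric vector of `t`
#'   values.
#' @return data frame with columns `t` and `fraction`.
#' @export
empirical_cost_cdf <- function(costs) {
  t_values <- if (inherits(costs, "normalized_costs")) costs$t_values
              else costs
  stopifnot(is.numeric(t_values), length(t_values) >= 1)
  ts <- sort(unique(unname(t_values)))
  data.frame(t = ts,
             fraction = vapply(ts, function(x) mean(t_values <= x),
                               numeric(1)))
}

#' Confidence band for the fitted chi(t) curve
#'
#' Because `chi(t; eta)` is strictly decreasing in `eta` for `t` in (0, 1),
#' the pointwise envelope of the curves over the confidence interval
#' `[ci_low, ci_high]` is `[chi(t; ci_high), chi(t; ci_low)]`. The band is
#' pinned to (0, 0) at `t = 0` and (1, 1) at `t = 1`.
#'
#' @param fit a `continuum_fit` with finite interval.
#' @param t_grid numeric vector of evaluation points in `[0, 1]`.
#' @return data frame `t`, `chi` (fitted curve), `lower`, `upper`; empty
#'   for a degenerate fit.
#' @export
fit_band <- function(fit, t_grid = seq(0, 1, by = 0.01)) {
  stopifnot(inherits(fit, "continuum_fit"))
  if (fit$degenerate || !is.finite(fit$ci_low) || !is.finite(fit$ci_high))
    return(data.frame(t = numeric(), chi = numeric(),
                      lower = numeric(), upper = numeric()))
  data.frame(t = t_grid,
             chi = continuum_cdf(t_grid, fit$eta_hat),
             lower = continuum_cdf(t_grid, fit$ci_high),
             upper = continuum_cdf(t_grid, fit$ci_low))
}
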