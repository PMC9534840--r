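#' Discrete and continuum maximum-entropy circle models
#'
#' @description
#' Closed-form mathematics of the layered ("social circle") structure of
#' ego-networks under a maximum-entropy resource-allocation model.
#'
#' In the discrete model an ego's `L` relationships fall into `r` cost
#' categories with strictly decreasing costs
#' `s_1 = s_max > s_2 > ... > s_r = s_min`. The probability that a
#' relationship belongs to category `k` is `p_k = exp(-mu_hat * s_k) / Z_r`,
#' where the Lagrange multiplier `mu_hat` enforces a fixed mean cost. With
#' the rescaled multiplier `mu = mu_hat * (s_max - s_min) / (r - 1)`, the
#' expected fraction of relationships at cost at least that of category `k`
#' (the cumulative circle size) is `chi_k = (exp(k*mu) - 1)/(exp(r*mu) - 1)`.
#'
#' The continuum model replaces the `r` categories by a normalized cost
#' `t in [0, 1]` (`t = 0` the most intense relationship, `t = 1` the least)
#' and a single scale parameter `eta`: the fraction of relationships with
#' normalized cost at most `t` is `chi(t) = (exp(eta*t) - 1)/(exp(eta) - 1)`.
#' `eta > 0` is the "normal" regime (many weak ties, circles scale by roughly
#' `exp(mu)` per layer); `eta < 0` the "inverted" regime (most ties intense);
#' `eta = 0` the uniform boundary. The two models are linked exactly by
#' `chi(k/r; eta = r*mu) = chi_k(mu, r)` and approximately, through the
#' logarithmic derivative of `chi`, by `eta ~ (r - 1)(exp(mu) - 1)`.
#'
#' All functions are overflow-safe for `|eta|` (or `|r*mu|`) up to several
#' hundred and treat the removable singularity at 0 by exact limits or
#' low-order series.
#'
#' @name circle-model
NULL

# series switch-over for the removable singularity at eta = 0
.ETA_EPS <- 1e-6

#' Layer membership probabilities of the discrete circle model
#'
#' Computes `p_k = exp(-mu_hat * s_k) / Z_r` over the `r` cost categories,
#' via a max-shifted softmax so that large `|mu_hat * s_k|` never overflows.
#'
#' @param cost_levels strictly decreasing numeric vector `s_1 > ... > s_r`.
#' @param mu_hat Lagrange multiplier (any finite real).
#' @return numeric vector of length `r` summing to 1.
#' @examples
#' layer_probabilities(c(1, 0), log(2))  # (1/3, 2/3)
#' @export
layer_probabilities <- function(cost_levels, mu_hat) {
  stopifnot(is.numeric(cost_levels), length(cost_levels) >= 2,
            is.finite(mu_hat))
  if (any(diff(cost_levels) >= 0))
    stop("`cost_levels` must be strictly decreasing (s_max first)")
  x <- -mu_hat * cost_levels
  x <- x - max(x)
  p <- exp(x)
  p / sum(p)
}

#' Cumulative circle sizes of the discrete model
#'
#' `chi_k = (exp(k*mu) - 1)/(exp(r*mu) - 1)` for `k = 1, ..., r`, the
#' expected fraction of relationships with cost at least that of category
#' `k` (`k = 1` is the innermost circle, `chi_r = 1`). `mu = 0` returns the
#' exact uniform limit `k/r`.
#'
#' @param mu rescaled Lagrange multiplier.
#' @param r number of relationship categories (integer >= 2).
#' @return numeric vector of length `r`, strictly increasing, ending at 1.
#' @examples
#' circle_sizes(log(3), 4)  # (2, 8, 26, 80)/80
#' @export
circle_sizes <- function(mu, r) {
  stopifnot(is.finite(mu), length(mu) == 1L, r >= 2, r == as.integer(r))
  k <- seq_len(r)
  if (mu == 0) return(k / r)
  if (mu > 0 && r * mu > 700) {
    # factor the dominant exponential: chi_k = e^{(k-r)mu} (1-e^{-k mu})/(1-e^{-r mu})
    return(exp((k - r) * mu) * (-expm1(-k * mu)) / (-expm1(-r * mu)))
  }
  # negative mu never overflows: expm1 saturates at -1
  expm1(k * mu) / expm1(r * mu)
}

#' Scaling ratio between consecutive circles
#'
#' Returns `chi_{k+1} / chi_k` of the discrete model. For large positive
#' `mu` the ratio tends to `exp(mu)` — the classical circle scaling ratio of
#' about 3 corresponds to `mu ~ 1` — and for large negative `mu` it tends
#' to 1 (all relationships in the innermost circle).
#'
#' @inheritParams circle_sizes
#' @param k circle index, `1 <= k < r`.
#' @return a single number.
#' @export
circle_scaling_ratio <- function(mu, r, k) {
  stopifnot(r >= 2)
  if (!(k >= 1 && k < r)) stop("`k` must satisfy 1 <= k < r")
  if (mu == 0) return((k + 1) / k)
  if (abs(mu) > 700 / r) {
    # chi_{k+1}/chi_k = e^mu (1 - e^{-(k+1)mu})/(1 - e^{-k mu}) for mu > 0
    if (mu > 0) return(exp(mu) * (-expm1(-(k + 1) * mu)) / (-expm1(-k * mu)))
    return(expm1((k + 1) * mu) / expm1(k * mu))
  }
  expm1((k + 1) * mu) / expm1(k * mu)
}

#' Continuum circle-size function chi(t)
#'
#' The fraction of an ego's relationships with normalized cost not larger
#' than `t`: `chi(t) = (exp(eta*t) - 1)/(exp(eta) - 1)`, with `chi(0) = 0`
#' and `chi(1) = 1`. Near `eta = 0` the second-order series
#' `t + eta*t*(t - 1)/2` is used to avoid catastrophic cancellation; large
#' positive `eta` is evaluated in the factored form
#' `exp(eta*(t-1)) * (1 - exp(-eta*t))/(1 - exp(-eta))`.
#'
#' `chi` is strictly decreasing in `eta` for fixed `t` in (0, 1), which is
#' what makes confidence bands a monotone envelope (see [fit_band()]).
#'
#' @param t numeric vector of normalized costs in `[0, 1]`.
#' @param eta scale parameter (single finite real).
#' @return numeric vector of the same length as `t`, in `[0, 1]`.
#' @examples
#' continuum_cdf(0.5, 6)  # ~ 0.047426
#' @export
continuum_cdf <- function(t, eta) {
  stopifnot(is.numeric(t), is.finite(eta), length(eta) == 1L)
  if (any(t < 0 | t > 1)) stop("`t` must lie in [0, 1]")
  if (abs(eta) < .ETA_EPS) return(t + eta * t * (t - 1) / 2)
  if (eta > 0) {
    exp(eta * (t - 1)) * (-expm1(-eta * t)) / (-expm1(-eta))
  } else {
    expm1(eta * t) / expm1(eta)
  }
}

#' Logarithmic derivative of chi(t)
#'
#' `d log chi / d t = eta * exp(eta*t)/(exp(eta*t) - 1)`, the continuum
#' analogue of the circle scaling ratio: it tends to `eta` as
#' `eta -> Inf` and to 0 as `eta -> -Inf`. At `eta = 0` the exact limit
#' `1/t` is returned. `t = 0` is a pole and is rejected.
#'
#' @param t numeric vector in `(0, 1]`.
#' @inheritParams continuum_cdf
#' @export
continuum_log_derivative <- function(t, eta) {
  stopifnot(is.numeric(t), is.finite(eta), length(eta) == 1L)
  if (any(t <= 0 | t > 1)) stop("`t` must lie in (0, 1]")
  if (eta == 0) return(1 / t)
  # eta / (1 - exp(-eta*t)): expm1 keeps this stable for small eta*t
  eta / (-expm1(-eta * t))
}

#' Mean normalized cost under the continuum model
#'
#' `E[t] = exp(eta)/(exp(eta) - 1) - 1/eta`, the model mean of the
#' normalized cost; strictly increasing in `eta`, equal to 1/2 at
#' `eta = 0` (series `1/2 + eta/12` near 0), and satisfying the mirror
#' symmetry `E[t; -eta] = 1 - E[t; eta]`. Estimation inverts this map:
#' the maximum-likelihood `eta` matches `E[t]` to the sample mean.
#'
#' @param eta numeric vector of scale parameters.
#' @return numeric vector in `(0, 1)`.
#' @examples
#' mean_normalized_cost(6)  # ~ 0.835818
#' @export
mean_normalized_cost <- function(eta) {
  stopifnot(is.numeric(eta), all(is.finite(eta)))
  vapply(eta, .mean_cost_scalar, numeric(1))
}

.mean_cost_scalar <- function(eta) {
  if (abs(eta) < .ETA_EPS) return(0.5 + eta / 12)
  if (eta > 0) return(1 / (-expm1(-eta)) - 1 / eta)
  1 - .mean_cost_scalar(-eta)
}

#' Model variance of the normalized cost
#'
#' `Var[t; eta] = d E[t] / d eta = 1/eta^2 - exp(eta)/(exp(eta) - 1)^2`,
#' the exponential-family identity used for the Wald interval on the mean
#' cost. Symmetric in `eta`; equals 1/12 at `eta = 0` (series
#' `1/12 - eta^2/240` near 0).
#'
#' @inheritParams mean_normalized_cost
#' @return numeric vector of variances in `(0, 1/12]`.
#' @export
cost_variance <- function(eta) {
  stopifnot(is.numeric(eta), all(is.finite(eta)))
  vapply(eta, function(e) {
    e <- abs(e)
    if (e < 1e-3) return(1 / 12 - e^2 / 240)
    q <- exp(-e)
    1 / e^2 - q / (1 - q)^2
  }, numeric(1))
}

#' Continuum scale parameter implied by the discrete model
#'
#' The discrete-continuum equivalence `eta ~ (r - 1)(exp(mu) - 1)`,
#' obtained by matching the discretized logarithmic derivative of `chi`
#' with layer spacing `1/(r - 1)`. With the classical `r = 4` layers and
#' per-layer scaling ratio `exp(mu) = 3`, it gives `eta = 6`.
#'
#' Note that the exact algebraic identity between the two models is
#' `eta = r * mu` (see [circle_sizes()]); this function implements the
#' approximate correspondence through the scaling ratio, which is the one
#' used to interpret fitted `eta` values in terms of layer ratios.
#'
#' @param mu rescaled Lagrange multiplier of the discrete model.
#' @param r number of layers (integer >= 2).
#' @return `(r - 1) * (exp(mu) - 1)`.
#' @examples
#' eta_from_mu(log(3), 4)  # 6
#' @export
eta_from_mu <- function(mu, r) {
  stopifnot(is.numeric(mu), r >= 2, r == as.integer(r))
  (r - 1) * expm1(mu)
}

#' Exact continuum parameter equivalent to the discrete model
#'
#' The identity `chi(k/r; r*mu) = chi_k(mu, r)` holds exactly for all `k`,
#' so `eta = r * mu` is the continuum parameter whose cdf interpolates the
#' discrete circle sizes. Exposed alongside [eta_from_mu()]; the
#' approximate form is the conventional default for interpreting scaling
#' ratios.
#'
#' @inheritParams eta_from_mu
#' @export
eta_from_mu_exact <- function(mu, r) {
  stopifnot(is.numeric(mu), r >= 2, r == as.integer(r))
  r * mu
}
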