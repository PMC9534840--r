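#' Synthetic focal-follow grooming data with known eta
#'
#' @description
#' Generates observation datasets with the statistical structure the
#' analysis pipeline assumes: several non-interacting groups of
#' individuals, each ego allocating grooming across its groupmates
#' according to the continuum model at a known, per-ego `eta_true`, sampled
#' through the scan-sampling observation protocol (10-minute follows, 10
#' instantaneous scans, at most one groomee recorded per scan). This gives
#' every downstream estimate a ground truth, which is what the
#' parameter-recovery and coverage experiments exercise.
#'
#' The observation model is deliberately simple: on each scan the focal is
#' grooming with probability `grooming_propensity`, and the groomee is
#' drawn with probability proportional to the ego's latent per-alter rates
#' `s_i`. Per-follow binarization then gives each dyad a hit probability of
#' `1 - (1 - p_i)^n_scans`, an analytic expectation the tests check. A
#' small fraction of follows is drawn with duration of five minutes or
#' less so that the curation filter is exercised.
#'
#' @name synthetic-data
NULL

#' Draw normalized costs from the continuum model
#'
#' Inverse-transform sampling of the density `p(t) = eta*exp(eta*t) /
#' (exp(eta) - 1)` on `[0, 1]`: `t = log(1 + u*(exp(eta) - 1))/eta` with
#' `u` uniform. `eta = 0` (and `|eta|` below the series threshold) reduces
#' to uniform draws.
#'
#' @param n number of draws.
#' @param eta scale parameter (single finite real, `|eta| <= 700`).
#' @return numeric vector of `n` values in `[0, 1]`.
#' @export
sample_costs <- function(n, eta) {
  stopifnot(n >= 0, is.finite(eta), abs(eta) <= 700)
  u <- stats::runif(n)
  if (abs(eta) < 1e-9) return(u)
  log1p(u * expm1(eta)) / eta
}

#' Map normalized costs back to grooming rates
#'
#' Inverts the normalization `t = (s_max - s)/(s_max - s_min)`:
#' `s = s_max - t*(s_max - s_min)`, so `t = 0` maps to the strongest
#' investment `s_max` and `t = 1` to the weakest `s_min`. Only ratios of
#' the `s_i` matter downstream (per-scan probabilities are proportional to
#' `s_i`), so the defaults of 10 and 1 are arbitrary units.
#'
#' @param t_values numeric vector in `[0, 1]`.
#' @param s_max,s_min latent extreme investments, `s_max > s_min > 0`.
#' @return numeric vector of latent rates.
#' @export
costs_to_rates <- function(t_values, s_max = 10, s_min = 1) {
  stopifnot(is.numeric(t_values), all(t_values >= 0 & t_values <= 1))
  if (!(s_max > s_min && s_min > 0))
    stop("need s_max > s_min > 0; equal extremes make the cost map degenerate")
  s_max - t_values * (s_max - s_min)
}

#' Configuration of a synthetic observation study
#'
#' Defaults emulate the study design the pipeline targets: four
#' non-interacting groups of 26, 60, 11 and 14 individuals, roughly 300
#' retained focal follows per individual over the study period, 10-minute
#' follows with 10 scans, and per-ego `eta_true` drawn from a log-normal
#' spread centered near 4 (the typical fitted mode for chimpanzee grooming
#' networks), so all true values are positive.
#'
#' @param groups named integer vector: group sizes (names are group ids).
#' @param eta_true one of: a single number (shared by all egos); a
#'   function `f(n)` drawing `n` values; or a named list keyed by group id
#'   whose elements are numbers or functions. Default
#'   `function(n) rlnorm(n, log(4), 0.4)`.
#' @param follows_per_ego number of full-length follows per individual.
#' @param scans_per_follow scans per full-length follow.
#' @param follow_minutes duration of a full-length follow, in minutes.
#' @param grooming_propensity probability that a scan records grooming.
#' @param short_follow_frac fraction of additional short (<= 5 min) follows
#'   per ego, which curation should discard.
#' @param s_max,s_min latent extreme investments (arbitrary units).
#' @param alters_per_ego number of groupmates each ego grooms; `NULL`
#'   (default) means all groupmates.
#' @param seed integer seed fixing the full output.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(groups = c(g1 = 26L, g2 = 60L, g3 = 11L, g4 = 14L),
                             eta_true = function(n) stats::rlnorm(n, log(4), 0.4),
                             follows_per_ego = 300L,
                             scans_per_follow = 10L,
                             follow_minutes = 10,
                             grooming_propensity = 0.2,
                             short_follow_frac = 0.05,
                             s_max = 10, s_min = 1,
                             alters_per_ego = NULL,
                             seed = 1L) {
  stopifnot(all(groups >= 2), !is.null(names(groups)),
            follows_per_ego >= 1, scans_per_follow >= 1,
            follow_minutes > 0,
            grooming_propensity >= 0, grooming_propensity <= 1,
            short_follow_frac >= 0, short_follow_frac < 1,
            s_max > s_min, s_min > 0)
  structure(list(groups = groups, eta_true = eta_true,
                 follows_per_ego = as.integer(follows_per_ego),
                 scans_per_follow = as.integer(scans_per_follow),
                 follow_minutes = follow_minutes,
                 grooming_propensity = grooming_propensity,
                 short_follow_frac = short_follow_frac,
                 s_max = s_max, s_min = s_min,
                 alters_per_ego = alters_per_ego,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# resolve the eta_true specification into one value per ego
.draw_eta_true <- function(spec, ego_ids, group_ids) {
  n <- length(ego_ids)
  if (is.function(spec)) return(spec(n))
  if (is.numeric(spec) && length(spec) == 1L) return(rep(spec, n))
  if (is.list(spec)) {
    out <- numeric(n)
    for (g in unique(group_ids)) {
      idx <- which(group_ids == g)
      el <- spec[[g]]
      if (is.null(el)) stop("eta_true list has no entry for group ", g)
      out[idx] <- if (is.function(el)) el(length(idx)) else rep(el, length(idx))
    }
    return(out)
  }
  stop("unsupported `eta_true` specification")
}

#' Simulate a focal-follow observation study
#'
#' For each individual (acting in turn as ego), draws latent per-alter
#' rates from the continuum model at that ego's `eta_true`, then simulates
#' every focal follow scan by scan: with probability `grooming_propensity`
#' the scan records grooming, toward an alter chosen with probability
#' proportional to the rates. Short follows (1-5 minutes, one scan per
#' minute) are appended at rate `short_follow_frac`. The result
#' round-trips through [parse_observations()].
#'
#' @param config a [synthetic_config()].
#' @return object of class `grooming_simulation`: list with
#'   `observations` (an `observation_set`), `truth` (data frame `ego_id`,
#'   `group_id`, `eta_true`, `n_alters`), `groups` (data frame
#'   `individual_id`, `group_id`) and `config`.
#' @export
simulate_focal_observations <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)

  group_ids <- rep(names(config$groups), config$groups)
  ego_ids <- unlist(lapply(names(config$groups), function(g)
    sprintf("%s_i%02d", g, seq_len(config$groups[[g]]))), use.names = FALSE)
  eta_true <- .draw_eta_true(config$eta_true, ego_ids, group_ids)

  n_short <- round(config$short_follow_frac * config$follows_per_ego)
  start_date <- as.Date("2015-01-01")

  fl_list <- vector("list", length(ego_ids))
  ev_list <- vector("list", length(ego_ids))
  n_alters <- integer(length(ego_ids))

  for (i in seq_along(ego_ids)) {
    ego <- ego_ids[i]
    g <- group_ids[i]
    mates <- ego_ids[group_ids == g & ego_ids != ego]
    if (!is.null(config$alters_per_ego) &&
        config$alters_per_ego < length(mates))
      mates <- sample(mates, config$alters_per_ego)
    L <- length(mates)
    n_alters[i] <- L

    t_i <- sample_costs(L, eta_true[i])
    s_i <- costs_to_rates(t_i, config$s_max, config$s_min)
    p <- config$grooming_propensity * s_i / sum(s_i)

    n_f <- config$follows_per_ego + n_short
    dur <- c(rep(config$follow_minutes, config$follows_per_ego),
             if (n_short > 0) sample(1:5, n_short, replace = TRUE))
    n_sc <- c(rep(config$scans_per_follow, config$follows_per_ego),
              if (n_short > 0) pmin(dur[-seq_len(config$follows_per_ego)],
                                    config$scans_per_follow))
    follow_id <- sprintf("%s_f%04d", ego, seq_len(n_f))
    fl_list[[i]] <- data.frame(
      follow_id = follow_id, group_id = g, focal_id = ego,
      date = as.character(start_date + (seq_len(n_f) - 1L) %% 1460L),
      duration_minutes = dur, n_scans = as.integer(n_sc),
      stringsAsFactors = FALSE)

    total <- sum(n_sc)
    # category 1 = no grooming; categories 2..(L+1) = alters
    cat <- sample.int(L + 1L, total, replace = TRUE,
                      prob = c(1 - config$grooming_propensity, p))
    hit <- cat > 1L
    if (any(hit)) {
      ev_list[[i]] <- data.frame(
        follow_id = rep(follow_id, n_sc)[hit],
        scan_index = sequence(n_sc)[hit],
        behavior = "grooming",
        partner_id = mates[cat[hit] - 1L],
        minutes = 1,
        stringsAsFactors = FALSE)
    }
  }

  follows <- do.call(rbind, fl_list)
  events <- do.call(rbind, ev_list[!vapply(ev_list, is.null, logical(1))])
  if (is.null(events))
    events <- data.frame(follow_id = character(), scan_index = integer(),
                         behavior = character(), partner_id = character(),
                         minutes = numeric(), stringsAsFactors = FALSE)
  rownames(follows) <- rownames(events) <- NULL

  structure(list(
    observations = parse_observations(follows, events),
    truth = data.frame(ego_id = ego_ids, group_id = group_ids,
                       eta_true = eta_true, n_alters = n_alters,
                       stringsAsFactors = FALSE),
    groups = data.frame(individual_id = ego_ids, group_id = group_ids,
                        stringsAsFactors = FALSE),
    config = config), class = "grooming_simulation")
}

#' @export
print.grooming_simulation <- function(x, ...) {
  cat(sprintf("<grooming_simulation> %d individuals in %d groups, %d follows, %d grooming events\n",
              nrow(x$truth), length(unique(x$truth$group_id)),
              nrow(x$observations$follows), nrow(x$observations$events)))
  invisible(x)
}

#' Write a simulation to CSV files
#'
#' Emits `follows.csv`, `events.csv`, `groups.csv` and `truth.csv` into
#' `dir`; identical simulations produce byte-identical files.
#'
#' @param sim a `grooming_simulation`.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of file paths.
#' @export
write_observation_set <- function(sim, dir) {
  stopifnot(inherits(sim, "grooming_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("follows.csv", "events.csv", "groups.csv",
                            "truth.csv"))
  utils::write.csv(sim$observations$follows, paths[1], row.names = FALSE)
  utils::write.csv(sim$observations$events, paths[2], row.names = FALSE)
  utils::write.csv(sim$groups, paths[3], row.names = FALSE)
  utils::write.csv(sim$truth, paths[4], row.names = FALSE)
  invisible(paths)
}

#' Parameter-recovery experiment
#'
#' For each row of `grid`, repeatedly draws data at the row's `eta_true`
#' and sample size, fits the model, and aggregates bias, RMSE and
#' confidence-interval coverage with Monte-Carlo standard errors.
#'
#' Two modes: `"direct"` draws `L` normalized costs straight from the model
#' density and fits them (isolating estimator properties from observation
#' noise); `"pipeline"` simulates a full one-group observation study
#' (`L + 1` individuals so each ego has `L` alters), runs curation, and
#' fits every retained ego, pooling egos within a replicate.
#'
#' @param grid data frame with columns `eta_true` and `L`; a
#'   `follows_per_ego` column is honored in pipeline mode.
#' @param replicates replicates per grid row.
#' @param mode `"direct"` or `"pipeline"`.
#' @param delta half-tail probability of the intervals.
#' @param seed integer seed.
#' @param grooming_propensity per-scan grooming probability (pipeline mode).
#' @return data frame, one row per grid row: `eta_true`, `L`, `replicates`,
#'   `n_fits`, `n_failed`, `mean_eta_hat`, `bias`, `rmse`, `coverage`,
#'   `coverage_se`.
#' @export
recovery_experiment <- function(grid, replicates = 200,
                                mode = c("direct", "pipeline"),
                                delta = 0.025, seed = 1L,
                                grooming_propensity = 0.2) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(grid), nrow(grid) >= 1,
            all(c("eta_true", "L") %in% names(grid)))
  set.seed(seed)
  out <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    eta0 <- grid$eta_true[r]
    L <- grid$L[r]
    eta_hat <- cover <- numeric(0)
    n_failed <- 0L
    for (rep_i in seq_len(replicates)) {
      res <- tryCatch({
        if (mode == "direct") {
          f <- fit_costs(sample_costs(L, eta0), delta)
          if (f$degenerate) stop("degenerate sample")
          list(eta = f$eta_hat,
               cov = (f$ci_low <= eta0 && eta0 <= f$ci_high))
        } else {
          fpe <- if ("follows_per_ego" %in% names(grid))
            grid$follows_per_ego[r] else 300L
          cfg <- synthetic_config(
            groups = stats::setNames(as.integer(L + 1), "g1"),
            eta_true = eta0, follows_per_ego = fpe,
            grooming_propensity = grooming_propensity,
            seed = sample.int(.Machine$integer.max, 1))
          sim <- simulate_focal_observations(cfg)
          pl <- run_pipeline(sim$observations$follows,
                             sim$observations$events,
                             groups = sim$groups, delta = delta)
          ok <- pl$fits[!pl$fits$degenerate, ]
          if (!nrow(ok)) stop("no non-degenerate fits")
          list(eta = mean(ok$eta_hat),
               cov = mean(ok$ci_low <= eta0 & eta0 <= ok$ci_high))
        }
      }, error = function(e) NULL)
      if (is.null(res)) n_failed <- n_failed + 1L
      else { eta_hat <- c(eta_hat, res$eta); cover <- c(cover, res$cov) }
    }
    out[[r]] <- data.frame(
      eta_true = eta0, L = L, replicates = replicates,
      n_fits = length(eta_hat), n_failed = n_failed,
      mean_eta_hat = mean(eta_hat), bias = mean(eta_hat) - eta0,
      rmse = sqrt(mean((eta_hat - eta0)^2)),
      coverage = mean(cover),
      coverage_se = stats::sd(cover) / sqrt(length(cover)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
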