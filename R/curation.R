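#' Curation of focal-follow grooming observations
#'
#' @description
#' Turns raw scan-sampled focal-follow records into per-ego directed
#' grooming networks. The observation protocol emulated here is the
#' standard one in primate behavioral monitoring: 10-minute focal follows
#' scored at 10 instantaneous scan points, with grooming by the focal
#' individual recorded per scan together with the partner's identity.
#'
#' Curation proceeds in fixed stages: follows of 5 minutes or less are
#' discarded (visibility-truncated follows carry unreliable scan counts);
#' grooming is aggregated per dyad either binarized per follow (at most one
#' interaction per partner per follow, the primary criterion) or as summed
#' grooming minutes; directed ego-networks are built per group; and egos
#' that groomed fewer than five distinct partners are excluded from fitting
#' while remaining available as alters in others' networks.
#'
#' @name curation
NULL

#' An observation set: focal follows plus scan-level grooming events
#'
#' @param follows data frame with columns `follow_id`, `group_id`,
#'   `focal_id`, `date`, `duration_minutes`, `n_scans`.
#' @param events data frame with columns `follow_id`, `scan_index`,
#'   `behavior`, `partner_id` and optionally `minutes`.
#' @param n_ignored number of non-grooming event rows dropped at parse.
#' @return an object of class `observation_set`.
#' @keywords internal
new_observation_set <- function(follows, events, n_ignored = 0L) {
  structure(list(follows = follows, events = events,
                 n_ignored_events = n_ignored),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("<observation_set> %d follows, %d grooming events (%d non-grooming rows ignored)\n",
              nrow(x$follows), nrow(x$events), x$n_ignored_events))
  invisible(x)
}

.follow_cols <- c("follow_id", "group_id", "focal_id", "date",
                  "duration_minutes", "n_scans")
.event_cols <- c("follow_id", "scan_index", "behavior", "partner_id")

.read_table <- function(x, what) {
  if (is.data.frame(x)) return(x)
  if (!file.exists(x)) stop(sprintf("%s file not found: %s", what, x))
  utils::read.csv(x, stringsAsFactors = FALSE)
}

#' Parse focal-follow and grooming-event tables
#'
#' Reads the two observation tables (CSV paths or data frames), keeps only
#' grooming events, validates the schema and checks referential integrity:
#' every event must point at an existing follow, durations must be positive
#' numbers, scan indices must lie within the follow's scan count, and the
#' focal cannot be its own grooming partner. Duplicate
#' `(follow_id, scan_index, partner_id)` rows — multi-observer entry noise —
#' are collapsed to one with a warning.
#'
#' @param follows CSV path or data frame; columns `follow_id`, `group_id`,
#'   `focal_id`, `date`, `duration_minutes`, `n_scans`.
#' @param events CSV path or data frame; columns `follow_id`, `scan_index`,
#'   `behavior`, `partner_id`, optional `minutes`. Only rows with
#'   `behavior == "grooming"` are consumed; the number of other rows is
#'   recorded in the returned object.
#' @return an `observation_set`.
#' @export
parse_observations <- function(follows, events) {
  fl <- .read_table(follows, "follows")
  ev <- .read_table(events, "events")

  miss <- setdiff(.follow_cols, names(fl))
  if (length(miss))
    stop("follows table is missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(.event_cols, names(ev))
  if (length(miss))
    stop("events table is missing column(s): ", paste(miss, collapse = ", "))
  if (!"minutes" %in% names(ev)) ev$minutes <- NA_real_

  fl$duration_minutes <- suppressWarnings(as.numeric(fl$duration_minutes))
  fl$n_scans <- suppressWarnings(as.integer(fl$n_scans))
  bad <- which(!is.finite(fl$duration_minutes) | fl$duration_minutes <= 0)
  if (length(bad))
    stop(sprintf("follows row %d: non-numeric or non-positive duration_minutes (follow_id %s)",
                 bad[1], fl$follow_id[bad[1]]))
  if (anyDuplicated(fl$follow_id))
    stop("duplicate follow_id in follows table: ",
         fl$follow_id[anyDuplicated(fl$follow_id)])

  n_ignored <- sum(ev$behavior != "grooming")
  ev <- ev[ev$behavior == "grooming", , drop = FALSE]

  if (nrow(ev)) {
    orphan <- which(!ev$follow_id %in% fl$follow_id)
    if (length(orphan))
      stop(sprintf("events row %d: follow_id '%s' not present in follows table",
                   orphan[1], ev$follow_id[orphan[1]]))
    idx <- match(ev$follow_id, fl$follow_id)
    if (any(ev$partner_id == fl$focal_id[idx])) {
      bad <- which(ev$partner_id == fl$focal_id[idx])[1]
      stop(sprintf("events row %d: partner equals the focal individual ('%s')",
                   bad, ev$partner_id[bad]))
    }
    out_of_range <- which(ev$scan_index < 1 | ev$scan_index > fl$n_scans[idx])
    if (length(out_of_range))
      stop(sprintf("events row %d: scan_index %d outside [1, n_scans] of follow '%s'",
                   out_of_range[1], ev$scan_index[out_of_range[1]],
                   ev$follow_id[out_of_range[1]]))
    key <- paste(ev$follow_id, ev$scan_index, ev$partner_id, sep = "\r")
    if (anyDuplicated(key)) {
      warning(sprintf("collapsed %d duplicate (follow, scan, partner) event row(s)",
                      sum(duplicated(key))))
      ev <- ev[!duplicated(key), , drop = FALSE]
    }
  }
  rownames(fl) <- rownames(ev) <- NULL
  new_observation_set(fl, ev, as.integer(n_ignored))
}

#' Discard visibility-truncated follows
#'
#' Removes follows whose duration is `threshold_minutes` or less (the
#' boundary is inclusive: a 5-minute follow is discarded, a 6-minute follow
#' retained), together with their events. Idempotent.
#'
#' @param obs an `observation_set`.
#' @param threshold_minutes discard follows with duration `<=` this (default 5).
#' @return a filtered `observation_set`.
#' @export
discard_short_follows <- function(obs, threshold_minutes = 5) {
  stopifnot(inherits(obs, "observation_set"))
  keep <- obs$follows$duration_minutes > threshold_minutes
  fl <- obs$follows[keep, , drop = FALSE]
  ev <- obs$events[obs$events$follow_id %in% fl$follow_id, , drop = FALSE]
  rownames(fl) <- rownames(ev) <- NULL
  new_observation_set(fl, ev, obs$n_ignored_events)
}

#' Per-dyad binarized grooming counts
#'
#' The primary weighting criterion: within one focal follow a partner
#' contributes at most 1 regardless of how many scans showed grooming, and
#' counts are summed over all retained follows of the ego across the study
#' period. This unifies bouts that start or end outside the observation
#' window.
#'
#' @param obs an `observation_set` (after [discard_short_follows()]).
#' @return data frame `ego_id`, `alter_id`, `weight` (one row per dyad with
#'   positive weight), sorted by ego then alter.
#' @export
binarize_grooming <- function(obs) {
  .dyad_weights(obs, mode = "count")
}

#' Per-dyad grooming minutes
#'
#' Alternative weighting: each grooming bout contributes the number of
#' minutes it lasted within the observation window, summed per dyad. Events
#' missing a `minutes` value are scored at one minute per scan (follows are
#' 10 minutes with 10 scans, so one scan corresponds to one minute).
#'
#' @inheritParams binarize_grooming
#' @return data frame `ego_id`, `alter_id`, `weight` in minutes.
#' @export
weight_grooming_minutes <- function(obs) {
  .dyad_weights(obs, mode = "minutes")
}

#' Dyadic grooming weights under a selectable criterion
#'
#' @inheritParams binarize_grooming
#' @param mode `"count"` for per-follow binarized counts (default) or
#'   `"minutes"` for summed grooming minutes.
#' @return data frame `ego_id`, `alter_id`, `weight`.
#' @export
dyad_weights <- function(obs, mode = c("count", "minutes")) {
  .dyad_weights(obs, match.arg(mode))
}

.dyad_weights <- function(obs, mode) {
  stopifnot(inherits(obs, "observation_set"))
  ev <- obs$events
  if (!nrow(ev))
    return(data.frame(ego_id = character(), alter_id = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  idx <- match(ev$follow_id, obs$follows$follow_id)
  ev$ego_id <- obs$follows$focal_id[idx]
  if (mode == "count") {
    # at most one contribution per (follow, partner)
    ev <- ev[!duplicated(paste(ev$follow_id, ev$partner_id, sep = "\r")), ]
    ev$w <- 1
  } else {
    ev$w <- ifelse(is.na(ev$minutes), 1, ev$minutes)
    if (any(ev$w <= 0)) stop("grooming minutes must be positive")
  }
  agg <- stats::aggregate(w ~ ego_id + partner_id, data = ev, FUN = sum)
  out <- data.frame(ego_id = agg$ego_id, alter_id = agg$partner_id,
                    weight = agg$w, stringsAsFactors = FALSE)
  out[order(out$ego_id, out$alter_id), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' One ego's directed grooming network
#'
#' @param ego_id,group_id identifiers.
#' @param weights named numeric vector of positive grooming weights, names
#'   are alter ids.
#' @param n_follows number of retained follows of this ego (optional).
#' @return object of class `ego_network` with fields `ego_id`, `group_id`,
#'   `weights`, `L` (number of alters), `s_max`, `s_min`, `n_follows`.
#' @export
ego_network <- function(ego_id, group_id, weights, n_follows = NA_integer_) {
  stopifnot(is.numeric(weights), !is.null(names(weights)))
  weights <- weights[weights > 0]
  if (ego_id %in% names(weights))
    stop(sprintf("ego '%s' appears among its own alters", ego_id))
  structure(list(ego_id = ego_id, group_id = group_id,
                 weights = weights, L = length(weights),
                 s_max = if (length(weights)) max(weights) else NA_real_,
                 s_min = if (length(weights)) min(weights) else NA_real_,
                 n_follows = n_follows),
            class = "ego_network")
}

#' @export
print.ego_network <- function(x, ...) {
  cat(sprintf("<ego_network> %s (group %s): L = %d alters, s in [%g, %g]\n",
              x$ego_id, x$group_id, x$L, x$s_min, x$s_max))
  invisible(x)
}

#' Build per-ego directed grooming networks
#'
#' One `ego_network` per individual that appears as a grooming actor.
#' Individuals that appear only as partners get no network of their own but
#' remain as alters. Group membership must be consistent: a grooming dyad
#' crossing two groups is a data-integrity error (study populations do not
#' interact).
#'
#' @param weights data frame `ego_id`, `alter_id`, `weight` (positive), as
#'   returned by [dyad_weights()].
#' @param groups data frame `individual_id`, `group_id`, or a named vector
#'   mapping individual to group; if `NULL`, groups are inferred only when
#'   `follows` is supplied.
#' @param follows optional follows table used to infer groups and count
#'   retained follows per ego.
#' @return named list of `ego_network` objects (names are ego ids).
#' @export
build_ego_networks <- function(weights, groups = NULL, follows = NULL) {
  stopifnot(is.data.frame(weights),
            all(c("ego_id", "alter_id", "weight") %in% names(weights)))
  if (is.null(groups)) {
    if (is.null(follows))
      stop("supply `groups` or a `follows` table to infer group membership")
    groups <- stats::setNames(follows$group_id, follows$focal_id)
    groups <- groups[!duplicated(names(groups))]
  } else if (is.data.frame(groups)) {
    stopifnot(all(c("individual_id", "group_id") %in% names(groups)))
    groups <- stats::setNames(groups$group_id, groups$individual_id)
  }
  if (!nrow(weights)) return(stats::setNames(list(), character()))

  g_ego <- groups[weights$ego_id]
  g_alt <- groups[weights$alter_id]
  if (any(is.na(g_ego)))
    stop("no group assignment for ego '",
         weights$ego_id[which(is.na(g_ego))[1]], "'")
  cross <- which(!is.na(g_alt) & g_alt != g_ego)
  if (length(cross))
    stop(sprintf("cross-group grooming dyad %s -> %s (groups %s / %s)",
                 weights$ego_id[cross[1]], weights$alter_id[cross[1]],
                 g_ego[cross[1]], g_alt[cross[1]]))

  nf <- NULL
  if (!is.null(follows)) nf <- table(follows$focal_id)
  egos <- unique(weights$ego_id)
  nets <- lapply(egos, function(e) {
    w <- weights[weights$ego_id == e, ]
    ego_network(e, unname(groups[e]),
                stats::setNames(w$weight, w$alter_id),
                n_follows = if (is.null(nf)) NA_integer_
                            else as.integer(nf[e]))
  })
  stats::setNames(nets, egos)
}

#' Exclude egos with too few grooming partners
#'
#' Egos that groomed fewer than `min_partners` distinct individuals over
#' the study period are excluded from fitting — with so few relationships
#' the fit of the circle-size curve is meaningless — but the grooming they
#' received is untouched: excluded individuals remain as alters in the
#' retained egos' networks, whose `L`, `s_max` and `s_min` are unchanged.
#' Five is the canonical size of the innermost grooming circle in primates.
#'
#' @param networks named list of `ego_network` objects.
#' @param min_partners retain egos with `L >= min_partners` (default 5).
#' @return list with components `retained` and `excluded` (both named lists
#'   of `ego_network`), plus an `exclusions` data frame
#'   (`ego_id`, `group_id`, `L`, `n_follows`).
#' @export
filter_egos <- function(networks, min_partners = 5) {
  L <- vapply(networks, `[[`, integer(1), "L")
  keep <- L >= min_partners
  excl <- networks[!keep]
  exclusions <- data.frame(
    ego_id = vapply(excl, `[[`, character(1), "ego_id"),
    group_id = vapply(excl, function(n) as.character(n$group_id), character(1)),
    L = vapply(excl, `[[`, integer(1), "L"),
    n_follows = vapply(excl, `[[`, integer(1), "n_follows"),
    stringsAsFactors = FALSE, row.names = NULL)
  list(retained = networks[keep], excluded = excl, exclusions = exclusions)
}

#' Long-format edge list of a set of ego-networks
#'
#' @param networks named list of `ego_network` objects.
#' @return data frame `ego_id`, `alter_id`, `weight`, `group_id`.
#' @export
networks_to_edge_list <- function(networks) {
  if (!length(networks))
    return(data.frame(ego_id = character(), alter_id = character(),
                      weight = numeric(), group_id = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(networks, function(n) {
    data.frame(ego_id = n$ego_id, alter_id = names(n$weights),
               weight = unname(n$weights),
               group_id = as.character(n$group_id),
               stringsAsFactors = FALSE, row.names = NULL)
  })) -> out
  rownames(out) <- NULL
  out
}
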