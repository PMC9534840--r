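#' Pipeline orchestration and reporting
#'
#' @description
#' [run_pipeline()] chains parsing, curation, network construction and
#' per-ego fitting, keeping a reconciled count of what each stage dropped.
#' The remaining helpers produce the standard outputs of an ego-network
#' circle analysis: per-group `eta` histograms with regime and mean
#' reference lines, GraphML exports of fitted ego-networks, and fit plots
#' (empirical cost cdf, fitted `chi(t)`, confidence band) each backed by a
#' machine-readable table.
#'
#' @name reporting
NULL

#' Run the full curation-and-fitting pipeline
#'
#' parse -> discard short follows -> dyadic weights -> ego-networks ->
#' partner filter -> per-ego fits -> group summaries. Deterministic given
#' its inputs.
#'
#' @param follows,events CSV paths or data frames (see
#'   [parse_observations()]).
#' @param groups optional `individual_id`/`group_id` table; inferred from
#'   the follows table when `NULL`.
#' @param mode dyadic weighting: `"count"` (binarized per follow, default)
#'   or `"minutes"`.
#' @param min_follow_minutes discard follows of this duration or less.
#' @param min_partners minimum number of groomed partners for fitting.
#' @param delta half-tail probability of the confidence intervals.
#' @return list with `fits` (data frame, one row per retained ego),
#'   `group_summary` (see [summarize_groups()]), `networks` (retained
#'   `ego_network` list), `exclusions` (data frame of filtered egos) and
#'   `stage_counts` (named vector reconciling what each stage dropped).
#' @export
run_pipeline <- function(follows, events, groups = NULL,
                         mode = c("count", "minutes"),
                         min_follow_minutes = 5, min_partners = 5,
                         delta = 0.025) {
  mode <- match.arg(mode)
  obs <- parse_observations(follows, events)
  n_follows_in <- nrow(obs$follows)
  obs_kept <- discard_short_follows(obs, min_follow_minutes)
  w <- dyad_weights(obs_kept, mode)
  nets <- build_ego_networks(w, groups = groups, follows = obs_kept$follows)
  flt <- filter_egos(nets, min_partners)
  fits <- fit_egos(flt$retained, delta = delta, min_partners = min_partners)
  counts <- c(n_follows_in = n_follows_in,
              n_follows_short = n_follows_in - nrow(obs_kept$follows),
              n_follows_kept = nrow(obs_kept$follows),
              n_events = nrow(obs_kept$events),
              n_events_ignored = obs$n_ignored_events,
              n_egos_pre_filter = length(nets),
              n_retained = length(flt$retained),
              n_excluded = length(flt$excluded),
              n_degenerate = sum(fits$degenerate))
  list(fits = fits,
       group_summary = summarize_groups(fits, flt$exclusions),
       networks = flt$retained,
       exclusions = flt$exclusions,
       stage_counts = counts)
}

#' Per-group summary of fitted eta values
#'
#' @param fits fits data frame from [fit_egos()] or [run_pipeline()].
#' @param exclusions optional exclusions data frame (to report pre-filter
#'   ego counts).
#' @param bin_width histogram bin width used for the modal eta (default 1).
#' @return data frame, one row per group: `group_id`, `n_pre_filter`,
#'   `n_retained`, `n_degenerate`, `eta_mean`, `eta_mode` (center of the
#'   fullest histogram bin), `n_inverted` (`eta_hat < 0`), `n_boundary`
#'   (interval straddles 0).
#' @export
summarize_groups <- function(fits, exclusions = NULL, bin_width = 1) {
  gs <- sort(unique(c(fits$group_id,
                      if (!is.null(exclusions)) exclusions$group_id)))
  rows <- lapply(gs, function(g) {
    f <- fits[fits$group_id == g & !fits$degenerate, ]
    n_excl <- if (is.null(exclusions)) 0L
              else sum(exclusions$group_id == g)
    n_ret <- sum(fits$group_id == g)
    data.frame(group_id = g,
               n_pre_filter = n_ret + n_excl,
               n_retained = n_ret,
               n_degenerate = n_ret - nrow(f),
               eta_mean = if (nrow(f)) mean(f$eta_hat) else NA_real_,
               eta_mode = if (nrow(f)) .hist_mode(f$eta_hat, bin_width)
                          else NA_real_,
               n_inverted = sum(f$eta_hat < 0),
               n_boundary = sum(f$regime == "boundary"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.hist_breaks <- function(x, bin_width) {
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  seq(lo, hi, by = bin_width)
}

.hist_mode <- function(x, bin_width) {
  h <- graphics::hist(x, breaks = .hist_breaks(x, bin_width), plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Binned eta histogram with reference lines
#'
#' Bins the fitted `eta` values of one group on a fixed-width grid and
#' records the two reference lines of the standard display: the regime
#' change at `eta = 0` and the group mean.
#'
#' @param eta_values numeric vector of fitted eta values (or a fits data
#'   frame, in which case non-degenerate `eta_hat` values are used).
#' @param bin_width bin width in eta units (default 1).
#' @return data frame `bin_low`, `bin_high`, `bin_mid`, `count`; attributes
#'   `eta_mean` (mean reference line), `regime_line` (0) and `n`.
#' @export
eta_histogram <- function(eta_values, bin_width = 1) {
  if (is.data.frame(eta_values))
    eta_values <- eta_values$eta_hat[!eta_values$degenerate]
  if (!length(eta_values)) {
    warning("no fitted eta values; empty histogram")
    out <- data.frame(bin_low = numeric(), bin_high = numeric(),
                      bin_mid = numeric(), count = integer())
  } else {
    br <- .hist_breaks(eta_values, bin_width)
    h <- graphics::hist(eta_values, breaks = br, plot = FALSE)
    out <- data.frame(bin_low = utils::head(br, -1), bin_high = br[-1],
                      bin_mid = h$mids, count = h$counts)
  }
  attr(out, "eta_mean") <- if (length(eta_values)) mean(eta_values) else NA_real_
  attr(out, "regime_line") <- 0
  attr(out, "n") <- length(eta_values)
  out
}

#' Export a fitted ego-network to GraphML
#'
#' Writes the directed star ego -> alters with per-edge `weight` (the
#' grooming investment `s_i`) and graph-level attributes `ego_id`,
#' `eta_hat` and `regime`, readable by any GraphML consumer.
#'
#' @param network an [ego_network()].
#' @param fit the matching `continuum_fit` (may be degenerate).
#' @param path output file path (`.graphml`).
#' @return invisibly, the igraph object written.
#' @export
export_ego_network <- function(network, fit, path) {
  stopifnot(inherits(network, "ego_network"),
            inherits(fit, "continuum_fit"))
  edges <- data.frame(from = network$ego_id, to = names(network$weights),
                      weight = unname(network$weights),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  g <- igraph::set_graph_attr(g, "ego_id", network$ego_id)
  g <- igraph::set_graph_attr(g, "eta_hat",
                              if (fit$degenerate) NA_real_ else fit$eta_hat)
  g <- igraph::set_graph_attr(g, "regime",
                              if (is.na(fit$regime)) "degenerate" else fit$regime)
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}

#' Fit plot with machine-readable backing tables
#'
#' Writes the backing data of the standard fit display — the fitted
#' `chi(t)` curve with its confidence band on a regular `t` grid, and the
#' empirical cost-cdf step points — as CSV files, and (when ggplot2 is
#' available) renders the figure. Degenerate fits are skipped with a
#' message.
#'
#' @param fit a `continuum_fit` carrying its `t_values`.
#' @param file_prefix path prefix; writes `<prefix>_curve.csv`,
#'   `<prefix>_points.csv` and, if possible, `<prefix>_fit.png`.
#' @param t_grid grid on which the curve and band are tabulated.
#' @return invisibly, a list with `curve` and `points` data frames (`NULL`
#'   for a degenerate fit).
#' @export
plot_fit <- function(fit, file_prefix,
                     t_grid = seq(0, 1, by = 0.01)) {
  stopifnot(inherits(fit, "continuum_fit"))
  if (fit$degenerate) {
    message(sprintf("skipping degenerate fit for ego '%s' (%s)",
                    fit$ego_id, fit$reason))
    return(invisible(NULL))
  }
  curve <- fit_band(fit, t_grid)
  points <- empirical_cost_cdf(fit$t_values)
  utils::write.csv(curve, paste0(file_prefix, "_curve.csv"),
                   row.names = FALSE)
  utils::write.csv(points, paste0(file_prefix, "_points.csv"),
                   row.names = FALSE)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    p <- ggplot2::ggplot(curve, ggplot2::aes(x = t)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                           fill = "steelblue", alpha = 0.25) +
      ggplot2::geom_line(ggplot2::aes(y = chi), colour = "steelblue",
                         linetype = "dashed") +
      ggplot2::geom_point(data = points,
                          ggplot2::aes(x = t, y = fraction),
                          colour = "firebrick") +
      ggplot2::labs(x = "normalized cost t",
                    y = expression(chi(t)),
                    title = sprintf("%s: eta = %.2f [%.2f, %.2f]",
                                    fit$ego_id, fit$eta_hat,
                                    fit$ci_low, fit$ci_high)) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(paste0(file_prefix, "_fit.png"), p,
                    width = 5, height = 4, dpi = 150)
  }
  invisible(list(curve = curve, points = points))
}

#' Write the standard report bundle of a pipeline run
#'
#' Emits `fits.csv`, `group_summary.csv`, `exclusions.csv`, a long-format
#' `networks.csv` edge list and per-ego GraphML files into `out_dir`.
#'
#' @param pipeline result of [run_pipeline()].
#' @param out_dir output directory (created if missing).
#' @param graphml also write one `.graphml` per retained ego (default
#'   `FALSE`; can be many files).
#' @return invisibly, the output directory.
#' @export
write_report <- function(pipeline, out_dir, graphml = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(pipeline$fits, file.path(out_dir, "fits.csv"),
                   row.names = FALSE)
  utils::write.csv(pipeline$group_summary,
                   file.path(out_dir, "group_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(pipeline$exclusions,
                   file.path(out_dir, "exclusions.csv"), row.names = FALSE)
  utils::write.csv(networks_to_edge_list(pipeline$networks),
                   file.path(out_dir, "networks.csv"), row.names = FALSE)
  if (graphml) {
    fits <- attr(pipeline$fits, "fits")
    for (id in names(pipeline$networks))
      export_ego_network(pipeline$networks[[id]], fits[[id]],
                         file.path(out_dir, paste0(id, ".graphml")))
  }
  invisible(out_dir)
}
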