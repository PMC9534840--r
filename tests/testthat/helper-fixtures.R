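# Hand-built toy observation study, small enough to curate by hand.
#
# Group "grp", egos A, B, C:
#   A: 10 full follows; grooms B in all 10 (3 scans of it in fA01),
#      C in 5, D in 2, E in 2, F in 1  -> counts (10, 5, 2, 2, 1)
#   B: grooms only 4 partners -> excluded by the partner filter (L = 4)
#   C: one 5-minute follow (discarded, its groomee Z with it), one 6-minute
#      follow (retained), final counts A = 3, B/D/E/F = 1 -> L = 5
# One non-grooming ("proximity") event row is ignored at parse.

toy_follows <- function() {
  rbind(
    data.frame(follow_id = sprintf("fA%02d", 1:10), group_id = "grp",
               focal_id = "A", date = sprintf("2016-01-%02d", 1:10),
               duration_minutes = 10, n_scans = 10L),
    data.frame(follow_id = sprintf("fB%02d", 1:3), group_id = "grp",
               focal_id = "B", date = sprintf("2016-02-%02d", 1:3),
               duration_minutes = 10, n_scans = 10L),
    data.frame(follow_id = sprintf("fC%02d", 1:4), group_id = "grp",
               focal_id = "C", date = sprintf("2016-03-%02d", 1:4),
               duration_minutes = c(10, 5, 10, 6), n_scans = c(10L, 5L, 10L, 6L))
  )
}

toy_events <- function() {
  ev <- function(follow, scan, partner, behavior = "grooming", minutes = 1)
    data.frame(follow_id = follow, scan_index = scan, behavior = behavior,
               partner_id = partner, minutes = minutes)
  rbind(
    # ego A
    ev(sprintf("fA%02d", 1:10), 1, "B"),
    ev("fA01", 2, "B"), ev("fA01", 3, "B"),   # same follow: binarizes to 1
    ev(sprintf("fA%02d", 1:5), 4, "C"),
    ev(sprintf("fA%02d", 1:2), 5, "D"),
    ev(sprintf("fA%02d", 3:4), 5, "E"),
    ev("fA05", 6, "F"),
    ev("fA01", 7, "C", behavior = "proximity"),  # ignored at parse
    # ego B: only 4 partners
    ev("fB01", 1, "A"), ev("fB01", 2, "C"),
    ev("fB02", 1, "D"), ev("fB03", 1, "E"),
    # ego C
    ev("fC01", 1, "A"), ev("fC01", 2, "D"), ev("fC01", 3, "E"),
    ev("fC02", 1, "Z"),                       # follow discarded with its event
    ev("fC03", 1, "A"), ev("fC03", 2, "B"), ev("fC03", 3, "F"),
    ev("fC04", 2, "A")
  )
}

toy_groups <- function() {
  data.frame(individual_id = c("A", "B", "C", "D", "E", "F", "Z"),
             group_id = "grp")
}

# classic 5-alter network with counts (10, 5, 2, 2, 1):
# sigma = 4, t_bar = 2/3, t = (0, 5/9, 8/9, 8/9, 1)
toy_network <- function() {
  ego_network("A", "grp", c(B = 10, C = 5, D = 2, E = 2, F = 1))
}

# Independent oracles for the mean-cost equation, written from the closed
# form (naive evaluation; adequate for moderate eta) rather than through
# the package's overflow-safe code paths.
oracle_mean_cost <- function(eta) {
  if (eta == 0) return(0.5)
  exp(eta) / (exp(eta) - 1) - 1 / eta
}

oracle_solve_eta <- function(t_bar, lo = -200, hi = 200) {
  f <- function(e) oracle_mean_cost(e) - t_bar
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# deterministic "sample" at the model quantiles (midpoint probabilities),
# so the sample mean is essentially E[t] at any L
sample_costs_quantiles <- function(L, eta) {
  p <- (seq_len(L) - 0.5) / L
  log1p(p * expm1(eta)) / eta
}

# log-likelihood of n iid normalized costs under the continuum density
# p(t) = eta * exp(eta * t) / (exp(eta) - 1)
oracle_loglik <- function(eta, t) {
  if (eta == 0) return(0)
  length(t) * (log(abs(eta)) - log(abs(expm1(eta)))) + eta * sum(t)
}
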