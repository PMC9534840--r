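test_that("parsing handles empty, identity, and malformed inputs", {
  hdr_f <- toy_follows()[0, ]
  hdr_e <- toy_events()[0, ]
  obs <- parse_observations(hdr_f, hdr_e)
  expect_s3_class(obs, "observation_set")
  expect_identical(nrow(obs$follows), 0L)
  expect_identical(nrow(obs$events), 0L)

  fl <- data.frame(follow_id = "f1", group_id = "g", focal_id = "A",
                   date = "2016-01-01", duration_minutes = 10, n_scans = 10L)
  ev <- data.frame(follow_id = "f1", scan_index = 1:3, behavior = "grooming",
                   partner_id = c("B", "C", "B"), minutes = 1)
  obs <- parse_observations(fl, ev)
  expect_identical(nrow(obs$follows), 1L)
  expect_identical(nrow(obs$events), 3L)

  # referential integrity: event pointing at a missing follow
  ev_bad <- ev; ev_bad$follow_id[2] <- "nope"
  expect_error(parse_observations(fl, ev_bad), "row 2.*nope")
  # missing column
  expect_error(parse_observations(fl[, -5], ev), "duration_minutes")
  # non-numeric duration
  fl_bad <- fl; fl_bad$duration_minutes <- "ten"
  expect_error(parse_observations(fl_bad, ev), "duration_minutes")
  # focal grooming itself
  ev_self <- ev; ev_self$partner_id[1] <- "A"
  expect_error(parse_observations(fl, ev_self), "focal")
  # scan index beyond the follow's scan count
  ev_scan <- ev; ev_scan$scan_index[1] <- 11L
  expect_error(parse_observations(fl, ev_scan), "scan_index")
})

test_that("duplicate (follow, scan, partner) rows collapse with a warning", {
  fl <- toy_follows()
  ev <- rbind(toy_events(), toy_events()[1, ])
  expect_warning(obs <- parse_observations(fl, ev), "duplicate")
  expect_identical(nrow(obs$events), nrow(parse_observations(fl, toy_events())$events))
})

test_that("non-grooming behavior rows are ignored but counted", {
  obs <- parse_observations(toy_follows(), toy_events())
  expect_identical(obs$n_ignored_events, 1L)
  expect_true(all(obs$events$behavior == "grooming"))
})

test_that("short-follow discard uses a strict 5-minute boundary and is idempotent", {
  obs <- parse_observations(toy_follows(), toy_events())
  kept <- discard_short_follows(obs)
  # the 5-minute follow goes, the 6- and 10-minute follows stay
  expect_false("fC02" %in% kept$follows$follow_id)
  expect_true(all(c("fC04", "fA01") %in% kept$follows$follow_id))
  expect_identical(nrow(kept$follows), nrow(obs$follows) - 1L)
  # its events go with it
  expect_false("Z" %in% kept$events$partner_id)
  # idempotence
  again <- discard_short_follows(kept)
  expect_identical(again$follows, kept$follows)
  expect_identical(again$events, kept$events)
})

test_that("binarized counts score one per follow-partner pair and aggregate over follows", {
  obs <- discard_short_follows(parse_observations(toy_follows(), toy_events()))
  w <- binarize_grooming(obs)
  wa <- w[w$ego_id == "A", ]
  expect_equal(stats::setNames(wa$weight, wa$alter_id),
               c(B = 10, C = 5, D = 2, E = 2, F = 1))
  wc <- w[w$ego_id == "C", ]
  expect_equal(stats::setNames(wc$weight, wc$alter_id),
               c(A = 3, B = 1, D = 1, E = 1, F = 1))
  # conservation: total count = number of (follow, partner) pairs with >= 1 scan
  pairs <- unique(obs$events[, c("follow_id", "partner_id")])
  expect_equal(sum(w$weight), nrow(pairs))
})

test_that("minute weighting sums scan-minutes per dyad", {
  obs <- discard_short_follows(parse_observations(toy_follows(), toy_events()))
  w <- weight_grooming_minutes(obs)
  wa <- w[w$ego_id == "A", ]
  # B was groomed on 3 scans of fA01 and 1 scan of each other follow: 12 min
  expect_equal(stats::setNames(wa$weight, wa$alter_id),
               c(B = 12, C = 5, D = 2, E = 2, F = 1))
  # explicit bout minutes are honored
  fl <- toy_follows()[1:2, ]
  ev <- data.frame(follow_id = c("fA01", "fA02"), scan_index = 1L,
                   behavior = "grooming", partner_id = "B", minutes = c(2, 4))
  w2 <- weight_grooming_minutes(parse_observations(fl, ev))
  expect_equal(w2$weight, 6)
})

test_that("curation output is invariant under permutation of input rows", {
  set.seed(11)
  fl <- toy_follows(); ev <- toy_events()
  obs1 <- discard_short_follows(parse_observations(fl, ev))
  obs2 <- discard_short_follows(
    parse_observations(fl[sample(nrow(fl)), ], ev[sample(nrow(ev)), ]))
  expect_equal(binarize_grooming(obs1), binarize_grooming(obs2))
})

test_that("ego-networks are built per actor with alters preserved", {
  w <- data.frame(ego_id = c("A", "A"), alter_id = c("B", "C"),
                  weight = c(10, 5))
  groups <- data.frame(individual_id = c("A", "B", "C"), group_id = "g1")
  nets <- build_ego_networks(w, groups)
  expect_named(nets, "A")
  expect_equal(nets$A$L, 2L)
  expect_equal(nets$A$s_max, 10)
  expect_equal(nets$A$s_min, 5)
  # B and C appear only as partners: no networks of their own
  expect_false(any(c("B", "C") %in% names(nets)))
  # empty weights -> empty collection
  expect_length(build_ego_networks(w[0, ], groups), 0)
  # cross-group dyad is a data-integrity error
  groups$group_id <- c("g1", "g1", "g2")
  expect_error(build_ego_networks(w, groups), "cross-group")
})

test_that("partner filter excludes below five but leaves retained networks untouched", {
  obs <- discard_short_follows(parse_observations(toy_follows(), toy_events()))
  nets <- build_ego_networks(binarize_grooming(obs), toy_groups(),
                             follows = obs$follows)
  flt <- filter_egos(nets)
  expect_setequal(names(flt$retained), c("A", "C"))
  expect_identical(flt$exclusions$ego_id, "B")
  expect_identical(flt$exclusions$L, 4L)
  # exclusion leaves the retained egos' weights, L and extremes unchanged;
  # the excluded ego B is still an alter of both A and C
  expect_identical(flt$retained$A, nets$A)
  expect_identical(flt$retained$C, nets$C)
  expect_true("B" %in% names(flt$retained$A$weights))
  expect_true("B" %in% names(flt$retained$C$weights))
  # boundary: exactly five partners is retained
  expect_true(flt$retained$C$L == 5L)
})

test_that("an ego cannot be its own alter", {
  expect_error(ego_network("A", "g", c(A = 1, B = 2)), "own alters")
})
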