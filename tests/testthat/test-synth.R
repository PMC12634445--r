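test_that("noise-free stimulus-only limit makes every participant identical", {
  cfg <- synth_config(n_participants = 4, n_regions = 2, n_runs = 1,
                      timepoints_per_run = 30, alpha = 1, beta = 0,
                      sigma = 0, seed = 5)
  ts <- generate_timeseries(cfg)
  mats <- ts$series
  for (m in mats[-1]) expect_equal(m, mats[[1]])
  isc <- compute_isc(ts)
  expect_equal(isc$isc_raw, rep(1, nrow(isc)), tolerance = 1e-12)
})

test_that("empirical ISC matches the closed form at long series", {
  cfg <- synth_config(n_participants = 8, n_regions = 1, n_runs = 1,
                      timepoints_per_run = 10000, n_communities = 2,
                      alpha = 1, beta = 1, sigma = 1, effect_regions = 1,
                      seed = 42)
  isc <- compute_isc(generate_timeseries(cfg))
  dy <- community_dyads(cfg)
  isc <- dplyr::left_join(isc, dy, by = c("dyad_i", "dyad_j"))
  expect_lt(abs(mean(isc$isc_raw[isc$same_comm]) - 2 / 3), 0.02)
  expect_lt(abs(mean(isc$isc_raw[!isc$same_comm]) - 1 / 3), 0.02)
})

test_that("closed-form ISC holds across a loading grid and under AR(1) noise", {
  grid <- list(c(1, 0, 1, 0), c(0.5, 1, 1, 0), c(1, 1, 2, 0), c(1, 1, 1, 0.4))
  for (g in grid) {
    cfg <- synth_config(n_participants = 6, n_regions = 1, n_runs = 1,
                        timepoints_per_run = 4000, n_communities = 2,
                        alpha = g[1], beta = g[2], sigma = g[3], ar1 = g[4],
                        effect_regions = 1, seed = 19)
    isc <- compute_isc(generate_timeseries(cfg))
    dy <- community_dyads(cfg)
    isc <- dplyr::left_join(isc, dy, by = c("dyad_i", "dyad_j"))
    for (same in c(TRUE, FALSE)) {
      expect_lt(abs(mean(isc$isc_raw[isc$same_comm == same]) -
                      expected_isc(cfg, same)), 0.03,
                label = paste("loadings", paste(g, collapse = "/"),
                              "same =", same))
    }
  }
})

test_that("non-effect regions carry no community signal", {
  cfg <- synth_config(n_participants = 6, n_regions = 2, n_runs = 1,
                      timepoints_per_run = 5000, n_communities = 2,
                      alpha = 1, beta = 2, sigma = 1, effect_regions = 1,
                      seed = 8)
  isc <- compute_isc(generate_timeseries(cfg))
  dy <- community_dyads(cfg)
  isc <- dplyr::left_join(isc, dy, by = c("dyad_i", "dyad_j"))
  r2 <- isc[isc$region == "r002", ]
  expect_lt(abs(mean(r2$isc_raw[r2$same_comm]) -
                  expected_isc(cfg, TRUE, effect_region = FALSE)), 0.03)
  expect_lt(abs(mean(r2$isc_raw[r2$same_comm]) -
                  mean(r2$isc_raw[!r2$same_comm])), 0.04)
})

test_that("generation is deterministic given the seed and varies across seeds", {
  cfg <- mini_config(seed = 3)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$timeseries$series, s2$timeseries$series)
  expect_identical(s1$networks, s2$networks)
  expect_identical(s1$ratings, s2$ratings)
  s3 <- simulate_study(mini_config(seed = 4))
  expect_false(identical(s1$timeseries$series[[1]], s3$timeseries$series[[1]]))
})

test_that("nomination rosters are simple directed relations", {
  cfg <- mini_config(seed = 6)
  nets <- generate_networks(cfg)
  expect_true(all(nets$src != nets$dst))
  expect_identical(nrow(dplyr::distinct(nets)), nrow(nets))
  expect_true(all(c(nets$src, nets$dst) %in% cfg$participants))
})

test_that("degenerate tie probabilities give the expected graphs", {
  cfg <- synth_config(n_participants = 5, n_regions = 1, n_runs = 1,
                      timepoints_per_run = 10, tie_p_within = 1,
                      tie_p_between = 1, churn_form = 0, churn_dissolve = 0,
                      seed = 2)
  nets <- generate_networks(cfg)
  for (w in c("T2", "T3")) {
    expect_identical(sum(nets$wave == w), 5L * 4L)
  }
  g <- build_reciprocal_graph(dplyr::filter(nets, wave == "T2"),
                              cfg$participants)
  d <- geodesic_distances(g)
  expect_true(all(d$distance == 1))
  # churn-free: identical waves, all change categories "same"
  dy <- study_dyads(nets, cfg$participants)
  expect_true(all(dy$change_category == "same"))
})

test_that("planted homophily yields denser within-community nominations", {
  cfg <- synth_config(n_participants = 40, n_regions = 1, n_runs = 1,
                      timepoints_per_run = 10, n_communities = 4,
                      tie_p_within = 0.8, tie_p_between = 0.05, seed = 11)
  nets <- dplyr::filter(generate_networks(cfg), wave == "T2")
  comm <- cfg$community
  same <- comm[match(nets$src, cfg$participants)] ==
    comm[match(nets$dst, cfg$participants)]
  n_within_pairs <- sum(outer(comm, comm, "==")) - length(comm)
  n_between_pairs <- length(comm)^2 - length(comm) - n_within_pairs
  expect_gt(sum(same) / n_within_pairs, sum(!same) / n_between_pairs)
})

test_that("ratings are integer Likert values whose structure tracks coupling", {
  cfg <- mini_config(seed = 9)
  rt <- generate_ratings(cfg)
  expect_true(all(rt$enjoyment %in% 1:5))
  expect_true(all(rt$interest %in% 1:5))
  expect_identical(nrow(rt), cfg$n_participants * 14L)

  # full coupling: ratings are a pure community profile
  cfg1 <- synth_config(n_participants = 8, n_communities = 2,
                       rating_coupling = 1, seed = 9)
  d1 <- dplyr::left_join(rating_similarity(generate_ratings(cfg1), "enjoyment"),
                         community_dyads(cfg1), by = c("dyad_i", "dyad_j"))
  expect_true(all(d1$rating_distance[d1$same_comm] == 0))
  expect_true(all(d1$rating_distance[!d1$same_comm] > 0))

  # constant ratings: all dyadic distances are zero
  const <- tidyr::expand_grid(participant = cfg$participants, stimulus = 1:14)
  const$enjoyment <- 3L
  expect_true(all(rating_similarity(const, "enjoyment")$rating_distance == 0))
})

test_that("demographics are more concordant within communities when coupled", {
  cfg <- synth_config(n_participants = 40, n_communities = 4,
                      rating_coupling = 0.9, seed = 21)
  demo <- generate_demographics(cfg)
  dy <- community_dyads(cfg)
  g <- demo$gender[match(dy$dyad_i, demo$participant)] ==
    demo$gender[match(dy$dyad_j, demo$participant)]
  m <- demo$major[match(dy$dyad_i, demo$participant)] ==
    demo$major[match(dy$dyad_j, demo$participant)]
  expect_gt(mean(g[dy$same_comm]), mean(g[!dy$same_comm]))
  expect_gt(mean(m[dy$same_comm]), mean(m[!dy$same_comm]))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(synth_config(alpha = -1), "non-negative")
  expect_error(synth_config(alpha = NaN), "finite")
  expect_error(synth_config(tie_p_within = 1.5), "probability")
  expect_error(synth_config(n_participants = 3), "at least 4")
  expect_error(synth_config(effect_regions = 999), "region indices")
  expect_identical(expected_isc(synth_config(alpha = 1, beta = 1, sigma = 1,
                                             effect_regions = 1), TRUE),
                   2 / 3)
})
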