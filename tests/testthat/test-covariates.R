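test_that("rating similarity is the Euclidean distance across stimuli", {
  mk <- function(scores) {
    tidyr::expand_grid(participant = c("a", "b"), stimulus = 1:14) |>
      dplyr::mutate(enjoyment = ifelse(participant == "a",
                                       scores[[1]], scores[[2]]))
  }
  expect_identical(rating_similarity(mk(list(3L, 3L)), "enjoyment")$rating_distance, 0)
  expect_equal(rating_similarity(mk(list(1L, 5L)), "enjoyment")$rating_distance,
               sqrt(224))
  # identical stimulus reordering leaves the distance unchanged
  r <- mk(list(1L, 5L))
  r$enjoyment <- r$enjoyment + rep(c(0L, 1L), 14)
  perm <- withr::with_seed(3, sample(14))
  r2 <- dplyr::mutate(r, stimulus = perm[stimulus])
  expect_equal(rating_similarity(r, "enjoyment")$rating_distance,
               rating_similarity(r2, "enjoyment")$rating_distance)
})

test_that("demographic similarity encodings match a hand-built oracle", {
  demo <- tibble::tibble(
    participant = c("a", "b", "c", "d"),
    age = c(28, 28, 31, 25),
    gender = c("f", "f", "m", "f"),
    nationality = c("USA", "Peru", "USA", "USA"),
    hometown_location = c("west", "west", "south", "abroad"),
    hometown_population = c(1e5, 1e6, 1e5, 1e3),
    alma_mater_location = c("west", "south", "south", "west"),
    institution_type = c("private", "public", "private", "private"),
    major = c("econ", "econ", "hum", "sci"),
    industry = c("fin", "tech", "fin", "fin")
  )
  got <- demographic_similarities(demo)
  z <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  # dyad order: ab, ac, ad, bc, bd, cd
  expect_equal(got$age_sim, z(-abs(c(0, 3, 3, 3, 3, 6))))
  expect_equal(got$gender_sim, z(c(1, 0, 1, 0, 1, 0)))
  expect_equal(got$hometown_population_sim, z(-abs(c(1, 0, 2, 1, 3, 2))))
  expect_equal(got$major_sim, z(c(1, 0, 0, 0, 0, 0)))
  sub <- demographic_similarities(demo, variables = c("gender", "age"))
  expect_identical(names(sub), c("dyad_i", "dyad_j", "gender_sim", "age_sim"))
})

test_that("residualization matches ordinary least squares exactly", {
  ids <- letters[1:5]
  pairs <- dyad_pairs(ids)
  withr::with_seed(9, {
    y <- rnorm(10)
    x <- rnorm(10)
  })
  isc <- manual_isc(ids, list(r1 = y))
  # ISC exactly linear in the covariate -> residuals all zero
  isc_lin <- manual_isc(ids, list(r1 = 2 * x - 1))
  cov_t <- dplyr::mutate(pairs, cov = x)
  r_lin <- residualize_isc(isc_lin, cov_t)
  expect_equal(r_lin$isc_normalized_resid, rep(0, 10), tolerance = 1e-12)
  # orthogonal covariate (zero sample correlation) -> centered values
  x_orth <- stats::residuals(stats::lm(x ~ y))
  r_orth <- residualize_isc(isc, dplyr::mutate(pairs, cov = x_orth))
  expect_equal(r_orth$isc_normalized_resid, y - mean(y), tolerance = 1e-10)
})

test_that("residuals agree with the normal-equations oracle on a larger fixture", {
  ids <- letters[1:8]  # 28 dyads
  pairs <- dyad_pairs(ids)
  withr::with_seed(23, {
    y <- rnorm(28)
    X <- matrix(rnorm(28 * 3), 28, 3)
  })
  isc <- manual_isc(ids, list(r1 = y))
  cov_t <- dplyr::bind_cols(pairs, tibble::as_tibble(X, .name_repair = ~paste0("c", 1:3)))
  got <- residualize_isc(isc, cov_t)$isc_normalized_resid
  M <- cbind(1, X)
  beta <- solve(t(M) %*% M, t(M) %*% y)
  expect_equal(got, as.numeric(y - M %*% beta), tolerance = 1e-10)
  # collinear column is dropped with a warning, order-stable
  cov_bad <- dplyr::mutate(cov_t, c4 = c1 + c2)
  expect_warning(got2 <- residualize_isc(isc, cov_bad), "Collinear")
  expect_equal(got2$isc_normalized_resid, got, tolerance = 1e-10)
})

test_that("controlled difference obeys the OLS projection identity", {
  cfg <- synth_config(n_participants = 10, n_regions = 1, n_runs = 1,
                      timepoints_per_run = 60, n_communities = 2,
                      effect_regions = 1, rating_coupling = 0.8, seed = 15)
  isc <- normalize_isc(compute_isc(generate_timeseries(cfg)))
  dy <- community_dyads(cfg)
  covs <- rating_similarity(generate_ratings(cfg), "enjoyment")
  res <- residualize_isc(isc, covs)
  d_raw <- group_difference(isc, dy, same_comm, !same_comm)$observed_diff
  d_ctl <- group_difference(
    dplyr::mutate(res, isc_normalized = isc_normalized_resid),
    dy, same_comm, !same_comm)$observed_diff
  fitted <- isc$isc_normalized - res$isc_normalized_resid
  d_fit <- group_difference(
    dplyr::mutate(isc, isc_normalized = fitted),
    dy, same_comm, !same_comm)$observed_diff
  expect_equal(d_raw - d_ctl, d_fit, tolerance = 1e-12)

  rt <- reduction_test(isc, dy, same_comm, !same_comm,
                       covariate_source = generate_ratings(cfg),
                       covariate = "enjoyment", n_perm = 19, seed = 2)
  expect_equal(rt$result$diff_raw, d_raw, tolerance = 1e-12)
  expect_equal(rt$result$diff_controlled, d_ctl, tolerance = 1e-12)
  expect_equal(rt$result$reduction, d_raw - d_ctl, tolerance = 1e-12)
})

test_that("participant-level covariate shuffles equal re-indexed dyad matrices", {
  cfg <- synth_config(n_participants = 8, n_communities = 2,
                      rating_coupling = 0.6, seed = 33)
  rt <- generate_ratings(cfg)
  ids <- cfg$participants
  x0 <- rating_similarity(rt, "enjoyment", ids)$rating_distance
  pairs <- dyad_pairs(ids)
  pos <- stats::setNames(seq_along(ids), ids)
  for (s in 1:5) {
    perm <- withr::with_seed(700 + s, sample(8))
    # shuffle whole rating vectors across participants
    map <- stats::setNames(ids, ids[perm])
    rt_shuf <- dplyr::mutate(rt, participant = unname(map[participant]))
    x_shuf <- rating_similarity(rt_shuf, "enjoyment", ids)$rating_distance
    src <- neurodyad:::dyad_linear_index(perm[pos[pairs$dyad_i]],
                                         perm[pos[pairs$dyad_j]], 8)
    expect_equal(x_shuf, x0[src])
  }
})

test_that("a constant covariate yields zero reduction and p = 1", {
  cfg <- mini_config(seed = 25)
  isc <- normalize_isc(compute_isc(generate_timeseries(cfg)))
  dy <- community_dyads(cfg)
  const <- tidyr::expand_grid(participant = cfg$participants, stimulus = 1:14)
  const$enjoyment <- 4L
  expect_warning(
    rr <- reduction_test(isc, dy, same_comm, !same_comm,
                         covariate_source = const, covariate = "enjoyment",
                         n_perm = 9, seed = 1),
    "Constant covariate"
  )
  expect_identical(rr$result$reduction, rep(0, 3))
  expect_identical(rr$result$p_value, rep(1, 3))
})

test_that("planted full mediation is detected by the reduction test", {
  cfg <- synth_config(n_participants = 16, n_regions = 1, n_runs = 1,
                      timepoints_per_run = 100, n_communities = 4,
                      effect_regions = 1, rating_coupling = 1, seed = 901)
  isc <- normalize_isc(compute_isc(generate_timeseries(cfg)))
  dy <- community_dyads(cfg)
  rr <- reduction_test(isc, dy, same_comm, !same_comm,
                       covariate_source = generate_ratings(cfg),
                       covariate = "enjoyment", n_perm = 199, seed = 4)
  expect_gt(rr$result$reduction, 0)
  expect_lt(rr$result$p_value, 0.05)
  gl <- glance(rr)
  expect_identical(gl$covariate, "enjoyment")
  expect_identical(gl$n_significant, 1L)
})
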