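#' Configuration for the synthetic study generator
#'
#' Bundles every generative parameter of the synthetic cohort: a set of
#' participants split into latent communities, regional BOLD-like time series
#' with a stimulus-locked shared signal and a community-specific shared
#' signal, two waves of directed friendship nominations whose density depends
#' on community co-membership, Likert stimulus ratings and sociodemographic
#' records whose concordance tracks community membership. Community
#' membership is the single latent driver of all four data streams, which is
#' the minimal structure reproducing neural homophily and its covariate
#' confounding.
#'
#' The signal model for region r, participant i, time t is
#' \deqn{x_{ir}(t) = \alpha s_r(t) + \beta_r u_{c(i),r}(t) + \sigma \epsilon_{ir}(t)}
#' with `s` (stimulus), `u` (community) and `eps` (idiosyncratic) independent
#' standard-normal processes. The expected dyadic Pearson correlation is
#' therefore closed-form (see [expected_isc()]): in an effect region,
#' \eqn{(\alpha^2 + \beta^2 [c(i) = c(j)]) / (\alpha^2 + \beta^2 + \sigma^2)};
#' in other regions the \eqn{\beta} terms are absent.
#'
#' @param n_participants Number of imaging participants (study cohort: 41).
#' @param n_regions Number of brain regions (study cohort: 214 = 200
#'   cortical parcels + 14 subcortical regions).
#' @param n_runs Number of scanner runs per participant (study: 6).
#' @param timepoints_per_run Time points per run.
#' @param n_communities Number of latent communities; participants are
#'   assigned round-robin.
#' @param alpha Loading (s.d. units) of the stimulus signal shared by all
#'   participants.
#' @param beta Loading of the community-shared signal in effect regions.
#' @param sigma Idiosyncratic noise s.d.
#' @param effect_regions Integer indices of regions where `beta` applies;
#'   elsewhere the community signal is absent.
#' @param tie_p_within,tie_p_between Probability that one participant
#'   nominates another at wave 1, by community co-membership.
#' @param churn_form,churn_dissolve Per directed pair, probability that an
#'   absent nomination appears / a present nomination disappears between the
#'   waves.
#' @param rating_coupling In `[0, 1]`: weight of the community mean profile in
#'   ratings, and strength of demographic concordance within communities. 0 =
#'   no planted covariate structure; 1 = ratings fully determined by
#'   community.
#' @param prior_interaction_rate Fraction of dyads flagged as having
#'   interacted before the scan (study: 18 of 820).
#' @param ar1 Optional AR(1) coefficient applied to all three signal
#'   processes; default 0 (white noise). ISC expectations are unchanged by
#'   temporal autocorrelation.
#' @param seed Integer RNG seed; all generators are deterministic given the
#'   config.
#' @return An object of class `synth_config` (a validated list), with the
#'   derived `participants` (ids `"p01"`, ...) and `community` (integer
#'   vector) fields.
#' @examples
#' cfg <- synth_config(n_participants = 8, n_regions = 3, seed = 1)
#' cfg$community
#' @export
synth_config <- function(n_participants = 41,
                         n_regions = 214,
                         n_runs = 6,
                         timepoints_per_run = 200,
                         n_communities = 4,
                         alpha = 1,
                         beta = 1,
                         sigma = 1,
                         effect_regions = integer(),
                         tie_p_within = 0.48,
                         tie_p_between = 0.18,
                         churn_form = 0.2,
                         churn_dissolve = 0.15,
                         rating_coupling = 0.5,
                         prior_interaction_rate = 18 / 820,
                         ar1 = 0,
                         seed = 1L) {
  for (nm in c("alpha", "beta", "sigma", "ar1")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      abort(paste0("`", nm, "` must be a single finite number."))
    }
  }
  if (alpha < 0 || beta < 0 || sigma < 0) {
    abort("Loadings `alpha`, `beta`, `sigma` must be non-negative.")
  }
  for (nm in c("tie_p_within", "tie_p_between", "churn_form",
               "churn_dissolve", "rating_coupling", "prior_interaction_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      abort(paste0("`", nm, "` must be a probability in [0, 1]."))
    }
  }
  if (n_participants < 4) abort("`n_participants` must be at least 4.")
  if (n_regions < 1) abort("`n_regions` must be at least 1.")
  if (n_runs < 1 || timepoints_per_run < 2) {
    abort("Need at least one run of at least two timepoints.")
  }
  if (n_communities < 1 || n_communities > n_participants) {
    abort("`n_communities` must be between 1 and `n_participants`.")
  }
  effect_regions <- sort(unique(as.integer(effect_regions)))
  if (length(effect_regions) &&
      (min(effect_regions) < 1 || max(effect_regions) > n_regions)) {
    abort("`effect_regions` must be region indices in 1..n_regions.")
  }
  if (abs(ar1) >= 1) abort("`ar1` must lie in (-1, 1).")
  participants <- sprintf("p%02d", seq_len(n_participants))
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_regions = as.integer(n_regions),
    n_runs = as.integer(n_runs),
    timepoints_per_run = as.integer(timepoints_per_run),
    n_communities = as.integer(n_communities),
    alpha = alpha, beta = beta, sigma = sigma,
    effect_regions = effect_regions,
    tie_p_within = tie_p_within, tie_p_between = tie_p_between,
    churn_form = churn_form, churn_dissolve = churn_dissolve,
    rating_coupling = rating_coupling,
    prior_interaction_rate = prior_interaction_rate,
    ar1 = ar1,
    seed = as.integer(seed),
    participants = participants,
    community = rep_len(seq_len(n_communities), n_participants)
  )
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  %d participants in %d communities; %d regions (%d effect), %d x %d timepoints\n",
              x$n_participants, x$n_communities, x$n_regions,
              length(x$effect_regions), x$n_runs, x$timepoints_per_run))
  cat(sprintf("  loadings alpha=%g beta=%g sigma=%g (ar1=%g); seed %d\n",
              x$alpha, x$beta, x$sigma, x$ar1, x$seed))
  invisible(x)
}

#' Closed-form expected dyadic ISC under a synthetic config
#'
#' @param config A [synth_config()].
#' @param same_community Logical: do the two participants share a community?
#' @param effect_region Logical: is the region in `effect_regions`?
#' @return Expected Pearson correlation between the two participants' series.
#' @examples
#' cfg <- synth_config(alpha = 1, beta = 1, sigma = 1, effect_regions = 1)
#' expected_isc(cfg, same_community = TRUE)   # 2/3
#' expected_isc(cfg, same_community = FALSE)  # 1/3
#' @export
expected_isc <- function(config, same_community, effect_region = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  b2 <- ifelse(effect_region, config$beta^2, 0)
  tot <- config$alpha^2 + b2 + config$sigma^2
  if (tot == 0) return(rep(NaN, length(same_community)))
  (config$alpha^2 + b2 * as.numeric(same_community)) / tot
}

# Standard-normal white or AR(1) process matrix (rows x cols), unit marginal
# variance either way.
rand_process <- function(nrow, ncol, ar1) {
  m <- matrix(rnorm(nrow * ncol), nrow, ncol)
  if (ar1 != 0) {
    innov_sd <- sqrt(1 - ar1^2)
    m[, 1] <- m[, 1]
    for (t in seq_len(ncol - 1)) {
      m[, t + 1] <- ar1 * m[, t] + innov_sd * m[, t + 1]
    }
  }
  m
}

#' Generate regional time series for every participant and run
#'
#' Draws the three latent processes per region (stimulus-shared,
#' community-shared in effect regions, idiosyncratic) and mixes them with the
#' configured loadings. Output mirrors parcel-averaged BOLD response
#' matrices, one per participant per run.
#'
#' @param config A [synth_config()].
#' @return A tibble with columns `participant`, `run`, and a list-column
#'   `series` of `n_regions x timepoints_per_run` matrices with region-id
#'   rownames (`"r001"`, ...).
#' @examples
#' ts <- generate_timeseries(synth_config(n_participants = 4, n_regions = 2,
#'                                        n_runs = 2, timepoints_per_run = 20))
#' dim(ts$series[[1]])
#' @export
generate_timeseries <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_participants
  R <- config$n_regions
  total_t <- config$n_runs * config$timepoints_per_run
  region_ids <- sprintf("r%03d", seq_len(R))
  is_effect <- seq_len(R) %in% config$effect_regions
  comm <- config$community
  k <- config$n_communities
  withr::with_seed(config$seed + 1L, {
    out <- vector("list", n)
    for (r in seq_len(R)) {
      s <- rand_process(1, total_t, config$ar1)            # stimulus signal
      u <- rand_process(k, total_t, config$ar1)            # community signals
      eps <- rand_process(n, total_t, config$ar1)
      beta_r <- if (is_effect[r]) config$beta else 0
      x <- config$alpha * matrix(s, n, total_t, byrow = TRUE) +
        beta_r * u[comm, , drop = FALSE] +
        config$sigma * eps
      for (i in seq_len(n)) {
        if (r == 1) out[[i]] <- matrix(NA_real_, R, total_t,
                                       dimnames = list(region_ids, NULL))
        out[[i]][r, ] <- x[i, ]
      }
    }
  })
  run_id <- sprintf("run%d", seq_len(config$n_runs))
  run_of_col <- rep(seq_len(config$n_runs), each = config$timepoints_per_run)
  tidyr::expand_grid(participant = config$participants, run = run_id) |>
    mutate(series = purrr::map2(.data$participant, .data$run, function(p, rn) {
      i <- match(p, config$participants)
      j <- match(rn, run_id)
      out[[i]][, run_of_col == j, drop = FALSE]
    }))
}

#' Generate two waves of directed friendship nominations
#'
#' Wave-1 nominations are independent Bernoulli draws whose probability
#' depends on community co-membership; wave 2 is wave 1 with independent
#' per-pair churn (absent ties form with `churn_form`, present ties dissolve
#' with `churn_dissolve`). No self-nominations.
#'
#' @param config A [synth_config()].
#' @return A tibble of directed nominations with columns `wave` (`"T2"`,
#'   `"T3"`), `src`, `dst`.
#' @export
generate_networks <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_participants
  comm <- config$community
  same <- outer(comm, comm, "==")
  p1 <- ifelse(same, config$tie_p_within, config$tie_p_between)
  withr::with_seed(config$seed + 2L, {
    a1 <- matrix(runif(n * n) < p1, n, n)
    diag(a1) <- FALSE
    flip_form <- matrix(runif(n * n) < config$churn_form, n, n)
    flip_diss <- matrix(runif(n * n) < config$churn_dissolve, n, n)
  })
  a2 <- (a1 & !flip_diss) | (!a1 & flip_form)
  diag(a2) <- FALSE
  adj_to_edges <- function(a, wave) {
    idx <- which(a, arr.ind = TRUE)
    tibble(wave = wave,
           src = config$participants[idx[, 1]],
           dst = config$participants[idx[, 2]]) |>
      arrange(.data$src, .data$dst)
  }
  bind_rows(adj_to_edges(a1, "T2"), adj_to_edges(a2, "T3"))
}

#' Generate Likert stimulus ratings
#'
#' Each community has a latent mean profile over the 14 stimuli for each of
#' the two scales (enjoyment, interest). A participant's latent rating is
#' `rating_coupling * community_profile + (1 - rating_coupling) * personal
#' noise`, centred on the scale midpoint, then rounded and clamped to the
#' 1..5 Likert range. With `rating_coupling = 1` ratings are identical within
#' a community; with 0 they carry no community structure.
#'
#' @param config A [synth_config()].
#' @param n_stimuli Number of rated stimuli (study: 14 movie clips).
#' @return A long tibble with columns `participant`, `stimulus` (integer),
#'   `enjoyment`, `interest` (integers in 1..5).
#' @export
generate_ratings <- function(config, n_stimuli = 14L) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_participants
  k <- config$n_communities
  w <- config$rating_coupling
  withr::with_seed(config$seed + 3L, {
    lat <- lapply(c(enjoyment = 1, interest = 2), function(scale) {
      prof <- matrix(rnorm(k * n_stimuli, sd = 1.2), k, n_stimuli)
      noise <- matrix(rnorm(n * n_stimuli, sd = 1.2), n, n_stimuli)
      3 + w * prof[config$community, , drop = FALSE] + (1 - w) * noise
    })
  })
  discretize <- function(x) pmin(5L, pmax(1L, as.integer(round(x))))
  tidyr::expand_grid(participant = config$participants,
                     stimulus = seq_len(n_stimuli)) |>
    mutate(
      enjoyment = discretize(lat$enjoyment[cbind(
        match(.data$participant, config$participants), .data$stimulus)]),
      interest = discretize(lat$interest[cbind(
        match(.data$participant, config$participants), .data$stimulus)])
    )
}

#' Generate sociodemographic records
#'
#' Categorical variables (gender, nationality, hometown location, alma-mater
#' location, institution type, undergraduate major, industry) take each
#' community's modal level with probability rising in `rating_coupling`, else
#' a uniformly random level, so within-community concordance exceeds
#' between-community concordance whenever `rating_coupling > 0`. Age is
#' normal around 28.6 (s.d. 2.15, the cohort's moments); hometown population
#' is log-normal spanning small towns to megacities.
#'
#' @param config A [synth_config()].
#' @return A tibble with one row per participant: `participant`, `age`,
#'   `gender`, `nationality`, `hometown_location`, `hometown_population`,
#'   `alma_mater_location`, `institution_type`, `major`, `industry`.
#' @export
generate_demographics <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_participants
  k <- config$n_communities
  w <- config$rating_coupling
  levs <- list(
    gender = c("female", "male"),
    nationality = c("USA", "India", "Australia", "Peru", "China", "Brazil"),
    hometown_location = c("northeast", "south", "midwest", "west", "abroad"),
    alma_mater_location = c("northeast", "south", "midwest", "west", "abroad"),
    institution_type = c("private", "public"),
    major = c("economics", "engineering", "humanities", "science", "business"),
    industry = c("finance", "consulting", "technology", "government", "health")
  )
  p_modal <- 0.5 + 0.5 * w  # concordance rises with coupling
  withr::with_seed(config$seed + 4L, {
    cats <- lapply(levs, function(lv) {
      modal <- sample(lv, k, replace = TRUE)
      take_modal <- runif(n) < p_modal
      draw <- sample(lv, n, replace = TRUE)
      ifelse(take_modal, modal[config$community], draw)
    })
    age <- round(rnorm(n, mean = 28.6, sd = 2.15), 1)
    pop <- round(10^rnorm(n, mean = 5.5, sd = 1))
  })
  tibble(participant = config$participants, age = age,
         gender = cats$gender, nationality = cats$nationality,
         hometown_location = cats$hometown_location,
         hometown_population = pop,
         alma_mater_location = cats$alma_mater_location,
         institution_type = cats$institution_type,
         major = cats$major, industry = cats$industry)
}

#' Generate prior-interaction dyad flags
#'
#' Flags a random subset of dyads as having interacted before the scan, at
#' the configured rate, for the dyad-exclusion sensitivity analysis.
#'
#' @param config A [synth_config()].
#' @return A tibble `dyad_i`, `dyad_j`, `prior_interaction` (logical) over
#'   the canonical dyad set.
#' @export
generate_dyad_flags <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  pairs <- dyad_pairs(config$participants)
  withr::with_seed(config$seed + 5L, {
    flag <- runif(nrow(pairs)) < config$prior_interaction_rate
  })
  mutate(pairs, prior_interaction = flag)
}

#' Simulate a complete synthetic study
#'
#' Runs all four generators and returns the in-memory study bundle the
#' pipeline functions consume.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_study`: `config`, `participants`,
#'   `community` (tibble participant/community), `timeseries`, `networks`,
#'   `ratings`, `demographics`, `dyad_flags`.
#' @examples
#' study <- simulate_study(synth_config(n_participants = 6, n_regions = 2,
#'                                      n_runs = 1, timepoints_per_run = 30))
#' names(study)
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  structure(list(
    config = config,
    participants = config$participants,
    community = tibble(participant = config$participants,
                       community = config$community),
    timeseries = generate_timeseries(config),
    networks = generate_networks(config),
    ratings = generate_ratings(config),
    demographics = generate_demographics(config),
    dyad_flags = generate_dyad_flags(config)
  ), class = "synth_study")
}
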