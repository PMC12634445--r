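#' Assemble the per-dyad metadata table for a study
#'
#' Builds the reciprocal friendship graph for each wave, reads geodesic
#' distances off the full cohort graph for the imaging participants, applies
#' the recoding cap, categorizes the direction of distance change, and joins
#' the prior-interaction flags. Both waves are capped so that every dyad
#' falls into one of the contrast levels even for sparse synthetic networks
#' (the study cohort needed the cap only at the earlier wave, where 4-step
#' dyads were recoded to 3).
#'
#' @param networks Directed nomination tibble with columns `wave` (`"T2"`,
#'   `"T3"`), `src`, `dst`.
#' @param participants Full cohort roster (vertex set; may be a superset of
#'   `imaging`).
#' @param imaging Imaging participants whose dyads are analyzed; defaults to
#'   all of `participants`.
#' @param dyad_flags Optional tibble `dyad_i`, `dyad_j`, `prior_interaction`.
#' @param cap Distance recoding cap (default 3).
#' @param unreachable Policy for disconnected dyads, see [recode_distances()].
#' @return Tibble `dyad_i`, `dyad_j`, `distance_t2`, `distance_t3`,
#'   `change_category`, `prior_interaction`.
#' @export
study_dyads <- function(networks, participants, imaging = NULL,
                        dyad_flags = NULL, cap = 3L,
                        unreachable = c("cap", "exclude")) {
  unreachable <- match.arg(unreachable)
  nets <- as_tibble(networks)
  if (!all(c("wave", "src", "dst") %in% names(nets))) {
    abort("`networks` needs columns wave, src, dst.")
  }
  imaging <- as.character(imaging %||% participants)
  dist_of <- function(w) {
    g <- build_reciprocal_graph(filter(nets, .data$wave == w), participants)
    recode_distances(geodesic_distances(g, imaging), cap = cap,
                     unreachable = unreachable)
  }
  out <- change_categories(dist_of("T2"), dist_of("T3"))
  if (!is.null(dyad_flags)) {
    flags <- align_dyads(dyad_flags, select(out, "dyad_i", "dyad_j"))
    out$prior_interaction <- flags$prior_interaction
  } else {
    out$prior_interaction <- FALSE
  }
  out
}

# Shared driver for the two analysis families.
run_contrast_family <- function(isc, dyads, specs, n_perm, n_boot, seed,
                                stage, exclude_prior, keep_null) {
  contrasts <- vector("list", length(specs))
  names(contrasts) <- names(specs)
  excl <- if (exclude_prior) rlang::quo(.data$prior_interaction) else rlang::quo(NULL)
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    contrasts[[k]] <- rlang::inject(isc_contrast(
      isc, dyads,
      group_a = !!sp$a, group_b = !!sp$b,
      stage = stage, n_perm = n_perm, n_boot = n_boot,
      seed = seed + k, name = names(specs)[k],
      exclude = !!excl,
      keep_null = keep_null
    ))
  }
  structure(list(
    results = bind_rows(lapply(contrasts, tidy)),
    contrasts = contrasts,
    dyads = dyads,
    settings = list(n_perm = n_perm, n_boot = n_boot, seed = seed,
                    stage = stage, exclude_prior = exclude_prior)
  ), class = "isc_analysis")
}

#' @export
print.isc_analysis <- function(x, ...) {
  cat(sprintf("<isc_analysis> %d contrast(s), %d regions each\n",
              length(x$contrasts), nrow(x$contrasts[[1]]$result)))
  print(bind_rows(lapply(x$contrasts, glance)))
  invisible(x)
}

#' Social-distance analysis family
#'
#' Runs the similarity chain (unless a prepared ISC table is supplied) and
#' the three distance contrasts at the chosen wave: friends (distance 1)
#' against distances 2 and 3 combined, then pairwise against distance 2 and
#' against distance 3. Each contrast gets the node-level permutation test,
#' FDR across regions, and the participant bootstrap interval.
#'
#' @param study A `synth_study` list from [simulate_study()] or
#'   [read_study()].
#' @param wave Which wave's distances define the groups: `"T3"` (primary) or
#'   `"T2"` (sensitivity).
#' @param n_perm,n_boot Permutation / bootstrap counts (study defaults 1000).
#' @param seed Integer seed.
#' @param cap,unreachable Distance recoding, see [study_dyads()].
#' @param exclude_prior Drop dyads flagged as having interacted before the
#'   scan (sensitivity analysis).
#' @param stage Similarity column to contrast.
#' @param winsorize Passed to [normalize_isc()].
#' @param isc Optional precomputed ISC table (from [normalize_isc()]) to
#'   skip the similarity chain.
#' @param keep_null Keep per-contrast null matrices.
#' @return An `isc_analysis` object: `$results` (tidy per-region table over
#'   contrasts), `$contrasts` (named [isc_contrast()] objects), `$dyads`.
#' @export
run_distance_analysis <- function(study, wave = c("T3", "T2"),
                                  n_perm = 1000, n_boot = 1000, seed = 1L,
                                  cap = 3L, unreachable = "cap",
                                  exclude_prior = FALSE,
                                  stage = "isc_normalized", winsorize = TRUE,
                                  isc = NULL, keep_null = FALSE) {
  wave <- match.arg(wave)
  isc <- isc %||% normalize_isc(compute_isc(study$timeseries),
                                winsorize = winsorize)
  dyads <- study_dyads(study$networks, study$participants,
                       imaging = sort(unique(c(isc$dyad_i, isc$dyad_j))),
                       dyad_flags = study$dyad_flags,
                       cap = cap, unreachable = unreachable)
  dcol <- rlang::sym(paste0("distance_", tolower(wave)))
  specs <- list(
    dist1_vs_dist23 = list(a = rlang::quo(!!dcol == 1),
                           b = rlang::quo(!!dcol %in% c(2, 3))),
    dist1_vs_dist2 = list(a = rlang::quo(!!dcol == 1),
                          b = rlang::quo(!!dcol == 2)),
    dist1_vs_dist3 = list(a = rlang::quo(!!dcol == 1),
                          b = rlang::quo(!!dcol == 3))
  )
  run_contrast_family(isc, dyads, specs, n_perm, n_boot, seed, stage,
                      exclude_prior, keep_null)
}

#' Change-in-social-distance analysis family
#'
#' Contrasts dyads that grew closer between the two waves against (a) all
#' dyads that did not, (b) dyads whose distance stayed the same, and (c)
#' dyads that grew apart, with the same inference machinery as
#' [run_distance_analysis()].
#'
#' @inheritParams run_distance_analysis
#' @return An `isc_analysis` object.
#' @export
run_change_analysis <- function(study, n_perm = 1000, n_boot = 1000,
                                seed = 1L, cap = 3L, unreachable = "cap",
                                exclude_prior = FALSE,
                                stage = "isc_normalized", winsorize = TRUE,
                                isc = NULL, keep_null = FALSE) {
  isc <- isc %||% normalize_isc(compute_isc(study$timeseries),
                                winsorize = winsorize)
  dyads <- study_dyads(study$networks, study$participants,
                       imaging = sort(unique(c(isc$dyad_i, isc$dyad_j))),
                       dyad_flags = study$dyad_flags,
                       cap = cap, unreachable = unreachable)
  specs <- list(
    closer_vs_not = list(
      a = rlang::quo(.data$change_category == "closer"),
      b = rlang::quo(.data$change_category %in% c("same", "apart"))),
    closer_vs_same = list(
      a = rlang::quo(.data$change_category == "closer"),
      b = rlang::quo(.data$change_category == "same")),
    closer_vs_apart = list(
      a = rlang::quo(.data$change_category == "closer"),
      b = rlang::quo(.data$change_category == "apart"))
  )
  run_contrast_family(isc, dyads, specs, n_perm, n_boot, seed, stage,
                      exclude_prior, keep_null)
}
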