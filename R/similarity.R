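#' Spatially average a voxel matrix into regions
#'
#' Each region's time course is the unweighted mean over its voxels at every
#' timepoint.
#'
#' @param voxel_matrix Numeric matrix, voxels x timepoints.
#' @param labels Integer (or factor/character) region label per voxel.
#' @param region_ids Optional ordered set of region ids to emit; defaults to
#'   the sorted unique labels. Regions with zero voxels yield a row of `NA`
#'   with a warning.
#' @return Numeric matrix, regions x timepoints, rownames the region ids.
#' @examples
#' parcellate(rbind(c(1, 2, 3), c(3, 4, 5)), labels = c(1, 1))
#' @export
parcellate <- function(voxel_matrix, labels, region_ids = NULL) {
  voxel_matrix <- as.matrix(voxel_matrix)
  if (length(labels) != nrow(voxel_matrix)) {
    abort("`labels` must have one entry per voxel row.")
  }
  labels <- as.character(labels)
  region_ids <- as.character(region_ids %||% sort(unique(labels)))
  out <- matrix(NA_real_, length(region_ids), ncol(voxel_matrix),
                dimnames = list(region_ids, colnames(voxel_matrix)))
  counts <- table(factor(labels, levels = region_ids))
  present <- names(counts)[counts > 0]
  if (length(present)) {
    sums <- rowsum(voxel_matrix, group = factor(labels, levels = region_ids))
    out[present, ] <- sums[present, , drop = FALSE] / as.numeric(counts[present])
  }
  empty <- setdiff(region_ids, present)
  if (length(empty)) {
    warn(paste0("Region(s) with zero voxels set to NA: ",
                paste(head(empty, 5), collapse = ", ")))
  }
  out
}

#' Concatenate a participant's runs into one time series
#'
#' @param series List of regions x timepoints matrices with identical
#'   rownames (region ids), in the order in which they should be joined.
#' @param run_subset Optional integer or name index selecting/ordering runs.
#' @return One regions x (total timepoints) matrix; the run boundaries are
#'   recorded in the `run_lengths` attribute.
#' @export
concatenate_runs <- function(series, run_subset = NULL) {
  if (!length(series)) abort("No runs to concatenate.")
  if (!is.null(run_subset)) series <- series[run_subset]
  ids <- rownames(series[[1]])
  ok <- vapply(series, function(m) identical(rownames(m), ids), logical(1))
  if (!all(ok)) abort("Runs have inconsistent region sets or ordering.")
  out <- do.call(cbind, series)
  attr(out, "run_lengths") <- vapply(series, ncol, integer(1))
  out
}

#' Dyadic inter-subject correlation per region
#'
#' For each unordered pair of participants, the Pearson correlation between
#' their concatenated regional time series, one value per region. Each dyad
#' is correlated over the intersection of the two members' available runs,
#' concatenated in run order, so both series stay time-locked to the same
#' stimuli even when a member is missing runs.
#'
#' @param timeseries Tibble with columns `participant`, `run`, `series`
#'   (list-column of regions x timepoints matrices sharing rownames), e.g.
#'   from [generate_timeseries()] or [read_timeseries_dir()].
#' @param participants Optional ordering/subset of participants; defaults to
#'   the sorted ids present.
#' @return Long tibble `dyad_i`, `dyad_j`, `region`, `isc_raw` over the
#'   canonical dyad set. Zero-variance series give `NA` with a warning.
#' @export
compute_isc <- function(timeseries, participants = NULL) {
  ts <- as_tibble(timeseries)
  if (!all(c("participant", "run", "series") %in% names(ts))) {
    abort("`timeseries` needs columns participant, run, series.")
  }
  participants <- as.character(participants %||% sort(unique(ts$participant)))
  ts <- filter(ts, .data$participant %in% participants)
  missing_p <- setdiff(participants, ts$participant)
  if (length(missing_p)) {
    abort(paste0("No runs for participant(s): ",
                 paste(head(missing_p, 5), collapse = ", ")))
  }
  region_ids <- rownames(ts$series[[1]])
  run_levels <- sort(unique(ts$run))
  runs_of <- split(ts$run, ts$participant)
  series_of <- split(ts$series, ts$participant)
  pairs <- dyad_pairs(participants)
  common <- purrr::map2(pairs$dyad_i, pairs$dyad_j, function(a, b) {
    sort(intersect(runs_of[[a]], runs_of[[b]]))
  })
  empty <- lengths(common) == 0
  if (any(empty)) abort("Some dyads share no usable runs.")
  keys <- vapply(common, paste, character(1), collapse = "|")
  ukeys <- unique(keys)
  out <- vector("list", length(ukeys))
  zero_var <- FALSE
  for (kk in seq_along(out)) {
    key <- ukeys[kk]
    sel <- which(keys == key)
    runs <- strsplit(key, "|", fixed = TRUE)[[1]]
    members <- unique(c(pairs$dyad_i[sel], pairs$dyad_j[sel]))
    concat <- lapply(stats::setNames(members, members), function(p) {
      ord <- match(runs, runs_of[[p]])
      concatenate_runs(series_of[[p]][ord])
    })
    # participants x time array per region -> full correlation matrix
    r_by_region <- lapply(seq_along(region_ids), function(r) {
      x <- t(vapply(members, function(p) concat[[p]][r, ],
                    numeric(ncol(concat[[members[1]]]))))
      sds <- apply(x, 1, stats::sd)
      if (any(sds == 0)) zero_var <<- TRUE
      suppressWarnings(cor(t(x)))
    })
    ii <- match(pairs$dyad_i[sel], members)
    jj <- match(pairs$dyad_j[sel], members)
    # regions x selected-dyads matrix of correlations
    vals <- vapply(r_by_region, function(m) m[cbind(ii, jj)],
                   numeric(length(sel)))
    vals <- matrix(vals, nrow = length(sel))  # vapply drops dims when sel == 1
    vals <- t(vals)
    out[[kk]] <- tibble(
      dyad_i = rep(pairs$dyad_i[sel], each = length(region_ids)),
      dyad_j = rep(pairs$dyad_j[sel], each = length(region_ids)),
      region = rep(region_ids, times = length(sel)),
      isc_raw = as.vector(vals)
    )
  }
  if (zero_var) {
    warn("Zero-variance series encountered; affected correlations are NA.")
  }
  res <- bind_rows(out)
  # canonical order: dyads in enumeration order, regions within dyad
  pos <- stats::setNames(seq_along(participants), participants)
  res |>
    arrange(dyad_linear_index(pos[.data$dyad_i], pos[.data$dyad_j],
                              length(participants)),
            match(.data$region, region_ids))
}

#' Winsorize a vector at the 1.5 x IQR fences
#'
#' Values above Q3 + 1.5*IQR are reassigned exactly that fence value; values
#' below Q1 - 1.5*IQR are reassigned the lower fence. Quartiles use linear
#' interpolation of order statistics (`stats::quantile` type 7, the common
#' default of mainstream numerical stacks).
#'
#' @param x Numeric vector (at least 4 finite values; `NA`s pass through).
#' @return `x` with outliers reassigned to the fences.
#' @examples
#' winsorize_iqr(c(1, 2, 3, 4, 100))  # 100 -> 4 + 1.5 * 2 = 7
#' @export
winsorize_iqr <- function(x) {
  fin <- is.finite(x)
  if (sum(fin) < 4) abort("Need at least 4 finite values to winsorize.")
  q <- quantile(x[fin], c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  out <- x
  out[fin & x < lo] <- lo
  out[fin & x > hi] <- hi
  out
}

#' Fisher z (variance-stabilizing) transform of a correlation
#'
#' `atanh(r)`; correlations of magnitude exactly 1 are clipped to
#' `1 - 1e-7` in magnitude with a warning, since `atanh` diverges there.
#'
#' @param r Numeric vector of correlations in `[-1, 1]`.
#' @return `atanh` of the (possibly clipped) correlations.
#' @examples
#' fisher_z(0.5)  # 0.5493
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) abort("Correlations must lie in [-1, 1].")
  at_limit <- !is.na(r) & abs(r) == 1
  if (any(at_limit)) {
    warn(sprintf("%d correlation(s) of magnitude 1 clipped before atanh.",
                 sum(at_limit)))
    r[at_limit] <- sign(r[at_limit]) * (1 - 1e-7)
  }
  atanh(r)
}

#' Z-score a vector with the population standard deviation
#'
#' Subtracts the mean and divides by the population (divide-by-n) standard
#' deviation, the convention of the standard scaler used for per-region
#' normalization of ISCs across dyads.
#'
#' @param x Numeric vector.
#' @return Standardized vector (all zeros if `x` is constant, with warning).
#' @export
normalize_zscore <- function(x) {
  fin <- is.finite(x)
  mu <- mean(x[fin])
  s <- sqrt(mean((x[fin] - mu)^2))
  if (s == 0) {
    warn("Constant vector: normalized values set to 0.")
    return(replace(x, fin, 0))
  }
  (x - mu) / s
}

#' Run the full similarity chain on raw dyadic correlations
#'
#' Per region, across the full set of included dyads and in this fixed
#' order: winsorize at the 1.5 x IQR fences, Fisher-z transform, then
#' z-score with the population s.d. The winsorization fences are computed
#' once here, on the full dyad set, and are not recomputed when later
#' analyses drop dyads.
#'
#' @param isc Long tibble from [compute_isc()] (columns `dyad_i`, `dyad_j`,
#'   `region`, `isc_raw`).
#' @param winsorize Set `FALSE` to skip the outlier step (then
#'   `isc_winsorized` equals `isc_raw`).
#' @return The input with columns `isc_winsorized`, `isc_fisher_z`,
#'   `isc_normalized` added.
#' @export
normalize_isc <- function(isc, winsorize = TRUE) {
  isc <- as_tibble(isc)
  isc |>
    group_by(.data$region) |>
    mutate(
      isc_winsorized = if (winsorize) winsorize_iqr(.data$isc_raw) else .data$isc_raw,
      isc_fisher_z = fisher_z(.data$isc_winsorized),
      isc_normalized = normalize_zscore(.data$isc_fisher_z)
    ) |>
    ungroup()
}
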