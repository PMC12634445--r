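# Parcel metadata for a synthetic region set: ids, a cycling network label,
# and a cortical flag (the last 14 regions are marked subcortical when the
# region count is large enough to mimic a cortical + subcortical scheme).
parcel_metadata <- function(n_regions) {
  nets <- c("visual", "somatomotor", "dorsal_attention", "ventral_attention",
            "limbic", "frontoparietal", "default_mode")
  region <- sprintf("r%03d", seq_len(n_regions))
  subcortical <- if (n_regions >= 28) {
    seq_len(n_regions) > n_regions - 14
  } else {
    rep(FALSE, n_regions)
  }
  tibble(
    region = region,
    name = ifelse(subcortical, paste0("subcortical_", region),
                  paste0("cortical_", region)),
    network = ifelse(subcortical, "subcortical",
                     rep_len(nets, n_regions)),
    cortical = !subcortical
  )
}

#' Write a complete synthetic input tree to disk
#'
#' Materializes a [simulate_study()] bundle in the delimited-text formats
#' the readers consume: one `<participant>_<run>.tsv` region-by-timepoint
#' matrix per participant and run (first column `region`), per-wave directed
#' edge lists `network_<wave>.csv` (`src,dst`), `participants.txt`,
#' `ratings.tsv`, `demographics.tsv`, `dyad_flags.tsv`, `parcels.tsv`, and a
#' `manifest.txt` (key=value) recording the generating config and seed.
#'
#' @param config A [synth_config()].
#' @param dir Output directory.
#' @param force Overwrite into an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
make_fixtures <- function(config, dir, force = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  if (dir.exists(dir) && length(list.files(dir)) && !force) {
    abort(paste0("Directory ", dir, " is non-empty; use force = TRUE."))
  }
  dir.create(file.path(dir, "timeseries"), recursive = TRUE,
             showWarnings = FALSE)
  study <- simulate_study(config)
  purrr::pwalk(study$timeseries, function(participant, run, series) {
    df <- bind_cols(tibble(region = rownames(series)),
                    as_tibble(series, .name_repair = function(x)
                      sprintf("t%04d", seq_along(x))))
    readr::write_tsv(df, file.path(dir, "timeseries",
                                   paste0(participant, "_", run, ".tsv")))
  })
  for (w in unique(study$networks$wave)) {
    readr::write_csv(
      select(filter(study$networks, .data$wave == w), "src", "dst"),
      file.path(dir, paste0("network_", w, ".csv"))
    )
  }
  writeLines(study$participants, file.path(dir, "participants.txt"))
  readr::write_tsv(study$ratings, file.path(dir, "ratings.tsv"))
  readr::write_tsv(study$demographics, file.path(dir, "demographics.tsv"))
  readr::write_tsv(study$dyad_flags, file.path(dir, "dyad_flags.tsv"))
  readr::write_tsv(parcel_metadata(config$n_regions),
                   file.path(dir, "parcels.tsv"))
  scalars <- config[!(names(config) %in% c("participants", "community",
                                           "effect_regions"))]
  manifest <- c(
    vapply(names(scalars), function(k) paste0(k, "=", scalars[[k]]),
           character(1)),
    paste0("effect_regions=",
           paste(config$effect_regions, collapse = ","))
  )
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Read a directory of regional time-series matrices
#'
#' Expects files named `<participant>_<run>.tsv`: tab-delimited with a
#' header, first column `region`, remaining columns timepoints.
#'
#' @param dir Directory containing the matrices.
#' @return Tibble `participant`, `run`, `series` (list-column of matrices)
#'   as consumed by [compute_isc()].
#' @export
read_timeseries_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files)) abort(paste0("No .tsv matrices found in ", dir, "."))
  parts <- strsplit(sub("\\.tsv$", "", basename(files)), "_")
  bad <- lengths(parts) != 2
  if (any(bad)) {
    abort("Time-series filenames must follow `<participant>_<run>.tsv`.")
  }
  tibble(
    participant = vapply(parts, `[`, character(1), 1),
    run = vapply(parts, `[`, character(1), 2),
    series = lapply(files, function(f) {
      df <- readr::read_tsv(f, show_col_types = FALSE, progress = FALSE)
      m <- as.matrix(df[, -1, drop = FALSE])
      rownames(m) <- df[[1]]
      dimnames(m)[2] <- list(NULL)
      m
    })
  )
}

#' Read a directed nomination edge list
#'
#' Delimited text with header columns `src`, `dst`, one row per directed
#' nomination.
#'
#' @param path File path.
#' @param wave Optional wave label to attach.
#' @return Tibble `src`, `dst` (plus `wave` if given).
#' @export
read_edgelist <- function(path, wave = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("src", "dst") %in% names(df))) {
    abort("Edge list needs header columns `src` and `dst`.")
  }
  out <- select(as_tibble(df), "src", "dst")
  if (!is.null(wave)) out <- bind_cols(tibble(wave = wave), out)
  out
}

#' Read a 0/1 adjacency table as a nomination edge list
#'
#' Square table with participant ids as header row and first column; cell
#' `[i, j] = 1` means i nominated j.
#'
#' @inheritParams read_edgelist
#' @return Tibble of directed nominations (`src`, `dst`, plus `wave`).
#' @export
read_adjacency <- function(path, wave = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != ncol(m) || !identical(ids, colnames(m))) {
    abort("Adjacency table must be square with matching row/column ids.")
  }
  if (!all(m %in% c(0, 1))) abort("Adjacency entries must be 0 or 1.")
  idx <- which(m == 1, arr.ind = TRUE)
  out <- tibble(src = ids[idx[, 1]], dst = ids[idx[, 2]]) |>
    arrange(.data$src, .data$dst)
  if (any(out$src == out$dst)) abort("Adjacency diagonal must be zero.")
  if (!is.null(wave)) out <- bind_cols(tibble(wave = wave), out)
  out
}

#' Read a study input tree written by [make_fixtures()]
#'
#' @param dir Directory containing the fixture tree.
#' @return A list shaped like [simulate_study()] output (`participants`,
#'   `timeseries`, `networks`, `ratings`, `demographics`, `dyad_flags`,
#'   plus `parcels`), consumable by the `run_*_analysis()` functions.
#' @export
read_study <- function(dir) {
  nets <- bind_rows(lapply(c("T2", "T3"), function(w) {
    read_edgelist(file.path(dir, paste0("network_", w, ".csv")), wave = w)
  }))
  structure(list(
    participants = readLines(file.path(dir, "participants.txt")),
    timeseries = read_timeseries_dir(file.path(dir, "timeseries")),
    networks = nets,
    ratings = readr::read_tsv(file.path(dir, "ratings.tsv"),
                              show_col_types = FALSE, progress = FALSE),
    demographics = readr::read_tsv(file.path(dir, "demographics.tsv"),
                                   show_col_types = FALSE, progress = FALSE),
    dyad_flags = readr::read_tsv(file.path(dir, "dyad_flags.tsv"),
                                 show_col_types = FALSE, progress = FALSE),
    parcels = readr::read_tsv(file.path(dir, "parcels.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  ), class = "synth_study")
}

#' Write per-contrast result tables
#'
#' One delimited file per contrast (`<name>.tsv`) with the per-region
#' results, plus the per-dyad metadata table (`dyads.tsv`).
#'
#' @param analysis An `isc_analysis` from [run_distance_analysis()] or
#'   [run_change_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(analysis, dir) {
  stopifnot(inherits(analysis, "isc_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(analysis$contrasts)) {
    readr::write_tsv(tidy(analysis$contrasts[[nm]]),
                     file.path(dir, paste0(nm, ".tsv")))
  }
  readr::write_tsv(analysis$dyads, file.path(dir, "dyads.tsv"))
  invisible(dir)
}
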