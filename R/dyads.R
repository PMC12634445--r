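#' Canonical dyad table for a set of participants
#'
#' Enumerates all unordered pairs of participants in a fixed canonical order:
#' pairs are listed with `dyad_i` earlier than `dyad_j` in the supplied
#' participant ordering, looping over `dyad_i` in the outer position. Every
#' dyadic quantity in the package is indexed by this enumeration, so the
#' `n * (n - 1) / 2` rows here define "the dyads" once and for all.
#'
#' @param participants Character vector of unique participant ids, in the
#'   ordering that defines the canonical dyad index.
#' @return A tibble with columns `dyad_i`, `dyad_j` (character) in canonical
#'   order.
#' @examples
#' dyad_pairs(c("a", "b", "c"))
#' @export
dyad_pairs <- function(participants) {
  participants <- as.character(participants)
  if (anyDuplicated(participants) > 0) {
    abort("`participants` must be unique.")
  }
  n <- length(participants)
  if (n < 2) {
    return(tibble(dyad_i = character(), dyad_j = character()))
  }
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  tibble(
    dyad_i = participants[idx[, "row"]],
    dyad_j = participants[idx[, "col"]]
  )
}

# Linear index of pair (i, j), i < j, into the canonical enumeration of
# dyad_pairs(); vectorized, positions are 1-based participant positions.
dyad_linear_index <- function(i, j, n) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  if (any(lo == hi)) abort("Self-pairs have no dyad index.")
  (lo - 1) * n - lo * (lo - 1) / 2 + (hi - lo)
}

# Sorts and validates a long per-dyad, per-region table against the canonical
# dyad order; returns list(values = regions x dyads matrix, regions, pairs).
dyad_value_matrix <- function(isc, participants, column) {
  pairs <- dyad_pairs(participants)
  n <- length(participants)
  pos <- stats::setNames(seq_len(n), participants)
  bad <- !(isc$dyad_i %in% participants) | !(isc$dyad_j %in% participants)
  if (any(bad)) {
    abort("ISC table contains dyads outside the participant set.")
  }
  d_idx <- dyad_linear_index(pos[isc$dyad_i], pos[isc$dyad_j], n)
  regions <- sort(unique(isc$region))
  r_idx <- match(isc$region, regions)
  values <- matrix(NA_real_, nrow = length(regions), ncol = nrow(pairs),
                   dimnames = list(regions, NULL))
  values[cbind(r_idx, d_idx)] <- isc[[column]]
  if (anyNA(values)) {
    abort(paste0(
      "Column `", column, "` is missing for some (dyad, region) cells; ",
      "the canonical dyad set must be complete."
    ))
  }
  list(values = values, regions = regions, pairs = pairs)
}
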