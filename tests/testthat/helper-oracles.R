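# Small fixture builders and independent oracles used across the suite.

# Compact study config for fast end-to-end runs.
mini_config <- function(seed = 1, ...) {
  synth_config(n_participants = 10, n_regions = 3, n_runs = 2,
               timepoints_per_run = 50, n_communities = 2,
               effect_regions = 1, seed = seed, ...)
}

# Attaches a same-community indicator to the canonical dyad table of a config.
community_dyads <- function(config) {
  dy <- dyad_pairs(config$participants)
  comm <- config$community
  dy$same_comm <- comm[match(dy$dyad_i, config$participants)] ==
    comm[match(dy$dyad_j, config$participants)]
  dy
}

# All-pairs shortest path oracle (Floyd-Warshall) on a 0/1 adjacency matrix.
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  d
}

# Benjamini-Hochberg step-up by direct construction.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Brute-force reimplementation of the similarity chain with direct formulas:
# per-dyad Pearson over concatenated runs, per-region winsorize at the
# 1.5*IQR fences, atanh, z-score with the population s.d.
chain_oracle <- function(timeseries, participants) {
  pearson <- function(x, y) {
    xm <- x - mean(x); ym <- y - mean(y)
    sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  }
  concat <- lapply(stats::setNames(participants, participants), function(p) {
    rows <- timeseries[timeseries$participant == p, ]
    rows <- rows[order(rows$run), ]
    do.call(cbind, rows$series)
  })
  regions <- rownames(concat[[1]])
  out <- NULL
  for (a_i in seq_along(participants)) {
    for (b_i in seq_along(participants)) {
      if (a_i >= b_i) next
      for (r in regions) {
        out <- rbind(out, data.frame(
          dyad_i = participants[a_i], dyad_j = participants[b_i], region = r,
          isc_raw = pearson(concat[[a_i]][r, ], concat[[b_i]][r, ])
        ))
      }
    }
  }
  for (r in regions) {
    v <- out$isc_raw[out$region == r]
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    lo <- q[1] - 1.5 * (q[2] - q[1]); hi <- q[2] + 1.5 * (q[2] - q[1])
    w <- pmin(pmax(v, lo), hi)
    z <- atanh(w)
    zn <- (z - mean(z)) / sqrt(mean((z - mean(z))^2))
    out$isc_winsorized[out$region == r] <- w
    out$isc_fisher_z[out$region == r] <- z
    out$isc_normalized[out$region == r] <- zn
  }
  out
}

# A raw tibble of per-dyad, per-region values over the canonical dyads of
# `participants`, with a fixed metadata table; used to feed contrasts with
# hand-chosen numbers.
manual_isc <- function(participants, values_by_region) {
  pairs <- dyad_pairs(participants)
  out <- NULL
  for (r in names(values_by_region)) {
    stopifnot(length(values_by_region[[r]]) == nrow(pairs))
    out <- rbind(out, cbind(pairs, region = r,
                            isc_normalized = values_by_region[[r]]))
  }
  tibble::as_tibble(out)
}

# Directed Erdos-Renyi nomination roster.
random_roster <- function(n, p, seed) {
  ids <- sprintf("v%02d", seq_len(n))
  withr::with_seed(seed, {
    a <- matrix(stats::runif(n * n) < p, n, n)
  })
  diag(a) <- FALSE
  idx <- which(a, arr.ind = TRUE)
  tibble::tibble(src = ids[idx[, 1]], dst = ids[idx[, 2]])
}
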