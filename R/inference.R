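# Aligns a per-dyad metadata table to the canonical pair enumeration
# (unordered match); every canonical pair must be covered exactly once.
align_dyads <- function(dyads, pairs) {
  dd <- as_tibble(dyads)
  if (!all(c("dyad_i", "dyad_j") %in% names(dd))) {
    abort("`dyads` needs columns `dyad_i` and `dyad_j`.")
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  kd <- key(dd$dyad_i, dd$dyad_j)
  if (anyDuplicated(kd) > 0) abort("`dyads` lists some pair more than once.")
  kp <- key(pairs$dyad_i, pairs$dyad_j)
  m <- match(kp, kd)
  if (anyNA(m)) {
    abort("`dyads` does not cover every dyad of the ISC table.")
  }
  dd <- dd[m, , drop = FALSE]
  dd$dyad_i <- pairs$dyad_i
  dd$dyad_j <- pairs$dyad_j
  dd
}

# Evaluates the two group predicates (+ optional exclusion) over the aligned
# dyad table; returns disjoint logical masks.
contrast_masks <- function(dyads, group_a, group_b, exclude) {
  a <- eval_tidy(group_a, data = dyads)
  b <- eval_tidy(group_b, data = dyads)
  if (!is.logical(a) || !is.logical(b) ||
      length(a) != nrow(dyads) || length(b) != nrow(dyads)) {
    abort("Group predicates must evaluate to per-dyad logical vectors.")
  }
  a[is.na(a)] <- FALSE
  b[is.na(b)] <- FALSE
  if (!quo_is_null(exclude)) {
    ex <- eval_tidy(exclude, data = dyads)
    ex[is.na(ex)] <- FALSE
    a <- a & !ex
    b <- b & !ex
  }
  if (any(a & b)) abort("Contrast groups overlap.")
  if (!any(a) || !any(b)) {
    abort(sprintf("Empty contrast group after exclusions (A: %d, B: %d dyads).",
                  sum(a), sum(b)))
  }
  list(a = a, b = b)
}

# n_perm random relabelings of 1..n, one per row; deterministic given seed.
permutation_indices <- function(n, n_perm, seed) {
  withr::with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
  })
}

# Source dyad index for every canonical dyad under relabeling `perm`:
# dyad (i, j) takes the value of dyad (perm[i], perm[j]).
relabel_dyad_index <- function(perm, pair_i, pair_j) {
  dyad_linear_index(perm[pair_i], perm[pair_j], length(perm))
}

#' Observed between-group difference in mean neural similarity
#'
#' Mean similarity over group-A dyads minus mean over group-B dyads, per
#' region. Group membership is expressed as tidy-eval predicates over the
#' per-dyad metadata table.
#'
#' @param isc ISC table from [normalize_isc()] (or [compute_isc()] when
#'   using `stage = "isc_raw"`).
#' @param dyads Per-dyad metadata covering every dyad of `isc` (columns
#'   `dyad_i`, `dyad_j` plus whatever the predicates use).
#' @param group_a,group_b Unquoted logical predicates over `dyads`, e.g.
#'   `distance_t3 == 1` and `distance_t3 %in% c(2, 3)`.
#' @param stage Which similarity column to contrast (default
#'   `"isc_normalized"`).
#' @param exclude Optional predicate flagging dyads to drop from both groups
#'   (e.g. `prior_interaction`).
#' @return Tibble `region`, `observed_diff`, `n_a`, `n_b`.
#' @export
group_difference <- function(isc, dyads, group_a, group_b,
                             stage = "isc_normalized", exclude = NULL) {
  participants <- sort(unique(c(isc$dyad_i, isc$dyad_j)))
  vm <- dyad_value_matrix(isc, participants, stage)
  dd <- align_dyads(dyads, vm$pairs)
  g <- contrast_masks(dd, enquo(group_a), enquo(group_b), enquo(exclude))
  tibble(
    region = vm$regions,
    observed_diff = unname(rowMeans(vm$values[, g$a, drop = FALSE]) -
                             rowMeans(vm$values[, g$b, drop = FALSE])),
    n_a = sum(g$a), n_b = sum(g$b)
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values across the family of tested regions (a thin
#' wrapper over [stats::p.adjust()]; missing p-values are dropped from the
#' family and returned as `NA`).
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return q-values of the same length.
#' @export
fdr_bh <- function(p) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in (0, 1].")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (sum(!ok)) inform(sprintf("%d missing p-value(s) dropped from the FDR family.",
                               sum(!ok)))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Contrast of dyadic neural similarity between two groups of dyads
#'
#' The package's central inference routine. Per region it computes the
#' observed difference in mean similarity between two groups of dyads, a
#' node-level permutation p-value, Benjamini-Hochberg q-values across
#' regions, and a participant-level bootstrap confidence interval.
#'
#' The permutation null shuffles which participant owns which neural dataset:
#' one relabeling per permutation, applied jointly to every region, with the
#' dyad's group membership (the social-network side) held fixed. Because a
#' dyad's similarity depends only on the unordered pair of datasets, the null
#' is formed by re-indexing the precomputed dyadic similarities — dyad
#' `(i, j)` takes the value of `(perm(i), perm(j))` — which is
#' permutation-for-permutation identical to re-correlating shuffled raw data.
#' One-sided p-values use add-one smoothing, `(1 + #\{null >= obs\}) / (1 +
#' n_perm)`, with ties counted conservatively.
#'
#' The bootstrap resamples participants with replacement, keeps the unique
#' set, forms all dyads among them, and recomputes the group difference from
#' the precomputed similarities; the interval is the 2.5% / 97.5% percentile
#' of the replicate distribution. Replicates that empty a group are redrawn
#' (bounded retries, count reported in the object).
#'
#' @inheritParams group_difference
#' @param n_perm Number of permutations (study default 1000).
#' @param n_boot Number of bootstrap replicates (study default 1000).
#' @param seed Integer seed; permutations and bootstrap use independent
#'   substreams derived from it.
#' @param level Confidence level of the bootstrap interval.
#' @param name Optional label for the contrast.
#' @param keep_null Keep the regions x n_perm null-difference matrix in the
#'   returned object (for audit); default `FALSE`.
#' @return An object of class `isc_contrast`; see [tidy()] / [glance()] /
#'   [autoplot()] methods.
#' @examples
#' study <- simulate_study(synth_config(n_participants = 8, n_regions = 2,
#'                                      n_runs = 1, timepoints_per_run = 40,
#'                                      seed = 7))
#' isc <- normalize_isc(compute_isc(study$timeseries))
#' dyads <- dplyr::mutate(generate_dyad_flags(study$config),
#'                        same_comm = study$config$community[match(dyad_i,
#'                          study$participants)] ==
#'                          study$config$community[match(dyad_j,
#'                          study$participants)])
#' fit <- isc_contrast(isc, dyads, same_comm, !same_comm,
#'                     n_perm = 50, n_boot = 50, seed = 1)
#' tidy(fit)
#' @export
isc_contrast <- function(isc, dyads, group_a, group_b,
                         stage = "isc_normalized",
                         n_perm = 1000, n_boot = 1000, seed = 1L,
                         level = 0.95, exclude = NULL, name = NULL,
                         keep_null = FALSE) {
  if (n_perm < 1 || n_boot < 1) abort("`n_perm` and `n_boot` must be >= 1.")
  participants <- sort(unique(c(isc$dyad_i, isc$dyad_j)))
  n <- length(participants)
  vm <- dyad_value_matrix(isc, participants, stage)
  dd <- align_dyads(dyads, vm$pairs)
  g <- contrast_masks(dd, enquo(group_a), enquo(group_b), enquo(exclude))
  V <- vm$values
  observed <- unname(rowMeans(V[, g$a, drop = FALSE]) -
                       rowMeans(V[, g$b, drop = FALSE]))

  pos <- stats::setNames(seq_len(n), participants)
  pair_i <- pos[vm$pairs$dyad_i]
  pair_j <- pos[vm$pairs$dyad_j]
  if (n < 500 && factorial(min(n, 10)) < n_perm) {
    inform("Few participants relative to n_perm: permutations are sampled with replacement.")
  }
  perms <- permutation_indices(n, n_perm, seed)
  null_diffs <- matrix(NA_real_, nrow(V), n_perm,
                       dimnames = list(rownames(V), NULL))
  for (k in seq_len(n_perm)) {
    src <- relabel_dyad_index(perms[k, ], pair_i, pair_j)
    null_diffs[, k] <- rowMeans(V[, src[g$a], drop = FALSE]) -
      rowMeans(V[, src[g$b], drop = FALSE])
  }
  p_value <- unname((1 + rowSums(null_diffs >= observed)) / (1 + n_perm))
  q_value <- fdr_bh(p_value)

  alpha <- (1 - level) / 2
  boot <- matrix(NA_real_, nrow(V), n_boot)
  redraws <- 0L
  withr::with_seed(seed + 1000003L, {
    for (b in seq_len(n_boot)) {
      repeat {
        uniq <- unique(sample.int(n, n, replace = TRUE))
        keep <- pair_i %in% uniq & pair_j %in% uniq
        a_b <- g$a & keep
        b_b <- g$b & keep
        if (any(a_b) && any(b_b)) break
        redraws <- redraws + 1L
        if (redraws > 1000L) abort("Bootstrap exceeded 1000 redraws of degenerate replicates.")
      }
      boot[, b] <- rowMeans(V[, a_b, drop = FALSE]) -
        rowMeans(V[, b_b, drop = FALSE])
    }
  })
  ci <- t(apply(boot, 1, quantile, probs = c(alpha, 1 - alpha), names = FALSE))

  res <- tibble(
    region = vm$regions,
    observed_diff = observed,
    p_value = p_value,
    q_value = q_value,
    ci_lower = ci[, 1],
    ci_upper = ci[, 2],
    n_a = sum(g$a),
    n_b = sum(g$b)
  )
  structure(list(
    result = res,
    name = name %||% "contrast",
    stage = stage,
    n_perm = n_perm, n_boot = n_boot, seed = as.integer(seed),
    level = level,
    boot_redraws = redraws,
    null_diffs = if (keep_null) null_diffs else NULL
  ), class = "isc_contrast")
}

#' Node-level permutation test without the bootstrap
#'
#' Convenience wrapper around [isc_contrast()] machinery returning only the
#' permutation side (observed difference, p, q) — useful in simulation loops.
#'
#' @inheritParams isc_contrast
#' @return Tibble `region`, `observed_diff`, `p_value`, `q_value`.
#' @export
node_permutation_test <- function(isc, dyads, group_a, group_b,
                                  stage = "isc_normalized",
                                  n_perm = 1000, seed = 1L, exclude = NULL) {
  participants <- sort(unique(c(isc$dyad_i, isc$dyad_j)))
  n <- length(participants)
  vm <- dyad_value_matrix(isc, participants, stage)
  dd <- align_dyads(dyads, vm$pairs)
  g <- contrast_masks(dd, enquo(group_a), enquo(group_b), enquo(exclude))
  V <- vm$values
  observed <- unname(rowMeans(V[, g$a, drop = FALSE]) -
                       rowMeans(V[, g$b, drop = FALSE]))
  pos <- stats::setNames(seq_len(n), participants)
  pair_i <- pos[vm$pairs$dyad_i]
  pair_j <- pos[vm$pairs$dyad_j]
  perms <- permutation_indices(n, n_perm, seed)
  exceed <- integer(nrow(V))
  for (k in seq_len(n_perm)) {
    src <- relabel_dyad_index(perms[k, ], pair_i, pair_j)
    nd <- rowMeans(V[, src[g$a], drop = FALSE]) -
      rowMeans(V[, src[g$b], drop = FALSE])
    exceed <- exceed + (nd >= observed)
  }
  p <- unname((1 + exceed) / (1 + n_perm))
  tibble(region = vm$regions, observed_diff = observed,
         p_value = p, q_value = fdr_bh(p))
}

#' Participant-level bootstrap confidence interval alone
#'
#' @inheritParams isc_contrast
#' @return Tibble `region`, `observed_diff`, `ci_lower`, `ci_upper`.
#' @export
bootstrap_ci <- function(isc, dyads, group_a, group_b,
                         stage = "isc_normalized",
                         n_boot = 1000, seed = 1L, level = 0.95,
                         exclude = NULL) {
  fit <- isc_contrast(isc, dyads, {{ group_a }}, {{ group_b }},
                      stage = stage, n_perm = 1, n_boot = n_boot,
                      seed = seed, level = level, exclude = {{ exclude }})
  select(fit$result, "region", "observed_diff", "ci_lower", "ci_upper")
}

#' @export
print.isc_contrast <- function(x, ...) {
  cat(sprintf("<isc_contrast> %s on %s (%d regions; %d vs %d dyads)\n",
              x$name, x$stage, nrow(x$result),
              x$result$n_a[1], x$result$n_b[1]))
  cat(sprintf("  n_perm = %d, n_boot = %d, seed = %d; %d region(s) with q < 0.05\n",
              x$n_perm, x$n_boot, x$seed, sum(x$result$q_value < 0.05)))
  invisible(x)
}

#' Tidy a dyadic similarity contrast
#'
#' @param x An [isc_contrast()] object.
#' @param ... Unused.
#' @return The per-region result tibble with a leading `contrast` column.
#' @export
tidy.isc_contrast <- function(x, ...) {
  bind_cols(tibble(contrast = x$name), x$result)
}

#' One-row summary of a dyadic similarity contrast
#'
#' @param x An [isc_contrast()] object.
#' @param ... Unused.
#' @return Tibble with region/dyad counts, settings, and the number of
#'   FDR-significant regions at q < 0.05.
#' @export
glance.isc_contrast <- function(x, ...) {
  tibble(
    contrast = x$name,
    n_regions = nrow(x$result),
    n_significant = sum(x$result$q_value < 0.05),
    min_q = min(x$result$q_value),
    n_a = x$result$n_a[1], n_b = x$result$n_b[1],
    n_perm = x$n_perm, n_boot = x$n_boot,
    boot_redraws = x$boot_redraws, seed = x$seed
  )
}

#' Plot a dyadic similarity contrast
#'
#' Regions ranked by observed group difference, with bootstrap intervals and
#' FDR-significant regions highlighted.
#'
#' @param object An [isc_contrast()] object.
#' @param alpha_q Significance threshold on the q-value for highlighting.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.isc_contrast <- function(object, alpha_q = 0.05, ...) {
  df <- object$result |>
    arrange(.data$observed_diff) |>
    mutate(rank = row_number(),
           significant = .data$q_value < alpha_q)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$observed_diff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$ci_lower,
                                         ymax = .data$ci_upper),
                            colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 1.2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
                                 name = sprintf("q < %.2f", alpha_q)) +
    ggplot2::labs(
      title = object$name,
      x = "region (ranked by observed difference)",
      y = sprintf("group difference in %s", object$stage)
    ) +
    ggplot2::theme_minimal()
}
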