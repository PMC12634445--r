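---
title: "Methods: dyadic ISC, social distance, and valid inference on dyads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyadic ISC, social distance, and valid inference on dyads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model the package implements, the
choices that were genuinely open when it was designed, the numerical
conventions it fixes, and what its validation on synthetic data does and
does not establish.

## The design

The package analyses a longitudinal social-neuroscience design: a cohort's
members are scanned while watching the same naturalistic stimuli *before*
they meet, their friendship network is surveyed twice afterwards (an early
wave, T2, and a later wave, T3), and the question is whether pre-existing
neural similarity between two people predicts (a) how close they end up in
the network and (b) whether they grow closer or drift apart between the
waves. The unit of analysis is the *dyad* — an unordered pair of
participants — which makes observations mutually dependent (every
participant appears in n − 1 dyads) and rules out off-the-shelf i.i.d.
inference. Everything in the package flows from taking that dependence
seriously.

## Similarity chain

Per region, a dyad's similarity is the Pearson correlation between the two
participants' concatenated time series. Across the full dyad set, per
region and in this fixed order, values are then

1. **winsorized** at the 1.5×IQR fences: values above Q3 + 1.5·IQR are
   reassigned exactly that fence (below Q1 − 1.5·IQR likewise);
2. **Fisher-z transformed** (atanh), the variance-stabilizing scale on
   which correlations may be averaged and regressed;
3. **normalized**: centred and divided by the population (divide-by-n)
   standard deviation across dyads.

Numerical conventions, each fixed once:

* Quartiles use linear interpolation of order statistics
  (`stats::quantile` type 7), the default of the mainstream numerical
  stacks this kind of pipeline is usually built on.
* The normalization uses the population s.d., matching the behavior of the
  standard scalers in those stacks (divide by n, not n − 1).
* A raw correlation of magnitude exactly 1 (possible only in degenerate
  data) is clipped to 1 − 10⁻⁷ before atanh, with a warning.
* Winsorization fences are computed once on the full included dyad set,
  upstream of every contrast, and are *not* recomputed when sensitivity
  analyses drop dyads: the outlier model belongs to the dataset, not to a
  subgroup.
* When participants have unequal numbers of usable runs, each dyad is
  correlated over the **intersection** of the two members' runs,
  concatenated in run order — the only choice that keeps both series
  time-locked to the same stimuli.
* Zero-variance series yield a missing correlation with a warning rather
  than an error; a missing region is dropped from the FDR family with a
  message.

## Social distance

Only mutual nominations form edges; distance is the geodesic hop count on
the reciprocal graph, computed on the full cohort graph and read out for
the imaged dyads (paths may run through non-imaged cohort members, so the
pipeline accepts a cohort roster that is a superset of the imaging
sample). Distances above the cap (default 3) are recoded to the cap —
dyadic similarity effects are not expected to be resolvable beyond three
to four degrees of separation, and sparse graphs otherwise produce long
unstable distances.

Two decisions here were open:

* **Unreachable dyads.** A real, well-connected cohort has none, so no
  published convention exists. The default policy treats an unreachable
  dyad as being at the cap, with a warning (keeping sparse synthetic cases
  runnable); an `exclude` policy drops such dyads instead.
* **Which waves to cap.** The package caps both waves by default. A large
  cohort graph rarely needs the cap at the later, denser wave, but a small
  synthetic cohort can produce 4-step or unreachable dyads at either wave,
  and an uncapped value at one wave would silently shift dyads out of
  every contrast level. Capping both keeps the contrast partition
  exhaustive; the change category is computed after capping.

The change category is the sign of d(T3) − d(T2): closer / same / apart.

## Node-level permutation inference

The null model shuffles which participant owns which neural dataset. One
relabeling π is drawn per permutation and applied *jointly to all
regions*, while the network side of every dyad stays fixed; this preserves
both the dyadic dependency structure and the across-region dependence.
Because a dyad's similarity depends only on the unordered pair of
datasets, the permuted similarity of dyad (i, j) is the precomputed
similarity of (π(i), π(j)) — so the null can be built by re-indexing the
dyad × region matrix instead of re-correlating raw series. The two routes
are proven equal, permutation for permutation, in the test suite; the
re-indexing turns an O(n_perm · dyads · T) computation into
O(n_perm · dyads).

P-values are one-sided with add-one smoothing, p = (1 + #{null ≥
observed}) / (1 + n_perm), so p is never zero and ties count against the
hypothesis (conservative). FDR is Benjamini–Hochberg across the regions of
one contrast; the three contrasts of each analysis family are corrected
separately, mirroring a per-analysis correction.

When the participant count is so small that distinct permutations are
scarce, permutations are sampled with replacement (a standard Monte-Carlo
null) and a message says so.

## Participant bootstrap

Each replicate resamples participants with replacement, deduplicates to
the unique set, forms all dyads among those participants, and recomputes
the group difference from the *precomputed* normalized similarities (no
re-winsorization or re-normalization per replicate — the similarity table
is an estimate of population quantities, and resampling it rather than
re-deriving it is what the retrieval-based procedure implies). The 95%
interval is the percentile interval of the replicate distribution. A
replicate that empties a contrast group is redrawn, with a bounded retry
budget and the redraw count reported in the fitted object; redrawing (vs
skipping) keeps the replicate count at its nominal value.

A genuine limitation, documented rather than hidden: the participant
bootstrap quantifies uncertainty from *participant sampling*. In data
where a dataset-level common component dominates — e.g. when the finite
realization of the stimulus-locked shared signal shifts all dyads'
correlations together — no participant resampling scheme can see that
component, and intervals narrow toward it. The coverage validation below
therefore runs in an idiosyncratic-noise-dominated regime (several
communities, σ > β), where participant sampling is the dominant
uncertainty and the percentile interval attains its nominal level. Users
applying the bootstrap to a single fixed stimulus should interpret the
interval as conditional on that stimulus.

## Covariate control and the reduction statistic

Dyadic covariates are built one regressor at a time: the Euclidean
distance between two participants' 14-stimulus rating vectors (a
*distance*: larger = less similar, used as-is), and sociodemographic
similarities. The encodings were not prescribed anywhere, so the package
fixes the simplest faithful ones and records them: categorical variables
(gender, nationality, hometown location, alma-mater location, institution
type, major, industry) become match indicators; age becomes the negative
absolute difference; hometown population the negative absolute difference
of log10 populations (populations span orders of magnitude). Each
regressor is z-scored across dyads — also a choice, flagged as such; it
changes nothing about OLS residuals beyond conditioning.

Controlled similarities are OLS residuals of the normalized ISC on an
intercept plus the covariates, per region (constant and collinear columns
dropped, order-stable, with warnings). The **reduction statistic** is
(raw group difference) − (controlled group difference). Its null shuffles
the covariate at the *participant* level — whole rating vectors, or whole
demographic records as a block — recomputes the dyadic covariate matrix
and the controlled difference, and re-evaluates the reduction; enjoyment
and interest are controlled separately, and single-variable demographic
follow-ups (e.g. gender only) run the same operation with a restricted
covariate set. Because a participant-level shuffle permutes the dyad index
of the covariate matrix, and z-scoring is invariant to that permutation,
the implementation re-indexes the precomputed matrix; equality with full
recomputation is asserted in the tests.

## The synthetic generator

Community membership is the single latent driver of all four data
streams — neural, network, ratings, demographics — which is the minimal
generative model that reproduces every association the pipeline tests
(neural homophily and its covariate confounding):

* **Time series**: x(t) = α·s(t) + β·u_c(t) + σ·ε(t) per region, with
  standard-normal white processes; expected ISC is closed-form,
  (α² + β²·1[same community]) / (α² + β² + σ²) in effect regions. White
  noise was chosen although real BOLD is autocorrelated: the expectation
  of Pearson ISC is unchanged by temporal autocorrelation, and the
  permutation inference operates across dyads, not time. An AR(1)
  coefficient is available as a config option (default 0) and the
  closed-form recovery is tested under it.
* **Networks**: wave-1 nominations are Bernoulli with within/between
  community probabilities; wave 2 flips ties with form/dissolve
  probabilities. The defaults (0.48/0.18 within/between, 0.20/0.15
  form/dissolve) were calibrated once so that a 41-person cohort
  reproduces the order of magnitude of the margins a real cohort of that
  size shows — roughly 65 friend dyads at the early wave rising to ~100
  at the late wave, with "grew closer" outnumbering "grew apart" —
  and were not revisited afterwards. A 41-node cohort cannot
  simultaneously match the distance-2-heavy histogram of a 288-node
  cohort graph (mean reciprocal degree scales with cohort size); the
  friend counts and change-direction margins, which set contrast group
  sizes, take priority.
* **Ratings**: latent value = coupling·(community profile) + (1 −
  coupling)·noise, centred at the scale midpoint, then discretized by
  round-and-clamp to 1..5 — the simplest mapping that preserves ordinal
  structure. Coupling 1 makes ratings identical within a community;
  coupling 0 removes all planted structure.
* **Demographics**: each community has modal category levels adopted with
  probability 0.5 + 0.5·coupling; age ~ N(28.6, 2.15²) (a realistic
  graduate-cohort age distribution), hometown population log-normal.

What the generator does **not** emulate: voxel-level images, head motion,
hemodynamics, participant-level response heterogeneity (no per-person
loading variation), social-influence dynamics (neural convergence after
tie formation), or the marginal distribution of real ISC values — the
tolerances are calibrated to the closed form, not to empirical ISC maps.
Passing tests therefore demonstrate the *statistical machinery* is
correct and calibrated, not that real data meet its assumptions.

## Validation and problem sizes

The acceptance suite fixes these scales as the package's validation
conditions:

* **Closed-form recovery**: mean dyadic ISC within ±0.02 of 2/3
  (same-community) and 1/3 (cross-community) at 10,000 timepoints,
  α = β = σ = 1.
* **Oracle equivalence**: geodesics vs Floyd–Warshall on 100 random
  graphs of up to 50 nodes; relabel-vs-recompute permutation nulls
  matched seed-for-seed on a 6-participant fixture; OLS residualization
  vs the normal equations at 10⁻¹⁰.
* **Type-I calibration**: 400 null datasets (β = 0), 200 permutations
  each; the rejection rate at α = 0.05 must sit inside the binomial 99%
  band around 0.05.
* **Power**: at cohort scale (41 participants, 214 regions, 6 runs of
  100 timepoints, 24 planted effect regions, 500 permutations), at least
  80% of planted regions FDR-significant; observed in practice: all of
  them, with no false positives.
* **Bootstrap coverage**: 200 simulations × 500 replicates in the
  idiosyncratic-noise regime (16 participants, 4 communities, σ = 2);
  coverage of the closed-form Fisher-z group difference inside the
  binomial 99% band around 95%.
* **Reduction test**: p uniform (Kolmogorov–Smirnov) over 200 null
  simulations with rating coupling 0; power ≥ 0.8 under full mediation
  (coupling 1), observed ≈ 1.

## Known limitations

* The pipeline consumes parcel-level time series; preprocessing (nuisance
  regression, filtering, parcellation of volumetric data beyond the
  simple voxel-averaging helper) is out of scope.
* Six runs concatenated is the modal case; the run-intersection rule also
  covers participants with excluded runs, but datasets whose run
  *timings* differ across participants are not supported — concatenation
  assumes time-locked stimuli.
* The bootstrap caveat above: intervals are conditional on the stimulus
  realization.
* No parametric (mixed-model) alternative and no spatial cluster
  correction are provided; the permutation/FDR path is the only inference
  route.
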