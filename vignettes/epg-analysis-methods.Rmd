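---
title: "Models and methods behind epgkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epgkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epgkit)
```

`epgkit` turns annotated electrical penetration graph (EPG) recordings of
aphid probing into behavioral variables, links them to aphid performance and
leaf condensed-tannin (CT) chemistry, and ships a behavioral simulator for
validating every step. This vignette explains the models, the conventions
and the tunable parameters, and states the design choices made where more
than one reasonable convention exists.

## Recordings and time representation

A recording is a contiguous partition of one session (default 8 h =
28 800 s) into labeled bouts over the waveform states `NP, C, PD, E1, E2,
F, G, RPD`. Onset times are read as decimal seconds and stored internally as
integer milliseconds, so segment durations telescope exactly: the sum of
per-label totals always equals the session length with no floating-point
drift. Adjacent same-label segments are merged at parse time, which makes
bout counts well defined ("pathway events per aphid" counts bouts, not
annotation lines). The annotation dialect — token plus onset per line,
whitespace or semicolon delimited, a terminal marker carrying the end time —
is deliberately minimal; `epg_codemap()` remaps other export vocabularies.

## Behavioral variable suite

`compute_parameters()` derives, per aphid, the standard probing-behavior
variables: counts, total/mean/max durations (reported in minutes), the PD
rate, the latency to first phloem salivation, the share of salivation in the
phloem phase, and per-activity time shares. Three rules deal with edge
cases and are applied uniformly:

* a waveform that never occurs contributes **0** to duration totals, a
  **missing value** to means (never a zero, which would bias cohort
  means), and the **full recording length** to its latency;
* a bout still running when the session ends is counted with its truncated
  duration;
* a pathway bout interrupted by potential drops counts as **one** bout
  whose duration sums the pathway pieces (PD punctuates pathway rather
  than terminating it; `merge_c_across_pd = FALSE` switches this off).
  PD time itself is excluded from pathway totals, and the PD rate divides
  the number of PD bouts by pathway minutes only.

Tunables (`param_config()`): the short-probe threshold (default 3 min), the
sustained-ingestion threshold (default 10 min), and the repetitive-PD
detector. Repetitive potential drops may arrive pre-annotated (`rpd_mode =
"annotated"`, the default, since annotators that distinguish them exist) or
be derived (`"derived"`): a maximal run of at least `rpd_min_pds = 2` PDs
separated only by pathway gaps of at most `rpd_gap_s = 15` s is relabeled as
one RPD bout from the first PD's onset to the last PD's offset. The gap and
run-length defaults encode the usual reading of "repetitive" cell punctures;
both are exposed because annotation practice varies between laboratories.

Cohort summaries report mean ± SE over non-missing values; the SE of a
single observation prints as 0 (the `x ± 0` convention of published cohort
tables), and percent-performing values are rounded half-up to integers.

## Life-table demography

For each founder aphid, `d` is the first observation day with a positive
nymph count and `M_d` the total nymph production (the summed daily counts
under the removal protocol; the final standing count under the census
protocol). The intrinsic rate of increase uses the Wyatt–White
approximation `r_m = 0.738 ln(M_d)/d` with the published cross-species
correction constant 0.738, and the doubling time is `DT = ln(2)/r_m`. The
`ln 2` numerator is a declared choice: the doubling-time definition is
sometimes printed without its argument, and `ln 2` is the standard
exponential-growth doubling constant (it also reproduces the familiar
`r_m ≈ 0.18 → DT ≈ 3.9 d` correspondence). Undefined quantities (`M_d = 0`,
or `r_m ≤ 0`) are reported as missing, never silently zeroed. Per-genotype
summaries average per-founder `r_m` and `DT` rather than evaluating the
formulas at averaged inputs.

## Statistical battery

* **Kruskal–Wallis / pairwise Mann–Whitney.** Tie-corrected H with a
  chi-square reference; pairwise tests are exact when both groups have at
  most 8 observations and no ties, otherwise the continuity- and
  tie-corrected normal approximation. Letters come from the
  insert-and-absorb compact-letter-display algorithm; two groups share a
  letter exactly when their pairwise p-value is at least `alpha`. No
  multiplicity adjustment is applied by default — letters reflect raw
  `p < .05` decisions, the convention of the cohort tables this mirrors —
  and a Holm option is available.
* **Sequential ANOVA.** Type I sums of squares in formula order, so df and
  SS are additive for unbalanced designs; rank deficiency beyond an
  estimable interaction is an error naming the aliased term.
* **Repeated-measures ANOVA.** Univariate mixed decomposition with the
  between factor tested against subject-within-group error and the within
  factor (and interaction) against the subject-by-time residual. Subjects
  with incomplete panels are dropped with a warning. The Greenhouse–Geisser
  epsilon is computed and attached, but uncorrected p-values are primary.
* **Negative-binomial mixed model.** `fit_nb_glmm()` maximizes the
  Laplace-approximated marginal likelihood of a log-link NB2 model
  (`Var = μ + μ²/θ`) with a Gaussian genotype random intercept, via
  glmmTMB. Degenerate designs fall back transparently: one group gives a
  plain NB GLM, a constant covariate an intercept-only fit whose intercept
  is the log sample mean. Non-convergence is flagged, never silent.
* **Overdispersion.** Pearson χ² against the fitted variance over residual
  df (`n` minus fixed effects, dispersion, and random-effect variance
  parameters); a ratio near 1 indicates the count model's variance is
  adequate. The check also accepts plain `glm` fits, where it exposes
  Poisson variance misspecification.
* **Normality.** Shapiro–Wilk on model residuals, `3 ≤ n ≤ 5000`.

## Sparse PLS-DA

The class contrast (high- vs low-CT host genotypes) uses a from-scratch
two-class sPLS-DA on the 16 duration-scale EPG variables — totals, means,
maxima, PD rate, and the salivation latency; counts and proportions are
excluded by design since they live on different scales and partly duplicate
the duration information. Per component the loading direction is the
dominant left singular vector of `X'Y` (X column-standardized, Y the
centered one-hot class indicator), soft-thresholded by absolute-value rank
so that exactly `keep_x` entries are nonzero (ties broken by column order),
renormalized, and both matrices are deflated in regression mode — making
successive scores orthogonal. `keep_x = 10` per component with two
components is the default working point ("a minimum of 10 variables" is
implemented as exactly 10, configurable). Classification assigns the
nearest class centroid in score space (Euclidean); cross-validation
stratifies folds and refits the entire pipeline — standardization included —
inside each fold, so no information leaks from held-out rows. In the dense
limit (`keep_x = p`) the fit coincides with reference PLS-DA
implementations to machine precision, which the test suite checks against
mixOmics.

Missing feature cells (mean-duration variables are missing when the
waveform never occurred) are mean-imputed with a logged count. The
pipeline-level wrapper additionally sets aside variables that are entirely
missing or constant in a given cohort, since they cannot be standardized.

## The synthetic-data generator

`simulate_recording()` draws a semi-Markov chain: from nonprobing,
alternately a gamma dwell time (per-state shape/scale, in seconds) and a
next state from an embedded transition matrix with zero diagonal. Stylet
logic is enforced structurally — from `NP` the only exit is into pathway;
`PD` and `E1` are enterable only from `C`; `E2` only from `E1`. Gamma (not
exponential) dwells let brief potential drops and hour-long phloem bouts
coexist in one family. The final bout is truncated at the session bound,
exactly as real recordings are.

The five shipped genotype profiles (two low-CT, three high-CT) are
calibrated only to reproduce the qualitative class contrasts reported for
aphids on aspen — longer nonprobing and phloem salivation on low-CT hosts;
more penetration difficulties and more xylem drinking (on the order of
10–20% of the session) on high-CT hosts — at realistic bout magnitudes.
They are not parameter estimates fitted to any real data set, and passing
simulator-based tests therefore demonstrates internal consistency of the
pipeline under plausible contrasts, not agreement with any particular
empirical cohort. Real EPG data also contain features the simulator does
not emulate: diurnal nonstationarity, annotator idiosyncrasies, within-
genotype plant effects, and serial dependence of dwell times.

Reproduction is simulated as `M ~ NB(mean = exp(a_g + β·CT_induced), θ)`
with default `β = −0.009` per mg/g and `θ = 2`; the first nymph appears on
day `d` by construction (so the life-table derivation inverts the simulator
exactly under the removal protocol) and remaining births decay
geometrically over a 20-day span. CT assays draw truncated-normal (≥ 0)
constitutive and induced concentrations per plant; the induction contrast
`delta_ct` is defined as induced − constitutive, so positive values mean
local CT accumulation in the colonized leaf — stated prominently because
the opposite sign convention also circulates. `simulate_nb_counts()`
exposes the bare count model (group intercepts `a_g ~ N(a, σ²)`, default
`σ² = 0.35`) for calibration studies.

## Numerical choices and problem sizes

Gradient-free conventions worth knowing: times live on the millisecond
grid; percent-performing rounds half-up; sPLS-DA threshold ties break by
column order; CV folds are a deterministic function of the seed. The test
suite validates the parameter suite against an independent brute-force
oracle on 1 000 random 8-h recordings, recovers the NB-GLMM slope over 200
replicates of a 5-genotype × 40-observation design (`β = −0.30`, `θ = 2`,
`σ² = 0.35`), calibrates the pairwise Mann–Whitney type-I error over
10 000 five-group null replicates, and checks the simulator's long-run
state shares against the semi-Markov stationary distribution at 100
sessions' length; these sizes keep the default run to a few minutes while
leaving Monte-Carlo error comfortably below the asserted bounds.

## Known limitations

Two-class discrimination only (the host contrast needs no multiclass
machinery); no zero-inflation or GEE variants of the count model; no
automatic waveform classification — annotation happens upstream; the
repeated-measures decomposition assumes complete panels after the drop
step; and the simulator's independence assumptions are stated above.
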