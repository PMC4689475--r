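---
title: "Models and methods behind emonet"
author: "emonet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind emonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emonet)
```

This vignette is the package's account of its statistical machinery: the
models it fits, the rules it applies, the generator it tests itself
against, and the choices made where more than one defensible option
existed.

## 1. The data model

An experience-sampling prompt yields one binary vector over a fixed,
ordered, valenced emotion checklist. `EmotionReportSet` stores a dataset as
a `SummarizedExperiment`: the `indicators` assay is an emotions × reports
0/1 matrix, `colData` holds participant id, timestamp and gender, and
`rowData` holds each emotion's valence. Two modelling commitments are baked
into the container rather than left to convention:

* **The all-zero vector is data, not missingness.** A prompt answered with
  "no emotion" is a legitimate report and is what the *none* category and
  the any-emotion complement are computed from. Skipped prompts, by
  contrast, simply never enter the dataset; the loader treats only answered
  prompts as reports, and no nonresponse model is attempted.
* **Timestamps are local clock time.** Hour-of-day analyses are about the
  participant's day (morning, mealtimes, evening), so timestamps are
  stored and binned in one clock with no timezone arithmetic. The hour bin
  is the floor of the clock hour; weekdays are ISO (Monday = 1).

Duplicate (participant, timestamp) pairs are kept with a warning — delayed
or snoozed prompts can legitimately produce them — and rows with
unparseable timestamps are rejected into a per-row log
(`metadata(x)$rejected`). A non-binary indicator value, by contrast, is
evidence of a malformed file and is fatal, naming the row and column.

## 2. Frequency estimation

The estimand for a target (an emotion, a report category, or "any
emotion") is the percentage of reports on which it is present. Reports are
nested in participants with wildly unequal cluster sizes (a handful of
reports to hundreds), so the pooled proportion's naive binomial interval
would be too narrow. `estimateFrequency()` fits a random-intercept linear
probability model

$$y_{ij} = \mu + u_i + e_{ij}, \qquad u_i \sim N(0, \sigma_u^2),$$

whose marginal covariance is compound symmetry (exchangeable within-person
correlation). The identity link is the default: the estimand is a marginal
percentage, and a linear model's intercept *is* that percentage, with a
symmetric Wald CI truncated to [0, 100]. A logit link (`glmer`) is offered
for users who prefer a bounded-scale model; note its intercept is a
conditional (median-participant) quantity, not the marginal one.

Degenerate inputs are handled explicitly rather than left to the fitter:

* variance component estimated at zero (singular fit) → pooled proportion
  with a cluster-robust CR0 standard error, small-sample corrected by
  G/(G−1) over G participants;
* a single participant → pooled proportion with an exact binomial CI,
  flagged `binomial-single-participant` (no between-person variance is
  estimable);
* a constant outcome (everyone endorses, or nobody does) → the CI
  collapses to the point estimate.

Every result row carries both the model-based estimate and the pooled
proportion, because the two answer slightly different questions and their
agreement is itself informative. The pooled category proportions satisfy
exact arithmetic — positive-only + negative-only + mixed + none = 100% and
any = 100% − none — by construction; the four independently fitted model
estimates satisfy it only approximately (well within half a percentage
point at the scales the package targets, tens of thousands of reports).

`frequencyTable()` emits 22 rows — 18 emotions sorted by descending
estimate (the canonical taxonomy order breaks ties), then the three
endorsement categories, then any-emotion — mirroring the conventional
presentation of such tables.

### Temporal profiles and fluctuation magnitude

`temporalProfile()` reports pooled per-bin frequencies. Two filters guard
against artefacts of uneven sampling: an hour window (default 6:00–22:00,
inclusive) excluding the sparsely sampled night, and a minimum bin size
(default 1,000 reports; lower it for desk-scale data — the rule, not the
constant, is the contract). The fluctuation-magnitude statistic is the mean
across an emotion set of the per-emotion standard deviation of hourly
frequencies, with the sample (n−1) denominator — the convention R's `sd()`
uses; with 17 hourly bins the choice moves the statistic by ~3%, and
nothing downstream depends on it. Profiles must span identical bins before
SDs are compared, so callers intersect bins first (the pipeline does this
automatically).

## 3. The emotion network

Edge weights are phi coefficients: Pearson correlations of the pooled 0/1
indicator vectors, computed across all reports of all participants. The
pooling is deliberate — the question "which emotions co-occur in everyday
moments" is about moments, not person-centered deviations — but a
`centered = TRUE` variant (participant means removed) is available as a
sensitivity analysis, and a permutation-based edge filter can be switched
on (`nPerm`); both are off by default because the primary analysis uses
raw correlation weights with no edge-level inference.

A constant indicator (a rare emotion never endorsed in a subsample) has no
defined correlation; those edges are stored as 0 and flagged in a mask, so
degree centrality — the sum of absolute incident weights, bounded by 17 —
remains defined in every sample. `degreeCentrality()` is a one-liner by
design; the test suite holds it against an explicit double-loop oracle.

### The connector / provincial / distal rule

The typology is defined by thresholding: an edge is *strong* iff
|φ| ≥ τ, and an emotion is

* **connector** — ≥1 strong same-valence *and* ≥1 strong opposite-valence
  edge;
* **provincial** — strong same-valence edges only;
* **distal** — no strong same-valence edge.

Two open points were decided here. First, τ: visual network inspection is
not reproducible, so the package makes the judgement explicit with a
default τ = 0.1 — small enough that genuine couplings at realistic
prevalences clear it, large enough that sampling noise at tens of
thousands of reports (SE ≈ 1/√n) does not. It is an operationalisation, and
τ is a first-class argument. Second, an emotion whose *only* strong edges
are opposite-valence: it co-occurs with nothing of its own kind, which is
closer to isolation than to brokerage, so it files as distal — and the
case is reported via a message so the user sees the judgement being made.

`compareCentrality()` is a paired t-test across the 18 emotions (df = 17)
with the paired Cohen's d = mean(Δ)/SD(Δ); an all-zero difference vector
returns t = d = 0 rather than an error, and a nonzero constant difference
is flagged degenerate. `frequencyCentralityCorrelation()` uses the Fisher
z interval at n = 18 via `cor.test`.

## 4. The synthetic generator

The generator exists so that every statistical claim in the package can be
tested against a known truth. It is a multivariate probit (thresholded
Gaussian copula) with one shared participant random intercept:

$$z_{ij} \sim \mathrm{MVN}(0, R), \qquad
  x_{ije} = \mathbf{1}\{u_i + z_{ije} + h_{t(ij),e} > c_e\},
  \qquad u_i \sim N(0, \sigma_u^2).$$

Thresholds are calibrated in closed form,
$c_e = \sqrt{1+\sigma_u^2}\,\Phi^{-1}(1-p_e)$, so marginal prevalences hit
their targets exactly regardless of $\sigma_u$. This is the simplest model
that simultaneously produces (a) arbitrary marginals, (b) a controllable
signed correlation structure, and (c) the within-person clustering the
multilevel frequency model assumes.

Defaults emulate a large smartphone ESM study: 11,572 participants; report
counts max(1, NegBin(μ = 5.7, size 0.3758)) — the size parameter follows
from the observed mean 5.7 and SD 9.6 via size = μ²/(σ²−μ), capturing the
heavy overdispersion of volunteer usage; 75% female; marginal prevalences
from joy 0.35 down to contempt 0.01; latent correlations +0.4 within
valence and −0.3 between (same-valence emotions co-occur, opposite-valence
emotions inhibit — a positive-definite two-block structure with
eigenvalues 7.3, 1.9, 0.6); prompt hours drawn from waking-hour weights
with a 9 AM mode inside a 9 AM–10 PM window. The random-intercept SD
defaults to $\sigma_u = 0.5$, i.e. a latent intraclass correlation of
$\sigma_u^2/(1+\sigma_u^2) = 0.2$ — a middle-of-the-road value for
momentary emotion endorsement, where person-level ICCs typically land
between 0.1 and 0.4. The optional `hourEffect` matrix adds an hour-specific
shift to the latent scale, giving hour-varying emission for tests of the
temporal machinery; it is zero by default.

Two numerical choices matter. MVN draws use the symmetric
eigendecomposition square root rather than Cholesky so that singular but
valid correlation matrices (a deliberately perfect ρ = 1 coupling) still
generate. And all randomness flows from the single config seed through one
sequential stream, so identical configs give bitwise-identical datasets.

### The implied-phi oracle

`impliedPhi()` converts a configuration into the population Pearson
correlation matrix of the *binary* indicators. Marginalising the shared
intercept, the total latent correlation is
$\rho^* = (\rho_{ab} + \sigma_u^2)/(1 + \sigma_u^2)$, and

$$\phi_{ab} = \frac{P_{11} - p_a p_b}
  {\sqrt{p_a(1-p_a)\,p_b(1-p_b)}}, \qquad
  P_{11} = P(Z_1 > \Phi^{-1}(1-p_a),\, Z_2 > \Phi^{-1}(1-p_b);\, \rho^*).$$

The orthant probability is computed by one-dimensional quadrature
(`integrate`, relative tolerance 1e−10) of
$\int_a^\infty \varphi(z)\,\Phi\!\big((\rho^* z - b)/\sqrt{1-\rho^{*2}}\big)\,dz$,
with exact limits at $\rho^* = \pm 1$; the test suite cross-checks it
against a 10⁶-draw Monte-Carlo estimate (agreement within 0.005) and
against the closed form $P_{11} = 1/4 + \arcsin(\rho)/(2\pi)$ at median
thresholds. Because phi is attenuated relative to the latent correlation —
heavily so at low prevalence — the oracle, not the latent matrix, is the
reference that `phiMatrix()` must recover on generated data (entrywise
within 0.02 at 2×10⁵ reports in the acceptance suite). A useful corollary
the tests assert: latent independence plus any $\sigma_u > 0$ implies
strictly positive phi between every pair — random intercepts alone
manufacture co-occurrence, which is exactly why the frequency model must
account for clustering.

Note one structural consequence of the defaults: with $\sigma_u = 0.5$ the
cross-valence total latent correlation is $(−0.3 + 0.25)/1.25 = −0.04$, so
implied cross-valence phi is near zero while same-valence phi stays well
above τ = 0.1 — the generating model's typology is "all provincial". The
typology recovery test checks that data reproduce exactly the labels
implied by thresholding `impliedPhi`, whatever those labels are.

### What the generator does and does not emulate

It reproduces marginal prevalences, a signed valence-block correlation
structure, participant-level clustering, overdispersed report counts, and
waking-hour prompt timing. It does **not** model serial dependence within
a day, nonresponse mechanisms (which emotions make people skip prompts),
arousal structure, or gender-specific correlation structure — men and
women are generated from the same process, so a group comparison on
synthetic data estimates a true difference of zero. Passing tests
therefore demonstrate that the estimators recover what they claim from
data satisfying their assumptions; they cannot certify behaviour under
real-world violations of those assumptions.

## 5. Problem sizes and reproducibility

The test suite works at three scales, chosen as the smallest at which each
property is actually about what it claims: hand-sized fixtures for exact
contracts; 10³–10⁵-report simulations for parameter recovery, coverage
(100 replicates of 500 participants × ~20 prompts) and the typology; and
one full-scale run (~65k reports) confirming the pipeline end-to-end. File
formats are engineered for exact round-trips: network weights are written
with 17 significant digits in both the edge-list CSV and GraphML, so
write-then-read reproduces the matrix bit-for-bit, and the pipeline's
bundle is byte-identical across reruns of the same config and seed (the
manifest records seed, config hash, package and R versions, warnings and
stage timings).

## 6. Known limitations

* The linear probability model can, in principle, produce CI endpoints
  outside [0, 100] before truncation; with percentages well inside the
  range and large n this is immaterial, but for very rare targets at small
  n the logit option is the better tool.
* Phi coefficients are bounded away from ±1 when marginals differ; comparing
  edge weights between emotions with very different prevalences conflates
  coupling strength with marginal mismatch. The typology threshold
  inherits this attenuation (a fixed τ is stricter, in latent terms, for
  rare emotions).
* The typology rule is an explicit stand-in for what is otherwise a visual
  judgement; labels near the threshold are sensitive to τ and to sampling
  error in small samples.
* Pooled phi mixes between- and within-person co-occurrence; the
  `centered` variant isolates the latter but changes the estimand.
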