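---
title: "Measuring healthcare acceptability from ordinal questionnaires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring healthcare acceptability from ordinal questionnaires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acceptindex)
```

## The measurement problem

Acceptability of care is a latent, multi-dimensional property: it cannot
be asked as a single question, but it shapes whether women use maternal
health services at all. This package operationalizes acceptability as
three constructs — the patient's interactions with healthcare
**Providers**, with the **Healthcare** system and its policies, and with
the surrounding **Community** — each measured through several ordinal
questionnaire items. The package's job is to go from a raw respondent ×
item table to (a) evidence that the items measure what they claim to
measure and (b) interpretable 0–100 indices per construct and overall.

## Data model and rescaling

Every item is mapped onto a common three-point scale: 1 (least
favorable), 2 (neutral), 3 (most favorable). The mapping lives in a
*codebook* (`item_spec()`, `codebook()`): each item carries its construct,
wording, polarity and an explicit label→score map. Two conventions are
worth stating:

* **Polarity is resolved in the codebook.** A reverse-worded item such as
  "Were you shouted at during labour?" maps its favorable answer ("no")
  to score 3. Downstream code therefore never branches on orientation.
* **Binary items never emit the neutral score.** A yes/no item maps its
  endpoints to 1 and 3 only; a 2 can appear for such an item only through
  imputation. This preserves the 1–3 bounds the index formula assumes
  while keeping the neutral score meaningful.

Missing responses are imputed to the neutral score and flagged
(`rescale_responses()`); the total count is carried in the result so
completeness is always visible. This treats missingness as ignorable — an
assumption, discussed under limitations.

## Suitability diagnostics

Index formation by factor analysis is only defensible when the items
actually co-vary. Three checks are applied (`fa_suitability()`), all of
which must pass: sample size above 250; Bartlett's sphericity test
(χ² = −[(n−1) − (2p+5)/6]·ln det R on p(p−1)/2 df) rejecting the identity
correlation matrix at p < 0.05; and overall KMO above 0.50, where KMO
compares squared correlations to squared anti-image partial correlations
computed from the scaled inverse of R. Correlations are ordinary Pearson
correlations of the 1–3 scores — the convention of the survey-analysis
lineage this package follows. Polychoric correlation would respect the
ordinal scale better but changes every downstream number; it is noted as
an extension, not silently substituted.

When factor analysis is unsuitable, the arithmetic route applies. Its own
suitability checks (`check_arith_suitability()`) are structural: equal
indicator counts per construct, a common scale, and a minimum sample
size. The reference rule for that minimum ("3 × number of items × number
of scale points", e.g. 3 × 18 × 3 = 162) is not defined precisely in the
source literature; the package implements this reading as a configurable
default rather than a fixed constant.

## Exploratory step

`principal_factor_extract()` performs **non-iterated principal-axis
factoring**: squared multiple correlations replace the diagonal of R and
the reduced matrix is eigendecomposed. This specific convention matters
for reproducibility: the reduced matrix has negative eigenvalues, and
variance proportions are computed against the *signed* total, so the
cumulative column can exceed 1 before returning to exactly 1.00 at the
last factor — the recognizable signature of this estimator in standard
survey software output. Retention uses eigenvalue > 1.0 with a warning
when the retained factors explain under 60 % of the variability.

Rotation (`rotate()`) delegates to `stats::varimax()` / `stats::promax()`.
Factor signs are arbitrary; before naming, each factor's sign is fixed so
its largest-|λ| loading is positive.

Cross-loading items (|λ| ≥ 0.4 on two or more retained factors) blur the
factor–construct correspondence. `prune_crossloadings()` removes them
iteratively, one per pass — the item whose construct is in the minority
among the salient items of its primary factor goes first, ties broken by
smallest communality — re-extracting after each removal. One-at-a-time
removal generalizes the single documented pruning action of the method's
origin while staying conservative; pruning refuses to push any construct
below three items, the floor for an identified measurement model.
`name_factors()` then names each factor by the construct owning the
majority of its salient items, and raises an ambiguity error rather than
guessing when two factors claim one construct.

## Confirmatory step

`build_model()` turns the three named factors into a measurement model:
each construct's indicators are the factor's salient items; latent
variances are fixed at 1 (so loadings are all free and latent covariances
are correlations). Identification by unit latent variance rather than by
a unit first loading was chosen deliberately: standardized-latent
parameterizations can legitimately produce standardized coefficients
slightly above 1 on ordinal data, and the reporting convention here marks
standardized values. Latent covariances are left free — the structure of
three related facets of one concept argues for it, and orthogonality is
testable afterwards through MSV.

`fit_ml()` minimizes the normal-theory discrepancy
F = ln|Σ| + tr(SΣ⁻¹) − ln|S| − p over loadings, latent correlations
(atanh-parameterized) and log unique variances with BFGS, starting from
per-construct principal components. χ² = (n−1)·F_min; the baseline model
is independence with free variances, so its χ² is −(n−1)·ln|R_S| on
p(p−1)/2 df. Standard errors come from the inverse observed information;
standardized loadings and their delta-method standard errors are computed
with a numerical Jacobian. Non-convergence returns a flagged result with
no indices rather than numbers of unknown provenance. Boundary
(Heywood-type) solutions surface as unavailable standard errors — again
visible, not masked.

The fit panel (`fit_indices()`) uses the max(·, 0) guarded definitions of
RMSEA and CFI so just-identified models report RMSEA 0 / CFI 1 instead of
NaN; the RMSEA 90 % CI inverts the noncentral χ² by root-finding, with
pclose = P(RMSEA ≤ 0.05); SRMR includes the diagonal of the standardized
residual matrix; CD = 1 − |Θ|/|Σ̂|, clamped to [0, 1]. The n−1 multiplier
convention is used throughout.

Since no independent structural-equation engine is available in this
package's dependency set, correctness of the ML fit is established in the
test suite through two independent routes: the closed-form solution of
the just-identified single-construct triad model (λ̂₁ = √(s₁₂s₁₃/s₂₃),
etc.), and parameter-recovery simulations from known generating models.

## Reliability and validity battery

Per construct: Cronbach's α = k/(k−1)·(1 − Σs²ᵢ/s²_T); composite
reliability CR = (Σλ)²/[(Σλ)² + Σ(1−λ²)] on **signed** standardized
loadings; AVE = mean(λ²); MSV = the maximum squared latent correlation
with any other construct. Two deliberate choices:

* **CR sums signed loadings.** A construct whose items load with mixed
  signs collapses toward CR ≈ 0 even when each |λ| is sizable. That is a
  real diagnostic — the items do not function as a consistent composite —
  and matches how CR is computed in the method's reference output. An
  `absolute = TRUE` option exists but is off by default.
* **MSV is the maximum squared inter-construct correlation**, not the
  square root of AVE. Verbal definitions of MSV sometimes conflate the
  two; only the squared-correlation definition is consistent with the
  near-zero MSV values that accompany weakly correlated constructs, and
  it is the standard definition. Discriminant validity is achieved iff
  AVE > MSV.

Verdict bands: α ideal > 0.70, acceptable 0.45–0.70; convergent validity
good if AVE > 0.50, borderline 0.35–0.50; CFI/TLI ideal > 0.95,
acceptable > 0.90; SRMR ideal < 0.05, acceptable 0.05–0.10; RMSEA ideal
< 0.05, acceptable 0.05–0.08 (stated in some templates with a shifted
decimal point — 0.5/0.8 — which contradicts the universal convention and
the pclose anchor at 0.05; the package applies the conventional scale and
says so in the report footer).

## The acceptability indices

The arithmetic construct index is implemented exactly as printed:

index = (n·max + 1 − Σsᵢ) / (n(max−min) + 1) × 100.

Evaluated verbatim, *low* scores yield *high* indices: all scores at the
minimum give 100, all at the maximum give 100/(n(max−min)+1) (≈ 7.69 for
n = 6 on 1–3, printed as 8). Because favorable responses are rescaled to
the highest scores, this subtractive orientation conflicts with the
natural reading "higher index = more acceptable". The package does not
resolve that conflict silently: the default is formula-verbatim, and an
`orientation = "favorable_low"` option reflects scores (s → min+max−s)
before the formula for callers who want the intuitive direction. The
overall index is the per-respondent mean of the three construct indices,
computed per respondent and then summarized — which is why the overall
summary can have fewer observations than the construct summaries when
some respondents lack a construct.

The factor-analysis-based index variant applies the same formula to each
construct's retained (salient) indicators and is tagged `factor_based`:
the original "proportion and cumulative variability" index construction
is not specified tightly enough to reproduce, so this surrogate is
provided and clearly labelled rather than an unverifiable imitation.

Summaries report obs/mean/sd (sample, n−1)/min/max, with means and SDs
rounded to 2 decimals and min/max to integers, mirroring the conventional
presentation. A single respondent yields SD 0 with an explicit flag.

## The synthetic-data generator

`simulate_responses()` draws correlated latent factors, forms each item's
continuous response with communality-consistent unique noise, and
discretizes at thresholds (default: standard-normal tertiles, a symmetric
choice made once in the absence of any stated response distribution).
Missingness is completely at random. `reach_fixture()` wraps this into a
25-item, 359-respondent survey shaped like the instrument the package
targets: 12/7/6 items per construct, ~1.77 % missingness, three weakly
correlated factors (r = 0.05, consistent with near-zero MSV), marker
items (P9, P11, P12 / H4, H5, H6 / C1, C4, C5) loading at 0.8 and the
remaining items at 0.25 — an instrument where a core of items carries the
construct signal and the rest are noisy.

What the generator does *not* emulate: real response distributions
(skewness, floor/ceiling effects), informative missingness, cohort
differences, item wording effects, or mixed-sign loadings within a
construct. Passing tests on synthetic data therefore demonstrate that the
pipeline's logic and estimators behave correctly under the model's own
assumptions — not that any particular real survey satisfies those
assumptions.

Tertile discretization attenuates Pearson correlations by roughly a
factor 0.79, so an item with latent loading 0.8 shows an observed-scale
loading near 0.7. Problem sizes in the test suite (n = 359–5000,
9–25 items, 5–200 replicate fits) were chosen so each property is tested
at the scale where its statistical claim is meaningful while the whole
suite stays quick to run.

## Numerical choices and degenerate inputs

* Bartlett requires det R > 0; singular correlation matrices are an
  error, not a warning.
* KMO on an identity matrix is 0/0 and raises an error.
* An identity correlation matrix yields all-zero SMCs and eigenvalues;
  retention then reports "not factorable" explicitly.
* The ML fit bounds unique variances positive through the log
  parameterization; latent correlations stay in (−1, 1) through atanh.
* Ties in pruning break by smallest communality; factor naming never
  assigns one construct to two factors.
* Round-trip serialization of rescaled matrices preserves imputation
  provenance (a `*` suffix per imputed cell).

## Limitations

* Pearson correlations on 3-point scores understate latent associations;
  all thresholds (KMO, eigenvalues, loadings) are applied to the
  attenuated scale.
* Neutral-score imputation shrinks variance slightly and assumes
  missingness carries no information.
* The ML fit assumes the score covariance is well summarized by normal
  theory; with 3-category items this is an approximation (ordinal
  estimators such as WLSMV are out of scope).
* The arithmetic index treats all indicators within a construct as
  equally weighted; that is its point, but also its strongest assumption.
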