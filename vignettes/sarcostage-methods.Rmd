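---
title: "Methods: staged sarcopenia risk screening and weighted intervention stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staged sarcopenia risk screening and weighted intervention stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcostage)
```

## The problem

Sarcopenia — age-related loss of skeletal muscle mass, strength and
function — is typically detected only after clinically evident decline,
because screening relies on instruments (SARC-F, DXA) that sit inside the
healthcare system. A community-level alternative is a self-assessment
questionnaire phrased in everyday functional terms (stair climbing,
carrying groceries, standing on a bus), scored and banded so that
individuals can be routed to graded interventions without a clinic visit.
`sarcostage` implements that full analysis pipeline: questionnaire scoring
and banding, an exclusion funnel for confounding pathologies, a four-stage
behavioural progression model, expert-derived dynamic indicator weighting
via the Analytic Hierarchy Process (AHP), and a three-grade intervention
mapping — together with a calibrated synthetic cohort generator so the
whole pipeline is testable end to end without survey microdata.

## Questionnaire model

Twelve items, each scored 0–3, cover four domains (strength, endurance,
balance, functional adaptation). The total (0–36) maps to four risk bands:

| Total | Band |
|---|---|
| 0–8 | Healthy |
| 9–16 | Pre-Sarcopenia Compensation |
| 17–24 | High Risk |
| ≥25 | Disabling Degeneration |

Scale quality is assessed with Cronbach's α (sample-variance, n−1
denominator, pinned in tests), the KMO sampling-adequacy measure computed
from anti-image partial correlations (`q = -S_ij/sqrt(S_ii S_jj)` with
`S = R^{-1}`), and Bartlett's sphericity test
(`χ² = −(n−1−(2k+5)/6)·ln det R`, `df = k(k−1)/2`). Participants with any
missing item are never imputed; they are routed to the missing-data
exclusion of the screening funnel.

## Screening funnel

Screening applies, in order: (1) missing-data exclusion (any missing
item); (2) comorbidity exclusion — any flag from a closed set of nine
confounding-pathology categories (joint, metabolic/endocrine,
neurological, cardiovascular, respiratory, postoperative, visual,
inflammatory/autoimmune, other), counting both confirmed and
symptomatic-undiagnosed statuses; (3) the 9-point diagnostic threshold
(totals ≤8 excluded). When a participant carries several comorbidity
flags, the attributed category is the highest-priority one under the fixed
category order above — a convention chosen because the published
per-category counts report exactly one category per excluded participant;
it is configurable in spirit (the screen exposes the parsed flag set).
Swapping stages (2) and (3) changes only the attribution of the overlap,
never the final cohort size; a property test asserts this.

## Staging and triangulation

Stages A–D (Functional Compensation, Compensation Attenuation,
Decompensation, Dependence) are a behavioural classification. The original
stage model was derived from qualitative interviews, so no closed-form
band→stage table exists; the package ships a deterministic, configurable
default: Pre-Sarcopenia → A; High Risk → B if ADL-independent
(ADL ≥ 90) else C; Disabling Degeneration → D. Stage severity is monotone
in the questionnaire total for fixed ADL status.

Socioeconomic status (SES) is scored 1–3 on each of income, education and
occupation; totals 3–4, 5–6 and 7–9 define the Low/Medium/High groups. The
shipped band criteria (income terciles at 4,000/9,000 CNY; education
≤6 / 7–12 / >12 years; occupation linked to education band in the
generator) stand in for the study's unpublished supplementary definitions.

Stage validation triangulates three methods on a subsample balanced across
SES groups (five per group by default): the questionnaire-derived stage,
a SARC-F-derived stage (0–1→A, 2–3→B, 4–6→C, 7–10→D; boundaries map to the
higher-severity side), and a DXA-derived stage from the appendicular lean
mass index with sex-specific thresholds (defaults anchored at the
conventional 7.0 kg/m² male / 5.5 kg/m² female low-muscle-mass reference
values, one step either side). The SARC-F and DXA cut-points are not part
of the published model; they are documented, overridable defaults, and the
tests assert mapping mechanics, not clinical validity.

## AHP engine

Priorities are derived by the principal-eigenvector method: power
iteration on the validated reciprocal matrix to a relative tolerance of
1e-12 (at most 10,000 iterations; convergence failure is a classed error
carrying the residual). `λ_max` is the Rayleigh mean of `(Aw)/w`;
`CI = (λ_max − n)/(n − 1)` (0 for n ≤ 2) and `CR = CI/RI(n)` with Saaty's
random-index table (0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49).
Expert matrices are aggregated entry-wise by geometric mean, which
preserves reciprocity exactly in exact arithmetic (asserted to 1e-12).
An independent full eigen-decomposition serves as the test oracle; the
row-geometric-mean approximation is deliberately not used as the
implementation.

The expert panel's raw judgment matrices are not publicly deposited. The
package ships *synthetic* fixture matrices
(`inst/extdata/expert_judgments_synthetic.json`, labelled as such):
consistent ratio matrices of the published weight structure snapped to the
Saaty scale, with a deterministic mild per-expert disagreement pattern.
All fixture matrices, individually and after aggregation, have CR < 0.1.
They demonstrate the methodology; the canonical weights used in scoring
come from the published table, not from these fixtures.

The hierarchy has three primary dimensions (physiological, psychological,
external), eight secondary indicators and seven self-care tertiary leaves,
for 14 leaves total. (The published hierarchy diagram nominally counts
nine secondary indicators while the weight table lists eight; the
hierarchy here follows the table.)

## Dynamic weighting and canonical local weights

Dimension weights shift with stage: physiological 70/65/60/55%,
psychological 20/25/30/35%, external fixed at 10%. Within-dimension local
weights are stage-invariant; a leaf's composite weight is its local weight
times the stage's dimension weight, and scoring always uses the un-rounded
products (3-decimal values are display-only).

The canonical local weights are back-derived once from the published
Stage A composite block. The printed physiological block sums to 0.699
rather than 0.700 (a 3-decimal rounding artefact), so a literal division
by 0.70 would leave locals summing to 0.99857 — breaking both the
sum-to-one invariant of the hierarchy and the exact score anchors below.
The package therefore normalizes each dimension's Stage A composites to
sum 1. Under this convention the rebuilt table matches the printed
3-decimal values in 52 of 56 cells; the four exceptions (Stage B feeding,
Stage C self-efficacy, Stage D social engagement, Stage D self-efficacy)
differ by exactly one rounding half-step, with un-rounded discrepancies
below 0.0008. These are documented, not silently corrected.

## Severity ratings and intervention grades

Each leaf is rated 1–4 from a mapped instrument: SARC-F for the two
mobility-related physiological leaves, ADL independence for the seven
self-care leaves, FES-I for movement anxiety, HADS for social engagement,
GSES (reverse-scored) for self-efficacy, and the SES total for both
external leaves. Cut-points are documented defaults (e.g. SARC-F
0–1/2–3/4–6/7–10 → 1/2/3/4; FES-I 16–19/20–27/28–37/≥38, anchored on its
conventional low/moderate/high concern bands); values at a cut-point map
to the higher-severity rating, and every mapping is overridable.

The total intervention score is `Σ rating × composite weight` over the 14
leaves. Because composite weights sum to 1, the score lives in [1, 4] with
exact anchors: all-1 ratings give 1.0, all-2 give 2.0, all-4 give 4.0.
Grades: I below 2, II from 2 to 3.2 inclusive, III above 3.2 (the
boundary convention "exactly 2 → II, exactly 3.2 → II" is pinned in
tests). A 1e-9 tolerance at the two cut-offs absorbs floating-point
round-off so that exact-boundary profiles always receive the inclusive
grade. Raising any single rating never decreases the score; for profiles
whose psychological ratings exceed their physiological ones, the score is
strictly increasing from Stage A to Stage D because the psychological
dimension weight grows monotonically.

## Synthetic cohort generator

The generator emulates the statistical shape of the study data, not
sarcopenia biology:

* **Age structure and demographics.** Seven age bands with the published
  screening-phase counts as the default mix
  (281/171/274/344/447/103/63 of 1,683), and per-band gender ratios,
  education, insurance categories and income as published. Overlapping
  study-phase rows are treated as annotations, not constraints.
* **Latent severity and items.** Each participant carries a latent band
  (Healthy / Pre-Sarcopenia / High Risk / Disabling) drawn from their age
  band's mixture, and a latent severity θ ~ Beta with band-specific mean
  and concentration 100. Item responses follow a graded ordered-threshold
  model, `P(item ≥ k) = logistic((θ − τ_k)/s)` with τ = (0.25, 0.50,
  0.75) and s = 0.08, drawn with a single shared uniform per item so that
  scores are monotone in θ for a fixed noise draw. This is the simplest
  mechanism that produces correlated items (overall α ≈ 0.9, subscale α
  ≈ 0.8 in generated cohorts) and band-consistent totals.
* **Calibration.** Band θ means are solved numerically so the expected
  total sits at each band's score midpoint (4, 12.5, 20.5, 30.5), which
  keeps banded participants inside their own band and makes the
  questionnaire recover the latent band for well over 80% of
  screening-funnel survivors. The 31–40 mixture is solved so the expected
  mean total equals the reported 8.2; the 51–60 mixture is the reported
  42.9/28.6/28.5% split. The item-level missing rate is solved from the
  participant-level figure (45 of 1,728 with ≥1 missing item), and
  per-category comorbidity rates are the published category shares
  rescaled so the expected any-flag share equals 950/1,683 under
  independent flags.
* **Instruments.** Truncated Gaussians (inverse-CDF, so draws stay
  seed-stable) around band-specific means: SARC-F (1/3/5/8, SD 1.2), ADL
  (100/90/70/45, SD 8, steps of 5), FES-I (20/30/42/54, SD 5), HADS
  (6/12/20/28, SD 4), GSES (34/28/22/16, SD 4), and sex-specific ALMI.

What the generator does **not** reproduce: correlation between
comorbidity and questionnaire score (flags are independent of severity,
so the simulated funnel does not reproduce the published 83
below-threshold exclusions — the funnel arithmetic is instead verified on
an exact-marginal fixture cohort), item-level local dependence beyond the
shared latent, cultural response styles, and any real biology of muscle
decline. Passing calibration tests therefore demonstrates that the
pipeline's statistical machinery is correct, not that the instrument is
clinically valid.

## Numerical choices and degenerate inputs

* Power iteration: tol 1e-12, max 10,000 iterations; non-convergence is a
  classed error, never a silent result.
* Reciprocity and unit diagonal validated to 1e-9 relative; violations
  name the offending cell.
* α is undefined for zero total variance; KMO for singular or exactly
  diagonal correlation matrices; Bartlett for non-positive-definite
  correlations — all classed degenerate-input errors.
* Published-table comparisons round half away from zero
  (`round_half_up()`), since base R's round-half-even differs on exact
  halves.
* The pipeline fans one top-level seed into per-stage child seeds with a
  MINSTD-style step (`(seed·48271 + k) mod 2³¹−1`), so each stage is
  independently reproducible and derived seeds stay below 2³¹.

## Problem sizes used in the tests

The stochastic calibration checks use cohorts of 1,000 participants,
matching the scale at which the reported age-band profiles are stated;
every stochastic test fixes its seed, and the mean/share checks use
3-binomial-SD or ±0.3-point bands at that n. The full default cohort
(n = 1,728) is exercised in the funnel and missingness tests. These sizes
keep every check statistically meaningful at interactive run times. Note
that a ±0.3-point band on a mean whose standard error is ≈0.16 at
n = 1,000 is a ≈1.9-SE check: it carries an inherent few-percent
per-seed Monte Carlo failure risk even for a perfectly calibrated
generator (the generator's large-sample mean is 8.198 against the 8.2
target).

## Known limitations

* The band→stage mapping, SARC-F/DXA staging cut-points, SES band
  criteria and instrument rating cut-points are modelling defaults
  standing in for unpublished supplementary material; conclusions that
  depend on their exact values should treat them as configuration, not
  findings.
* The three-grade intervention mapping ends at the grade label; the
  package deliberately implements no intervention content.
* Real-data statistics (the reported α = 0.89, observed prevalences)
  cannot be reproduced without the original survey records; the package
  covers them only through calibration round-trips on synthetic cohorts.
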