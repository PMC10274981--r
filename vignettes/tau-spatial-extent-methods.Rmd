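---
title: "Spatial extent analysis of tau-PET abnormality: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial extent analysis of tau-PET abnormality: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tauextent)
```

# The scientific problem

Tau pathology in sporadic Alzheimer's disease is believed to spread through
a stereotyped sequence of brain regions (Braak stages), yet individual
tau-PET scans show considerable person-to-person variation in exactly which
regions are abnormal. `tauextent` implements a whole-brain, region-level
analysis of that variation. Its central quantity is the **spatial extent
index**: the number of brain regions — among the 34 bilateral cortical
regions of the Desikan atlas plus the two amygdalae, 70 regions in all —
whose standardized uptake value ratio (SUVR) meets or exceeds a
region-specific, data-driven abnormality cutoff. The hippocampus (Braak
stage II) is excluded throughout because the flortaucipir tracer suffers
known choroid-plexus off-target binding there; the staging precedence chain
used everywhere is therefore I < III < IV < V < VI.

# Data-driven abnormality thresholds

For each region, the baseline SUVR values of the entire cross-sectional
sample are modelled as a two-component Gaussian mixture,

$$f(x) = w_{lo}\,\phi(x;\mu_{lo},\sigma_{lo}) +
         w_{hi}\,\phi(x;\mu_{hi},\sigma_{hi}),$$

where the higher-mean component is interpreted as the abnormal (tau-positive)
population. The regional cutoff is the SUVR $x^\*$ at which the *posterior*
probability of the abnormal component equals one half:

$$w_{hi}\,\phi(x^\*;\mu_{hi},\sigma_{hi}) =
  w_{lo}\,\phi(x^\*;\mu_{lo},\sigma_{lo}).$$

Two points deserve emphasis. First, this is the weight-adjusted posterior
crossing, not the equal-weight density intersection: in a cohort where only
30% of scans are abnormal, the cutoff sits closer to the abnormal mean than
the naive midpoint. Second, binarization uses a closed lower bound: a value
exactly at the cutoff is coded abnormal.

## EM details and numerical choices

The mixture is fitted by EM with free component variances. Defaults, chosen
for reproducibility where the procedure itself leaves them open:

* 10 restarts; the first initialises at the 25th/85th percentiles with a
  0.3 abnormal weight, the rest at seeded random locations; the best
  log-likelihood wins.
* Convergence at $|\Delta\ell| < 10^{-6}$, at most 500 iterations, variance
  floor $10^{-6}$ (prevents singular collapse on near-duplicate values).
* Component labels are sorted so $\mu_{lo} \le \mu_{hi}$ always holds; an
  all-identical input is an error, not a silent fit.
* The posterior-0.5 point is located by sign-change bracketing on a 2000
  point grid over $(\mu_{lo}, \mu_{hi})$ followed by bisection to
  $|P(\text{abnormal}) - 0.5| < 10^{-8}$. Under extreme weight/variance
  asymmetry no interior crossing exists; the cutoff then falls back to the
  argmin of $|P - 0.5|$ over the observed range and the region is flagged
  (`no_interior_crossing`). A fitted separation
  $(\mu_{hi}-\mu_{lo})/\sigma_{pooled} < 1$ raises a `low_separation` flag
  but no automatic fallback: the procedure does not invent a cutoff where
  the data show no bimodality.
* Whether the underlying mixture should share one variance was genuinely
  open; free variances were chosen because regional SUVR distributions show
  visibly wider abnormal components, and the fitted cutoff is the quantity
  of interest, not the variance structure.

Stage-level positivity applies the same machinery to the unweighted mean
SUVR over the member regions of each Braak stage (and of the temporal
meta-ROI: entorhinal, parahippocampal, inferior temporal, middle temporal,
fusiform, amygdala — both hemispheres, 12 regions).

The default Braak stage map ships the flortaucipir staging scheme from the
in-vivo staging literature (I = entorhinal; III = parahippocampal, fusiform,
lingual, amygdala; IV = eight limbic/temporal regions; V = seventeen
association-cortex regions; VI = five primary sensorimotor/visual regions).
Exact stage composition varies somewhat between published schemes,
particularly for a few stage-V/VI assignments; the map is therefore
overridable by a JSON file (`region_registry(stage_map = ...)`).

# Staging conformance

Cross-sectionally, a tau-positive subject *conforms* to Braak staging when
positivity at the most advanced (highest) positive stage implies positivity
at every earlier stage. "Most advanced" means the highest positive stage,
not the highest contiguous one — a subject positive on IV with a gap at III
is counted as non-conforming at IV, which is what makes the measure
informative. Subjects with no positive stage are excluded from every
denominator. Per-stage percentages condition, by default, on the highest
positive stage being that stage; conditioning on mere positivity at the
stage is available (`condition = "positive"`) because the two readings are
both defensible and differ in small samples.

Longitudinally, for each stage that newly becomes positive at the last
scan, conformance requires every earlier stage to have been positive at
baseline or to have become positive during follow-up; the percentage is
computed over subjects who progressed on at least one stage.

# Progression states and annual change

Regions are classified between a subject's first and last scan as
stable-negative (0→0), stable-positive (1→1), progressor (0→1) or regressor
(1→0). Intermediate visits do not affect the label (they do enter the
mixed models). Annual change in any measure — spatial extent, meta-ROI
SUVR, a single region's SUVR or its 0/1 positivity (a linear probability
model, deliberately, since the procedure specifies linear mixed models
throughout) — is estimated by REML linear mixed models with random
intercepts and random slopes per subject. Per-subject slopes are the fixed
effect plus the BLUP of the random slope. When the random-slope variance is
estimated on the boundary (or the model is unidentifiable, as with exactly
two visits per subject), the model falls back to a random intercept only
and says so (`fallback_intercept_only`). On noise-free linear data the
mixed-model slope equals the per-subject OLS slope exactly, which the test
suite asserts.

# Heterogeneity via Jaccard similarity

Pattern overlap between two subjects is the Jaccard index of their
positive-region sets, $|A \cap B| / |A \cup B|$; each subject's
heterogeneity score is the mean similarity to all other eligible subjects
of the same diagnostic group, and analyses are restricted to subjects with
at least one positive region (two empty sets have no defined overlap).

For progression patterns the sets contain (region, state) pairs with state
in {progressor, regressor, stable-positive}. Stable-negative agreements are
*excluded* from the set construction by default: the 4-state index is not
formally defined in the source procedure, and counting the (typically vast)
stable-negative background would saturate overlap toward 1 in low-burden
groups, contradicting the observation that longitudinal overlap is lower
than cross-sectional overlap. The inclusive variant remains available
(`include_stable_negative = TRUE`). Group summaries report the mean and the
n−1 standard deviation of the per-subject means.

# Associations with cognition

Baseline cognitive performance (the composite score closest in time to the
scan, within a ±2-year window) and cognitive decline (per-subject
mixed-model slopes over all cognitive visits, requiring at least three
timepoints) are regressed on one tau measure at a time — the spatial extent
index or the temporal meta-ROI SUVR — adjusted for age, sex and education.
Standardized betas z-score the outcome and the tau predictor on the
analysis subsample while leaving covariates raw, so the covariate betas
stay interpretable; the standardized coefficient is obtained by exact
rescaling of the raw one, not by refitting.

Non-nested model fit is compared with Vuong's closeness test:
$z = \sum_i d_i / (\sqrt{n}\,\mathrm{sd}(d))$ with $d_i$ the pointwise
log-likelihood difference. The reported p-value is the one-sided normal
tail in the observed direction, $\Phi(-|z|)$, the convention under which
z = −1.92 corresponds to p = 0.027, −1.13 to 0.13 and 0.01 to 0.50 at the
precision these statistics are usually quoted. The models being
compared always have identical parameter counts (one tau predictor plus
three covariates), so the AIC/BIC correction term of the general statistic
cancels and is omitted. In pipeline outputs the meta-ROI model is the first
argument, so a *negative* z favours the spatial extent index. Identical
pointwise log-likelihoods make the statistic degenerate; that case is
flagged, never silently zero.

Multiple comparisons use Benjamini–Hochberg FDR. The family is a genuine
ambiguity: for region-wise maps the correction is applied within each
(diagnostic group × composite) family of 70 regional p-values; for the
primary two-predictor analyses it is applied within diagnostic group across
the fitted models. Both families are what the surrounding text most
plausibly describes, and both are single `fdr_adjust()` calls, so a user
can re-group at will.

The amyloid–tau link is a maximum-likelihood logistic regression of any
tau positivity (extent ≥ 1) on continuous centiloid, reported as an odds
ratio per centiloid with a Wald 95% CI. Complete or quasi-complete
separation is detected and flagged; no estimate is reported in that case.

# The synthetic cohort generator

Real tau-PET cohorts of this kind are access-controlled, so the package
ships a generator that emulates the statistical structure the pipeline
assumes, with every generating quantity exposed for recovery tests
(`truth`). A cohort is produced in five steps:

1. **Demographics and amyloid.** Diagnosis counts default to 463 CU / 277
   MCI / 92 AD with amyloid-positive fractions 0.351 / 0.477 / 0.837 and
   centiloid distributions per diagnosis and amyloid status typical of
   amyloid-stratified flortaucipir cohorts (e.g. amyloid-positive AD:
   90.1 ± 32.9 centiloids).
2. **Latent stage.** Any tau positivity follows a logistic link on
   centiloid with a default odds ratio of 1.04 per centiloid (intercept
   −3.0); given positivity, a latent Braak stage is drawn from a
   diagnosis-specific distribution (CU concentrated at stage I, AD shifted
   toward V–VI). Amyloid-negative positive subjects are capped at stage I
   with probability 0.97, reflecting the low tau binding of
   amyloid-negative participants.
3. **Heterogeneity.** With probability *h* per region and subject, a
   region's stage membership is swapped with a randomly chosen region of an
   adjacent stage. Swapping (rather than fully random activation) preserves
   broad Braak ordering while diversifying fine-grained patterns — the
   qualitative structure of the real data, where stage conformance exceeds
   80–91% yet regional overlap is below 50%. Default h = 0.1.
4. **SUVR emission.** Regions at or below the subject's latent stage draw
   from N(1.60, 0.15²), others from N(1.10, 0.07²), with small per-region
   jitter of the component means (so each region has its own analytic
   cutoff). Abnormal SUVR drifts upward 0.02/yr.
5. **Longitudinal spread and cognition.** Still-negative regions cross to
   abnormal at Poisson rates of 2.5 (MCI), 0.968 (CU) and 0.865 (AD) newly
   abnormal regions per year — rates in the range reported for
   flortaucipir cohorts, used as generating truths that the mixed-model
   recovery tests must find — in the subject's stage order; abnormal regions
   regress with probability 0.01 per interval (small but nonzero, since
   ~15% of real longitudinal subjects showed at least one regressing
   region). Cognition composites decline linearly with true baseline
   extent, with age/education/sex effects and residual sd 0.4.

Determinism: one master seed fully determines the cohort, and the
caller's RNG state is restored afterwards.

## What the generator does and does not emulate

It reproduces bimodal regional SUVR, Braak-ordered accumulation, tunable
heterogeneity, diagnosis-dependent spread rates, the centiloid link, and
extent-linked cognitive decline. It does **not** model spatially correlated
noise between neighbouring regions, off-target binding artifacts,
frontier-stage partial expression, attrition, or image-level effects.
Passing recovery tests on this generator therefore demonstrates that the
pipeline measures what it claims on data with the assumed structure, not
that any real cohort's effect sizes are reproduced — which is also why the
validation checks are property-based rather than comparisons against
access-controlled clinical data.

Two structural consequences matter when interpreting the staging checks.
First, binarizing *sampled* stage composites has irreducible Gaussian
tails, so "100% conformance at h = 0" is a statement about the
by-construction stage status (`truth$stage_binary_by_visit`, noise-free
composites against analytic cutoffs), which is exactly 100% for any seed.
Second, count-preserving adjacent swaps erode observed stage conformance
only gradually (a stage composite must lose roughly half its members to
flip), so the monotone decline of conformance in h is assessed as a mean
over replicate cohorts — five 500-subject cohorts per h level — where the
ordering is reliable.

## Problem sizes used by tests and scripts

Recovery and calibration checks run at sizes chosen to make their
statistical assertions reliable while remaining desk-scale: 500-subject
staging-enriched cohorts (all amyloid-positive, uniform latent stages —
conformance is only defined on tau-positive subjects); 2000-point mixture
refits; 100-replicate coverage checks for mixed-model slopes (n = 60 × 3
visits) and the logistic link (n = 800); 1000-replicate Vuong calibration
at n = 200; 500-replicate FDR checks at n = 60. The analysis drivers use
the full 832-subject default cohort with three annual visits.

# Known limitations

* The Braak stage map is one published flortaucipir scheme; real analyses
  should confirm stage membership against their own staging source.
* The linear probability model for per-region positivity change can emit
  fitted values outside [0, 1]; it is used because the reference procedure
  specifies linear mixed models, and only slopes are interpreted.
* Mixture thresholds assume a meaningful abnormal subpopulation in the
  fitting sample; in cohorts with very low tau burden, cutoffs for late
  stages rest on few abnormal scans and carry `low_separation` flags that
  should be taken seriously.
* Vuong inference here is the plain statistic without the variance test
  for model distinguishability; degenerate equality is flagged, but near
  degenerate comparisons will simply return small |z|.
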