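---
title: "Methods: cross-center adaptation and AVS triage for primary aldosteronism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-center adaptation and AVS triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PAtriage)
```

# The clinical problem

Primary aldosteronism (PA) has two main subtypes with opposite treatments:
aldosterone-producing adenomas (APA) are cured by unilateral adrenalectomy,
idiopathic hyperaldosteronism (IHA) is managed with mineralocorticoid
receptor antagonists. Adrenal venous sampling (AVS) is the reference test for
subtyping, but it is invasive, technically demanding and scarce. CT is cheap
and universal but fails in two ways: APAs below the detection limit
(about 6 mm) are invisible, and incidental non-functioning nodules can sit on
the wrong side. The question this package answers is not "unilateral or
bilateral?" but the operational one: *which patients can safely skip AVS*,
going directly to surgery (CT-visible APA on the correct side) or to
medication (IHA), and which truly need it.

The package casts this as a three-way retrospective labeling
(`surgery-track`, `medication-track`, `AVS-recommended`) plus two binary
classifiers and a sequential decision flowchart, with a cross-center
imputation model in front so that one trained pipeline can be applied to
hospitals with different missing-marker patterns.

# Cohort representation

A cohort is a `PACohort`, a `SummarizedExperiment` with rows = encoded
markers, columns = patients, and two assays: `values` (numeric; `NA` is the
internal sentinel for unobserved cells) and `observed` (the logical mask;
true exactly where the value is finite). Center and subtype label live in
`colData`; the governing `MarkerSchema` in `metadata()`. Serialization uses
CSV with a literal `"NA"` missing token and schema column order; numeric
cells are written with 17 significant digits so write/load round-trips are
bit-exact.

The default schema (`paSchema()`) reconstructs the 36 predictor columns
from the published cohort tables plus the CT feature rules: 28 continuous
markers (demographics, baseline biochemistry, captopril-challenge,
ACTH-infusion, dexamethasone-suppression, furosemide-upright and
saline-loading readouts, per-side/larger tumor diameters), 4 binary markers
(sex, potassium supplementation, larger-side indicators) and a 4-level CT
laterality expanded to indicator columns. Two encoding choices deserve
comment:

* **No baseline level is dropped** for CT laterality. An image-negative
  indicator is itself a clinically meaningful predictor (it is reported as
  a dominant coefficient in both track models), so all four indicators are
  kept; with them the encoded width is exactly 36.
* **Indicators are treated as continuous in [0, 1]** inside the
  linear-Gaussian imputer and left unthresholded for the classifiers. This
  is the simplest scheme compatible with a Gaussian latent factor model;
  a reporting flag can round them.

Only continuous markers are z-scored (`standardizeCohort()`), always against
the *reference* cohort's observed-entry statistics, so reference and target
centers share one coordinate system. The exact identity of the 36 markers in
any given hospital system will differ; the schema is a constructor argument
everywhere, not a constant.

# The adaptation module: variational BPCA with missing data

The imputer is a linear-Gaussian latent factor model fitted on the reference
cohort. For patient $n$ with observed coordinate set $O_n$:

$$x_{n} = W z_n + \mu + \varepsilon_n, \qquad z_n \sim N(0, I_q), \qquad
\varepsilon_n \sim N(0, \tau^{-1} I_d),$$

with an automatic relevance determination (ARD) prior on each loading
column, $w_j \sim N(0, (\tau \alpha_j)^{-1} I_d)$, and broad conjugate
Gamma(10⁻³, 10⁻³) hyperpriors on $\tau$ and each $\alpha_j$. Coupling the
column prior to the noise precision is the classical choice for
missing-value BPCA: a column survives only if its loading norm is large
relative to the noise scale (roughly $\lVert w_j\rVert^2 \gtrsim d\sigma^2$),
which is what makes the dimensionality selection automatic rather than a
tuning knob. We verified empirically that the alternative,
noise-independent prior $w_j \sim N(0, \alpha_j^{-1} I_d)$ retains
sampling-noise directions in realistic regimes and does not recover the true
rank; the noise-coupled form does (see the dimension-recovery test).

Inference is mean-field variational EM over $q(Z)\,q(W)\,q(\alpha)\,q(\tau)$
with a point estimate for $\mu$. Missingness is marginalized patient-wise:
only the observed rows of $W$ enter patient $n$'s posterior, so patients
with different observed patterns get different latent posteriors
$N(m_n, S_n)$, and patients sharing a pattern share $S_n$ (patterns are
grouped for speed). Every update is an exact coordinate ascent step on the
evidence lower bound, so the ELBO is non-decreasing; the fit stops when its
relative change falls below `tol` (default 10⁻⁷, maximum 2000 iterations).

Numerical choices:

* **Initialization** is deterministic: $\mu$ from observed column means,
  $W$ from the SVD of the mean-imputed standardized matrix, $\tau$ from the
  residual variance after the rank-$q$ reconstruction (floored at 10⁻⁹ so
  noiseless data do not divide by zero).
* **Latent dimension cap** $q$ defaults to $\min(d-1, n-1)$; ARD prunes
  from there. `qEff` counts columns whose posterior-mean loading norm
  exceeds 10⁻³ on the standardized scale — pruned columns collapse by many
  orders of magnitude, so the threshold is not delicate.
* **Degenerate inputs**: a marker with fewer than two observed entries is a
  hard error (its mean/variance are unidentified); a patient with *no*
  observed entries is imputed to $\mu$ with the marginal predictive SD
  $\sqrt{\operatorname{diag}(WW^\top) + \tau^{-1}}$, with a warning.

Imputation (`bpcaImpute()`) freezes the model, forms each patient's latent
posterior from their observed entries and fills missing cells with the
posterior predictive mean, reporting the predictive SD. Observed entries are
never altered — this is asserted exactly, not within tolerance. Because the
fill is conditional on the patient's observed values, two patients missing
the same marker generally receive different values whenever that marker
loads on the latent space; column-mean imputation is the degenerate special
case $W = 0$.

`adaptCenter()` exposes two adaptation modes. Whether per-center parameters
should be re-estimated during adaptation is genuinely open; we provide
`"frozen"` (default: the reference model is applied unchanged, the pure
transfer-learning reading) and `"recenter"` (the mean vector is re-estimated
on the center's observed entries with loadings, noise and ARD state frozen,
for centers with systematic assay-level shifts). Recentring has a known
degeneracy — a shift inside the column span of $W$ can be absorbed by the
latent scores — but imputed *values* are invariant to how the shift is
attributed, which is why the tests assert imputation accuracy rather than
$\mu$ itself.

# The classification module

Two binary questions are asked of every patient: surgery-track vs the rest,
and medication-track vs the rest (a direct three-class classifier is
deliberately out of scope; the AVS-recommended class is heterogeneous and is
handled by the flowchart instead). Model families:

| family | engine | objective | key hyperparameters |
|---|---|---|---|
| `lr-l2`, `lr-l1` | glmnet | penalized negative log-likelihood | `C` (inverse penalty; `lambda = 1/(nC)`) |
| `rf` | randomForest | Gini impurity | `nTrees` |
| `mlp` | nnet | binary cross-entropy | `size`, `epochs`, `decay` |

`class_weight = "balanced"` (default for the logistic and perceptron
families) weights patients inversely to class frequency; the decision
threshold is the conventional 0.5 on the predicted probability that balanced
weighting targets, and is configurable. The perceptron is a single
hidden-layer network fitted by full-batch quasi-Newton optimization; widths
and epoch caps are hyperparameters, but there is no minibatch size in this
optimizer. Stochastic families are seeded, and refitting with the same seed
reproduces predictions exactly.

Model selection is a plain grid search maximizing the validation **f-score**
— the harmonic mean of sensitivity and specificity, which is 0 as soon as
either rate collapses and therefore punishes the trivial always-positive /
always-negative solutions that plain accuracy rewards on imbalanced data.
Ties go to the earlier grid point, and the full grid trace is returned.
Default grids span `C` in {0.005, 0.11, 1, 4} for either penalty, forests of
500–2000 trees, and perceptron widths 5–6. Two validation designs are
supported: a seeded stratified split of the reference cohort (default), or
validation on the labeled target cohort itself — the two-cohort design in
which training and test data are separate by construction. The first is the
conservative choice (validating on the target risks optimistic selection);
both are one argument away.

Training and evaluation refuse cohorts containing masked entries. This is a
deliberate contract: imputation precedes classification in this framework,
and silently dropping or mean-filling rows here would undermine the
adaptation module's role.

# The triage flowchart

Routing is sequential and mirrors how the decision would be taken in clinic:

1. **Surgery model first.** A surgery-positive patient goes to surgery only
   if (a) the post-captopril aldosterone-to-renin ratio strictly exceeds
   73.0 — a confirmatory-test gate against false positives — and (b) CT
   offers a defined larger tumor side, which becomes the adrenalectomy side.
   Failing either gate means AVS. Cutoffs are strict inequalities
   throughout (`> 20` for screening ARR, `> 73.0` for the surgery gate),
   and bilateral tumors of exactly equal size leave no larger side: the one
   clue CT offers for laterality is absent, so such patients are never
   routed to surgery.
2. **Medication model on the surgery-negatives.** Medication-positive *and*
   CT image-negative goes to medication; a visible nodule in a
   medication-positive patient still warrants AVS to rule out a surgical
   target; patients claimed by neither model go to AVS.

The gate order matters: the published branch accounting only reproduces with
the surgery model first, then the ARR gate, then the medication model on the
surgery-negatives. By default the ARR gate reads the completed (possibly
imputed) value; `arrGate = "observed"` restricts it to observed values and
routes missing-ARR surgery candidates to AVS conservatively.

`summarizeFlowchart()` reports per-route and per-branch tallies, the AVS
fraction, and the decision accuracy, defined over *decided* (non-AVS)
patients only: AVS is the honest "don't know" answer, so it is excluded from
the numerator and denominator. This accuracy-over-decided-cases definition
is the only one consistent with the published branch counts, and the
accounting identities (routes partition the cohort; percentages recompute
from tallies) are asserted exactly in the tests. Percentages are reported to
one decimal.

# The synthetic cohort generator

Patient-level data are not public, so the generator emulates the cohort the
analysis assumes, and its defaults *are* those study conditions, not tuning
dials:

* **Class mix** 84/18/108 over surgery-track / AVS-recommended /
  medication-track, drawn multinomially.
* **Marker distributions** are class-conditional: symmetric markers normal
  with the published class mean ± SD (e.g. surgery-track age 50.5 ± 11.1 yr,
  medication-track serum potassium 3.7 ± 0.4 mmol/L); skewed markers
  (hormones, ratios, durations, doses) log-normal with parameters solved
  from the published median and IQR (e.g. ARR after captopril 105.8
  [62.6–214] in the surgery track vs 55.9 [38.0–151.6] in the
  AVS-recommended group — the overlap of these two around the 73.0 cutoff is
  what makes the ARR gate informative but imperfect, exactly as in the
  flowchart accounting). Markers not printed in the tables (sodium, ACTH,
  some confirmatory-test readouts) use representative clinic values graded
  across classes; they are config entries, chosen once.
* **CT structure** follows the published laterality rows
  (34/37/13/0 surgery, 1/4/6/7 AVS-recommended, 7/16/9/76 medication over
  right/left/bilateral/image-negative) with visible diameters truncated at
  the 6 mm detection limit (surgery-track nodules 15.7 ± 6.2 mm). Labels are
  consistent with the labeling rule *by construction*: surgery-track APAs
  sit on the larger visible side, AVS-recommended APAs are CT-negative,
  behind the smaller of bilateral nodules, or contralateral to the only
  visible one; medication-track patients are IHA with at most incidental
  nodules. A module-consistency test asserts that `assignSubtypeLabel()`
  applied to the ground truth reproduces the generator's labels exactly.
* **Missingness** is applied per center per marker with all rates in
  [0, 0.2] (the marker-selection rule of the original design: markers
  missing in more than 20% of any institution were excluded up front, so
  rates above 0.2 are a config error). Default rates give each center a
  small base rate on lab markers plus one systematically under-collected
  dynamic-test panel; CT features and demographics are always observed
  (CT is the entry point of the triage). MCAR is the default; a MAR option
  doubles/halves each rate by the patient's age relative to the center
  median, capped at 0.2.
* **Correlation.** Markers are class-conditionally independent by default —
  the published tables give no covariance, and inventing one would be a
  claim about the real cohort. An optional shared low-rank block
  (`latentRank`, `latentShare`) adds a common-factor structure on the draw
  scale so that the BPCA imputer has a recoverable subspace; the imputation
  benchmark uses it.
* **Floors** truncate implausible draws (creatinine ≥ 0.2 mg/dl, age ≥ 18
  yr, …). Truncation slightly biases the means of the affected normals, so
  the distribution-fidelity tests check means only for markers whose floor
  is far in the tail and medians (floor-invariant) for the log-normals.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: inter-marker correlations beyond the optional
single shared block (real hormone panels are correlated in structured,
class-dependent ways), assay calibration differences between centers (the
real motivation for the `"recenter"` mode), informative missingness beyond
the age-keyed MAR option, label noise in the retrospective subtyping, and
longitudinal/treatment dynamics. Synthetic pipeline accuracy is therefore a
check that the machinery extracts the signal the generator plants, not an
estimate of clinical performance.

One seed governs everything; sub-stages (labels/centers, markers, CT,
missingness) draw from fixed offsets of it, so each stage is independently
reproducible and any single stage can be regenerated without replaying the
others.

# Problem sizes and reproducibility

The shipped tests and the acceptance script run at the sizes the framework
is designed around: a reference center of 278 patients, a multicenter target
of 210, 36 encoded markers. BPCA property tests use compact latent
benchmarks (d = 10–12, n = 300–1000, true rank 1–3, signal-to-noise ≥ 5,
10–20% missingness, 20 seeded replicates for the rank-recovery check);
coefficient-sign recovery uses n = 2000. Everything is seeded; the pipeline
is deterministic end to end, and `scripts/acceptance.R --seed S --out F`
regenerates all headline numbers from scratch under seed `S`.

# Known limitations

* The imputer is linear-Gaussian: it cannot represent multimodal or
  nonlinearly coupled marker distributions, and binary/indicator columns are
  filled on the linear scale. This is the intended trade-off — a model with
  essentially no free hyperparameters that works at a few hundred samples —
  not an oversight.
* With heteroscedastic noise (real standardized clinical data), ARD retains
  extra latent directions to absorb per-marker noise differences; `qEff` is
  then an effective model order, not an estimate of a "true" rank. Rank
  recovery is only a meaningful claim under isotropic noise, and is tested
  there.
* The decision threshold (0.5), the ARR gates (20, 73.0) and the pruning
  threshold (10⁻³) are conventions of the implemented procedure, exposed as
  arguments; none is re-estimated from data at run time.
* Surgically treated bilateral-APA cases are labeled by their dominant
  resected lesion; cohorts in which both sides were resected with no
  dominant lesion have no defined label under this rule.
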