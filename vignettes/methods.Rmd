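---
title: "Methods: median-effect synergy, signature screening and survival scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: median-effect synergy, signature screening and survival scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergysig)
```

# The problem

A recurring preclinical question in oncology: a targeted inhibitor is
combined at a fixed molar ratio with a chemotherapy backbone across a
dilution series — is the interaction synergistic, and which molecular
features predict it? `synergysig` implements the standard analysis chain
for this design: median-effect dose-response fitting, the Chou-Talalay
combination index, a gene-expression/IC50 correlation screen, a
first-principal-component signature with survival dichotomization, and
immunohistochemistry product scoring. Everything is exercised on
synthetic data with known ground truth, so each stage's correctness is
established by recovery of planted parameters, not by eyeballing.

# The median-effect model

Viability is first normalized per plate to the mean untreated-control
signal (`normalize_viability()`); replicate wells stay as separate rows
and values above 1 are retained. The dose-effect law is the two-parameter
median-effect equation

$$\frac{f_a}{f_u} = \left(\frac{D}{D_m}\right)^m,$$

with $f_a = 1 - \text{viability}$ the affected fraction, $f_u = 1 - f_a$,
$D_m$ the dose for a 50% effect (the model's IC50) and $m$ the
sigmoidicity. Taking logs makes this a straight line in
$(\log_{10} D,\ \log_{10} f_a/f_u)$, and `fit_median_effect()` estimates
it by ordinary least squares, the classical procedure this model implies.
Nonlinear least squares on viability would weight the data differently;
the linearized fit was chosen because it is the convention the
combination-index literature assumes and it makes the noiseless case
exactly recoverable (the tests demand $(D_m, m)$ back to a relative
$10^{-9}$).

Numerical choices:

* **fa clipping.** Points with $f_a$ outside $[0.01, 0.99]$ are excluded
  (configurable via `fa_clip`): $\log(f_a/f_u)$ is undefined at the
  boundaries and its variance explodes near them. `n_used` reports what
  actually entered the fit and at least 3 points are required.
* **Replicates** are averaged per dose before clipping
  (`average_replicates = FALSE` switches to per-well fitting).
* **Log base 10** throughout. Any base gives identical $(D_m, m)$; fixing
  one makes intercepts reproducible.
* A non-positive fitted slope means viability did not fall with dose; the
  fit refuses ("non-monotone dose-effect") rather than returning a
  meaningless negative $m$.

`predict_fa()` and `dose_for_effect()` are the two closed-form inverses
$f_a(D) = (D/D_m)^m / (1 + (D/D_m)^m)$ and
$D_x = D_m (f_a/(1-f_a))^{1/m}$; they round-trip to $10^{-9}$ by
construction and the tests assert it.

# Combination index

For a constant-ratio mixture, `combination_index()` computes the
mutually-nonexclusive-drugs form

$$CI = \frac{(D)_1}{(D_x)_1} + \frac{(D)_2}{(D_x)_2} +
       \frac{(D)_1 (D)_2}{(D_x)_1 (D_x)_2},$$

with $(D_x)_i$ the single-agent dose producing effect level $f_a$ alone
and $(D)_i = \text{fraction}_i \times D_c$ the component doses inside the
iso-effective mixture dose $D_c$. $CI < 1$ is synergism, $= 1$ additive,
$> 1$ antagonism (`classify_ci()`, strict thresholds by default with an
optional additive band for noisy data).

Design choices worth knowing:

* **Summary effect level.** A single CI per experiment is conventionally
  reported without always stating the level; the package defaults to
  $f_a = 0.5$ — the IC50 level, where $D_x = D_m$ for every fit — and
  exposes `ci_curve()` over a grid for transparency. When the three
  slopes $m$ coincide, CI is constant in $f_a$ (the odds factor cancels);
  otherwise it varies, which is exactly why the curve is provided.
* **Two-agent reduction.** A chemotherapy doublet given at a fixed
  internal molar ratio (e.g. carboplatin:paclitaxel at 20,000:1) is
  treated as a single agent at that ratio, so three-drug experiments
  reduce to two-agent CI; the internal ratio is metadata.
* **Sham property.** The nonexclusive cross term makes a drug "combined"
  with itself score $CI = 1 + f(1-f) > 1$ at any split $f$ — a documented
  property of this CI variant, asserted in the tests, and a useful
  negative control for pipelines.

# Correlation screen

`pearson_screen()` correlates each gene with the per-sample phenotype —
$\log_{10}$ IC50 by default, since dose scales are log-normal; the raw
scale is an option. Two-sided p-values come from
$t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ degrees of freedom; q-values from
the hand-implemented Benjamini-Hochberg step-up (`bh_fdr()`,
cross-checked against `stats::p.adjust` in the tests). Missing values are
handled pairwise per gene; genes with fewer than 3 complete pairs or zero
variance are skipped with a warning.

Both published-style filters — raw $P < 0.001$ and $FDR < 0.2$ — are
exposed in `select_genes()` and exactly one must be chosen per call;
neither is hard-coded as "the" filter because sources state both without
saying which produced a given list. Selection uses strict inequality and
orders by $|r|$ descending with lexicographic tie-breaks, so output is
deterministic.

# PCA signature and survival

`fit_pc1()` standardizes each signature gene (center, unit variance) and
takes the first left singular vector of the standardized matrix as the
loading vector $w$, the unit-norm ($\sum w_i^2 = 1$, asserted to
$10^{-12}$) direction maximizing the variance of the sample scores
$\sum_i w_i z_{ij}$. Standardization — correlation-PCA — was chosen so
loadings are comparable across genes on different intensity scales; the
alternative (covariance-PCA) would let bright genes dominate.

The sign of a principal component is arbitrary. `fix_sign()` applies one
fixed convention — $\sum_i w_i \ge 0$, "high score = high aggregate
signature expression" — and the tests verify the invariance that
matters: negating all loadings swaps group labels but changes no
p-value.

`score_samples()` computes $\sum w_i z_i$ per sample; genes absent from a
matrix (or missing in a sample) are dropped and the remaining weights
renormalized to unit norm, requiring at least 50% of the signature
present — drop-and-renormalize rather than imputation, because an
imputed standardized value of 0 silently shrinks scores toward the
median exactly where the split decision is made.

`median_split()` dichotomizes at the median score with ties to the low
group (deterministic); `km_estimate()` is the product-limit estimator
with censored subjects leaving the risk set after their time; and
`logrank_test()` sums observed-minus-hypergeometric-expected events over
distinct event times, referring $(O-E)^2/V$ to $\chi^2_1$. Tied event
times are handled through the summed hypergeometric moments — no
additional tie corrections. Both are independently checked against the
`survival` package (`survfit`, `survdiff`) and against hand-computed
examples; the package's own implementations are used in the pipeline so
the tie rules and output formats are fully specified here.

# IHC product score

`expression_score()` is intensity grade × cellularity grade, both 0–3,
giving $\{0,1,2,3,4,6,9\}$. `cellularity_grade()` bands a stained-cell
percentage as ≤ 33% → 1, 34–65% → 2, ≥ 66% → 3, with half-up rounding in
the unprinted gaps and — the one interpretive decision — 0% → 0: the
published banding starts at grade 1 yet scored tables contain cellularity
0 rows, and mapping zero staining to grade 0 is the only reading
consistent with both. `prevalence()` counts score ≥ 1 among evaluable
records; acellular/unscorable rows are excluded from the denominator by
default (configurable), because the published prevalence fractions cannot
be reproduced exactly from their own printed tables under either rule —
the bundled fixtures give 75/78 (primary tumors) and 33/40 (cell lines)
versus the published "73/79 (92%)" and "34/41 (83%)". The package
reports what its inputs support and documents the discrepancy rather
than resolving it.

# What the synthetic data emulates — and what it does not

The generators (`sim_config()`, `gen_dose_response()`,
`gen_combination()`, `gen_expression_phenotype()`, `gen_survival()`) are
first-class, tested code. Their defaults are the stated world of the
studies this pipeline serves:

* **Viability**: median-effect curves with multiplicative Gaussian noise
  (CV 5% by default) — plate fluorescence noise is scale-proportional —
  on an 8-point two-fold dilution grid spanning $D_m$, triplicate wells,
  untreated controls included.
* **Known-CI mixtures**: `gen_combination()` inverts the CI equation at
  $f_a = 0.5$ — the mixture $D_m$ is the positive root of
  $(f/D_{x1} + (1-f)/D_{x2})\,D_c + \frac{f(1-f)}{D_{x1} D_{x2}} D_c^2 = CI$
  — so the pipeline can be tested for exact CI recovery on noiseless
  data (tolerance $10^{-6}$).
* **Expression**: standard-normal log-scale marginals (consistent with
  RMA-style normalized arrays); each of 47 signal genes is
  $r z + \sqrt{1-r^2}\,\varepsilon$ against standardized log IC50 with
  $r = 0.95$, among 103 independent nulls, $n = 30$ samples. log10 IC50
  is Normal(0.5, 0.5) — IC50s centred near 3 µM spanning roughly
  0.3–30 µM, a realistic potency range for a kinase inhibitor panel.
* **Survival**: exponential event times, high/low-score hazard ratio 2.5
  at $n = 218$ (the clinical-cohort scale), baseline hazard
  $\log 2 / 36$ per month (36-month median survival, typical of advanced
  serous ovarian carcinoma), independent Uniform$(0, \tau)$ censoring
  with $\tau$ solved numerically for the target censored fraction
  (30% by default).

Not emulated: array probe structure, batch effects, plate-position
effects, correlated null genes, non-proportional hazards, informative
censoring. A green test therefore establishes that the algorithms are
implemented correctly and recover truth under the stated statistical
structure — not that real screens, with their correlated noise and
batch artifacts, will behave as cleanly. One further simplification:
`simulate_scenario()` generates survival on the same samples as the
expression screen, whereas real studies validate the signature on an
independent clinical cohort; the package's scoring functions support
that (score any matrix containing the signature genes), the simulation
simply does not model two separate cohorts.

# Determinism and reproducibility

Every generator seeds the RNG from `sim_config()$seed` and restores the
caller's RNG state, so fixed seed means byte-identical outputs and
simulation never perturbs the session. Pipeline runners
(`run_synergy()`, `run_signature()`) validate their configs (unknown
keys rejected), echo them to a JSON manifest with input MD5 hashes and
package versions, and write no timestamps — identical config and inputs
give byte-identical outputs.

# Known limitations

* Only the mutually nonexclusive CI form is implemented (no exclusive
  variant, Bliss, ZIP or HSA scores, no dose-reduction index).
* Only the median-effect dose-response family: no 4PL/5PL logistic
  fits, no plate-effect correction.
* Survival analysis is the two-group log-rank comparison; no Cox
  modeling or multivariate adjustment.
* The screen assumes an already-normalized expression matrix; probe
  summarization and normalization are upstream concerns.
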