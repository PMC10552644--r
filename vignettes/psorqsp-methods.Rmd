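---
title: "Methods: a virtual trial of certolizumab pegol in psoriasis"
author: "psorqsp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a virtual trial of certolizumab pegol in psoriasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psorqsp)
```

# Overview

`psorqsp` simulates a two-arm virtual clinical trial of certolizumab
pegol (CZP), a PEGylated anti-TNF Fab', in moderate-to-severe plaque
psoriasis, and analyses the per-patient molecular response. The pipeline
has six stages:

1. **Virtual population** — patients sampled to reproduce pooled
   reference-trial demographics (sex ratio, age, weight, BMI) with
   comorbidity tags.
2. **PBPK** — a two-compartment (skin depot to blood) pharmacokinetic
   model of each subcutaneous regimen, individualized per patient.
3. **Synthetic protein activity** — a generator emulating per-patient,
   per-protein predicted activities in $[-1, 1]$, with an
   exposure-linked drug effect and planted mechanistic group structure.
4. **tSignal** — the sign-weighted mean activity over a disease effector
   set, calibrated against clinical efficacy (PASI75) with greedy
   protein-set pruning.
5. **Clustering** — arm-normalized activities, dimensionality reduction,
   a multi-algorithm grid with index-based selection of the cluster
   number, stability diagnostics, and cluster characterization.
6. **Enrichment** — hypergeometric enrichment of cluster-differential
   proteins against annotation collections, linked into a network by a
   modified Hausdorff distance over a protein-interaction graph.

The proprietary network-propagation engine that produces predicted
protein activities in the original study is not publicly available, so
stage 3 here is an explicit synthetic model. It is first-class, tested
code: it defines what the downstream statistics are *able* to recover
under controlled conditions, not a claim about real psoriasis biology.

# Virtual population

## Model

Each patient carries sex, age, height, weight, BMI, and a set of
comorbidity tags. Sex is Bernoulli with the reference female fraction
(34.4%). Age and BMI are drawn from truncated normal distributions, age
on $[18, 90]$ years and BMI on $[15, 60]$ kg/m², bounds chosen to
exclude impossible patients. Height is disease-independent and drawn per
sex from configurable European adult values (male $177.6 \pm 7.0$ cm,
female $164.6 \pm 6.5$ cm — configuration defaults, not reference
claims). Weight is **derived** as $\mathrm{BMI} \cdot h^2$, which makes
the BMI–weight–height identity hold exactly for every patient, and the
joint sample is then re-drawn until the realized weight mean and sd each
fall within 0.5 standard errors of the weight marginal (budget 10,000
redraws; an unsatisfiable combination of marginals fails with the
violated marginal named). This acceptance loop is a documented stand-in
for the original covariate-matching algorithm, whose precise acceptance
criterion is not public. Because the implied weight mean
($E[\mathrm{BMI}] \cdot E[h^2]$ under the default height model) sits
about 1% above the printed weight target, acceptance relies on sampling
fluctuation: the 0.5-SE window is comfortable at trial-scale n (a
handful of redraws at n = 500) but impractically narrow for very large
populations, where `tol_se` should be widened.

A design choice worth stating: the truncated normal distributions are
parameterized by **moment matching** — the parent mean and sd are solved
(Nelder–Mead on the two moment equations) so that the *truncated*
distribution reproduces the printed mean and sd. Naively plugging
printed moments into the parent normal would bias the generated mean
upward by roughly $0.6$ years for age and $0.26$ kg/m² for BMI (the
truncation at 18 years and 15 kg/m² clips a visible tail), enough to
inflate the false-rejection rate of the validation t-tests.

## Comorbidities

Tags are assigned by independent Bernoulli draws at their target
frequencies, with no modeled co-occurrence. Obesity is the exception:
it may only be granted to patients with BMI > 30 kg/m², and its default
frequency is "all eligible patients", so obesity prevalence follows the
generated BMI distribution (about half the population under the
reference marginals). The diabetes frequency ships as 0.0438 — the
value consistent with the stated requirement that a 15-patient diabetic
cohort needs $\lceil 15 / 0.0438 \rceil = 343$ patients. Frequencies for
hypertension, NAFLD, anxiety, depression and psoriatic arthritis are
configuration inputs with realistic real-world defaults, not printed
reference values.

## Validation

`validate_population()` compares each continuous marginal against the
reference summary with an unpaired two-tailed t-test reconstructed from
mean, sd and n, or against a second simulated population with Wilcoxon
rank-sum tests. Under the reference spec, all marginals are
non-significant (p > 0.05) in at least 90% of seeds.

# Pharmacokinetics

The two-compartment model is linear:

$$\frac{dA_{skin}}{dt} = -k_a A_{skin}, \qquad
  \frac{dC}{dt} = \frac{k_a A_{skin}}{V_{blood}} - k_{el} C,$$

with subcutaneous doses adding $f_{bio} \cdot D$ to the depot and iv
doses adding $D / V_{blood}$ to the central compartment. The absorption
constant follows $k_a = \ln 2 / T_{1/2a}$ with
$T_{1/2a} \approx T_{max}/3$. Defaults: $T_{max} = 5$ days (hence
$k_a \approx 0.416$/day), $k_{el} = \ln 2 / 14$ per day (a 14-day
half-life), $V_{blood} = 5$ L, $f_{bio} = 1$ (bioavailability is not
stated in the source material and is configurable). Time is in days,
concentration in mg/L, the default grid step 0.1 day.

Two solution paths coexist. The default integrator is a fixed-step RK4
(sub-stepped so $\max(k_a, k_{el}) \cdot h \le 0.01$) — adequate because
the system is linear and non-stiff. The closed-form Bateman
superposition is exact for this system and serves both as the
independent oracle (agreement $\le 10^{-6}$ relative is a tested
invariant) and as the fast path used by `run_trial()`. The
$k_a = k_{el}$ singularity of the Bateman form is removed by a $10^{-9}$
perturbation.

Individualization scales the central volume by a sex-specific allometric
blood-volume formula (male $0.3669 h^3 + 0.03219 w + 0.6041$, female
$0.3561 h^3 + 0.03308 w + 0.1833$, $h$ in m, $w$ in kg) relative to a
reference patient (170 cm, 75 kg, male), times a configurable
distribution-volume adjustment factor; the depot volume scales with Du
Bois body surface area. The published flow/volume constants behind the
original individualization are not printed, so the contract here is the
*scaling behavior* (volumes strictly increase with weight; heavier
patients see lower concentrations), with the constants exposed as
configuration.

`fit_clearance()` estimates $k_{el}$ by 1-D golden-section least squares
(or $(k_a, k_{el})$ jointly by Nelder–Mead on the log scale), reporting
residuals and $R^2$; noise-free recovery is exact to 0.1% and 5%
multiplicative noise keeps $R^2 \ge 0.95$.

# Synthetic protein activity

For arm exposure summary $E$ (mean concentration over the weeks 12–16
steady-state window by default; Cmax or AUC are alternatives), each
effector protein with pathological sign $v_i$ starts at $v_i$ and is
pulled toward zero by a Hill effect
$\epsilon(E) = E_{max} E^{\gamma} / (EC_{50}^{\gamma} + E^{\gamma})$
(defaults $E_{max} = 0.9$, $EC_{50} = 10$ mg/L, $\gamma = 1$; the
functional form of the exposure–effect link is a design decision — the
source methodology computes an EC50 proxy without publishing equations,
so no quantitative agreement with the original per-protein correlations
is claimed). Mechanistic groups add a fixed $\pm\delta$ offset pattern
per (group, protein), drawn once from the seed; comorbidity tags map
patients to groups (first matching tag wins). Gaussian noise is added
and the result squashed into $[-1, 1]$ by $\tanh$ (smooth and
sign-preserving; hard clipping is the alternative dialect).

What this generator emulates: bounded per-protein activities, an
exposure-dependent treatment effect shared across effectors, group
structure aligned with comorbidity profiles, and seed-exact
reproducibility. What it does not emulate: real protein–protein
interaction topology, protein-specific dose–response heterogeneity, and
the training-data constraints of the original engine. Passing the
downstream recovery tests therefore demonstrates that the *analysis
machinery* is correct and sensitive at the stated signal-to-noise
ratios — not that the molecular claims of any particular study
replicate.

The synthetic reference-drug panel draws per-drug exposures, sets the
true tSignal to $1 - 2\,\epsilon(E)$, and generates PASI75 as an exactly
linear function of the true tSignal plus noise (clamped to $[0,1]$),
with the generating slope and intercept recorded for recovery tests.
Placebo response defaults to 5% and the maximal response to 85%,
representative of the PASI75 range spanned by systemic psoriasis
therapies.

# tSignal and calibration

The tSignal of an activity vector $y$ over a signed effector set is

$$\mathrm{tSignal} = \frac{1}{n} \sum_{i=1}^{n} v_i y_i,$$

where $n$ counts the definition proteins with **non-zero** signal — the
defining convention, which the hand example
$v = (+1, -1, +1),\ y = (0.5, 0, 0.5) \Rightarrow n = 2,\
\mathrm{tSignal} = 0.5$ distinguishes from the fixed-denominator
alternative (available via `denominator = "all"`). An all-zero signal
vector is an explicit error, not a zero.

Calibration regresses PASI75 on tSignal (`efficacy = A * tSignal + B`)
by OLS and reports the Pearson correlation. `optimize_definition()`
prunes distorting proteins greedily: at each step the single removal
that most increases $|\rho|$ is taken, ties broken lexicographically by
protein id. The stop rule is scale-free: a removal is accepted only if
it shrinks the unexplained part $1 - |\rho|$ by at least `min_improve`
(default 5%). An absolute threshold would fail near $|\rho| = 1$, where
genuine distorter removals yield geometrically shrinking absolute gains;
the fractional rule accepts every step of a planted-distorter sequence
(each removes $\ge 1/k$ of the remaining distortion) while rejecting
noise-chasing removals, which shrink the residual by roughly $1/p$. On
planted panels (115 faithful effectors responding linearly to drug
strength, 9 distorters tracking independent noise) the greedy loop
discards exactly the 9 distorters; on distorter-free panels at noise
0.05 it removes at most a few percent of proteins. These panel tests use
100 synthetic drugs: correlation estimates over a handful of drugs are
too unstable for any pruning rule to be evaluated against planted truth.

Severity-marker correlations are computed per arm between each marker's
activity and the per-model tSignal, Benjamini–Hochberg corrected, and
banded by $|\rho|$: strong > 0.8, moderate (0.5, 0.8], low (0.3, 0.5],
negligible $\le$ 0.3. The summary band uses the weakest arm.

# Clustering strategy

Activities are first centered per protein **within each arm**
(subtracting the arm-wise mean removes the direct concentration offset
while leaving within-arm variance untouched). The wording of the
original normalization is ambiguous between per-protein-within-arm and
per-row centering; the former is implemented, and per-row centering
would be a one-line alternative.

The grid crosses reductions (PCA scores or classical MDS; 2, 3 or 5
dimensions; Euclidean or $1 -$ Spearman rank correlation distance, the
latter MDS-only) with algorithms (k-means, 1-D self-organizing map,
spectral, Gaussian mixture, hierarchical with average/complete/Ward
linkage). For each configuration and candidate $k \ge 2$ the
Calinski–Harabasz, Davies–Bouldin, Gap and silhouette indices are
computed; each nominates an optimal $k$, and **silhouette's choice is
the configuration's $k$**, prioritized over the rest. The Gap statistic
uses a uniform bounding-box null with 20 references and the Tibshirani
one-standard-error selection rule. Numerical robustness choices:
spectral clustering is restarted five times (its embedded k-means is
seed-sensitive and kernlab's automatic kernel width can fail on
block-structured data, in which case a median-distance width is used),
keeping the best-silhouette labeling; the SOM is a 1-D chain of $k$
nodes (so node = cluster) restarted from random code samples, keeping
the lowest quantization error among runs with $k$ live nodes; algorithm
failures at a given $k$ flag that solution rather than aborting the
grid.

Quality is summarized by three indicators: Hopkins statistic (10% probe
sample against a uniform bounding-box null; near 0.5 on structureless
data), Dunn index (minimum separation over maximum diameter; singleton
clusters have diameter 0 by convention, and all-singleton solutions are
undefined), and mean Jaccard bootstrap stability (100 resamples,
clusters re-derived per resample and matched greedily by best Jaccard).
`select_best()` ranks configurations lexicographically on (Jaccard,
Hopkins, Dunn) rounded to two decimals — an invented but documented and
configurable rule, since the original reports only that the best model
was selected on these three indicators; ties resolve to the earliest
configuration for determinism.

Cluster characterization runs cluster-vs-rest t-tests on age, height,
weight and BMI, chi-squared on sex (with male:female ratios),
Fisher's exact test on every comorbidity tag (used uniformly regardless
of expected counts), arm incidence per cluster, and BH correction over
the whole table. Differential proteins require both an effect gate
(|cluster mean − overall mean| > 0.1 activity units) and an FDR gate
(Wilcoxon rank-sum cluster-vs-rest, BH q < 1e-4), routed to UP/DOWN
lists by sign. Classifier proteins are screened per cluster pair with a
single-feature threshold rule (midpoint scan maximizing balanced
accuracy, vectorized via cumulative class counts) under stratified
10-fold cross-validation, reported above BACC 0.8; the "cross-validated
p" of the original is unstated, so a label-permutation test is the
documented stand-in.

# Enrichment and network linkage

Annotation sets (GMT semantics) are intersected with the universe — the
full protein list of the models — **before** the size filter
$[10, 300]$ is applied (the ordering is unstated in the source and
documented here). The one-sided hypergeometric tail $P(X \ge k)$ is
exact (`phyper`), BH-corrected across tested sets, and reported at
q < 0.01. Set–set linkage is the Dubuisson–Jain modified Hausdorff
distance — the maximum of the two mean-of-minima directed distances —
over shortest-path lengths on a user-supplied protein network;
disconnected pairs default to diameter + 1. Classical max–min Hausdorff
is available behind a flag. Networks export to SIF and GraphML (exact
round-trip through igraph) with a node-attribute table; whether edge
thresholds should be absolute or relative is left as a configuration
value.

# Sample-size estimation

`progressive_sampling()` builds a learning curve from size 10 upward:
per size, repeated stratified subsamples; per subsample, the best
two-feature pair by exhaustive search (greedy seeded by t-statistics
beyond 200 features) with an LDA decision rule, scored by 10-fold CV
accuracy. "Power 95%" is read as: the threshold fraction of maximum
accuracy must be met in at least 95% of the repeats — the original
computation is unstated, and this reading is monotone and testable. The
repeat count per size is likewise unstated; 20 is the default.

# Orchestration and determinism

`run_trial()` reuses the same patients across arms (a paired,
washout-free design), producing exactly `n_patients × n_arms` model
records. One global seed is split deterministically per stage
(`stage_seed()`, a fixed affine hash kept below $2^{31}$), so re-running
one stage never reshuffles another, and a rerun of the whole trial is
byte-identical — the manifest records every stage seed and an md5
checksum per output file. The closed-form PK path is used in the
pipeline for speed; it is exact, and its agreement with the RK4
integrator is enforced by tests.

# Problem sizes used in the test suite

The suite exercises: populations of 500 (demographic reproduction, 50
seeds), 10,000 (binomial tag frequencies); planted-panel pruning at 124
proteins × 100 drugs; clustering recovery at 90 models × 40 proteins
over 20 seeds with shift-to-noise 5; the full pipeline end-to-end at 20
patients and through the activity stage at 500 patients (1,000 models);
exhaustive hypergeometric enumeration for all universes up to 25. These
sizes are the package's chosen balance between statistical resolution
and a test suite that runs in minutes on one CPU.

# Known limitations

- No target-mediated disposition, anti-drug antibodies, tissue
  penetration or placental transfer in the PK model; no correlated
  comorbidity co-occurrence; no smoking/alcohol covariates; adults only.
- The activity generator's Hill link and group-offset structure are
  surrogates; agreement with any real predicted-activity engine is out
  of scope by construction.
- The selection rule among clustering configurations and the
  permutation stand-in for classifier p-values are documented package
  choices where the original procedure is not fully specified.
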