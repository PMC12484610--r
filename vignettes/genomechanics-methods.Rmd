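---
title: "Models and methods behind genomechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind genomechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomechanics)
```

This vignette is the package's own account of the science it implements:
the mechanical models fitted to AFM force curves, the expression and
network statistics layered on top of them, what the synthetic-data
generators do and do not emulate, and the numerical choices made where the
underlying procedures leave room.

## The mechanical models

### Elasticity: Hertzian sphere-on-half-space contact

A cell indented by a spherical probe of radius $r$ behaves, to first
order, like an elastic half-space. The approach segment of a force curve
is fitted with the Hertz contact force

$$F = \tfrac{4}{3}\, E^{*} \sqrt{r\, d^{3}},$$

where $E^{*}$ is the apparent Young's modulus (Pa) and $d$ the indentation
depth (m). Force comes from the calibrated cantilever through Hooke's law,
$F = k\,\delta$, and indentation is the piezo travel past contact minus
the change in cantilever deflection,

$$d = (z - z_c) - (\delta - \delta_c),$$

clipped at zero. This accounts for the fact that part of the piezo motion
bends the lever rather than indenting the cell. Because the model is
linear in $E^{*}$, the least-squares estimate is computed in closed form
(a one-dimensional projection, clipped at zero); there is no optimizer and
no convergence tolerance to tune in the elastic fit.

**Contact-point detection.** The contact point $z_c$ is first estimated by
the classical two-line construction: a least-squares line through the
first 30% of approach samples (the flat baseline) intersected with a line
through the last 20% (firm contact). Both windows are configurable
(`baseline_fraction`, `contact_fraction`). On a convex Hertz approach this
intersection is systematically *late* — the chord through the contact
region crosses the baseline past the true touch point — so the two-line
result is treated strictly as an initializer. The true contact point is
then found by residual minimization: every approach sample within
`refine_window` (default ±25 samples) of the estimate is tried as a
candidate contact, a full Hertz fit is performed for each, and the
candidate with the smallest residual sum of squares wins. When the
minimum lands on the edge of the window the search re-centers there and
repeats, so the refinement descends to a local RSS minimum even when the
initial estimate is off by more than one window width. By construction
the refined RSS never exceeds the RSS at the starting estimate; on
noiseless synthetic curves the procedure recovers the exact contact
sample.

### Viscosity: standard-linear-solid relaxation

While the piezo is held at constant position after reaching the 5 nN
trigger, the compressive force relaxes. A standard linear solid — an
elastic spring in parallel with two Maxwell (spring–dashpot) elements —
predicts a biexponential decay toward an asymptote:

$$F(t) = C + (F_0 - C)\left[A e^{-(t - t_0)\lambda_1}
        + (1 - A) e^{-(t - t_0)\lambda_2}\right],$$

with $C$ the asymptote (N), $F_0$ the force at the start of the dwell,
$A \in [0, 1]$ the weight of the fast component, and
$\lambda_1 \ge \lambda_2 > 0$ the fast and slow viscous rate constants
(1/s). The fast rate is usually interpreted as membrane-scale relaxation
and the slow rate as cytoskeletal rearrangement; larger values mean
faster relaxation.

Numerical choices in `fit_sls_relaxation()`:

* $t_0$ is fixed at the first dwell timestamp — it is a property of the
  measurement, not a free parameter — leaving five fitted parameters.
* Optimization is Levenberg–Marquardt (`minpack.lm`) with box constraints
  ($0 \le A \le 1$, rates positive). The biexponential objective is
  multimodal in the rates, so the fit is started from a grid: $A_0 = 0.5$,
  $F_0$ at the first dwell sample, $C_0$ at the last-decile mean, and all
  ordered pairs of six log-spaced rate guesses spanning 10/duration up to
  half the sampling rate. The best-RSS start wins.
* The two exponential components are exchangeable
  ($(\lambda_1, A) \leftrightarrow (\lambda_2, 1 - A)$ gives the same
  curve), so labels are normalized after optimization: rates are swapped
  and $A \mapsto 1 - A$ whenever needed to enforce
  $\lambda_1 \ge \lambda_2$.
* When $\lambda_1 = \lambda_2$ the weight $A$ is unidentifiable and the
  model collapses to a single exponential; the fit still converges to the
  correct curve (RSS matches the single-exponential optimum), only the
  labels are arbitrary there.
* Optimizer failure returns `converged = FALSE` rather than an error, so
  batch analysis over hundreds of curves never aborts midway.
* A constant dwell force is rejected as degenerate (the rates are
  unidentifiable), and fits with fewer samples than parameters are errors.

**Fit quality.** Each relaxation fit carries its residual sum of squares;
`quality_ok` flags fits whose RSS falls below a configurable bound
(default $5 \times 10^{-17}$, interpreted in N² since all forces are
handled in newtons — the bound is configurable precisely because the
units convention of any particular instrument pipeline may differ).

**Baseline drift.** No drift correction is applied by default; an
optional linear baseline subtraction (the fitted baseline line removed
from the whole deflection channel) is available behind
`baseline_correction = TRUE` for curves acquired with noticeable
photodiode drift.

## The synthetic-data generators

Every input the pipeline consumes can be generated, with full seed
control; each generator is a pure function of its configuration, and the
caller's RNG state is left untouched.

**Force curves** (`simulate_force_curve()`). The forward model composes
the same two equations the fitting stages assume. During approach the
piezo advances at 2 μm/s and, per sample, the implicit balance
$d + F(d)/k = z - z_c$ is solved by Newton iteration (the measured
deflection subtracts from the travel available for indentation), so
noiseless simulated curves satisfy the Hertz equation to machine
precision under the package's own indentation definition. The approach
ends exactly at the 5 nN trigger; the dwell then follows the SLS decay
with $F_0$ equal to the trigger force and $C$ defaulting to 20% of it
(1 nN). Defaults mirror a typical beaded-cantilever cell measurement:
5.24 μm bead, $k = 0.02$ N/m (inside the usual 10–25 pN/nm calibration
range), 10 s dwell, 200 Hz sampling, 2 μm of pre-contact baseline. Noise
is additive i.i.d. Gaussian force noise — a deliberate simplification;
real instrument noise is colored and includes drift, so recovery results
on simulated curves bound what clean instruments achieve, not what
drifting ones do. Retract segments and adhesion are not simulated.

**Expression coupled to mechanics**
(`simulate_expression_mechanics()`). A Gaussian copula: a latent normal
vector over (λ₁, λ₂, stiffness, genes) with latent Pearson correlations
$r = 2\sin(\pi\rho_s/6)$, the exact conversion under which the copula
reproduces a requested Spearman $\rho_s$. Mechanical marginals are
log-normal (positive, right-skewed, typical of AFM moduli and rates;
medians default to 3 /s, 0.3 /s and 1 kPa), expression marginals normal
on the housekeeping-normalized $-\Delta C_t$ scale. The default 91 cells
matches a realistic per-line panel size. Because gene–gene and
property–property latent correlations are fixed at zero, a requested
coupling pattern is feasible only if the implied latent matrix is
positive semi-definite — e.g. many genes all strongly coupled to the same
property is impossible without gene–gene correlation — and infeasible
requests fail with an explicit suggestion to reduce $|\rho|$. Real
single-cell panels have correlated genes, dropouts and batch structure;
none of that is emulated, so passing screens here demonstrate
correctness of the statistics, not robustness to real-data artifacts.

**Ct tables** (`simulate_ct_table()`). Treated-group target Cts are
shifted by $-\log_2(\text{fold})$ against a shared housekeeping baseline,
with Gaussian replicate noise in cycles. At zero noise the downstream
ddCt stage recovers the configured fold exactly — the round trip used
throughout validation.

**Signed networks** (`simulate_network()`). Regulator out-degrees are
drawn from a discrete power law $P(k) \propto k^{-\alpha}$ truncated to
$[1, n_\text{genes}]$ and rescaled (rounded, clamped) to the requested
mean out-degree — the simplest model with a tunable hub character; targets
are sampled uniformly without replacement and each edge is an activation
with the configured probability.

## Expression quantification (ddCt)

$\Delta C_t$ normalizes each target to the *arithmetic mean* of the
housekeeping Cts — exactly the geometric mean of housekeeping expression
on the $2^{-C_t}$ scale. Passing a single reference id gives the
single-housekeeping mode used for miRNA panels. $\Delta\Delta C_t$
contrasts group means and the fold change is $2^{-\Delta\Delta C_t}$,
with PCR efficiency fixed at the ideal 2 (per-assay efficiencies are out
of scope; the pipeline consumes Ct values, not amplification curves).

Uncertainty propagates by independent-error quadrature,
$\mathrm{sd}_{\Delta\Delta C_t} = \sqrt{\mathrm{sd}^2_{\Delta C_t,\text{ctrl}}
+ \mathrm{sd}^2_{\Delta C_t,\text{trt}}}$, followed by a first-order delta
method for the exponential transform,
$\mathrm{sd}_\text{fold} = \text{fold} \cdot \ln 2 \cdot
\mathrm{sd}_{\Delta\Delta C_t}$. In the full table workflow the per-group
SDs are taken from the replicate $\Delta C_t$ values, which already carry
the housekeeping-reference variance — the reference term of the quadrature
is therefore not added a second time. The delta method is accurate to a
few percent for $\mathrm{sd}_{\Delta\Delta C_t} \lesssim 0.2$ cycles
(validated against Monte Carlo in the test suite); for noisier assays the
reported SD underestimates the true spread of the log-normal fold
distribution.

Significance uses Welch's two-sample t-test on replicate $\Delta C_t$
values, two-sided (sidedness is a package choice; nothing in the workflow
justifies a one-sided test). Twofold threshold flags use inclusive
boundaries (fold ≥ 2 is "up", ≤ 0.5 is "down"). Alignment against
network-predicted directions is judged only on significant changes
(p < 0.05): aligned/misaligned per target, and a per-condition summary of
aligned / misaligned / mixed.

## The correlation screen

Each gene is tested against each of λ₁, λ₂ and stiffness with Spearman's
rank correlation on complete cases, average ranks for ties. Two-sided
p-values are exact for $n \le 8$ — computed by full enumeration of all
$n!$ rank permutations, $p = \Pr(|\rho^*| \ge |\rho_\text{obs}|)$ — and
use the t-approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ above. The
screen filters at raw p < 0.05 by default, as is conventional for this
kind of hypothesis-generating screen; a `p.adjust` method can be switched
on for familywise control. Constant vectors are skipped with a warning
rather than reported as $\rho = 0$. The screen pools all supplied cells;
stratified (per-cell-line) screening is done by subsetting the input
tables, which keeps the interface free of an extra grouping convention.

Significant genes are partitioned into property-unique sets and a
"multiple" block. The partition satisfies, and the tests assert, the
conservation identity: each property's significant count equals its
unique block plus its members of the multiple block.

## Upstream regulator scoring

Given a signed regulator→gene network and observed per-gene directions
(the sign of each gene's correlation with the property under study),
three statistics are computed per regulator:

* **Overlap p** — right-tailed hypergeometric probability of the overlap
  between the regulator's target set and the observed gene set
  (right-tailed Fisher's exact test). Zero overlap gives p = 1.
* **Activation z-score** — over the $N$ targeted genes with an observed
  direction, $z = (N^+ - N^-)/\sqrt{N}$, where an edge is consistent when
  its sign times the observed direction is +1. This is the unweighted
  form of the causal-analytics activation score; published tables
  produced with curated knowledge bases occasionally print values
  (e.g. 2.065, 2.111) that no $(N^+ - N^-)/\sqrt{N}$ can yield, which
  indicates edge weighting — only the unweighted statistic is claimed or
  implemented here.
* **Hub-bias-corrected p** — genes targeted by many regulators inflate
  naive overlap statistics, so an empirical null is built by uniformly
  reassigning the observed directions across the observed genes (the
  +1/−1 counts and the entire network degree structure are preserved) and
  recomputing $z^*$; $p = (1 + \#\{|z^*| \ge |z|\})/(n_\text{perm} + 1)$,
  seeded, default 10,000 permutations. This is a stated substitute for
  the proprietary analytic correction used by commercial pathway tools,
  whose exact null is not public; it corrects the same bias by direct
  permutation.

Control nodes are retained at $|z| \ge 2$ (boundary inclusive) and
corrected p < 0.01, and labeled activated (z > 0) or inhibited (z < 0).
The sign algebra for interventions follows: activating a positive-z
regulator is predicted to increase the property; inhibiting a negative-z
regulator is a double negation and also predicts an increase.

## Shared statistics

Welch's t (with Welch–Satterthwaite fractional df) wraps `stats::t.test`;
Tukey HSD uses `stats::aov` + `stats::TukeyHSD`, i.e. pooled within-group
variance and the studentized range with the Tukey–Kramer unequal-n
adjustment, applied to raw (untransformed) values. The migration standard
curve is an ordinary least-squares line from fluorescence to cell count,
with predictions clipped at zero cells; linearity is an assumption of the
assay's calibration range, not a fitted choice.

## Reproducibility and I/O conventions

All generators and the permutation test take explicit seeds; the demo
pipeline derives fixed per-stage seed offsets from one global seed, so
stages are independently reproducible and a rerun is byte-identical.
Tables are CSV/TSV with headers; numeric columns are written with 17
significant digits so finite doubles survive a write/read round trip to
the last bit (12 digits would not), at a negligible file-size cost.
Configuration is JSON, schema-checked with errors that name every invalid
key.

## Problem sizes used in validation

The shipped validation (test suite and `scripts/acceptance.R`) uses: 100
noisy plus 15 noiseless simulated curves at 200 Hz for parameter
recovery; 50 noiseless curves for contact recovery; 100 copula seeds at
91 cells for screen power; 50 networks of 20 regulators × 100 genes with
400-permutation corrected p-values for null calibration of the
control-node filter; and $10^5$ Monte-Carlo draws for the delta-method
check. These sizes give stable medians and rate estimates while keeping a
full validation run in the low minutes on one core.

## Known limitations

* The mechanics stage assumes spherical probes and Hertzian contact;
  sharp tips, adhesion (retract analysis), poroelastic or power-law
  rheology are out of scope.
* The SLS fit assumes an ideal constant-position dwell; piezo feedback
  dynamics and drift during the 10 s hold are not modeled.
* The copula generator reproduces rank couplings and marginals, not the
  full complexity of single-cell expression data.
* The regulator statistics operate on a single-layer signed edge list;
  multi-step causal depth, edge confidence weights and curated-knowledge
  content are out of scope (users supply their own edge lists).
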