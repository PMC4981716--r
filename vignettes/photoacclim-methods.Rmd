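---
title: "Models and methods behind photoacclim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind photoacclim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoacclim)
```

photoacclim analyses irradiance-controlled steady-state growth of
cyanobacteria in turbidostat photobioreactors. This vignette is the
package's own account of the models it implements, the defaults it
chooses where a choice was genuinely open, and what its synthetic-data
generator does and does not emulate.

## The steady-state O₂ mass balance

At steady state, the dissolved-O₂ balance over the stirred liquid
volume links net photosynthetic O₂ production to the washout and
gas-stripping fluxes:

$$ q_{O_2}\,x \;=\; D\,([O_2]-[O_2]_{in}) \;+\; k_La\,([O_2]-k_H\,p_{O_2,in}) $$

with $q_{O_2}$ the net specific O₂ production (mmol h⁻¹ g$_{AFDW}$⁻¹),
$x$ the biomass concentration (g AFDW L⁻¹), $D$ the dilution rate
(h⁻¹), $k_La$ the lumped gas–liquid transfer coefficient and $k_H$ the
Henry's-law partitioning coefficient for O₂ (mM atm⁻¹). The same
balance is often written consumption-positive with both differences
reversed; `compute_qO2()` uses the production-positive arrangement
above so that an actively photosynthesising culture sparged with
O₂-free gas has $q_{O_2} > 0$, and a negative value simply means net
consumption. Internally everything is normalised to h⁻¹, µM and
g AFDW L⁻¹; `gas_params()` accepts $k_La$ tagged in min⁻¹ and converts
(0.83 min⁻¹ = 49.8 h⁻¹).

The carbon-mole biomass production rate assumes a dry-biomass
"molecular weight" of 24.59 g AFDW per C-mol:
$q_X = \mu \cdot 1000 / 24.59$ (Cmmol h⁻¹ g⁻¹).

Under turbidostat control the optical density is held constant, so the
dilution rate equals the specific growth rate; the analysis accepts
either column as µ. Physiological steady state is declared by
`detect_steady_state()` when every monitored channel (OD₇₃₀, pH,
dissolved O₂) varies by at most 3% between consecutive measurements —
an inclusive threshold, with relative variation defined as
|difference| / pair mean — and at least five residence times have
elapsed.

## The light-response model

Growth and photosynthesis rates against incident irradiance $I_i$ are
fit with a Platt-type saturating/photoinhibition curve,

$$ R \;=\; R_{max}\,\bigl[1-e^{-I_i/I_k}\bigr]\,e^{-I_i/\beta}, $$

where $I_k$ is the theoretical saturating irradiance and $\beta$ the
irradiance threshold of inhibition, in the same units as $I_i$ (both
exponents are ratios of irradiances; $\beta \to \infty$ recovers the
Webb saturating exponential). Useful derived quantities: the initial
slope $\alpha = R_{max}/I_k$ and, for finite $\beta$, the peak
irradiance $I_{peak} = I_k \ln(1+\beta/I_k)$ from setting
$dR/dI_i = 0$.

`fit_light_response()` minimises the weighted sum of squares with
Levenberg–Marquardt iterations from five data-driven multi-starts
($R_{max,0}$ = observed maximum; $I_{k,0}$ = irradiance at half
maximum; $\beta_0 \in \{2\max I_i,\ 10^4 \max I_i\}$; deterministic
log-normal jitter). Choices that matter:

* **Weights.** $w_i = 1/sd_i^2$ when per-point standard deviations
  (e.g. replicate sds) are supplied, otherwise 1. No other scheme is
  offered; weighting is what the replicate structure supports.
* **Parameter scale and bounds.** Parameters are optimised as
  logarithms (they are positive scales) inside wide data-driven boxes
  ($I_k$ within 20× the observed irradiance range, $R_{max}$ within
  100× the observed maximum). Outside those boxes only the ratio
  $R_{max}/I_k$ is identified — the curve degenerates to a straight
  line — and an unbounded optimiser occasionally wanders there on
  noisy data.
* **Model selection.** The three-parameter model always fits at least
  as well as its $\beta = \infty$ submodel, so finite $\beta$ is
  retained only when the extra-sum-of-squares F test rejects the
  submodel at α = 0.05. This prevents spurious inhibition being
  reported for saturating data; both SSEs and the F p-value are kept
  in the fit object.
* **Regime classification.** Light-limited and light-saturated
  regimes are separated by a transitional band of fractional width
  δ = 0.25 around $I_k$ ($I_i < 0.75 I_k$ limited,
  $I_i > 1.25 I_k$ saturated). No numeric width exists for "at or near
  $I_k$" in the field; 0.25 places single steady states on either side
  of the transition into the band without emptying the outer regimes.

The growth-to-photosynthesis yield (photosynthetic quotient)
$Q$ (Cmmol biomass per mmol O₂) is the OLS slope of $q_X$ on $q_{O_2}$
per regime, fit with an intercept by default — forcing the origin is an
extra physical assumption, available via `intercept = FALSE`. The
pipeline computes these slopes on per-steady-state mean rates (one
point per irradiance), the resolution at which rate–rate plots of
means ± sd live; slopes over few points are heavy-tailed, and the
per-regime standard error is reported alongside.

## PAM fluorometry

`compute_rETR()` implements rETR = PAR·(F$_m'$−F)/F$_m'$. Anomalous
F > F$_m'$ pairs yield negative values that are flagged, never clamped:
the anomaly is information. Rapid light curves are fit with the
saturating submodel via the same machinery as growth; rETR$_{max}$ is
the fitted asymptote (the observed maximum is also reported, the
fitted value is primary) and α$_r$ = R$_{max}$/I$_k$ the initial
slope. The post-illumination fluorescence rise in darkness — reduction
of the plastoquinone pool by stromal reductant after actinic light
stops — is summarised by `estimate_rCEF()` as the OLS slope of F
against time over the first 10 s of the 30-s dark phase. The window is
configurable; 10 s captures the initial transient before the rise
rolls over, and the estimate is labelled a slope (fluorescence units
s⁻¹) because the literature's "rise" is not otherwise quantified.
Trace phases are required input labels in the order
saturating-pulse (200 ms), far-red (5 s), actinic (15 s), dark (30 s);
inferring phases from a light program would be a second model with its
own failure modes.

## Expression clustering and enrichment

The RPKM matrix is filtered, transformed and clustered in that order:

1. **Filter.** Per condition, the bottom 20% of genes by rank (ties
   broken by gene identifier, so the bottom set has exactly
   ⌊0.2·n⌋ members). The default policy removes a gene only when it is
   in the bottom set at *every* condition — reading "at each level" as
   universal quantification; `policy = "any"` is the alternative.
2. **Transform.** $z = (\log_2(\mathrm{RPKM}+1) - \bar{\cdot})/sd$ per
   gene, with the *population* sd so every retained row has mean
   exactly 0 and sd exactly 1. The pseudocount of 1 RPKM is
   configurable; genes constant across conditions are excluded and
   reported, not silently zeroed.
3. **Cluster.** Agglomerative hierarchical clustering, Euclidean
   distance on standardized profiles, average linkage — the common
   default for standardized expression profiles; both are
   configurable. Rows are ordered by gene identifier before the
   distance computation, making the result independent of input
   order. The tree is cut at k = 6 profiles and profiles whose
   eigengenes correlate above r = 0.8 are merged, which reduces an
   over-segmented cut to its major clusters (four, on the archetypal
   structure) without choosing k = 4 a priori.

The **eigengene** of a cluster is the first right singular vector of
its genes × conditions submatrix: the unit-norm condition profile
explaining the largest share of cluster variance, with its sign chosen
to correlate non-negatively with the cluster's mean profile. A
singleton cluster is the exact rank-1 case. Eigengene alignment with
phenotype (e.g. µ per condition) is plain Pearson correlation.

**Enrichment** per (cluster, category) is the one-sided (greater)
Fisher exact test on the 2×2 table over the gene universe, because
enrichment is defined as a category being over-represented, not merely
different. The default universe is the post-filter expressed gene set;
the whole annotation can be supplied instead — the ratio denominators
of published enrichment tables are rarely reconstructable, so both are
exposed. Raw p-values are compared against α = 0.05 by default, with
an optional Benjamini–Hochberg column; genes carrying several
categories at one level count once per category.

## Morphometrics

Cells are treated as prolate spheroids measured by minor-axis and
major-axis *diameters* a and b, giving $V = (\pi/6)a^2b$. The same
formula is sometimes quoted as $(4/3)\pi a^2 b$ with a and b still
called diameters; that form is only consistent if a and b are
semi-axes and is 8× larger when fed diameters — micrometre-scale
diameters and cell volumes of a few µm³ require the (π/6) form, which
is the default (`formula = "as_printed"` exposes the other reading).
Pairs with a > b are swapped with a warning; per-condition summaries
report the sample sd (n−1), undefined at n = 1.

## The synthetic-data generator

Every pipeline input can be generated with known ground truth, carried
in `truth_*` columns that no estimator reads (the pipeline strips them
before any computation, and a test corrupts them to prove it).

* **Steady states.** µ follows the light-response curve at
  $R_{max} = 0.20$ h⁻¹, $I_k = 164$, $\beta = \infty$ over eight
  irradiances from 33 to 760 µmol photons m⁻² s⁻¹, in triplicate;
  D = µ by the turbidostat identity; OD₇₃₀ 0.082 with
  36 mg AFDW L⁻¹ at setpoint. The simulated $q_{O_2}$ comes from the
  per-regime yields $Q_{lim} = 1.3$ and $Q_{sat} = 0.6$, interpolated
  linearly across the transitional band (a hard step would make
  downstream slope estimates discontinuous in the fitted $I_k$, an
  artifact of the generator rather than the analysis), and the
  dissolved O₂ is the exact solution of the mass balance for that
  $q_{O_2}$ — so the balance inverts to machine precision at zero
  noise. Measurement noise is multiplicative log-normal with unit mean,
  per channel: CV 5% on rates, 3.7% on OD₇₃₀, 2% on dissolved O₂,
  matching the relative precisions such instruments deliver. Rates are
  positive and their spread grows with the mean, which is what makes
  the log-normal the natural noise model here.
* **Expression.** Four archetype condition profiles — monotone up,
  monotone down, minimum at the transition, maximum at the transition,
  with the extremum at the condition nearest $I_k$ — populated by
  809/724/648/551 genes (2,732 total). The up/minimum shapes are
  piecewise-linear in condition index; their counterparts fall with
  mild curvature (power 1.3) so the four shapes are linearly
  independent rather than exact mirror images. Gene profiles are the
  archetype plus N(0, 0.3) noise in standardized units, mapped to
  positive RPKM as $100 \cdot 2^{z}$; annotation maps carry planted
  enriched categories (by default a translation-like category at 13.1%
  of the up-cluster against a background giving a ratio of 2.5) plus
  uniform null categories.
* **Fluorometry.** Four-phase traces with the protocol durations
  above and a configurable linear dark-phase rise; rapid light curves
  generated by inverting the rETR definition at constant F$_m'$.
* **Cell measurements.** Log-normal minor axes at fixed mean aspect
  ratio 1.8, scaled so mean volumes centre on 3.23/4.84/9.69 µm³ at
  66/98/395 µmol photons m⁻² s⁻¹ with 104/107/65 cells — a doubling
  across the light-limited → light-saturated transition and a ~3×
  span across the irradiance scale.

What the generator does **not** emulate: pre-steady-state reactor
dynamics, self-shading and photon transport, read-level RNA-seq (it
produces RPKM directly), correlated noise between channels, diurnal or
batch effects, and cell-shape classes beyond prolate spheroids.
Passing recovery tests on this generator therefore demonstrates the
estimators are correct and unbiased under the stated noise model — not
that they are robust to structured artefacts of real instruments.

## Numerical choices and problem sizes

Determinism is a contract throughout: every simulator takes a seed and
identical seeds give byte-identical outputs; clustering breaks ties by
gene identifier; the optimiser's start jitter is seeded. Degenerate
inputs are reported, not patched: constant genes are excluded with
names, regimes with fewer than two points or zero variance are
flagged without a slope, all-zero rapid light curves are flagged
degenerate, and non-physical simulator configurations (negative
dissolved O₂) name the offending irradiance.

The test suite sizes its simulations to exercise the estimators
without ceremony: 200-seed Monte-Carlo runs for parameter-recovery
bias, 100–1000 random instances for the oracle equivalences (Fisher
tails, OLS slopes, brute-force linkage on ≤8 genes, 50³ grid searches),
and 200-gene-per-archetype matrices for cluster recovery. The
replicated acceptance computation averages 20 simulated experiments by
median, the stable summary for the heavy-tailed regime slopes.

## Known limitations

* The three-parameter fit needs irradiances beyond the curve maximum
  to pin down β; data truncated below $I_{peak}$ leave β (and hence
  $I_{peak}$) poorly identified, which the per-parameter standard
  errors make visible.
* Q slopes over regimes containing few steady states inherit large
  sampling error, and measurement noise in $q_{O_2}$ attenuates OLS
  slopes toward zero (errors-in-variables); with the per-channel noise
  defaults this bias is ≲5%, but it grows with electrode noise.
* The enrichment universe choice changes ratios and p-values;
  cross-study comparisons should state it explicitly.
* Eigengene sign is a convention; only |r| against phenotypes is
  meaningful across datasets.
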