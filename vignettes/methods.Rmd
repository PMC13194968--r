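---
title: "Methods: contamination indices and probabilistic soil health risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contamination indices and probabilistic soil health risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilrisk)
```

# Scope and data model

`soilrisk` assesses heavy metal(loid) contamination of soils around an
industrial point source and the human health risk it implies. The working
unit is a *sample table*: one row per composite soil sample, one strictly
positive concentration column (mg kg⁻¹) per metal in
{As, Pb, Zn, Fe, Cd, Cu, Cr, Ni}. Positivity is a hard invariant — every
index below takes a ratio or a logarithm — and is enforced at construction
with errors naming the offending sample and metal. Concentrations are
mg kg⁻¹ throughout; Fe is not special-cased despite its magnitude.

Two geochemical background sets ship with the package: average shale
values (ASV) and upper continental crust (UCC). All index computation uses
ASV — appropriate for fine-grained alluvial soils and applied uniformly so
the four indices are comparable — while UCC is retained for context ratios
only.

# Pollution indices

For a metal with sample concentration $C_n$ and background $B_n$:

$$EF = \frac{(C_n/C_{Fe})_{sample}}{(B_n/B_{Fe})_{background}}, \qquad
I_{geo} = \log_2\frac{C_n}{1.5\,B_n}, \qquad
CF = \frac{C_n}{B_n}, \qquad
PLI = \Big(\prod_{i=1}^{n} CF_i\Big)^{1/n}.$$

Fe is the EF normalizer (abundant, conservative; its own EF is 1 by
construction). The 1.5 in $I_{geo}$ absorbs lithogenic background
variation. PLI is the geometric mean of one sample's CFs across metals.
Useful identities, all enforced as property tests: $I_{geo} =
\log_2(CF/1.5)$; CF is linear in concentration, so the mean CF across
samples equals CF of the mean concentration; PLI is scale-covariant.

Classification schemes (seven Müller classes for $I_{geo}$, five
enrichment groups for EF, four Hakanson groups for CF, four PLI groups,
plus HI and TCR risk bands) live in a CSV shipped with the package, not in
code, so bounds can be corrected without touching the implementation.
Intervals are left-closed and a value exactly on a bound belongs to the
*upper* class — a deliberate, documented tie rule. Indices are reported to
two decimals in summaries; full precision is kept internally.

# Deterministic exposure and risk

The USEPA residential soil model with three pathways and two receptors.
With exposure frequency $EF_d$ (days yr⁻¹), duration $ED$ (yr), body
weight $BW$ (kg) and averaging time $AT$ (days):

$$ADI_{ing} = \frac{C \cdot IngR \cdot EF_d \cdot ED}{BW \cdot AT}\times10^{-6},
\quad
ADI_{inh} = \frac{C \cdot InhR \cdot EF_d \cdot ED}{BW \cdot AT \cdot PEF},
\quad
ADI_{derm} = \frac{C \cdot SA \cdot AF \cdot ABS \cdot EF_d \cdot ED}{BW \cdot AT}\times10^{-6}.$$

The $10^{-6}$ factor converts mg of metal per kg of soil times mg of soil
into mg of metal; the inhalation equation carries no such factor because
the particle emission factor PEF (m³ kg⁻¹) already converts soil mass to
air volume. Non-carcinogenic doses use $AT_{nc} = ED \times 365$;
carcinogenic doses use the same equations with the lifetime averaging time
$AT_{ca} = 70 \times 365$ days. The two averaging times are kept on
type-distinct call paths (`at = p$at_nc` vs `p$at_ca`) so they cannot be
swapped silently.

Hazard quotients are $HQ = ADI/RfD$ per pathway and $HI = \sum HQ$
(threshold 1); cancer risks are $CR = ADI \times CSF$ and
$TCR = \sum CR$ (insignificant below $10^{-6}$, tolerable to $10^{-4}$,
unacceptable above). Pathways lacking a slope factor contribute zero and
are flagged; metals with no slope factor at all (Zn, Cu, Fe in the default
registry) are excluded from cancer outputs with a notice rather than
silently zeroed.

## Default registries

Site-specific exposure surveys rarely exist, so the package ships the
standard RAGS/RSL residential defaults (child: IngR 200 mg d⁻¹, InhR
7.6 m³ d⁻¹, BW 15 kg, ED 6 y, SA 2800 cm², AF 0.2 mg cm⁻² d⁻¹; adult:
IngR 100, InhR 20, BW 70, ED 24, SA 5700, AF 0.07; both EF$_d$ 350 d y⁻¹,
PEF 1.36×10⁹ m³ kg⁻¹) and an IRIS/RSL-convention toxicity registry
(dermal RfD = oral RfD × gastrointestinal absorption fraction where no
direct value exists). Every toxicity row carries a provenance string, and
both registries are plain CSVs overridable per run. Risk *orderings*
(child above adult; ingestion above inhalation) are robust to these
choices because they follow from the dose-coefficient ratios; absolute
magnitudes are registry-dependent and should be read accordingly.

# Monte Carlo propagation

`run_simulation()` draws joint parameter vectors, evaluates a vectorized
risk model per draw, and summarizes the output with mean, SD, P5/P50/P95
and exceedance probabilities (defaults HI > 1, TCR > 10⁻⁴). Numerical
choices:

- Empirical quantiles use linear interpolation of order statistics (R
  type 7), one definition everywhere.
- All sampling is inverse-CDF, including truncation (the uniform variate
  is mapped into $[F(low), F(high)]$) — exact, no rejection loop, and it
  preserves stratification when the base sample is a Latin hypercube.
- Determinism: identical (seed, n, distributions) give bit-identical
  summaries; multi-simulation runs derive one seed per (receptor, metal)
  from the master seed by a fixed counter scheme so any cell is
  reproducible in isolation.
- A point-mass specification for every parameter reduces the simulation
  exactly to the deterministic module (tested to 1e-12 relative) — the
  bridge between the two code paths.

## Default input distributions

The defaults encode standard probabilistic soil-risk practice:

| parameter | family | spread | rationale |
|---|---|---|---|
| concentration | lognormal | CV = site CV / √n | uncertainty of the chronic exposure-point (site-mean) concentration; spatial variability across samples is the deterministic module's job |
| IngR | lognormal, truncated [mean/20, 5·mean] | CV 60% | soil ingestion is the dominant and most right-skewed exposure uncertainty |
| BW | normal, truncated [0.4, 2]·mean | CV 20% | anthropometric variability |
| InhR, SA, AF | triangular | ±30% around default | moderate, bounded uncertainty |
| EF$_d$, ED | point | — | scenario definitions, not uncertain quantities |

Treating the concentration input as uncertainty in the *mean* (standard
error scale) rather than full spatial variability is a deliberate design
choice: the probabilistic question is the chronic risk of a typical
receptor on the site, and it keeps the variance budget where exposure
assessments place it — on the behavioural and physiological factors. With
these defaults the ingestion rate carries the largest total-order Sobol
index and body weight the second largest, with concentration a distant
third; this ordering is asserted in the acceptance suite.

## Convergence

`convergence_check()` draws `max(ns)` iterations once and compares the
statistics of nested prefixes (default 5,000/10,000/15,000) against the
largest run, flagging relative differences above 2%. Nested prefixes share
draws (common random numbers), the standard and lower-variance form of
this diagnostic. For the default child-Cr HI model all tracked statistics
differ by well under 2% between 10,000 and 15,000 iterations, which is why
10,000 is the default iteration count.

# Sobol sensitivity analysis

`saltelli_sample()` builds the radial Saltelli design — base matrices A
and B plus the cross matrices $A_B^{(i)}$ and $B_A^{(i)}$, i.e.
$N(2D{+}2)$ model runs — from a Latin-hypercube uniform sample transformed
to the target marginals by inverse CDF. Estimators: Saltelli (2010) for
first-order, Jansen for total-order (both chosen for low estimator
variance), and the closed-pair formula for second-order. Outputs are
normalized by the base-block mean and SD before estimation, which makes
the indices exactly invariant under affine rescaling of the output.
Negative estimates near zero are reported as-is — clipping would hide
non-convergence. Confidence half-widths come from a row bootstrap
(100 resamples). The default base size is $N = 1024$ (a power of two;
other sizes warn). At that size, first-order estimates on the Ishigami
benchmark are within ±0.05 of the closed form, and the total-versus-first
order inequality $ST \ge S1$ holds up to an estimator-noise tolerance of
0.05; second-order estimates carry roughly twice that noise.
`rank_parameters()` applies the conventional $ST > 0.1$ cutoff.

# Source apportionment

Clustering operates on the *metals* (variables), not the samples: the
standardized columns are transposed and clustered with Euclidean distance
and Ward's minimum-variance linkage. Merge heights are on the `ward.D2`
scale, $\sqrt{2\,\Delta SS}$, which the tests pin to a brute-force
$O(n^3)$ Ward implementation. The automatic dendrogram cut follows the
largest fusion-coefficient increase, with a `k` override.

PCA is the eigendecomposition of the correlation matrix of the z-scored
data; components with eigenvalue > 1 are retained (Kaiser) and
varimax-rotated. Communalities are invariant under the rotation (tested to
1e-10), eigenvalues sum to the number of metals, and each loading column
is sign-flipped so its largest-magnitude entry is positive — resolving the
reflection indeterminacy deterministically. Loadings above 0.5 in absolute
value are read as strong associations, 0.3–0.5 as moderate. With only 20
samples and 8 metals, loadings are indicative rather than definitive;
the implementation warns when samples do not exceed variables.

# Synthetic site generator

`generate_site()` emulates a point-source-contaminated site:

$$C_i = \big[b + A\,e^{-d_i/\lambda}\big]\,e^{\varepsilon_i},
\qquad \varepsilon_i \sim N(0, \sigma^2),$$

with $d_i$ the distance from the source. The noise is multiplicative
lognormal, guaranteeing positivity and reproducing the strong right skew
and leptokurtosis of smelter-impacted concentration data; with
$\sigma = 0$ concentration is non-increasing in distance (tested). The
default geometry is 20 samples on a 5 × 4 unit grid with the source at
the origin, a decay length of 2 grid units, background at the reference
site's per-metal minimum (a far-field proxy), half the
lognormal-equivalent of the site CV assigned to noise (the rest comes
from spatial decay), and the amplitude solved from the generator's
analytic mean so that $E[C]$ equals the reference mean. What the
generator does *not* emulate: spatial autocorrelation beyond the single
decay trend, correlated multi-metal noise, censoring at detection limits,
and analytical error structure — so passing tests demonstrate pipeline
correctness on realistic marginal distributions, not geostatistical
fidelity.

`moment_match()` complements it for exact reproduction tasks: interior
points are drawn uniformly, the extremes pinned, and the interior
affinely contracted toward the matched extreme so per-metal min, max and
mean equal the targets to floating-point accuracy. Only those three
statistics are matched; matching SD or skewness simultaneously would
over-constrain a 20-point sample. Pinning both extremes requires the mean
to lie within $[\min + (\max-\min)/n,\ \max - (\max-\min)/n]$; targets
outside that band error explicitly.

# Problem sizes and reproducibility

The test and acceptance workloads use 20-sample sites, 10,000–15,000
Monte Carlo iterations, Sobol base size 1024 (8 parameters → 18,432 model
evaluations), and 1000 random small instances for the Ward oracle — sizes
chosen to match the study design the defaults emulate while keeping the
whole suite fast on a laptop. Every stochastic stage takes an explicit
seed; the pipeline's `run_all()` writes bit-identical outputs for
identical configurations, echoes its configuration verbatim, and logs
every registry value and derived seed used.

# Known limitations

- Only soil pathways: no dietary, water or crop-uptake exposure, so risk
  totals are conservative lower bounds on multi-pathway exposure.
- Two fixed receptors; no age-integrated lifetime risk.
- No geostatistical simulation or interpolation — 20 widely spaced samples
  cannot support variogram modelling.
- Registry defaults are conventions, not site measurements; absolute risk
  magnitudes inherit their uncertainty.
- No receptor-model source apportionment (PMF/UNMIX) or isotopic
  confirmation; the multivariate stage is exploratory.
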