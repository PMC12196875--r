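---
title: "Methods: probabilistic odor-risk screening for VOC-contaminated waste excavation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic odor-risk screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odorisk)
```

## The problem

Emergency excavation of illegally dumped waste contaminated with volatile
organic compounds (VOCs) disturbs the waste's pore space and releases its
pore-gas VOC inventory to ambient air. For the aromatic solvents typically
involved — ethylbenzene, toluene, styrene, m/p-xylene — the solid-phase
contents are usually *below* soil health screening values, yet the same
pore gas can exceed olfactory thresholds by two to three orders of
magnitude. The operational question is therefore not toxicological but
sensory: how strong an odor will residents downwind perceive, with what
probability will it cross the nuisance criterion, and how large a buffer
distance (or how calm a weather window) keeps that probability acceptable.

`odorisk` implements the screening chain
*source partitioning → excavation emission → Gaussian plume transport →
odor perception → Monte Carlo exceedance analysis* as composable,
seed-reproducible functions.

## Model chain and assumptions

### Three-phase source partitioning

Pore-gas concentration follows linear equilibrium partitioning among the
sorbed, dissolved and vapor phases, the same model vapor-intrusion
guidance uses:

$$C_{air} = \frac{C_s\,H\,\rho}{\theta_w + \rho\,K_{oc}\,f_{oc} + H\,\theta_{air}}$$

As customarily printed (with $\rho$ in g/cm³, $K_{oc}$ in cm³/g, $f_{oc}$
in g/kg) this expression is not dimensionally closed, so the package
normalizes to SI at load time — $\rho$ in kg/m³, $K_{oc}$ in m³/kg,
$f_{oc}$ in kg/kg — and $C_{air}$ emerges in mg/m³ from $C_s$ in mg/kg.
Each conversion happens exactly once, in the constructors
(`pollutant_properties()`, `waste_matrix()`), which also makes the
analytic limit $\theta_w = f_{oc} = 0 \Rightarrow C_{air} = C_s\rho/\theta_{air}$
(Henry constant cancelling) hold exactly. Assumptions: full reversible
equilibrium, instantaneous balance, no competitive sorption between
pollutants, no temperature dependence.

### Excavation emission

The source term is deliberately conservative: every excavated pore volume
is assumed to release its entire pore-gas inventory,

$$ER = V\,N\,\theta_{air}\,C_{air},$$

with the dig rate $V$ converted from m³/h to m³/s. The default
$V = 150$ m³/h is a typical single-excavator rate; $N$ defaults to 1.
There is no kinetic (diffusion-limited) volatilization model; `odorisk`
is a screening tool and the conservative flux is the point.

### Gaussian plume transport

Transport to a downwind receptor uses the ground-reflecting Gaussian
plume for a continuous point source:

$$EPC = \frac{ER}{2\pi U \sigma_y \sigma_z}
  \exp\!\left(-\frac{y^2}{2\sigma_y^2}\right)
  \left[\exp\!\left(-\frac{(z-h)^2}{2\sigma_z^2}\right) +
        \exp\!\left(-\frac{(z+h)^2}{2\sigma_z^2}\right)\right]$$

with spread power laws $\sigma_y = \gamma_1 x^{\alpha_1}$,
$\sigma_z = \gamma_2 x^{\alpha_2}$ per Pasquill stability class (A very
unstable … F stable). Geometry convention: the excavation face is treated
as a ground-level release ($h = 0$ by default) and receptors are
evaluated at breathing-zone height $z = 1.5$ m. The vertical-term symbols
are sometimes used ambiguously in screening guidance (receptor height vs.
release height); `receptor()` exposes both fields so either reading is
configurable, and the ground-release default makes the reflection term a
clean factor of 2 at grade. Receptors upwind of the source are rejected
rather than silently returned as zero. The areal extent of the pit is not
modeled (no virtual-source correction), and there is no plume rise,
deposition, or building downwash.

**Dispersion coefficient table.** The class-specific regression constants
belong to a national standard whose tables are not redistributable here.
The packaged default (`inst/extdata/dispersion_briggs_fit.yaml`) is a
clearly-labelled synthetic stand-in: log-log least-squares power-law fits
to the published Briggs open-country curves, one regime over 10–1000 m
and one over 1000–10 000 m with the far coefficient chosen so the two
curves meet exactly at 1000 m. Within the 20–250 m screening band the fit
deviates from the Briggs curves by at most ~5 % (class D $\sigma_z$;
under 1.1 % elsewhere). The table preserves the physical ordering —
$\sigma$ decreasing monotonically from class A to class F at fixed
distance — and users holding an exact standard table can substitute their
own file (`load_dispersion_table()`).

Mass conservation is checked numerically: `crosswind_integrated_flux()`
integrates $U \cdot EPC$ over the crosswind plane by nested adaptive
quadrature (relative tolerance $10^{-8}$) and the test-suite requires
flux/ER within 0.1 % for every class at 50, 100 and 250 m.

### Odor perception

Odor activity value, total odor activity (used as the model's odor
concentration, i.e. dilutions-to-threshold), and Weber–Fechner intensity:

$$OAV_i = C_i / CT_i,\qquad OAV = \textstyle\sum_i OAV_i,\qquad
  OI_i = k_i \log_{10} OAV_i + B_i$$

The six-level intensity scale (0 none, 1 slight, 2 weak, 3 noticeable,
4 strong, 5 unbearable) is reported as `clamp(floor(OI + 0.5), 0, 5)`
with the continuous value preserved alongside; **all exceedance tests use
the continuous value**. Negative intensities are legitimate (a source
just below threshold) and are never floored. `odor_intensity()` treats
$OAV \le 0$ as a domain error; the Monte Carlo layer instead maps
zero-OAV draws to a $-\infty$ sentinel counted below every level.

The hazard screening indices are plain ratios with deliberately different
numerators: health PHI compares mean *solid-phase* content to the soil
screening value; odor PHI compares mean *pore-gas* concentration to the
olfactory threshold. Their quotient is independent of the source content
— it depends only on partitioning constants and the two limits — which
is why odor PHIs sit orders of magnitude above health PHIs for these
compounds.

## Parameters and defaults

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| Henry constant $H$ | – | per pollutant (e.g. 0.272 toluene) | standard 25 °C literature values; overridable in the registry YAML |
| $K_{oc}$ | cm³/g in, m³/kg stored | 234–446 | literature values |
| Olfactory threshold $CT$ | mg/m³ | 0.085 / 0.403 / 0.158 / 0.431 (ET/TO/ST/M,p-X) | triangle odor-bag method compilations |
| Weber–Fechner $k$, $B$ | – | $k$ 1.25–1.40, $B = 1$ | see below |
| Screening value | mg/kg | 28 (ethylbenzene) etc. | first-category soil screening values |
| $\rho$, $\theta_w$, $\theta_{air}$, $f_{oc}$ | g/cm³, –, –, g/kg | 1.5, 0.2, 0.3, 10 | plausible compacted mixed waste; synthetic fixture values, flagged assumed |
| $V$, $N$ | m³/h, – | 150, 1 | typical single excavator |
| receptor height | m | 1.5 | breathing zone |
| wind per class | m/s | uniform: A [1, 2.5], B [1.5, 3], C [2, 5], D [2.5, 6], E [2, 4], F [1, 2.5] | occurrence conditions of the Pasquill scheme |

**Weber–Fechner coefficients.** Published $k_i$, $B_i$ pairs for these
compounds vary by panel and study, and the reported intensity ranges do
not pin them down uniquely. The packaged defaults are chosen once, on two
physical anchors: $B = 1$ places intensity exactly at Level 1 ("slight
perception") when the concentration equals the olfactory threshold
($OAV = 1$) — consistent with how the threshold is defined — and the
slopes (ET 1.35, TO 1.38, ST 1.25, M/p-X 1.40 per decade) lie in the
range reported for single aromatic odorants. They are shipped as
registry-file entries flagged literature-informed and user-overridable;
no constant is hard-coded outside the registry.

## Uncertainty propagation

`run_monte_carlo()` draws a parameter vector per iteration and pushes it
through the full chain. Defaults: $n = 10\,000$ iterations, seed 0
(always recorded in the result and report metadata), with the solid-phase
content $C_s$ (lognormal, fitted to the sample table by
`fit_lognormal()`) and the wind speed (class-conditional uniform) random.
Stability is fixed per run for class sweeps, or drawn from a discrete
frequency table for pooled-meteorology runs — the pooled mode is this
package's interpretation of mixed-condition cumulative-frequency curves,
and is flagged as such. $\theta_{air}$, $\theta_w$ and $f_{oc}$ can be
randomized the same way when distributions are supplied.

Numerical conventions, stated because they are exactly the places where
two implementations of the same model disagree:

* **Percentiles** use linear interpolation between order statistics
  (R's `type = 7`), so the median of samples $1..100$ is 50.5 and printed
  median-to-95th ratios are reproducible.
* **Exceedance** uses strict inequality, $P(OI > L)$; ties are
  measure-zero under continuous inputs.
* The single-number reporting concentration is the **95th percentile** of
  the simulated distribution (the empirical upper bound of the 95 %
  band), not a parametric UCL95 — medians understate and maxima
  overstate episodic odor risk.
* **Seeding**: `set.seed(seed)` once per run, caller RNG state restored
  afterwards; draws occur in a fixed documented order so identical
  seed + config is bit-identical. No hidden entropy anywhere in the
  pipeline.
* With only $C_s$ lognormal, $OI$ is exactly normal (affine in
  $\log_{10} C_s$); the test-suite exploits this closed-form pushforward
  as an oracle for exceedance probabilities and percentiles at
  $n = 10\,000$.

### Buffer distance

`buffer_distance()` returns the smallest setback at which
$P(OI > L) \le p_{max}$ *at that distance and everywhere beyond it*. The
tail qualifier matters: for stable classes and a breathing-zone receptor
the exceedance curve can rise before it decays (the thin near-field plume
passes below 1.5 m), so "first distance that qualifies" would pick a
point inside the near-field shadow that protects nobody farther out. A
coarse log-spaced scan brackets the last criterion crossing and bisection
refines it to 1 m. Every evaluation reuses the same seed (common random
numbers), making the estimated curve deterministic and the search
well-posed.

## The synthetic site generator

No site measurements are distributable, so `synthetic_data` generates
them: `generate_waste_samples()` draws independent lognormal solid-phase
contents per pollutant (lognormality is the standard model for
right-skewed environmental concentration data, and is an assumption here,
not a measured fact), and `generate_meteo_set()` draws
(stability, wind) pairs from a frequency table with class-conditional
uniform winds. `make_case_study_scenario()` packages a complete
demonstration site: 100 samples, four pollutants, ethylbenzene arithmetic
mean 18 mg/kg (`meanlog` is offset by $\sigma^2/2$ so the *arithmetic*
mean is exact), the other three set so the odor-PHI ranking is
toluene > m/p-xylene > styrene > ethylbenzene, log-sd 0.5 throughout,
receptor distances 20–250 m, and a class A–F sweep. These are fixture
choices, not ground truth, and the bundle is labelled synthetic.

What passing tests on this fixture do and do not show: they demonstrate
the *chain's* correctness (arithmetic, conservation, distributional
pushforward, orderings, determinism) and the *qualitative* risk structure
— intensity decaying with distance, exceedance growing from class A to F,
heavy right tails. They do not validate the absolute intensities for any
real site, which hinge on unpublished waste properties, local
meteorology, and panel-specific Weber–Fechner coefficients. Real data
features the generator deliberately omits: spatial correlation between
samples, censored non-detects, multi-day excavation scheduling.

## Problem sizes

The default Monte Carlo size is 10 000 iterations; the packaged test
suite runs the full-chain checks at that size and the faster structural
checks at a few hundred iterations, which together keep a complete run in
the seconds-to-a-minute range on a single core. The conservation
quadrature uses adaptive integration and is exact to well below the 0.1 %
assertion everywhere in the 20–250 m band.

## Known limitations

* Screening-tier physics only: equilibrium source, point-source plume,
  no near-field building effects; results beyond ~10 km or inside ~10 m
  are outside the dispersion table's validity and are refused, not
  extrapolated.
* The default dispersion table is a documented approximation (fits to
  Briggs curves), not the national-standard regression table.
* Weber–Fechner coefficients dominate absolute intensity levels and are
  panel-specific; treat shipped defaults as placeholders to override
  with local olfactometry when available.
* Odor concentration is reported as total OAV (dilutions-to-threshold
  equivalence assumed), without mixture interactions beyond summation.
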