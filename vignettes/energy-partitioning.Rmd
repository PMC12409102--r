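---
title: "Partitioning the fates of absorbed photons in forest canopies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning the fates of absorbed photons in forest canopies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafquanta)
```

## The measurement model

Steady-state pulse-amplitude-modulated (PAM) fluorometry resolves three
relative fluorescence levels on an illuminated leaf: the steady state Fs,
the maximum Fm′ during a saturation pulse, and the minimum Fo′ after
far-red re-oxidation of the primary quinone acceptor. Under the lake model
of connected PSII antennae these determine how absorbed photons are
partitioned among photochemistry (ΦPSII), regulated heat dissipation
(ΦNPQ) and nonregulated losses (ΦNO — basal heat plus the fluorescence
re-emission that passive SIF instruments observe):

$$\mathrm{NPQ_t} = \frac{4.88}{F_m'/F_o' - 1} - 1, \qquad
  q_L = \frac{F_m' - F_s}{F_m' - F_o'}\cdot\frac{F_o'}{F_s},$$

$$\Phi_{NO} = \frac{1}{1 + 4.88\,q_L + \mathrm{NPQ_t}}, \qquad
  \Phi_{PSII} = \frac{F_m' - F_s}{F_m'}, \qquad
  \Phi_{NPQ} = 1 - \Phi_{PSII} - \Phi_{NO}.$$

Two conventions deserve comment, because the compact typography of the
NPQt and ΦNO expressions is easy to misread:

- the constant 4.88 encodes an assumed dark-adapted Fm/Fo of 5.88
  (Fv/Fm ≈ 0.83, an unstressed leaf). It is exposed as the `k_dark`
  argument throughout; every identity below holds for any positive value.
- ΦNO is the reciprocal of the *whole* sum `1 + 4.88 qL + NPQt`. This is
  the only parenthesization under which the dark-adapted state
  (qL = 1, NPQt = 0) satisfies ΦPSII + ΦNO = 1 exactly with ΦNPQ = 0,
  which pins the algebra down unambiguously.

Because ΦNPQ is defined by the unit-sum identity, the partition is exact by
construction; it is *not* a model check. What is checkable is positivity:
noisy raw measurements (chamber movement, insufficient foliage) produce
negative yields, and `qc_filter()` rejects those rows with a per-rule
ledger rather than clamping them — mirroring how field campaigns exclude
noisy observations. The sum rule only bites for externally supplied yields
(tolerance `1e-6`).

### The exact inverse as an oracle

`forward_fluorescence()` maps a regulatory state (qL, NPQt) back to
(Fs, Fm′, Fo′) under the normalization Fo = 1, Fm = 5.88, using
Fm′ = Fm/(1 + NPQt), the Oxborough–Baker relation
1/Fo′ = 1/Fo − 1/Fm + 1/Fm′, and the qL definition solved for Fs. The
forward/inverse round trip is exact to ~1e−14 over the whole state grid;
the test suite asserts ≤ 1e−10. The synthetic generator emits raw
fluorescence through this map, so the pipeline is exercised end to end
from instrument-scale inputs.

VPD, when not supplied, is derived from air temperature and relative
humidity with the Tetens saturation pressure
`0.61078 exp(17.27 T / (T + 237.3))` kPa — the standard closed form; the
function is documented and swappable.

## The synthetic campaign generator

The generator is first-class, tested code: its defaults define the study
conditions under which the pipeline's recovery properties are judged.

**Design.** Two seasons (wet, dry); three height strata (tree tops drawn
in 8–19 m, 22–38 m, 41–50 m); 25 trees per stratum; three crown positions
per tree at 55/75/95 % of tree height; five leaves per branch — 1125
records per season, comparable to a real multi-campaign deposit. Species
pools of 14 (wet) and 18 (dry) with lognormal random effects on NPQt
(sd 0.15 / 0.25): the dry season carries the larger interspecific variance,
so the species share of ΦNO variance is biggest there.

**Microenvironment.** Mean PAR follows Beer–Lambert extinction
(k = 0.55 per LAI unit) of the top-of-canopy irradiance through a
two-layer leaf-area profile (LAI 4 below 20 m, 3 in the 25–45 m crown),
with unit-mean lognormal sunfleck noise (σ = 0.35). VPD and temperature
rise linearly with height (0.8 → 2.4 kPa wet, 0.8 → 3.2 kPa dry;
26 → 31 °C) with Gaussian scatter. The VPD scatter (sd 0.6 kPa) is
deliberately large: weather varies independently of where a leaf sits, and
without it VPD would be a near-deterministic function of height and the
three regression predictors would be unusably collinear — with it, VIFs
sit in the 2–4 range, dominated by the physically unavoidable PAR–height
coupling.

**Physiology.** The regulatory state responds to light and dryness as

$$E[\mathrm{NPQ_t}] = \mathrm{npq_{max}}\,
   \frac{\mathrm{PAR}^{3}}{300^{3} + \mathrm{PAR}^{3}}\,
   (1 + \beta_{\mathrm{vpd}}\,\mathrm{VPD})\, e^{s}, \qquad
  E[q_L] = 0.02 + \frac{0.98}{(1 + \mathrm{PAR}/120)^{0.5}},$$

with species effect *s* and lognormal biological noise. The seasons share
all physiology except four constants: `par_top` (550 wet — overcast,
diffuse light — vs 2200 dry), `npq_max` (6.5 wet vs 2.4 dry),
`beta_vpd` (0.05 vs 0.08) and the species sd. The *lower* dry-season NPQt
ceiling is the mechanistic heart of the stress phase: sustained dry-season
photoinhibition is represented as a reduced capacity for regulated
quenching, so at extreme PAR the saturated NPQt no longer compensates the
continuing qL decline and ΦNO rises again. Composing the noise-free curves
(`canopy_response_curve()`, `analytic_extrema()`) gives the generator's
ground truth: the dry ΦNO(PAR) curve rises to a maximum near
PAR ≈ 157 µmol m⁻² s⁻¹ (ΦPSII ≈ 0.71), falls to a minimum near 657
(ΦPSII ≈ 0.35), then rises — a triphasic ΦNO–ΦPSII relationship; the wet
season, capped at 550 µmol, never reaches its minimum and stays biphasic.
The phase-shift ΦPSII of ~0.71 sits at the upper end of the 0.6–0.76 span
reported for high-latitude forests; curve families that push it toward
0.55 make the high-PAR ΦNO rise an order of magnitude smaller than
realistic leaf-to-leaf noise, so the package trades that cosmetic match
for a recoverable third phase.

**Measurement noise and corruption.** Raw channels get a common lognormal
gain (sd 0.01) plus Fs-specific jitter (sd 0.004). Because every derived
quantity is a ratio, the common gain cancels exactly; jitter on the
Fm′/Fo′ ratio is available (`ratio_noise_sd`) but defaults to zero, since
it makes measured NPQt negative wherever the true value is near zero (deep
shade) and the quality-control rejections would then no longer coincide
with the deliberately corrupted rows — a seeded 5 % of rows whose Fs is
pushed above Fm′, which QC must (and does) identify exactly.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: leaf-age effects (mature leaves only), diurnal
hysteresis, spatially correlated sunflecks, instrument drift,
heteroscedastic sensor error, true radiative transfer within crowns, and
ratio-distorting channel noise under the defaults. Recovery rates measured
here are upper bounds for field conditions.

## Statistical components

**Strata and profiles.** Strata are half-open intervals [0, 20), [20, 40),
[40, ∞) m — the boundary heights go upward, a convention the source
descriptions leave open. Strata comparisons use Kruskal–Wallis followed by
pairwise Mann–Whitney tests; pairwise p-values are reported raw and
Holm-adjusted, and the compact letter display (insert-and-absorb
algorithm) is built on the adjusted values at α = 0.05. Vertical profiles
use 1-m bins with Student-t confidence intervals (90 % default; undefined
for single-record bins). Lower-to-upper canopy changes in yields are
expressed in percentage points, `100·(mean_S3 − mean_S1)` — the natural
scale for quantities that are themselves fractions.

**Mixed models.** `fit_lmm()` standardizes predictors (not the response),
so coefficients are comparable across predictors; significance is a Wald
95 % CI excluding zero. The family is Gaussian on the yield scale — the
choice that makes variance-component R² well-defined; a beta-likelihood
alternative is available through `fit_gamm(..., k = 5)`'s machinery for
users who prefer a bounded likelihood. `r2_nakagawa()` computes
marginal = Vf/(Vf+Vr+Ve) and conditional = (Vf+Vr)/(Vf+Vr+Ve) from the
fitted variance components (no small-sample adjustment); their difference
is the species share. Singular random-effect fits fall back to fixed
effects with a warning rather than reporting a degenerate component.

**Additive models.** `fit_gamm()` uses a beta likelihood with logit link,
cubic regression splines with basis dimension k = 5 per smooth, one smooth
per season per covariate, a parametric season term, a ridge-penalized
species random intercept, and maximum-likelihood smoothness selection.
Boundary responses are squeezed by `(y(n−1)+0.5)/n` with a warning.
Seasonal differences (`smooth_difference()`) are computed on the link
scale through prediction-matrix contrasts: the contrast keeps the selected
term's seasonal smooths and the parametric season effect (a level shift
between seasons is part of the seasonal contrast) and zeroes the species
columns; CI = ±1.96 SE. Hierarchical partitioning refits all 2^p predictor
subsets and averages marginal deviance contributions over orderings;
negative averaged shares are floored at zero and renormalized (logged), so
shares always sum to the full model's explained deviance. p ≤ 4 keeps the
2^p fits tractable.

**Phase analysis.** ΦNO is smoothed on ΦPSII with two knot policies —
restricted (k = 5) and unrestricted (k = 20) — compared by AIC (the
unrestricted policy wins on campaign-scale data here, matching how such
analyses typically resolve). Derivatives are central finite differences on
a 1000-point grid spanning the 1st–99th percentile of observed ΦPSII; the
trim avoids the edge artifacts of penalized splines, and derivative
magnitudes below 1e−6 are treated as zero so plateaus do not generate
spurious crossings. A breakpoint is a sign change, located by linear
interpolation of the derivative's zero crossing; both directions are
reported, since the triphasic structure needs the rise-to-fall maximum
*and* the fall-to-rise minimum. Phases are labeled from segment slopes:
negative-slope segments above the NPQ-limited (positive-slope) region are
PQ-limited, below it stress. PAR at a breakpoint inverts the same season's
fitted monotone ΦPSII(PAR) smooth on a grid — regressing PAR on ΦPSII
would answer a different question — and uncertainties come from a seeded
200-replicate nonparametric bootstrap over records that refits both
smooths, since no analytic SE exists for the composed estimator.

## Numerical and testing choices

Test problem sizes are chosen to make sampling noise small relative to the
tolerances: 100×100 state grids for the exact round trip; 20 campaigns per
season for phase recovery (the dry stress upturn is subtle by
construction, and roughly one campaign in twenty draws species effects
that flatten it — the tests therefore require the stress phase in ≥ 18 of
20 and the phase-shift MAE ≤ 0.05); 200 replicates of n = 240 for CI
coverage; n = 5000 with 200 groups for variance-component recovery, where
the realized random-effect variance is within a few percent of its target.
`mgcv`'s ML smoothing on *pure-noise* responses can leave effective
degrees of freedom well above 1 while explaining essentially no deviance,
so degenerate-input tests assert trivial explained deviance and
near-affine predictions rather than edf ≈ 1 literally; exactly-constant
responses are intercept-only fits by construction.

## Limitations

The stress phase's ΦNO rise is small (≈ 0.01 absolute) even under the
favorable dry-season defaults, so its breakpoint carries an order of
magnitude more uncertainty than the phase shift — visible in the bootstrap
SEs — and its mapped PAR depends on inverting the extreme tail of the
light response, where the fitted curve is flattest. Campaign-level species
draws can occasionally mask the third phase entirely; this is a property
of the sampling design, not of the detector, and it is why the recovery
tests are framed as rates over many seeded campaigns. The mixed models
treat species as the only grouping factor (no tree- or branch-level
nesting), matching the intended analysis scale; within-branch
pseudoreplication therefore inflates nominal precision slightly on
generator data.
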