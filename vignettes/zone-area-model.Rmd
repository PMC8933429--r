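---
title: "Modelling the absolute area of ICROP Zone I in the growing preterm eye"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the absolute area of ICROP Zone I in the growing preterm eye}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ropzone)
```

## The problem

Retinopathy of prematurity (ROP) is staged by the zone of the retina the
disease reaches. Zone I, the most posterior zone, is defined as the circle
centred on the optic nerve whose radius is twice the nerve-to-fovea
distance — equivalently, the circle subtending a 30-degree visual angle at
the posterior nodal point of the eye. Because the preterm eye grows and
changes refractive power throughout the screening period, the *absolute*
retinal area corresponding to this angular definition is not constant.
`ropzone` quantifies that: it converts one eye's biometry into the absolute
Zone I area, and propagates literature growth curves of the biometric
parameters into age-resolved min/max area ranges.

## The schematic eye

The model is a paraxial two-element system. The cornea is a single thin
element of power $P_c$ (diopters) at the corneal vertex; the crystalline
lens is a symmetric thin element of power $P_l$ placed at
$d = \mathrm{ACD} + \mathrm{LT}/2$ mm from the vertex. Three media are
used: air ($n = 1.0000$) in front of the cornea, a combined cornea/aqueous
medium ($n = 1.3375$, the keratometric convention) between the elements,
and a combined lens/vitreous medium ($n' = 1.4000$) behind the lens. The
equivalent power is the Gullstrand combination

$$P_{eq} = P_c + P_l - \frac{d}{1000\,n}\,P_c P_l ,$$

and the image-side principal point and posterior nodal point sit at

$$z_{H'} = d\left(1 - \frac{n' P_c}{n\,P_{eq}}\right), \qquad
  z_{N'} = z_{H'} + \frac{1000\,(n' - 1)}{P_{eq}}$$

mm from the corneal vertex (positive toward the retina). The distance from
the nodal point to the back of the eye is $L = \mathrm{AL} - z_{N'}$, and

$$r = L \tan 30^\circ, \qquad A = \pi r^2, \qquad
  d_{nf} = r/2$$

give the Zone I radius, its area (planar approximation — retinal curvature
is ignored), and the implied nerve-to-fovea distance. The 30-degree figure
is the *half*-angle from the optical axis to the zone edge, not a full
cone, and is configurable through `zone_config()`.

```{r}
eye <- ocular_biometry(p_cornea = 53, acd = 2.4, p_lens = 43,
                       lt = 3.6, al = 15.5)
zone_metrics(eye)
```

### Verification by ray tracing

The closed-form cardinal-point algebra is cross-checked by an independent
code path, `ray_trace_nodal_point()`: a paraxial ray is traced surface by
surface (refraction $u' = u - P y$ on the reduced angle $u = n\theta$,
transfer $y' = y + t\theta$), the entrance height is solved so that the
exit angle equals the entrance angle — the defining property of the nodal
points — and the ray's axial crossing in image space is returned. The two
routes agree to well below $10^{-6}$ mm across the physiological range,
and by paraxial linearity the traced position is independent of the test
angle (asserted for $10^{-4}$ to $10^{-2}$ rad). Two analytic limits are
also enforced: with $P_l = 0$ and equal media indices $n$ the model
collapses to the reduced eye, $z_{N'} = 1000\,(n-1)/P_c$ exactly; and the
composed ray-transfer matrix is unimodular with its coupling entry equal
to $-P_{eq}$.

Degenerate inputs raise classed errors rather than returning negative
geometry: a non-positive equivalent power (`ropzone_error_nonconvergent`),
a nodal point at or behind the retina (`ropzone_error_degenerate_eye`),
or a lens placed outside the globe (`ropzone_error_invalid_geometry`).
The enumerator below counts such combinations instead of aborting.

## Growth curves

Each biometric parameter's dependence on postmenstrual age (PMA, weeks) is
represented as a per-study quadratic $v = a_0 + a_1 w + a_2 w^2$ with a
stated PMA domain; evaluation outside the domain is flagged as
extrapolation rather than refused. Raw (PMA, value) datasets are fitted by
ordinary least squares (`stats::lm`), with $R^2 = 1 - SS_{res}/SS_{tot}$
reported as `NA` — not 0 — when the response has no variance. For studies
that published their own equations, the $R^2$ is metadata carried through
unchanged, never recomputed, because the raw points behind it are not
available.

Two unit conversions used when assembling such curves are provided: the
keratometric conversion $P_c = 337.5/r$ from corneal radius of curvature,
and a phakic Hoffer Q back-calculation of crystalline lens power from
axial length, keratometry, anterior-segment geometry and (vertex-corrected)
refraction. The Hoffer Q constants — the 0.05 mm retinal-thickness term,
the 1.336/1336 index pair, and the 12 mm default vertex distance — follow
the published formula and are all exposed as arguments. A stepwise
vergence-propagation oracle in the test suite confirms the implementation
to 0.01 D.

## Combinatorial ranges

At a given PMA, each parameter has one candidate value per source curve.
`enumerate_zone_area_range()` evaluates the model on the full Cartesian
product of candidates — literally, not by optimisation; the grids are at
most a few hundred combinations — and reports the extreme areas together
with the combinations achieving them, the number of combinations, and the
number excluded as degenerate. Ties are broken by the first combination in
enumeration order (first parameter varying fastest), and the extremes are
invariant to candidate permutation. No physiological cross-filtering of
combinations is applied (a long eye may be paired with a steep cornea).

Two "how much can Zone I grow" summaries are built on top:

* `al_extremes_range(pma, al_min, al_max, other)` fixes AL at two observed
  extremes and enumerates the rest;
* `zone_area_expansion(curves, pma_from, pma_to)` compares two ages.

Both report a *maximum percent increase* whose pairing semantics were a
genuinely open design choice. The default, `method = "paired"`, holds the
other parameters (or source combination) identical across the pair and
maximizes the increase over those shared combinations — the most direct
reading of "up to X% larger". The alternative, `method = "pooled"`,
compares the largest area on one side with the smallest on the other and
is necessarily at least as large. Results below are from the built-in
fixtures.

```{r}
fx <- builtin_fixtures()
ext <- al_extremes_range(32, 14.20, 16.58, fx)
ext$max_percent_increase
zone_area_expansion(fx, 31, 38)$max_percent_increase
```

## The synthetic generator and fixtures

The generator emulates the statistical structure the fitter assumes: a
true quadratic trend in PMA plus i.i.d. Gaussian noise
(`generate_growth_dataset()`), and per-parameter truncated-Gaussian
dispersion around candidate midpoints for eye cohorts
(`generate_cohort()`). Everything is bit-reproducible from an integer
seed, and the caller's RNG stream is left untouched. What it does *not*
emulate: within-eye longitudinal correlation, correlations between
parameters (long eyes tend to have deeper chambers), non-Gaussian
measurement error, and cohort selection effects — so passing tests
demonstrate correctness of the machinery under the model's own
assumptions, not fidelity to any particular clinical cohort.

The built-in fixtures (`builtin_fixtures()`) are a complete five-parameter
curve set, clearly labelled `synthetic-*`, used whenever no user curve
table is supplied. Each curve is an exact quadratic through three control
points chosen to be physiologically plausible for PMA 25–50 weeks, with
source multiplicities mirroring the literature the model draws on (3
corneal-power, 3 ACD, 2 lens-power, 2 lens-thickness, 8 axial-length
curves; 288 combinations). Two published anchors pin the set down: the
lowest and highest AL curves pass exactly through 14.20 and 16.58 mm at
PMA 32 weeks, and the AL envelope at PMA 50 weeks is set so the pipeline's
Zone I radius range at that age brackets the published 6.40–7.89 mm while
staying inside a [6.0, 8.3] mm plausibility envelope. Given physiological
corneal and lens powers at PMA 50, bracketing a 7.89 mm radius forces the
long end of the AL envelope to roughly 20.7 mm — longer than typical
population means at that age; this is a property inherited from the anchor
itself ($r = 7.89$ mm requires $\mathrm{AL} - z_{N'} \approx 13.7$ mm).
The fixtures are honest synthetics anchored to printed values; they are
*not* the source publications' fitted coefficient tables, and
quantitative results obtained from them (e.g. the ~69% maximum increase
at PMA 32 above) should be read as fixture-conditional. Supplying the real
coefficient tables as a `curves.csv` (see `read_curves_csv()`) switches
the entire pipeline to exact-reproduction mode.

## Numerical choices

* Lengths are mm externally and converted to meters only where multiplied
  by diopters; powers are diopters throughout.
* Areas and lengths are rounded (integer mm², 2 dp) only in `*_display`
  columns at the presentation layer; all returned values are full
  precision.
* The ray-trace solve is a two-point linear solve (exit angle is affine in
  entrance height), so it has no iteration tolerance.
* Quadratic fitting uses `stats::lm` on raw polynomial terms; an
  independent normal-equations solve in the tests agrees to $10^{-8}$.
* Cohort draws are truncated to the candidate hull widened by two standard
  deviations, with a bounded redraw loop (default 100 retries) guarding
  the biometry invariants.

## Problem sizes

The shipped test-suite settings are: 1000 random eyes for the
ray-trace/closed-form comparison, 100 random grids of up to 3 candidates
per parameter for the enumeration oracle, 100 replicates of $n = 200$
noisy observations for the coefficient-recovery rate, and 200 replicates
of $n = 50$ for the $R^2$ comparison. These sizes make the sampling
properties being asserted (e.g. the $\ge 93\%$ 3-standard-error coverage
implied by OLS theory) stable without being wasteful.

## Limitations

* The planar $\pi r^2$ area ignores retinal surface curvature and the
  growth of the pars plana; both would lower the retinal-surface area
  fraction represented by a fixed visual angle at later ages.
* The two-element paraxial model has no astigmatism, no thick-lens
  structure and no accommodation; it is a Gaussian-optics estimate.
* Average fit quality across the literature datasets and age-specific
  percent differences that depend on unpublished per-age extremes cannot
  be recomputed here; they would require the original raw datasets.
* Absolute areas from the fixtures are fixture-conditional (see above);
  only the anchored quantities carry over exactly.
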