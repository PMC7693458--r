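---
title: "Modelling intrafloral colour patterns through bee vision: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intrafloral colour patterns through bee vision: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexflora)
```

hexflora analyses how colour is organised *within* a flower as a bee sees
it. Its pipeline takes reflectance spectra of floral patches (tip and base
of sepals, petals and the labellum, measured on many plant individuals),
maps them through a trichromatic bee visual system into the hexagon colour
space, extracts hue, spectral purity and chromatic contrast per patch,
quantifies among-individual colour distances, and tests whether patches
form intrafloral colour modules — sets of patches whose colours covary
among individuals more with each other than with the rest of the flower.
This vignette explains the models, the tunable parameters, the numerical
choices, and what the simulation-based tests do and do not establish.

## The colour vision model

For receptor class $i \in \{\mathrm{UV}, \mathrm{blue}, \mathrm{green}\}$
with spectral sensitivity $S_i(\lambda)$, stimulus reflectance
$I_S(\lambda)$, adaptation background $I_B(\lambda)$ and illuminant
$D(\lambda)$, the package computes

$$Q_i = \int I_S(\lambda)\, S_i(\lambda)\, D(\lambda)\, d\lambda, \qquad
  P_i = \frac{Q_i}{\int I_B(\lambda) S_i(\lambda) D(\lambda)\, d\lambda},
  \qquad E_i = \frac{P_i}{P_i + 1}.$$

$P_i$ is the quantum catch after von Kries adaptation to the background
(so the background gives $P_i = 1$ in every receptor) and $E_i \in [0, 1)$
is the bounded receptor excitation, which equals $0.5$ at the adapting
background. The hexagon chromaticity coordinates are

$$x = \frac{\sqrt{3}}{2}\,(E_{\mathrm{green}} - E_{\mathrm{UV}}), \qquad
  y = E_{\mathrm{blue}} - \tfrac{1}{2}(E_{\mathrm{UV}} + E_{\mathrm{green}}),$$

placing the background at the origin and pure single-receptor excitation
at unit-radius vertices. The model is noise-free by construction; no
receptor noise term or discrimination threshold is modelled anywhere.

Integrals use the trapezoid rule on the working grid, 300–700 nm at 1 nm
(the bee-visible range; receptor sensitivity is negligible outside it).
The 1 nm trapezoid agrees with a 0.1 nm Riemann sum to better than
$10^{-3}$ in every excitation for smooth spectra, which is far below any
quantity interpreted downstream.

The axis convention above (green–UV difference on $x$) is one of several
in use. Hue *angles* depend on it; Euclidean and angular *distances*, and
spectral purity, do not. A `rotation_deg` option on `hexagon_coords()`,
`build_spectrum_locus()` and the pipeline lets users match any other
published orientation; purity is invariant under that rotation and hue
shifts by exactly the rotation angle (this is a tested property).

### Packaged curves and their provenance

* **Illuminant** — the CIE standard daylight D65 relative spectral power
  distribution, from a packaged 10 nm table (300–700 nm), interpolated to
  the working grid and normalised to 100 at 560 nm.
* **Background** — a *parametric* green-foliage reflectance,
  $R(\lambda) = 0.04 + 0.10\,e^{-((\lambda-550)/40)^2} +
  0.05/(1+e^{-(\lambda-680)/12})$: low UV/blue, green peak near 550 nm,
  moderate far-red rise. It is a documented stand-in for a measured leaf
  standard, not a claim to match any particular leaf; supply your own
  background spectrum to `viewing_context()` when you have one.
* **Receptor sensitivities** — the A1 visual-pigment alpha-band template
  of Govardovskii et al. (2000), parameterised by peak wavelength, with
  defaults 328, 428 and 536 nm following measured *Bombus terrestris*
  sensitivities. The curve is shifted by under 1.5 nm so its maximum sits
  exactly at the stated peak, and an optional beta-band is available
  (off by default). Users can override the peaks or supply measured
  sensitivity curves.

## Colour descriptors

*Chromatic contrast* is the Euclidean distance of a locus from the origin
(hexagon units): the model's proxy for detectability against the
background. *Hue* is the angle of the locus, counterclockwise from the
positive $x$-axis, in $[0, 360)$; loci within $10^{-9}$ of the origin
have undefined hue, are flagged, and are excluded from circular
statistics with a logged count. *Spectral purity* is the radius of the
locus divided by the radius of the spectrum-locus boundary along the same
hue ray — 0 at the background, 1 for maximally saturated stimuli.

### The spectrum locus and the purity denominator

In this nonlinear colour space the position of a monochromatic light
depends on its intensity: excitation saturates, so each wavelength traces
a curve from the origin out and back as intensity grows. The boundary
relevant to purity is the *maximal* saturation attainable at each hue, so
each locus vertex is computed at the intensity that maximises its radius
(a one-dimensional optimisation per wavelength). The vertices for
monochromatic stimuli from 300 to 700 nm (step configurable, default
1 nm) are joined in wavelength order and closed by the purple line
between the two spectral endpoints. The purity of a colour locus is then
`radius(locus) / radius(first boundary crossing of its hue ray)`, by
segment–ray intersection, clamped to $[0, 1]$ with clamp events counted
(none are expected, and none occur, for smooth reflectances).

Two geometric facts about this boundary are worth knowing. First, at both
spectral ends essentially a single receptor class responds, so the end
vertices bunch at nearly constant hue and the polygon is locally
multivalued in hue; purity there is measured against the nearest
crossing. Second, because the two end hues are nearly antipodal, the
purple line passes close to the origin; loci whose hue ray meets the
purple line get purity relative to that segment. The exact
"half the boundary radius gives purity one half" identity therefore holds
on the monotone 380–540 nm stretch of the boundary, which is where the
test suite asserts it; floral loci from the packaged generator (hues near
100° and 340°) sit away from the folded end regions.

## Distances among individuals

Within each of the six patches, every unordered pair of plants
contributes one record: the Euclidean distance between loci (a proxy for
chromatic contrast between two individuals' patches) and the angular
distance (their hue difference, the shortest arc in $[0, 180]$ degrees).
Thirty complete plants give $\binom{30}{2} = 435$ records per patch,
2610 in all. Plants missing any patch are dropped with a warning rather
than silently imputed; cross-patch distances are not part of any
statistic but are available through the API.

## Inferential statistics

**Purity model.** Spectral purity is analysed with floral structure
(sepal/petal/labellum), measurement position (tip/base) and their
interaction as explanatory terms and plant identity as a block: a
randomized-complete-block ANOVA. For this balanced design (every plant
measured once per patch) the resulting F tests are *exactly* those of the
corresponding random-intercept mixed model — an equivalence the test
suite verifies against both an explicit sums-of-squares oracle and an
independent REML fit — so no mixed-model machinery is used, and the
function refuses unbalanced layouts instead of approximating. Post hoc
comparisons are paired t tests between all 15 patch pairs with
Benjamini–Hochberg step-up control at level 0.05 and a compact-letter
display.

**Distance model.** The square root of the Euclidean distance is the
response (a variance-stabilising choice for nonnegative distances), with
the plant pair as block and the same fixed terms; patch means are
back-transformed (squared) for reporting on the hexagon-unit scale.

**Circular statistics.** Hue is compared among patches with the
Watson–Williams one-way test: the high-concentration F statistic with
the $1 + 3/(8\hat\kappa)$ correction, $\hat\kappa$ estimated from the
pooled mean resultant length. A warning is issued when
$\hat\kappa < 1$, where the approximation degrades, and a group with
vanishing resultant is an error (its mean direction is undefined). The
one-way layout cannot accommodate a structure-by-position interaction, so
the six patches enter as a single factor. Post hoc homogeneity uses
Watson's two-sample $U^2$ on the pooled circular empirical CDFs
(tie-aware, origin-invariant), with a seeded random-permutation null
(default 10000 permutations) instead of critical-value tables: published
tables do not resolve the conservative 0.001 level used when many
uncorrected pairwise comparisons are made. Angles are degrees at every
interface and radians internally.

## The covariance-ratio modularity test

The module hypothesis is evaluated on the plants-by-18 matrix of
photoreceptor excitations (6 patches × 3 receptors), each column
z-scored ("normalized" here means per-variable standardisation; a
per-flower simplex normalisation would be an alternative reading, not
implemented). Excitations rather than $(x, y)$ coordinates carry the
test because they are the receptor-level quantities with direct
physiological meaning.

For modules $A, B$ with between-module covariance block $S_{AB}$ and
within-module blocks $\tilde S_{AA}, \tilde S_{BB}$ (diagonals zeroed),

$$CR_{AB} = \sqrt{\frac{\operatorname{tr}(S_{AB} S_{BA})}
  {\sqrt{\operatorname{tr}(\tilde S_{AA}\tilde S_{AA})\,
         \operatorname{tr}(\tilde S_{BB}\tilde S_{BB})}}},$$

and the overall CR for three modules is the mean over the three pairs.
CR near 0 indicates modularity; values near or above 1 indicate
among-module covariation comparable to within-module covariation. The
implementation is verified to $10^{-10}$ against an independent
brute-force covariance-summation oracle and against the closed form
$CR = \sqrt{2}$ for two modules of perfectly correlated variable copies.

**Permutation null.** Significance is the add-one-corrected proportion of
permuted-assignment CR values at or below the observed one
($p = (\#\{CR^* \le CR\} + 1)/(n_{perm}+1)$; "at or below" with add-one
is conservative and avoids zero p-values). Two permutation units are
provided, and the choice matters:

* **Variable-level** (default): the 18 columns are reassigned to modules
  of sizes 12/3/3. This gives fine-grained p-values (a patch-level scheme
  admits only $\binom{6}{4} \cdot 2 = 30$ distinct assignments and can
  never report $p < 0.001$). Its null requires the *columns* to be
  exchangeable.
* **Patch-level** (`unit = "patch"`): whole patches are reassigned. For
  spectra-derived excitations the three receptors of one patch respond
  jointly to any change of that patch's spectrum and are therefore
  strongly mutually correlated *whatever* the among-patch structure; the
  columns are never exchangeable, and variable-level permutation rejects
  far above nominal even on data with no among-patch covariance at all.
  The patch is the exchangeable unit for such data, and the patch-level
  test holds its nominal size on the package's non-modular generator (a
  tested property), at the price of p-value granularity of about 1/30.

The practical reading: use the variable-level p-value to rank and report
fine significance when the module hypothesis is strongly supported, and
confirm with the patch-level p-value, which is the one with a guaranteed
type-I interpretation for spectra data. The test suite calibrates
variable-level permutation on matrices of independent columns (where its
null premise holds) and patch-level permutation on the spectra-based
non-modular generator.

**Bootstrap interval.** The 95% interval is the 2.5%/97.5% percentile
range of CR over resamples of plants with replacement. Resampling rows
with replacement duplicates plants, which inflates apparent among-module
covariance, so the bootstrap CR distribution sits visibly above the point
estimate: expect a right-shifted interval whose lower bound the point
estimate hugs. The interval is best read as a stability range for CR
under plant resampling, not as a bias-corrected confidence set.

## The synthetic-data generator

Raw reflectance data for the motivating system are available only on
request, so the package ships a generator whose defaults emulate the
study conditions: 30 plants × 6 patches (180 spectra), pink
sepals/petals reflecting in blue (Gaussian band near 440 nm) and red
(sigmoidal rise near 620 nm), a more saturated labellum tip with its
band shifted toward UV-blue (425 nm), and a yellow UV-absorbing labellum
base (reflectance below 0.10 under 400 nm, sigmoidal rise near 520 nm).

Among-plant variation is built from:

* one latent amplitude factor per module and plant (SD 0.10) shared by
  all patches of that module — a mechanistic stand-in for module-specific
  pigment regulation;
* an independent per-patch amplitude perturbation (SD 0.05, half the
  module SD, so within-module covariation dominates);
* per-patch hue jitter as band-centre shifts (SD 8 nm for sepals and
  petals, 2 nm labellum tip, 1.5 nm labellum base — the labellum base is
  the most hue-constrained patch, as in the motivating system);
* iid measurement noise per wavelength (SD 0.004, Gaussian), with
  negative values clipped at zero and counted.

The planted module assignment is sepals+petals / labellum tip / labellum
base. The matched null generator draws one *independent* factor per patch
with total SD $\sqrt{0.10^2 + 0.05^2}$, keeping every marginal
distribution while removing all among-patch covariance. Both generators
are byte-deterministic under a seed.

These defaults were chosen once, to produce purity in the range the
motivating study reports (roughly 0.25–0.47 with the labellum tip
highest), hue sectors on the correct sides of the hexagon (blue for the
pink patches, blue-green for the yellow labellum base), a
purity–contrast correlation around 0.9, and a clearly detectable planted
module structure, and then frozen. On these defaults the pipeline's CR
test detects the planted structure in essentially every replicate, and
the observed CR and its bootstrap interval on a default run (about 0.44,
interval 0.43–0.78) sit in the same region the motivating study reports
for real flowers — a consistency check, not a reproduction of those
data-dependent numbers, which the spectra on request would be needed to
reproduce.

What the generator does *not* emulate: instrument-specific noise spectra
and smoothing of the raw spectrophotometer output, within-flower spatial
heterogeneity, correlated (non-iid) measurement error, pigment chemistry
beyond two additive band families, and any relationship between colour
and morphology. Passing simulation suites therefore demonstrates that the
statistical machinery is calibrated and powerful under the stated
covariance structure — not that real floral data satisfy that structure.

## Problem sizes and reproducibility

The simulation suites use 200 replicate datasets for the type-I and
power studies of the CR test (500 permutations each), 500 replicates for
the circular-test calibrations, and 200 replicates for the block-ANOVA
null-uniformity and power checks; these sizes put the binomial 95% band
for a nominal 0.05 rejection rate at roughly 0.02–0.09, which is the
band the suites assert. The full analysis defaults (10000 permutations,
1000 bootstrap resamples) run in seconds on one core. Every stochastic
step — generator, permutation, bootstrap, post hocs — takes a seed
derived from one root seed, restores the caller's RNG state, and
reproduces bit-identically under the same seed.

## Known limitations

* The hexagon model is noise-free; no receptor-noise-limited or
  discrimination-threshold modelling is provided, and equal Euclidean
  distances need not mean equal discriminability to real bees.
* Purity against the purple line and near the spectral ends depends on
  the documented nearest-crossing convention (see above).
* The block ANOVAs require complete balanced designs by design; there is
  no REML fallback for unbalanced data.
* The circular one-way test cannot represent a structure-by-position
  interaction; the Watson–Williams approximation assumes concentrated
  (roughly von Mises) samples.
* Variable-level CR permutation p-values on spectra data are
  anticonservative (see the modularity section); patch-level p-values
  are coarse. Both caveats are inherent to the permutation designs, not
  to this implementation.

## A minimal run

```{r example, eval = FALSE}
res <- run_pipeline(list(seed = 1, generator = list()))
res
# patch-level confirmation of the modularity test
M <- normalize_excitations(res$patch_table)
cr_permutation_test(M, default_module_assignment(),
                    n_perm = 2000, seed = 2, unit = "patch")
```
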