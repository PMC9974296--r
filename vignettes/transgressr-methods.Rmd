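---
title: "Methods: models, parameters and design choices in transgressr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in transgressr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transgressr)
```

transgressr asks a single scientific question along several independent axes:
is a focal individual a hybrid, and if so, is its phenotype *transgressive* —
outside the range spanned by its two parental species? The package was built
around iridescent gorget colour in *Heliodoxa* hummingbirds, where the
phenotype of interest is produced by a melanosome multilayer inside feather
barbules, but every stage is generic. This vignette documents the models, the
parameters that matter, and the places where the design was genuinely open.

## 1. Avian colour vision and the receptor-noise model

Reflectance spectra are reduced to cone quantum catches
$q_i = \int R(\lambda)\,C_i(\lambda)\,I(\lambda)\,d\lambda$, computed by the
trapezoid rule on a 1 nm grid (`quantumCatches()`, `step` tunable). The
default visual phenotype (`avianVisualSystem()`) is an ultraviolet-sensitive
tetrachromat with pigment templates peaking at 370/440/508/560 nm, generated
from a standard visual-pigment nomogram. These template curves stand in for
measured hummingbird sensitivities, which are not bundled; measured curves
can be supplied via the `sensitivity` argument or `readSensitivities()`.

Discriminability uses the receptor-noise limited model: with
$\Delta f_i = \ln(q_i^A/q_i^B)$ and channel noises
$e_i = \omega\sqrt{n_\mathrm{ref}/n_i}$, the distance $\Delta S$ (in
just-noticeable differences, JND) is the standard quadratic form over cone
pairs and triples. Defaults follow the conventional parameterisation: cone
density ratios 1:2:2:4, Weber fraction $\omega = 0.1$ on the most abundant
(l) cone, so $e = (0.2, 0.141, 0.141, 0.1)$. A distance of 1 JND is the
conventional discriminability threshold.

Two deliberately fixed conventions, since the upstream literature permits
either choice:

* **Illuminant**: flat ("ideal"), with no von Kries normalisation. Measured
  irradiance spectra can be passed via `illuminant`.
* **Group centroids in bootstrapping**: geometric means of catches
  (arithmetic means of log-catches), matching the log-scale at which the
  receptor-noise model operates. `bootstrapGroupDistance()` resamples
  specimens within groups, reports the bootstrap mean and 95% percentile
  interval, and flags divergence as significant when the CI lower bound
  exceeds 1 JND.

`noiseScaledCoords()` maps catches into 3-D coordinates in which Euclidean
distance equals $\Delta S$ exactly: log-catches are projected onto the
subspace orthogonal to $(1,1,1,1)$ (removing overall intensity) and
transformed by a Cholesky factor of the noise metric restricted to that
subspace. These JND-scaled coordinates are the input to the transgression
metrics and the rate analyses, so that all downstream distances are
perceptual. The tetrahedral convention of `tetraCoords()` puts the u vertex
at $(0,0,0.75)$ and the achromatic point at the origin; it is recorded so
coordinates are reproducible bit-for-bit.

## 2. Optical model of the feather multilayer

`simulateFeatherSpectrum()` treats a barbule cross-section as a 1-D stack:
keratin cortex, a surficial melanosome platelet, then alternating keratin
gaps and hollow melanin platelets over a semi-infinite keratin substrate.
Reflectance is computed per wavelength with the standard characteristic
(transfer) matrix method; at oblique incidence the unpolarised reflectance is
the mean of the s- and p-polarised values.

Geometric interpretation of the measured traits (all nm): `cortex`, `ker`
and `air` are used directly; the reported melanin thickness `mel` is read as
the **total melanin per platelet, split equally into two walls** around the
air core. This is forced by the data: reported air diameters exceed reported
melanin thicknesses, so `mel` cannot be the whole-platelet thickness. The
top platelet is a sandwich with core `ptTop - mel`, or solid melanin when
`topPlateletSolid = TRUE`.

Air spaces within a platelet are `"block"` (air fraction constant at
`lateralFill` through the core) or `"sphere"` (parabolic profile
$\phi\,(1 - (2z/\mathrm{core})^2)$). Each depth slice's refractive index is
the volume-fraction-weighted arithmetic mean of the component complex
indices — the simplest effective-medium rule consistent with slicing the
structure into uniform layers. Dispersion follows a Cauchy model
$n = A + B/\lambda^2$ with exponential absorption
$k = k_0 e^{-\lambda/\lambda_k}$; the shipped coefficients (keratin
$A = 1.532$, $B = 5890\,\mathrm{nm}^2$; melanin $A = 1.648$,
$B = 23700\,\mathrm{nm}^2$, $k_0 = 0.56$, $\lambda_k = 270$ nm) are
configurable defaults representative of published feather-material
measurements, not asserted constants.

Numerical choices: curved (sphere) cores are discretised at `sliceThickness`
(default 1 nm; refinement to 0.25 nm changes reflectance by well under
$10^{-3}$, and uniform block cores are handled as single exact layers). The
recursion follows the $N = n - ik$ sign convention so absorbing stacks decay
rather than amplify; closed-form checks (bare-interface Fresnel,
quarter-wave stack, zero-contrast layer insertion, stack reversal) hold to
$10^{-10}$ or better in the test suite.

**Air-space shape and the 400–500 nm secondary peak.** With the bundled
gorget trait means, the sphere model predicts a secondary short-wavelength
reflectance peak for both parental phenotypes that is essentially absent for
the hybrid, robustly across the entire lateral-fill range. The block model
reproduces that ordering only in a narrow lateral-fill window (about
0.8–0.85): at `lateralFill = 1` a block core is a pure air slab with no
melanin partitions, the branickii secondary peak merges into its main peak,
and thin-film ripples of the (thicker) hybrid stack exceed it. Because the
lateral packing of real air cavities is not measured by the bundled traits,
the package keeps `airShape = "block"`, `lateralFill = 1` as the simulation
default but performs the peak-structure comparison in its tests under the
sphere model, where the prediction does not depend on the unmeasured fill
parameter. `secondaryPeakProminence()` quantifies the feature as the
topographic prominence of the strongest local maximum inside the band.

## 3. Transgression metrics

`parentBiasMismatch()` decomposes a hybrid's position relative to the line
joining the parental centroids: the along-transect component is normalised
by *half* the parental separation (so a hybrid sitting exactly on a parent
scores 1) and the orthogonal component by the *full* separation (so a score
of 1 means the hybrid is as far off the transect as the parents are from
each other). These two normalisations pin the two interpretation anchors —
"1 = exactly like one parent" and ">1 = more than the parental distance" —
and make both metrics invariant under rotation, reflection and uniform
scaling. `averagePairwiseDivergence()` applies the 2-D metric to every
unordered pair of trait columns and averages, since the underlying framework
is defined for trait pairs; centroids are arithmetic means of group rows,
computed on raw traits by default (PC scores may be supplied instead).
Colour inputs should be noise-scaled (JND) coordinates, which is why colour
divergence values are naturally an order of magnitude larger than raw
tetrahedral coordinates would give.

## 4. Rates of colour evolution and phylogenetic signal

`multivariateRate()` estimates a multivariate Brownian rate from scaled
phylogenetic independent contrasts (via `ape::pic`): at each internal node
the squared contrast length is **summed over the trait axes**, and the rate
$\sigma^2$ is the mean across nodes, in units of squared JND per My. Summing
(rather than averaging) across axes makes the units squared Euclidean
distance in colour space, which is what the divergence-time arithmetic
needs; `perAxis = TRUE` gives the mean-across-axes variant (exactly 3×
smaller for three axes). With three independent axes of per-axis rate $s$,
the estimator's expectation is $3s$; simulation recovery is part of the test
suite. Polytomies are rejected rather than silently resolved to zero-length
branches, because resolution changes the contrast count.

`blombergK()` implements a multivariate Blomberg's K: the ratio of observed
to phylogenetically-corrected mean squared deviation from the phylogenetic
mean, scaled by its Brownian expectation
$(\mathrm{tr}(C) - n/\Sigma C^{-1})/(n-1)$. K averages 1 under Brownian
motion (verified by simulation), and the univariate case agrees with an
independent reference implementation. The permutation test shuffles tip
assignments and uses the add-one convention, so p-values are in
$(0, 1]$ and seeded.

`divergenceTime()` is the closed-form waiting time $T = \Delta S^2/\sigma^2$.
With the worked inputs $\Delta S = 0.207$ JND and
$\sigma^2 = 0.0043\,\mathrm{JND^2\,My^{-1}}$ it returns 9.965 My —
10.0 My at the two-significant-figure precision the rounded inputs support.

## 5. Hybrid ancestry from diagnostic SNPs

The chain is `readGenotypes()` (VCF via vcfR; multiallelic records dropped
with a count) → `filterSNPs()` → `diagnosticLoci()` → `hybridIndex()` /
`interspecificHeterozygosity()` → `classifyHybrid()`.

Filtering applies the thresholds as strict inequalities — a call passes only
with depth > 5 and quality Q > 20 — and a locus is dropped entirely when any
*parental* call fails, since fixity cannot be assessed on unreliable calls;
failing focal calls become missing. Diagnostic loci require every
non-missing parent1 call homozygous for one allele and every parent2 call
homozygous for the other (sample-relative fixity; the minimum number of
parental calls per panel is a tunable, default 1). The returned matrix is
polarized so dosage counts parent2 alleles regardless of REF/ALT labelling,
which makes the estimators invariant to allele relabelling and maps a
parental-label swap to $h \mapsto 1 - h$.

The hybrid index is the binomial proportion
$h = (\text{parent2 alleles})/(2 \times \text{loci})$, with a 95%
profile-likelihood interval (log-likelihood drop of 1.92) under locus
independence; the construction is recorded in the output since other CI
recipes exist. Interspecific heterozygosity is the fraction of diagnostic
loci carrying one allele from each species. `classifyHybrid()` compares the
$(h, het)$ point against the canonical triangle expectations — parentals at
the corners, F1 at $(0.5, 1)$, F2 at $(0.5, 0.5)$, backcrosses halving
toward a corner each generation (BC1–BC3 on each side) — and reports the
nearest class with all distances, after checking the triangle constraint
$het \le 2\min(h, 1-h)$ up to a tolerance.

## 6. Ellipsoid niche models

Environmental layers live in a small in-package raster stack (`EnvGrid`)
serialised as a headered CSV grid; coordinates are unprojected degrees and
area distortion is ignored, as appropriate for the ~1 km cells of the
motivating analysis. `fitMVE()` re-implements the minimum-volume-ellipsoid
search: candidate ellipsoids from (d+1)-point subsets (exhaustive for small
problems, otherwise 500 seeded random subsets), each inflated to cover
⌈coverage·n⌉ points, minimal volume kept, followed by a reweighting step
that recomputes location/scatter from the covered points (this stabilises
the raw subset estimate and matches standard robust-estimation practice; the
independent MASS implementation is used as a cross-check in tests, never as
the implementation). Suitability is $\exp(-D^2/2)$ of the Mahalanobis
distance, and the binary surface thresholds at the 90th percentile of the
fitting occurrences' $D^2$ ("90% data inclusion"), which by construction
keeps at least 90% of them.

Overlap is Schoener's $D = 1 - \frac12\sum|p_A - p_B|$ on surfaces
normalised over shared data cells. The continuous surface is the default
for $D$ (the binary mode is also provided; which surface entered the
original comparisons is not stated). The permutation design is a
*background similarity* test: per direction, random cells are drawn
uniformly from the focal species' M (accessible-area) polygon, pseudomodels
are fitted, and the observed $D$ is compared with the null distribution of
pseudomodel-versus-true-model overlaps; small add-one p-values support
niche similarity beyond the background expectation. The pooled-relabelling
*identity/equivalency* permutation test is a different design and is out of
scope here.

## 7. What the synthetic generators emulate — and what they do not

Every stage has a matched generator with a recorded truth, so the pipeline
is testable end to end without any download:

* `genSpectra()`: smooth Gaussian-peaked spectra with iid noise, clipped at
  zero. Emulates peak placement and group separation only — not the angular
  dependence, UV structure or multi-peak shapes of real iridescent plumage.
* `genNanostructure()`: independent normal draws around stated trait means,
  truncated at zero, with 95% CI half-widths converted to sds as
  halfwidth/1.96 (the bundled intervals describe within-individual
  variation). Trait correlations present in real barbules are not emulated.
* `genCross()`: parental panels fixed for alternative alleles, Mendelian
  gamete sampling, unlinked loci; realised (not expected) $h$ and $het$
  recorded. No linkage, no genotyping error model beyond missingness.
* `genTreeTraits()`: pure-birth (Yule) trees rescaled to a stated depth;
  Brownian traits with per-branch increments $N(0, \sigma^2 b)$. Tree shape
  does not matter for the estimator calibrations, which is why the simplest
  clock-scaled generator suffices.
* `genNicheSystem()`: Gaussian-random-field layers (blurred white noise,
  standardised), occurrences sampled proportional to a Gaussian niche
  density, M polygons as buffered occurrence bounding boxes. Spatial
  sampling bias, which motivates presence-only ellipsoids in real data, is
  *not* emulated — so passing tests show estimator correctness, not
  robustness to survey bias.

Problem sizes used in the routine checks (100 trees of 100 tips for rate
recovery; 200 replicates for K and for BC1 ancestry at 1000 loci; a 50×60
grid with 40 occurrences per species and 99 pseudomodel replicates for the
niche test) were chosen as the smallest sizes at which Monte-Carlo error is
comfortably below the effects being tested.

## 8. Known limitations

* Cone sensitivities are nomogram templates, not measured hummingbird
  curves; oil-droplet filtering and luminance channels are not modelled.
* The optical model is strictly 1-D: no lateral scattering, no angular
  (iridescence) sweeps beyond a single configurable incidence angle, no
  pigmentary component, and the effective-medium slice approximation for
  block-shaped cavities is least reliable at full lateral fill (section 2
  above).
* Rate estimation assumes homogeneous-rate Brownian motion; OU/early-burst
  alternatives and clade-specific rates are out of scope.
* Ancestry estimation treats loci as independent and fixity as
  sample-relative; with small parental panels, apparent fixed differences
  can be polymorphism sampled shallowly.
* The niche machinery ignores geographic projection and treats occurrence
  cells as exchangeable within M.
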