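# transgressr

Quantifying transgressive hybrid phenotypes across colour, nanostructure,
genome and ecological niche.

When a putative hybrid individual turns up with a phenotype unlike either
parental species — the motivating case is a *Heliodoxa* hummingbird with a
gorget colour matching neither *H. branickii* nor *H. gularis* — several
independent lines of evidence have to be quantified together:

* **Is the colour really different, to the birds?** Reflectance spectra are
  run through a receptor-noise limited visual model of a UVS tetrachromat
  (cone ratios 1:2:2:4, Weber fraction ω = 0.1). Chromatic distance is

  ΔS² = Σ₍pairs jk₎ (Π other e)² (Δfⱼ − Δf_k)² / Σ₍triples₎ (e·e·e)²,

  with Δfᵢ = ln(qᵢᴬ/qᵢᴮ) and eᵢ = ω√(n_ref/nᵢ); distances above 1 JND are
  discriminable. `noiseScaledCoords()` gives 3-D coordinates whose Euclidean
  distances equal ΔS exactly, and `bootstrapGroupDistance()` puts bootstrap
  CIs on group differences.
* **Does the nanostructure explain the colour?** `simulateFeatherSpectrum()`
  turns measured barbule geometry (keratin cortex, hollow melanosome
  platelets, air spaces) into a reflectance spectrum via the transfer-matrix
  method, with sphere- or block-shaped air cavities and dispersive,
  absorbing melanin.
* **Is the phenotype transgressive?** `parentBiasMismatch()` decomposes the
  hybrid's position against the parental transect: parent-bias (0 =
  intermediate, 1 = on a parent) and mismatch (orthogonal offset in units of
  the parental separation), averaged over all trait pairs.
* **How unusual is the divergence on macroevolutionary timescales?**
  `multivariateRate()` estimates σ² (JND² My⁻¹) from squared independent
  contrasts summed over colour axes; `divergenceTime()` converts an observed
  distance into a Brownian waiting time T = ΔS²/σ²; `blombergK()` measures
  multivariate phylogenetic signal.
* **Is the individual genetically a hybrid, and of what class?** From a VCF,
  `filterSNPs()` (depth > 5, Q > 20) and `diagnosticLoci()` (opposite
  parental fixation) yield loci on which `hybridIndex()` and
  `interspecificHeterozygosity()` place the individual in the ancestry
  triangle; `classifyHybrid()` names the nearest canonical class (F1, F2,
  BC1–BC3 toward either parent).
* **Could the parents even meet?** `fitMVE()` fits presence-only
  minimum-volume-ellipsoid niche models, `suitabilityMap()` thresholds them
  at 90% data inclusion, and `backgroundSimilarityTest()` compares observed
  Schoener's D against pseudomodels drawn from each species' accessible
  area.

Every stage has a synthetic-data generator with recorded truth
(`genSpectra()`, `genNanostructure()`, `genCross()`, `genTreeTraits()`,
`genNicheSystem()`), so the whole pipeline runs and is tested without any
external download. `runPipeline()` orchestrates an end-to-end reproducible
demo from a single YAML config and seed.

## Worked example

```r
library(transgressr)

# two species whose gorgets peak at 480 vs 560 nm, 10 specimens each
groups  <- data.frame(label = c("gularis", "branickii"),
                      peak = c(480, 560), height = 30, width = 40)
spectra <- genSpectra(groups, nPerGroup = 10, noiseSd = 0.5, seed = 1)
vs      <- avianVisualSystem()
grp     <- specimenInfo(spectra)$group
bootstrapGroupDistance(spectra[grp == "gularis"],
                       spectra[grp == "branickii"], vs,
                       nBoot = 1000, seed = 1)
#> ColourDistance: dS = 18.6 JND [95% CI 18.45-18.74] *above 1 JND*

# a second-generation backcross, recovered from its (synthetic) VCF
x   <- genCross(1000, 5, "BC2_P1", seed = 1)
est <- hybridIndex(diagnosticLoci(filterSNPs(x$gm)))
est
#> AncestryEstimate: h = 0.124 [0.110-0.139], het = 0.248 (1000 loci,
#>   binomial profile likelihood CI)
classifyHybrid(est@h, est@het)$class
#> [1] "BC2_P1"

# optical simulation from measured gorget nanostructure (branickii means)
p <- nanostructure(cortex = 173, ptTop = 168, mel = 52, ker = 39,
                   air = 126, nLayers = 9, airShape = "sphere")
simulateFeatherSpectrum(p)
#> SimulatedSpectrum: 401 wavelengths, hue 665 nm, max R 0.572

# time to evolve an observed colour distance at the estimated Brownian rate
divergenceTime(0.207, 0.0043)
#> [1] 9.964884
```

The colour distance (≈19 JND) says the two synthetic species are far apart
perceptually and the CI excludes the 1 JND threshold; the ancestry estimate
lands at the BC2 corner-ward position (h ≈ 0.125, het ≈ 0.25) and is
classified accordingly; the optical model predicts the hue of the simulated
multilayer; and the divergence-time arithmetic converts a 0.207 JND gorget
difference at σ² = 0.0043 JND² My⁻¹ into ≈10 My of Brownian evolution.

See `vignettes/transgressr-methods.Rmd` for the full model descriptions,
parameter conventions and design decisions.

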