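## Central S4 containers. Validity methods enforce the structural invariants
## that downstream numerics rely on (monotone wavelength grids, non-negative
## reflectance, matching dimensions), so every constructor can assume them.

#' ReflectanceSpectra: a set of reflectance spectra on a shared wavelength grid
#'
#' Stores measured or simulated reflectance spectra (percent reflectance per
#' wavelength) for one or more specimens, together with per-specimen metadata
#' (specimen id, group label such as species or patch, measurement geometry).
#'
#' @slot wavelength numeric, strictly increasing, nm, within 300--700.
#' @slot reflectance numeric matrix, wavelengths x specimens, >= 0 (% units).
#' @slot specimen data.frame with one row per specimen; must contain a
#'   `specimen_id` column and may carry `group`, `patch` and `geometry`.
#' @exportClass ReflectanceSpectra
setClass("ReflectanceSpectra",
  slots = c(wavelength = "numeric", reflectance = "matrix",
            specimen = "data.frame"))

setValidity("ReflectanceSpectra", function(object) {
  wl <- object@wavelength
  if (length(wl) < 2L) return("need at least 2 wavelengths")
  if (any(diff(wl) <= 0)) return("wavelengths must be strictly increasing")
  if (min(wl) < 300 - 1e-9 || max(wl) > 700 + 1e-9)
    return("wavelengths must lie within [300, 700] nm")
  if (nrow(object@reflectance) != length(wl))
    return("reflectance rows must match wavelength grid")
  if (ncol(object@reflectance) != nrow(object@specimen))
    return("reflectance columns must match specimen table rows")
  if (!"specimen_id" %in% names(object@specimen))
    return("specimen table needs a 'specimen_id' column")
  neg <- colSums(object@reflectance < 0, na.rm = TRUE) > 0
  if (any(neg))
    return(paste0("negative reflectance in specimen(s): ",
                  paste(object@specimen$specimen_id[neg], collapse = ", ")))
  TRUE
})

#' VisualSystem: a receptor-noise limited visual phenotype
#'
#' Cone spectral sensitivities, relative cone densities, Weber fraction and
#' illuminant for a tetrachromatic (or generally k-chromatic) viewer. The
#' default constructor [avianVisualSystem()] builds a UVS-type hummingbird
#' system from a visual-pigment nomogram.
#'
#' @slot wavelength nm grid of the sensitivity curves.
#' @slot sensitivity matrix wavelength x cone class; column names are the cone
#'   labels (default `u`, `s`, `m`, `l`).
#' @slot density relative cone densities, one per class (default 1:2:2:4).
#' @slot weber Weber fraction of the reference cone channel (default 0.1).
#' @slot refCone label of the reference (most abundant) cone.
#' @slot illuminant irradiance spectrum on the same grid (default flat).
#' @exportClass VisualSystem
setClass("VisualSystem",
  slots = c(wavelength = "numeric", sensitivity = "matrix",
            density = "numeric", weber = "numeric", refCone = "character",
            illuminant = "numeric"))

setValidity("VisualSystem", function(object) {
  if (any(diff(object@wavelength) <= 0))
    return("wavelengths must be strictly increasing")
  if (nrow(object@sensitivity) != length(object@wavelength))
    return("sensitivity rows must match wavelength grid")
  if (is.null(colnames(object@sensitivity)))
    return("sensitivity columns must be named by cone class")
  if (any(object@sensitivity < 0)) return("sensitivities must be >= 0")
  if (length(object@density) != ncol(object@sensitivity))
    return("one density per cone class")
  if (any(object@density <= 0)) return("densities must be > 0")
  if (length(object@weber) != 1L || object@weber <= 0)
    return("weber must be a single positive number")
  if (!object@refCone %in% colnames(object@sensitivity))
    return("refCone must name a cone class")
  if (length(object@illuminant) != length(object@wavelength))
    return("illuminant must match wavelength grid")
  if (any(object@illuminant < 0)) return("illuminant must be >= 0")
  TRUE
})

#' QuantumCatch: photon catches of each cone class
#'
#' @slot q matrix specimens x cone classes of absolute quantum catches.
#' @slot relative matrix of relative catches; rows sum to 1.
#' @exportClass QuantumCatch
setClass("QuantumCatch", slots = c(q = "matrix", relative = "matrix"))

setValidity("QuantumCatch", function(object) {
  if (!all(dim(object@q) == dim(object@relative)))
    return("q and relative must have matching dimensions")
  if (any(object@q <= 0)) return("absolute catches must be > 0")
  if (any(abs(rowSums(object@relative) - 1) > 1e-12))
    return("relative catches must sum to 1 per specimen")
  TRUE
})

#' ColourDistance: a receptor-noise colour distance with bootstrap CI
#'
#' @slot dS point estimate, just-noticeable differences (JND).
#' @slot ci length-2 numeric, 95% percentile bootstrap interval (NA when no
#'   bootstrap was run).
#' @slot boot numeric vector of bootstrap replicates (may be empty).
#' @slot significant logical; TRUE when the CI lower bound exceeds 1 JND.
#' @exportClass ColourDistance
setClass("ColourDistance",
  slots = c(dS = "numeric", ci = "numeric", boot = "numeric",
            significant = "logical"))

setValidity("ColourDistance", function(object) {
  if (object@dS < 0) return("dS must be >= 0")
  if (length(object@ci) != 2L) return("ci must have length 2")
  if (!any(is.na(object@ci)) && (object@ci[1] > object@ci[2]))
    return("ci lower bound must not exceed upper bound")
  TRUE
})

#' NanostructureParams: cross-sectional geometry of an iridescent barbule
#'
#' Mean per-image feather nanostructure measurements: keratin cortex thickness,
#' top (surficial) melanosome platelet thickness, melanin thickness per
#' platelet, keratin spacing between platelets, air space diameter and the
#' number of melanosome layers, plus optical-model options (air space shape,
#' lateral fill fraction, whether the surficial platelet is solid).
#'
#' @slot cortex,ptTop,mel,ker,air thickness/diameter in nm (>= 0).
#' @slot nLayers number of melanosome layers (integer >= 1).
#' @slot airShape `"block"` or `"sphere"` air-space cross-section.
#' @slot lateralFill lateral air filling fraction phi in (0, 1].
#' @slot topPlateletSolid logical; TRUE when the surficial platelet has no
#'   air core.
#' @exportClass NanostructureParams
setClass("NanostructureParams",
  slots = c(cortex = "numeric", ptTop = "numeric", mel = "numeric",
            ker = "numeric", air = "numeric", nLayers = "integer",
            airShape = "character", lateralFill = "numeric",
            topPlateletSolid = "logical"),
  prototype = list(airShape = "block", lateralFill = 1,
                   topPlateletSolid = FALSE))

setValidity("NanostructureParams", function(object) {
  lens <- c(object@cortex, object@ptTop, object@mel, object@ker, object@air)
  if (any(lens < 0)) return("all lengths must be >= 0")
  if (object@nLayers < 1L) return("nLayers must be >= 1")
  if (!object@airShape %in% c("block", "sphere"))
    return("airShape must be 'block' or 'sphere'")
  if (object@lateralFill <= 0 || object@lateralFill > 1)
    return("lateralFill must be in (0, 1]")
  TRUE
})

#' LayerStack: a 1-D optical multilayer at a set of wavelengths
#'
#' Ordered finite slices (thickness + complex refractive index per wavelength)
#' between a semi-infinite incident medium and substrate. Indices are stored
#' per wavelength so dispersive materials are supported.
#'
#' @slot wavelength nm grid the indices are evaluated on.
#' @slot thickness slice thicknesses, nm (> 0); may be empty (bare interface).
#' @slot index complex matrix, slices x wavelengths.
#' @slot n0 complex vector: incident-medium index per wavelength.
#' @slot nSub complex vector: substrate index per wavelength.
#' @exportClass LayerStack
setClass("LayerStack",
  slots = c(wavelength = "numeric", thickness = "numeric", index = "matrix",
            n0 = "complex", nSub = "complex"))

setValidity("LayerStack", function(object) {
  nw <- length(object@wavelength)
  if (length(object@thickness) > 0 && any(object@thickness <= 0))
    return("slice thicknesses must be > 0")
  if (length(object@thickness) != nrow(object@index))
    return("index rows must match slice count")
  if (nrow(object@index) > 0 && ncol(object@index) != nw)
    return("index columns must match wavelength grid")
  if (length(object@n0) != nw || length(object@nSub) != nw)
    return("n0 and nSub must match wavelength grid")
  TRUE
})

#' SimulatedSpectrum: output of the optical model
#'
#' @slot wavelength nm grid.
#' @slot reflectance fraction in [0, 1] per wavelength.
#' @slot hue predicted hue: wavelength of maximum reflectance, nm.
#' @exportClass SimulatedSpectrum
setClass("SimulatedSpectrum",
  slots = c(wavelength = "numeric", reflectance = "numeric", hue = "numeric"))

setValidity("SimulatedSpectrum", function(object) {
  if (length(object@reflectance) != length(object@wavelength))
    return("reflectance must match wavelength grid")
  if (any(object@reflectance < -1e-12 | object@reflectance > 1 + 1e-12))
    return("reflectance must be a fraction in [0, 1]")
  TRUE
})

#' DivergenceResult: hybrid transgression metrics
#'
#' Parent-bias distance (0 = exactly intermediate, 1 = sitting on a parent)
#' and mismatch distance (orthogonal displacement from the parental transect
#' in units of the parental separation), averaged over trait pairs.
#'
#' @slot parentBias,mismatch non-negative averages across trait pairs.
#' @slot pairs data.frame breakdown with one row per unordered trait pair.
#' @exportClass DivergenceResult
setClass("DivergenceResult",
  slots = c(parentBias = "numeric", mismatch = "numeric",
            pairs = "data.frame"))

setValidity("DivergenceResult", function(object) {
  if (object@parentBias < 0 || object@mismatch < 0)
    return("metrics must be >= 0")
  TRUE
})

#' RateEstimate: multivariate Brownian rate of trait evolution
#'
#' @slot sigma2 rate in squared trait distance per unit branch length
#'   (e.g. JND^2 per My).
#' @slot nodeSq per-internal-node squared contrast lengths (summed over axes).
#' @slot nNodes number of internal nodes (contrasts) used.
#' @exportClass RateEstimate
setClass("RateEstimate",
  slots = c(sigma2 = "numeric", nodeSq = "numeric", nNodes = "integer"))

setValidity("RateEstimate", function(object) {
  if (object@sigma2 < 0) return("sigma2 must be >= 0")
  TRUE
})

#' SignalResult: phylogenetic signal statistic
#'
#' @slot K multivariate Blomberg's K (>= 0; 1 expected under Brownian motion).
#' @slot p permutation p-value (add-one convention); NA when no permutations
#'   were requested.
#' @slot nPerm number of tip permutations.
#' @slot seed RNG seed used for the permutations.
#' @exportClass SignalResult
setClass("SignalResult",
  slots = c(K = "numeric", p = "numeric", nPerm = "integer", seed = "integer"))

setValidity("SignalResult", function(object) {
  if (object@K < 0) return("K must be >= 0")
  if (!is.na(object@p) && (object@p <= 0 || object@p > 1))
    return("p must be in (0, 1]")
  TRUE
})

#' GenotypeMatrix: biallelic SNP genotypes with depth/quality metadata
#'
#' Genotypes are stored as ALT-allele dosage (0, 1, 2, NA) in a loci x
#' individuals integer matrix; once [diagnosticLoci()] has polarized the
#' matrix, dosage counts parent2-derived alleles instead.
#'
#' @slot geno integer matrix loci x individuals, values 0/1/2/NA.
#' @slot dp,gq numeric matrices of read depth and genotype quality (may have
#'   zero rows when the source VCF lacks the fields).
#' @slot pop character per individual: `parent1`, `parent2` or `focal`.
#' @slot loci character locus identifiers.
#' @slot polarized logical; TRUE when dosage counts parent2 alleles.
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  slots = c(geno = "matrix", dp = "matrix", gq = "matrix", pop = "character",
            loci = "character", polarized = "logical"),
  prototype = list(polarized = FALSE))

setValidity("GenotypeMatrix", function(object) {
  if (ncol(object@geno) != length(object@pop))
    return("one population label per individual")
  if (!all(object@pop %in% c("parent1", "parent2", "focal")))
    return("populations must be parent1, parent2 or focal")
  if (nrow(object@geno) != length(object@loci))
    return("one locus id per row")
  vals <- object@geno[!is.na(object@geno)]
  if (length(vals) && !all(vals %in% 0:2))
    return("genotypes must be dosages 0, 1, 2 or NA")
  for (s in c("dp", "gq")) {
    m <- slot(object, s)
    if (nrow(m) > 0 && !all(dim(m) == dim(object@geno)))
      return(paste(s, "must match genotype dimensions"))
    if (length(m) && any(m[!is.na(m)] < 0)) return(paste(s, "must be >= 0"))
  }
  TRUE
})

#' AncestryEstimate: hybrid index and interspecific heterozygosity
#'
#' @slot h hybrid index: proportion of parent2 alleles at diagnostic loci.
#' @slot ci 95% profile-likelihood confidence interval for h.
#' @slot het interspecific heterozygosity: fraction of diagnostic loci with
#'   one allele from each parental species.
#' @slot nLoci number of non-missing diagnostic loci used.
#' @slot ciMethod how the interval was constructed.
#' @exportClass AncestryEstimate
setClass("AncestryEstimate",
  slots = c(h = "numeric", ci = "numeric", het = "numeric",
            nLoci = "integer", ciMethod = "character"))

setValidity("AncestryEstimate", function(object) {
  if (object@h < 0 || object@h > 1) return("h must be in [0, 1]")
  if (object@het < 0 || object@het > 1) return("het must be in [0, 1]")
  if (length(object@ci) != 2L) return("ci must have length 2")
  if (!any(is.na(object@ci))) {
    if (object@ci[1] < 0 || object@ci[2] > 1) return("ci must be within [0, 1]")
    if (object@h < object@ci[1] - 1e-9 || object@h > object@ci[2] + 1e-9)
      return("ci must contain h")
  }
  TRUE
})

#' EnvGrid: an aligned stack of environmental raster layers
#'
#' A lightweight in-memory raster stack: a rows x cols x layers array with a
#' rectangular extent in unprojected lon/lat. Cells with NA in any layer are
#' treated as no-data. Serialised to/from a headered CSV grid format by
#' [writeEnvGrid()] / [readEnvGrid()].
#'
#' @slot data numeric array rows x cols x layers; row 1 is the northern edge.
#' @slot layers layer names.
#' @slot extent named numeric: xmin, xmax, ymin, ymax.
#' @exportClass EnvGrid
setClass("EnvGrid",
  slots = c(data = "array", layers = "character", extent = "numeric"))

setValidity("EnvGrid", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3-D array")
  if (dim(object@data)[3] != length(object@layers))
    return("one name per layer")
  ex <- object@extent
  if (!all(c("xmin", "xmax", "ymin", "ymax") %in% names(ex)))
    return("extent must name xmin, xmax, ymin, ymax")
  if (ex["xmax"] <= ex["xmin"] || ex["ymax"] <= ex["ymin"])
    return("extent must be non-degenerate")
  TRUE
})

#' MVEModel: a minimum-volume-ellipsoid niche model
#'
#' @slot centre ellipsoid centre in environmental units.
#' @slot shape symmetric positive-definite shape matrix (Mahalanobis metric).
#' @slot coverage fraction of fitting points the ellipsoid was inflated to
#'   cover.
#' @slot t90 squared Mahalanobis threshold containing 90% of the fitting
#'   occurrences.
#' @slot layers names of the environmental axes.
#' @exportClass MVEModel
setClass("MVEModel",
  slots = c(centre = "numeric", shape = "matrix", coverage = "numeric",
            t90 = "numeric", layers = "character"))

setValidity("MVEModel", function(object) {
  S <- object@shape
  if (nrow(S) != length(object@centre)) return("shape must match centre")
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    return("shape must be symmetric")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return("shape must be positive-definite")
  if (object@t90 <= 0) return("t90 must be > 0")
  TRUE
})

#' SuitabilityMap: gridded suitability from an ellipsoid niche model
#'
#' @slot suit continuous suitability in [0, 1] (exp(-D^2/2)); NA = no data.
#' @slot binary logical matrix: cells within the 90% Mahalanobis threshold.
#' @slot extent named numeric extent, as [EnvGrid-class].
#' @exportClass SuitabilityMap
setClass("SuitabilityMap",
  slots = c(suit = "matrix", binary = "matrix", extent = "numeric"))

setValidity("SuitabilityMap", function(object) {
  if (!all(dim(object@suit) == dim(object@binary)))
    return("suit and binary must have matching dimensions")
  v <- object@suit[!is.na(object@suit)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    return("suitability must be in [0, 1]")
  if (any(object@binary[is.na(object@suit)], na.rm = TRUE))
    return("binary cells must lie within the data mask")
  TRUE
})

#' OverlapResult: observed niche overlap against a background null
#'
#' @slot D observed Schoener's D in [0, 1].
#' @slot null null distribution of D from pseudomodels.
#' @slot p add-one permutation p-value for the null hypothesis that observed
#'   overlap does not exceed the background expectation.
#' @slot nReps number of pseudomodel replicates.
#' @slot seed RNG seed.
#' @slot direction label, e.g. "A->B": pseudomodels drawn in A's M region.
#' @exportClass OverlapResult
setClass("OverlapResult",
  slots = c(D = "numeric", null = "numeric", p = "numeric", nReps = "integer",
            seed = "integer", direction = "character"))

setValidity("OverlapResult", function(object) {
  if (object@D < 0 || object@D > 1) return("D must be in [0, 1]")
  if (!is.na(object@p) && (object@p <= 0 || object@p > 1))
    return("p must be in (0, 1]")
  TRUE
})
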