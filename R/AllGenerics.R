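## Accessor generics and show methods. Slot access from user code is
## discouraged; these are the supported surface.

#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))
#' @export
setGeneric("reflectance", function(x) standardGeneric("reflectance"))
#' @export
setGeneric("specimenInfo", function(x) standardGeneric("specimenInfo"))
#' @export
setGeneric("catches", function(x) standardGeneric("catches"))
#' @export
setGeneric("relCatches", function(x) standardGeneric("relCatches"))
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))
#' @export
setGeneric("gridData", function(x) standardGeneric("gridData"))
#' @export
setGeneric("gridExtent", function(x) standardGeneric("gridExtent"))

#' Accessors for package containers
#'
#' `wavelengths()`, `reflectance()` and `specimenInfo()` expose the grid,
#' matrix and metadata of a [ReflectanceSpectra-class] (or the grid and curve
#' of a [SimulatedSpectrum-class]); `catches()`/`relCatches()` the absolute
#' and relative cone catches of a [QuantumCatch-class]; `genotypes()` and
#' `populations()` the dosage matrix and population labels of a
#' [GenotypeMatrix-class]; `gridData()`/`gridExtent()` the array and extent of
#' an [EnvGrid-class].
#'
#' @param x the object.
#' @return The corresponding slot value.
#' @name accessors
#' @aliases wavelengths reflectance specimenInfo catches relCatches genotypes
#'   populations gridData gridExtent
NULL

#' @rdname accessors
#' @export
setMethod("wavelengths", "ReflectanceSpectra", function(x) x@wavelength)
#' @rdname accessors
#' @export
setMethod("reflectance", "ReflectanceSpectra", function(x) x@reflectance)
#' @rdname accessors
#' @export
setMethod("specimenInfo", "ReflectanceSpectra", function(x) x@specimen)
#' @rdname accessors
#' @export
setMethod("wavelengths", "SimulatedSpectrum", function(x) x@wavelength)
#' @rdname accessors
#' @export
setMethod("reflectance", "SimulatedSpectrum", function(x) x@reflectance)
#' @rdname accessors
#' @export
setMethod("catches", "QuantumCatch", function(x) x@q)
#' @rdname accessors
#' @export
setMethod("relCatches", "QuantumCatch", function(x) x@relative)
#' @rdname accessors
#' @export
setMethod("genotypes", "GenotypeMatrix", function(x) x@geno)
#' @rdname accessors
#' @export
setMethod("populations", "GenotypeMatrix", function(x) x@pop)
#' @rdname accessors
#' @export
setMethod("gridData", "EnvGrid", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("gridExtent", "EnvGrid", function(x) x@extent)

#' Subset spectra by specimen
#'
#' @param x a [ReflectanceSpectra-class].
#' @param i specimen index, logical mask or specimen_id values.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "ReflectanceSpectra", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@specimen$specimen_id)
  new("ReflectanceSpectra", wavelength = x@wavelength,
      reflectance = x@reflectance[, i, drop = FALSE],
      specimen = x@specimen[i, , drop = FALSE])
})

setMethod("show", "ReflectanceSpectra", function(object) {
  cat("ReflectanceSpectra:", ncol(object@reflectance), "specimen(s),",
      length(object@wavelength), "wavelengths",
      sprintf("(%g-%g nm)\n", min(object@wavelength), max(object@wavelength)))
  if ("group" %in% names(object@specimen)) {
    tab <- table(object@specimen$group)
    cat("  groups:", paste(sprintf("%s (%d)", names(tab), tab),
                           collapse = ", "), "\n")
  }
})

setMethod("show", "VisualSystem", function(object) {
  cat("VisualSystem:", paste(colnames(object@sensitivity), collapse = "/"),
      "cones, densities", paste(object@density, collapse = ":"),
      sprintf("| Weber %.3g on '%s'\n", object@weber, object@refCone))
})

setMethod("show", "ColourDistance", function(object) {
  cat(sprintf("ColourDistance: dS = %.4g JND", object@dS))
  if (!any(is.na(object@ci)))
    cat(sprintf(" [95%% CI %.4g-%.4g]%s", object@ci[1], object@ci[2],
                if (isTRUE(object@significant)) " *above 1 JND*" else ""))
  cat("\n")
})

setMethod("show", "SimulatedSpectrum", function(object) {
  cat(sprintf("SimulatedSpectrum: %d wavelengths, hue %g nm, max R %.3f\n",
              length(object@wavelength), object@hue,
              max(object@reflectance)))
})

setMethod("show", "DivergenceResult", function(object) {
  cat(sprintf(
    "DivergenceResult: parent-bias %.3f, mismatch %.3f (%d trait pair(s))\n",
    object@parentBias, object@mismatch, nrow(object@pairs)))
})

setMethod("show", "RateEstimate", function(object) {
  cat(sprintf("RateEstimate: sigma2 = %.4g per My over %d nodes\n",
              object@sigma2, object@nNodes))
})

setMethod("show", "SignalResult", function(object) {
  cat(sprintf("SignalResult: K = %.3f", object@K))
  if (!is.na(object@p))
    cat(sprintf(", p = %.4g (%d permutations)", object@p, object@nPerm))
  cat("\n")
})

setMethod("show", "GenotypeMatrix", function(object) {
  tab <- table(object@pop)
  cat(sprintf("GenotypeMatrix: %d loci x %d individuals (%s)%s\n",
              nrow(object@geno), ncol(object@geno),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              if (object@polarized) " [polarized to parent2 dosage]" else ""))
})

setMethod("show", "AncestryEstimate", function(object) {
  cat(sprintf(
    "AncestryEstimate: h = %.3f [%.3f-%.3f], het = %.3f (%d loci, %s CI)\n",
    object@h, object@ci[1], object@ci[2], object@het, object@nLoci,
    object@ciMethod))
})

setMethod("show", "EnvGrid", function(object) {
  d <- dim(object@data)
  cat(sprintf("EnvGrid: %d x %d cells, %d layer(s): %s\n", d[1], d[2], d[3],
              paste(object@layers, collapse = ", ")))
})

setMethod("show", "MVEModel", function(object) {
  cat(sprintf("MVEModel: %d-D ellipsoid, coverage %.2f, t90 = %.3g\n",
              length(object@centre), object@coverage, object@t90))
})

setMethod("show", "OverlapResult", function(object) {
  cat(sprintf("OverlapResult (%s): D = %.3f", object@direction, object@D))
  if (!is.na(object@p))
    cat(sprintf(", p = %.4g (%d pseudomodels)", object@p, object@nReps))
  cat("\n")
})
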