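## 1-D optical model of iridescent feather barbules: the melanosome
## multilayer is discretised into depth slices of uniform complex refractive
## index and reflectance is computed with the transfer-matrix (characteristic
## matrix) method.

#' Default material dispersion set
#'
#' Cauchy coefficients n(lambda) = A + B/lambda^2 plus an exponential
#' absorption term k(lambda) = k0 exp(-lambda/lambdaK) for feather keratin
#' and eumelanin; air is 1 + 0i. The shipped coefficients (keratin A = 1.532,
#' B = 5890 nm^2; melanin A = 1.648, B = 23700 nm^2, k0 = 0.56, lambdaK =
#' 270 nm) are configurable defaults representative of published
#' measurements on feather materials.
#'
#' @param keratin,melanin,air named lists with elements `A`, `B`, `k0`,
#'   `lambdaK` overriding the defaults.
#' @return named list of per-material coefficient lists.
#' @export
opticalDispersion <- function(keratin = list(), melanin = list(),
                              air = list()) {
  merge1 <- function(def, upd) { def[names(upd)] <- upd; def }
  list(
    keratin = merge1(list(A = 1.532, B = 5890, k0 = 0, lambdaK = 270),
                     keratin),
    melanin = merge1(list(A = 1.648, B = 23700, k0 = 0.56, lambdaK = 270),
                     melanin),
    air = merge1(list(A = 1, B = 0, k0 = 0, lambdaK = 270), air))
}

#' Complex refractive index of a feather material
#'
#' @param material `"keratin"`, `"melanin"` or `"air"`.
#' @param lambda wavelength(s), nm.
#' @param dispersion a dispersion set from [opticalDispersion()].
#' @return complex vector n(lambda) = A + B/lambda^2 + i k0 exp(-lambda/lambdaK).
#' @examples
#' materialIndex("keratin", 500)   # 1.532 + 5890/500^2 = 1.55556
#' @export
materialIndex <- function(material, lambda, dispersion = opticalDispersion()) {
  if (!material %in% names(dispersion)) stop("unknown material: ", material)
  if (any(lambda <= 0)) stop("wavelengths must be positive")
  p <- dispersion[[material]]
  complex(real = p$A + p$B / lambda^2,
          imaginary = p$k0 * exp(-lambda / p$lambdaK))
}

#' Construct a LayerStack directly from thicknesses and indices
#'
#' Convenience constructor for closed-form checks and user-defined stacks.
#' `index` may be a vector (one constant index per slice) or a slices x
#' wavelengths matrix.
#'
#' @param wavelength nm grid.
#' @param thickness slice thicknesses, nm (may be empty for a bare interface).
#' @param index complex slice indices (vector or matrix).
#' @param n0 incident-medium index (scalar or per-wavelength).
#' @param nSub substrate index (scalar or per-wavelength).
#' @return A [LayerStack-class].
#' @export
layerStack <- function(wavelength, thickness = numeric(0),
                       index = complex(0), n0 = 1 + 0i, nSub = 1.5 + 0i) {
  nw <- length(wavelength)
  if (is.null(dim(index)))
    index <- matrix(as.complex(index), length(index), nw)
  if (length(n0) == 1L) n0 <- rep(as.complex(n0), nw)
  if (length(nSub) == 1L) nSub <- rep(as.complex(nSub), nw)
  new("LayerStack", wavelength = wavelength, thickness = thickness,
      index = index, n0 = as.complex(n0), nSub = as.complex(nSub))
}

# One platelet = mel/2 wall, air core, mel/2 wall. Returns a list of
# (thickness, airFrac, material) slice rows; the core is discretised at
# sliceThickness with a parabolic air-fraction profile for spheres and a
# constant profile (phi) for blocks.
.plateletSlices <- function(core, mel, shape, phi, sliceThickness) {
  rows <- list()
  if (mel > 0)
    rows[[length(rows) + 1L]] <- list(t = mel / 2, f = 0, mat = "melanin")
  if (core > 0) {
    if (shape == "block") {
      rows[[length(rows) + 1L]] <- list(t = core, f = phi, mat = "melanin")
    } else {
      ns <- max(1L, round(core / sliceThickness))
      dt <- core / ns
      z <- (seq_len(ns) - 0.5) * dt - core / 2     # signed depth from centre
      fr <- pmin(1, pmax(0, phi * (1 - (2 * z / core)^2)))
      for (i in seq_len(ns))
        rows[[length(rows) + 1L]] <- list(t = dt, f = fr[i], mat = "melanin")
    }
  }
  if (mel > 0)
    rows[[length(rows) + 1L]] <- list(t = mel / 2, f = 0, mat = "melanin")
  rows
}

#' Discretise a feather nanostructure into a 1-D optical layer stack
#'
#' From the incident air medium downward: the keratin cortex, the surficial
#' (top) melanosome platelet, then `nLayers - 1` repeats of a keratin gap
#' followed by an inner platelet, over a semi-infinite keratin substrate.
#' Each inner platelet is a melanin/air/melanin sandwich: the reported
#' melanin thickness is split equally into the two walls around an air core
#' of extent `air` (the walls' total equals `mel`; the reported air diameters
#' exceed the melanin thicknesses, so `mel` cannot be the whole-platelet
#' thickness). The top platelet is solid melanin of thickness `ptTop` when
#' `topPlateletSolid`, else the same sandwich with core `ptTop - mel`.
#' Within an air core, a block-shaped space fills fraction `lateralFill` of
#' every slice; a sphere-shaped space at signed depth z from the core centre
#' fills `lateralFill * (1 - (2 z / core)^2)`. Each slice's index is the
#' volume-fraction-weighted arithmetic mean of the component complex indices.
#'
#' @param params a [NanostructureParams-class] (see [nanostructure()]).
#' @param wavelength nm grid.
#' @param sliceThickness target slice thickness, nm (> 0); only curved
#'   (sphere) air cores are actually subdivided, since uniform slices merge
#'   exactly.
#' @param dispersion a dispersion set from [opticalDispersion()].
#' @return A [LayerStack-class].
#' @export
buildStack <- function(params, wavelength = seq(300, 700, by = 1),
                       sliceThickness = 1,
                       dispersion = opticalDispersion()) {
  stopifnot(is(params, "NanostructureParams"))
  validObject(params)
  if (sliceThickness <= 0) stop("sliceThickness must be > 0")
  rows <- list()
  if (params@cortex > 0)
    rows[[1]] <- list(t = params@cortex, f = 0, mat = "keratin")
  if (params@topPlateletSolid) {
    if (params@ptTop > 0)
      rows[[length(rows) + 1L]] <- list(t = params@ptTop, f = 0,
                                        mat = "melanin")
  } else {
    core <- max(params@ptTop - params@mel, 0)
    rows <- c(rows, .plateletSlices(core, params@mel, params@airShape,
                                    params@lateralFill, sliceThickness))
  }
  if (params@nLayers > 1L) {
    for (i in seq_len(params@nLayers - 1L)) {
      if (params@ker > 0)
        rows[[length(rows) + 1L]] <- list(t = params@ker, f = 0,
                                          mat = "keratin")
      rows <- c(rows, .plateletSlices(params@air, params@mel,
                                      params@airShape, params@lateralFill,
                                      sliceThickness))
    }
  }
  nk <- materialIndex("keratin", wavelength, dispersion)
  nm <- materialIndex("melanin", wavelength, dispersion)
  na <- materialIndex("air", wavelength, dispersion)
  thick <- vapply(rows, `[[`, numeric(1), "t")
  keep <- thick > 0
  rows <- rows[keep]; thick <- thick[keep]
  idx <- matrix(0i, length(rows), length(wavelength))
  for (i in seq_along(rows)) {
    base <- if (rows[[i]]$mat == "keratin") nk else nm
    idx[i, ] <- rows[[i]]$f * na + (1 - rows[[i]]$f) * base
  }
  new("LayerStack", wavelength = wavelength, thickness = thick, index = idx,
      n0 = na, nSub = nk)
}

#' Constructor for nanostructure parameters
#'
#' @param cortex,ptTop,mel,ker,air geometry in nm (see
#'   [NanostructureParams-class]).
#' @param nLayers number of melanosome layers (>= 1).
#' @param airShape `"block"` (default) or `"sphere"`.
#' @param lateralFill lateral air filling fraction in (0, 1].
#' @param topPlateletSolid logical.
#' @return A [NanostructureParams-class].
#' @export
nanostructure <- function(cortex, ptTop, mel, ker, air, nLayers,
                          airShape = "block", lateralFill = 1,
                          topPlateletSolid = FALSE) {
  new("NanostructureParams", cortex = cortex, ptTop = ptTop, mel = mel,
      ker = ker, air = air, nLayers = as.integer(nLayers),
      airShape = airShape, lateralFill = lateralFill,
      topPlateletSolid = topPlateletSolid)
}

#' Transfer-matrix reflectance of a layer stack
#'
#' Standard characteristic-matrix recursion per wavelength. At oblique
#' incidence the unpolarised reflectance is the mean of the s- and
#' p-polarised values; at normal incidence (the default) they coincide.
#'
#' @param stack a [LayerStack-class].
#' @param angle incidence angle in degrees (default 0).
#' @return A [SimulatedSpectrum-class] on the stack's wavelength grid.
#' @export
tmmReflectance <- function(stack, angle = 0) {
  stopifnot(is(stack, "LayerStack"))
  wl <- stack@wavelength
  th0 <- angle * pi / 180
  # indices are stored as n + ik; the characteristic-matrix recursion below
  # follows the N = n - ik sign convention, so conjugate on entry
  n0c <- Conj(stack@n0); nSubc <- Conj(stack@nSub)
  sin0 <- n0c * sin(th0)               # conserved transverse component
  onePol <- function(pol) {
    eta <- function(n) {
      ct <- sqrt(1 - (sin0 / n)^2)
      if (pol == "s") n * ct else n / ct
    }
    B <- rep(1 + 0i, length(wl)); C <- eta(nSubc)
    for (j in rev(seq_along(stack@thickness))) {
      nj <- Conj(stack@index[j, ])
      ct <- sqrt(1 - (sin0 / nj)^2)
      delta <- 2 * pi * nj * stack@thickness[j] * ct / wl
      ej <- if (pol == "s") nj * ct else nj / ct
      cb <- cos(delta); sb <- sin(delta)
      Bn <- cb * B + (1i * sb / ej) * C
      Cn <- (1i * ej * sb) * B + cb * C
      B <- Bn; C <- Cn
    }
    e0 <- eta(n0c)
    r <- (e0 * B - C) / (e0 * B + C)
    Mod(r)^2
  }
  R <- if (angle == 0) onePol("s") else (onePol("s") + onePol("p")) / 2
  R <- pmin(pmax(R, 0), 1)
  new("SimulatedSpectrum", wavelength = wl, reflectance = R,
      hue = wl[which.max(R)])
}

#' Simulate the reflectance spectrum of a feather nanostructure
#'
#' Convenience wrapper: [buildStack()] followed by [tmmReflectance()] on a
#' 300--700 nm grid; the predicted hue is the wavelength of maximum
#' reflectance.
#'
#' @param params a [NanostructureParams-class].
#' @param wavelength nm grid (default 300--700 at 1 nm).
#' @param sliceThickness slice thickness for curved air cores, nm.
#' @param angle incidence angle, degrees.
#' @param dispersion dispersion set.
#' @return A [SimulatedSpectrum-class].
#' @examples
#' p <- nanostructure(cortex = 173, ptTop = 168, mel = 52, ker = 39,
#'                    air = 126, nLayers = 9)
#' s <- simulateFeatherSpectrum(p)
#' s
#' @export
simulateFeatherSpectrum <- function(params,
                                    wavelength = seq(300, 700, by = 1),
                                    sliceThickness = 1, angle = 0,
                                    dispersion = opticalDispersion()) {
  stack <- buildStack(params, wavelength, sliceThickness, dispersion)
  tmmReflectance(stack, angle)
}

#' Mean hue offset between simulated and empirical spectra
#'
#' @param simulated,empirical numeric vectors of hues (nm), or lists of
#'   [SimulatedSpectrum-class] / [ReflectanceSpectra-class] objects from
#'   which hues are taken via [huePeak()].
#' @return mean(simulated hue - empirical hue) in nm; positive = model
#'   red-shifted relative to measurement.
#' @export
compareModelToEmpirical <- function(simulated, empirical) {
  toHue <- function(x) {
    if (is.numeric(x)) return(x)
    if (is(x, "SimulatedSpectrum")) return(x@hue)
    if (is(x, "ReflectanceSpectra")) return(unname(huePeak(x)))
    if (is.list(x)) return(unlist(lapply(x, toHue)))
    stop("cannot extract hues from class ", class(x)[1])
  }
  sh <- toHue(simulated); eh <- toHue(empirical)
  if (length(sh) == 0 || length(eh) == 0) stop("empty input")
  mean(sh) - mean(eh)
}

#' Topographic prominence of the strongest peak in a wavelength band
#'
#' Finds interior local maxima of a reflectance curve whose wavelength falls
#' in `band` and returns the largest topographic prominence among them (the
#' peak height above the higher of the two bounding saddles, walking outward
#' until terrain higher than the peak — or the spectrum edge — is reached).
#' Returns 0 when the band contains no local maximum. Used to test for the
#' presence/absence of a secondary reflectance peak (e.g. near 450 nm).
#'
#' @param x a [SimulatedSpectrum-class] or [ReflectanceSpectra-class] with a
#'   single specimen.
#' @param band length-2 numeric wavelength window, nm.
#' @return prominence in the reflectance units of `x` (fraction or percent).
#' @export
secondaryPeakProminence <- function(x, band = c(400, 500)) {
  wl <- wavelengths(x)
  r <- if (is(x, "SimulatedSpectrum")) x@reflectance else {
    stopifnot(ncol(reflectance(x)) == 1L)
    as.numeric(reflectance(x))
  }
  n <- length(r)
  isMax <- c(FALSE, r[2:(n - 1)] > r[1:(n - 2)] & r[2:(n - 1)] >= r[3:n],
             FALSE)
  cand <- which(isMax & wl >= band[1] & wl <= band[2])
  if (!length(cand)) return(0)
  prom <- vapply(cand, function(i) {
    left <- r[seq_len(i - 1)]
    hiL <- which(left > r[i])
    minL <- min(r[(if (length(hiL)) max(hiL) else 1):i])
    right <- r[(i + 1):n]
    hiR <- which(right > r[i])
    minR <- min(r[i:(i + (if (length(hiR)) min(hiR) else length(right)))])
    r[i] - max(minL, minR)
  }, numeric(1))
  max(prom)
}
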