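## Avian colour vision: quantum catches, tetrahedral colour space and the
## receptor-noise limited discrimination model.

# Visual-pigment absorbance template (A1 nomogram, alpha + beta bands).
.pigmentTemplate <- function(lambda, lmax) {
  x <- lmax / lambda
  a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lmax
  bw <- -40.5 + 0.195 * lmax
  beta <- 0.26 * exp(-((lambda - lmb) / bw)^2)
  pmax(alpha + beta, 0)
}

#' Construct an avian UVS-type visual system
#'
#' Builds a [VisualSystem-class] for a tetrachromatic viewer. By default the
#' four cone sensitivity curves are generated from a standard visual-pigment
#' nomogram with peak sensitivities at 370 (u), 440 (s), 508 (m) and 560 nm
#' (l) — a template ultraviolet-sensitive system of the kind found in
#' hummingbirds — with relative cone densities 1:2:2:4, a Weber fraction of
#' 0.1 applied to the most abundant (l) cone, and a flat (ideal) illuminant.
#' Measured sensitivity curves can be supplied instead via `sensitivity`, or
#' loaded from a CSV (`wavelength_nm,u,s,m,l`) via [readSensitivities()].
#'
#' @param lambdaMax named numeric of pigment peak wavelengths, nm.
#' @param density relative cone densities, same order as `lambdaMax`.
#' @param weber Weber fraction of the reference cone channel.
#' @param refCone name of the reference cone (default the most abundant).
#' @param wavelength grid for the curves, nm.
#' @param illuminant irradiance on the grid (default flat).
#' @param sensitivity optional matrix of measured curves (wavelength x cone);
#'   overrides the nomogram.
#' @return A [VisualSystem-class].
#' @examples
#' vs <- avianVisualSystem()
#' vs
#' @export
avianVisualSystem <- function(lambdaMax = c(u = 370, s = 440, m = 508, l = 560),
                              density = c(1, 2, 2, 4), weber = 0.1,
                              refCone = NULL,
                              wavelength = seq(300, 700, by = 1),
                              illuminant = NULL, sensitivity = NULL) {
  if (is.null(sensitivity)) {
    sensitivity <- vapply(lambdaMax,
                          function(lm) .pigmentTemplate(wavelength, lm),
                          numeric(length(wavelength)))
    colnames(sensitivity) <- names(lambdaMax)
  }
  if (is.null(refCone))
    refCone <- colnames(sensitivity)[which.max(density)]
  if (is.null(illuminant)) illuminant <- rep(1, length(wavelength))
  new("VisualSystem", wavelength = wavelength, sensitivity = sensitivity,
      density = density, weber = weber, refCone = refCone,
      illuminant = illuminant)
}

#' Read cone sensitivity curves from CSV (`wavelength_nm,u,s,m,l`)
#' @param path CSV path; first column is the wavelength grid, remaining
#'   columns one cone class each.
#' @return matrix wavelength x cone with the grid as an attribute-free first
#'   use in [avianVisualSystem()]: pass both `wavelength` and `sensitivity`.
#' @export
readSensitivities <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (names(df)[1] != "wavelength_nm") stop("first column must be wavelength_nm")
  m <- as.matrix(df[, -1, drop = FALSE])
  attr(m, "wavelength") <- df$wavelength_nm
  m
}

#' Read reflectance spectra from the shared CSV dialect
#'
#' Expects column 1 `wavelength_nm` and one column per specimen. Wavelengths
#' must be strictly increasing; rows outside 300--700 nm are trimmed with a
#' warning; any negative reflectance raises an error naming the specimen.
#'
#' @param path CSV path.
#' @param specimenInfo optional data.frame (`specimen_id`, plus e.g. `group`)
#'   to attach; by default group labels are recovered from column names of
#'   the form `<group>_<nn>`.
#' @return A [ReflectanceSpectra-class].
#' @export
readSpectra <- function(path, specimenInfo = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "wavelength_nm")
    stop("malformed header: first column must be 'wavelength_nm'")
  wl <- df[[1]]
  if (any(diff(wl) <= 0)) stop("wavelengths must be strictly increasing")
  keep <- wl >= 300 & wl <= 700
  if (!all(keep)) {
    warning(sum(!keep), " wavelength row(s) outside [300, 700] nm trimmed")
    df <- df[keep, , drop = FALSE]; wl <- wl[keep]
  }
  refl <- as.matrix(df[, -1, drop = FALSE])
  neg <- colSums(refl < 0, na.rm = TRUE) > 0
  if (any(neg))
    stop("negative reflectance in specimen(s): ",
         paste(colnames(refl)[neg], collapse = ", "))
  if (is.null(specimenInfo)) {
    ids <- colnames(refl)
    specimenInfo <- data.frame(specimen_id = ids,
                               group = sub("_[0-9]+$", "", ids),
                               stringsAsFactors = FALSE)
  }
  new("ReflectanceSpectra", wavelength = wl, reflectance = refl,
      specimen = specimenInfo)
}

#' Hue as the wavelength of peak reflectance
#'
#' Returns the wavelength of the global reflectance maximum per specimen,
#' after optional box smoothing over `smoothingSpan` nm. Exact ties are
#' broken toward the shortest wavelength; an all-zero spectrum has no defined
#' hue and raises an error.
#'
#' @param x a [ReflectanceSpectra-class] or [SimulatedSpectrum-class].
#' @param smoothingSpan box-filter width in nm (0 = off, the default).
#' @return named numeric vector of hues, nm.
#' @export
huePeak <- function(x, smoothingSpan = 0) {
  wl <- wavelengths(x)
  refl <- if (is(x, "SimulatedSpectrum")) cbind(x@reflectance) else reflectance(x)
  step <- stats::median(diff(wl))
  apply1 <- function(r) {
    if (all(r == 0)) stop("undefined hue: all-zero spectrum")
    if (smoothingSpan > 0) {
      k <- max(1L, round(smoothingSpan / step))
      if (k %% 2 == 0) k <- k + 1L
      r <- as.numeric(stats::filter(r, rep(1 / k, k), sides = 2))
      r[is.na(r)] <- -Inf
    }
    wl[which.max(r)]       # which.max takes the first (shortest-wavelength) tie
  }
  out <- apply(refl, 2, apply1)
  if (is(x, "ReflectanceSpectra")) names(out) <- x@specimen$specimen_id
  out
}

#' Cone quantum catches of reflectance spectra
#'
#' For each spectrum and cone class i, computes the quantum catch
#' q_i = integral of R(lambda) C_i(lambda) I(lambda) d lambda by the
#' trapezoid rule on a 1 nm grid over the common support of the spectrum and
#' the visual system, plus relative catches normalised to sum to 1. A zero
#' catch in any class is an error (its logarithm is undefined downstream).
#'
#' @param x a [ReflectanceSpectra-class].
#' @param vs a [VisualSystem-class].
#' @param step quadrature grid step in nm (default 1).
#' @return A [QuantumCatch-class]; rows are specimens.
#' @export
quantumCatches <- function(x, vs, step = 1) {
  stopifnot(is(x, "ReflectanceSpectra"), is(vs, "VisualSystem"))
  lo <- max(min(x@wavelength), min(vs@wavelength))
  hi <- min(max(x@wavelength), max(vs@wavelength))
  grid <- seq(lo, hi, by = step)
  sens <- apply(vs@sensitivity, 2,
                function(s) .interpTo(vs@wavelength, s, grid))
  illum <- .interpTo(vs@wavelength, vs@illuminant, grid)
  q <- matrix(NA_real_, ncol(x@reflectance), ncol(sens),
              dimnames = list(x@specimen$specimen_id, colnames(sens)))
  for (j in seq_len(ncol(x@reflectance))) {
    r <- .interpTo(x@wavelength, x@reflectance[, j], grid)
    for (i in seq_len(ncol(sens)))
      q[j, i] <- .trapz(grid, r * sens[, i] * illum)
  }
  if (any(q <= 0))
    stop("zero quantum catch for specimen(s): ",
         paste(unique(rownames(q)[rowSums(q <= 0) > 0]), collapse = ", "))
  new("QuantumCatch", q = q, relative = q / rowSums(q))
}

#' Tetrahedral colour-space coordinates from relative catches
#'
#' Maps relative catches (u, s, m, l summing to 1) into the regular
#' tetrahedron with the u vertex on +Z at 0.75 and the achromatic point at
#' the origin:
#' X = ((1 - 2s - m - u)/2) sqrt(3/2), Y = (-1 + 3m + u) / (2 sqrt 2),
#' Z = u - 1/4.
#'
#' @param rel numeric vector of 4 relative catches in order u, s, m, l, or a
#'   matrix with those columns (e.g. from [relCatches()]).
#' @return matrix with columns X, Y, Z.
#' @export
tetraCoords <- function(rel) {
  if (is.null(dim(rel))) rel <- rbind(rel)
  if (ncol(rel) != 4) stop("need 4 relative catches (u, s, m, l)")
  if (any(abs(rowSums(rel) - 1) > 1e-9)) stop("relative catches must sum to 1")
  u <- rel[, 1]; s <- rel[, 2]; m <- rel[, 3]
  cbind(X = ((1 - 2 * s - m - u) / 2) * sqrt(3 / 2),
        Y = (-1 + 3 * m + u) / (2 * sqrt(2)),
        Z = u - 1 / 4)
}

# Channel noises e_i = weber * sqrt(n_ref / n_i).
.channelNoise <- function(vs) {
  n <- vs@density
  names(n) <- colnames(vs@sensitivity)
  vs@weber * sqrt(n[vs@refCone] / n)
}

# Receptor-noise metric M such that dS^2 = t(df) %*% M %*% df for
# df = ln(qA) - ln(qB). Null space is the all-ones vector. Works for any
# number of cone classes >= 2 (dichromat reduction included).
.noiseMetric <- function(e) {
  k <- length(e)
  A <- matrix(0, k, k)
  for (pr in utils::combn(k, 2, simplify = FALSE)) {
    j <- pr[1]; l <- pr[2]
    w <- prod(e[-c(j, l)]^2)          # empty product = 1 for the dichromat
    A[j, j] <- A[j, j] + w; A[l, l] <- A[l, l] + w
    A[j, l] <- A[j, l] - w; A[l, j] <- A[l, j] - w
  }
  den <- sum(vapply(seq_len(k), function(j) prod(e[-j]^2), numeric(1)))
  A / den
}

#' Receptor-noise limited colour distance (JND)
#'
#' The chromatic contrast between two stimuli under the receptor-noise
#' limited model: with ln-catch differences df_i = ln(q_i^A / q_i^B) and
#' channel noises e_i = omega sqrt(n_ref / n_i), the distance is the standard
#' quadratic form whose numerator sums, over cone pairs, the squared product
#' of the remaining channels' noises times (df_j - df_k)^2, and whose
#' denominator sums the squared noise products over cone triples. For two
#' cone classes this reduces to |df_1 - df_2| / sqrt(e_1^2 + e_2^2).
#'
#' @param qA,qB positive absolute quantum catch vectors (same cone order as
#'   the visual system).
#' @param vs a [VisualSystem-class] (supplies densities and Weber fraction).
#' @return the distance in JND (numeric scalar). Values above 1 are
#'   conventionally discriminable.
#' @export
receptorNoiseDistance <- function(qA, qB, vs) {
  qA <- as.numeric(qA); qB <- as.numeric(qB)
  if (any(qA <= 0) || any(qB <= 0)) stop("quantum catches must be positive")
  e <- .channelNoise(vs)
  if (length(qA) != length(e) || length(qB) != length(e))
    stop("catch vectors must match the number of cone classes")
  df <- log(qA) - log(qB)
  M <- .noiseMetric(e)
  sqrt(max(0, drop(t(df) %*% M %*% df)))
}

# Orthonormal basis of the subspace orthogonal to (1,...,1) (Helmert rows).
.contrastBasis <- function(k) {
  B <- matrix(0, k, k - 1L)
  for (j in seq_len(k - 1L)) {
    B[seq_len(j), j] <- 1
    B[j + 1L, j] <- -j
    B[, j] <- B[, j] / sqrt(j * (j + 1))
  }
  B
}

#' Noise-scaled (perceptually uniform) colour coordinates
#'
#' Maps quantum catches into a (k-1)-dimensional space in which ordinary
#' Euclidean distance equals the receptor-noise distance
#' [receptorNoiseDistance()] exactly: ln-catches are projected onto the
#' subspace orthogonal to (1,...,1) (making the coordinates invariant to
#' common scaling of the catches) and then transformed by a Cholesky factor
#' of the receptor-noise metric restricted to that subspace. For a
#' tetrachromat the result is 3-D JND-unit coordinates suitable as input to
#' transgression metrics and evolutionary rate estimation.
#'
#' @param q matrix of absolute catches (rows = specimens) or a single
#'   numeric vector; or a [QuantumCatch-class].
#' @param vs a [VisualSystem-class].
#' @return matrix with `k - 1` columns named `jnd1`, `jnd2`, ...
#' @export
noiseScaledCoords <- function(q, vs) {
  if (is(q, "QuantumCatch")) q <- catches(q)
  if (is.null(dim(q))) q <- rbind(q)
  if (any(q <= 0)) stop("quantum catches must be positive")
  e <- .channelNoise(vs)
  k <- length(e)
  if (ncol(q) != k) stop("catch columns must match cone classes")
  B <- .contrastBasis(k)
  M <- .noiseMetric(e)
  U <- chol(t(B) %*% M %*% B)
  out <- log(q) %*% B %*% t(U)
  colnames(out) <- paste0("jnd", seq_len(k - 1L))
  out
}

#' Bootstrapped colour distance between two groups of spectra
#'
#' Computes the receptor-noise distance between the geometric-mean quantum
#' catches of two specimen groups, with a nonparametric bootstrap over
#' specimens (resampled with replacement within each group) giving the mean
#' and 95% percentile confidence interval. The divergence is flagged
#' significant when the CI lower bound exceeds 1 JND.
#'
#' @param groupA,groupB [ReflectanceSpectra-class] objects with >= 2
#'   specimens each.
#' @param vs a [VisualSystem-class].
#' @param nBoot bootstrap replicates.
#' @param seed integer RNG seed (identical seeds give identical intervals).
#' @return A [ColourDistance-class].
#' @export
bootstrapGroupDistance <- function(groupA, groupB, vs, nBoot = 1000,
                                   seed = 1) {
  qA <- catches(quantumCatches(groupA, vs))
  qB <- catches(quantumCatches(groupB, vs))
  if (nrow(qA) < 2 || nrow(qB) < 2) stop("each group needs >= 2 spectra")
  geo <- function(q) exp(colMeans(log(q)))
  boot <- .withSeed(seed, vapply(seq_len(nBoot), function(b) {
    ia <- sample.int(nrow(qA), replace = TRUE)
    ib <- sample.int(nrow(qB), replace = TRUE)
    receptorNoiseDistance(geo(qA[ia, , drop = FALSE]),
                          geo(qB[ib, , drop = FALSE]), vs)
  }, numeric(1)))
  ci <- unname(quantile(boot, c(0.025, 0.975)))
  new("ColourDistance", dS = mean(boot), ci = ci, boot = boot,
      significant = ci[1] > 1)
}
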