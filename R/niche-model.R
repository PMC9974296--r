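## Presence-only ellipsoid niche models: robust minimum-volume-ellipsoid
## location/scatter in environmental space, Mahalanobis suitability surfaces
## thresholded at 90% data inclusion, Schoener's D overlap and a background
## similarity permutation test.

# Cell (row, col) of lon/lat points on an EnvGrid; NA outside the extent.
.cellOf <- function(env, lon, lat) {
  d <- dim(env@data); ex <- env@extent
  cw <- (ex["xmax"] - ex["xmin"]) / d[2]
  chh <- (ex["ymax"] - ex["ymin"]) / d[1]
  col <- floor((lon - ex["xmin"]) / cw) + 1L
  row <- floor((ex["ymax"] - lat) / chh) + 1L
  # points exactly on the max edge belong to the last cell
  col[lon == ex["xmax"]] <- d[2]; row[lat == ex["ymin"]] <- d[1]
  bad <- col < 1 | col > d[2] | row < 1 | row > d[1]
  row[bad] <- NA; col[bad] <- NA
  cbind(row = as.integer(row), col = as.integer(col))
}

# Cell-centre coordinates for every cell, in column-major cell order.
.cellCentres <- function(env) {
  d <- dim(env@data); ex <- env@extent
  cw <- (ex["xmax"] - ex["xmin"]) / d[2]
  chh <- (ex["ymax"] - ex["ymin"]) / d[1]
  idx <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  cbind(lon = ex["xmin"] + (idx$col - 0.5) * cw,
        lat = ex["ymax"] - (idx$row - 0.5) * chh)
}

#' Extract environmental values at occurrence points
#'
#' Nearest-cell extraction from an [EnvGrid-class]. Points falling outside
#' the grid or on no-data cells are dropped with a message; the count is
#' attached as attribute `dropped`.
#'
#' @param occ data.frame with `lon`, `lat` (and any other columns, kept).
#' @param env an [EnvGrid-class].
#' @return the occurrence data.frame with one numeric column per layer
#'   appended; attribute `dropped` holds the number of discarded points.
#' @export
extractEnv <- function(occ, env) {
  stopifnot(is(env, "EnvGrid"), all(c("lon", "lat") %in% names(occ)))
  rc <- .cellOf(env, occ$lon, occ$lat)
  nl <- length(env@layers)
  vals <- matrix(NA_real_, nrow(occ), nl, dimnames = list(NULL, env@layers))
  ok <- !is.na(rc[, 1])
  for (k in seq_len(nl))
    vals[ok, k] <- env@data[, , k][rc[ok, , drop = FALSE]]
  keep <- ok & rowSums(is.na(vals)) == 0
  nDrop <- sum(!keep)
  if (nDrop) message(nDrop, " point(s) off-grid or on no-data cells dropped")
  if (!any(keep)) stop("all points fall outside the data grid")
  out <- cbind(occ[keep, , drop = FALSE], as.data.frame(vals[keep, , drop = FALSE]))
  rownames(out) <- NULL
  attr(out, "dropped") <- nDrop
  out
}

#' Fit a minimum-volume-ellipsoid niche model
#'
#' Robust MVE location/scatter search: candidate ellipsoids are built from
#' (d + 1)-point subsets (exhaustive when few enough, else `nSubsets` seeded
#' random draws), each inflated to cover ceiling(coverage x n) points, and
#' the minimum-volume candidate is kept. The returned shape matrix is scaled
#' so the covered points satisfy Mahalanobis D^2 <= 1, and `t90` records the
#' squared-distance threshold containing at least 90% of the fitting points
#' (used by [suitabilityMap()] for the binary surface). Singular candidate
#' subsets are skipped. `method = "classical"` returns the ordinary
#' mean/covariance instead (non-robust).
#'
#' @param envMat numeric matrix (points x environmental axes), e.g. the
#'   layer columns of [extractEnv()] output; needs n >= d + 2 rows.
#' @param coverage fraction of points the ellipsoid must cover, in (0.5, 1].
#' @param nSubsets number of random candidate subsets.
#' @param seed integer RNG seed.
#' @param method `"mve"` (robust, default) or `"classical"`.
#' @return An [MVEModel-class].
#' @export
fitMVE <- function(envMat, coverage = 0.9, nSubsets = 500, seed = 1,
                   method = c("mve", "classical")) {
  method <- match.arg(method)
  envMat <- as.matrix(envMat)
  n <- nrow(envMat); d <- ncol(envMat)
  if (n < d + 2) stop("need at least d + 2 points to fit a ", d, "-D ellipsoid")
  if (coverage <= 0.5 || coverage > 1) stop("coverage must be in (0.5, 1]")
  hCov <- ceiling(coverage * n)
  finish <- function(centre, S) {
    d2 <- mahalanobis(envMat, centre, S)
    t90 <- sort(d2)[ceiling(0.9 * n)]
    new("MVEModel", centre = centre, shape = S, coverage = coverage,
        t90 = t90, layers = colnames(envMat) %||% paste0("env", seq_len(d)))
  }
  if (method == "classical")
    return(finish(colMeans(envMat), cov(envMat)))
  subsets <- if (choose(n, d + 1) <= 20000) {
    utils::combn(n, d + 1, simplify = FALSE)
  } else {
    .withSeed(seed, replicate(nSubsets, sample.int(n, d + 1),
                              simplify = FALSE))
  }
  best <- NULL; bestVol <- Inf
  for (sub in subsets) {
    pts <- envMat[sub, , drop = FALSE]
    m <- colMeans(pts); S <- cov(pts)
    detS <- suppressWarnings(det(S))
    if (!is.finite(detS) || detS <= 1e-300) next   # singular candidate
    d2 <- tryCatch(mahalanobis(envMat, m, S), error = function(e) NULL)
    if (is.null(d2)) next
    s <- sort(d2)[hCov]                 # inflation to cover hCov points
    if (!is.finite(s) || s <= 0) next
    logVol <- log(detS) + d * log(s)    # ellipsoid volume up to constants
    if (logVol < bestVol) { bestVol <- logVol; best <- list(m = m, S = S * s) }
  }
  if (is.null(best)) stop("all candidate subsets were singular")
  # reweighting step: recompute location/scatter from the points covered by
  # the best candidate ellipsoid (stabilises the raw (d+1)-subset estimate)
  d2 <- mahalanobis(envMat, best$m, best$S)
  covered <- d2 <= 1 + 1e-9
  mu <- colMeans(envMat[covered, , drop = FALSE])
  S <- cov(envMat[covered, , drop = FALSE])
  s <- sort(mahalanobis(envMat, mu, S))[hCov]
  finish(mu, S * s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gridded suitability from an ellipsoid niche model
#'
#' Per data cell x: squared Mahalanobis distance D^2 = (x - mu)' Sigma^-1
#' (x - mu); continuous suitability exp(-D^2 / 2) (1 at the niche centre);
#' binary suitability D^2 <= t90, the 90% data-inclusion threshold stored in
#' the model. By construction the binary surface contains at least 90% of
#' the fitting occurrences.
#'
#' @param model an [MVEModel-class].
#' @param env an [EnvGrid-class] whose layers match the model's axes.
#' @return A [SuitabilityMap-class].
#' @export
suitabilityMap <- function(model, env) {
  stopifnot(is(model, "MVEModel"), is(env, "EnvGrid"))
  d <- dim(env@data)
  if (length(model@centre) != d[3])
    stop("model dimensionality must match layer count")
  X <- matrix(env@data, d[1] * d[2], d[3])
  ok <- rowSums(is.na(X)) == 0
  d2 <- rep(NA_real_, nrow(X))
  d2[ok] <- mahalanobis(X[ok, , drop = FALSE], model@centre, model@shape)
  suit <- matrix(exp(-d2 / 2), d[1], d[2])
  binary <- matrix(!is.na(d2) & d2 <= model@t90, d[1], d[2])
  new("SuitabilityMap", suit = suit, binary = binary, extent = env@extent)
}

#' Schoener's D niche overlap between two suitability surfaces
#'
#' Both surfaces are normalised to sum to 1 over their shared data cells;
#' D = 1 - 0.5 sum |p_A - p_B|, from 0 (no overlap) to 1 (identical).
#'
#' @param a,b [SuitabilityMap-class] objects on identical grids (or plain
#'   numeric matrices).
#' @param mode `"continuous"` (default) uses the continuous suitability,
#'   `"binary"` the thresholded surface.
#' @return D in [0, 1].
#' @export
schoenersD <- function(a, b, mode = c("continuous", "binary")) {
  mode <- match.arg(mode)
  pick <- function(x) {
    if (is(x, "SuitabilityMap"))
      return(if (mode == "continuous") x@suit else x@binary * 1)
    as.matrix(x)
  }
  ma <- pick(a); mb <- pick(b)
  if (!all(dim(ma) == dim(mb))) stop("grids must be identical")
  ok <- !is.na(ma) & !is.na(mb)
  pa <- ma[ok]; pb <- mb[ok]
  if (sum(pa) <= 0 || sum(pb) <= 0) stop("zero-sum suitability map")
  pa <- pa / sum(pa); pb <- pb / sum(pb)
  1 - 0.5 * sum(abs(pa - pb))
}

# Indices (column-major cell order) of data cells whose centres fall inside
# a polygon ring.
.cellsInPolygon <- function(env, poly) {
  cc <- .cellCentres(env)
  inside <- .pointInPolygon(cc[, "lon"], cc[, "lat"], poly)
  X <- matrix(env@data, nrow(cc), dim(env@data)[3])
  which(inside & rowSums(is.na(X)) == 0)
}

#' Background similarity test for niche overlap
#'
#' Asks whether the observed niche overlap between two species exceeds what
#' random occurrence sets drawn from each species' accessible area (M)
#' would produce. Per direction (A then B): draw as many random data cells
#' within the focal species' M polygon as it has occurrences, fit a
#' pseudomodel, and compute Schoener's D between the pseudomodel's
#' suitability surface and the other species' true-model surface; repeat
#' `nReps` times. The add-one p-value is the proportion of null D values at
#' least as large as the observed D — small p supports niche similarity
#' beyond the background expectation.
#'
#' @param occA,occB occurrence data.frames (`lon`, `lat`).
#' @param mA,mB polygon vertex matrices (closed rings) for each species' M.
#' @param env an [EnvGrid-class].
#' @param nReps pseudomodel replicates per direction (>= 99).
#' @param seed integer RNG seed.
#' @param coverage,nSubsets passed to [fitMVE()].
#' @param mode surface used for D (see [schoenersD()]).
#' @return named list of two [OverlapResult-class] objects (`AtoB`: null
#'   from A's M; `BtoA`: null from B's M).
#' @export
backgroundSimilarityTest <- function(occA, occB, mA, mB, env, nReps = 99,
                                     seed = 1, coverage = 0.9,
                                     nSubsets = 200,
                                     mode = c("continuous", "binary")) {
  mode <- match.arg(mode)
  if (nReps < 99) stop("use nReps >= 99")
  eA <- extractEnv(occA, env); eB <- extractEnv(occB, env)
  envCols <- env@layers
  fit1 <- function(m, sd2) fitMVE(as.matrix(m[, envCols, drop = FALSE]),
                                  coverage, nSubsets, seed = sd2)
  mapA <- suitabilityMap(fit1(eA, seed), env)
  mapB <- suitabilityMap(fit1(eB, seed + 1L), env)
  obsD <- schoenersD(mapA, mapB, mode)
  cc <- .cellCentres(env)
  oneDirection <- function(occEnv, mPoly, otherMap, seedDir, label) {
    cells <- .cellsInPolygon(env, mPoly)
    nOcc <- nrow(occEnv)
    if (length(cells) < nOcc)
      stop("M polygon contains fewer data cells than occurrences")
    nullD <- .withSeed(seedDir, vapply(seq_len(nReps), function(b) {
      pick <- sample(cells, nOcc, replace = FALSE)
      pseudoOcc <- data.frame(lon = cc[pick, "lon"], lat = cc[pick, "lat"])
      pe <- suppressMessages(extractEnv(pseudoOcc, env))
      pm <- fitMVE(as.matrix(pe[, envCols, drop = FALSE]), coverage,
                   nSubsets, seed = b)
      schoenersD(suitabilityMap(pm, env), otherMap, mode)
    }, numeric(1)))
    p <- (1 + sum(nullD >= obsD)) / (nReps + 1)
    new("OverlapResult", D = obsD, null = nullD, p = p,
        nReps = as.integer(nReps), seed = as.integer(seedDir),
        direction = label)
  }
  list(AtoB = oneDirection(eA, mA, mapB, seed + 2L, "A->B"),
       BtoA = oneDirection(eB, mB, mapA, seed + 3L, "B->A"))
}

#' PCA of pooled environmental data
#'
#' Centred and scaled principal components of environmental vectors pooled
#' across species, delegating to [traitPCA()].
#'
#' @param envMats list (or single matrix) of points x layers matrices.
#' @return as [traitPCA()], plus `species`: the group label per score row
#'   when a named list was supplied.
#' @export
envPCA <- function(envMats) {
  if (is.matrix(envMats) || is.data.frame(envMats))
    envMats <- list(all = as.matrix(envMats))
  pooled <- do.call(rbind, lapply(envMats, as.matrix))
  out <- traitPCA(pooled, center = TRUE, scale. = TRUE)
  out$species <- rep(names(envMats), vapply(envMats, nrow, integer(1)))
  out
}
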