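#' Simulate environmental layers, occurrences and accessible areas
#'
#' Builds a self-contained niche-modelling system: `nEnvLayers` smooth
#' Gaussian-random-field environmental layers (white noise blurred with a
#' Gaussian kernel, then standardised to mean 0, sd 1), per-species
#' occurrences sampled with probability proportional to a Gaussian niche
#' density evaluated at each cell's environment, and per-species M
#' (accessible-area) polygons taken as the bounding box of the species'
#' occurrences buffered by `bufferCells` cells. Grid coordinates are
#' unprojected with unit cells: cell (row, col) has centre
#' (col - 0.5, rows - row + 0.5).
#'
#' @param gridShape c(rows, cols) of the raster grid.
#' @param nEnvLayers number of environmental layers (default 4: analogues of
#'   annual precipitation, precipitation seasonality, continentality and
#'   elevation).
#' @param nicheCentre list (one per species) of numeric niche optima in
#'   standardised environment units.
#' @param nicheCov list of symmetric positive-definite niche covariance
#'   matrices.
#' @param nOccurrences occurrences per species (scalar or vector); must be
#'   >= nEnvLayers + 2 so downstream ellipsoids are fittable.
#' @param smoothSigma Gaussian blur sd in cells (spatial autocorrelation
#'   scale).
#' @param bufferCells M-polygon buffer around the occurrence bounding box.
#' @param species species labels.
#' @param seed integer RNG seed.
#' @return list with `env` ([EnvGrid-class]), `occurrences` (data.frame
#'   `species,lon,lat`), and `M` (named list of polygon vertex matrices,
#'   closed rings).
#' @export
genNicheSystem <- function(gridShape = c(60, 80), nEnvLayers = 4,
                           nicheCentre = list(c(1, 1, 0, 0), c(-1, -1, 0, 0)),
                           nicheCov = NULL, nOccurrences = 40,
                           smoothSigma = 3, bufferCells = 2,
                           species = NULL, seed = 1) {
  nSp <- length(nicheCentre)
  if (is.null(species)) species <- paste0("sp", seq_len(nSp))
  if (is.null(nicheCov))
    nicheCov <- replicate(nSp, diag(0.25, nEnvLayers), simplify = FALSE)
  if (length(nOccurrences) == 1L) nOccurrences <- rep(nOccurrences, nSp)
  for (s in seq_len(nSp)) {
    if (length(nicheCentre[[s]]) != nEnvLayers)
      stop("niche centre length must equal nEnvLayers")
    S <- nicheCov[[s]]
    if (max(abs(S - t(S))) > 1e-9 ||
        min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("niche covariance must be symmetric positive-definite")
    if (nOccurrences[s] < nEnvLayers + 2)
      stop("need at least nEnvLayers + 2 occurrences per species")
  }
  rows <- gridShape[1]; cols <- gridShape[2]
  .withSeed(seed, {
    arr <- array(NA_real_, c(rows, cols, nEnvLayers))
    for (k in seq_len(nEnvLayers)) {
      m <- .gaussBlur(matrix(rnorm(rows * cols), rows, cols), smoothSigma)
      arr[, , k] <- (m - mean(m)) / sd(m)
    }
    env <- new("EnvGrid", data = arr,
               layers = paste0("env", seq_len(nEnvLayers)),
               extent = c(xmin = 0, xmax = cols, ymin = 0, ymax = rows))
    cellEnv <- matrix(arr, rows * cols, nEnvLayers)   # column-major cell order
    occ <- list(); M <- list()
    for (s in seq_len(nSp)) {
      w <- .dmvnorm(cellEnv, nicheCentre[[s]], nicheCov[[s]])
      idx <- sample.int(rows * cols, nOccurrences[s], replace = TRUE,
                        prob = w)
      row <- (idx - 1L) %% rows + 1L
      col <- (idx - 1L) %/% rows + 1L
      lon <- col - 0.5
      lat <- rows - row + 0.5
      occ[[s]] <- data.frame(species = species[s], lon = lon, lat = lat,
                             stringsAsFactors = FALSE)
      b <- bufferCells
      xr <- range(lon) + c(-b, b); yr <- range(lat) + c(-b, b)
      M[[species[s]]] <- cbind(
        x = c(xr[1], xr[2], xr[2], xr[1], xr[1]),
        y = c(yr[1], yr[1], yr[2], yr[2], yr[1]))
    }
    list(env = env, occurrences = do.call(rbind, occ), M = M)
  })
}

#' Environmental grid CSV serialisation
#'
#' Plain-text raster interchange: a one-line header comment encoding the grid
#' shape and extent, followed by a long-format CSV (`layer,row,col,value`).
#' `readEnvGrid()` inverts `writeEnvGrid()` exactly.
#'
#' @param env an [EnvGrid-class].
#' @param path file path.
#' @return `writeEnvGrid()` returns `path` invisibly; `readEnvGrid()` an
#'   [EnvGrid-class].
#' @export
writeEnvGrid <- function(env, path) {
  stopifnot(is(env, "EnvGrid"))
  d <- dim(env@data); ex <- env@extent
  hdr <- sprintf("# envgrid rows=%d cols=%d xmin=%.10g xmax=%.10g ymin=%.10g ymax=%.10g",
                 d[1], d[2], ex["xmin"], ex["xmax"], ex["ymin"], ex["ymax"])
  idx <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(hdr, "layer,row,col,value"), con)
  for (k in seq_len(d[3])) {
    vals <- env@data[, , k][cbind(idx$row, idx$col)]
    writeLines(sprintf("%s,%d,%d,%.17g", env@layers[k], idx$row, idx$col,
                       vals), con)
  }
  invisible(path)
}

#' @rdname writeEnvGrid
#' @export
readEnvGrid <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!grepl("^# envgrid ", hdr)) stop("not an envgrid file: missing header")
  kv <- regmatches(hdr, gregexpr("[a-z]+=[-0-9.e+]+", hdr))[[1]]
  vals <- setNames(as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  df <- read.csv(path, skip = 1L, stringsAsFactors = FALSE)
  layers <- unique(df$layer)
  arr <- array(NA_real_,
               c(unname(vals["rows"]), unname(vals["cols"]), length(layers)))
  for (k in seq_along(layers)) {
    sub <- df[df$layer == layers[k], ]
    arr[cbind(sub$row, sub$col, k)] <- sub$value
  }
  new("EnvGrid", data = arr, layers = layers,
      extent = vals[c("xmin", "xmax", "ymin", "ymax")])
}

#' Occurrence CSV serialisation (`species,lon,lat`)
#' @param occ data.frame with columns `species`, `lon`, `lat`.
#' @param path file path.
#' @return `writeOccurrences()` returns `path` invisibly.
#' @export
writeOccurrences <- function(occ, path) {
  stopifnot(all(c("species", "lon", "lat") %in% names(occ)))
  write.csv(occ[, c("species", "lon", "lat")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeOccurrences
#' @export
readOccurrences <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' M-polygon GeoJSON serialisation
#'
#' Writes a named list of polygon rings (2-column vertex matrices) as a
#' GeoJSON FeatureCollection with a `species` property per feature;
#' `readMPolygons()` inverts it.
#'
#' @param M named list of closed polygon vertex matrices.
#' @param path file path.
#' @return `writeMPolygons()` returns `path` invisibly; `readMPolygons()` a
#'   named list of vertex matrices.
#' @export
writeMPolygons <- function(M, path) {
  feats <- lapply(names(M), function(sp) {
    ring <- M[[sp]]
    if (!all(ring[1, ] == ring[nrow(ring), ]))
      ring <- rbind(ring, ring[1, ])
    list(type = "Feature", properties = list(species = sp),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(i) as.numeric(ring[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMPolygons
#' @export
readMPolygons <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  out <- list()
  for (f in gj$features) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) unlist(p)))
    colnames(ring) <- c("x", "y")
    out[[f$properties$species]] <- ring
  }
  out
}
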