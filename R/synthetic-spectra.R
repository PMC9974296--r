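#' Generate synthetic reflectance spectra as sums of Gaussian peaks
#'
#' Builds grouped reflectance spectra with known structure: each group is
#' defined by one (optionally two) Gaussian peaks in percent reflectance, and
#' each specimen is the group curve plus iid Gaussian noise, clipped at zero.
#' This emulates smooth iridescent plumage spectra — e.g. a gorget whose
#' colour difference between two species lies in the presence or absence of a
#' secondary short-wavelength peak — while keeping the generating truth known
#' for downstream colour-model tests.
#'
#' @param groups data.frame with columns `label`, `peak` (nm), `height`
#'   (percent reflectance, in (0, 100]), `width` (Gaussian sd, nm) and
#'   optionally `peak2`, `height2`, `width2` for a secondary peak (NA to
#'   omit).
#' @param nPerGroup specimens per group (>= 1).
#' @param noiseSd sd of additive reflectance noise, percent.
#' @param wavelength strictly increasing grid in nm within [300, 700].
#' @param seed integer RNG seed; identical seeds give identical spectra.
#' @return A [ReflectanceSpectra-class] whose specimen table carries the group
#'   labels.
#' @examples
#' g <- data.frame(label = c("sp1", "sp2"), peak = c(480, 560),
#'                 height = 30, width = 40)
#' sp <- genSpectra(g, nPerGroup = 5, noiseSd = 0.5, seed = 1)
#' sp
#' @export
genSpectra <- function(groups, nPerGroup = 10, noiseSd = 0.5,
                       wavelength = seq(300, 700, by = 1), seed = 1) {
  if (!is.data.frame(groups) || nrow(groups) == 0)
    stop("'groups' must be a non-empty data.frame")
  need <- c("label", "peak", "height", "width")
  if (!all(need %in% names(groups)))
    stop("'groups' needs columns: ", paste(need, collapse = ", "))
  if (nPerGroup < 1) stop("nPerGroup must be >= 1")
  if (any(groups$height <= 0 | groups$height > 100))
    stop("peak heights must be in (0, 100]")
  .withSeed(seed, {
    cols <- list(); meta <- list()
    for (gi in seq_len(nrow(groups))) {
      g <- groups[gi, ]
      base <- g$height * exp(-(wavelength - g$peak)^2 / (2 * g$width^2))
      if (!is.null(g$peak2) && !is.na(g$peak2))
        base <- base +
          g$height2 * exp(-(wavelength - g$peak2)^2 / (2 * g$width2^2))
      for (k in seq_len(nPerGroup)) {
        r <- base + rnorm(length(wavelength), 0, noiseSd)
        cols[[length(cols) + 1L]] <- pmax(r, 0)
        meta[[length(meta) + 1L]] <-
          data.frame(specimen_id = sprintf("%s_%02d", g$label, k),
                     group = g$label, stringsAsFactors = FALSE)
      }
    }
    new("ReflectanceSpectra", wavelength = wavelength,
        reflectance = do.call(cbind, cols),
        specimen = do.call(rbind, meta))
  })
}

#' Write / read spectra in the shared CSV dialect
#'
#' Column 1 is `wavelength_nm`; every further column is one specimen. Group
#' labels survive a round trip through an optional sidecar convention: column
#' names are `<group>_<nn>` when written from a generator, and
#' `readSpectra()` can recover groups with `groupFromName = TRUE`.
#'
#' @param x a [ReflectanceSpectra-class].
#' @param path CSV file path.
#' @return `writeSpectra()` returns `path` invisibly.
#' @seealso [readSpectra()]
#' @export
writeSpectra <- function(x, path) {
  stopifnot(is(x, "ReflectanceSpectra"))
  df <- data.frame(wavelength_nm = x@wavelength, x@reflectance,
                   check.names = FALSE)
  colnames(df) <- c("wavelength_nm", x@specimen$specimen_id)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Draw per-image nanostructure measurements around stated trait means
#'
#' Samples feather nanostructure traits (cortex, top platelet, melanin,
#' keratin spacing, air diameter, number of layers) independently from normal
#' distributions centred on supplied means, with sds derived from 95%
#' confidence half-widths as `halfwidth / 1.96`. Draws are truncated at zero
#' by rejection; layer counts are rounded to the nearest integer and floored
#' at 1. The bundled table of measured Heliodoxa trait means (see
#' [nanostructureMeans()]) supplies realistic defaults.
#'
#' @param taxonMeans data.frame with columns `trait`, `mean` and either
#'   `ci_lo`/`ci_hi` or `sd`. Trait names must include `cortex`, `pt_top`,
#'   `mel`, `ker`, `air`, `n_layers`.
#' @param nImages number of TEM images (rows) to simulate.
#' @param seed integer RNG seed.
#' @return data.frame with one row per image and one column per trait.
#' @export
genNanostructure <- function(taxonMeans, nImages = 10, seed = 1) {
  stopifnot(is.data.frame(taxonMeans),
            all(c("trait", "mean") %in% names(taxonMeans)))
  if (any(taxonMeans$mean <= 0)) stop("all trait means must be positive")
  if ("sd" %in% names(taxonMeans)) {
    sds <- taxonMeans$sd
  } else if (all(c("ci_lo", "ci_hi") %in% names(taxonMeans))) {
    sds <- (taxonMeans$ci_hi - taxonMeans$ci_lo) / 2 / 1.96
  } else stop("taxonMeans needs 'sd' or 'ci_lo'/'ci_hi' columns")
  if (any(sds < 0)) stop("trait sds must be >= 0")
  .withSeed(seed, {
    out <- lapply(seq_len(nrow(taxonMeans)), function(i) {
      m <- taxonMeans$mean[i]; s <- sds[i]
      if (s == 0) return(rep(m, nImages))
      draws <- numeric(0)
      while (length(draws) < nImages) {         # truncation at 0 by rejection
        cand <- rnorm(2L * nImages, m, s)
        draws <- c(draws, cand[cand > 0])
      }
      draws[seq_len(nImages)]
    })
    names(out) <- taxonMeans$trait
    df <- as.data.frame(out)
    if ("n_layers" %in% names(df))
      df$n_layers <- pmax(1L, as.integer(round(df$n_layers)))
    df
  })
}

#' Bundled nanostructure trait means for the three Heliodoxa phenotypes
#'
#' Returns the packaged summary table of feather nanostructure traits (means
#' and 95% confidence intervals of within-individual variation, nm except for
#' layer counts) for *Heliodoxa branickii*, *H. gularis* and the putative
#' backcross hybrid, for the crown, gorget and tail patches. These values
#' parameterise realistic optical-model inputs and the synthetic
#' nanostructure generator.
#'
#' @param taxon optional filter: one of `"branickii"`, `"hybrid"`,
#'   `"gularis"`.
#' @param patch optional filter: `"crown"`, `"gorget"` or `"tail"`.
#' @return data.frame with columns `taxon`, `patch`, `trait`, `mean`,
#'   `ci_lo`, `ci_hi`.
#' @examples
#' nanostructureMeans("branickii", "gorget")
#' @export
nanostructureMeans <- function(taxon = NULL, patch = NULL) {
  path <- system.file("extdata", "heliodoxa_nanostructure_means.csv",
                      package = "transgressr", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(taxon)) df <- df[df$taxon == taxon, , drop = FALSE]
  if (!is.null(patch)) df <- df[df$patch == patch, , drop = FALSE]
  rownames(df) <- NULL
  df
}
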