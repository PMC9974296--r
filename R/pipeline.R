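## Configuration and orchestration: run the synthetic demo pipeline (or any
## subset of stages) reproducibly from a single YAML config and a single
## global seed that fans out to per-stage seeds.

.stageOrder <- function() c("simulate", "colour", "optics", "divergence",
                            "rate", "ancestry", "niche")

#' Default pipeline configuration
#'
#' The full parameter block tree consumed by [runPipeline()], mirroring every
#' stage's defaults. The global `seed` fans out as `seed + stage index`, so
#' stages can be rerun independently yet reproducibly.
#'
#' @return nested named list.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    outDir = "transgressr_out",
    spectra = list(nPerGroup = 10L, noiseSd = 0.5,
                   peak1 = 480, peak2 = 560, height = 30, width = 40),
    colour = list(nBoot = 500L),
    optics = list(sliceThickness = 1, airShape = "block", lateralFill = 1,
                  angle = 0),
    cross = list(nLoci = 1000L, nParentalPerSpecies = 5L,
                 crossType = "BC3_P1", missingRate = 0),
    tree = list(nTips = 50L, totalDepth = 10, sigma2True = 0.005,
                nAxes = 3L, nPerm = 199L),
    niche = list(rows = 60L, cols = 80L, nOccurrences = 40L, nReps = 99L,
                 coverage = 0.9)
  )
}

# Recursive merge of user config into defaults; unknown keys and type
# mismatches are errors so typos never silently fall back to defaults.
.mergeConfig <- function(def, usr, path = "") {
  for (k in names(usr)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(def)) stop("unknown config key: '", full, "'")
    if (is.list(def[[k]])) {
      if (!is.list(usr[[k]]))
        stop("config key '", full, "' must be a parameter block")
      def[[k]] <- .mergeConfig(def[[k]], usr[[k]], full)
    } else {
      if (is.list(usr[[k]]) || length(usr[[k]]) != 1)
        stop("config key '", full, "' must be a single ",
             if (is.numeric(def[[k]])) "numeric" else "character", " value")
      if (is.numeric(def[[k]]) && !is.numeric(usr[[k]]))
        stop("config key '", full, "' must be a single numeric value")
      if (is.character(def[[k]]) && !is.character(usr[[k]]))
        stop("config key '", full, "' must be a single character value")
      def[[k]] <- usr[[k]]
    }
  }
  def
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, validates it against [defaultPipelineConfig()]
#' (unknown keys and type mismatches are errors naming the offending key),
#' fills unspecified values with defaults and echoes the effective
#' configuration to the message stream. An empty file yields the full
#' default configuration.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @param quiet suppress the effective-config echo.
#' @return validated nested list.
#' @export
loadConfig <- function(path = NULL, quiet = FALSE) {
  usr <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(usr)) usr <- list()
  cfg <- .mergeConfig(defaultPipelineConfig(), usr)
  if (!quiet)
    message("effective config:\n", yaml::as.yaml(cfg))
  cfg
}

#' Write a configuration back to YAML
#' @param cfg configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the analysis pipeline on synthetic data
#'
#' Executes the requested stages in dependency order inside `cfg$outDir`:
#' `simulate` generates every fixture (spectra CSV, nanostructure CSV,
#' genotypes VCF + population map, Newick tree + tip traits, environmental
#' grid + occurrences + M polygons); `colour` computes bootstrapped group
#' colour distances; `optics` simulates spectra from the nanostructure
#' table; `divergence` computes transgression metrics in noise-scaled colour
#' space; `rate` estimates the Brownian rate and phylogenetic signal;
#' `ancestry` estimates hybrid index/heterozygosity from the VCF; `niche`
#' fits ellipsoid models and runs the background similarity test. Rerunning
#' with an identical configuration reproduces every artefact hash.
#'
#' @param cfg configuration from [loadConfig()] /
#'   [defaultPipelineConfig()].
#' @param stages subset of stages to run (dependencies must already have
#'   produced their artefacts).
#' @return data.frame manifest: stage, artifact, path, md5, seed.
#' @export
runPipeline <- function(cfg = defaultPipelineConfig(),
                        stages = .stageOrder()) {
  all <- .stageOrder()
  bad <- setdiff(stages, all)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- all[all %in% stages]
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(cfg$outDir, f)
  needs <- function(f) {
    if (!file.exists(art(f)))
      stop("missing upstream artefact '", f, "': run the simulate stage first")
    art(f)
  }
  stageSeed <- function(s) as.integer(cfg$seed) + match(s, all)
  manifest <- list()
  note <- function(stage, f, seed) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, artifact = f, path = art(f),
      md5 = unname(tools::md5sum(art(f))), seed = seed,
      stringsAsFactors = FALSE)
  }

  if ("simulate" %in% stages) {
    sd0 <- stageSeed("simulate")
    sp <- cfg$spectra
    groups <- data.frame(label = c("parent1", "parent2"),
                         peak = c(sp$peak1, sp$peak2),
                         height = sp$height, width = sp$width)
    writeSpectra(genSpectra(groups, sp$nPerGroup, sp$noiseSd, seed = sd0),
                 art("spectra.csv"))
    nano <- do.call(rbind, lapply(
      c("branickii", "hybrid", "gularis"), function(tx) {
        tm <- nanostructureMeans(tx, "gorget")
        cbind(taxon = tx, genNanostructure(tm, nImages = 5, seed = sd0))
      }))
    write.csv(nano, art("nanostructure.csv"), row.names = FALSE)
    cr <- genCross(cfg$cross$nLoci, cfg$cross$nParentalPerSpecies,
                   cfg$cross$crossType, missingRate = cfg$cross$missingRate,
                   seed = sd0)
    writeGenotypesVCF(cr$gm, art("genotypes.vcf"))
    write.csv(data.frame(sample = colnames(genotypes(cr$gm)),
                         population = populations(cr$gm)),
              art("popmap.csv"), row.names = FALSE)
    write.csv(cr$truth, art("cross_truth.csv"), row.names = FALSE)
    tt <- genTreeTraits(cfg$tree$nTips, cfg$tree$totalDepth,
                        cfg$tree$sigma2True, cfg$tree$nAxes, seed = sd0)
    ape::write.tree(tt$tree, art("tree.nwk"))
    writeTipTraits(tt$traits, art("tip_traits.csv"))
    ns <- genNicheSystem(c(cfg$niche$rows, cfg$niche$cols),
                         nOccurrences = cfg$niche$nOccurrences, seed = sd0)
    writeEnvGrid(ns$env, art("envgrid.csv"))
    writeOccurrences(ns$occurrences, art("occurrences.csv"))
    writeMPolygons(ns$M, art("m_polygons.geojson"))
    for (f in c("spectra.csv", "nanostructure.csv", "genotypes.vcf",
                "popmap.csv", "cross_truth.csv", "tree.nwk",
                "tip_traits.csv", "envgrid.csv", "occurrences.csv",
                "m_polygons.geojson"))
      note("simulate", f, sd0)
  }

  if ("colour" %in% stages) {
    sd1 <- stageSeed("colour")
    spx <- readSpectra(needs("spectra.csv"))
    vs <- avianVisualSystem()
    gs <- unique(specimenInfo(spx)$group)
    cd <- bootstrapGroupDistance(spx[specimenInfo(spx)$group == gs[1]],
                                 spx[specimenInfo(spx)$group == gs[2]],
                                 vs, nBoot = cfg$colour$nBoot, seed = sd1)
    write.csv(data.frame(groupA = gs[1], groupB = gs[2], dS = cd@dS,
                         ci_lo = cd@ci[1], ci_hi = cd@ci[2],
                         significant = cd@significant),
              art("colour_distances.csv"), row.names = FALSE)
    note("colour", "colour_distances.csv", sd1)
  }

  if ("optics" %in% stages) {
    nano <- read.csv(needs("nanostructure.csv"), stringsAsFactors = FALSE)
    op <- cfg$optics
    sims <- lapply(seq_len(nrow(nano)), function(i) {
      p <- nanostructure(nano$cortex[i], nano$pt_top[i], nano$mel[i],
                         nano$ker[i], nano$air[i], nano$n_layers[i],
                         airShape = op$airShape,
                         lateralFill = op$lateralFill)
      simulateFeatherSpectrum(p, sliceThickness = op$sliceThickness,
                              angle = op$angle)
    })
    wl <- wavelengths(sims[[1]])
    out <- data.frame(wavelength_nm = wl,
                      vapply(sims, reflectance, numeric(length(wl))) * 100)
    colnames(out) <- c("wavelength_nm",
                       sprintf("%s_%02d", nano$taxon,
                               stats::ave(seq_len(nrow(nano)), nano$taxon,
                                          FUN = seq_along)))
    write.csv(out, art("simulated_spectra.csv"), row.names = FALSE)
    note("optics", "simulated_spectra.csv", stageSeed("optics"))
  }

  if ("divergence" %in% stages) {
    spx <- readSpectra(needs("spectra.csv"))
    vs <- avianVisualSystem()
    q <- quantumCatches(spx, vs)
    coords <- noiseScaledCoords(q, vs)
    grp <- specimenInfo(spx)$group
    gs <- unique(grp)
    tab <- data.frame(coords,
                      group = ifelse(grp == gs[1], "parent1", "parent2"))
    # demo focal point: the first specimen doubles as the 'hybrid' row
    hyb <- tab[1, , drop = FALSE]
    hyb$group <- "hybrid"
    dv <- averagePairwiseDivergence(rbind(tab, hyb))
    write.csv(dv@pairs, art("divergence_pairs.csv"), row.names = FALSE)
    note("divergence", "divergence_pairs.csv", stageSeed("divergence"))
  }

  if ("rate" %in% stages) {
    sd4 <- stageSeed("rate")
    tree <- ape::read.tree(needs("tree.nwk"))
    traits <- readTipTraits(needs("tip_traits.csv"))
    re <- multivariateRate(tree, traits)
    sig <- blombergK(tree, traits, nPerm = cfg$tree$nPerm, seed = sd4)
    jsonlite::write_json(
      list(sigma2 = re@sigma2, n_nodes = re@nNodes, K = sig@K, p = sig@p),
      art("rate_report.json"), auto_unbox = TRUE, digits = NA)
    note("rate", "rate_report.json", sd4)
  }

  if ("ancestry" %in% stages) {
    popMap <- read.csv(needs("popmap.csv"), stringsAsFactors = FALSE)
    gm <- readGenotypes(needs("genotypes.vcf"), popMap)
    gm <- filterSNPs(gm)
    dl <- diagnosticLoci(gm)
    est <- hybridIndex(dl)
    cls <- classifyHybrid(est@h, est@het)
    jsonlite::write_json(
      list(n_input_loci = length(gm@loci), n_diagnostic = length(dl@loci),
           h = est@h, ci = est@ci, het = est@het, class = cls$class),
      art("ancestry_report.json"), auto_unbox = TRUE, digits = NA)
    note("ancestry", "ancestry_report.json", stageSeed("ancestry"))
  }

  if ("niche" %in% stages) {
    sd6 <- stageSeed("niche")
    env <- readEnvGrid(needs("envgrid.csv"))
    occ <- readOccurrences(needs("occurrences.csv"))
    M <- readMPolygons(needs("m_polygons.geojson"))
    sps <- unique(occ$species)
    res <- backgroundSimilarityTest(occ[occ$species == sps[1], ],
                                    occ[occ$species == sps[2], ],
                                    M[[sps[1]]], M[[sps[2]]], env,
                                    nReps = cfg$niche$nReps, seed = sd6,
                                    coverage = cfg$niche$coverage)
    jsonlite::write_json(
      list(D_obs = res$AtoB@D,
           p_AtoB = res$AtoB@p, p_BtoA = res$BtoA@p,
           n_reps = res$AtoB@nReps),
      art("niche_report.json"), auto_unbox = TRUE, digits = NA)
    note("niche", "niche_report.json", sd6)
  }

  do.call(rbind, manifest)
}
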