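test_that("noise-free spectra peak exactly at the specified wavelength", {
  g <- data.frame(label = "only", peak = 550, height = 40, width = 30)
  sp <- genSpectra(g, nPerGroup = 5, noiseSd = 0, seed = 1)
  expect_true(all(huePeak(sp) == 550))
  expect_true(all(reflectance(sp) >= 0))
})

test_that("spectrum generation is deterministic per seed and rejects bad specs", {
  a <- twoGroupSpec(seed = 7)
  b <- twoGroupSpec(seed = 7)
  expect_identical(reflectance(a), reflectance(b))
  c <- twoGroupSpec(seed = 8)
  expect_false(identical(reflectance(a), reflectance(c)))
  expect_error(genSpectra(data.frame()), "non-empty")
  g <- data.frame(label = "x", peak = 500, height = 150, width = 30)
  expect_error(genSpectra(g), "heights")
})

test_that("secondary peaks and zero-clipping are honoured", {
  g <- data.frame(label = "dbl", peak = 560, height = 30, width = 25,
                  peak2 = 450, height2 = 15, width2 = 20)
  sp <- genSpectra(g, nPerGroup = 1, noiseSd = 0, seed = 1)
  expect_gt(secondaryPeakProminence(sp, c(400, 500)), 10)
  spN <- genSpectra(data.frame(label = "n", peak = 500, height = 1,
                               width = 10),
                    nPerGroup = 3, noiseSd = 5, seed = 2)
  expect_true(all(reflectance(spN) >= 0))   # noise clipped at zero
})

test_that("bundled trait means match the published summary and feed the generator", {
  bg <- nanostructureMeans("branickii", "gorget")
  m <- setNames(bg$mean, bg$trait)
  expect_equal(unname(m[c("air", "cortex", "n_layers")]), c(126, 173, 9))
  # zero CI half-width -> degenerate distribution
  bg0 <- transform(bg, ci_lo = mean, ci_hi = mean)
  d <- genNanostructure(bg0, nImages = 4, seed = 1)
  expect_true(all(d$air == 126) && all(d$cortex == 173))
  expect_true(is.integer(d$n_layers) && all(d$n_layers >= 1))
})

test_that("nanostructure draws recover the stated mean (CLT check)", {
  tm <- data.frame(trait = "air", mean = 100, ci_lo = 100 - 1.96 * 15,
                   ci_hi = 100 + 1.96 * 15)
  d <- genNanostructure(tm, nImages = 10000, seed = 3)
  se <- 15 / sqrt(10000)
  expect_lt(abs(mean(d$air) - 100), 3 * se + 0.05)  # slight truncation bias allowed
  expect_error(genNanostructure(transform(tm, mean = -1)), "positive")
})

test_that("F1 and parental crosses have exact realised ancestry", {
  f1 <- genCross(500, 3, "F1", seed = 1)
  expect_equal(f1$truth$h, 0.5)
  expect_equal(f1$truth$het, 1.0)
  p1 <- genCross(100, 2, "P1", seed = 2)
  expect_equal(c(p1$truth$h, p1$truth$het), c(0, 0))
  p2 <- genCross(100, 2, "P2", seed = 3)
  expect_equal(c(p2$truth$h, p2$truth$het), c(1, 0))
  expect_error(genCross(100, 2, "F3"), "cross_type")
  expect_error(genCross(100, 2, "F1", missingRate = 1), "missingRate")
})

test_that("BC1 realised ancestry matches Mendelian expectations", {
  tr <- t(vapply(1:200, function(i) {
    x <- genCross(1000, 1, "BC1_P1", seed = i)
    c(x$truth$h, x$truth$het)
  }, numeric(2)))
  # per-locus gamete enumeration: h = (0 + Bernoulli(1/2))/2, het = Bern(1/2)
  seH <- sqrt(0.25 * 0.75 / (2 * 1000)) / sqrt(200) * sqrt(2)  # conservative
  expect_lt(abs(mean(tr[, 1]) - 0.25), 3 * sqrt(var(tr[, 1]) / 200))
  expect_lt(abs(mean(tr[, 2]) - 0.5), 3 * sqrt(var(tr[, 2]) / 200))
})

test_that("cross generation is deterministic and respects missingness", {
  a <- genCross(200, 2, "F2", missingRate = 0.2, seed = 5)
  b <- genCross(200, 2, "F2", missingRate = 0.2, seed = 5)
  expect_identical(genotypes(a$gm), genotypes(b$gm))
  fracNA <- mean(is.na(genotypes(a$gm)))
  expect_lt(abs(fracNA - 0.2), 0.05)
})

test_that("tree+trait generation obeys Brownian closed forms", {
  z <- genTreeTraits(10, totalDepth = 5, sigma2True = 0, seed = 1)
  expect_true(all(z$traits == 0))                    # zero variance
  a <- genTreeTraits(12, 8, 0.01, seed = 4)
  b <- genTreeTraits(12, 8, 0.01, seed = 4)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$traits, b$traits)
  expect_true(ape::is.ultrametric(a$tree, tol = 1e-8))
  expect_equal(max(ape::node.depth.edgelength(a$tree)), 8)
  # 2-tip tree at depth t: Var(x1 - x2) = 2 sigma2 t per axis
  t <- 3; s <- 0.02
  d <- vapply(1:500, function(i) {
    x <- genTreeTraits(2, t, s, nAxes = 1, seed = 1000 + i)
    x$traits[1, 1] - x$traits[2, 1]
  }, numeric(1))
  expect_lt(abs(var(d) - 2 * s * t), 4 * (2 * s * t) * sqrt(2 / 499))
})

test_that("niche system generation succeeds at the minimal size with full-rank env", {
  ns <- genNicheSystem(gridShape = c(30, 30), nEnvLayers = 4,
                       nOccurrences = 6, seed = 2)
  e <- extractEnv(ns$occurrences[ns$occurrences$species == "sp1", ], ns$env)
  S <- cov(as.matrix(e[, ns$env@layers]))
  expect_equal(qr(S)$rank, 4)
  expect_error(genNicheSystem(nOccurrences = 4), "at least")
  badCov <- replicate(2, matrix(1, 4, 4), simplify = FALSE)
  expect_error(genNicheSystem(nicheCov = badCov), "positive-definite")
})

test_that("well-separated niches give disjoint thresholded maps", {
  ns <- genNicheSystem(gridShape = c(50, 60), nOccurrences = 40,
                       nicheCentre = list(c(3, 0, 0, 0), c(-3, 0, 0, 0)),
                       nicheCov = replicate(2, diag(0.25, 4),
                                            simplify = FALSE),
                       seed = 6)
  occ <- ns$occurrences
  maps <- lapply(c("sp1", "sp2"), function(sp) {
    e <- extractEnv(occ[occ$species == sp, ], ns$env)
    suitabilityMap(fitMVE(as.matrix(e[, ns$env@layers]), seed = 1), ns$env)
  })
  expect_equal(sum(maps[[1]]@binary & maps[[2]]@binary), 0)
})

test_that("all synthetic artefacts round-trip through their writers and readers", {
  tmp <- withr::local_tempdir()
  # spectra
  sp <- twoGroupSpec(nPerGroup = 3, seed = 1)
  f <- file.path(tmp, "s.csv"); writeSpectra(sp, f)
  sp2 <- readSpectra(f)
  expect_equal(wavelengths(sp2), wavelengths(sp))
  expect_equal(unname(reflectance(sp2)), unname(reflectance(sp)),
               tolerance = 1e-12)
  expect_equal(specimenInfo(sp2)$group, specimenInfo(sp)$group)
  # genotypes (VCF)
  x <- genCross(40, 2, "F2", missingRate = 0.1, seed = 7)
  fv <- file.path(tmp, "g.vcf"); writeGenotypesVCF(x$gm, fv)
  pm <- data.frame(sample = colnames(genotypes(x$gm)),
                   population = populations(x$gm))
  gm2 <- readGenotypes(fv, pm)
  expect_identical(unname(genotypes(gm2)), unname(genotypes(x$gm)))
  expect_identical(populations(gm2), populations(x$gm))
  # tree + traits
  tt <- genTreeTraits(8, 5, 0.01, seed = 2)
  ft <- file.path(tmp, "t.nwk"); ape::write.tree(tt$tree, ft)
  expect_setequal(ape::read.tree(ft)$tip.label, tt$tree$tip.label)
  fc <- file.path(tmp, "tr.csv"); writeTipTraits(tt$traits, fc)
  expect_equal(readTipTraits(fc), tt$traits, tolerance = 1e-12)
  # env grid, occurrences, polygons
  ns <- genNicheSystem(gridShape = c(12, 15), nOccurrences = 8, seed = 3)
  fe <- file.path(tmp, "e.csv"); writeEnvGrid(ns$env, fe)
  e2 <- readEnvGrid(fe)
  expect_equal(gridData(e2), gridData(ns$env), tolerance = 1e-12)
  expect_equal(gridExtent(e2), gridExtent(ns$env))
  fo <- file.path(tmp, "o.csv"); writeOccurrences(ns$occurrences, fo)
  expect_equal(readOccurrences(fo), ns$occurrences)
  fp <- file.path(tmp, "m.geojson"); writeMPolygons(ns$M, fp)
  M2 <- readMPolygons(fp)
  expect_equal(lapply(M2, unname), lapply(ns$M, unname), tolerance = 1e-12)
})
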