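test_that("environment extraction is exact nearest-cell indexing", {
  ns <- genNicheSystem(gridShape = c(20, 25), nOccurrences = 10, seed = 1)
  env <- ns$env
  # a point at a known cell centre returns that cell's values exactly
  pt <- data.frame(lon = 3.5, lat = 19.5)   # col 4, row 1
  e <- extractEnv(pt, env)
  expect_equal(as.numeric(e[1, env@layers]),
               as.numeric(gridData(env)[1, 4, ]))
  # off-grid points are dropped and counted
  far <- data.frame(lon = c(3.5, -10), lat = c(19.5, 19.5))
  expect_message(e2 <- extractEnv(far, env), "1 point\\(s\\)")
  expect_equal(nrow(e2), 1L)
  expect_equal(attr(e2, "dropped"), 1L)
  expect_error(suppressMessages(
    extractEnv(data.frame(lon = -5, lat = -5), env)), "outside")
  # random points match a direct indexing oracle
  set.seed(4)
  pts <- data.frame(lon = runif(100, 0, 25), lat = runif(100, 0, 20))
  e3 <- extractEnv(pts, env)
  col <- floor(pts$lon) + 1L
  row <- floor(20 - pts$lat) + 1L
  oracle <- vapply(seq_len(100),
                   function(i) gridData(env)[row[i], col[i], 1],
                   numeric(1))
  expect_equal(e3$env1, oracle)
})

test_that("MVE fitting is seeded, centred and robust to gross outliers", {
  set.seed(42)
  X <- matrix(rnorm(80 * 3), 80, 3)
  m1 <- fitMVE(X, coverage = 0.9, seed = 5)
  m2 <- fitMVE(X, coverage = 0.9, seed = 5)
  expect_identical(m1@centre, m2@centre)
  expect_identical(m1@shape, m2@shape)
  # clean data: centre near the sample mean
  expect_lt(sqrt(sum((m1@centre - colMeans(X))^2)), 3 * sqrt(3 / 80))
  # 10% gross outliers at 20 SD barely move the MVE centre
  Xc <- rbind(X, matrix(rnorm(8 * 3, mean = 20), 8, 3))
  mr <- fitMVE(Xc, coverage = 0.9, seed = 1)
  dRobust <- sqrt(sum((mr@centre - colMeans(X))^2))
  dClassical <- sqrt(sum((colMeans(Xc) - colMeans(X))^2))
  expect_lt(dRobust, dClassical)
  # agreement with the independent reference implementation
  ref <- MASS::cov.mve(X, quantile.used = ceiling(0.9 * nrow(X)))
  expect_lt(sqrt(sum((m1@centre - ref$center)^2)), 0.6)
  expect_error(fitMVE(X[1:3, ]), "at least")
  expect_error(fitMVE(X, coverage = 0.4), "coverage")
})

test_that("suitability surfaces follow the Mahalanobis geometry", {
  # hand-constructed model: diagonal shape, offset (2, 3) -> D^2 = 2
  model <- methods::new("MVEModel", centre = c(0, 0),
                        shape = diag(c(4, 9)), coverage = 0.9, t90 = 3,
                        layers = c("env1", "env2"))
  arr <- array(0, c(1, 2, 2))
  arr[1, 2, ] <- c(2, 3)
  env <- methods::new("EnvGrid", data = arr, layers = c("env1", "env2"),
                      extent = c(xmin = 0, xmax = 2, ymin = 0, ymax = 1))
  sm <- suitabilityMap(model, env)
  expect_equal(sm@suit[1, 1], 1)                    # at the centre
  expect_equal(sm@suit[1, 2], exp(-1))              # D^2 = 1 + 1 = 2
  expect_true(sm@binary[1, 1] && sm@binary[1, 2])
  # the binary surface contains >= 90% of the fitting occurrences
  ns <- genNicheSystem(gridShape = c(30, 40), nOccurrences = 50, seed = 9)
  occ <- ns$occurrences[ns$occurrences$species == "sp1", ]
  e <- extractEnv(occ, ns$env)
  mv <- fitMVE(as.matrix(e[, ns$env@layers]), seed = 2)
  sm2 <- suitabilityMap(mv, ns$env)
  rc <- cbind(floor(30 - occ$lat) + 1L, floor(occ$lon) + 1L)
  expect_gte(mean(sm2@binary[rc]), 0.9)
})

test_that("suitability is invariant to affine rescaling of a layer", {
  ns <- genNicheSystem(gridShape = c(25, 30), nOccurrences = 30, seed = 3)
  occ <- ns$occurrences[ns$occurrences$species == "sp1", ]
  e <- as.matrix(extractEnv(occ, ns$env)[, ns$env@layers])
  m1 <- suitabilityMap(fitMVE(e, seed = 4), ns$env)
  # rescale layer 1 everywhere and refit
  e2 <- e; e2[, 1] <- 10 * e2[, 1] - 3
  envR <- ns$env
  envR@data[, , 1] <- 10 * envR@data[, , 1] - 3
  m2 <- suitabilityMap(fitMVE(e2, seed = 4), envR)
  expect_equal(m2@suit, m1@suit, tolerance = 1e-8)
})

test_that("Schoener's D has its closed-form anchors and symmetry", {
  a <- matrix(c(1, 0), 1); b <- matrix(c(0.5, 0.5), 1)
  expect_equal(schoenersD(a, b), 0.5)               # hand arithmetic
  expect_equal(schoenersD(a, a), 1)
  expect_equal(schoenersD(a, b), schoenersD(b, a))
  disjA <- matrix(c(1, 0, 0, 0), 2); disjB <- matrix(c(0, 0, 0, 1), 2)
  expect_equal(schoenersD(disjA, disjB), 0)
  expect_error(schoenersD(a, matrix(0, 1, 2)), "zero-sum")
  expect_error(schoenersD(a, matrix(1, 2, 2)), "identical")
})

test_that("background similarity test separates similar from dissimilar niches", {
  # dissimilar: niches 6 SD apart -> observed D not in the upper tail
  ns <- genNicheSystem(gridShape = c(40, 50), nOccurrences = 30,
                       nicheCentre = list(c(1.5, 0, 0, 0),
                                          c(-1.5, 0, 0, 0)),
                       nicheCov = replicate(2, diag(0.25, 4),
                                            simplify = FALSE),
                       seed = 12)
  occ <- ns$occurrences
  res <- backgroundSimilarityTest(occ[occ$species == "sp1", ],
                                  occ[occ$species == "sp2", ],
                                  ns$M$sp1, ns$M$sp2, ns$env,
                                  nReps = 99, seed = 7, nSubsets = 100)
  expect_gt(res$AtoB@p, 0.05)
  expect_equal(res$AtoB@nReps, 99L)
  expect_length(res$AtoB@null, 99)
  # seeded determinism of the null distribution
  res2 <- backgroundSimilarityTest(occ[occ$species == "sp1", ],
                                   occ[occ$species == "sp2", ],
                                   ns$M$sp1, ns$M$sp2, ns$env,
                                   nReps = 99, seed = 7, nSubsets = 100)
  expect_identical(res$AtoB@null, res2$AtoB@null)
  expect_error(backgroundSimilarityTest(occ[occ$species == "sp1", ],
                                        occ[occ$species == "sp2", ],
                                        ns$M$sp1, ns$M$sp2, ns$env,
                                        nReps = 10), "nReps")
})

test_that("environmental PCA separates species along a constructed axis", {
  set.seed(6)
  eA <- cbind(l1 = rnorm(40, 3), l2 = rnorm(40), l3 = rnorm(40))
  eB <- cbind(l1 = rnorm(40, -3), l2 = rnorm(40), l3 = rnorm(40))
  p <- envPCA(list(A = eA, B = eB))
  expect_equal(t(p$loadings) %*% p$loadings, diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(p$varExplained), 1, tolerance = 1e-12)
  pc1 <- p$scores[, 1]
  expect_gt(abs(mean(pc1[p$species == "A"]) - mean(pc1[p$species == "B"])),
            1)
  expect_gt(abs(p$loadings["l1", 1]), max(abs(p$loadings[c("l2", "l3"), 1])))
})
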