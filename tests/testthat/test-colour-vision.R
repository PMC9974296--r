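vs <- avianVisualSystem()

test_that("spectra reader validates its dialect", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  sp <- twoGroupSpec(nPerGroup = 2, seed = 1)
  writeSpectra(sp, tmp)
  rt <- readSpectra(tmp)
  expect_s4_class(rt, "ReflectanceSpectra")
  expect_equal(length(wavelengths(rt)), 401)      # 300-700 at 1 nm
  # negative value -> error naming the specimen
  df <- read.csv(tmp, check.names = FALSE)
  df[10, 2] <- -0.5
  write.csv(df, tmp, row.names = FALSE)
  expect_error(readSpectra(tmp), "short_01")
  # out-of-range rows trimmed with a warning
  df[10, 2] <- 0.5
  df$wavelength_nm[1] <- 299   # still increasing (grid starts at 300)
  df <- rbind(df, transform(df[401, ], wavelength_nm = 701))
  write.csv(df, tmp, row.names = FALSE)
  expect_warning(rt2 <- readSpectra(tmp), "trimmed")
  expect_equal(length(wavelengths(rt2)), 400)
  # malformed header and non-monotone grid
  names(df)[1] <- "wl"
  write.csv(df, tmp, row.names = FALSE)
  expect_error(readSpectra(tmp), "malformed header")
  names(df)[1] <- "wavelength_nm"
  df$wavelength_nm[2] <- df$wavelength_nm[3]
  write.csv(df, tmp, row.names = FALSE)
  expect_error(readSpectra(tmp), "increasing")
})

test_that("hue detection handles boundaries, ties and degenerate input", {
  g <- data.frame(label = "a", peak = 550, height = 30, width = 30)
  expect_equal(unname(huePeak(genSpectra(g, 1, 0, seed = 1))), 550)
  wl <- seq(300, 700, by = 1)
  mono <- methods::new("ReflectanceSpectra", wavelength = wl,
                       reflectance = cbind(seq_along(wl) / 10),
                       specimen = data.frame(specimen_id = "m"))
  expect_equal(unname(huePeak(mono)), 700)        # grid boundary
  r <- rep(0, length(wl)); r[wl == 450] <- 5; r[wl == 600] <- 5
  tie <- methods::new("ReflectanceSpectra", wavelength = wl,
                      reflectance = cbind(r),
                      specimen = data.frame(specimen_id = "t"))
  expect_equal(unname(huePeak(tie)), 450)         # tie -> shortest wavelength
  zero <- methods::new("ReflectanceSpectra", wavelength = wl,
                       reflectance = cbind(rep(0, length(wl))),
                       specimen = data.frame(specimen_id = "z"))
  expect_error(huePeak(zero), "undefined hue")
})

test_that("equal-area sensitivities and a flat stimulus give equal catches", {
  wl <- seq(300, 700, by = 1)
  # four non-negative bumps normalised to unit area
  sens <- vapply(c(350, 450, 550, 650), function(mu) {
    s <- exp(-(wl - mu)^2 / (2 * 30^2))
    s / sum(diff(wl) * (head(s, -1) + tail(s, -1)) / 2)
  }, numeric(length(wl)))
  colnames(sens) <- c("u", "s", "m", "l")
  vsEq <- avianVisualSystem(wavelength = wl, sensitivity = sens)
  flat <- methods::new("ReflectanceSpectra", wavelength = wl,
                       reflectance = cbind(rep(50, length(wl))),
                       specimen = data.frame(specimen_id = "flat"))
  rel <- relCatches(quantumCatches(flat, vsEq))
  expect_equal(unname(rel[1, ]), rep(0.25, 4), tolerance = 1e-9)
})

test_that("trapezoid catches agree with a midpoint-rule oracle at 0.1 nm", {
  wlF <- seq(300, 700, by = 0.1)
  vsF <- avianVisualSystem(wavelength = wlF)
  spF <- twoGroupSpec(nPerGroup = 1, noiseSd = 0, seed = 1, wavelength = wlF)
  q1 <- catches(quantumCatches(spF["short_01"], vsF, step = 1))
  # independent midpoint-rule quadrature on the same analytic curves
  refl <- reflectance(spF)[, 1]
  mids <- (head(wlF, -1) + tail(wlF, -1)) / 2
  oracle <- vapply(seq_len(4), function(i) {
    f <- approx(wlF, refl * vsF@sensitivity[, i], xout = mids)$y
    sum(diff(wlF) * f)
  }, numeric(1))
  expect_equal(unname(q1[1, ] / sum(q1)), oracle / sum(oracle),
               tolerance = 1e-6)
})

test_that("catches scale linearly with the stimulus; relative catches do not", {
  sp <- twoGroupSpec(nPerGroup = 1, noiseSd = 0, seed = 1)
  sp2 <- methods::new("ReflectanceSpectra", wavelength = wavelengths(sp),
                      reflectance = reflectance(sp) * 2,
                      specimen = specimenInfo(sp))
  qa <- quantumCatches(sp, vs); qb <- quantumCatches(sp2, vs)
  expect_equal(catches(qb), catches(qa) * 2, tolerance = 1e-12)
  expect_equal(relCatches(qb), relCatches(qa), tolerance = 1e-12)
  zero <- methods::new("ReflectanceSpectra", wavelength = wavelengths(sp),
                       reflectance = cbind(rep(0, 401)),
                       specimen = data.frame(specimen_id = "z"))
  expect_error(quantumCatches(zero, vs), "zero quantum catch")
})

test_that("tetrahedral coordinates place the landmarks correctly", {
  expect_equal(unname(tetraCoords(rep(0.25, 4))[1, ]), c(0, 0, 0))
  expect_equal(unname(tetraCoords(c(1, 0, 0, 0))[1, ]), c(0, 0, 0.75))
  verts <- tetraCoords(diag(4))
  d <- dist(verts)
  expect_equal(as.numeric(d), rep(sqrt(1.5), 6), tolerance = 1e-12)
  expect_error(tetraCoords(c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})

test_that("receptor-noise distance is a proper metric with the known closed forms", {
  q <- c(u = 2, s = 3, m = 1.5, l = 4)
  expect_equal(receptorNoiseDistance(q, q, vs), 0)
  set.seed(11)
  for (i in 1:20) {
    qa <- exp(rnorm(4)); qb <- exp(rnorm(4))
    expect_equal(receptorNoiseDistance(qa, qb, vs),
                 receptorNoiseDistance(qb, qa, vs), tolerance = 1e-12)
    expect_gte(receptorNoiseDistance(qa, qb, vs), 0)
  }
  # dichromat reduction: dS = |df1 - df2| / sqrt(e1^2 + e2^2)
  vs2 <- avianVisualSystem(lambdaMax = c(a = 400, b = 550),
                           density = c(1, 1), weber = 0.1)
  dS <- receptorNoiseDistance(exp(c(0.2, 0)), c(1, 1), vs2)
  expect_equal(dS, 0.2 / sqrt(0.02), tolerance = 1e-12)
  expect_error(receptorNoiseDistance(c(0, 1, 1, 1), q, vs), "positive")
})

test_that("noise-scaled coordinates reproduce the receptor-noise metric", {
  set.seed(21)
  for (i in 1:200) {
    qa <- exp(rnorm(4, sd = 0.5)); qb <- exp(rnorm(4, sd = 0.5))
    d1 <- receptorNoiseDistance(qa, qb, vs)
    d2 <- sqrt(sum((noiseScaledCoords(qa, vs) - noiseScaledCoords(qb, vs))^2))
    expect_equal(d1, d2, tolerance = 1e-9)
  }
  qa <- c(1, 2, 3, 4)
  expect_equal(noiseScaledCoords(qa, vs), noiseScaledCoords(qa, vs))
  # invariance to common scaling of the catches
  expect_equal(noiseScaledCoords(qa * 7.3, vs), noiseScaledCoords(qa, vs),
               tolerance = 1e-12)
})

test_that("quadrature refinement barely changes dS for smooth spectra", {
  wlF <- seq(300, 700, by = 0.1)
  vsF <- avianVisualSystem(wavelength = wlF)
  spF <- twoGroupSpec(nPerGroup = 1, noiseSd = 0, seed = 1, wavelength = wlF)
  qA1 <- catches(quantumCatches(spF["short_01"], vsF, step = 1))
  qB1 <- catches(quantumCatches(spF["long_01"], vsF, step = 1))
  qA0 <- catches(quantumCatches(spF["short_01"], vsF, step = 0.1))
  qB0 <- catches(quantumCatches(spF["long_01"], vsF, step = 0.1))
  expect_lt(abs(receptorNoiseDistance(qA1, qB1, vsF) -
                receptorNoiseDistance(qA0, qB0, vsF)), 1e-4)
})

test_that("bootstrap group distances behave at the degenerate and separated ends", {
  sp <- twoGroupSpec(nPerGroup = 4, noiseSd = 0, seed = 1)
  grp <- specimenInfo(sp)$group
  a <- sp[grp == "short"]
  same <- bootstrapGroupDistance(a, a, vs, nBoot = 200, seed = 1)
  expect_equal(same@dS, 0)
  expect_equal(same@ci, c(0, 0))
  r1 <- bootstrapGroupDistance(sp[grp == "short"], sp[grp == "long"], vs,
                               nBoot = 200, seed = 5)
  r2 <- bootstrapGroupDistance(sp[grp == "short"], sp[grp == "long"], vs,
                               nBoot = 200, seed = 5)
  expect_identical(r1@ci, r2@ci)                    # seeded determinism
  expect_error(bootstrapGroupDistance(sp[1], a, vs), ">= 2 spectra")
})

test_that("constructed 480 vs 560 nm groups are discriminably different", {
  sp <- twoGroupSpec(nPerGroup = 10, noiseSd = 0.5, seed = 2)
  grp <- specimenInfo(sp)$group
  cd <- bootstrapGroupDistance(sp[grp == "short"], sp[grp == "long"], vs,
                               nBoot = 500, seed = 3)
  expect_gt(cd@ci[1], 1)                            # above 1 JND
  expect_true(cd@significant)
})
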