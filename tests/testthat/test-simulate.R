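test_that("reference simulation respects truncation bounds and moments", {
  kexin <- defaultVarieties()[[1]]
  x <- simulateReference(kexin, seed = 1)
  expect_length(x, 68)
  expect_true(all(x >= kexin$starchMin & x <= kexin$starchMax))
  # near-degenerate SD concentrates at the mean
  tight <- varietySpec("tight", 50, 10, 1e-9, 0, 20)
  expect_equal(simulateReference(tight, seed = 2), rep(10, 50),
               tolerance = 1e-6)
  # law of large numbers at n = 10000 with wide bounds
  wide <- varietySpec("wide", 10000, 10.23, 2.95,
                      10.23 - 29.5, 10.23 + 29.5)
  expect_lt(abs(mean(simulateReference(wide, seed = 3)) - 10.23), 0.1)
  # invalid dispersion is rejected at construction
  expect_error(varietySpec("bad", 5, 10, 0, 1, 20), "starchSd")
  # reproducibility
  expect_identical(simulateReference(kexin, seed = 7),
                   simulateReference(kexin, seed = 7))
})

test_that("absorption dip depth increases with starch when noise is off", {
  cfg <- quietSimConfig()
  s1 <- simulateSpectrum(5, cfg)
  s2 <- simulateSpectrum(20, cfg)
  i980 <- which.min(abs(cfg$wavelengths - 980))
  base <- quietSimConfig(peakStarchGain = 0)
  flat5 <- simulateSpectrum(5, base)
  # dip depth relative to the zero-gain baseline
  expect_gt((flat5 - s2)[i980], (flat5 - s1)[i980])
})

test_that("zero gain and zero starch give the undisturbed baseline", {
  cfg <- quietSimConfig(peakStarchGain = 0, baselineTilt = 0,
                        baselineCurve = 0)
  s <- simulateSpectrum(0, cfg)
  expect_equal(as.numeric(s), rep(cfg$baseline, length(cfg$wavelengths)))
})

test_that("spectrum simulation is deterministic given a seed", {
  cfg <- simConfig()
  expect_identical(simulateSpectrum(12, cfg, seed = 5),
                   simulateSpectrum(12, cfg, seed = 5))
  s <- simulateSpectrum(12, cfg, seed = 5)
  expect_true(all(s > 0 & s <= 1))
})

test_that("noise-free spectra carry a perfectly linear 980 nm signal", {
  cfg <- quietSimConfig()
  starch <- seq(3, 22, length.out = 15)
  i980 <- which.min(abs(cfg$wavelengths - 980))
  band <- vapply(starch, function(s) simulateSpectrum(s, cfg)[i980],
                 numeric(1))
  expect_equal(abs(cor(starch, band)), 1, tolerance = 1e-12)
})

test_that("field-free cubes are spatially constant with uniformity 1", {
  cfg <- quietSimConfig(illumAmp = 0, textureAmp = 0, spikeDensity = 0,
                        cubeRows = 12, cubeCols = 12,
                        wavelengths = seq(400, 1000, length.out = 20),
                        peakCenters = c(450, 700, 950))
  cube <- simulateCube(10, cfg, seed = 1)
  arr <- cubeData(cube)
  expect_equal(max(apply(arr, 3, function(b) diff(range(b)))), 0)
  # a constant image quantizes to level 0 with uniformity exactly 1
  f <- glcmFeatures(glcm(quantizeImage(arr[, , 1], 64), 64, angle = 0))
  expect_equal(as.numeric(f["uniformity"]), 1)
})

test_that("cube simulation is deterministic given a seed", {
  cfg <- simConfig(cubeRows = 30, cubeCols = 30,
                   wavelengths = seq(400, 1000, length.out = 30),
                   peakCenters = c(450, 700, 950))
  c1 <- simulateCube(15, cfg, seed = 11)
  c2 <- simulateCube(15, cfg, seed = 11)
  expect_identical(cubeData(c1), cubeData(c2))
})

test_that("high-starch cubes have lower PC2 uniformity on average", {
  cfg <- simConfig()
  u <- vapply(1:8, function(s) {
    vapply(c(5, 20), function(st) {
      cube <- simulateCube(st, cfg, seed = 400 + 10 * s + st)
      st3 <- pcaScoreImages(extractROI(cube, size = 100), 3)
      as.numeric(textureVector(st3)["uniformity_PC2"])
    }, numeric(1))
  }, numeric(2))
  expect_lt(mean(u[2, ]), mean(u[1, ]))
})

test_that("texture-starch correlation has the planted sign pattern", {
  cfg <- simConfig()
  set.seed(70)
  starch <- runif(50, 4, 21.5)
  Tm <- t(vapply(seq_along(starch), function(i) {
    cube <- simulateCube(starch[i], cfg, seed = 700 + i)
    textureVector(pcaScoreImages(extractROI(cube, size = 100), 3))
  }, numeric(12)))
  r <- cor(Tm, starch)[, 1]
  expect_lt(r["uniformity_PC2"], 0)
  expect_gt(r["correlation_PC2"], 0)
})

test_that("dataset simulation reproduces the two-variety study design", {
  ds <- simulateDataset(simConfig(seed = 1), cubes = FALSE)
  expect_equal(nrow(ds$reference), 96)
  expect_equal(sum(ds$reference$variety == "Kexin No.1"), 68)
  expect_equal(sum(ds$reference$variety == "Holland No.15"), 28)
  lims <- do.call(rbind, lapply(defaultVarieties(), function(v)
    data.frame(variety = v$name, lo = v$starchMin, hi = v$starchMax)))
  m <- merge(ds$reference, lims)
  expect_true(all(m$starch_g_per_100g >= m$lo & m$starch_g_per_100g <= m$hi))
  # determinism of the whole reference table
  ds2 <- simulateDataset(simConfig(seed = 1), cubes = FALSE)
  expect_identical(ds$reference, ds2$reference)
})

test_that("small datasets generate one cube per sample and a valid CSV", {
  cfg <- simConfig(varieties = list(varietySpec("Solo", 3, 10, 2, 5, 15)),
                   cubeRows = 10, cubeCols = 10,
                   wavelengths = seq(400, 1000, length.out = 12),
                   peakCenters = c(450, 700, 950), seed = 4)
  ds <- simulateDataset(cfg)
  expect_length(ds$cubes, 3)
  expect_s4_class(ds$cubes[[1]], "Hypercube")
  dir <- file.path(tempdir(), "simout")
  ds2 <- simulateDataset(cfg, dir = dir)
  expect_length(ds2$paths, 3)
  expect_true(all(file.exists(ds2$paths)))
  back <- readENVI(ds2$paths[1])
  expect_equal(cubeData(back), cubeData(ds$cubes[[1]]), tolerance = 1e-12)
  ref <- read.csv(file.path(dir, "reference.csv"))
  expect_equal(nrow(ref), 3)
  expect_equal(ref$starch_g_per_100g, ds$reference$starch_g_per_100g)
})
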