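# Shared fixture builders. Everything is generated in code at test time.

# Noise-free generator configuration: deterministic spectra/cubes.
quietSimConfig <- function(...) {
  simConfig(depthNoiseSd = 0, scatterMultSd = 0, scatterAddSd = 0,
            spectralNoiseSd = 0, pixelNoiseSd = 0, grainJitterSd = 0,
            spikeJitterSd = 0, ...)
}

# Small, fast configuration for end-to-end pipeline tests: one variety,
# few bands, small cubes.
smallRunConfig <- function(seed = 1, n = 18, outDir = NULL) {
  wl <- seq(400, 1000, length.out = 60)
  sim <- simConfig(
    varieties = list(varietySpec("Demo", n, 12, 4, 2, 22)),
    cubeRows = 40, cubeCols = 40, wavelengths = wl,
    peakCenters = c(450, 700, 950), peakDepthOffset = c(15, 18, 22),
    seed = seed)
  runConfig(mode = "simulate", sim = sim, roiSize = 30,
            cars = carsConfig(nRuns = 12, seed = seed),
            maxLV = 5, cvFolds = 4, seed = seed, outDir = outDir)
}

# A tiny cube with prescribed values.
tinyCube <- function(rows = 2, cols = 2, bands = 3, data = NULL) {
  if (is.null(data)) data <- array(seq_len(rows * cols * bands) / 10,
                                   dim = c(rows, cols, bands))
  Hypercube(data, seq(500, by = 50, length.out = bands))
}
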