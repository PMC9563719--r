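# Synthetic potato hypercube generator.
#
# The generator plants the statistical structure the analysis assumes:
# starch reference values drawn per variety from truncated normals; sample
# spectra with absorption dips near 410/680/980 nm whose depths grow with
# starch; cubes whose PC2-direction surface texture becomes finer-grained
# and less speckled as starch rises, so GLCM uniformity falls and GLCM
# correlation rises with starch.

#' Variety specification
#'
#' Starch distribution of one potato variety: mean, SD and hard bounds of a
#' truncated normal (g/100 g).
#'
#' @param name variety label.
#' @param nSamples number of tubers (>= 1).
#' @param starchMean,starchSd mean and SD of the underlying normal.
#' @param starchMin,starchMax truncation bounds, `starchMin < starchMax`.
#' @return list of class `VarietySpec`.
#' @export
varietySpec <- function(name, nSamples, starchMean, starchSd,
                        starchMin, starchMax) {
  stopifnot(nSamples >= 1, starchSd > 0, starchMin < starchMax)
  structure(list(name = name, nSamples = as.integer(nSamples),
                 starchMean = starchMean, starchSd = starchSd,
                 starchMin = starchMin, starchMax = starchMax),
            class = "VarietySpec")
}

#' Default variety set
#'
#' The two-variety study design: 68 Kexin No.1 tubers (starch
#' 10.23 +/- 2.95 g/100 g, range 1.77-18.31) and 28 Holland No.15 tubers
#' (18.96 +/- 1.29 g/100 g, range 17.01-22.81), 96 samples in total.
#'
#' @return list of two [varietySpec()] objects.
#' @export
defaultVarieties <- function() {
  list(varietySpec("Kexin No.1", 68, 10.23, 2.95, 1.77, 18.31),
       varietySpec("Holland No.15", 28, 18.96, 1.29, 17.01, 22.81))
}

#' Simulation configuration
#'
#' All knobs of the synthetic hypercube generator. Spectral model: a fixed
#' tilted baseline minus Gaussian dips (SD `peakWidth` nm) centred at
#' `peakCenters`, with dip depth affine and increasing in starch
#' (`depth = peakStarchGain * (peakDepthOffset + starch)`), plus per-sample
#' multiplicative/additive scatter, per-peak depth noise (chemistry not
#' explained by starch) and i.i.d. band noise. Spatial model per cube: a
#' coarse illumination field along the spectrum direction plus a
#' starch-dependent texture field along a fixed orthogonal spectral
#' direction, composed of Gaussian-filtered white noise whose correlation
#' length (`grain`) decreases with starch and sparse speckles whose
#' amplitude decays with starch, plus i.i.d. pixel noise.
#'
#' @param varieties list of [varietySpec()] objects.
#' @param cubeRows,cubeCols cube size in pixels (default 120 x 120 so the
#'   100 x 100 ROI fits).
#' @param wavelengths band grid (default 428 points, 382-1004 nm).
#' @param peakCenters absorption dip centres in nm.
#' @param peakWidth Gaussian dip SD in nm.
#' @param baseline mean baseline reflectance.
#' @param baselineTilt,baselineCurve linear and quadratic coefficients of
#'   the fixed (starch-independent) baseline shape across the grid.
#' @param peakDepthOffset per-peak affine offsets (starch-equivalent units).
#' @param peakStarchGain dip-depth gain per g/100 g starch.
#' @param depthNoiseSd SD of per-peak depth noise (reflectance units).
#' @param scatterMultSd,scatterAddSd SDs of per-sample multiplicative /
#'   additive scatter.
#' @param spectralNoiseSd SD of i.i.d. band noise on the sample spectrum.
#' @param pixelNoiseSd SD of i.i.d. per-pixel-per-band cube noise.
#' @param illumAmp,illumGrain amplitude and correlation length (px) of the
#'   multiplicative illumination field.
#' @param textureAmp amplitude (reflectance units) of the smooth texture
#'   field along the texture spectral direction.
#' @param grainIntercept,grainSlope,grainMin texture correlation length in
#'   pixels: `max(grainMin, grainIntercept - grainSlope * starch)`.
#' @param grainMax upper clamp on the (jittered) grain so the smoothing
#'   kernel always fits inside the cube.
#' @param grainJitterSd lognormal jitter SD of the per-sample grain.
#' @param spikeDensity fraction of speckle pixels.
#' @param spikeAmpMax,spikeDecay speckle amplitude
#'   `spikeAmpMax * exp(-starch / spikeDecay)`.
#' @param spikeJitterSd lognormal jitter SD of the per-sample speckle
#'   amplitude.
#' @param spikeAmpCap upper clamp on the jittered speckle amplitude, so
#'   speckles never clip against the reflectance bounds.
#' @param textureCenter,textureWidth centre/width (nm) of the texture
#'   spectral direction (unit-norm Gaussian bump).
#' @param seed base RNG seed; per-sample seeds are derived from it.
#' @return list of class `SimConfig`.
#' @export
simConfig <- function(varieties = defaultVarieties(),
                      cubeRows = 120, cubeCols = 120,
                      wavelengths = defaultWavelengths(),
                      peakCenters = c(410, 680, 980),
                      peakWidth = 15,
                      baseline = 0.55,
                      baselineTilt = 0.25, baselineCurve = 0.2,
                      peakDepthOffset = c(15, 18, 22),
                      peakStarchGain = 0.006,
                      depthNoiseSd = 0.025,
                      scatterMultSd = 0.12,
                      scatterAddSd = 0.05,
                      spectralNoiseSd = 0.012,
                      pixelNoiseSd = 0.003,
                      illumAmp = 0.06, illumGrain = 12,
                      textureAmp = 0.03,
                      grainIntercept = 7, grainSlope = 0.2, grainMin = 1.5,
                      grainMax = 14, grainJitterSd = 0.7,
                      spikeDensity = 0.003,
                      spikeAmpMax = 1.5, spikeDecay = 5,
                      spikeJitterSd = 1.0, spikeAmpCap = 1.0,
                      textureCenter = 850, textureWidth = 40,
                      seed = 1) {
  stopifnot(length(peakCenters) == length(peakDepthOffset),
            cubeRows >= 1, cubeCols >= 1,
            all(is.finite(c(peakStarchGain, depthNoiseSd, scatterMultSd,
                            scatterAddSd, spectralNoiseSd, pixelNoiseSd,
                            illumAmp, textureAmp, spikeAmpMax))))
  structure(as.list(environment()), class = "SimConfig")
}

#' Simulate starch reference values for one variety
#'
#' Draws from a normal with the variety's mean/SD, truncated to
#' `[starchMin, starchMax]` by rejection (exact at these sample sizes).
#'
#' @param spec a [varietySpec()].
#' @param seed RNG seed; the draw is reproducible given it.
#' @return numeric vector of `spec$nSamples` starch values (g/100 g).
#' @export
simulateReference <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "VarietySpec"))
  if (spec$starchSd <= 0) stop("starchSd must be positive")
  withSeed(seed, {
    out <- numeric(0)
    while (length(out) < spec$nSamples) {
      draw <- rnorm(2 * spec$nSamples, spec$starchMean, spec$starchSd)
      out <- c(out, draw[draw >= spec$starchMin & draw <= spec$starchMax])
    }
    out[seq_len(spec$nSamples)]
  })
}

#' Simulate one sample's reflectance spectrum
#'
#' Baseline reflectance minus Gaussian absorption dips whose depths are an
#' affine increasing function of starch, subjected to per-sample scatter
#' (multiplicative and additive), per-peak depth noise and i.i.d. band
#' noise, then clipped to (0, 1]. With all noise SDs zero the spectrum is
#' a deterministic function of starch.
#'
#' @param starch starch content (g/100 g, >= 0).
#' @param config a [simConfig()].
#' @param seed RNG seed; `NULL` draws from the current stream.
#' @return reflectance vector over `config$wavelengths`.
#' @export
simulateSpectrum <- function(starch, config = simConfig(), seed = NULL) {
  stopifnot(inherits(config, "SimConfig"), starch >= 0)
  withSeed(seed, {
    wl <- config$wavelengths
    depths <- config$peakStarchGain * (config$peakDepthOffset + starch)
    if (config$depthNoiseSd > 0)
      depths <- depths + rnorm(length(depths), 0, config$depthNoiseSd)
    u <- (wl - min(wl)) / diff(range(wl))
    r <- config$baseline + config$baselineTilt * (u - 0.5) -
      config$baselineCurve * (u - 0.5)^2
    for (k in seq_along(config$peakCenters))
      r <- r - depths[k] *
        exp(-(wl - config$peakCenters[k])^2 / (2 * config$peakWidth^2))
    a <- if (config$scatterMultSd > 0) 1 + rnorm(1, 0, config$scatterMultSd)
         else 1
    b <- if (config$scatterAddSd > 0) rnorm(1, 0, config$scatterAddSd) else 0
    eps <- if (config$spectralNoiseSd > 0)
      rnorm(length(wl), 0, config$spectralNoiseSd) else 0
    pmin(pmax(a * r + b + eps, 1e-6), 1)
  })
}

# Unit-SD Gaussian-filtered white-noise field. The filter support must fit
# inside the image, which bounds the usable sigma.
.smooth_field <- function(rows, cols, sigma) {
  sigma <- min(max(sigma, 0.3), (min(rows, cols) - 3) / 7)
  f <- EBImage::gblur(matrix(rnorm(rows * cols), rows, cols), sigma = sigma)
  (f - mean(f)) / stats::sd(f)
}

# Unit-norm spectral direction of the texture component.
.texture_direction <- function(config) {
  v <- exp(-(config$wavelengths - config$textureCenter)^2 /
             (2 * config$textureWidth^2))
  v / sqrt(sum(v^2))
}

#' Simulate one sample's hypercube
#'
#' Every pixel carries the sample's [simulateSpectrum()] output modulated
#' by a coarse multiplicative illumination field, plus a starch-dependent
#' texture component along a fixed spectral direction (smooth field whose
#' grain shrinks with starch, speckles whose amplitude decays with starch)
#' and i.i.d. pixel noise. Deterministic given `seed`.
#'
#' @param starch starch content (g/100 g).
#' @param config a [simConfig()].
#' @param seed RNG seed.
#' @return A [Hypercube-class] of `cubeRows` x `cubeCols` pixels.
#' @export
simulateCube <- function(starch, config = simConfig(), seed = 1) {
  stopifnot(inherits(config, "SimConfig"))
  rows <- config$cubeRows; cols <- config$cubeCols
  withSeed(seed, {
    s <- simulateSpectrum(starch, config, seed = NULL)
    grain <- max(config$grainMin,
                 config$grainIntercept - config$grainSlope * starch)
    if (config$grainJitterSd > 0)
      grain <- grain * exp(rnorm(1, 0, config$grainJitterSd))
    grain <- min(max(grain, config$grainMin), config$grainMax)
    illum <- 1 + config$illumAmp * .smooth_field(rows, cols, config$illumGrain)
    tex <- config$textureAmp * .smooth_field(rows, cols, grain)
    spike_amp <- config$spikeAmpMax * exp(-starch / config$spikeDecay)
    if (config$spikeJitterSd > 0)
      spike_amp <- spike_amp * exp(rnorm(1, 0, config$spikeJitterSd))
    spike_amp <- min(spike_amp, config$spikeAmpCap)
    if (config$spikeDensity > 0 && spike_amp > 0) {
      mask <- runif(rows * cols) < config$spikeDensity
      spikes <- numeric(rows * cols)
      spikes[mask] <- sample(c(-1, 1), sum(mask), replace = TRUE) * spike_amp
      tex <- tex + matrix(spikes, rows, cols)
    }
    v2 <- .texture_direction(config)
    cube <- outer(illum, s) + outer(tex, v2)
    if (config$pixelNoiseSd > 0)
      cube <- cube + array(rnorm(length(cube), 0, config$pixelNoiseSd),
                           dim = dim(cube))
    cube <- pmin(pmax(cube, 1e-6), 1)
    Hypercube(cube, config$wavelengths)
  })
}

#' Simulate a full dataset
#'
#' Draws per-variety starch references (seeds `seed + variety index`),
#' assembles the reference table and generates one cube per sample with
#' per-sample seeds `seed + 100 + sample index`. With the default
#' configuration this emulates the 96-sample two-variety study design.
#'
#' @param config a [simConfig()].
#' @param dir optional directory; when given, cubes are written there as
#'   ENVI pairs (`<sample_id>.hdr/.dat`) instead of being returned in
#'   memory (a full default dataset is several GB in RAM).
#' @param cubes set `FALSE` to generate only the reference table.
#' @return list with `reference` (data.frame: sample_id, variety,
#'   starch_g_per_100g) and either `cubes` (list of [Hypercube-class]) or
#'   `paths` (character vector of ENVI header paths).
#' @export
simulateDataset <- function(config = simConfig(), dir = NULL, cubes = TRUE) {
  stopifnot(inherits(config, "SimConfig"))
  refs <- lapply(seq_along(config$varieties), function(v)
    simulateReference(config$varieties[[v]], seed = config$seed + v))
  reference <- data.frame(
    sample_id = sprintf("S%03d", seq_len(sum(lengths(refs)))),
    variety = rep(vapply(config$varieties, `[[`, "", "name"),
                  lengths(refs)),
    starch_g_per_100g = unlist(refs),
    stringsAsFactors = FALSE
  )
  out <- list(reference = reference)
  if (!cubes) return(out)
  gen <- function(i) simulateCube(reference$starch_g_per_100g[i], config,
                                  seed = config$seed + 100 + i)
  if (is.null(dir)) {
    out$cubes <- lapply(seq_len(nrow(reference)), gen)
  } else {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$paths <- vapply(seq_len(nrow(reference)), function(i) {
      base <- file.path(dir, reference$sample_id[i])
      writeENVI(gen(i), base)[1]
    }, character(1))
    utils::write.csv(reference, file.path(dir, "reference.csv"),
                     row.names = FALSE)
  }
  out
}
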