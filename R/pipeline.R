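# End-to-end driver: features -> split -> selection -> five PLSR models.

#' Pipeline configuration
#'
#' @param mode `"simulate"` (generate cubes on the fly) or `"cubes"` (read
#'   ENVI pairs listed in `cubePaths` with reference values from
#'   `referenceCsv`).
#' @param sim a [simConfig()] (simulate mode).
#' @param cubePaths character vector of ENVI header paths (cube mode).
#' @param referenceCsv CSV with columns `sample_id`, `variety`,
#'   `starch_g_per_100g`, in cube order (cube mode).
#' @param roiSize region-of-interest edge length in pixels (default 100).
#' @param glcmLevels gray levels for texture quantization (default 64).
#' @param cars a [carsConfig()] for wavelength selection.
#' @param corThreshold absolute-correlation threshold for texture
#'   selection (default 0.3, strict >).
#' @param maxLV latent-variable ceiling for the final models (default 15).
#' @param cvFolds folds for latent-variable selection (default 5).
#' @param seed seed controlling simulation, CARS and fold shuffles.
#' @param outDir optional output directory; when given, all intermediate
#'   tables, selection results, reports and a run log are written there.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(mode = c("simulate", "cubes"), sim = NULL,
                      cubePaths = NULL, referenceCsv = NULL,
                      roiSize = 100, glcmLevels = 64,
                      cars = NULL, corThreshold = 0.3,
                      maxLV = 15, cvFolds = 5, seed = 1, outDir = NULL) {
  mode <- match.arg(mode)
  if (mode == "cubes") {
    if (is.null(cubePaths) || is.null(referenceCsv))
      stop("cube mode needs cubePaths and referenceCsv")
    missing <- cubePaths[!file.exists(cubePaths)]
    if (length(missing)) stop("missing cube files: ",
                              paste(missing, collapse = ", "))
    if (!file.exists(referenceCsv)) stop("missing reference CSV")
  }
  if (is.null(sim)) sim <- simConfig(seed = seed)
  if (is.null(cars)) cars <- carsConfig(seed = seed)
  structure(list(mode = mode, sim = sim, cubePaths = cubePaths,
                 referenceCsv = referenceCsv, roiSize = roiSize,
                 glcmLevels = glcmLevels, cars = cars,
                 corThreshold = corThreshold, maxLV = maxLV,
                 cvFolds = cvFolds, seed = seed, outDir = outDir),
            class = "RunConfig")
}

# Per-sample feature extraction: ROI mean spectrum + 12 texture features.
.extract_features <- function(cube, roi_size, levels, sample_id) {
  roi <- extractROI(cube, size = roi_size)
  stack <- pcaScoreImages(roi, 3, sampleId = sample_id)
  list(spectrum = meanSpectrum(roi),
       texture = textureVector(stack, levels = levels),
       explainedVariance = stack@explainedVariance)
}

#' Run the full spectral-textural fusion pipeline
#'
#' Chains every stage: cube acquisition (simulated or read from ENVI),
#' ROI mean spectra, SNV, per-sample PC score images, GLCM texture,
#' rank-order calibration/prediction split, CARS and correlation variable
#' selection on the calibration set, low- and mid-level fusion, and five
#' cross-validated PLSR models (raw spectra, SNV spectra, texture,
#' low-level fusion, mid-level fusion) evaluated by Rc/RMSEC/Rp/RMSEP/RPD.
#'
#' @param config a [runConfig()].
#' @return invisibly, a list with `comparison` (five-row data.frame in the
#'   conventional model-comparison layout), `reports` (list of
#'   [EvalReport-class]), `cars` ([CARSResult-class]), `textureSelection`
#'   ([SelectionReport-class]), `split`, `spectraRaw`, `spectraSnv`,
#'   `texture`, `reference` and `config`.
#' @export
runPipeline <- function(config = runConfig()) {
  stopifnot(inherits(config, "RunConfig"))
  if (config$mode == "simulate") {
    ds <- simulateDataset(config$sim, cubes = FALSE)
    reference <- ds$reference
    get_cube <- function(i) simulateCube(reference$starch_g_per_100g[i],
                                         config$sim,
                                         seed = config$sim$seed + 100 + i)
  } else {
    reference <- utils::read.csv(config$referenceCsv)
    if (nrow(reference) != length(config$cubePaths))
      stop("reference CSV rows and cubePaths length differ")
    get_cube <- function(i) readENVI(config$cubePaths[i])
  }
  n <- nrow(reference)
  ids <- reference$sample_id
  y <- reference$starch_g_per_100g

  feats <- vector("list", n)
  for (i in seq_len(n)) {
    feats[[i]] <- tryCatch(
      .extract_features(get_cube(i), config$roiSize, config$glcmLevels,
                        ids[i]),
      error = function(e) stop(sprintf("stage 'features' failed for %s: %s",
                                       ids[i], conditionMessage(e))))
  }
  wl <- if (config$mode == "simulate") config$sim$wavelengths else
    as.numeric(names(feats[[1]]$spectrum))
  Xraw <- SpectrumTable(do.call(rbind, lapply(feats, `[[`, "spectrum")),
                        wl, ids)
  Xsnv <- snv(Xraw)
  Tmat <- textureTable(lapply(feats, `[[`, "texture"), ids)

  split <- rankOrderSplit(y, ids)
  cal <- split@calibration; prd <- split@prediction

  # variable selection on the calibration set only (no leakage)
  cars_res <- carsSelect(Xsnv@X[cal, , drop = FALSE], y[cal],
                         config = config$cars, wavelengths = wl)
  tex_sel <- correlationSelect(Tmat[cal, , drop = FALSE], y[cal],
                               threshold = config$corThreshold)

  blocks <- list(
    "Raw spectra" = Xraw@X,
    "SNV preprocessed" = Xsnv@X,
    "Texture" = Tmat,
    "Low-level fusion" = fuseLow(Xsnv, Tmat),
    "Mid-level fusion" = fuseMid(Xsnv, cars_res, Tmat, tex_sel)
  )
  reports <- lapply(names(blocks), function(nm) {
    M <- blocks[[nm]]
    n_cal <- length(cal)
    cv <- selectLvCV(M[cal, , drop = FALSE], y[cal],
                     maxLV = min(config$maxLV, ncol(M),
                                 n_cal - ceiling(n_cal / config$cvFolds) - 1),
                     folds = config$cvFolds, seed = config$seed)
    m <- plsFit(M[cal, , drop = FALSE], y[cal], cv$bestLV)
    evaluateModel(m, M[cal, , drop = FALSE], y[cal],
                  M[prd, , drop = FALSE], y[prd], label = nm)
  })
  names(reports) <- names(blocks)
  comparison <- evalTable(reports)

  res <- list(comparison = comparison, reports = reports, cars = cars_res,
              textureSelection = tex_sel, split = split,
              spectraRaw = Xraw, spectraSnv = Xsnv, texture = Tmat,
              reference = reference, config = config)
  if (!is.null(config$outDir)) .write_pipeline_outputs(res, config)
  invisible(res)
}

.round_comparison <- function(comparison) {
  out <- comparison
  out$Rc <- round(out$Rc, 4); out$Rp <- round(out$Rp, 4)
  out$RMSEC <- round(out$RMSEC, 2); out$RMSEP <- round(out$RMSEP, 2)
  out$RPD <- round(out$RPD, 2)
  out
}

.write_pipeline_outputs <- function(res, config) {
  dir <- config$outDir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeSpectrumTable(res$spectraRaw, file.path(dir, "spectra_raw.csv"))
  writeSpectrumTable(res$spectraSnv, file.path(dir, "spectra_snv.csv"))
  utils::write.csv(
    data.frame(sample_id = rownames(res$texture), res$texture,
               check.names = FALSE),
    file.path(dir, "texture.csv"), row.names = FALSE)
  utils::write.csv(res$reference, file.path(dir, "reference.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    seed = config$seed,
    cars = list(selected_indices = res$cars@selectedIndices,
                selected_wavelengths_nm = res$cars@selectedWavelengths,
                best_run = res$cars@bestRun,
                rmsecv_by_run = res$cars@rmsecvByRun,
                retained_count_by_run = res$cars@retainedCountByRun),
    texture = list(r = as.list(res$textureSelection@r),
                   selected = res$textureSelection@selected,
                   threshold = res$textureSelection@threshold)
  ), file.path(dir, "selection.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(lapply(res$reports, function(r) list(
    data = r@label, NVs = r@nVars, LVs = r@nLV, Rc = r@rc, RMSEC = r@rmsec,
    Rp = r@rp, RMSEP = r@rmsep, RPD = r@rpd
  )), file.path(dir, "reports.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(.round_comparison(res$comparison),
                   file.path(dir, "comparison.csv"), row.names = FALSE)
  log <- list(
    seed = config$seed, mode = config$mode,
    roi = list(size = config$roiSize, placement = "centered",
               indexing = "0-based half-open"),
    snv = "row-wise, n-1 standard deviation",
    pca = "per-sample on ROI pixels; sign: largest-|loading| positive",
    glcm = list(levels = config$glcmLevels, distance = 1,
                angles = c(0, 45, 90, 135), symmetric = TRUE,
                entropy_base = 2),
    cars = unclass(config$cars),
    texture_threshold = list(value = config$corThreshold,
                             comparison = "strict >"),
    pls = list(maxLV = config$maxLV, cvFolds = config$cvFolds,
               scaling = "predictors autoscaled, response centred",
               cars_input = "SNV spectra",
               selection_samples = "calibration set only"),
    split = "rank-order, middle of each starch-sorted triplet -> prediction"
  )
  yaml::write_yaml(log, file.path(dir, "runlog.yaml"))
  invisible(dir)
}
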