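#' @import methods
#' @importFrom stats cor sd rnorm runif
NULL

# ---------------------------------------------------------------------------
# Hypercube: a reflectance image cube bound to its wavelength grid
# ---------------------------------------------------------------------------

#' Hypercube class
#'
#' A 3-D reflectance array (rows x cols x bands) bound to a strictly
#' increasing wavelength grid in nanometres. Reflectance is dimensionless
#' and nominally in \[0, 1\].
#'
#' @slot data numeric array, rows x cols x bands.
#' @slot wavelengths numeric vector of band centres (nm), strictly increasing.
#' @slot metadata list of free-form provenance entries (e.g. counts of
#'   invalid pixels after reflectance calibration).
#'
#' @seealso [readENVI()], [writeENVI()], [calibrateReflectance()]
#' @export
setClass("Hypercube",
  slots = c(data = "array", wavelengths = "numeric", metadata = "list"),
  prototype = prototype(metadata = list())
)

setValidity("Hypercube", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L)
    return("data must be a 3-D array (rows x cols x bands)")
  if (dim(d)[3] != length(object@wavelengths))
    return(sprintf("band count (%d) != length(wavelengths) (%d)",
                   dim(d)[3], length(object@wavelengths)))
  if (length(object@wavelengths) > 1 && any(diff(object@wavelengths) <= 0))
    return("wavelengths must be strictly increasing")
  if (!all(is.finite(d)))
    return("cube data must be finite")
  TRUE
})

#' Construct a Hypercube
#'
#' @param data rows x cols x bands numeric array of reflectance.
#' @param wavelengths band centres in nm, strictly increasing; length must
#'   equal `dim(data)[3]`.
#' @param metadata optional list of provenance entries.
#' @return A [Hypercube-class] object.
#' @examples
#' cube <- Hypercube(array(0.5, c(4, 4, 3)), c(500, 600, 700))
#' dim(cubeData(cube))
#' @export
Hypercube <- function(data, wavelengths, metadata = list()) {
  new("Hypercube", data = data, wavelengths = as.numeric(wavelengths),
      metadata = metadata)
}

#' @describeIn Hypercube compact display
#' @param object a `Hypercube`
#' @export
setMethod("show", "Hypercube", function(object) {
  d <- dim(object@data)
  wl <- object@wavelengths
  cat(sprintf("Hypercube: %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(wl), max(wl)))
  cat(sprintf("  reflectance range: [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

#' Wavelength grid accessor
#' @param x a `Hypercube` or `SpectrumTable`
#' @return numeric vector of band centres in nm.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "Hypercube", function(x) x@wavelengths)

#' Cube data accessor
#' @param x a `Hypercube`
#' @return the rows x cols x bands array.
#' @export
cubeData <- function(x) {
  stopifnot(is(x, "Hypercube"))
  x@data
}

# ---------------------------------------------------------------------------
# SpectrumTable: sample x band reflectance matrix
# ---------------------------------------------------------------------------

#' SpectrumTable class
#'
#' An n_samples x n_bands matrix of (ROI-mean) reflectance spectra with the
#' shared wavelength grid and per-row sample identifiers.
#'
#' @slot X numeric matrix, samples in rows, bands in columns.
#' @slot wavelengths band centres (nm).
#' @slot sampleIds character vector of row labels.
#' @export
setClass("SpectrumTable",
  slots = c(X = "matrix", wavelengths = "numeric", sampleIds = "character")
)

setValidity("SpectrumTable", function(object) {
  if (ncol(object@X) != length(object@wavelengths))
    return("ncol(X) must equal length(wavelengths)")
  if (nrow(object@X) != length(object@sampleIds))
    return("nrow(X) must equal length(sampleIds)")
  if (length(object@wavelengths) > 1 && any(diff(object@wavelengths) <= 0))
    return("wavelengths must be strictly increasing")
  TRUE
})

#' Construct a SpectrumTable
#'
#' @param X samples x bands numeric matrix.
#' @param wavelengths band centres (nm).
#' @param sampleIds row labels; defaults to `rownames(X)` or `S001`, ...
#' @return A [SpectrumTable-class].
#' @export
SpectrumTable <- function(X, wavelengths, sampleIds = NULL) {
  X <- as.matrix(X)
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(rownames(X))) rownames(X) else
      sprintf("S%03d", seq_len(nrow(X)))
  rownames(X) <- sampleIds
  colnames(X) <- sprintf("%.2f", wavelengths)
  new("SpectrumTable", X = X, wavelengths = as.numeric(wavelengths),
      sampleIds = as.character(sampleIds))
}

#' @describeIn SpectrumTable compact display
#' @param object a `SpectrumTable`
#' @export
setMethod("show", "SpectrumTable", function(object) {
  cat(sprintf("SpectrumTable: %d samples x %d bands (%.1f-%.1f nm)\n",
              nrow(object@X), ncol(object@X),
              min(object@wavelengths), max(object@wavelengths)))
})

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectrumTable", function(x) x@wavelengths)

#' Sample identifiers of a SpectrumTable
#' @param x a `SpectrumTable`
#' @return character vector of sample ids.
#' @export
sampleIds <- function(x) x@sampleIds

#' Spectral matrix accessor
#' @param x a `SpectrumTable`
#' @return the samples x bands matrix.
#' @export
spectraMatrix <- function(x) {
  stopifnot(is(x, "SpectrumTable"))
  x@X
}

# ---------------------------------------------------------------------------
# PCImageStack: per-sample principal-component score images
# ---------------------------------------------------------------------------

#' PCImageStack class
#'
#' The first k (default 3) principal-component score images of one sample's
#' ROI cube, with the loading vectors, their explained-variance fractions
#' and the band means used for centering.
#'
#' @slot images rows x cols x k array of score images.
#' @slot loadings k x n_bands matrix; rows are orthonormal loading vectors.
#' @slot explainedVariance k fractions of total pixel variance,
#'   non-increasing, each in \[0, 1\].
#' @slot center band means removed before projection.
#' @slot sampleId label of the originating sample.
#' @export
setClass("PCImageStack",
  slots = c(images = "array", loadings = "matrix",
            explainedVariance = "numeric", center = "numeric",
            sampleId = "character")
)

setValidity("PCImageStack", function(object) {
  k <- dim(object@images)[3]
  if (nrow(object@loadings) != k || length(object@explainedVariance) != k)
    return("images, loadings and explainedVariance disagree on component count")
  ev <- object@explainedVariance
  if (any(ev < -1e-12) || any(ev > 1 + 1e-12))
    return("explainedVariance fractions must lie in [0, 1]")
  if (any(diff(ev) > 1e-12))
    return("explainedVariance must be non-increasing")
  G <- tcrossprod(object@loadings)
  if (max(abs(G - diag(k))) > 1e-6)
    return("loading rows must be orthonormal")
  TRUE
})

#' @describeIn PCImageStack compact display
#' @param object a `PCImageStack`
#' @export
setMethod("show", "PCImageStack", function(object) {
  d <- dim(object@images)
  cat(sprintf("PCImageStack [%s]: %d score images of %d x %d pixels\n",
              object@sampleId, d[3], d[1], d[2]))
  cat("  explained variance:",
      paste(sprintf("%.3f", object@explainedVariance), collapse = ", "), "\n")
})

#' Score image accessor
#' @param x a `PCImageStack`
#' @param k component index (1-based)
#' @return rows x cols matrix of PC-k scores.
#' @export
scoreImage <- function(x, k = 1) {
  stopifnot(is(x, "PCImageStack"), k >= 1, k <= dim(x@images)[3])
  x@images[, , k]
}

#' PCA loadings accessor
#' @param x a `PCImageStack`
#' @return k x n_bands matrix of loading vectors.
#' @export
pcLoadings <- function(x) {
  stopifnot(is(x, "PCImageStack"))
  x@loadings
}

# ---------------------------------------------------------------------------
# PLSModel: NIPALS partial least squares regression model
# ---------------------------------------------------------------------------

#' PLSModel class
#'
#' A univariate-response NIPALS PLS regression model. Predictors are
#' autoscaled (calibration mean/SD), the response is centred only, and the
#' composed coefficient vector reproduces the score-recursion predictions.
#'
#' @slot nLV number of latent variables.
#' @slot weights p x nLV matrix W of X-weights.
#' @slot xLoadings p x nLV matrix P of X-loadings.
#' @slot yLoadings length-nLV vector q of y-loadings.
#' @slot coef composed regression coefficients (scaled-X basis).
#' @slot intercept prediction intercept (the calibration mean of y).
#' @slot xCenter,xScale column statistics used for autoscaling.
#' @slot yCenter calibration mean of the response.
#' @export
setClass("PLSModel",
  slots = c(nLV = "integer", weights = "matrix", xLoadings = "matrix",
            yLoadings = "numeric", coef = "numeric", intercept = "numeric",
            xCenter = "numeric", xScale = "numeric", yCenter = "numeric")
)

setValidity("PLSModel", function(object) {
  a <- object@nLV
  p <- length(object@coef)
  if (a < 1L) return("nLV must be >= 1")
  if (ncol(object@weights) != a || ncol(object@xLoadings) != a ||
      length(object@yLoadings) != a)
    return("component dimensions disagree with nLV")
  if (nrow(object@weights) != p || length(object@xCenter) != p ||
      length(object@xScale) != p)
    return("predictor dimensions disagree")
  TRUE
})

#' @describeIn PLSModel compact display
#' @param object a `PLSModel`
#' @export
setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d predictors, %d latent variable(s)\n",
              length(object@coef), object@nLV))
})

# ---------------------------------------------------------------------------
# CARSResult
# ---------------------------------------------------------------------------

#' CARSResult class
#'
#' Result of competitive adaptive reweighted sampling: the wavelength subset
#' with minimum cross-validated RMSE over the Monte-Carlo runs, plus the
#' per-run RMSECV and retained-count traces.
#'
#' @slot selectedIndices column indices of the winning subset (sorted).
#' @slot selectedWavelengths corresponding wavelengths (nm); empty when no
#'   grid was supplied.
#' @slot rmsecvByRun cross-validated RMSE after each run.
#' @slot retainedCountByRun number of retained variables after each run
#'   (non-increasing, floor of 2).
#' @slot bestRun index of the run minimising RMSECV.
#' @slot subsets list of retained index sets per run.
#' @export
setClass("CARSResult",
  slots = c(selectedIndices = "integer", selectedWavelengths = "numeric",
            rmsecvByRun = "numeric", retainedCountByRun = "integer",
            bestRun = "integer", subsets = "list")
)

setValidity("CARSResult", function(object) {
  if (any(diff(object@retainedCountByRun) > 0L))
    return("retained counts must be non-increasing")
  b <- object@bestRun
  if (b < 1L || b > length(object@rmsecvByRun))
    return("bestRun out of range")
  if (!identical(object@selectedIndices,
                 as.integer(sort(object@subsets[[b]]))))
    return("selectedIndices must equal the best run's retained set")
  TRUE
})

#' @describeIn CARSResult compact display
#' @param object a `CARSResult`
#' @export
setMethod("show", "CARSResult", function(object) {
  cat(sprintf("CARSResult: %d variables selected at run %d/%d (RMSECV %.4g)\n",
              length(object@selectedIndices), object@bestRun,
              length(object@rmsecvByRun),
              object@rmsecvByRun[object@bestRun]))
  if (length(object@selectedWavelengths))
    cat("  wavelengths (nm):",
        paste(sprintf("%.0f", object@selectedWavelengths), collapse = ", "),
        "\n")
})

#' Selected wavelengths of a CARS result
#' @param x a `CARSResult`
#' @return numeric vector (nm).
#' @export
selectedWavelengths <- function(x) {
  stopifnot(is(x, "CARSResult"))
  x@selectedWavelengths
}

#' Selected variable indices
#' @param x a `CARSResult` or `SelectionReport`
#' @return for a `CARSResult`, sorted integer column indices; for a
#'   `SelectionReport`, the selected feature names.
#' @export
selectedVariables <- function(x) {
  if (is(x, "CARSResult")) return(x@selectedIndices)
  if (is(x, "SelectionReport")) return(x@selected)
  stop("selectedVariables() expects a CARSResult or SelectionReport")
}

# ---------------------------------------------------------------------------
# SelectionReport (texture correlation analysis)
# ---------------------------------------------------------------------------

#' SelectionReport class
#'
#' Pearson correlations between each texture feature and the response, and
#' the names passing the absolute-correlation threshold (strict >).
#'
#' @slot r named numeric vector of Pearson correlations.
#' @slot selected names with |r| > threshold.
#' @slot threshold the absolute-correlation cut-off.
#' @export
setClass("SelectionReport",
  slots = c(r = "numeric", selected = "character", threshold = "numeric")
)

setValidity("SelectionReport", function(object) {
  if (any(abs(object@r) > 1 + 1e-12)) return("|r| must be <= 1")
  if (!all(object@selected %in% names(object@r)))
    return("selected names must be a subset of the feature names")
  TRUE
})

#' @describeIn SelectionReport compact display
#' @param object a `SelectionReport`
#' @export
setMethod("show", "SelectionReport", function(object) {
  cat(sprintf("SelectionReport: %d/%d features with |r| > %.2f\n",
              length(object@selected), length(object@r), object@threshold))
  ord <- order(-abs(object@r))
  top <- utils::head(ord, 4)
  cat("  strongest:",
      paste(sprintf("%s (%.2f)", names(object@r)[top], object@r[top]),
            collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# SampleSplit
# ---------------------------------------------------------------------------

#' SampleSplit class
#'
#' Disjoint calibration/prediction partition of the samples (by index into
#' the original sample order).
#'
#' @slot calibration,prediction integer indices; disjoint, union = all.
#' @slot ids sample labels in original order.
#' @export
setClass("SampleSplit",
  slots = c(calibration = "integer", prediction = "integer", ids = "character")
)

setValidity("SampleSplit", function(object) {
  all_idx <- sort(c(object@calibration, object@prediction))
  if (anyDuplicated(all_idx))
    return("calibration and prediction sets must be disjoint")
  if (!identical(all_idx, seq_along(object@ids)))
    return("calibration and prediction must partition all samples")
  TRUE
})

#' @describeIn SampleSplit compact display
#' @param object a `SampleSplit`
#' @export
setMethod("show", "SampleSplit", function(object) {
  cat(sprintf("SampleSplit: %d calibration / %d prediction samples\n",
              length(object@calibration), length(object@prediction)))
})

# ---------------------------------------------------------------------------
# EvalReport
# ---------------------------------------------------------------------------

#' EvalReport class
#'
#' Regression performance of a fitted PLS model on a calibration/prediction
#' split: Pearson correlations (Rc, Rp), root-mean-square errors (RMSEC,
#' RMSEP, g/100 g) and the residual predictive deviation
#' RPD = SD(prediction-set reference) / RMSEP.
#'
#' @slot label name of the predictor set.
#' @slot nVars,nLV number of predictor variables / latent variables.
#' @slot rc,rmsec calibration-set correlation and RMSE.
#' @slot rp,rmsep prediction-set correlation and RMSE.
#' @slot rpd residual predictive deviation (>= 2 is usable for screening).
#' @export
setClass("EvalReport",
  slots = c(label = "character", nVars = "integer", nLV = "integer",
            rc = "numeric", rmsec = "numeric",
            rp = "numeric", rmsep = "numeric", rpd = "numeric")
)

setValidity("EvalReport", function(object) {
  if (object@rmsec < 0 || object@rmsep < 0) return("RMSE must be >= 0")
  if (abs(object@rc) > 1 + 1e-12 || abs(object@rp) > 1 + 1e-12)
    return("|R| must be <= 1")
  TRUE
})

#' @describeIn EvalReport compact display
#' @param object an `EvalReport`
#' @export
setMethod("show", "EvalReport", function(object) {
  cat(sprintf(
    "EvalReport [%s]: NVs=%d LVs=%d Rc=%.4f RMSEC=%.2f Rp=%.4f RMSEP=%.2f RPD=%.2f\n",
    object@label, object@nVars, object@nLV, object@rc, object@rmsec,
    object@rp, object@rmsep, object@rpd))
})

#' Convert an EvalReport (or list of them) to a one-row-per-model data.frame
#'
#' Columns follow the conventional model-comparison layout: data, NVs, LVs,
#' Rc, RMSEC, Rp, RMSEP, RPD.
#'
#' @param x an `EvalReport` or a list of them.
#' @return data.frame with one row per report.
#' @export
evalTable <- function(x) {
  if (is(x, "EvalReport")) x <- list(x)
  do.call(rbind, lapply(x, function(r) {
    data.frame(data = r@label, NVs = r@nVars, LVs = r@nLV,
               Rc = r@rc, RMSEC = r@rmsec, Rp = r@rp, RMSEP = r@rmsep,
               RPD = r@rpd, stringsAsFactors = FALSE)
  }))
}
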