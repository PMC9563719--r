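# ROI extraction, mean spectra and SNV preprocessing.

#' Extract a square region of interest
#'
#' Cuts an axis-aligned `size` x `size` sub-cube. Indexing follows a
#' 0-based half-open convention: the ROI starting at offset `s` covers
#' pixels `s .. s+size-1`. The default placement is centred,
#' `s = floor((dim - size) / 2)` per axis.
#'
#' @param cube a [Hypercube-class].
#' @param center optional `(row, col)` ROI centre (1-based pixel index); by
#'   default the image centre.
#' @param size ROI edge length in pixels (default 100).
#' @return A [Hypercube-class] of `size` x `size` pixels.
#' @export
extractROI <- function(cube, center = NULL, size = 100) {
  stopifnot(is(cube, "Hypercube"), size >= 1)
  d <- dim(cube@data)
  if (size > d[1] || size > d[2])
    stop(sprintf("ROI of %d px does not fit a %d x %d cube", size, d[1], d[2]))
  if (is.null(center)) {
    r0 <- floor((d[1] - size) / 2)   # 0-based start, centred placement
    c0 <- floor((d[2] - size) / 2)
  } else {
    # start = centre pixel (0-based) - floor(size/2); for the default
    # centre pixel floor(dim/2) this reduces to floor((dim - size)/2)
    r0 <- round(center[1]) - 1 - floor(size / 2)
    c0 <- round(center[2]) - 1 - floor(size / 2)
  }
  if (r0 < 0 || c0 < 0 || r0 + size > d[1] || c0 + size > d[2])
    stop("ROI exceeds cube bounds")
  Hypercube(cube@data[(r0 + 1):(r0 + size), (c0 + 1):(c0 + size), ,
                      drop = FALSE],
            cube@wavelengths)
}

#' ROI mean spectrum
#'
#' Per-band arithmetic mean over all pixels of a (ROI) cube.
#'
#' @param roi a [Hypercube-class].
#' @return numeric vector of length `n_bands`, named by wavelength.
#' @export
meanSpectrum <- function(roi) {
  stopifnot(is(roi, "Hypercube"))
  d <- dim(roi@data)
  m <- colMeans(matrix(roi@data, nrow = d[1] * d[2], ncol = d[3]))
  names(m) <- sprintf("%.2f", roi@wavelengths)
  m
}

#' Standard normal variate (SNV) preprocessing
#'
#' Row-wise normalisation of a spectral matrix: each spectrum has its mean
#' subtracted and is divided by its standard deviation (n-1 denominator),
#' removing additive baseline offsets and multiplicative scatter effects.
#'
#' @param X a [SpectrumTable-class] or a samples x bands numeric matrix.
#' @return object of the same type with every row at mean 0, SD 1.
#' @examples
#' snv(matrix(c(1, 2, 3), nrow = 1))  # -1 0 1
#' @export
snv <- function(X) {
  if (is(X, "SpectrumTable")) {
    out <- snv(X@X)
    return(SpectrumTable(out, X@wavelengths, X@sampleIds))
  }
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("SNV needs at least two bands")
  mu <- rowMeans(X)
  sdev <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1))
  zero <- sdev <= 0
  if (any(zero)) {
    who <- if (!is.null(rownames(X))) rownames(X)[zero] else which(zero)
    stop("constant spectrum (zero SD), cannot apply SNV: sample ",
         paste(who, collapse = ", "))
  }
  (X - mu) / sdev
}

#' Serialize / read a SpectrumTable as CSV
#'
#' First column `sample_id`, remaining columns named by wavelength (nm, two
#' decimals).
#'
#' @param x a [SpectrumTable-class].
#' @param path CSV file path.
#' @return `writeSpectrumTable` invisibly returns `path`;
#'   `readSpectrumTable` returns a [SpectrumTable-class].
#' @export
writeSpectrumTable <- function(x, path) {
  stopifnot(is(x, "SpectrumTable"))
  df <- data.frame(sample_id = x@sampleIds, x@X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectrumTable
#' @export
readSpectrumTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wl <- as.numeric(colnames(df)[-1])
  SpectrumTable(as.matrix(df[, -1, drop = FALSE]), wl, df$sample_id)
}
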