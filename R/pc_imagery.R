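# Per-sample PCA score images and gray-level quantization.

#' Principal-component score images of a cube
#'
#' Treats every ROI pixel as an observation and every band as a variable,
#' mean-centres, and projects onto the leading principal components,
#' producing one spatial score image per component. Components are ordered
#' by decreasing explained variance; each loading vector is oriented so its
#' largest-magnitude element is positive, which stabilises score-image sign
#' across samples.
#'
#' The decomposition uses the eigendecomposition of the bands x bands pixel
#' covariance (via a crossproduct of the centred pixel matrix), which for
#' reflectance data of magnitude ~1 is numerically equivalent to an SVD of
#' the pixel matrix and far cheaper for 10^4 pixels x 428 bands.
#'
#' @param roi a [Hypercube-class] (typically the extracted ROI).
#' @param nComponents number of components to keep (default 3).
#' @param sampleId label stored in the result.
#' @return A [PCImageStack-class].
#' @export
pcaScoreImages <- function(roi, nComponents = 3, sampleId = "sample") {
  stopifnot(is(roi, "Hypercube"), nComponents >= 1)
  d <- dim(roi@data)
  npix <- d[1] * d[2]
  if (npix <= nComponents)
    stop("ROI pixel count must exceed the number of components")
  M <- matrix(roi@data, nrow = npix, ncol = d[3])
  mu <- colMeans(M)
  Mc <- sweep(M, 2, mu)
  C <- crossprod(Mc) / (npix - 1)
  total_var <- sum(diag(C))
  if (total_var <= 0)
    stop("degenerate cube: zero pixel variance, PCA undefined")
  ee <- eigen(C, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  k <- min(nComponents, ncol(M))
  V <- ee$vectors[, seq_len(k), drop = FALSE]
  # sign convention: largest-|.| loading element positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) V[, j] <- -V[, j]
  }
  scores <- Mc %*% V
  new("PCImageStack",
      images = array(scores, dim = c(d[1], d[2], k)),
      loadings = t(V),
      explainedVariance = vals[seq_len(k)] / total_var,
      center = mu,
      sampleId = sampleId)
}

#' Quantize an image to discrete gray levels
#'
#' Linear min-max mapping to integers `0 .. levels-1`: the minimum maps to
#' level 0, the maximum to `levels - 1` and intermediate values by
#' `floor((x - min) / (max - min) * levels)` capped at `levels - 1`. A
#' constant image maps entirely to level 0. The mapping is invariant to
#' positive affine transforms of the input.
#'
#' @param image numeric matrix with finite entries.
#' @param levels number of gray levels (default 64).
#' @return integer matrix with values in `{0, ..., levels - 1}`.
#' @export
quantizeImage <- function(image, levels = 64) {
  stopifnot(is.matrix(image), levels >= 2)
  if (!all(is.finite(image)))
    stop("image contains non-finite pixels")
  rng <- range(image)
  if (rng[1] == rng[2])
    return(matrix(0L, nrow(image), ncol(image)))
  q <- floor((image - rng[1]) / (rng[2] - rng[1]) * levels)
  mode(q) <- "integer"
  q[q > levels - 1L] <- levels - 1L
  q
}
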