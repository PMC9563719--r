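# Gray-level co-occurrence matrices and Haralick-type texture features.
#
# Conventions: symmetric GLCM (both pair orders accumulated), normalised to
# sum 1; offsets with rows increasing downward are 0 deg -> (0, +d),
# 45 deg -> (-d, +d), 90 deg -> (-d, 0), 135 deg -> (-d, -d).

.glcm_offsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                      `90` = c(-1L, 0L), `135` = c(-1L, -1L))

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurring gray-level pairs at a fixed offset, accumulated in
#' both orders (symmetric) and normalised to total probability 1.
#'
#' @param image_q integer matrix of gray levels in `{0, ..., levels - 1}`
#'   (see [quantizeImage()]).
#' @param levels number of gray levels.
#' @param distance offset length in pixels (default 1).
#' @param angle direction in degrees, one of 0, 45, 90, 135.
#' @return `levels` x `levels` probability matrix.
#' @export
glcm <- function(image_q, levels = 64, distance = 1,
                 angle = c(0, 45, 90, 135)) {
  angle <- as.character(angle[1])
  off <- .glcm_offsets[[angle]]
  if (is.null(off)) stop("angle must be one of 0, 45, 90, 135")
  stopifnot(is.matrix(image_q), distance >= 1)
  if (any(image_q < 0L) || any(image_q > levels - 1L))
    stop("image values must lie in {0, ..., levels-1}")
  dr <- off[1] * distance; dc <- off[2] * distance
  nr <- nrow(image_q); nc <- ncol(image_q)
  if (nr - abs(dr) < 1 || nc - abs(dc) < 1)
    stop("image too small for the requested offset")
  r1 <- (1 + max(0, -dr)):(nr - max(0, dr))
  c1 <- (1 + max(0, -dc)):(nc - max(0, dc))
  i <- image_q[r1, c1, drop = FALSE]
  j <- image_q[r1 + dr, c1 + dc, drop = FALSE]
  idx <- c(i * levels + j, j * levels + i) + 1L    # symmetric accumulation
  counts <- tabulate(idx, nbins = levels * levels)
  P <- matrix(counts, levels, levels, byrow = TRUE)
  P / sum(P)
}

#' Texture features of a GLCM
#'
#' The four standard scalar statistics:
#' contrast \eqn{\sum_{ij} (i-j)^2 p_{ij}},
#' correlation \eqn{\sum_{ij} (i-\mu_i)(j-\mu_j) p_{ij} / (\sigma_i \sigma_j)},
#' entropy \eqn{-\sum p_{ij} \log_2 p_{ij}} (bits, p > 0 terms only), and
#' uniformity (angular second moment) \eqn{\sum p_{ij}^2}. When the GLCM is
#' degenerate (\eqn{\sigma_i \sigma_j = 0}, e.g. a constant image) the
#' correlation is defined as 0.
#'
#' @param P a GLCM probability matrix (see [glcm()]).
#' @return named numeric vector `c(correlation, contrast, entropy,
#'   uniformity)`.
#' @export
glcmFeatures <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (abs(sum(P) - 1) > 1e-8) stop("GLCM must be normalised to sum 1")
  lv <- seq_len(nrow(P)) - 1
  pi_ <- rowSums(P)
  pj_ <- colSums(P)
  mu_i <- sum(lv * pi_)
  mu_j <- sum(lv * pj_)
  var_i <- sum((lv - mu_i)^2 * pi_)
  var_j <- sum((lv - mu_j)^2 * pj_)
  D <- outer(lv, lv, "-")
  contrast <- sum(D^2 * P)
  corr <- if (var_i <= 0 || var_j <= 0) 0 else
    sum(outer(lv - mu_i, lv - mu_j) * P) / sqrt(var_i * var_j)
  pp <- P[P > 0]
  entropy <- -sum(pp * log2(pp))
  c(correlation = corr, contrast = contrast, entropy = entropy,
    uniformity = sum(P^2))
}

#' Texture feature names
#'
#' Column names of the texture feature table, `{feature}_PC{k}` with
#' features ordered correlation, contrast, entropy, uniformity within each
#' principal-component image.
#'
#' @param nComponents number of PC images (default 3).
#' @return character vector of length `4 * nComponents`.
#' @export
textureFeatureNames <- function(nComponents = 3) {
  as.vector(vapply(seq_len(nComponents), function(k)
    paste0(c("correlation", "contrast", "entropy", "uniformity"), "_PC", k),
    character(4)))
}

#' Direction-averaged texture vector of a PC image stack
#'
#' For each score image: quantize to `levels` gray levels, compute the GLCM
#' at distance 1 in the four directions (0, 45, 90, 135 degrees), compute
#' the four features per direction and average each feature over the
#' directions. Blocks are concatenated PC1, PC2, PC3 in feature order
#' correlation, contrast, entropy, uniformity, giving 12 values for the
#' default 3-component stack.
#'
#' @param stack a [PCImageStack-class].
#' @param levels gray levels for quantization (default 64).
#' @param distance GLCM offset length (default 1).
#' @return named numeric vector of length `4 * nComponents`.
#' @export
textureVector <- function(stack, levels = 64, distance = 1) {
  stopifnot(is(stack, "PCImageStack"))
  k <- dim(stack@images)[3]
  out <- lapply(seq_len(k), function(ki) {
    q <- quantizeImage(stack@images[, , ki], levels)
    feats <- vapply(c(0, 45, 90, 135), function(a)
      glcmFeatures(glcm(q, levels, distance, a)), numeric(4))
    rowMeans(feats)
  })
  v <- unlist(out, use.names = FALSE)
  names(v) <- textureFeatureNames(k)
  v
}

#' Assemble a texture feature table
#'
#' Stacks per-sample texture vectors into an n_samples x 12 matrix with
#' `{feature}_PC{k}` column names.
#'
#' @param vectors a list of vectors from [textureVector()] (or a matrix).
#' @param sampleIds optional row labels.
#' @return numeric matrix, one row per sample.
#' @export
textureTable <- function(vectors, sampleIds = NULL) {
  T <- if (is.matrix(vectors)) vectors else do.call(rbind, vectors)
  if (!is.null(sampleIds)) rownames(T) <- sampleIds
  T
}
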