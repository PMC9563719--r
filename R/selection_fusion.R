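# CARS wavelength selection, correlation-based texture selection, and
# low-/mid-level block fusion.

#' CARS configuration
#'
#' Hyperparameters of competitive adaptive reweighted sampling. Defaults
#' follow the method's canonical settings: 50 Monte-Carlo runs, 80%
#' calibration sampling per run, at most 10 latent variables inside the
#' selector and 5-fold cross-validation for scoring each retained subset.
#'
#' @param nRuns number of Monte-Carlo runs N (>= 2).
#' @param calibFraction fraction of samples drawn per run (0 < f < 1).
#' @param maxLV latent-variable ceiling for the internal PLS models.
#' @param cvFolds folds for the per-run RMSECV.
#' @param seed RNG seed; the whole selection is deterministic given it.
#' @return a list of class `CARSConfig`.
#' @export
carsConfig <- function(nRuns = 50, calibFraction = 0.8, maxLV = 10,
                       cvFolds = 5, seed = 1) {
  stopifnot(nRuns >= 2, calibFraction > 0, calibFraction < 1,
            maxLV >= 1, cvFolds >= 2)
  structure(list(nRuns = as.integer(nRuns), calibFraction = calibFraction,
                 maxLV = as.integer(maxLV), cvFolds = as.integer(cvFolds),
                 seed = seed),
            class = "CARSConfig")
}

#' Exponentially decreasing retention schedule
#'
#' The fraction of variables retained at CARS run i follows
#' \eqn{r_i = a e^{-k i}} with the two boundary conditions \eqn{r_1 = 1}
#' (all p variables kept at the first run) and \eqn{r_N = 2/p} (two
#' variables at the last), i.e. \eqn{k = \log(p/2)/(N-1)} and
#' \eqn{a = e^{k}}.
#'
#' @param i run index, `1 <= i <= N`.
#' @param N total number of runs.
#' @param p total number of variables (> 2).
#' @return retention fraction in (0, 1].
#' @examples
#' edfRatio(1, 50, 428)            # 1
#' edfRatio(50, 50, 428) * 428     # 2
#' @export
edfRatio <- function(i, N, p) {
  stopifnot(i >= 1, i <= N, N >= 2)
  if (p <= 2) stop("EDF schedule requires p > 2 variables")
  k <- log(p / 2) / (N - 1)
  exp(-k * (i - 1))
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Iterative wavelength selection. At run i (of N): (a) a Monte-Carlo
#' calibration subset of `ceiling(calibFraction * n)` samples is drawn
#' without replacement; (b) a PLS model is fitted on the currently retained
#' variables (autoscaled internally); (c) each variable is weighted by its
#' normalised absolute regression coefficient \eqn{w_j = |b_j|/\sum|b|};
#' (d) enforced selection keeps the top `ceiling(edfRatio(i, N, p) * p)`
#' variables by weight, never fewer than 2; (e) adaptive reweighted
#' sampling draws the retained set for the next run from those with
#' probability proportional to \eqn{w_j}, without replacement and at the
#' same count; (f) the retained subset is scored by k-fold RMSECV of a PLS
#' model on all n samples. The subset with minimum RMSECV wins. The whole
#' procedure is deterministic given `config$seed`.
#'
#' @param X n x p predictor matrix (n >= 10, p >= 3).
#' @param y length-n response.
#' @param config a [carsConfig()] list.
#' @param wavelengths optional band grid; stored selections are reported in
#'   nm as well as column indices.
#' @return A [CARSResult-class].
#' @export
carsSelect <- function(X, y, config = carsConfig(), wavelengths = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(inherits(config, "CARSConfig"))
  if (n < 10) stop("CARS needs at least 10 samples")
  if (p < 3) stop("CARS needs at least 3 variables")
  if (!is.null(wavelengths) && length(wavelengths) != p)
    stop("wavelengths length must match ncol(X)")
  N <- config$nRuns
  withSeed(config$seed, {
    retained <- seq_len(p)
    subsets <- vector("list", N)
    rmsecv <- numeric(N)
    counts <- integer(N)
    for (i in seq_len(N)) {
      cal <- sort(sample.int(n, ceiling(config$calibFraction * n)))
      a_fit <- min(config$maxLV, length(retained), length(cal) - 1)
      m <- plsFit(X[cal, retained, drop = FALSE], y[cal], a_fit)
      w <- abs(m@coef)
      if (sum(w) <= 0) w <- rep(1, length(w))
      w <- w / sum(w)
      # epsilon guards against FP dust in r_i * p at the boundaries
      keep <- max(2L, min(length(retained),
                          as.integer(ceiling(edfRatio(i, N, p) * p - 1e-9))))
      top <- order(w, decreasing = TRUE)[seq_len(keep)]
      # adaptive reweighted sampling: weighted draw without replacement of
      # `keep` variables from the enforced top set (membership-preserving
      # by construction; kept for fidelity to the sampling formulation)
      ars <- sample(top, size = keep, replace = FALSE, prob = w[top])
      retained <- sort(retained[ars])
      subsets[[i]] <- retained
      counts[i] <- length(retained)
      a_cv <- min(config$maxLV, length(retained),
                  n - ceiling(n / config$cvFolds) - 1)
      cv <- selectLvCV(X[, retained, drop = FALSE], y,
                       maxLV = a_cv, folds = config$cvFolds,
                       seed = sample.int(.Machine$integer.max, 1))
      rmsecv[i] <- min(cv$rmsecv)
    }
    best <- which.min(rmsecv)
    sel <- as.integer(subsets[[best]])
    new("CARSResult",
        selectedIndices = sel,
        selectedWavelengths = if (is.null(wavelengths)) numeric(0) else
          as.numeric(wavelengths[sel]),
        rmsecvByRun = rmsecv,
        retainedCountByRun = counts,
        bestRun = as.integer(best),
        subsets = subsets)
  })
}

#' Correlation-based texture variable selection
#'
#' Pearson correlation of each texture feature with the response; features
#' whose absolute correlation strictly exceeds the threshold are selected.
#' Constant columns get r = 0 (never selected).
#'
#' @param T n x k feature matrix with column names.
#' @param y length-n response (n >= 3).
#' @param threshold absolute-correlation cut-off (default 0.3, strict >).
#' @return A [SelectionReport-class].
#' @export
correlationSelect <- function(T, y, threshold = 0.3) {
  T <- as.matrix(T)
  n <- nrow(T)
  stopifnot(length(y) == n)
  if (n < 3) stop("correlation selection needs at least 3 samples")
  if (is.null(colnames(T)))
    colnames(T) <- sprintf("V%d", seq_len(ncol(T)))
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  r <- vapply(seq_len(ncol(T)), function(j) {
    xc <- T[, j] - mean(T[, j])
    sx <- sqrt(sum(xc^2))
    if (sx == 0 || sy == 0) 0 else sum(xc * yc) / (sx * sy)
  }, numeric(1))
  names(r) <- colnames(T)
  new("SelectionReport", r = r,
      selected = colnames(T)[abs(r) > threshold],
      threshold = threshold)
}

#' Low-level fusion
#'
#' Column-wise concatenation of the full spectral block and the full
#' texture block (spectral first), preserving column names. An empty
#' texture block returns the spectral matrix unchanged.
#'
#' @param X n x p spectral matrix (or [SpectrumTable-class]).
#' @param T n x k texture matrix.
#' @return n x (p + k) matrix.
#' @export
fuseLow <- function(X, T) {
  if (is(X, "SpectrumTable")) X <- X@X
  X <- as.matrix(X)
  if (is.null(T) || NCOL(T) == 0) return(X)
  T <- as.matrix(T)
  if (nrow(X) != nrow(T))
    stop(sprintf("row mismatch: %d spectral vs %d texture samples",
                 nrow(X), nrow(T)))
  cbind(X, T)
}

#' Mid-level fusion
#'
#' Concatenation of the CARS-selected spectral columns and the
#' correlation-selected texture columns, in that order.
#'
#' @param X n x p spectral matrix (or [SpectrumTable-class]).
#' @param cars a [CARSResult-class] (or an integer vector of column
#'   indices).
#' @param T n x k texture matrix with column names.
#' @param sel a [SelectionReport-class] (or a character vector of selected
#'   column names).
#' @return n x (k1 + k2) matrix of the selected variables.
#' @export
fuseMid <- function(X, cars, T, sel) {
  if (is(X, "SpectrumTable")) X <- X@X
  X <- as.matrix(X); T <- as.matrix(T)
  idx <- if (is(cars, "CARSResult")) cars@selectedIndices else as.integer(cars)
  keep <- if (is(sel, "SelectionReport")) sel@selected else as.character(sel)
  if (length(idx) == 0 && length(keep) == 0)
    stop("both selections are empty; nothing to fuse")
  if (nrow(X) != nrow(T))
    stop("row mismatch between spectral and texture blocks")
  cbind(X[, idx, drop = FALSE], T[, keep, drop = FALSE])
}
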