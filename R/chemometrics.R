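# NIPALS PLS regression, cross-validated latent-variable selection,
# rank-order sample splitting and Rc/RMSE/RPD evaluation.

#' Rank-order calibration/prediction split
#'
#' Sorts the samples by response value (ascending, ties kept in input
#' order), partitions them into consecutive triplets and assigns the middle
#' sample of every full triplet to the prediction set; the rest (including
#' any leftover 1-2 samples) form the calibration set. With n divisible by
#' 3 this yields a 2n/3 / n/3 split whose prediction-set range lies inside
#' the calibration-set range.
#'
#' @param y numeric response vector (n >= 3).
#' @param ids optional sample labels.
#' @return A [SampleSplit-class].
#' @examples
#' s <- rankOrderSplit(c(1, 2, 3, 4, 5, 6))
#' s@prediction   # samples with y = 2 and 5
#' @export
rankOrderSplit <- function(y, ids = NULL) {
  n <- length(y)
  if (n < 3) stop("need at least 3 samples to split")
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  ord <- order(y)                     # stable: ties by input order
  n_full <- n %/% 3
  pred <- ord[3 * seq_len(n_full) - 1]
  cal <- setdiff(seq_len(n), pred)
  new("SampleSplit", calibration = as.integer(sort(cal)),
      prediction = as.integer(sort(pred)), ids = as.character(ids))
}

# Autoscaling statistics; zero-SD columns get scale 1 (they then carry no
# information but do not poison the fit).
.autoscale_stats <- function(X) {
  ctr <- colMeans(X)
  scl <- colSds(X)
  scl[scl <= 0] <- 1
  list(center = ctr, scale = scl)
}

#' Fit a NIPALS PLS regression model
#'
#' Univariate-response partial least squares by the NIPALS algorithm:
#' components are extracted sequentially, each maximising covariance
#' between an X-score and the (deflated) response, with X deflation after
#' every component. Predictors are autoscaled internally (mean 0, SD 1 per
#' column, calibration statistics); the response is centred only. The
#' composed coefficient vector b satisfies
#' `predict = scale(X_new) %*% b + mean(y)`.
#'
#' @param X n x p predictor matrix.
#' @param y length-n response.
#' @param nLV number of latent variables, `1 <= nLV <= min(n - 1, p)`.
#' @return A [PLSModel-class].
#' @seealso [plsPredict()], [selectLvCV()]
#' @export
plsFit <- function(X, y, nLV) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  nLV <- as.integer(nLV)
  if (nLV < 1 || nLV > min(n - 1, p))
    stop(sprintf("nLV must be in 1..min(n-1, p) = %d", min(n - 1, p)))
  if (stats::sd(y) == 0) stop("response has zero variance")
  st <- .autoscale_stats(X)
  Xs <- sweep(sweep(X, 2, st$center), 2, st$scale, "/")
  y_ctr <- mean(y)
  yd <- y - y_ctr
  W <- P <- matrix(0, p, nLV)
  q <- numeric(nLV)
  Xd <- Xs
  for (a in seq_len(nLV)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) {            # residual orthogonal to y: stop early
      nLV <- a - 1L
      if (nLV < 1L) stop("predictors carry no covariance with the response")
      W <- W[, seq_len(nLV), drop = FALSE]
      P <- P[, seq_len(nLV), drop = FALSE]
      q <- q[seq_len(nLV)]
      break
    }
    w <- w / nw
    t_ <- Xd %*% w
    tt <- sum(t_^2)
    p_ <- crossprod(Xd, t_) / tt
    q_ <- sum(yd * t_) / tt
    Xd <- Xd - tcrossprod(t_, p_)
    yd <- yd - q_ * t_
    W[, a] <- w; P[, a] <- p_; q[a] <- q_
  }
  R <- W %*% solve(crossprod(P, W))
  b <- as.numeric(R %*% q)
  new("PLSModel", nLV = nLV, weights = W, xLoadings = P, yLoadings = q,
      coef = b, intercept = y_ctr, xCenter = st$center, xScale = st$scale,
      yCenter = y_ctr)
}

#' Predict from a PLS model
#'
#' @param model a [PLSModel-class].
#' @param X_new matrix with the same column count (and order) as the
#'   calibration predictors.
#' @return numeric vector of predictions.
#' @export
plsPredict <- function(model, X_new) {
  stopifnot(is(model, "PLSModel"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model@coef))
    stop(sprintf("X_new has %d columns, model expects %d",
                 ncol(X_new), length(model@coef)))
  Xs <- sweep(sweep(X_new, 2, model@xCenter), 2, model@xScale, "/")
  as.numeric(Xs %*% model@coef + model@intercept)
}

# Cumulative predictions after 1..nLV components, via the score recursion.
# Used by cross-validation so one fit serves every component count.
.pls_predict_components <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  Xd <- sweep(sweep(X_new, 2, model@xCenter), 2, model@xScale, "/")
  a_max <- model@nLV
  out <- matrix(0, nrow(X_new), a_max)
  acc <- rep(model@intercept, nrow(X_new))
  for (a in seq_len(a_max)) {
    t_ <- Xd %*% model@weights[, a, drop = FALSE]
    Xd <- Xd - tcrossprod(t_, model@xLoadings[, a, drop = FALSE])
    acc <- acc + model@yLoadings[a] * t_
    out[, a] <- acc
  }
  out
}

#' Cross-validated latent-variable selection
#'
#' K-fold cross-validation of the NIPALS PLS model over component counts
#' `1..maxLV`. Folds are contiguous blocks of a seeded random shuffle of
#' the samples. The selected count is the smallest one within 1e-10 of the
#' minimum RMSECV (parsimony tie-break). If `maxLV` exceeds the feasible
#' rank for some training fold it is truncated with a warning.
#'
#' @param X n x p predictor matrix.
#' @param y length-n response.
#' @param maxLV largest component count to consider (default 15).
#' @param folds number of folds (default 5); `folds = n` gives
#'   leave-one-out.
#' @param seed RNG seed for the shuffle.
#' @return list with elements `bestLV` and `rmsecv` (one value per
#'   component count).
#' @export
selectLvCV <- function(X, y, maxLV = 15, folds = 5, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, folds >= 2, folds <= n)
  fold_sizes <- rep(n %/% folds, folds) + c(rep(1, n %% folds),
                                            rep(0, folds - n %% folds))
  min_train <- n - max(fold_sizes)
  a_eff <- min(maxLV, min_train - 1, ncol(X))
  if (a_eff < maxLV)
    warning(sprintf("maxLV truncated from %d to %d (feasible rank)",
                    maxLV, a_eff))
  if (a_eff < 1) stop("too few samples for cross-validation")
  perm <- withSeed(seed, sample.int(n))
  fold_id <- rep(seq_len(folds), times = fold_sizes)
  sse <- numeric(a_eff)
  for (f in seq_len(folds)) {
    val <- perm[fold_id == f]
    tr <- setdiff(perm, val)
    m <- plsFit(X[tr, , drop = FALSE], y[tr], a_eff)
    pred <- .pls_predict_components(m, X[val, , drop = FALSE])
    a_m <- m@nLV                      # may be < a_eff if X ran out of signal
    if (a_m < a_eff)
      pred <- cbind(pred, matrix(pred[, a_m], nrow(pred), a_eff - a_m))
    sse <- sse + colSums((pred - y[val])^2)
  }
  rmsecv <- sqrt(sse / n)
  best <- which(rmsecv <= min(rmsecv) + 1e-10)[1]
  list(bestLV = as.integer(best), rmsecv = rmsecv)
}

#' Regression metrics
#'
#' Pearson correlation and root-mean-square error between observed and
#' predicted values, plus the residual predictive deviation
#' `RPD = sd(obs) / RMSE` (n-1 SD). Used on the prediction set this is the
#' conventional RPD; a perfect fit reports `RPD = Inf`.
#'
#' @param obs,pred numeric vectors of equal length.
#' @return list with elements `r`, `rmse`, `rpd`.
#' @export
regressionMetrics <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) >= 2)
  rmse <- sqrt(mean((obs - pred)^2))
  r <- if (stats::sd(pred) == 0 || stats::sd(obs) == 0) 0 else
    stats::cor(obs, pred)
  rpd <- if (rmse == 0) Inf else stats::sd(obs) / rmse
  list(r = r, rmse = rmse, rpd = rpd)
}

#' Evaluate a fitted PLS model on a calibration/prediction split
#'
#' Computes Rc/RMSEC on the calibration set, Rp/RMSEP on the prediction
#' set, and RPD = SD(prediction-set reference values) / RMSEP.
#'
#' @param model a [PLSModel-class] fitted on the calibration set.
#' @param X_cal,y_cal calibration predictors and reference values.
#' @param X_pred,y_pred prediction-set predictors and reference values.
#' @param label name of the predictor set (for reporting).
#' @return An [EvalReport-class].
#' @export
evaluateModel <- function(model, X_cal, y_cal, X_pred, y_pred,
                          label = "model") {
  mc <- regressionMetrics(y_cal, plsPredict(model, X_cal))
  mp <- regressionMetrics(y_pred, plsPredict(model, X_pred))
  new("EvalReport", label = label, nVars = length(model@coef),
      nLV = model@nLV, rc = mc$r, rmsec = mc$rmse,
      rp = mp$r, rmsep = mp$rmse,
      rpd = if (mp$rmse == 0) Inf else stats::sd(y_pred) / mp$rmse)
}
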