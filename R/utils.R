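# Internal helpers.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. seed = NULL uses the current stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Column standard deviations with the n-1 denominator.
colSds <- function(X) {
  n <- nrow(X)
  if (n < 2) stop("need at least two rows to compute column SDs")
  mu <- colMeans(X)
  sqrt(colSums(sweep(X, 2, mu)^2) / (n - 1))
}

#' Default wavelength grid
#'
#' The 428-point visible/near-infrared grid spanning 382-1004 nm used by
#' the pipeline's reference instrument configuration.
#'
#' @return numeric vector of 428 band centres (nm).
#' @examples
#' length(defaultWavelengths())
#' range(defaultWavelengths())
#' @export
defaultWavelengths <- function() {
  seq(382, 1004, length.out = 428)
}
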