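# Intensities are modelled on log10 scale: ion counts span several orders
# of magnitude and the decoder's inverse transform (de-standardize, then
# exponentiate) guarantees strictly positive output intensities.

#' Log-transform and standardize an intensity matrix
#'
#' Computes `z = (log10(x) - mu) / sigma` per feature, where `mu` and
#' `sigma` are the feature-wise mean and standard deviation of the
#' log10 intensities.  Constant features (zero standard deviation) are
#' centered but not scaled.
#'
#' @param m numeric matrix of strictly positive intensities,
#'   samples in rows, features in columns.
#' @return A list with `x` (the standardized matrix), `mu` and `sigma`
#'   (feature-wise statistics, on log10 scale), to be passed to
#'   [inverse_preprocess()].
#' @seealso [inverse_preprocess()]
#' @export
preprocess_intensities <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("preprocess_intensities() requires strictly positive, finite intensities; ",
         "run apply_min_intensity() first")
  }
  lx <- log10(m)
  mu <- colMeans(lx)
  sigma <- apply(lx, 2, sd)
  sigma[sigma < .Machine$double.eps] <- 1  # constant features: center only
  x <- sweep(sweep(lx, 2, mu, "-"), 2, sigma, "/")
  list(x = x, mu = mu, sigma = sigma)
}

#' Map a standardized matrix back to intensity scale
#'
#' Inverse of [preprocess_intensities()]: de-standardizes with the stored
#' feature statistics and exponentiates (base 10).  Output is strictly
#' positive by construction.
#'
#' @param x standardized matrix (samples x features).
#' @param pp preprocessing statistics as returned by
#'   [preprocess_intensities()].
#' @return Numeric matrix on intensity scale.
#' @export
inverse_preprocess <- function(x, pp) {
  stopifnot(is.matrix(x), ncol(x) == length(pp$mu))
  10^(sweep(sweep(x, 2, pp$sigma, "*"), 2, pp$mu, "+"))
}
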