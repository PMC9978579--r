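# Autoencoder + batch classifier.  The architecture is deliberately
# shallow (one leaky-ReLU hidden layer of bottleneck width on each side
# of the bottleneck, linear softmax classifier on the latent codes) so a
# full grid search stays desk-scale on one CPU.  Weights live in a plain
# list; gradients are computed analytically in training.R.

#' Choose the bottleneck width by principal component analysis
#'
#' Returns the smallest number of principal components whose cumulative
#' explained variance reaches `variance_ratio` (default 0.9).  PCA is run
#' on the preprocessed (log10, feature-standardized) matrix, so variance
#' is on correlation scale and high-abundance features do not dominate.
#'
#' @param x preprocessed matrix (samples x features), see
#'   [preprocess_intensities()].
#' @param variance_ratio target cumulative explained-variance fraction in
#'   (0, 1].
#' @return Integer bottleneck width `k`, `1 <= k <= min(n_samples - 1,
#'   n_features)`.
#' @export
select_latent_dim <- function(x, variance_ratio = 0.9) {
  stopifnot(is.matrix(x), variance_ratio > 0, variance_ratio <= 1)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  tot <- sum(ev)
  if (tot < .Machine$double.eps) stop("matrix has zero total variance")
  cum <- cumsum(ev) / tot
  k <- which(cum >= variance_ratio - 1e-12)[1]
  if (is.na(k)) k <- length(ev)
  as.integer(k)
}

#' Build encoder, decoder and batch classifier
#'
#' Encoder: `n_features -> latent_dim (leaky ReLU) -> latent_dim`
#' (linear bottleneck).  Decoder mirrors the encoder back to
#' `n_features`.  Classifier: linear map `latent_dim -> n_batches`
#' followed by softmax.  Initialization is Glorot-uniform and
#' reproducible from `seed`.
#'
#' @param n_features input width.
#' @param latent_dim bottleneck width (see [select_latent_dim()]).
#' @param n_batches number of batch classes.
#' @param seed integer seed for weight initialization.
#' @return Object of class `"mb_model"`: list of weight matrices/biases
#'   `W1..W5`, `b1..b5` plus dimensions.
#' @export
build_models <- function(n_features, latent_dim, n_batches, seed = 1) {
  stopifnot(latent_dim >= 1, latent_dim <= n_features, n_batches >= 2)
  set.seed(seed)
  glorot <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(runif(nin * nout, -lim, lim), nin, nout)
  }
  structure(list(
    W1 = glorot(n_features, latent_dim), b1 = numeric(latent_dim),
    W2 = glorot(latent_dim, latent_dim), b2 = numeric(latent_dim),
    W3 = glorot(latent_dim, latent_dim), b3 = numeric(latent_dim),
    W4 = glorot(latent_dim, n_features), b4 = numeric(n_features),
    W5 = glorot(latent_dim, n_batches), b5 = numeric(n_batches),
    n_features = n_features, latent_dim = latent_dim, n_batches = n_batches,
    slope = 0.01
  ), class = "mb_model")
}

.lrelu <- function(a, slope) ifelse(a > 0, a, slope * a)
.lrelu_grad <- function(a, slope) ifelse(a > 0, 1, slope)

.affine <- function(x, W, b) sweep(x %*% W, 2, b, "+")

# full forward pass keeping intermediates for backprop
.forward <- function(model, x) {
  a1 <- .affine(x, model$W1, model$b1)
  h1 <- .lrelu(a1, model$slope)
  z <- .affine(h1, model$W2, model$b2)
  a3 <- .affine(z, model$W3, model$b3)
  h2 <- .lrelu(a3, model$slope)
  xhat <- .affine(h2, model$W4, model$b4)
  logits <- .affine(z, model$W5, model$b5)
  p <- .softmax(logits)
  list(a1 = a1, h1 = h1, z = z, a3 = a3, h2 = h2, xhat = xhat,
       logits = logits, p = p)
}

.softmax <- function(logits) {
  e <- exp(logits - apply(logits, 1, max))
  e / rowSums(e)
}

#' Encode samples to latent codes
#' @param model an `"mb_model"`.
#' @param x preprocessed matrix.
#' @return Matrix of latent codes (samples x latent_dim).
#' @export
encode <- function(model, x) {
  h1 <- .lrelu(.affine(x, model$W1, model$b1), model$slope)
  .affine(h1, model$W2, model$b2)
}

#' Decode latent codes to the preprocessed feature space
#' @param model an `"mb_model"`.
#' @param z latent matrix.
#' @return Reconstruction matrix (samples x n_features).
#' @export
decode <- function(model, z) {
  h2 <- .lrelu(.affine(z, model$W3, model$b3), model$slope)
  .affine(h2, model$W4, model$b4)
}

#' Batch-probability predictions from latent codes
#' @param model an `"mb_model"`.
#' @param z latent matrix.
#' @return Row-stochastic matrix of batch probabilities.
#' @export
classify <- function(model, z) {
  .softmax(.affine(z, model$W5, model$b5))
}
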