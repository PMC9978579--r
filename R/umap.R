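# Compact UMAP implementation (exact k-NN, fuzzy simplicial set, SGD
# layout in C++).  Only what the grouping reward needs: deterministic
# 2-D embeddings of at most a few thousand points.  The fuzzy-set
# construction and sampling schedule follow the reference algorithm;
# initialization is PCA (deterministic) rather than spectral.

.find_ab_params <- function(spread = 1, min_dist = 0.1) {
  xv <- seq(0, spread * 3, length.out = 300)
  yv <- ifelse(xv < min_dist, 1, exp(-(xv - min_dist) / spread))
  fit <- function(par) {
    a <- par[1]; b <- par[2]
    sum((1 / (1 + a * xv^(2 * b)) - yv)^2)
  }
  res <- optim(c(1, 1), fit, method = "L-BFGS-B",
               lower = c(1e-3, 1e-3), upper = c(100, 100))
  res$par
}

.smooth_knn <- function(knn_dist, target) {
  # per-point bandwidth sigma and connectivity offset rho
  n <- nrow(knn_dist)
  rho <- numeric(n); sigma <- numeric(n)
  for (i in seq_len(n)) {
    d <- knn_dist[i, ]
    nonzero <- d[d > 0]
    rho[i] <- if (length(nonzero)) min(nonzero) else 0
    lo <- 0; hi <- Inf; mid <- 1
    for (iter in 1:64) {
      val <- sum(exp(-pmax(d - rho[i], 0) / mid))
      if (abs(val - target) < 1e-5) break
      if (val > target) { hi <- mid; mid <- (lo + hi) / 2 }
      else { lo <- mid; mid <- if (is.finite(hi)) (lo + hi) / 2 else mid * 2 }
    }
    sigma[i] <- max(mid, 1e-3 * mean(d))
  }
  list(rho = rho, sigma = sigma)
}

#' Embed samples in two dimensions with UMAP
#'
#' Deterministic given `seed`: exact nearest neighbours, PCA
#' initialization, and a seeded stochastic-gradient layout.
#'
#' @param x numeric matrix (samples x dims).
#' @param n_neighbors neighbourhood size (capped at `nrow(x) - 1`).
#' @param min_dist minimum embedding distance parameter.
#' @param n_epochs layout optimization epochs.
#' @param n_components embedding dimensionality.
#' @param seed integer seed for the layout RNG.
#' @return Matrix `nrow(x) x n_components`.
#' @export
umap_embed <- function(x, n_neighbors = 15, min_dist = 0.1, n_epochs = 200,
                       n_components = 2, seed = 42) {
  stopifnot(is.matrix(x), nrow(x) >= 3)
  n <- nrow(x)
  k <- min(n_neighbors, n - 1)
  d <- as.matrix(dist(x))

  knn_idx <- t(apply(d, 1, function(r) order(r)[2:(k + 1)]))
  knn_dist <- t(vapply(seq_len(n), function(i) d[i, knn_idx[i, ]],
                       numeric(k)))
  sk <- .smooth_knn(knn_dist, target = log2(k))

  # directed membership strengths, then fuzzy union P + P' - P.P'
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w <- exp(-pmax(knn_dist[i, ] - sk$rho[i], 0) / sk$sigma[i])
    P[i, knn_idx[i, ]] <- w
  }
  G <- P + t(P) - P * t(P)

  ab <- .find_ab_params(1, min_dist)

  keep <- which(G > max(G) / (n_epochs * 4), arr.ind = TRUE)
  keep <- keep[keep[, 1] < keep[, 2], , drop = FALSE]   # undirected once
  w <- G[keep]
  eps <- max(w) / w

  init <- prcomp(x, center = TRUE, scale. = FALSE)$x[, seq_len(n_components),
                                                     drop = FALSE]
  if (ncol(init) < n_components) {
    init <- cbind(init, matrix(0, n, n_components - ncol(init)))
  }
  span <- max(abs(init))
  if (span > 0) init <- init / span * 10

  emb <- umap_layout_cpp(init, as.integer(keep[, 1] - 1L),
                         as.integer(keep[, 2] - 1L), eps,
                         as.integer(n_epochs), 1.0, ab[1], ab[2], 5,
                         as.numeric(seed))
  rownames(emb) <- rownames(x)
  emb
}
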