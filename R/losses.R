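# The three loss terms and their aggregation
#   L = lambda_g * (reconstruction + r_g) - lambda_d * L_d + lambda_v * L_v
# The classifier term enters the autoencoder objective with a negative
# sign (adversarial); the classifier itself is trained to minimize L_d.

#' Loss weights
#' @param lambda_g,lambda_d,lambda_v non-negative finite reals weighting
#'   the regularized reconstruction, adversarial classifier, and
#'   variation terms.
#' @return List of class `"mb_weights"`.
#' @export
loss_weights <- function(lambda_g = 1, lambda_d = 1, lambda_v = 1) {
  w <- list(lambda_g = lambda_g, lambda_d = lambda_d, lambda_v = lambda_v)
  stopifnot(all(vapply(w, function(v) is.finite(v) && v >= 0, logical(1))))
  structure(w, class = "mb_weights")
}

#' Reconstruction loss
#'
#' Mean squared (default) or mean absolute error over all cells, on the
#' preprocessed scale.
#'
#' @param x,x_hat matrices of identical shape.
#' @param type `"mse"` or `"mae"`.
#' @return Non-negative scalar; zero iff `x == x_hat`.
#' @export
reconstruction_loss <- function(x, x_hat, type = c("mse", "mae")) {
  type <- match.arg(type)
  if (!identical(dim(x), dim(x_hat))) stop("shape mismatch")
  if (type == "mse") mean((x - x_hat)^2) else mean(abs(x - x_hat))
}

# fraction of same-group pairs NOT sharing a cluster; noise points count
# as their own singleton clusters
.pair_separation <- function(cluster_labels, groups) {
  labs <- as.integer(cluster_labels)
  noise <- labs == 0L
  labs[noise] <- -seq_len(sum(noise))     # singletons
  total <- 0L; together <- 0L
  for (g in unique(groups[groups != ""])) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    pairs <- utils::combn(idx, 2)
    total <- total + ncol(pairs)
    together <- together + sum(labs[pairs[1, ]] == labs[pairs[2, ]])
  }
  if (total == 0L) return(NA_real_)
  1 - together / total
}

#' Grouping reward term r_g
#'
#' Flattens the embedding input to two dimensions with UMAP, clusters it
#' with density-based clustering, and scores how frequently reference
#' samples of the same group land in the same cluster:
#' `r_g = 1 - (co-clustered same-group pairs) / (all same-group pairs)`.
#' Zero at perfect co-clustering, one when no same-group pair shares a
#' cluster.  Noise points count as singleton clusters.
#'
#' @param latent numeric matrix of latent codes (samples x dims), rows
#'   aligned with `b`.
#' @param b batch info `data.frame` with a `group` column (`""` =
#'   non-reference).
#' @param min_cluster_size smallest cluster size for the clustering step;
#'   defaults to the size of the smallest reference group.
#' @param seed seed for the UMAP layout.
#' @return `r_g` in `[0, 1]`.  If no same-group pair is evaluable the
#'   term is 0 with a warning (training degrades gracefully to a purely
#'   adversarial autoencoder).
#' @export
grouping_term <- function(latent, b, min_cluster_size = NULL, seed = 42) {
  stopifnot(is.matrix(latent), nrow(latent) == nrow(b))
  groups <- b$group
  sizes <- table(groups[groups != ""])
  if (length(sizes) == 0 || max(sizes) < 2) {
    warning("no evaluable reference pairs; r_g set to 0")
    return(0)
  }
  if (is.null(min_cluster_size)) min_cluster_size <- max(2, min(sizes))
  emb <- if (ncol(latent) > 2 && nrow(latent) >= 5) {
    umap_embed(latent, seed = seed)
  } else latent
  labs <- hdbscan_cluster(emb, min_cluster_size = min_cluster_size)
  r <- .pair_separation(labs, groups)
  if (is.na(r)) {
    warning("no evaluable reference pairs; r_g set to 0")
    return(0)
  }
  r
}

#' Distance-based grouping term
#'
#' Scale-free alternative to the clustering reward: mean pairwise
#' Euclidean distance between same-group reference samples in latent
#' space, divided by the mean pairwise distance over all samples.  Zero
#' when replicates coincide; about one when replicates are scattered like
#' arbitrary samples.
#'
#' @inheritParams grouping_term
#' @return Non-negative scalar.
#' @export
grouping_term_distance <- function(latent, b) {
  stopifnot(is.matrix(latent), nrow(latent) == nrow(b))
  d <- as.matrix(dist(latent))
  groups <- b$group
  same <- numeric(0)
  for (g in unique(groups[groups != ""])) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    pairs <- utils::combn(idx, 2)
    same <- c(same, d[cbind(pairs[1, ], pairs[2, ])])
  }
  if (!length(same)) stop("no evaluable reference pairs")
  denom <- mean(d[upper.tri(d)])
  if (denom == 0) return(0)
  mean(same) / denom
}

#' Batch-classifier cross-entropy
#'
#' @param probs row-stochastic matrix of predicted batch probabilities,
#'   columns named by batch.
#' @param batch_labels character/factor vector of true batches.
#' @return Multiclass cross-entropy (natural log).
#' @export
classifier_loss <- function(probs, batch_labels) {
  stopifnot(is.matrix(probs), nrow(probs) == length(batch_labels))
  if (length(unique(batch_labels)) < 2) stop("need >= 2 batches")
  j <- match(as.character(batch_labels), colnames(probs))
  if (anyNA(j)) stop("batch label absent from prediction columns")
  p <- probs[cbind(seq_len(nrow(probs)), j)]
  -mean(log(pmax(p, 1e-12)))
}

# VC = sd/mean per (reference group, batch, feature) over replicate
# samples; shared by variation_loss() and batch_vc()
.vc_table <- function(m, b) {
  stopifnot(is.matrix(m), nrow(m) == nrow(b) || !is.null(rownames(m)))
  if (!is.null(rownames(m)) && !identical(rownames(m), b$sample)) {
    b <- b[match(rownames(m), b$sample), , drop = FALSE]
  }
  out <- list(); k <- 0
  for (g in unique(b$group[b$group != ""])) {
    for (bt in unique(b$batch[b$group == g])) {
      idx <- which(b$group == g & b$batch == bt)
      if (length(idx) < 2) next
      sub <- m[idx, , drop = FALSE]
      mu <- colMeans(sub)
      s <- sqrt(colSums(sweep(sub, 2, mu, "-")^2) / (length(idx) - 1))
      k <- k + 1
      out[[k]] <- data.frame(group = g, batch = bt,
                             feature = colnames(m) %||% seq_len(ncol(m)),
                             vc = s / mu, row.names = NULL)
    }
  }
  if (k == 0) return(NULL)
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Variation loss
#'
#' Mean coefficient of variation (sd/mean) of reconstructed intensities
#' over all (reference group, batch, feature) cells with at least two
#' replicate samples.  Zero iff replicate reconstructions are identical
#' within every batch.  Counters the VC inflation that batch normalizers
#' tend to introduce.
#'
#' @param x_hat_intensity reconstructed matrix on intensity scale
#'   (strictly positive), rows aligned with `b` (or matched by rownames).
#' @param b batch info `data.frame`.
#' @return Non-negative scalar.
#' @export
variation_loss <- function(x_hat_intensity, b) {
  tab <- .vc_table(x_hat_intensity, b)
  if (is.null(tab)) stop("no (group, batch) with >= 2 replicate samples")
  mean(tab$vc)
}

#' Aggregate the three-term autoencoder loss
#'
#' `L = lambda_g * (reconstruction + r_g) - lambda_d * L_d +
#' lambda_v * L_v`.  The classifier loss is subtracted: the autoencoder
#' is rewarded when the batch classifier fails.
#'
#' @param reconstruction,r_g,l_d,l_v the four scalar parts, computed on
#'   the same forward pass.
#' @param weights a [loss_weights()] object.
#' @return Scalar aggregate loss.
#' @export
aggregate_loss <- function(reconstruction, r_g, l_d, l_v, weights) {
  weights$lambda_g * (reconstruction + r_g) -
    weights$lambda_d * l_d +
    weights$lambda_v * l_v
}

# value and analytic gradient of the variation loss with respect to the
# *preprocessed* reconstruction (chain rule through the inverse
# transform y = 10^(xhat * sigma + mu)); used by the training loop
.variation_loss_grad <- function(xhat, pp, rep_sets) {
  y <- inverse_preprocess(xhat, pp)
  grad <- matrix(0, nrow(xhat), ncol(xhat))
  total <- 0; count <- 0L
  for (idx in rep_sets) {
    m <- length(idx)
    ys <- y[idx, , drop = FALSE]
    mu <- colMeans(ys)
    dev <- sweep(ys, 2, mu, "-")
    s <- sqrt(colSums(dev^2) / (m - 1))
    vc <- s / mu
    total <- total + sum(vc)
    count <- count + length(vc)
    # dVC/dy_i = (y_i - mu)/((m-1) s mu) - s/(m mu^2); 0 where s ~ 0
    ok <- s > 1e-12
    t1 <- sweep(dev, 2, ifelse(ok, (m - 1) * s * mu, 1), "/")
    t1[, !ok] <- 0
    t2 <- ifelse(ok, s / (m * mu^2), 0)
    g <- sweep(t1, 2, t2, "-")
    grad[idx, ] <- grad[idx, ] + g
  }
  if (count == 0L) return(list(value = 0, grad = grad))
  grad <- grad / count
  # chain through y = 10^(xhat*sigma + mu): dy/dxhat = y ln(10) sigma
  grad <- grad * y * log(10)
  grad <- sweep(grad, 2, pp$sigma, "*")
  list(value = total / count, grad = grad)
}
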