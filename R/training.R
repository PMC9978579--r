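# Adversarial training loop, early stopping, randomized grid search and
# rank-based model selection.
#
# Update schedule per minibatch: one classifier step minimizing the
# cross-entropy L_d on the current latent codes, then one autoencoder
# step minimizing  lambda_g * recon - lambda_d * L_d + lambda_v * L_v.
# The clustering reward r_g is piecewise constant in the parameters
# (UMAP + density clustering), so it carries no gradient; it is
# evaluated once per epoch on the full data, enters the reported
# aggregate loss, and steers model selection.

#' Hyperparameters for one training run
#'
#' @param lambda_g,lambda_d,lambda_v loss weights, see [loss_weights()].
#' @param lr_ae,lr_cls Adam learning rates for autoencoder and
#'   classifier.
#' @param epochs training epochs (>= 1).
#' @param batch_size minibatch size.
#' @param seed integer seed controlling initialization and shuffling.
#' @param variance_ratio PCA explained-variance target sizing the
#'   bottleneck; ignored when `latent_dim` is given.
#' @param latent_dim explicit bottleneck width override (`NA` = use the
#'   PCA rule).
#' @param patience consecutive epochs of rising classifier loss that
#'   trigger early stopping.
#' @param window burn-in: epochs of history required before the
#'   classifier-loss rule may fire (adversarial training routinely
#'   drives the classifier loss up during the first epochs and then
#'   recovers; stopping inside that transient would abort healthy runs).
#' @param collapse_ratio output/input variance ratio below which the
#'   solution counts as collapsed.
#' @param reconstruction `"mse"` or `"mae"`.
#' @param rg_every evaluate the clustering reward every this many epochs.
#' @return List of class `"mb_hyperparams"`.
#' @export
hyperparams <- function(lambda_g = 1, lambda_d = 1, lambda_v = 1,
                        lr_ae = 2e-3, lr_cls = 2e-3,
                        epochs = 100, batch_size = 32, seed = 1,
                        variance_ratio = 0.9, latent_dim = NA,
                        patience = 5, window = 20, collapse_ratio = 1e-3,
                        reconstruction = "mse", rg_every = 1) {
  hp <- as.list(environment())
  stopifnot(hp$epochs >= 1, hp$lr_ae > 0, hp$lr_cls > 0, hp$batch_size >= 2,
            hp$lambda_g >= 0, hp$lambda_d >= 0, hp$lambda_v >= 0)
  structure(hp, class = "mb_hyperparams")
}

.adam_new <- function() list(m = NULL, v = NULL, t = 0)

.adam_step <- function(state, params, grads, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state$m)) {
    state$m <- lapply(grads, function(g) g * 0)
    state$v <- lapply(grads, function(g) g * 0)
  }
  state$t <- state$t + 1
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

# replicate index sets (>= 2 members) per (group, batch) within `rows`
.replicate_sets <- function(b, rows = seq_len(nrow(b))) {
  bs <- b[rows, , drop = FALSE]
  key <- paste(bs$group, bs$batch, sep = "\r")
  key[bs$group == ""] <- NA
  sets <- split(rows, key)
  sets[lengths(sets) >= 2]
}

#' Train the adversarial normalizer
#'
#' @param m intensity matrix, strictly positive (run
#'   [apply_min_intensity()] first), samples in rows.
#' @param b batch info `data.frame` covering every row of `m`.
#' @param hp a [hyperparams()] object.
#' @return Object of class `"mb_result"`: `normalized` (intensity-scale
#'   matrix, same shape and dimnames as `m`, strictly positive),
#'   `history` (per-epoch loss breakdown), `stop_reason` (`"completed"`,
#'   `"early_stop_classifier"`, `"early_stop_collapse"` or
#'   `"diverged"`), `hyperparams`, `latent_dim`, `model`.
#' @export
train_normalizer <- function(m, b, hp = hyperparams()) {
  stopifnot(is.matrix(m), inherits(hp, "mb_hyperparams"))
  b <- b[match(rownames(m), b$sample), , drop = FALSE]
  if (anyNA(b$sample)) stop("batch info missing for some samples")
  batches <- factor(b$batch)
  if (nlevels(batches) < 2) stop("need >= 2 batches")

  set.seed(hp$seed)
  pp <- preprocess_intensities(m)
  x <- pp$x
  n <- nrow(x); f <- ncol(x); nb <- nlevels(batches)

  latent <- if (is.na(hp$latent_dim)) {
    select_latent_dim(x, hp$variance_ratio)
  } else as.integer(hp$latent_dim)
  model <- build_models(f, latent, nb, seed = hp$seed)

  y_onehot <- matrix(0, n, nb, dimnames = list(NULL, levels(batches)))
  y_onehot[cbind(seq_len(n), as.integer(batches))] <- 1

  ae_names <- c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")
  cls_names <- c("W5", "b5")
  ad_ae <- .adam_new(); ad_cls <- .adam_new()
  in_var <- var(as.vector(x))
  history <- vector("list", hp$epochs)
  stop_reason <- "completed"
  last_rg <- NA_real_

  for (epoch in seq_len(hp$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = hp$batch_size)
    for (s in starts) {
      rows <- ord[s:min(s + hp$batch_size - 1, n)]
      if (length(rows) < 2) next
      xb <- x[rows, , drop = FALSE]
      yb <- y_onehot[rows, , drop = FALSE]

      # --- classifier step: minimize L_d at fixed encoder -----------
      z <- encode(model, xb)
      pc <- .softmax(.affine(z, model$W5, model$b5))
      gl <- (pc - yb) / nrow(xb)
      cls_grads <- list(W5 = crossprod(z, gl), b5 = colSums(gl))
      up <- .adam_step(ad_cls, model[cls_names], cls_grads, hp$lr_cls)
      ad_cls <- up$state; model[cls_names] <- up$params

      # --- autoencoder step: minimize lg*recon - ld*L_d + lv*L_v ----
      fw <- .forward(model, xb)
      nf <- length(xb)
      g_xhat <- if (hp$reconstruction == "mse") {
        hp$lambda_g * 2 * (fw$xhat - xb) / nf
      } else {
        hp$lambda_g * sign(fw$xhat - xb) / nf
      }
      if (hp$lambda_v > 0) {
        sets <- .replicate_sets(b, rows)
        sets <- lapply(sets, function(ix) match(ix, rows))
        if (length(sets)) {
          lv <- .variation_loss_grad(fw$xhat, pp, sets)
          g_xhat <- g_xhat + hp$lambda_v * lv$grad
        }
      }
      g_h2 <- g_xhat %*% t(model$W4)
      g_a3 <- g_h2 * .lrelu_grad(fw$a3, model$slope)
      g_z <- g_a3 %*% t(model$W3)
      if (hp$lambda_d > 0) {
        gl2 <- (fw$p - yb) / nrow(xb)
        g_z <- g_z - hp$lambda_d * gl2 %*% t(model$W5)
      }
      g_h1 <- g_z %*% t(model$W2)
      g_a1 <- g_h1 * .lrelu_grad(fw$a1, model$slope)
      ae_grads <- list(
        W1 = crossprod(xb, g_a1), b1 = colSums(g_a1),
        W2 = crossprod(fw$h1, g_z), b2 = colSums(g_z),
        W3 = crossprod(fw$z, g_a3), b3 = colSums(g_a3),
        W4 = crossprod(fw$h2, g_xhat), b4 = colSums(g_xhat))
      up <- .adam_step(ad_ae, model[ae_names], ae_grads, hp$lr_ae)
      ad_ae <- up$state; model[ae_names] <- up$params
    }

    # --- epoch bookkeeping on the full data -------------------------
    fw <- .forward(model, x)
    colnames(fw$p) <- levels(batches)
    recon <- reconstruction_loss(x, fw$xhat, hp$reconstruction)
    l_d <- classifier_loss(fw$p, as.character(b$batch))
    sets_full <- .replicate_sets(b)
    l_v <- if (length(sets_full)) {
      variation_loss(inverse_preprocess(fw$xhat, pp), b)
    } else 0
    if (epoch %% hp$rg_every == 0 || is.na(last_rg)) {
      last_rg <- suppressWarnings(
        grouping_term(fw$z, b, seed = hp$seed + epoch))
    }
    acc <- mean(max.col(fw$p) == as.integer(batches))
    var_ratio <- var(as.vector(fw$xhat)) / in_var
    loss <- aggregate_loss(recon, last_rg, l_d, l_v,
                           loss_weights(hp$lambda_g, hp$lambda_d, hp$lambda_v))
    history[[epoch]] <- data.frame(
      epoch = epoch, recon = recon, r_g = last_rg, l_d = l_d, l_v = l_v,
      loss = loss, cls_accuracy = acc, var_ratio = var_ratio)

    hist_df <- do.call(rbind, history[seq_len(epoch)])
    if (!all(is.finite(unlist(hist_df[epoch, ])))) {
      stop_reason <- "diverged"
      break
    }
    es <- early_stop_check(hist_df, window = hp$window,
                           patience = hp$patience,
                           collapse_ratio = hp$collapse_ratio)
    if (es$stop) {
      stop_reason <- es$reason
      break
    }
  }

  history <- do.call(rbind, history[!vapply(history, is.null, logical(1))])
  xhat <- decode(model, encode(model, x))
  normalized <- inverse_preprocess(xhat, pp)
  dimnames(normalized) <- dimnames(m)
  structure(list(normalized = normalized, history = history,
                 stop_reason = stop_reason, hyperparams = hp,
                 latent_dim = latent, model = model, preprocessing = pp),
            class = "mb_result")
}

#' @exportS3Method base::print
print.mb_result <- function(x, ...) {
  cat("Adversarial normalization result\n")
  cat("  samples x features:", nrow(x$normalized), "x", ncol(x$normalized), "\n")
  cat("  latent dim:", x$latent_dim,
      " epochs run:", nrow(x$history),
      " stop:", x$stop_reason, "\n")
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final losses: recon %.4g  r_g %.3f  L_d %.4g  L_v %.4g\n",
              last$recon, last$r_g, last$l_d, last$l_v))
  invisible(x)
}

#' Early-stopping decision
#'
#' Signals a stop when (a) the classifier loss has increased strictly
#' monotonically over `patience` consecutive epochs (the classifier is
#' losing irrecoverably, the precursor of collapsed solutions), or (b)
#' the variance of the reconstructed output has fallen below
#' `collapse_ratio` times the input variance (the decoder output is
#' near-constant).  The classifier rule is suppressed during the first
#' `window` epochs: the early adversarial transient routinely drives the
#' classifier loss up before reconstruction takes over.
#'
#' @param history per-epoch data.frame with columns `l_d` and
#'   `var_ratio` (see [train_normalizer()]).
#' @param window epochs of history required before rule (a) may fire.
#' @param patience number of consecutive increases required.
#' @param collapse_ratio variance-ratio floor.
#' @return List with `stop` (logical) and `reason` (`"continue"`,
#'   `"early_stop_classifier"`, `"early_stop_collapse"`).
#' @export
early_stop_check <- function(history, window = 20, patience = 5,
                             collapse_ratio = 1e-3) {
  n <- nrow(history)
  if (n >= 1 && history$var_ratio[n] < collapse_ratio) {
    return(list(stop = TRUE, reason = "early_stop_collapse"))
  }
  if (n >= max(window, patience + 1)) {
    d <- diff(history$l_d[(n - patience):n])
    if (all(d > 0)) {
      return(list(stop = TRUE, reason = "early_stop_classifier"))
    }
  }
  list(stop = FALSE, reason = "continue")
}

#' Randomized hyperparameter grid search
#'
#' Samples `config$grid_size` hyperparameter sets (loss weights and
#' learning rates log-uniform over their configured ranges), trains a
#' model for each, and evaluates every non-failed run.  Fully
#' deterministic given `config$seed`.
#'
#' @param m strictly positive intensity matrix.
#' @param b batch info `data.frame`.
#' @param config configuration list, see [default_config()].
#' @param cores number of CPU processes for whole runs
#'   (`parallel::mclapply`); per-run determinism is unaffected.
#' @return List of class `"mb_grid"`: per-run results (each with an
#'   `$evaluation` report or an `$error` message).
#' @export
grid_search <- function(m, b, config = default_config(), cores = 1) {
  stopifnot(config$grid_size >= 1)
  set.seed(config$seed)
  gs <- config$grid_size
  logu <- function(rg, k) exp(runif(k, log(rg[1]), log(rg[2])))
  hps <- data.frame(
    lambda_g = logu(config$lambda_g_range, gs),
    lambda_d = logu(config$lambda_d_range, gs),
    lambda_v = logu(config$lambda_v_range, gs),
    lr_ae = logu(config$lr_range, gs),
    lr_cls = logu(config$lr_range, gs),
    seed = sample.int(.Machine$integer.max - 1, gs))
  run_one <- function(i) {
    hp <- hyperparams(
      lambda_g = hps$lambda_g[i], lambda_d = hps$lambda_d[i],
      lambda_v = hps$lambda_v[i], lr_ae = hps$lr_ae[i],
      lr_cls = hps$lr_cls[i], epochs = config$epochs,
      batch_size = config$batch_size, seed = hps$seed[i],
      variance_ratio = config$variance_ratio,
      latent_dim = config$latent_dim,
      patience = config$patience, window = config$window,
      collapse_ratio = config$collapse_ratio,
      reconstruction = config$reconstruction)
    res <- tryCatch(train_normalizer(m, b, hp), error = function(e) {
      structure(list(stop_reason = "error", error = conditionMessage(e),
                     hyperparams = hp), class = "mb_result")
    })
    if (is.null(res$error)) {
      res$evaluation <- tryCatch(
        evaluate_normalization(m, res$normalized, b, seed = hps$seed[i]),
        error = function(e) NULL)
    }
    res
  }
  results <- if (cores > 1) {
    parallel::mclapply(seq_len(gs), run_one, mc.cores = cores)
  } else {
    lapply(seq_len(gs), run_one)
  }
  structure(list(results = results, grid = hps, config = config),
            class = "mb_grid")
}

#' Select the best run from a grid search
#'
#' Ranks candidates by the sum of ranks over four evaluation criteria:
#' higher mean between-batch replicate correlation, lower mean batch VC,
#' lower VC-inflation fraction, and probe batch-classifier accuracy
#' closest to chance.  Ties are broken by the between-batch correlation.
#' Runs that failed, diverged or whose evaluation contains non-finite
#' criteria are excluded.
#'
#' @param grid an `"mb_grid"` from [grid_search()] (or a plain list of
#'   `"mb_result"` objects carrying `$evaluation`).
#' @return The winning `"mb_result"`, with the full ranking table
#'   attached as `$ranking`.
#' @export
select_best <- function(grid) {
  results <- if (inherits(grid, "mb_grid")) grid$results else grid
  crit <- lapply(results, function(r) {
    if (!is.null(r$error) || is.null(r$evaluation)) return(NULL)
    ev <- r$evaluation
    c(between = ev$between_batch_corr[["mean"]],
      vc = ev$mean_batch_vc,
      inflation = ev$vc_inflation,
      mix = abs(ev$batch_mixing$accuracy - ev$batch_mixing$chance))
  })
  ok <- which(vapply(crit, function(x) !is.null(x) && all(is.finite(x)),
                     logical(1)))
  if (!length(ok)) stop("all grid-search runs failed")
  tab <- do.call(rbind, crit[ok])
  rank_sum <- rank(-tab[, "between"]) + rank(tab[, "vc"]) +
    rank(tab[, "inflation"]) + rank(tab[, "mix"])
  ord <- order(rank_sum, -tab[, "between"])
  ranking <- data.frame(run = ok[ord], rank_sum = rank_sum[ord],
                        tab[ord, , drop = FALSE],
                        stop_reason = vapply(results[ok[ord]], `[[`, "",
                                             "stop_reason"),
                        row.names = NULL)
  best <- results[[ok[ord][1]]]
  best$ranking <- ranking
  best
}
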