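# Evaluation metrics: replicate cross-correlation, batch VCs, VC
# inflation, a quantitative batch-mixing probe, and spectra
# preservation.  All pure functions of their inputs (plus explicit
# seeds).

#' Replicate cross-correlations within and between batches
#'
#' Pearson correlation of the full feature vectors (log10 scale) for
#' every pair of same-group reference samples, split by whether the two
#' samples sit in the same batch.
#'
#' @param m strictly positive intensity matrix.
#' @param b batch info `data.frame`.
#' @param log_scale correlate log10 intensities (default) or raw.
#' @return List with numeric vectors `within` and `between` and summary
#'   lists (`mean`, `median`, `q25`, `q75`) for each.
#' @export
replicate_correlations <- function(m, b, log_scale = TRUE) {
  b <- .align_info(m, b)
  x <- if (log_scale) log10(m) else m
  within <- numeric(0); between <- numeric(0)
  for (g in unique(b$group[b$group != ""])) {
    idx <- which(b$group == g)
    if (length(idx) < 2) next
    pairs <- utils::combn(idx, 2)
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      r <- suppressWarnings(cor(x[i, ], x[j, ]))
      if (b$batch[i] == b$batch[j]) within <- c(within, r)
      else between <- c(between, r)
    }
  }
  if (!length(within) && !length(between)) stop("no evaluable replicate pairs")
  summ <- function(v) {
    if (!length(v)) return(list(mean = NA_real_, median = NA_real_,
                                q25 = NA_real_, q75 = NA_real_))
    list(mean = mean(v), median = median(v),
         q25 = unname(quantile(v, 0.25)), q75 = unname(quantile(v, 0.75)))
  }
  list(within = within, between = between,
       within_summary = summ(within), between_summary = summ(between))
}

.align_info <- function(m, b) {
  b2 <- b[match(rownames(m), b$sample), , drop = FALSE]
  if (anyNA(b2$sample)) stop("batch info missing for some samples")
  b2
}

#' Batch variation coefficients
#'
#' VC = sd/mean of intensities per (reference group, batch, feature)
#' across that batch's replicate samples; the same quantity the
#' variation loss minimizes, evaluated on intensity scale.
#'
#' @param m strictly positive intensity matrix.
#' @param b batch info `data.frame`.
#' @return List with `table` (`data.frame` group/batch/feature/vc) and
#'   `mean` (grand mean VC).
#' @export
batch_vc <- function(m, b) {
  b <- .align_info(m, b)
  tab <- .vc_table(m, b)
  if (is.null(tab)) stop("no (group, batch) with >= 2 replicate samples")
  list(table = tab, mean = mean(tab$vc))
}

#' Fraction of features whose replicate VC inflates upon normalization
#'
#' A feature counts as inflated when its mean replicate VC after
#' normalization exceeds the VC before by at least `threshold` (default
#' 5%).  Normalizers that trade inter-batch bias for intra-batch noise
#' score high here.
#'
#' @param before,after intensity matrices of identical shape/ids.
#' @param b batch info `data.frame`.
#' @param threshold relative VC increase counted as inflation.
#' @return Fraction in `[0, 1]`; the per-(group, batch, feature) cell
#'   fraction is attached as attribute `"cell_fraction"`.
#' @export
vc_inflation <- function(before, after, b, threshold = 0.05) {
  if (!identical(dim(before), dim(after))) stop("shape mismatch")
  stopifnot(threshold > 0)
  b <- .align_info(before, b)
  tb <- .vc_table(before, b)
  ta <- .vc_table(after, b)
  if (is.null(tb) || is.null(ta)) stop("no evaluable replicate VCs")
  key <- function(t) paste(t$group, t$batch, t$feature, sep = "\r")
  ta <- ta[match(key(tb), key(ta)), ]
  # relative epsilon keeps the >= cutoff well-defined under float noise
  cut <- function(a, bfr) a > bfr & a >= (1 + threshold) * bfr * (1 - 1e-9)
  inflated_cell <- cut(ta$vc, tb$vc)
  pf_before <- tapply(tb$vc, tb$feature, mean)
  pf_after <- tapply(ta$vc, ta$feature, mean)
  pf_after <- pf_after[names(pf_before)]
  inflated <- cut(pf_after, pf_before)
  structure(mean(inflated), cell_fraction = mean(inflated_cell))
}

#' Batch-mixing probe
#'
#' Cross-validated accuracy of a linear multinomial (ridge-penalized)
#' classifier predicting batch from log10 intensities.  Well-mixed
#' batches are unpredictable: accuracy close to the majority-class
#' chance level.
#'
#' @param m strictly positive intensity matrix.
#' @param b batch info `data.frame`.
#' @param seed seed for the fold assignment.
#' @param folds number of cross-validation folds.
#' @return List with `accuracy` and `chance`.
#' @export
batch_mixing <- function(m, b, seed = 1, folds = 5) {
  b <- .align_info(m, b)
  y <- factor(b$batch)
  if (nlevels(y) < 2) stop("need >= 2 batches")
  x <- scale(log10(m))
  x[!is.finite(x)] <- 0
  set.seed(seed)
  fold <- integer(length(y))
  for (idx in split(seq_along(y), y)) {   # stratified by batch
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  pred <- character(length(y))
  for (k in seq_len(folds)) {
    tr <- which(fold != k); te <- which(fold == k)
    if (!length(te) || length(unique(y[tr])) < 2) next
    fit <- suppressWarnings(        # small folds trip glmnet's n-per-class nag
      glmnet::glmnet(x[tr, , drop = FALSE], y[tr],
                     family = "multinomial", alpha = 0,
                     lambda = 0.01, standardize = FALSE))
    pr <- predict(fit, x[te, , drop = FALSE], type = "class")
    pred[te] <- pr[, 1]
  }
  list(accuracy = mean(pred == as.character(y)),
       chance = max(table(y)) / length(y))
}

#' Spectra-preservation summary
#'
#' Normalization should roughly maintain the ranking of features by
#' average intensity, so the normalized table still resembles a mass
#' spectrum.  Reports the Spearman correlation of per-feature mean
#' intensities before vs after, and the largest displacement of
#' z-scored mean intensities.
#'
#' @param before,after intensity matrices sharing the feature set.
#' @return List with `rank_correlation` and `max_z_displacement`.
#' @export
spectra_shift <- function(before, after) {
  if (ncol(before) != ncol(after)) stop("feature sets differ")
  mb <- colMeans(before); ma <- colMeans(after)
  zb <- as.vector(scale(mb)); za <- as.vector(scale(ma))
  list(rank_correlation = suppressWarnings(cor(mb, ma, method = "spearman")),
       max_z_displacement = max(abs(za - zb)))
}

#' Full evaluation report
#'
#' Bundles all evaluation criteria for a before/after pair.
#'
#' @param before input intensity matrix (post minimum-intensity rule).
#' @param after normalized intensity matrix.
#' @param b batch info `data.frame`.
#' @param seed seed for the batch-mixing probe.
#' @return List of class `"mb_eval"` with elements
#'   `within_batch_corr`, `between_batch_corr` (summary lists),
#'   `mean_batch_vc`, `vc_inflation`, `batch_mixing`, `spectra_shift`,
#'   plus the input matrix' own `input_between_corr`, `input_mean_vc`
#'   and `input_mixing` for reference.
#' @export
evaluate_normalization <- function(before, after, b, seed = 1) {
  rc <- replicate_correlations(after, b)
  rc0 <- replicate_correlations(before, b)
  structure(list(
    within_batch_corr = rc$within_summary,
    between_batch_corr = rc$between_summary,
    mean_batch_vc = batch_vc(after, b)$mean,
    vc_inflation = as.numeric(vc_inflation(before, after, b)),
    batch_mixing = batch_mixing(after, b, seed = seed),
    spectra_shift = spectra_shift(before, after),
    input_between_corr = rc0$between_summary,
    input_mean_vc = batch_vc(before, b)$mean,
    input_mixing = batch_mixing(before, b, seed = seed)
  ), class = "mb_eval")
}

#' @exportS3Method base::print
print.mb_eval <- function(x, ...) {
  cat("Normalization evaluation\n")
  cat(sprintf("  between-batch replicate correlation: %.3f (input %.3f)\n",
              x$between_batch_corr$mean, x$input_between_corr$mean))
  cat(sprintf("  mean batch VC: %.3f (input %.3f)\n",
              x$mean_batch_vc, x$input_mean_vc))
  cat(sprintf("  VC-inflation fraction: %.3f\n", x$vc_inflation))
  cat(sprintf("  batch-mixing probe accuracy: %.3f (chance %.3f, input %.3f)\n",
              x$batch_mixing$accuracy, x$batch_mixing$chance,
              x$input_mixing$accuracy))
  cat(sprintf("  spectra rank correlation: %.3f\n",
              x$spectra_shift$rank_correlation))
  invisible(x)
}
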