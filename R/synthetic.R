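# Synthetic multi-batch generator.  Emulates the structure of a
# multi-batch benchmarking panel: reference sample groups aliquoted from
# one master mix and re-measured in (a subset of) every batch, plus
# batch-specific study samples.  The generative model is the standard
# ion-suppression picture: a batch acts multiplicatively and
# feature-wise on true abundances,
#     observed[i, j] = true[i, j] * batch_factor[batch(i), j] * noise[i, j]
# with log-normal true abundances spanning several orders of magnitude,
# log-normal batch factors, multiplicative measurement noise of a given
# CV, and detection-limit censoring below `censor_threshold`.

#' Describe a synthetic multi-batch experiment
#'
#' Defaults describe a mid-sized panel: 5 batches of 40 samples (two
#' reference groups in triplicate plus 34 study samples per batch) and 60
#' features.  Base intensities are log-normal with log10-mean 5 and
#' log10-sd 1 (ion counts spanning roughly 3 to 7 decades); batch factors
#' are log-normal with natural-log sd 0.8; measurement noise has a CV of
#' 0.1; cells below 1000 counts are censored to missing.
#'
#' @param n_batches number of batches (>= 2).
#' @param n_features number of features.
#' @param reference_groups list of reference-group descriptors, each a
#'   list with `name`, `n_replicates` (per batch) and `batches` (integer
#'   indices of the batches the group is measured in).
#' @param n_nonreference number of batch-specific study samples per batch.
#' @param base_log10_mean,base_log10_sd log10-normal parameters of true
#'   abundances.
#' @param batch_log_sd natural-log sd of the per-(batch, feature)
#'   multiplicative batch factor; 0 disables batch effects.
#' @param noise_cv coefficient of variation of multiplicative measurement
#'   noise; 0 disables noise.
#' @param censor_threshold detection limit in counts; observed cells below
#'   it are emitted as missing.  0 disables censoring.
#' @return Object of class `"mb_design"`.
#' @export
simulation_design <- function(n_batches = 5,
                              n_features = 60,
                              reference_groups = NULL,
                              n_nonreference = 34,
                              base_log10_mean = 5,
                              base_log10_sd = 1,
                              batch_log_sd = 0.8,
                              noise_cv = 0.1,
                              censor_threshold = 1000) {
  if (is.null(reference_groups)) {
    reference_groups <- list(
      list(name = "QC_pool", n_replicates = 3, batches = seq_len(n_batches)),
      list(name = "QC_spike", n_replicates = 3, batches = seq_len(n_batches))
    )
  }
  d <- list(n_batches = n_batches, n_features = n_features,
            reference_groups = reference_groups,
            n_nonreference = n_nonreference,
            base_log10_mean = base_log10_mean, base_log10_sd = base_log10_sd,
            batch_log_sd = batch_log_sd, noise_cv = noise_cv,
            censor_threshold = censor_threshold)
  stopifnot(d$n_batches >= 2, d$n_features >= 1,
            d$base_log10_sd >= 0, d$batch_log_sd >= 0, d$noise_cv >= 0,
            d$censor_threshold >= 0)
  for (g in d$reference_groups) {
    stopifnot(is.character(g$name), g$n_replicates >= 1,
              all(g$batches >= 1 & g$batches <= n_batches))
  }
  structure(d, class = "mb_design")
}

#' Simulate a multi-batch intensity table with known ground truth
#'
#' Every member of a reference group shares one true abundance profile
#' drawn once per group; study samples get individual profiles.  Batch
#' effects are per-(batch, feature) multiplicative factors, noise is
#' multiplicative log-normal with unit mean, and cells falling below the
#' censoring threshold are emitted as missing.  Runs are bit-reproducible
#' for a fixed design and seed.
#'
#' @param design an [simulation_design()] object.
#' @param seed integer seed.
#' @return List with `intensities` (matrix, `NA` = censored), `batch_info`
#'   (`data.frame` sample/batch/group) and `truth` (list with
#'   `true_matrix`, `batch_factors`, `noise`; `true_matrix * factors *
#'   noise` reproduces the pre-censoring observations cell-wise).
#' @export
simulate_batches <- function(design, seed = 1) {
  stopifnot(inherits(design, "mb_design"))
  set.seed(seed)
  nb <- design$n_batches
  f <- design$n_features
  feat_ids <- sprintf("mz_%03d", seq_len(f))

  # one true profile per reference group
  group_profiles <- lapply(design$reference_groups, function(g) {
    10^rnorm(f, design$base_log10_mean, design$base_log10_sd)
  })
  names(group_profiles) <- vapply(design$reference_groups, `[[`, "", "name")

  rows <- list(); info <- list(); k <- 0
  for (bi in seq_len(nb)) {
    for (gi in seq_along(design$reference_groups)) {
      g <- design$reference_groups[[gi]]
      if (!(bi %in% g$batches)) next
      for (r in seq_len(g$n_replicates)) {
        k <- k + 1
        rows[[k]] <- group_profiles[[g$name]]
        info[[k]] <- c(sprintf("B%d_%s_r%d", bi, g$name, r),
                       sprintf("B%d", bi), g$name)
      }
    }
    for (s in seq_len(design$n_nonreference)) {
      k <- k + 1
      rows[[k]] <- 10^rnorm(f, design$base_log10_mean, design$base_log10_sd)
      info[[k]] <- c(sprintf("B%d_S%03d", bi, s), sprintf("B%d", bi), "")
    }
  }
  true_matrix <- do.call(rbind, rows)
  binfo <- as.data.frame(do.call(rbind, info), stringsAsFactors = FALSE)
  names(binfo) <- c("sample", "batch", "group")
  rownames(true_matrix) <- binfo$sample
  colnames(true_matrix) <- feat_ids

  batch_factors <- matrix(exp(rnorm(nb * f, 0, design$batch_log_sd)),
                          nrow = nb, dimnames = list(sprintf("B%d", seq_len(nb)),
                                                     feat_ids))
  # unit-mean log-normal noise at the requested CV
  sl <- sqrt(log1p(design$noise_cv^2))
  noise <- matrix(exp(rnorm(length(true_matrix), -sl^2 / 2, sl)),
                  nrow = nrow(true_matrix), dimnames = dimnames(true_matrix))

  bi_idx <- match(binfo$batch, rownames(batch_factors))
  observed <- true_matrix * batch_factors[bi_idx, , drop = FALSE] * noise
  if (design$censor_threshold > 0) {
    observed[observed < design$censor_threshold] <- NA
  }
  list(intensities = observed, batch_info = binfo,
       truth = list(true_matrix = true_matrix, batch_factors = batch_factors,
                    noise = noise))
}

#' Ablate a dataset for robustness experiments
#'
#' Three modes mirror the robustness experiments run on multi-batch data:
#' `"drop_batches"` removes the `amount` most recent batches (chronology =
#' order of first appearance in `b`); `"drop_features"` keeps a random
#' fraction `amount` of the features; `"inject_missing"` replaces a random
#' fraction `amount` of cells with missing values.
#'
#' @param m intensity matrix.
#' @param b batch info `data.frame`.
#' @param mode one of `"drop_batches"`, `"drop_features"`,
#'   `"inject_missing"`.
#' @param amount mode-dependent: batch count to drop, feature fraction to
#'   keep, or cell fraction to blank.
#' @param seed integer seed for the random modes.
#' @return List with ablated `intensities` and `batch_info`.
#' @export
ablate_dataset <- function(m, b,
                           mode = c("drop_batches", "drop_features",
                                    "inject_missing"),
                           amount, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(m), is.data.frame(b))
  if (mode == "drop_batches") {
    stopifnot(amount >= 0, amount == round(amount))
    chron <- unique(b$batch[match(rownames(m), b$sample)])
    if (length(chron) - amount < 2) stop("ablation would leave < 2 batches")
    keep_batches <- chron[seq_len(length(chron) - amount)]
    keep <- b$batch[match(rownames(m), b$sample)] %in% keep_batches
    m2 <- m[keep, , drop = FALSE]
    b2 <- b[b$sample %in% rownames(m2), , drop = FALSE]
    return(list(intensities = m2, batch_info = b2))
  }
  if (mode == "drop_features") {
    stopifnot(amount > 0, amount <= 1)
    n_keep <- round(amount * ncol(m))
    if (n_keep < 1) stop("ablation would leave 0 features")
    set.seed(seed)
    keep <- sort(sample.int(ncol(m), n_keep))
    return(list(intensities = m[, keep, drop = FALSE], batch_info = b))
  }
  # inject_missing
  stopifnot(amount >= 0, amount <= 1)
  set.seed(seed)
  n_cells <- round(amount * length(m))
  if (n_cells > 0) {
    idx <- sample.int(length(m), n_cells)
    m[idx] <- NA
  }
  list(intensities = m, batch_info = b)
}
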